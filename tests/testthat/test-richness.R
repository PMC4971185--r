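# Octave binning, lognormal fitting, extrapolation, capture statistics.

test_that("octave_histogram applies the tie-split convention", {
  h <- octave_histogram(c(1, 1, 2, 4))
  expect_equal(h$octave, 0:2)
  expect_equal(h$count, c(2.5, 1.0, 0.5))
  expect_equal(attr(h, "n_species"), 4)
  h3 <- octave_histogram(3)
  expect_equal(h3$octave, c(0, 1))
  expect_equal(h3$count, c(0, 1))
  h0 <- octave_histogram(numeric(0))
  expect_equal(nrow(h0), 0)
  expect_equal(attr(h0, "n_species"), 0)
  expect_error(octave_histogram(c(1, 0)), ">= 1")
  # floor-only binning behind the flag
  hf <- octave_histogram(4, tiesplit = FALSE)
  expect_equal(hf$count[hf$octave == 2], 1)
})

test_that("singleton_split moves half of the singletons past the veil", {
  h <- octave_histogram(c(1, 1, 2, 4), singleton_split = TRUE)
  expect_equal(h$octave, -1:2)
  expect_equal(h$count, c(1.0, 1.5, 1.0, 0.5))
  expect_equal(sum(h$count), 4)
})

test_that("octave conservation holds for random abundances", {
  set.seed(3)
  for (i in 1:10) {
    ab <- sample(1:200, sample(5:80, 1), replace = TRUE)
    expect_equal(sum(octave_histogram(ab)$count), length(ab))
    expect_equal(sum(octave_histogram(ab, singleton_split = TRUE)$count),
                 length(ab))
    expect_equal(sum(octave_histogram(ab, tiesplit = FALSE)$count),
                 length(ab))
  }
})

test_that("noise-free Gaussian octaves are refit exactly by both methods", {
  R <- 0:12
  S0 <- 64; R0 <- 5; sigma <- 2
  h <- data.frame(octave = R, count = S0 * exp(-(R - R0)^2 / (2 * sigma^2)))
  for (method in c("poisson_glm", "least_squares")) {
    fit <- fit_lognormal(h, method = method)
    expect_lt(abs(fit$S0 - S0) / S0, 1e-6)
    expect_lt(abs(fit$R0 - R0) / R0, 1e-6)
    expect_lt(abs(fit$sigma - sigma) / sigma, 1e-6)
    expect_equal(fit$S_total, fit$S0 * fit$sigma * sqrt(2 * pi))
    expect_lt(abs(fit$S_total - 64 * 2 * sqrt(2 * pi)), 1e-4)
    expect_lt(abs(fit$S_total - 320.85), 0.01)
    # fixed point: refitting the fitted values reproduces the parameters
    h2 <- data.frame(octave = R, count = fit$fitted)
    fit2 <- fit_lognormal(h2, method = method)
    expect_lt(abs(fit2$S0 - fit$S0) / fit$S0, 1e-6)
    expect_lt(abs(fit2$sigma - fit$sigma) / fit$sigma, 1e-6)
  }
})

test_that("fit_lognormal rejects under-determined and degenerate input", {
  h2 <- data.frame(octave = 0:1, count = c(3, 5))
  expect_error(fit_lognormal(h2), "at least 3")
  mono <- data.frame(octave = 0:5, count = c(1, 2, 4, 9, 32, 130))
  expect_error(fit_lognormal(mono), "degenerate")
})

test_that("the octave fit matches vegan::prestonfit", {
  ab <- sample_species_abundances(300, n_specimens = 6000, seed = 12)
  obs <- ab[ab > 0]
  h <- octave_histogram(obs, singleton_split = TRUE)
  fit <- fit_lognormal(h[h$count > 0, , drop = FALSE])
  vf <- vegan::prestonfit(obs, tiesplit = TRUE)
  expect_equal(fit$sigma, unname(vf$coefficients["width"]), tolerance = 1e-8)
  expect_equal(fit$S0, unname(vf$coefficients["S0"]), tolerance = 1e-8)
  # octave convention differs by a constant shift of 1; S_total is invariant
  expect_equal(fit$R0, unname(vf$coefficients["mode"]) - 1, tolerance = 1e-8)
  expect_equal(fit$S_total,
               unname(vf$coefficients["S0"] * vf$coefficients["width"] *
                        sqrt(2 * pi)),
               tolerance = 1e-8)
})

test_that("estimate_total and bin_sp_ratio follow the printed arithmetic", {
  fake_fit <- structure(list(S_total = 130), class = "lognormal_fit")
  est <- estimate_total(fake_fit, 100)
  expect_equal(est$B_e, 130)
  expect_equal(est$pct_undersampled, 30)
  expect_equal(estimate_total(structure(list(S_total = 100),
                                        class = "lognormal_fit"),
                              100)$pct_undersampled, 0)
  expect_error(estimate_total(fake_fit, 0), "positive")
  expect_equal(bin_sp_ratio(10, 5), 2.00)
  expect_equal(bin_sp_ratio(0, 5), 0.00)
  expect_equal(bin_sp_ratio(7, 7), 1.00)
  expect_error(bin_sp_ratio(3, 0), "positive")
  expect_error(bin_sp_ratio(-1, 5), "non-negative")
})

test_that("capture_stats reproduces the bundled checklist fractions", {
  cs <- capture_stats(capture_checklist())
  expect_equal(nrow(cs$rows), 25)
  car <- cs$rows[cs$rows$family == "Carabidae", ]
  expect_equal(car$capture_fraction, 0.24)
  agg <- cs$aggregates
  expect_equal(agg$mean_capture_pct[agg$order == "Coleoptera"], 23)
  expect_equal(agg$mean_capture_pct[agg$order == "Hemiptera"], 32)
  expect_equal(agg$mean_capture_pct[agg$order == "Lepidoptera"], 54)
  expect_equal(cs$missed_pct, 63)
  expect_equal(cs$overall_capture_pct + cs$missed_pct, 100)
})

test_that("capture_stats applies the eligibility rules", {
  ck <- data.frame(order = rep("Coleoptera", 3),
                   family = c("famA", "famB", "famC"),
                   known_species = c(20, 10, 30),
                   captured_species = c(10, 5, 15),
                   id_fraction = c(0.9, 0.9, 0.5))
  cs <- capture_stats(ck)
  expect_equal(cs$rows$family, "famA")  # famB fails min_K, famC id_fraction
  expect_equal(cs$rows$capture_fraction, 0.50)
  ck0 <- data.frame(order = "x", family = "f", known_species = 0,
                    captured_species = 0)
  expect_error(capture_stats(ck0), "zero")
  expect_error(capture_stats(ck, min_K = 100), "eligible")
})

test_that("family_share and project_global follow the printed arithmetic", {
  expect_equal(family_share(8467, 46937), 18.0)
  expect_equal(family_share(0, 100), 0.0)
  expect_equal(family_share(50, 50), 100.0)
  expect_error(family_share(10, 0), "positive")
  expect_error(family_share(60, 50), "lie in")
  expect_equal(project_global(94000, 0.01), 9.4e6)
  expect_equal(project_global(20000, 0.01), 2.0e6)
  expect_equal(project_global(123, 1), 123)
  expect_error(project_global(100, 0), "fraction")
})

test_that("survey counts are internally consistent", {
  sc <- survey_counts()
  expect_equal(sc[["diptera_tree_representatives"]] +
                 sc[["other_orders_tree_representatives"]],
               sc[["total_bins"]])
  expect_equal(family_share(sc[["cecidomyiidae_bins"]], sc[["total_bins"]]),
               18.0)
})

test_that("sample_species_abundances is deterministic and conserves depth", {
  a1 <- sample_species_abundances(100, n_specimens = 2000, seed = 4)
  a2 <- sample_species_abundances(100, n_specimens = 2000, seed = 4)
  expect_identical(a1, a2)
  expect_equal(sum(a1), 2000)
  expect_length(a1, 100)
})

test_that("extrapolate_richness wires histogram, fit and estimate together", {
  ab <- sample_species_abundances(250, n_specimens = 5000, seed = 6)
  ex <- extrapolate_richness(ab)
  expect_equal(ex$B_o, sum(ab > 0))
  expect_equal(ex$B_e, round(ex$fit$S_total))
  expect_equal(ex$pct_undersampled, 100 * (ex$B_e - ex$B_o) / ex$B_o)
  expect_equal(sum(ex$hist$count), ex$B_o)
})
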