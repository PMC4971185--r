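# Richness diagnostics and truncated-lognormal extrapolation.
#
# Species (or BIN) abundances are binned into Preston octaves — doubling
# abundance classes [2^R, 2^(R+1)) — and a Gaussian in R,
#   S(R) = S0 * exp(-(R - R0)^2 / (2 * sigma^2)),
# is fitted by least squares. Its full integral,
#   S_total = S0 * sigma * sqrt(2 * pi),
# extrapolates past the veil line (octaves truncated by undersampling) to an
# expected total richness B_e; the shortfall (B_e - B_o)/B_o quantifies
# undersampling.

#' Preston octave histogram of species abundances
#'
#' Abundance n falls in octave floor(log2 n). Exact powers of two (n = 2^k,
#' k >= 1) sit on an octave boundary and are split half-and-half between
#' octaves k-1 and k; singletons (n = 1) count fully to octave 0. Half-counts
#' keep the histogram total equal to the number of species.
#'
#' @param abundances Integer vector of per-species counts, all >= 1.
#' @param tiesplit If FALSE, boundary abundances go fully to octave
#'   floor(log2 n) instead of being split.
#' @param singleton_split Singletons (n = 1) also sit on an octave boundary.
#'   By default they count fully to octave 0. With `singleton_split = TRUE`
#'   they are split like other boundary abundances, half to octave 0 and half
#'   to octave -1 (the class just past the veil line) — Preston's original
#'   treatment and the one used by the conventional octave-fitting routines;
#'   the extrapolation path uses this form.
#' @return Data frame with columns `octave` and `count` (possibly
#'   half-integer); attribute `n_species` holds the total.
#' @export
octave_histogram <- function(abundances, tiesplit = TRUE,
                             singleton_split = FALSE) {
  if (length(abundances) == 0L) {
    out <- data.frame(octave = integer(0), count = numeric(0))
    attr(out, "n_species") <- 0
    return(out)
  }
  if (any(abundances < 1)) stop("abundances must be >= 1")
  k <- floor(log2(abundances))
  minoct <- if (singleton_split && any(abundances == 1)) -1L else 0L
  maxoct <- max(k)
  counts <- stats::setNames(numeric(maxoct - minoct + 1L),
                            minoct:maxoct)
  oct <- function(r) as.character(r)
  for (i in seq_along(abundances)) {
    n <- abundances[i]
    boundary <- 2^k[i] == n
    if (tiesplit && boundary && n > 1) {
      counts[oct(k[i] - 1L)] <- counts[oct(k[i] - 1L)] + 0.5
      counts[oct(k[i])] <- counts[oct(k[i])] + 0.5
    } else if (tiesplit && singleton_split && n == 1) {
      counts[oct(-1L)] <- counts[oct(-1L)] + 0.5
      counts[oct(0L)] <- counts[oct(0L)] + 0.5
    } else {
      counts[oct(k[i])] <- counts[oct(k[i])] + 1
    }
  }
  out <- data.frame(octave = minoct:maxoct, count = unname(counts))
  attr(out, "n_species") <- length(abundances)
  out
}

#' Fit a truncated lognormal (Gaussian on octaves) to an octave histogram
#'
#' Fits `S0 * exp(-(R - R0)^2 / (2 sigma^2))` to the octave counts. The
#' default method regresses counts on a quadratic in R with a Poisson
#' log-link (quasi-likelihood, so half-counts are fine) and converts the
#' polynomial coefficients to (S0, R0, sigma); this weighting anchors the fit
#' at the well-observed mode and is stable under veiling, which is why it is
#' the standard approach for octave fits. `"least_squares"` performs
#' unweighted nonlinear least squares on the raw counts instead (initialized
#' from the histogram's weighted moments); it gives the counts of every
#' octave equal standing and is markedly less stable on strongly veiled
#' histograms.
#'
#' @param hist Data frame from [octave_histogram()].
#' @param method `"poisson_glm"` (default) or `"least_squares"`.
#' @param tol Convergence tolerance on parameters (default 1e-8).
#' @return A `lognormal_fit` list: `S0`, `R0`, `sigma`, `S_total`
#'   (= S0 * sigma * sqrt(2 pi)), `residual_ss`, `octaves_used`, `fitted`,
#'   `method`.
#' @export
fit_lognormal <- function(hist, method = c("poisson_glm", "least_squares"),
                          tol = 1e-8) {
  method <- match.arg(method)
  pos <- hist$count > 0
  if (sum(pos) < 3L)
    stop("need at least 3 octaves with positive counts to fit")
  R <- hist$octave
  y <- hist$count
  if (method == "poisson_glm") {
    fit <- suppressWarnings(
      stats::glm(y ~ R + I(R^2), family = stats::quasipoisson(link = "log"),
                 control = stats::glm.control(epsilon = tol^1.5,
                                              maxit = 200)))
    b <- stats::coef(fit)
    if (!all(is.finite(b)) || b[3] >= 0)
      stop("lognormal fit degenerate: no interior mode (octave counts do ",
           "not decay); more sampling depth is needed")
    sigma <- sqrt(-1 / (2 * b[3]))
    R0 <- -b[2] / (2 * b[3])
    S0 <- exp(b[1] - b[2]^2 / (4 * b[3]))
    fitted_y <- unname(stats::fitted(fit))
  } else {
    w_mom <- y[pos] / sum(y[pos])
    R0_0 <- sum(w_mom * R[pos])
    sig_0 <- sqrt(max(sum(w_mom * (R[pos] - R0_0)^2), 0.25))
    S0_0 <- max(y)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ S0 * exp(-(R - R0)^2 / (2 * sigma^2)),
        start = list(S0 = S0_0, R0 = R0_0, sigma = sig_0),
        lower = c(S0 = 1e-9, R0 = -Inf, sigma = 1e-9),
        control = minpack.lm::nls.lm.control(ptol = tol, ftol = tol,
                                             maxiter = 500)),
      error = function(e) stop("lognormal fit failed to converge: ",
                               conditionMessage(e)))
    p <- stats::coef(fit)
    S0 <- unname(p["S0"]); R0 <- unname(p["R0"]); sigma <- unname(p["sigma"])
    fitted_y <- unname(stats::fitted(fit))
  }
  structure(list(S0 = unname(S0), R0 = unname(R0), sigma = unname(sigma),
                 S_total = unname(S0 * sigma * sqrt(2 * pi)),
                 residual_ss = sum((y - fitted_y)^2),
                 octaves_used = sum(pos),
                 fitted = fitted_y,
                 method = method),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("Truncated-lognormal octave fit\n")
  cat(sprintf("  S0 = %.3f  R0 = %.3f  sigma = %.3f\n", x$S0, x$R0, x$sigma))
  cat(sprintf("  S_total = %.2f  (over %d positive octaves, RSS %.4g)\n",
              x$S_total, x$octaves_used, x$residual_ss))
  invisible(x)
}

#' Expected richness and undersampling percentage from a fit
#'
#' @param fit A `lognormal_fit`.
#' @param B_o Observed cluster (BIN) count, > 0.
#' @return List: `B_e` (expected count, rounded to an integer) and
#'   `pct_undersampled` (100 * (B_e - B_o) / B_o).
#' @export
estimate_total <- function(fit, B_o) {
  if (B_o <= 0) stop("observed count must be positive")
  B_e <- round(fit$S_total)
  list(B_e = B_e, pct_undersampled = 100 * (B_e - B_o) / B_o)
}

#' Ratio of observed BIN count to known species count
#'
#' Values above 1 indicate overlooked species; values below 1 indicate
#' undersampling (BIN sharing between insect species is rare).
#'
#' @param B_o Observed BIN count (>= 0).
#' @param K Known species count (> 0).
#' @return The ratio rounded to 2 decimals.
#' @export
bin_sp_ratio <- function(B_o, K) {
  if (K <= 0) stop("known species count must be positive")
  if (B_o < 0) stop("BIN count must be non-negative")
  round(B_o / K, 2)
}

#' Capture-fraction table and per-order aggregates
#'
#' For each eligible family computes the capture fraction C/K (species
#' captured over species known); per-order aggregates are unweighted means of
#' the family fractions reported as integer percentages, and the overall
#' missed fraction is 1 minus the unweighted mean over all eligible rows.
#'
#' @param checklist Data frame with columns `order`, `family`,
#'   `known_species` (K), `captured_species` (C), and optionally
#'   `id_fraction` (fraction of the family's BINs identified to species
#'   level).
#' @param min_K Minimum K for eligibility, inclusive (default 15).
#' @param min_id_fraction Minimum `id_fraction` for eligibility when the
#'   column is present (default 0.85).
#' @return List: `rows` (eligible rows with `capture_fraction` rounded to 2
#'   decimals), `aggregates` (per order: `n_families`,
#'   `mean_capture_pct`), `overall_capture_pct` and `missed_pct` (integer
#'   percentages).
#' @export
capture_stats <- function(checklist, min_K = 15, min_id_fraction = 0.85) {
  if (any(checklist$known_species == 0))
    stop("known species count of zero in checklist")
  elig <- checklist$known_species >= min_K
  if ("id_fraction" %in% names(checklist))
    elig <- elig & checklist$id_fraction >= min_id_fraction
  rows <- checklist[elig, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no eligible families")
  frac <- rows$captured_species / rows$known_species
  rows$capture_fraction <- round(frac, 2)
  agg_mean <- vapply(split(frac, rows$order), mean, numeric(1))
  aggregates <- data.frame(order = names(agg_mean),
                           n_families = as.integer(table(rows$order)[names(agg_mean)]),
                           mean_capture_pct = round(100 * agg_mean),
                           stringsAsFactors = FALSE, row.names = NULL)
  overall <- mean(frac)
  list(rows = rows, aggregates = aggregates,
       overall_capture_pct = round(100 * overall),
       missed_pct = round(100 * (1 - overall)))
}

#' Share of total BINs contributed by one family
#'
#' @param B_family Family BIN count.
#' @param B_total Total BIN count (> 0).
#' @return Percentage rounded to 1 decimal.
#' @export
family_share <- function(B_family, B_total) {
  if (B_total <= 0) stop("total BIN count must be positive")
  if (B_family < 0 || B_family > B_total)
    stop("family BIN count must lie in [0, total]")
  round(100 * B_family / B_total, 1)
}

#' Project a national richness estimate to a global one
#'
#' @param national_estimate Estimated national species count.
#' @param national_fraction Fraction of the global fauna the nation hosts,
#'   in (0, 1].
#' @return Global estimate `national_estimate / national_fraction`.
#' @export
project_global <- function(national_estimate, national_fraction) {
  if (national_fraction <= 0 || national_fraction > 1)
    stop("national_fraction must lie in (0, 1]")
  national_estimate / national_fraction
}

#' Lognormal community abundances under multinomial sampling
#'
#' Abundance-only companion to [generate_community()]: draws per-species
#' expected abundances from a lognormal and samples `n_specimens` specimens
#' multinomially, returning the realized per-species counts (zeros mark
#' species missed by the sampling programme).
#'
#' @param n_species True species count.
#' @param meanlog,sdlog Lognormal parameters on the natural-log scale.
#' @param n_specimens Sampling depth.
#' @param seed Integer seed.
#' @return Integer vector of length `n_species`.
#' @export
sample_species_abundances <- function(n_species, meanlog = 3,
                                      sdlog = 1.4 * log(2),
                                      n_specimens = 10000L, seed = 1L) {
  with_rng(seed, {
    lambda <- stats::rlnorm(n_species, meanlog, sdlog)
    as.integer(stats::rmultinom(1L, n_specimens, lambda / sum(lambda)))
  })
}

#' Octave fit and extrapolation for a vector of observed abundances
#'
#' Convenience wrapper: bins the positive abundances (with singletons split
#' across the veil line, the convention of the standard octave-fitting
#' routines), fits the truncated lognormal, and extrapolates the expected
#' total.
#'
#' @param abundances Per-species counts; zeros (unobserved species) are
#'   dropped before binning.
#' @param ... Passed to [fit_lognormal()].
#' @return List: `hist`, `fit`, `B_o` (observed species count), `B_e`,
#'   `pct_undersampled`.
#' @export
extrapolate_richness <- function(abundances, ...) {
  obs <- abundances[abundances > 0]
  h <- octave_histogram(obs, singleton_split = TRUE)
  fit <- fit_lognormal(h[h$count > 0, , drop = FALSE], ...)
  est <- estimate_total(fit, length(obs))
  list(hist = h, fit = fit, B_o = length(obs), B_e = est$B_e,
       pct_undersampled = est$pct_undersampled)
}

#' Published Canadian capture checklist (25 families, three orders)
#'
#' Known (K) and captured (C) species counts plus BIN counts for 25 insect
#' families in Coleoptera, Hemiptera and Lepidoptera, as printed in the
#' Canadian barcode survey. Shipped as a plain-text input for the
#' capture-fraction computations.
#'
#' @return Data frame: `order`, `family`, `known_species`,
#'   `captured_species`, `n_bins`.
#' @export
capture_checklist <- function() {
  read_tsv_file(system.file("extdata", "canada_capture_table.tsv",
                            package = "barcodecensus", mustWork = TRUE))
}

#' Headline counts of the Canadian barcode survey
#'
#' BIN and representative counts printed in the survey (total BINs, the two
#' validation-tree representative counts, and the Cecidomyiidae BIN count),
#' shipped as inputs for consistency and share computations.
#'
#' @return Named numeric vector.
#' @export
survey_counts <- function() {
  df <- read_tsv_file(system.file("extdata", "canada_survey_counts.tsv",
                                  package = "barcodecensus", mustWork = TRUE))
  stats::setNames(df$value, df$quantity)
}
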