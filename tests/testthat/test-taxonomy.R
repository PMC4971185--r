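# Assignment cascade, NJ validation trees, misplacement/conflict detection.

test_that("bin_consensus_assign walks ranks and flags disagreement", {
  lab <- function(...) {
    df <- as.data.frame(list(...), stringsAsFactors = FALSE)
    df[, c("order", "family", "genus", "species")]
  }
  # unanimous to species
  full <- lab(order = rep("Lepidoptera", 2), family = rep("Nymphalidae", 2),
              genus = rep("Danaus", 2), species = rep("Danaus plexippus", 2))
  r <- bin_consensus_assign(full)
  expect_equal(r$rank, "species")
  expect_equal(r$name, "Danaus plexippus")
  expect_equal(r$method, "bin_consensus")
  expect_false(r$conflict)
  # two species, same genus: genus rank + conflict note
  two <- full
  two$species <- c("Danaus plexippus", "Danaus gilippus")
  r2 <- bin_consensus_assign(two)
  expect_equal(r2$rank, "genus")
  expect_true(r2$conflict)
  expect_match(r2$note, "species")
  # no expert ids: fall through (method NA)
  r3 <- bin_consensus_assign(full[0, ])
  expect_true(is.na(r3$method))
  # missing deeper ranks stop the walk without conflict
  part <- lab(order = "Diptera", family = "", genus = "", species = "")
  r4 <- bin_consensus_assign(part)
  expect_equal(r4$rank, "order")
  expect_false(r4$conflict)
})

ref_fixture <- function() {
  # three references: two congeneric (genA, famX), one in another family
  taxa <- data.frame(cluster_id = c("r1", "r2", "r3"),
                     family = c("famX", "famX", "famY"),
                     genus = c("genA", "genA", "genB"),
                     stringsAsFactors = FALSE)
  tree <- ape::read.tree(text = "((r1:0.01,r2:0.01):0.05,(r3:0.02,q:0.02):0.05);")
  list(taxa = taxa, tree = tree)
}

test_that("id_engine_assign applies the 5%/10% thresholds with monophyly", {
  fx <- ref_fixture()
  d3 <- c(r1 = 0.03, r2 = 0.04, r3 = 0.2)
  g <- id_engine_assign(d3, fx$taxa, fx$tree)
  expect_equal(g$rank, "genus")
  expect_equal(g$name, "genA")
  expect_equal(g$family, "famX")
  expect_equal(g$method, "id_engine")
  f <- id_engine_assign(c(r1 = 0.07, r2 = 0.09, r3 = 0.2), fx$taxa, fx$tree)
  expect_equal(f$rank, "family")
  expect_equal(f$name, "famX")
  p <- id_engine_assign(c(r1 = 0.15, r2 = 0.2, r3 = 0.3), fx$taxa, fx$tree)
  expect_equal(p$method, "morphology_pending")
  expect_match(p$note, "exceeds")
  s <- id_engine_assign(c(r1 = NA, r2 = NA, r3 = NA), fx$taxa, fx$tree)
  expect_equal(s$method, "morphology_pending")
  expect_match(s$note, "saturation")
  # nearest reference not in a monophyletic clade of its genus: r3's
  # smallest clade contains the non-reference tip q, so genus fails
  m <- id_engine_assign(c(r1 = 0.2, r2 = 0.2, r3 = 0.03), fx$taxa, fx$tree)
  expect_equal(m$method, "morphology_pending")
})

test_that("build_nj_tree recovers a 4-leaf additive tree exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0.5);")
  d <- ape::cophenetic.phylo(true)
  nj <- build_nj_tree(d)
  expect_s3_class(nj, "phylo")
  expect_equal(phangorn::RF.dist(ape::unroot(true), nj), 0)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
})

test_that("3-leaf star has the closed-form branch lengths", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3, dimnames = list(ids, ids))
  tr <- build_nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
})

test_that("build_nj_tree validates its input", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(build_nj_tree(d2), "at least 3")
  ids <- c("A", "B", "C")
  dna <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
                dimnames = list(ids, ids))
  expect_error(build_nj_tree(dna), "NA")
})

test_that("NJ is exact on random additive matrices and matches ape::nj", {
  set.seed(2024)
  for (i in 1:20) {
    case <- random_additive_case(sample(4:12, 1))
    nj <- build_nj_tree(case$d)
    expect_equal(phangorn::RF.dist(case$tree, nj), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(case$d), colnames(case$d)],
                 case$d, tolerance = 1e-8)
    expect_equal(phangorn::RF.dist(ape::nj(case$d), nj), 0)
  }
})

test_that("branch lengths are never negative (clamping)", {
  set.seed(11)
  for (i in 1:10) {
    case <- random_additive_case(8)
    d <- case$d
    noise <- matrix(runif(length(d), 0, 0.2 * mean(d)), nrow(d))
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    tr <- build_nj_tree(d + noise)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("detect_misplacements flags unanimous foreign neighbourhoods", {
  # one Coleoptera leaf nested inside a Diptera clade
  tips <- c(sprintf("d%02d", 1:10), "beetle")
  nwk <- "((((d01:.01,d02:.01):.01,(d03:.01,beetle:.001):.01):.02,((d04:.01,d05:.01):.01,(d06:.01,d07:.01):.01):.02):.05,(d08:.01,(d09:.01,d10:.01):.01):.05);"
  tree <- ape::read.tree(text = nwk)
  orders <- stats::setNames(c(rep("Diptera", 10), "Coleoptera"), tips)
  fl <- detect_misplacements(tree, orders, k = 5)
  expect_equal(fl$tip, "beetle")
  expect_equal(fl$own_order, "Coleoptera")
  expect_equal(fl$neighbourhood_order, "Diptera")
  # homogeneous tree: nothing flagged
  hom <- stats::setNames(rep("Diptera", 11), tips)
  expect_equal(nrow(detect_misplacements(tree, hom, k = 5)), 0)
  # mixed neighbourhood: unanimity required, not flagged
  mixed <- orders
  mixed[c("d01", "d04", "d08")] <- "Hymenoptera"
  expect_false("beetle" %in% detect_misplacements(tree, mixed, k = 5)$tip)
  expect_error(detect_misplacements(tree, orders, k = 11), "smaller")
})

test_that("detect_conflicts reports mismatches with causes", {
  out <- detect_conflicts(c("s1", "s2", "s3"),
                          c("Lepidoptera", "Diptera", ""),
                          c("Diptera", "Diptera", "Diptera"))
  expect_equal(out$specimen_id, "s1")
  expect_match(out$note, "parasitoid")
  none <- detect_conflicts("s1", "Diptera", "Diptera")
  expect_equal(nrow(none), 0)
})

test_that("assign_clusters runs the cascade over a small community", {
  p <- community_params(n_species = 20, n_specimens = 300,
                        artifact_rates = c(short = 0, contaminated = 0,
                                           none = 0),
                        expert_id_fraction = 0.4, seed = 21)
  com <- generate_community(p)
  d <- distance_matrix(com$sequences)
  bins <- cluster_bins(d)
  reps <- bins$summary$representative
  dr <- d[reps, reps]
  dimnames(dr) <- list(bins$summary$cluster_id, bins$summary$cluster_id)
  tree <- build_nj_tree(dr)
  asg <- assign_clusters(bins, com$specimens, d, tree)
  expect_equal(nrow(asg), length(bins$clusters))
  # cascade accounting: every cluster gets a method and an order placement
  expect_true(all(asg$method %in% c("bin_consensus", "id_engine",
                                    "morphology_pending")))
  expect_true(all(!is.na(asg$order) & asg$order != ""))
  # consensus assignments are truthful at species rank
  cons <- asg[asg$method == "bin_consensus" & asg$rank == "species", ]
  truth_sp <- truth_membership(com, names(bins$membership))
  for (i in seq_len(nrow(cons))) {
    members <- bins$clusters[[match(cons$cluster_id[i],
                                    bins$summary$cluster_id)]]
    expect_equal(unique(unname(truth_sp[members])), cons$name[i])
  }
})
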