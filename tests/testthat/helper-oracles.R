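# Independent oracles used by the property tests. These deliberately avoid
# the package's own primitives (site bookkeeping, union-find, clustering
# recursion) so that agreement is evidence, not tautology.

# Adjusted Rand index between two labelings of the same ids.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Site-counting K2P oracle: plain per-site loop over two equal-length
# ACGT/'-' strings; returns list(P, Q, n, d).
oracle_k2p <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(x) == length(y))
  bases <- c("A", "C", "G", "T")
  purine <- function(z) z %in% c("A", "G")
  P <- 0L; Q <- 0L; n <- 0L
  for (i in seq_along(x)) {
    if (!(x[i] %in% bases) || !(y[i] %in% bases)) next
    n <- n + 1L
    if (x[i] == y[i]) next
    if (purine(x[i]) == purine(y[i])) P <- P + 1L else Q <- Q + 1L
  }
  p <- P / n; q <- Q / n
  list(P = p, Q = q, n = n,
       d = -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q))
}

# Brute-force transitive closure of d(i,j) < threshold: boolean reachability
# by iterated squaring of the adjacency matrix.
oracle_closure <- function(d, threshold) {
  adj <- (d < threshold) & !is.na(d)
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(nrow(d))
  cur <- 0L
  for (i in seq_len(nrow(d))) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[adj[i, ]] <- cur
    }
  }
  groups <- split(rownames(d), comp)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1L))])
}

# All ways to split ids into two non-empty groups (as a list of g1 index
# subsets); used to enumerate candidate refinement splits.
all_two_partitions <- function(ids) {
  n <- length(ids)
  out <- list()
  for (mask in 1:(2^(n - 1) - 1)) {
    pick <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    out[[length(out) + 1L]] <- list(g1 = ids[pick], g2 = ids[!pick])
  }
  out
}

# TRUE if the (g1, g2) split of a cluster satisfies the refinement rule.
valid_refine_split <- function(g1, g2, d, refine_gap) {
  between_min <- min(d[g1, g2])
  wmax <- function(g) if (length(g) < 2L) 0 else max(d[g, g])
  between_min > refine_gap && wmax(g1) < between_min && wmax(g2) < between_min
}

# Random symmetric distance matrix with ids and zero diagonal.
random_dist_matrix <- function(n, max_d = 0.1, ids = sprintf("s%02d", 1:n)) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(m)
  m[ut] <- stats::runif(sum(ut), 0, max_d)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Random tree with strictly positive branch lengths and its additive
# (path-length) distance matrix.
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Sort the tip.labels within a partition list for comparison.
canon_partition <- function(groups) {
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1L))])
}

# Membership vector (id -> species) from a community truth table, restricted
# to the given specimen ids.
truth_membership <- function(community, ids) {
  m <- community$truth$species_id[match(ids, community$truth$specimen_id)]
  stats::setNames(m, ids)
}
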