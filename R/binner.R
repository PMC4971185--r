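# BIN-surrogate clustering: single linkage with a gap-based refinement pass.
#
# Initial clusters are the transitive closure of "distance < threshold"
# (single linkage). The refinement pass splits chained clusters across a
# barcode gap: a cluster is split into two groups when the smallest
# between-group distance exceeds `refine_gap` and both within-group maxima
# fall below that between-group minimum; the rule is applied recursively and
# never merges.

#' Single-linkage clusters at a distance threshold
#'
#' Computes the transitive closure of the relation `d(i, j) < threshold`
#' (strict) via union-find. `NA` entries (saturated or insufficient overlap)
#' never link.
#'
#' @param d Symmetric distance matrix with id dimnames.
#' @param threshold Linkage threshold in (0, 0.75); default 0.022, the
#'   conventional barcode-cluster seed threshold.
#' @return List of character vectors (member ids, sorted), ordered by smallest
#'   member id.
#' @export
single_linkage_clusters <- function(d, threshold = 0.022) {
  n <- nrow(d)
  if (is.null(n) || n == 0L) stop("empty distance matrix")
  if (!(threshold > 0 && threshold < 0.75))
    stop("threshold must lie in (0, 0.75)")
  ids <- rownames(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  if (nrow(link) > 0L) {
    for (r in seq_len(nrow(link))) {
      a <- find(link[r, 1L]); b <- find(link[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- unname(split(ids, roots))
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

# Top single-linkage split of a set of ids: returns list(g1, g2, height) where
# height is the merge height joining them (the between-group minimum when the
# split is clean), or NULL for fewer than 2 ids.
.top_split <- function(ids, d) {
  if (length(ids) < 2L) return(NULL)
  if (length(ids) == 2L)
    return(list(g1 = ids[1L], g2 = ids[2L], height = d[ids[1L], ids[2L]]))
  hc <- stats::hclust(stats::as.dist(d[ids, ids]), method = "single")
  grp <- stats::cutree(hc, k = 2L)
  list(g1 = ids[grp == 1L], g2 = ids[grp == 2L],
       height = max(hc$height))
}

#' Refine chained clusters across a barcode gap
#'
#' @param clusters List of member-id vectors (from
#'   [single_linkage_clusters()]).
#' @param d Distance matrix.
#' @param refine_gap Minimum between-group distance for a split
#'   (default 0.042).
#' @return Refined cluster list, same ordering convention; the member multiset
#'   is preserved (splits only, never merges).
#' @export
refine_clusters <- function(clusters, d, refine_gap = 0.042) {
  split_one <- function(ids) {
    if (length(ids) < 2L) return(list(ids))
    if (anyNA(d[ids, ids])) return(list(ids))
    sp <- .top_split(ids, d)
    between_min <- suppressWarnings(min(d[sp$g1, sp$g2], na.rm = TRUE))
    within_max <- function(g) {
      if (length(g) < 2L) return(0)
      m <- d[g, g]
      if (anyNA(m)) return(Inf)  # unverifiable tightness: do not split
      max(m)
    }
    if (is.finite(between_min) && between_min > refine_gap &&
        within_max(sp$g1) < between_min && within_max(sp$g2) < between_min) {
      c(split_one(sort(sp$g1)), split_one(sort(sp$g2)))
    } else {
      list(ids)
    }
  }
  out <- unlist(lapply(clusters, split_one), recursive = FALSE)
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Medoid representative of a cluster
#'
#' The member minimizing summed distance to all other members; ties resolve
#' to the lexicographically smallest id.
#'
#' @param members Character vector of member ids (non-empty).
#' @param d Distance matrix.
#' @return A specimen id.
#' @export
select_representative <- function(members, d) {
  if (length(members) == 0L) stop("empty cluster")
  if (length(members) == 1L) return(members)
  members <- sort(members)
  sums <- rowSums(d[members, members, drop = FALSE], na.rm = TRUE)
  members[which.min(sums)]  # which.min takes the first (smallest id) on ties
}

# Content-addressed cluster id: two independent polynomial hashes (mod large
# primes, double-safe) over the sorted member ids, printed as 16 hex digits.
.poly_hash <- function(bytes, mult, mod) {
  h <- 0
  for (b in bytes) h <- (h * mult + b) %% mod
  h
}

cluster_hash_id <- function(members) {
  bytes <- utf8ToInt(paste(sort(members), collapse = "|"))
  h1 <- .poly_hash(bytes, 31, 2147483647)
  h2 <- .poly_hash(bytes, 131, 2147483629)
  paste0("BC", sprintf("%08x%08x", h1, h2))
}

#' BOLD-style alias codes for report readability
#'
#' Generates sequential `AAA0001`-style aliases; purely cosmetic alternatives
#' to the content-addressed cluster ids.
#'
#' @param n Number of aliases.
#' @return Character vector of length `n`.
#' @export
bold_aliases <- function(n) {
  idx <- seq_len(n) - 1L
  block <- idx %/% 9999L
  num <- idx %% 9999L + 1L
  l3 <- block %% 26L
  l2 <- (block %/% 26L) %% 26L
  l1 <- (block %/% 676L) %% 26L
  paste0(LETTERS[l1 + 1L], LETTERS[l2 + 1L], LETTERS[l3 + 1L],
         sprintf("%04d", num))
}

#' Cluster BIN-compliant sequences into BIN surrogates
#'
#' Runs single linkage, the gap refinement pass and representative selection.
#'
#' @param d Distance matrix over BIN-compliant specimens.
#' @param threshold Linkage threshold (default 0.022).
#' @param refine_gap Refinement gap (default 0.042).
#' @return List with `clusters` (list of member vectors), `membership` (named
#'   vector id -> cluster id), `table` (data frame: specimen_id, cluster_id,
#'   representative_flag) and `summary` (cluster_id, alias, n_members,
#'   representative, max_intra_distance).
#' @export
cluster_bins <- function(d, threshold = 0.022, refine_gap = 0.042) {
  cl <- refine_clusters(single_linkage_clusters(d, threshold), d, refine_gap)
  cids <- vapply(cl, cluster_hash_id, character(1))
  reps <- vapply(cl, select_representative, character(1), d = d)
  maxd <- vapply(cl, function(g)
    if (length(g) < 2L) 0 else max(d[g, g]), numeric(1))
  membership <- stats::setNames(
    rep(cids, lengths(cl)), unlist(cl))
  tab <- data.frame(specimen_id = unlist(cl),
                    cluster_id = rep(cids, lengths(cl)),
                    representative_flag = unlist(cl) %in% reps,
                    stringsAsFactors = FALSE, row.names = NULL)
  summ <- data.frame(cluster_id = cids, alias = bold_aliases(length(cl)),
                     n_members = lengths(cl), representative = reps,
                     max_intra_distance = maxd,
                     stringsAsFactors = FALSE, row.names = NULL)
  list(clusters = cl, membership = membership, table = tab, summary = summ)
}
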