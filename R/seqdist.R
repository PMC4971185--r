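# Reference-frame placement and Kimura two-parameter (K2P) distances.
#
# K2P corrects observed divergence separately for transitions (proportion P)
# and transversions (proportion Q):
#   d = -1/2 * ln(1 - 2P - Q) - 1/4 * ln(1 - 2Q)
# P and Q are computed over sites where both sequences carry an unambiguous
# base (pairwise deletion); ambiguity codes and gaps are excluded.

#' Place a barcode sequence onto the 658-site reference frame
#'
#' Tries every ungapped offset of the query against the bundled (or supplied)
#' reference and keeps the placement maximizing amino-acid identity between
#' the query's translation (in the reference codon frame, invertebrate
#' mitochondrial code) and the reference translation. A placement whose best
#' translation still contains internal stop codons indicates a reading-frame
#' shift and is rejected.
#'
#' @param seq Query nucleotide string (passed QC).
#' @param reference Reference nucleotide string (default [coi_reference()]).
#' @param min_overlap Minimum overlap with the reference (default 500).
#' @return An `aligned_seq` list: `bases` (character vector, reference length,
#'   gap `-` outside the placement), `offset` (0-based), `covered` (sites) and
#'   `aa_identity`.
#' @export
map_to_reference <- function(seq, reference = coi_reference(),
                             min_overlap = 500L) {
  ref <- seq_chars(reference)
  ch <- seq_chars(seq)
  L <- length(ref)
  len <- length(ch)
  if (len > L) stop("query longer than the reference frame")
  if (len < min_overlap)
    stop("overlap with reference below min_overlap (", min_overlap, " bp)")
  ref_aa <- translate_mito(paste(ref, collapse = ""))
  score_at <- function(o) {
    phase <- o %% 3L
    skip <- (3L - phase) %% 3L
    sub <- ch[(skip + 1L):len]
    n_codon <- length(sub) %/% 3L
    if (n_codon == 0L) return(list(id = -Inf, stops = NA_integer_))
    aa <- translate_mito(paste(sub[seq_len(3L * n_codon)], collapse = ""))
    first_codon <- (o + skip) %/% 3L + 1L
    ref_part <- ref_aa[first_codon:(first_codon + n_codon - 1L)]
    internal <- if (length(aa) > 1L) aa[-length(aa)] else aa
    list(id = mean(aa == ref_part), stops = sum(internal == "*"))
  }
  offsets <- 0:(L - len)
  scores <- lapply(offsets, score_at)
  ids <- vapply(scores, `[[`, numeric(1), "id")
  best <- which.max(ids)
  if (!is.finite(ids[best])) stop("no placement possible")
  if (scores[[best]]$stops > 0L)
    stop("no stop-free placement: probable reading-frame shift")
  bases <- rep("-", L)
  o <- offsets[best]
  bases[(o + 1L):(o + len)] <- ch
  structure(list(bases = bases, offset = o, covered = len,
                 aa_identity = ids[best]),
            class = "aligned_seq")
}

.aligned_chars <- function(x) {
  if (inherits(x, "aligned_seq")) x$bases else seq_chars(x)
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' @param P Transition proportion among shared sites.
#' @param Q Transversion proportion among shared sites.
#' @return K2P distance (substitutions/site).
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop("K2P distance saturated (log argument <= 0)")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter distance between two placed sequences
#'
#' Uses pairwise deletion: P and Q are computed over sites where both
#' sequences carry an unambiguous ACGT base.
#'
#' @param a,b `aligned_seq` objects or equal-length nucleotide strings (gaps
#'   as `-`).
#' @param min_shared Minimum number of shared unambiguous sites (default 300).
#' @return K2P distance.
#' @export
k2p_distance <- function(a, b, min_shared = 300L) {
  x <- .aligned_chars(a)
  y <- .aligned_chars(b)
  if (length(x) != length(y)) stop("sequences must share a reference frame")
  ok <- x %in% .BASES & y %in% .BASES
  n <- sum(ok)
  if (n < min_shared)
    stop("shared unambiguous sites (", n, ") below min_shared (",
         min_shared, ")")
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  ts <- diff & (.TRANSITION[xs] == ys)
  P <- sum(ts) / n
  Q <- (sum(diff) - sum(ts)) / n
  k2p_from_pq(P, Q)
}

#' Pairwise K2P distance matrix
#'
#' Computes all pairwise K2P distances with pairwise deletion using a
#' vectorized one-hot formulation (a handful of crossproducts rather than a
#' per-pair scan). Pairs with fewer than `min_shared` shared sites or a
#' saturated distance are set to `NA` and listed in the `flagged` attribute.
#'
#' @param seqs Named character vector of equal-length placed sequences, or a
#'   list of `aligned_seq` objects with names.
#' @param min_shared Minimum shared unambiguous sites per pair.
#' @return Symmetric numeric matrix with zero diagonal and id dimnames;
#'   attribute `flagged` holds a data frame of problem pairs (if any).
#' @export
distance_matrix <- function(seqs, min_shared = 300L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences must have unique names")
  chs <- lapply(seqs, .aligned_chars)
  L <- unique(lengths(chs))
  if (length(L) != 1L) stop("sequences must share a reference frame")
  m <- do.call(rbind, chs)
  onehot <- lapply(.BASES, function(b) (m == b) * 1)
  names(onehot) <- .BASES
  V <- Reduce(`+`, onehot)
  S <- V %*% t(V)                                   # shared sites
  M <- Reduce(`+`, lapply(onehot, function(X) X %*% t(X)))   # matches
  PU <- onehot$A + onehot$G
  PY <- onehot$C + onehot$T
  Qc <- PU %*% t(PY) + PY %*% t(PU)                 # transversions
  Pc <- (S - M) - Qc                                # transitions
  P <- Pc / S
  Q <- Qc / S
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  bad_shared <- S < min_shared
  bad_sat <- w1 <= 0 | w2 <= 0
  d[bad_shared | bad_sat] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  bad <- (bad_shared | bad_sat)
  diag(bad) <- FALSE
  if (any(bad)) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    attr(d, "flagged") <- data.frame(
      id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
      reason = ifelse(bad_shared[idx], "insufficient_overlap", "saturated"),
      stringsAsFactors = FALSE)
  }
  d
}

#' Write / read a distance matrix as square TSV
#'
#' @param d Symmetric matrix with id dimnames.
#' @param path File path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}

#' Nearest-neighbour distances per cluster
#'
#' The nearest-neighbour (NN) distance of a cluster is the minimum K2P
#' distance between any of its members and any member of any other cluster.
#' With a single cluster NN is undefined and reported as `NA`.
#'
#' @param d Distance matrix (ids in dimnames).
#' @param membership Named vector mapping every id in `d` to a cluster id.
#' @return Data frame: `cluster_id`, `nn_distance`, `nn_cluster` (the cluster
#'   attaining the minimum).
#' @export
nn_distances <- function(d, membership) {
  ids <- rownames(d)
  mem <- membership[ids]
  if (anyNA(mem)) stop("every id in the matrix needs a cluster")
  cl <- sort(unique(as.character(mem)))
  rows <- lapply(cl, function(cid) {
    inside <- ids[mem == cid]
    outside <- ids[mem != cid]
    if (length(outside) == 0L)
      return(data.frame(cluster_id = cid, nn_distance = NA_real_,
                        nn_cluster = NA_character_, stringsAsFactors = FALSE))
    sub <- d[inside, outside, drop = FALSE]
    j <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    data.frame(cluster_id = cid, nn_distance = min(sub, na.rm = TRUE),
               nn_cluster = as.character(mem[outside[j[["col"]]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Family-level summary of nearest-neighbour distances
#'
#' @param nn Data frame from [nn_distances()].
#' @param family_of Named vector mapping cluster id to family.
#' @return Data frame: `family`, `n_clusters`, `nn_mean`, `nn_sd`.
#' @export
nn_family_summary <- function(nn, family_of) {
  fam <- family_of[nn$cluster_id]
  agg <- split(nn$nn_distance, fam)
  data.frame(family = names(agg),
             n_clusters = vapply(agg, length, integer(1)),
             nn_mean = vapply(agg, function(v) mean(v, na.rm = TRUE),
                              numeric(1)),
             nn_sd = vapply(agg, function(v) stats::sd(v, na.rm = TRUE),
                            numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
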