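# Tiered taxonomic assignment and neighbour-joining validation.
#
# Cascade: (1) BIN consensus — if a cluster contains expert-identified
# members and all expert labels agree at a rank, the whole cluster inherits
# the deepest consistent rank; (2) identification-engine — nearest-reference
# K2P distance with monophyly confirmation (< 5 % for genus, < 10 % for
# family); (3) morphology_pending — an explicit export state for specimens
# needing morphological work. Placements are validated on NJ trees built from
# K2P distances over cluster representatives.

.RANKS <- c("order", "family", "genus", "species")

#' Consensus taxonomy of a cluster from expert-identified members
#'
#' Walks ranks from order to species; at each rank the non-missing expert
#' labels must be unanimous for the cluster to inherit it. The first
#' disagreement stops the descent and is flagged as a conflict.
#'
#' @param expert_labels Data frame with columns `order`, `family`, `genus`,
#'   `species` (empty string = missing), one row per expert-identified member
#'   (zero rows allowed).
#' @return List: `rank` (deepest consistent rank or NA), `name`, `method`
#'   (`bin_consensus` or NA when no expert labels exist), `conflict`
#'   (logical), `note`.
#' @export
bin_consensus_assign <- function(expert_labels) {
  out <- list(rank = NA_character_, name = NA_character_,
              method = NA_character_, conflict = FALSE, note = "")
  if (nrow(expert_labels) == 0L) return(out)
  any_label <- FALSE
  for (rk in .RANKS) {
    vals <- expert_labels[[rk]]
    vals <- vals[!is.na(vals) & vals != ""]
    if (length(vals) == 0L) break
    if (length(unique(vals)) > 1L) {
      out$conflict <- TRUE
      out$note <- paste0("expert disagreement at rank ", rk, ": ",
                         paste(sort(unique(vals)), collapse = " vs "))
      break
    }
    out$rank <- rk
    out$name <- vals[1L]
    any_label <- TRUE
  }
  if (any_label) out$method <- "bin_consensus"
  out
}

# Leaves of the smallest clade (>= 2 leaves) containing `tip` in `tree`.
.smallest_clade_tips <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  ape::extract.clade(tree, parent)$tip.label
}

#' Identification-engine assignment for an unassigned cluster
#'
#' Finds the nearest reference cluster by K2P distance. A hit below the genus
#' threshold whose neighbourhood in the validation tree is monophyletic for
#' the candidate genus yields a genus (and family) placement; a hit below the
#' family threshold with family-level monophyly yields a family placement;
#' otherwise the cluster is exported as `morphology_pending`.
#'
#' Monophyly is operationalized as: the smallest clade of the validation tree
#' containing the nearest reference consists only of references of the
#' candidate taxon, at least two of them.
#'
#' @param ref_dist Named numeric vector: distance from the query to each
#'   reference cluster representative (names = reference cluster ids).
#' @param ref_taxa Data frame: `cluster_id`, `family`, `genus` for the
#'   references.
#' @param tree Validation tree (`phylo`) whose tips include the reference
#'   cluster ids, or NULL to skip the monophyly confirmation.
#' @param genus_threshold,family_threshold Distance thresholds
#'   (defaults 0.05 and 0.10).
#' @return List: `rank`, `name`, `family`, `method`, `note`.
#' @export
id_engine_assign <- function(ref_dist, ref_taxa, tree = NULL,
                             genus_threshold = 0.05,
                             family_threshold = 0.10) {
  pend <- list(rank = NA_character_, name = NA_character_,
               family = NA_character_, method = "morphology_pending",
               note = "")
  usable <- ref_dist[!is.na(ref_dist)]
  if (length(usable) == 0L) {
    pend$note <- "no computable distance to any reference (saturation)"
    return(pend)
  }
  best <- names(usable)[which.min(usable)]
  dstar <- min(usable)
  cand <- ref_taxa[match(best, ref_taxa$cluster_id), ]
  mono <- function(rank_col) {
    if (is.null(tree)) return(TRUE)
    tips <- .smallest_clade_tips(tree, best)
    tips <- intersect(tips, ref_taxa$cluster_id)
    vals <- ref_taxa[[rank_col]][match(tips, ref_taxa$cluster_id)]
    length(tips) >= 2L && all(vals == cand[[rank_col]])
  }
  if (dstar < genus_threshold && !is.na(cand$genus) && cand$genus != "" &&
      mono("genus")) {
    return(list(rank = "genus", name = cand$genus, family = cand$family,
                method = "id_engine",
                note = sprintf("nearest reference %s at %.4f", best, dstar)))
  }
  if (dstar < family_threshold && !is.na(cand$family) && cand$family != "" &&
      mono("family")) {
    return(list(rank = "family", name = cand$family, family = cand$family,
                method = "id_engine",
                note = sprintf("nearest reference %s at %.4f", best, dstar)))
  }
  pend$note <- sprintf("nearest reference %s at %.4f exceeds thresholds",
                       best, dstar)
  pend
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour joining: at each step the pair minimizing
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` is joined (ties broken by the
#' lexicographically smallest pair of node labels), branch lengths follow the
#' standard formulas, and negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch so path lengths through the new
#' node are preserved.
#'
#' @param d Symmetric distance matrix with id dimnames, >= 3 leaves.
#' @return An unrooted `phylo` tree.
#' @export
build_nj_tree <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 3L) stop("neighbour joining needs at least 3 leaves")
  if (anyNA(d))
    stop("distance matrix contains NA (saturated or low-overlap pairs); ",
         "neighbour joining needs a complete matrix")
  labs <- rownames(d)
  D <- unname(d)
  frag <- labs                 # newick fragment per active node
  key <- labs                  # tie-break key: smallest leaf label in subtree
  active <- seq_len(n)
  clamp <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }
  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Qm <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm <= qmin + 1e-12 & upper.tri(Qm), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      pk <- apply(cand, 1L, function(ij) {
        ks <- sort(c(key[active[ij[1]]], key[active[ij[2]]]))
        paste(ks, collapse = "\r")
      })
      cand <- cand[order(pk), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    ai <- active[i]; aj <- active[j]
    dij <- Dm[i, j]
    vi <- 0.5 * dij + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dij - vi
    v <- clamp(vi, vj)
    # distances from the new node to the others
    newd <- (D[ai, active] + D[aj, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, active] <- newd
    D[active, u] <- newd
    D[u, u] <- 0
    frag <- c(frag, sprintf("(%s:%.15g,%s:%.15g)", frag[ai], v[1],
                            frag[aj], v[2]))
    key <- c(key, min(key[ai], key[aj]))
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[a], va, frag[b], vb, frag[c3], vc)
  ape::read.tree(text = nwk)
}

#' Flag leaves placed among many leaves of a different order
#'
#' A leaf is flagged when its `k` nearest leaves by path length all carry the
#' same order label and that label differs from the leaf's own — the
#' tree-inspection rule for detecting contamination or misidentification
#' (e.g. a beetle BIN nested among fly BINs).
#'
#' @param tree `phylo` validation tree.
#' @param orders Named character vector: tip label -> order.
#' @param k Neighbourhood size (default 5); must be < number of leaves.
#' @return Data frame of flagged tips: `tip`, `own_order`,
#'   `neighbourhood_order`.
#' @export
detect_misplacements <- function(tree, orders, k = 5L) {
  n <- length(tree$tip.label)
  if (k >= n) stop("k must be smaller than the number of leaves")
  if (!all(tree$tip.label %in% names(orders)))
    stop("every leaf needs an order label")
  pd <- ape::cophenetic.phylo(tree)
  rows <- lapply(tree$tip.label, function(tip) {
    dv <- pd[tip, setdiff(colnames(pd), tip)]
    nb <- names(sort(dv))[seq_len(k)]
    nb_orders <- unique(orders[nb])
    if (length(nb_orders) == 1L && nb_orders != orders[[tip]]) {
      data.frame(tip = tip, own_order = orders[[tip]],
                 neighbourhood_order = nb_orders, stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tip = character(0), own_order = character(0),
                      neighbourhood_order = character(0),
                      stringsAsFactors = FALSE)
  out
}

#' Conflicts between pre-sequencing order ids and assigned orders
#'
#' @param specimen_id Character vector of ids.
#' @param pre_order Ordinal identification made before sequencing (may be
#'   empty/NA; such records are skipped).
#' @param assigned_order Post-assignment order.
#' @return Data frame of conflicting records with a `note` listing likely
#'   causes (parasitoid amplification, contamination, non-target tissue).
#' @export
detect_conflicts <- function(specimen_id, pre_order, assigned_order) {
  keep <- which(!is.na(pre_order) & pre_order != "" &
                  !is.na(assigned_order) & assigned_order != "" &
                  pre_order != assigned_order)
  data.frame(
    specimen_id = specimen_id[keep],
    pre_order = pre_order[keep],
    assigned_order = assigned_order[keep],
    note = rep("possible parasitoid amplification, contamination or non-target tissue",
               length(keep)),
    stringsAsFactors = FALSE)
}

#' Run the full assignment cascade over clusters
#'
#' Applies BIN-consensus first; clusters without expert support are queried
#' against the consensus-assigned references through the identification
#' engine; the remainder are exported as `morphology_pending`. Every cluster
#' keeps at least an order-rank placement from the modal pre-sequencing
#' ordinal identification of its members.
#'
#' @param bins Result of [cluster_bins()].
#' @param meta Specimen metadata data frame (columns `specimen_id`,
#'   `order_pre_id`, `order`, `family`, `genus`, `species`, `id_method`).
#' @param d Distance matrix over specimens (used for representative-level
#'   queries).
#' @param tree Optional validation tree over cluster representatives, tips
#'   named by cluster id.
#' @param genus_threshold,family_threshold Identification-engine thresholds.
#' @return Data frame, one row per cluster: `cluster_id`, `order` (modal
#'   pre-id), `rank`, `name`, `family`, `method`, `conflict`, `note`.
#' @export
assign_clusters <- function(bins, meta, d, tree = NULL,
                            genus_threshold = 0.05, family_threshold = 0.10) {
  unan <- function(v) {
    v <- v[!is.na(v) & v != ""]
    if (length(v) > 0L && length(unique(v)) == 1L) v[1L] else NA_character_
  }
  rows <- lapply(seq_along(bins$clusters), function(ci) {
    members <- bins$clusters[[ci]]
    mm <- meta[match(members, meta$specimen_id), ]
    modal_order <- names(sort(table(mm$order_pre_id), decreasing = TRUE))[1L]
    experts <- mm[mm$id_method == "expert",
                  c("order", "family", "genus", "species"), drop = FALSE]
    cons <- bin_consensus_assign(experts)
    depth <- match(cons$rank, .RANKS)
    data.frame(cluster_id = bins$summary$cluster_id[ci],
               order = modal_order,
               rank = cons$rank, name = cons$name,
               family = if (!is.na(depth) && depth >= 2L)
                 unan(experts$family) else NA_character_,
               genus = if (!is.na(depth) && depth >= 3L)
                 unan(experts$genus) else NA_character_,
               method = cons$method, conflict = cons$conflict,
               note = cons$note, stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, rows)
  refs <- asg[!is.na(asg$method) & asg$method == "bin_consensus" &
                !is.na(asg$family), ]
  todo <- which(is.na(asg$method))
  if (length(todo) > 0L && nrow(refs) > 0L) {
    rep_of <- stats::setNames(bins$summary$representative,
                              bins$summary$cluster_id)
    ref_taxa <- data.frame(cluster_id = refs$cluster_id,
                           family = refs$family,
                           genus = ifelse(is.na(refs$genus), "", refs$genus),
                           stringsAsFactors = FALSE)
    for (ci in todo) {
      q_rep <- rep_of[[asg$cluster_id[ci]]]
      rd <- d[q_rep, rep_of[ref_taxa$cluster_id]]
      names(rd) <- ref_taxa$cluster_id
      hit <- id_engine_assign(rd, ref_taxa, tree,
                              genus_threshold, family_threshold)
      asg$rank[ci] <- hit$rank
      asg$name[ci] <- hit$name
      asg$family[ci] <- hit$family
      if (hit$method == "id_engine" && hit$rank == "genus")
        asg$genus[ci] <- hit$name
      asg$method[ci] <- hit$method
      asg$note[ci] <- hit$note
    }
  }
  asg$method[is.na(asg$method)] <- "morphology_pending"
  asg
}
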