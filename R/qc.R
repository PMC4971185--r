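# Quality triage: classify each specimen record into the sequencing outcome
# classes (BIN-compliant / short / contaminated / none) and pass only
# BIN-compliant sequences downstream.

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-")

#' QC configuration
#'
#' @param min_length Minimum sequence length (bp) for BIN compliance; a record
#'   must exceed this length. The conventional threshold is 500 bp, though
#'   487 bp is also in circulation for BIN compliance; both are supported via
#'   this parameter.
#' @param max_n_fraction Maximum tolerated fraction of uncertain base calls
#'   (all non-ACGT IUPAC codes count as uncertain).
#' @param contaminant_identity Minimum anchored pairwise identity to a
#'   contaminant reference for a contamination call.
#' @param contaminant_min_overlap Minimum overlap (bp) for the contaminant
#'   comparison to be attempted.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_length = 500L, max_n_fraction = 0.01,
                      contaminant_identity = 0.95,
                      contaminant_min_overlap = 300L) {
  structure(list(min_length = as.integer(min_length),
                 max_n_fraction = max_n_fraction,
                 contaminant_identity = contaminant_identity,
                 contaminant_min_overlap = as.integer(contaminant_min_overlap)),
            class = "qc_config")
}

# Start-anchored ungapped identity against one reference over ACGT sites.
# Barcode amplicons share a primer-anchored 5' end, so anchored comparison
# suffices for contaminant screening.
.anchored_identity <- function(ch, ref_ch, min_overlap) {
  ov <- min(length(ch), length(ref_ch))
  if (ov < min_overlap) return(NA_real_)
  a <- ch[seq_len(ov)]
  b <- ref_ch[seq_len(ov)]
  ok <- a %in% .BASES & b %in% .BASES
  if (!any(ok)) return(NA_real_)
  sum(a[ok] == b[ok]) / sum(ok)
}

#' Check reading frames of a barcode sequence
#'
#' Translates all three forward frames under the invertebrate mitochondrial
#' code and counts internal stop codons (the final complete codon of each
#' frame is not counted as internal). A frame shift in the amplicon leaves no
#' stop-free frame, which is what this screen detects.
#'
#' @param seq Nucleotide string, length >= 100.
#' @return List with `best_frame` (0-based index of the frame with fewest
#'   internal stops; ties resolved to the lowest index), `stop_counts`
#'   (integer vector for frames 0..2) and `frame_ok` (TRUE if some frame has
#'   zero internal stops).
#' @export
frame_check <- function(seq) {
  ch <- seq_chars(seq)
  if (length(ch) < 100L) stop("sequence too short to frame-check (< 100 bp)")
  stops <- vapply(0:2, function(f) {
    aa <- translate_mito(paste(ch, collapse = ""), frame = f)
    if (length(aa) > 1L) aa <- aa[-length(aa)]
    sum(aa == "*")
  }, integer(1))
  best <- which.min(stops) - 1L
  list(best_frame = best, stop_counts = stops, frame_ok = any(stops == 0L))
}

#' Classify a specimen record into a triage category
#'
#' Applies, in order: empty sequence -> `none`; anchored identity to any
#' contaminant reference at or above the configured threshold ->
#' `contaminated` (subtype `contaminant`); length at or below `min_length` ->
#' `short`; excessive uncertain base calls or no stop-free reading frame ->
#' `contaminated` with subtype `excised` (records the pre-clustering excision
#' of frame-shifted reads while preserving the four-class table structure);
#' otherwise `bin_compliant`.
#'
#' @param seq Nucleotide string (possibly empty).
#' @param contaminant_refs Named character vector of contaminant references
#'   (may be empty).
#' @param config A [qc_config()].
#' @return List with fields `category`, `subtype`, `length`, `n_fraction`,
#'   `frame_ok`, `contaminant_hit` (name or NA) and `contaminant_identity`.
#' @export
classify_record <- function(seq, contaminant_refs = contaminant_library(),
                            config = qc_config()) {
  ch <- seq_chars(seq)
  if (length(ch) == 1L && ch[1] == "") ch <- character(0)
  bad <- setdiff(unique(ch), .IUPAC)
  if (length(bad) > 0L)
    stop("non-IUPAC character in sequence: ", paste(bad, collapse = ", "))
  len <- length(ch)
  res <- list(category = NA_character_, subtype = NA_character_,
              length = len, n_fraction = NA_real_, frame_ok = NA,
              contaminant_hit = NA_character_,
              contaminant_identity = NA_real_)
  if (len == 0L) {
    res$category <- "none"
    return(res)
  }
  res$n_fraction <- sum(!ch %in% .BASES) / len
  if (length(contaminant_refs) > 0L) {
    ids <- vapply(contaminant_refs, function(r)
      .anchored_identity(ch, seq_chars(r), config$contaminant_min_overlap),
      numeric(1))
    if (any(!is.na(ids)) && max(ids, na.rm = TRUE) >= config$contaminant_identity) {
      hit <- which.max(ids)
      res$category <- "contaminated"
      res$subtype <- "contaminant"
      res$contaminant_hit <- names(contaminant_refs)[hit]
      res$contaminant_identity <- ids[hit]
      return(res)
    }
  }
  if (len <= config$min_length) {
    res$category <- "short"
    return(res)
  }
  fc <- frame_check(paste(ch, collapse = ""))
  res$frame_ok <- fc$frame_ok
  if (res$n_fraction >= config$max_n_fraction || !fc$frame_ok) {
    res$category <- "contaminated"
    res$subtype <- "excised"
    return(res)
  }
  res$category <- "bin_compliant"
  res
}

#' Triage a set of specimen sequences
#'
#' Vectorized wrapper around [classify_record()].
#'
#' @param sequences Named character vector (specimen id -> sequence).
#' @param contaminant_refs,config Passed to [classify_record()].
#' @return Data frame with one row per specimen: `specimen_id`, `category`,
#'   `subtype`, `length`, `n_fraction`, `frame_ok`, `contaminant_hit`.
#' @export
qc_specimens <- function(sequences, contaminant_refs = contaminant_library(),
                         config = qc_config()) {
  if (length(sequences) == 0L) stop("empty record set")
  rows <- lapply(seq_along(sequences), function(i) {
    r <- classify_record(sequences[[i]], contaminant_refs, config)
    data.frame(specimen_id = names(sequences)[i], category = r$category,
               subtype = r$subtype, length = r$length,
               n_fraction = r$n_fraction, frame_ok = r$frame_ok,
               contaminant_hit = r$contaminant_hit, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-order triage summary table
#'
#' Tabulates counts and percentages of the four triage classes per order, plus
#' a grand-total row, in the shape of a sequencing-success summary table.
#'
#' @param results Data frame from [qc_specimens()] (needs `category`).
#' @param orders Character vector of order labels, one per result row.
#' @return Data frame: `order`, `n`, then percentage columns `bin_compliant`,
#'   `short`, `contaminated`, `none` (rounded to 1 decimal) and the four raw
#'   count columns (`*_n`).
#' @export
triage_table <- function(results, orders) {
  if (nrow(results) == 0L) stop("empty triage input")
  if (length(orders) != nrow(results))
    stop("need one order label per result row")
  cats <- c("bin_compliant", "short", "contaminated", "none")
  one <- function(idx, label) {
    cnt <- vapply(cats, function(k) sum(results$category[idx] == k),
                  numeric(1))
    n <- length(idx)
    row <- data.frame(order = label, n = n, stringsAsFactors = FALSE)
    for (k in cats) row[[k]] <- round(100 * cnt[[k]] / n, 1)
    for (k in cats) row[[paste0(k, "_n")]] <- cnt[[k]]
    row
  }
  per <- lapply(sort(unique(orders)), function(o) one(which(orders == o), o))
  total <- one(seq_len(nrow(results)), "total")
  do.call(rbind, c(per, list(total)))
}
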