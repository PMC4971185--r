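# Run orchestration: read specimens, triage, distances, clustering,
# assignment/validation, richness estimation, report files.

#' Pipeline run configuration
#'
#' Collects paths and all module thresholds; the configuration (plus seed) is
#' serialized into the output directory so any run can be regenerated.
#'
#' @param fasta,metadata,checklist,out_dir File paths; `checklist` (TSV with
#'   `order` and `known_species`) may be NULL, in which case the BIN/SP stage
#'   is skipped.
#' @param contaminants Named character vector of contaminant references
#'   (default the bundled synthetic library).
#' @param min_length,max_n_fraction,contaminant_identity QC thresholds.
#' @param min_shared Minimum shared sites for a pairwise distance.
#' @param linkage_threshold,refine_gap Clustering thresholds.
#' @param genus_threshold,family_threshold Identification-engine thresholds.
#' @param misplacement_k Neighbourhood size for tree inspection.
#' @param global_fraction Fraction of the global fauna the surveyed nation
#'   hosts (for projections).
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, metadata, out_dir, checklist = NULL,
                       contaminants = contaminant_library(),
                       min_length = 500L, max_n_fraction = 0.01,
                       contaminant_identity = 0.95, min_shared = 300L,
                       linkage_threshold = 0.022, refine_gap = 0.042,
                       genus_threshold = 0.05, family_threshold = 0.10,
                       misplacement_k = 5L, global_fraction = 0.01,
                       seed = 1L) {
  stopifnot(linkage_threshold > 0, linkage_threshold < 0.75,
            refine_gap > 0, refine_gap < 0.75,
            genus_threshold < family_threshold,
            global_fraction > 0, global_fraction <= 1)
  structure(list(fasta = fasta, metadata = metadata, checklist = checklist,
                 out_dir = out_dir, contaminants = contaminants,
                 min_length = as.integer(min_length),
                 max_n_fraction = max_n_fraction,
                 contaminant_identity = contaminant_identity,
                 min_shared = as.integer(min_shared),
                 linkage_threshold = linkage_threshold,
                 refine_gap = refine_gap,
                 genus_threshold = genus_threshold,
                 family_threshold = family_threshold,
                 misplacement_k = as.integer(misplacement_k),
                 global_fraction = global_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read specimen records from FASTA + metadata
#'
#' Joins sequences to metadata rows by specimen id. Metadata rows without a
#' sequence get an empty sequence (triaged as `none` downstream); FASTA ids
#' absent from the metadata are reported in the `unmatched` element.
#'
#' @param fasta_path FASTA file (ids = specimen ids).
#' @param metadata_path TSV with a `specimen_id` column.
#' @return List: `sequences` (named vector, metadata order), `metadata`
#'   (data frame), `unmatched` (FASTA ids without metadata).
#' @export
read_specimens <- function(fasta_path, metadata_path) {
  seqs <- read_fasta(fasta_path)
  meta <- read_tsv_file(metadata_path)
  if (anyDuplicated(meta$specimen_id))
    stop("duplicate specimen id in metadata: ",
         meta$specimen_id[duplicated(meta$specimen_id)][1])
  if (anyDuplicated(names(seqs)))
    stop("duplicate specimen id in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1])
  unmatched <- setdiff(names(seqs), meta$specimen_id)
  out <- seqs[match(meta$specimen_id, names(seqs))]
  out[is.na(out)] <- ""
  names(out) <- meta$specimen_id
  list(sequences = out, metadata = meta, unmatched = unmatched)
}

#' Run the full census pipeline
#'
#' Stages: QC triage -> distance matrix over BIN-compliant specimens ->
#' single-linkage + refinement clustering -> taxonomic assignment with NJ
#' validation -> richness estimation (octave fit, BIN/SP) -> report files.
#' Every intermediate artifact is written under `config$out_dir`, together
#' with the serialized configuration; the run is idempotent for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Run summary list (also written as `run_summary.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- read_specimens(config$fasta, config$metadata)
  meta <- spec$metadata
  n_in <- length(spec$sequences)

  qc_cfg <- qc_config(min_length = config$min_length,
                      max_n_fraction = config$max_n_fraction,
                      contaminant_identity = config$contaminant_identity)
  qc <- qc_specimens(spec$sequences, config$contaminants, qc_cfg)
  write_tsv_file(qc, file.path(config$out_dir, "qc.tsv"))
  triage <- triage_table(qc, meta$order_pre_id)
  write_tsv_file(triage, file.path(config$out_dir, "triage_table.tsv"))

  ok <- qc$specimen_id[qc$category == "bin_compliant"]
  if (length(ok) < 2L)
    stop("stage distances: fewer than 2 BIN-compliant sequences")
  ref <- coi_reference()
  L <- nchar(ref)
  seqs_ok <- spec$sequences[ok]
  if (!all(nchar(seqs_ok) == L)) {
    placed <- lapply(seqs_ok, map_to_reference, reference = ref,
                     min_overlap = config$min_shared)
    seqs_ok <- vapply(placed, function(a) paste(a$bases, collapse = ""),
                      character(1))
  }
  d <- distance_matrix(seqs_ok, min_shared = config$min_shared)
  write_distance_matrix(d, file.path(config$out_dir, "distance_matrix.tsv"))

  bins <- cluster_bins(d, config$linkage_threshold, config$refine_gap)
  write_tsv_file(bins$table, file.path(config$out_dir, "clusters.tsv"))
  write_tsv_file(bins$summary, file.path(config$out_dir,
                                         "cluster_summary.tsv"))

  tree <- NULL
  misplaced <- data.frame()
  if (length(bins$clusters) >= 3L) {
    reps <- bins$summary$representative
    dr <- d[reps, reps]
    dimnames(dr) <- list(bins$summary$cluster_id, bins$summary$cluster_id)
    tree <- build_nj_tree(dr)
    ape::write.tree(tree, file.path(config$out_dir, "validation_tree.nwk"))
  }
  asg <- assign_clusters(bins, meta, d, tree,
                         config$genus_threshold, config$family_threshold)
  write_tsv_file(asg, file.path(config$out_dir, "assignments.tsv"))
  if (!is.null(tree) && length(bins$clusters) > config$misplacement_k) {
    orders <- stats::setNames(asg$order, asg$cluster_id)
    misplaced <- detect_misplacements(tree, orders, config$misplacement_k)
    write_tsv_file(misplaced, file.path(config$out_dir, "misplacements.tsv"))
  }
  cl_order <- stats::setNames(asg$order, asg$cluster_id)
  conf <- detect_conflicts(bins$table$specimen_id,
                           meta$order_pre_id[match(bins$table$specimen_id,
                                                   meta$specimen_id)],
                           cl_order[bins$table$cluster_id])
  write_tsv_file(conf, file.path(config$out_dir, "conflicts.tsv"))

  nn <- nn_distances(d, bins$membership)
  write_tsv_file(nn, file.path(config$out_dir, "nn_distances.tsv"))

  abund <- as.numeric(table(bins$membership))
  B_o <- length(bins$clusters)
  hist <- octave_histogram(abund)
  write_tsv_file(hist, file.path(config$out_dir, "octaves.tsv"))
  est <- NULL
  ex <- tryCatch(extrapolate_richness(abund), error = function(e) NULL)
  if (!is.null(ex)) {
    est <- list(S0 = ex$fit$S0, R0 = ex$fit$R0, sigma = ex$fit$sigma,
                S_total = ex$fit$S_total, B_e = ex$B_e,
                pct_undersampled = ex$pct_undersampled)
  }

  bin_sp <- NULL
  if (!is.null(config$checklist)) {
    ck <- read_tsv_file(config$checklist)
    per_order <- table(asg$order)
    bin_sp <- data.frame(order = ck$order,
                         known_species = ck$known_species,
                         bin_count = as.integer(per_order[ck$order]),
                         stringsAsFactors = FALSE)
    bin_sp$bin_count[is.na(bin_sp$bin_count)] <- 0L
    bin_sp$bin_sp <- vapply(seq_len(nrow(bin_sp)), function(i)
      bin_sp_ratio(bin_sp$bin_count[i], bin_sp$known_species[i]), numeric(1))
    write_tsv_file(bin_sp, file.path(config$out_dir, "bin_sp.tsv"))
  } else {
    warning("no checklist supplied: BIN/SP stage skipped")
  }

  summary <- list(
    seed = config$seed,
    counts = list(specimens_in = n_in,
                  bin_compliant = length(ok),
                  short = sum(qc$category == "short"),
                  contaminated = sum(qc$category == "contaminated"),
                  none = sum(qc$category == "none"),
                  clusters = B_o,
                  conflicts = nrow(conf),
                  misplacement_flags = nrow(misplaced)),
    methods = list(bin_consensus = sum(asg$method == "bin_consensus"),
                   id_engine = sum(asg$method == "id_engine"),
                   morphology_pending = sum(asg$method ==
                                              "morphology_pending")),
    richness = est,
    bin_sp = bin_sp,
    config = config[setdiff(names(config), "contaminants")])
  jsonlite::write_json(summary, file.path(config$out_dir,
                                          "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}

#' Write the human-readable report for a completed run
#'
#' Assembles the table-shaped artifacts of a run directory into a single
#' plain-text report (triage table, cluster and assignment counts, richness
#' extrapolation, BIN/SP rows).
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @return Invisibly, the report path.
#' @export
write_report <- function(out_dir) {
  summ <- jsonlite::read_json(file.path(out_dir, "run_summary.json"),
                              simplifyVector = TRUE)
  lines <- c("Barcode census run report", "=========================", "")
  cts <- summ$counts
  lines <- c(lines, sprintf("specimens in:        %d", cts$specimens_in),
             sprintf("BIN-compliant:       %d", cts$bin_compliant),
             sprintf("short:               %d", cts$short),
             sprintf("contaminated:        %d", cts$contaminated),
             sprintf("no sequence:         %d", cts$none),
             sprintf("clusters (BINs):     %d", cts$clusters),
             sprintf("pre-id conflicts:    %d", cts$conflicts),
             sprintf("misplacement flags:  %d", cts$misplacement_flags), "")
  if (!is.null(summ$richness) && length(summ$richness) > 0) {
    r <- summ$richness
    lines <- c(lines, "Richness extrapolation (truncated lognormal):",
               sprintf("  S0 = %.2f, R0 = %.2f, sigma = %.2f",
                       r$S0, r$R0, r$sigma),
               sprintf("  observed BINs B_o = %d, expected B_e = %d (%+.1f%%)",
                       cts$clusters, r$B_e, r$pct_undersampled), "")
  } else {
    lines <- c(lines, "Richness extrapolation: skipped (too few octaves)", "")
  }
  if (is.null(summ$bin_sp) || length(summ$bin_sp) == 0)
    lines <- c(lines, "BIN/SP stage: skipped (no checklist)")
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
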