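# Synthetic COI barcode communities with known ground truth.
#
# The generator realizes the statistical structure the downstream analysis
# assumes: lognormal species abundances sampled multinomially, a barcode gap
# (intraspecific divergence well below congeneric divergence), sequencing
# failure classes (short / contaminated / none), and partial expert
# identification. Every output is reproducible from (params, seed).

#' Parameters of a synthetic barcode community
#'
#' @param n_species Number of species (>= 2).
#' @param abundance_log_mean,abundance_log_sd Mean and standard deviation of
#'   per-species expected abundance on the natural-log scale. The default
#'   width `1.4 * log(2)` is Preston's canonical lognormal (1.4 octaves).
#' @param n_specimens Total number of specimens to sample (multinomial over
#'   species with probabilities proportional to expected abundances).
#' @param taxonomy_shape List with `n_orders`, `families_per_order` and
#'   `genera_per_family`; species are allocated to genera cyclically.
#' @param interspecific_min,interspecific_max Bounds of the uniform proportion
#'   divergence between a species barcode and its genus ancestor; congeneric
#'   species therefore differ by roughly the sum of two such draws.
#' @param intraspecific_max Maximum proportion divergence of a specimen from
#'   its species barcode.
#' @param artifact_rates Named numeric vector with elements `short`,
#'   `contaminated` and `none`: per-specimen probabilities of the three
#'   sequencing failure classes. Must sum to < 1.
#' @param expert_id_fraction Fraction of specimens carrying a species-rank
#'   expert identification in the metadata.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `community_params` list, validated.
#' @export
community_params <- function(n_species = 100L,
                             abundance_log_mean = 3,
                             abundance_log_sd = 1.4 * log(2),
                             n_specimens = 5000L,
                             taxonomy_shape = list(n_orders = 5L,
                                                   families_per_order = 2L,
                                                   genera_per_family = 3L),
                             interspecific_min = 0.03,
                             interspecific_max = 0.15,
                             intraspecific_max = 0.01,
                             artifact_rates = c(short = 0.03,
                                                contaminated = 0.005,
                                                none = 0.09),
                             expert_id_fraction = 0.3,
                             seed = 1L) {
  p <- list(n_species = as.integer(n_species),
            abundance_log_mean = abundance_log_mean,
            abundance_log_sd = abundance_log_sd,
            n_specimens = as.integer(n_specimens),
            taxonomy_shape = taxonomy_shape,
            interspecific_min = interspecific_min,
            interspecific_max = interspecific_max,
            intraspecific_max = intraspecific_max,
            artifact_rates = artifact_rates,
            expert_id_fraction = expert_id_fraction,
            seed = as.integer(seed))
  class(p) <- "community_params"
  validate_community_params(p)
  p
}

validate_community_params <- function(p) {
  if (p$n_species < 2L) stop("n_species must be at least 2")
  if (p$n_specimens < 1L) stop("n_specimens must be positive")
  if (!(0 <= p$intraspecific_max &&
        p$intraspecific_max < p$interspecific_min &&
        p$interspecific_min < p$interspecific_max &&
        p$interspecific_max <= 0.75))
    stop("need 0 <= intraspecific_max < interspecific_min < ",
         "interspecific_max <= 0.75")
  r <- p$artifact_rates
  if (!all(c("short", "contaminated", "none") %in% names(r)))
    stop("artifact_rates must name short, contaminated and none")
  if (any(r < 0) || any(r >= 1)) stop("artifact rates must lie in [0, 1)")
  if (sum(r) >= 1) stop("artifact rates must sum to < 1")
  if (p$expert_id_fraction < 0 || p$expert_id_fraction > 1)
    stop("expert_id_fraction must lie in [0, 1]")
  invisible(p)
}

.ORDER_POOL <- c("Diptera", "Hymenoptera", "Coleoptera", "Lepidoptera",
                 "Hemiptera", "Trichoptera", "Orthoptera", "Plecoptera",
                 "Neuroptera", "Ephemeroptera")

# Allocate species to a nested order/family/genus taxonomy, cyclically.
.build_taxonomy <- function(n_species, shape) {
  n_orders <- shape$n_orders
  n_fam <- n_orders * shape$families_per_order
  n_gen <- n_fam * shape$genera_per_family
  orders <- rep(.ORDER_POOL, length.out = n_orders)
  fam_order <- rep(seq_len(n_orders), each = shape$families_per_order)
  families <- paste0("fam", sprintf("%02d", seq_len(n_fam)))
  gen_fam <- rep(seq_len(n_fam), each = shape$genera_per_family)
  genera <- paste0("gen", sprintf("%03d", seq_len(n_gen)))
  gidx <- rep(seq_len(n_gen), length.out = n_species)
  species <- data.frame(
    species_id = paste0("sp", sprintf("%04d", seq_len(n_species))),
    order = orders[fam_order[gen_fam[gidx]]],
    family = families[gen_fam[gidx]],
    genus = genera[gidx],
    genus_index = gidx,
    stringsAsFactors = FALSE)
  list(species = species, fam_order = fam_order, gen_fam = gen_fam,
       n_orders = n_orders, n_fam = n_fam, n_gen = n_gen)
}

# Hierarchical ancestor sequences: one root, then order, family and genus
# ancestors each `lineage_div` (proportion) from their parent. Bounding the
# total divergence between any two community sequences keeps every K2P
# distance computable (a uniform-random ancestor per genus would put
# unrelated genera near 75 % divergence, past K2P saturation) and gives the
# validation trees a real phylogenetic signal.
.build_ancestors <- function(tax, L = 658L, lineage_div = 0.04) {
  nsub <- round(lineage_div * L)
  root <- random_coding_sequence(L %/% 3L, extra = L %% 3L)
  derive <- function(parents, n) {
    seeds <- sample.int(.Machine$integer.max, n)
    vapply(seq_len(n), function(i)
      mutate_sequence(parents[i], nsub, seed = seeds[i], avoid_stops = TRUE),
      character(1))
  }
  order_anc <- derive(rep(root, tax$n_orders), tax$n_orders)
  fam_anc <- derive(order_anc[tax$fam_order], tax$n_fam)
  gen_anc <- derive(fam_anc[tax$gen_fam], tax$n_gen)
  gen_anc
}

#' Generate a synthetic barcode community
#'
#' Draws per-species expected abundances from the configured lognormal,
#' allocates `n_specimens` specimens multinomially, builds species barcodes by
#' mutating a per-genus ancestor (divergence uniform in
#' `[interspecific_min, interspecific_max]`), mutates each specimen's sequence
#' from its species barcode by at most `intraspecific_max` substitutions, and
#' injects sequencing artifacts at the configured rates.
#'
#' @param params A [community_params()] object.
#' @return A `synthetic_community` list with elements `params`, `species`
#'   (species table with true barcodes and abundances), `specimens` (metadata
#'   data frame), `sequences` (named vector, specimen id -> sequence) and
#'   `truth` (specimen id -> species id and artifact class).
#' @export
generate_community <- function(params) {
  validate_community_params(params)
  p <- params
  L <- 658L
  with_rng(p$seed, {
    taxinfo <- .build_taxonomy(p$n_species, p$taxonomy_shape)
    tax <- taxinfo$species
    lambda <- stats::rlnorm(p$n_species, p$abundance_log_mean,
                            p$abundance_log_sd)
    counts <- as.integer(stats::rmultinom(1L, p$n_specimens,
                                          lambda / sum(lambda)))
    ancestors <- .build_ancestors(taxinfo, L)
    sp_seeds <- sample.int(.Machine$integer.max, p$n_species)
    div <- stats::runif(p$n_species, p$interspecific_min, p$interspecific_max)
    barcodes <- vapply(seq_len(p$n_species), function(i)
      mutate_sequence(ancestors[tax$genus_index[i]], round(div[i] * L),
                      seed = sp_seeds[i], avoid_stops = TRUE), character(1))
    species <- cbind(tax[, c("species_id", "order", "family", "genus")],
                     data.frame(barcode = barcodes,
                                expected_abundance = lambda,
                                realized_count = counts,
                                stringsAsFactors = FALSE))

    n <- p$n_specimens
    sp_of <- rep(seq_len(p$n_species), counts)
    specimen_id <- paste0("SPEC", sprintf("%06d", seq_len(n)))
    max_intra <- floor(p$intraspecific_max * L)
    spec_seeds <- sample.int(.Machine$integer.max, n)
    n_sub <- sample.int(max_intra + 1L, n, replace = TRUE) - 1L
    sequences <- vapply(seq_len(n), function(j)
      mutate_sequence(barcodes[sp_of[j]], n_sub[j], seed = spec_seeds[j],
                      avoid_stops = TRUE), character(1))
    names(sequences) <- specimen_id

    inj <- inject_artifacts(sequences, p$artifact_rates,
                            contaminant_library(),
                            seed = sample.int(.Machine$integer.max, 1L))

    expert <- stats::runif(n) < p$expert_id_fraction
    meta <- data.frame(
      specimen_id = specimen_id,
      order_pre_id = species$order[sp_of],
      order = ifelse(expert, species$order[sp_of], ""),
      family = ifelse(expert, species$family[sp_of], ""),
      genus = ifelse(expert, species$genus[sp_of], ""),
      species = ifelse(expert, species$species_id[sp_of], ""),
      id_method = ifelse(expert, "expert", "none"),
      site = sample(paste0("site", 1:8), n, replace = TRUE),
      lat = round(stats::runif(n, 42, 62), 4),
      lon = round(stats::runif(n, -130, -55), 4),
      date = format(as.Date("2010-01-01") +
                      sample.int(1825L, n, replace = TRUE), "%Y-%m-%d"),
      stringsAsFactors = FALSE)

    truth <- data.frame(specimen_id = specimen_id,
                        species_id = species$species_id[sp_of],
                        artifact_class = inj$classes,
                        stringsAsFactors = FALSE)

    out <- list(params = p, species = species, specimens = meta,
                sequences = inj$sequences, truth = truth)
    class(out) <- "synthetic_community"
    out
  })
}

#' Inject sequencing failure artifacts into specimen sequences
#'
#' Each record is independently assigned an artifact class with the given
#' probabilities: `short` truncates the sequence below the BIN compliance
#' length, `contaminated` replaces it with a contaminant-library sequence, and
#' `none` empties it (failed amplification/sequencing). Remaining records are
#' labelled `intact`.
#'
#' @param sequences Named character vector of specimen sequences.
#' @param artifact_rates Named numeric vector (`short`, `contaminated`,
#'   `none`) summing to < 1.
#' @param contaminants Named character vector of contaminant sequences;
#'   required non-empty when the contaminated rate is positive.
#' @param seed Integer seed.
#' @return List with `sequences` (modified vector) and `classes` (named
#'   character vector of injected classes).
#' @export
inject_artifacts <- function(sequences, artifact_rates,
                             contaminants = contaminant_library(),
                             seed = 1L) {
  if (length(sequences) == 0L) stop("empty record set")
  r <- artifact_rates[c("short", "contaminated", "none")]
  if (anyNA(r)) stop("artifact_rates must name short, contaminated and none")
  if (any(r < 0) || sum(r) >= 1) stop("artifact rates invalid")
  if (r[["contaminated"]] > 0 && length(contaminants) == 0L)
    stop("contaminant library required when contaminated rate > 0")
  with_rng(seed, {
    cls <- sample(c("short", "contaminated", "none", "intact"),
                  length(sequences), replace = TRUE,
                  prob = c(r, 1 - sum(r)))
    out <- sequences
    for (j in which(cls == "short")) {
      keep <- sample(150:450, 1L)
      out[j] <- substr(out[j], 1L, min(keep, nchar(out[j])))
    }
    n_cont <- sum(cls == "contaminated")
    if (n_cont > 0L)
      out[cls == "contaminated"] <-
        contaminants[sample.int(length(contaminants), n_cont, replace = TRUE)]
    out[cls == "none"] <- ""
    names(cls) <- names(sequences)
    list(sequences = out, classes = cls)
  })
}

#' Write a synthetic community to disk
#'
#' Emits the specimen FASTA (ids are specimen ids), the metadata TSV and the
#' truth map TSV into `dir`.
#'
#' @param community A `synthetic_community`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "specimens.fasta")
  meta <- file.path(dir, "metadata.tsv")
  truth <- file.path(dir, "truth.tsv")
  write_fasta(community$sequences, fasta)
  write_tsv_file(community$specimens, meta)
  write_tsv_file(community$truth, truth)
  invisible(c(fasta = fasta, metadata = meta, truth = truth))
}
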