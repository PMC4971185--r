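# Low-level sequence utilities shared by the simulator, QC and distance code.

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

# Transition partner of each base; any other change is a transversion.
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

seq_chars <- function(seq) {
  if (length(seq) == 1L) strsplit(toupper(seq), "")[[1]] else toupper(seq)
}

#' Translate a nucleotide sequence under the invertebrate mitochondrial code
#'
#' Translates complete codons of `seq` starting at `frame` (0, 1 or 2 skipped
#' bases) using the invertebrate mitochondrial genetic code, in which TAA and
#' TAG are the only stop codons (TGA encodes tryptophan and AGA/AGG serine).
#' Trailing partial codons are ignored. Codons containing ambiguity codes
#' translate to `X`.
#'
#' @param seq Single nucleotide string (IUPAC codes allowed).
#' @param frame Integer offset in 0:2.
#' @return Character vector of one-letter amino acids (`*` marks a stop).
#' @export
translate_mito <- function(seq, frame = 0L) {
  ch <- seq_chars(seq)
  stopifnot(frame %in% 0:2)
  ch <- ch[(frame + 1L):length(ch)]
  n_codon <- length(ch) %/% 3L
  if (n_codon == 0L) return(character(0))
  ch <- ch[seq_len(3L * n_codon)]
  aa <- seqinr::translate(tolower(ch), numcode = 5, ambiguous = FALSE)
  aa[is.na(aa)] <- "X"
  aa
}

# Random stop-free coding sequence (frame 1) under the invertebrate
# mitochondrial code; `extra` additional bases pad a trailing partial codon.
random_coding_sequence <- function(n_codons, extra = 0L) {
  stops <- c("TAA", "TAG")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(.BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  tail <- if (extra > 0L) paste(sample(.BASES, extra, replace = TRUE),
                                collapse = "") else ""
  paste0(paste(codons, collapse = ""), tail)
}

# TRUE if substituting `base` at position `pos` (1-based) of the character
# vector `ch` creates an in-frame (frame 1) TAA/TAG stop codon.
.makes_stop <- function(ch, pos, base) {
  cstart <- pos - ((pos - 1L) %% 3L)
  if (cstart + 2L > length(ch)) return(FALSE)
  codon <- ch[cstart:(cstart + 2L)]
  codon[pos - cstart + 1L] <- base
  paste(codon, collapse = "") %in% c("TAA", "TAG")
}

#' Mutate a sequence by an exact number of substitutions
#'
#' Applies `n_subs` substitutions at distinct sites so that the result has
#' Hamming distance exactly `n_subs` from the input. Each substitution is a
#' transition with probability `ts_tv / (ts_tv + 1)` and otherwise a random
#' transversion, giving a configurable transition:transversion ratio
#' (default 2:1). Length is preserved; no indels are introduced.
#'
#' @param seq Single nucleotide string over ACGT.
#' @param n_subs Number of substitutions, `0 <= n_subs <= nchar(seq)`.
#' @param seed Integer seed; the same call is byte-reproducible.
#' @param ts_tv Transition:transversion odds (default 2).
#' @param avoid_stops If TRUE, substitutions that would create an in-frame
#'   (frame 1) stop codon under the invertebrate mitochondrial code are
#'   redirected to another base or site, so a stop-free input stays stop-free.
#' @return Mutated nucleotide string of the same length.
#' @export
mutate_sequence <- function(seq, n_subs, seed, ts_tv = 2, avoid_stops = FALSE) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n_subs < 0 || n_subs > n)
    stop("n_subs must be between 0 and the sequence length")
  if (!all(ch %in% .BASES))
    stop("mutate_sequence requires an unambiguous ACGT sequence")
  if (n_subs == 0) return(paste(ch, collapse = ""))
  with_rng(seed, {
    sites <- sample.int(n, n_subs)
    done <- 0L
    used <- rep(FALSE, n)
    used[sites] <- TRUE
    i <- 1L
    while (done < n_subs) {
      if (i > length(sites)) {
        # all candidate bases at some site were stop-forming; draw a new site
        free <- which(!used)
        s <- free[sample.int(length(free), 1L)]
        used[s] <- TRUE
        sites <- c(sites, s)
      }
      pos <- sites[i]
      orig <- ch[pos]
      ts <- .TRANSITION[[orig]]
      tv <- setdiff(.BASES, c(orig, ts))
      cand <- if (stats::runif(1) < ts_tv / (ts_tv + 1)) {
        c(ts, sample(tv))
      } else {
        c(sample(tv), ts)
      }
      if (avoid_stops)
        cand <- cand[!vapply(cand, function(b) .makes_stop(ch, pos, b),
                             logical(1))]
      if (length(cand) > 0L) {
        ch[pos] <- cand[1L]
        done <- done + 1L
      }
      i <- i + 1L
    }
    paste(ch, collapse = "")
  })
}

#' Bundled synthetic contaminant library
#'
#' Two deterministic synthetic stand-ins for the contaminant classes commonly
#' recovered in insect barcode surveys: a human-like and a proteobacterium-like
#' COI fragment. They are generated sequences, not GenBank records; their only
#' load-bearing property is being far (> 25 % divergence) from any simulated
#' insect community, which suffices for identity-threshold screening.
#'
#' @return Named character vector of two nucleotide sequences.
#' @export
contaminant_library <- function() {
  with_rng(424243L, {
    human <- random_coding_sequence(219L, extra = 1L)
    proteo <- random_coding_sequence(219L, extra = 1L)
    c(human_coi_synthetic = human, proteobacteria_coi_synthetic = proteo)
  })
}

#' Bundled COI reference frame
#'
#' A deterministic 658 bp synthetic reference for the barcode region with a
#' stop-free reading frame starting at position 1 (invertebrate mitochondrial
#' code). Sequences are placed onto this frame before distance computation.
#'
#' @return Single 658-character nucleotide string.
#' @export
coi_reference <- function() {
  with_rng(65865L, random_coding_sequence(219L, extra = 1L))
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector, names from FASTA headers, sequences in
#'   upper case. Empty sequences are preserved as "".
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = FALSE)
  out <- toupper(vapply(fa, function(s) as.character(s)[1], character(1)))
  out[out == "EMPTY"] <- ""  # placeholder used by write_fasta for no-sequence
  names(out) <- names(fa)
  out
}

#' Write sequences to FASTA
#'
#' Records with empty sequences (failed sequencing) are written with the
#' placeholder body `EMPTY` so their ids survive the round trip.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  body <- ifelse(nchar(seqs) == 0L, "EMPTY", seqs)
  seqinr::write.fasta(as.list(body), names = names(seqs), file.out = path,
                      nbchar = 80)
  invisible(path)
}

# TSV helpers: tab-separated, header, '.' decimal, UTF-8.
read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
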