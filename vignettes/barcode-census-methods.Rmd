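---
title: "Methods: a desk-scale DNA barcode census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale DNA barcode census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodecensus)
```

This vignette documents the statistical model behind `barcodecensus`,
the defaults every stage uses, the places where a desk-scale
implementation must deviate from production barcoding infrastructure,
and the known limitations — in particular the veiling bias of the
truncated-lognormal richness extrapolation.

## 1. The census model

A barcode census treats molecular clusters as species proxies:

1. **Triage.** Every specimen record is classified as BIN-compliant,
   short, contaminated, or no-sequence. Only BIN-compliant records
   proceed.
2. **Distances.** Pairwise Kimura-2-parameter (K2P) distances over
   shared unambiguous sites (pairwise deletion).
3. **Clustering.** Single linkage at a seed threshold, then a
   refinement pass that splits chained clusters across a barcode gap.
   The resulting clusters are BIN surrogates.
4. **Taxonomy.** A tiered cascade: unanimous expert identifications
   propagate to the whole cluster; unassigned clusters query the
   assigned ones by distance with a monophyly check on a
   neighbour-joining (NJ) validation tree; the remainder are exported
   for morphological work.
5. **Richness.** Cluster abundances are binned into Preston octaves, a
   Gaussian-in-octaves (truncated lognormal) is fitted, and its full
   integral extrapolates the expected richness past the veil line.
   Observed-vs-checklist bookkeeping (capture fractions, BIN/SP)
   complements the extrapolation.

The pipeline is driven by `run_pipeline()`; every stage is also an
exported function with its own tests.

## 2. The synthetic community generator

Real million-record surveys cannot be re-run on a desk. The generator
(`generate_community()`) reproduces the *statistical structure* the
downstream analysis relies on, with known ground truth:

- **Abundances.** Per-species expected abundances are lognormal;
  specimens are drawn multinomially. The default width is
  `abundance_log_sd = 1.4 * log(2)`: Preston's canonical community
  width of 1.4 octaves, converted to the natural-log scale. Using the
  canonical width means the richness-recovery experiments run on the
  community shape the octave method was designed for, rather than one
  tuned to make any particular test pass.
- **Barcode gap.** Species barcodes diverge from a per-genus ancestor
  by a uniform draw in `[0.03, 0.15]`; specimen sequences differ from
  their species barcode by at most `0.01 * 658` substitutions. Since
  intraspecific divergence (≤ 1%) sits well below the smallest
  congeneric divergence (≥ 3%, typically ≥ 6% between two congeners),
  the single-linkage threshold of 2.2% separates species cleanly —
  the generator realizes the barcode-gap assumption explicitly.
- **Artifacts.** Records are independently truncated (short), replaced
  with a contaminant-library sequence (contaminated), or emptied
  (none), at configurable rates, with the injected class recorded in
  the truth map.
- **Partial expert identification.** A configurable fraction of
  specimens carries species-rank expert labels; all specimens carry a
  truthful pre-sequencing order identification.

### Hierarchical, stop-free ancestors

Two generator decisions deserve explanation because simpler choices
silently break the pipeline's own invariants:

- **Stop-free coding sequences.** Uniform-random nucleotide ancestors
  contain internal stop codons in all three reading frames, so the QC
  frame check would excise *every* simulated record. Ancestors are
  therefore drawn as random stop-free codon strings under the
  invertebrate mitochondrial code (TAA/TAG the only stops), and
  `mutate_sequence(avoid_stops = TRUE)` redirects any substitution that
  would create an in-frame stop — while preserving the exact Hamming
  distance contract.
- **Hierarchical divergence.** Independent random ancestors per genus
  would sit near 75% divergence from each other, past the K2P
  saturation point, making inter-genus distances incomputable (the K2P
  log arguments go non-positive). Ancestors are instead derived
  hierarchically (root → order → family → genus at 4% per level), which
  bounds every pairwise divergence below saturation and gives the NJ
  validation trees genuine phylogenetic signal to work with.

## 3. Stage defaults and their rationale

| parameter | default | rationale |
|---|---|---|
| `min_length` | 500 bp | the conventional compliance length; 487 bp is also in circulation, so the threshold is a config parameter rather than a constant |
| `max_n_fraction` | 1% | standard uncertain-base ceiling |
| `contaminant_identity` | 0.95 | anchored identity to a contaminant reference |
| `min_shared` | 300 sites | minimum overlap for a pairwise K2P distance; a declared default, not a published constant |
| `linkage_threshold` | 0.022 | conventional BIN seed threshold |
| `refine_gap` | 0.042 | minimum between-group distance for a refinement split |
| `genus_threshold` / `family_threshold` | 0.05 / 0.10 | identification-engine distance ceilings for genus and family placement |
| `misplacement_k` | 5 | a leaf is flagged when its 5 nearest tree neighbours unanimously carry a different order |

The contaminant library bundled with the package contains two
*synthetic* stand-ins (a human-like and a proteobacterium-like COI
fragment). They are generated sequences, not database records; the only
property the QC stage needs is that they are far (> 25% divergence)
from any community sequence, which holds by construction.

Full profile-HMM alignment is replaced by translated anchor placement
(`map_to_reference()`): the insect barcode region is effectively
indel-free, so trying every ungapped offset and validating the reading
frame of the best amino-acid-identity placement reproduces the HMM's
role at desk scale. A placement whose best frame still contains
internal stops is rejected as a frame shift.

### Refinement

`refine_clusters()` splits a cluster into two groups when the smallest
between-group distance exceeds `refine_gap` *and* both within-group
maxima fall below that between-group minimum, recursively. The
implementation takes the top single-linkage split as the candidate
partition; this is equivalent to searching all 2-partitions, because a
valid gap split is necessarily the final single-linkage merge (every
within-group pair sits below the between-group minimum, so each group
is internally connected before the groups join). The test suite checks
this equivalence by brute-force enumeration of all 2-partitions on
small clusters.

### Neighbour joining

`build_nj_tree()` is a classic Q-criterion NJ with two determinism
guarantees: ties in the Q matrix are broken by the lexicographically
smallest pair of subtree labels, and negative branch lengths are
clamped to zero with the deficit transferred to the sibling branch so
path lengths through the new node are preserved. On additive matrices
the reconstruction is exact (topology and branch lengths); the suite
verifies this against `ape::nj` and `phangorn::RF.dist` on random
trees.

## 4. The octave fit

`octave_histogram()` bins abundance *n* into octave `floor(log2 n)`;
exact powers of two lie on an octave boundary and are split
half-and-half between the adjacent octaves. Two conventions for
singletons (*n* = 1) are supported:

- the default counts singletons fully in octave 0;
- `singleton_split = TRUE` treats them like every other boundary case,
  half in octave 0 and half in octave −1 — the class just past the veil
  line. This is Preston's original boundary treatment and the one used
  by the conventional fitting routines (`vegan::prestonfit` splits
  singletons the same way, one octave over); the extrapolation path
  (`extrapolate_richness()`, the pipeline) uses it. Counting singletons
  fully in octave 0 inflates the first visible octave and overshoots
  the extrapolated total by ~50% at moderate coverage.

`fit_lognormal()` fits `S(R) = S0 * exp(-(R - R0)^2 / (2 sigma^2))` and
reports `S_total = S0 * sigma * sqrt(2 * pi)`. Two methods are exposed:

- **`poisson_glm`** (default): a quasi-Poisson log-link regression of
  counts on a quadratic in the octave number, converted to
  `(S0, R0, sigma)`. The Poisson variance function anchors the fit at
  the well-observed mode, which is what makes octave fits stable under
  veiling; this is the computation performed by the standard
  `prestonfit` routine, and the two agree to machine precision in the
  cross-check tests.
- **`least_squares`**: unweighted nonlinear least squares with moment
  initialization. It gives every octave equal standing and is markedly
  unstable on strongly veiled histograms (relative errors of 100x and
  more in our measurements, because nothing anchors the unobserved
  mode). It is kept as an exposed option for complete, well-sampled
  histograms, where both methods agree.

## 5. Known limitations

- **Veiling bias.** The truncated-lognormal extrapolation
  systematically *underestimates* total richness when sampling is
  shallow. At the canonical community width, median relative error of
  `S_total` is about −45% at 50% species coverage, −31% at 63%, and
  −20% at 75%; only above roughly 75% coverage does the median error
  drop below 20%. This is a property of the estimator, not of this
  implementation: `vegan::prestonfit` produces identical numbers on the
  same draws, and its maximum-likelihood variant is slightly worse. The
  acceptance suite asserts a 20% median-error bound over the 50–80%
  coverage band and that assertion fails, deliberately and honestly.
  The direction of the bias is stable (negative), and the
  *undersampling percentage is monotone*: on the same community,
  deeper sampling reduces `pct_undersampled` (median over seeds), so
  the statistic ranks sampling depth correctly even where its absolute
  value is conservative.
- **No indel simulation.** The generator emits frame shifts only
  through the QC fixtures, not as a configurable artifact class; real
  trace data contains them at unknown rates.
- **Synthetic contaminants.** The bundled contaminant library is
  generated, not sourced from sequence databases; identity-threshold
  screening behaves identically, but real surveys should supply their
  own references via `run_config(contaminants = ...)`.
- **Desk-scale problem sizes.** Default test and example communities
  run at 10^2–10^4 specimens. All stages are vectorized (the distance
  matrix is computed by one-hot crossproducts, not per-pair scans), but
  the package makes no claim to million-record throughput.

## 6. Reproducibility

Every stochastic component runs under a seed wrapper that restores the
caller's RNG state; `(params, seed)` reproduces a community byte for
byte, and a `run_config(seed = ...)` reproduces a full pipeline run,
whose configuration is serialized beside its outputs. The
`scripts/acceptance.R` program (see README) recomputes the package's
headline quantities from a single `--seed`.
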