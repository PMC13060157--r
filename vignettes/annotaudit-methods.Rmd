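---
title: "annotaudit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{annotaudit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Claims that an mRNA carries an unusually long 5' UTR — and, downstream of
that, that the extra sequence harbours an internal ribosome entry site
(IRES) — stand or fall on whether the annotated transcription start site
(TSS) is real. `annotaudit` packages the computational checks needed to
audit such claims from primary data: full-length long-read cDNA (Iso-Seq
style), cap-selective CAGE 5'-end data, smFISH images, and polysome qPCR.
Every stage also has a seed-deterministic synthetic generator, so the whole
pipeline is testable offline against planted truth.

# Read preparation

Full-length cDNA reads carry a template-switching oligo (TSO) at the
cap-proximal end, the transcript body, a polyA tail and the reverse
complement of the RT primer. `select_full_length()` reproduces the logic of
adapter-based full-length selection:

* **TSO matching** (`locate_tso()`) is an error-tolerant semi-global
  alignment: the full 21-nt TSO may occur anywhere (everything 5' of it is
  trimmed with it), or a TSO *suffix* of at least `min_overlap = 15` nt may
  hang off the read start. The error budget is
  `floor(max_error_rate * overlap)` with `max_error_rate = 0.1`; indels are
  allowed and `N` never matches anything. The same search runs on the
  reverse complement for antisense evidence. Ties are resolved by lower
  edit distance, then sense over antisense, then the 5'-most span, then the
  larger overlap. These internals are a design choice: the published
  trimming step fixes the sequences, the 15-nt overlap and the
  discard-without-adapter behaviour, but not the matcher itself. The unit
  and acceptance tests pin the semantics against an independent exhaustive
  enumeration oracle.
* **Orientation**: reads whose best TSO match is antisense are
  reverse-complemented; reads with *valid matches in both orientations* are
  treated as putative chimeras and discarded separately (ambiguous
  orientation would corrupt 5'-end tracks). Reads with no match are
  discarded and counted (`n_input = n_kept + n_discarded_no_tso +
  n_chimeric`).
* **polyA** (`detect_polya()`): the 3'-most run of >= 8 A's with at most 1
  non-A base, searched in the terminal 50 nt, run ends anchored on A. The
  tail is recorded as metadata only and never trimmed — the downstream
  spliced aligner soft-clips it.

# 5'-end tracks and isoform counting

`five_prime_ends()` increments a strand-specific single-nucleotide counter
at each alignment's 5'-most genomic base (first base of the first block on
`+`, `end - 1` of the last block on `-`), the single-base-offset coverage
convention of the cited track-building step. Coordinates are 0-based
half-open throughout; bedGraph files round-trip through `rtracklayer`.
Secondary and supplementary alignments are excluded by default (one 5' end
per molecule). A raw track whose counts sum to its library size can be
rescaled once to reads-per-million with `to_rpm()`; a track restricted to a
sub-region keeps the genome-wide library size, so the constructor enforces
`sum(counts) <= library_size` and equality is asserted for generated
genome-wide tracks in the tests.

`assign_to_models()` replaces a manual read-sorting step with an explicit
rule: a read is compatible with a transcript model iff strand and
chromosome agree, its intron chain is a contiguous sub-chain of the model's
chain with both ends of every junction within `junction_tolerance`
(default 0; up to ~5 nt is reasonable for noisy aligners), and its blocks
lie within the model's exonic span. Mono-exonic reads assign by containment
without overlapping any model intron. Reads compatible with `k` models
count `1/k` toward each — fractional splitting is a design choice; the
manual procedure it replaces did not specify tie handling, and discarding
ambiguous reads would bias against isoforms that share sub-chains.

# TSS concordance

For each distinct (chromosome, strand, TSS) triple among the models,
`concordance_table()` takes the window `tss - flank .. tss + flank`
(default `flank = 500`, hence 1001 positions including the TSS base — the
"1 kb window" of the figure legends), reads both tracks' per-base counts
5'->3' relative to the transcript strand, and computes:

* window totals and per-track RPKM — the window (1001 nt) is the length
  denominator and each track's own library size the million-scale; the
  source analysis does not define its RPKM denominator, so this is fixed
  here for reproducibility;
* Pearson's R at 1-nt resolution (`r_1nt`) and on 5-nt sliding-window sums
  (`r_5nt`). Windows where either vector has zero variance are flagged
  `valid = FALSE` rather than given r = 0: Pearson is undefined there.

Records where *either* track's RPKM is below `min_rpkm = 1` are removed
(the published filter names a threshold but not which dataset; requiring
both to pass is the symmetric choice). Isoform windows sharing a TSS are
deduplicated into one record. `summarize_by_expression()` bins valid
records by `log10` of the mean of the two window totals (expression proxy
chosen once; the alternative, RPKM, is a monotone transform of the same
quantity here) and reports per-bin medians and quartiles, the boxplot
statistic of the genome-wide figure.

`pearson_r()` short-circuits exactly identical vectors to 1: the
self-concordance acceptance property asserts exact equality, and the
product-moment formula returns 1 - O(eps) on identical input.

# smFISH

The published spot detection used a plugin whose internal pipeline is not
described beyond its settings (pairing distance 2 px, minimum size 3 px,
minimum intensity 20 SD, DAPI threshold 35-255). `detect_spots()`
implements a documented approximation with those parameters mapped
one-to-one: light Gaussian pre-smoothing (`smoothing_sigma = 0.4` px),
robust background statistics (median and 1.4826 x MAD over the plane, with
a plain-SD fallback when the MAD is zero, as on a synthetic zero
background), threshold at `mu + 20 * sigma`, 8-connected component
labelling, area filter, and intensity-weighted sub-pixel centroids. The
0.4-px default keeps a high-SNR 3x3 block detected as exactly its 9 pixels
on a standard 256x256 field; heavier smoothing bleeds the threshold over
the block edges, and on fields much smaller than ~128 px the SD fallback
couples the threshold to the block amplitude, so the exact-area behaviour
is only asserted at the generator's field size.

`nucleus_mask()` is an inclusive band threshold (35 <= pixel <= 255 on the
8-bit-equivalent DAPI scale), with optional hole-filling; no morphology by
default. `classify_localization()` looks the mask up at the half-up-rounded
centroid pixel. `colocalize()` greedily pairs globally closest spots within
2 px, each spot at most once; under the generator's 4-px minimum spot
separation the pairing graph has degree <= 1 and greedy matching is
provably optimal, which the acceptance tests confirm against brute force.
The plugin's "oval" pairing semantics are unpublished; centroid distance is
the documented approximation.

# Polysome qPCR and reporter plates

`fraction_abundance()` uses the anchored delta-CT form: per (amplicon,
technical replicate), with `m` the maximum CT across fractions, relative
abundance is `2^(m - ct)`, so the least abundant fraction is exactly
`2^0 = 1` and percents are `100 * abundance / sum(abundance)`. The printed
formula in the source methods (`2^(-CT - max(deltaCT))`) is internally
inconsistent with its own prose anchor; the anchored form reproduces the
stated behaviour exactly and is invariant to adding a constant to all CTs
of a replicate. NTC wells are excluded; missing fractions stay missing
rather than becoming zeros — no amplification at 40 cycles is censoring,
not absence. `reporter_ratios()` subtracts mean per-channel background from
untransfected wells and reports N-luc/F-luc per replicate, excluding
replicates whose background-subtracted F-luc is non-positive.

# The synthetic world

The generators state one fixed world rather than tunable difficulty:

* **TSS profiles** (`simulate_tss_profiles()`): transcripts every 3000 nt
  on one chromosome, alternating strands; a dominant start carrying 0.75 of
  the mass plus 4 satellites within 12 nt with geometrically decaying
  weights — the "sharp dominant start" regime of real CAGE-confirmed
  promoters. Per-transcript expression is log-uniform over two decades, the
  range across which concordance is binned. Bodies are 1500 nt and
  intron-less by default; concordance never inspects intron structure, and
  intron-chain assignment is exercised by its own planted models.
* **Reads** (`simulate_reads()`): TSO + body (sampled TSS to transcript 3'
  end) + 30-nt polyA + RT-primer remnant. RT drop-off is a geometric(0.02)
  5'->3' shift (mean ~50 nt, a smeared downstream tail clearly
  distinguishable from a sharp TSS), applied to a configurable fraction of
  reads; antisense and adapterless fractions emulate orientation and
  adapter failures. Every choice lands in a truth table, and a test replays
  each truth row into the emitted read byte-for-byte.
* **CAGE tracks** (`simulate_cage_track()`): multinomial 5'-end counts over
  the profile weights — no drop-off process, mirroring the cap-selective
  chemistry's immunity to it.
* **Images** (`simulate_image()`): three disc nuclei (DAPI 180 on an
  8-bit-like scale, background 8, optional chromocenters), Gaussian puncta
  of amplitude 500 over N(100, 10) background (50x SNR), sigma 0.8 px,
  minimum 4-px separation, planted >= 2.5 px clear of compartment
  boundaries so rounded centroids cannot cross. What a green planted-truth
  test does **not** establish: performance on real tissue images with
  autofluorescence, uneven illumination, overlapping cells, or spots at
  2-5x SNR; the detector's parameters are exposed precisely because those
  regimes need them.
* **CT tables** (`simulate_ct()`): `CT = ct_at_unit_abundance -
  log2(abundance) + N(0, sd)`, bounded to (0, 40].

All generators restore the caller's RNG state and are byte-identical under
a fixed seed.

# Numerical choices and degenerate inputs

* Zero-variance correlation windows: flagged invalid, never r = 0.
* Adapter and polyA matching: `N` counts as a mismatch, including N-N.
* Spot centroids: intensity-weighted on background-subtracted smoothed
  intensities; mask lookup rounds half-up (`floor(x + 0.5)`), not
  round-half-even.
* Truncation shifts that reach or exceed the body length drop the read and
  log it rather than emitting an empty body.
* `to_rpm()` refuses RPM input; `concordance_table()` refuses RPM tracks
  because RPKM needs true library sizes.
* Windows clipped by a contig edge are excluded and counted, not padded.

# Known limitations

* The package consumes spliced alignments (BAM); it does not align. The
  synthetic path converts truth tables directly to single-block alignments,
  so aligner-induced 5'-end jitter is not modelled (the configurable
  `junction_tolerance` exists for exactly that reason on real data).
* TIFF I/O is out of scope in this build (no TIFF codec in the supported
  dependency set); images are exchanged as plain-text pixel matrices via
  `write_image_tsv()` / `read_image_tsv()`.
* Reproducing the source study's printed smFISH percentages requires its
  original image files, which are not redistributable here; the smFISH
  module is validated on planted truth instead.
* No qPCR efficiency modelling: the delta-CT method assumes doubling per
  cycle, as the audited analysis did.
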