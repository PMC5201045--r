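---
title: "Differential binding classes and regulatory motif grammar with peakgrammar"
author: "peakgrammar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential binding classes and regulatory motif grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakgrammar)
```

# Scope and model

`peakgrammar` implements the computational core of an integrative
regulatory-genomics analysis of transcription-factor dynamics in hemogenic
endothelium: how AP-1 (FOS/JUN) and TEAD4 binding change when AP-1 is
blocked by a dominant-negative FOS peptide, and what sequence grammar —
co-occurring, footprinted motifs at fixed oriented spacings — underlies the
AP-1-dependent sites. Upstream steps (read alignment, peak calling,
footprint detection, de-novo motif discovery) are out of scope; peaks,
footprints and tag positions are inputs, and known position weight
matrices replace discovered motifs.

The pipeline has four analytical layers:

1. **Differential binding classes.** Tags are counted in a ±`flank`
   (default 1000 bp) window around each peak summit, binned at
   `bin_width` (50 bp). Per-region totals are normalised to tags per 10
   million, a pseudocount (1.0) is added, and the log2 fold change of
   condition B over A is thresholded at ±1 log2 unit: class 1 "lost"
   (`log2fc <= -1`), class 3 "gained" (`log2fc >= +1`), class 2 "shared"
   otherwise. The boundary belongs to the extreme classes, making
   "shared" an open interval — with ties at exactly the cutoff this is a
   convention, stated rather than consequential.

2. **Peak-to-gene annotation and overlap statistics.** Each peak's
   reference point (summit if known, else the integer midpoint) is
   assigned to the nearest TSS; ties go to the lower TSS coordinate, then
   the lexicographically smaller symbol. Signed distances are positive
   downstream of the TSS in the gene's reading direction. Interval-set
   overlaps are tested with an upper-tail hypergeometric p-value,
   `P(X >= k)` for `N` population regions, `K = |a|`, `n = |b|`. The
   population size is a genuine modelling choice the upstream literature
   leaves implicit; our default divides the effective genome length by
   the mean interval width of the union of the two sets, and any value
   can be supplied instead.

3. **Motif grammar.** PWMs are count matrices with a pseudocount
   (log-odds in bits against a uniform background); scanning reports
   every window on either strand scoring at least 80% of the maximum
   attainable score, skipping windows containing N. Co-occurrence of
   footprinted motifs is measured as the number of occupied hit pairs
   whose match centers lie within 50 bp, and referenced against 1000
   equally sized without-replacement subsamples of background regions:
   `z = (obs - mean)/sd` of the subsample counts. Composite spacing is
   the oriented distance from anchor motif to partner motif, by default
   end-to-start in the anchor's reading direction; a configuration
   switch (`spacing_anchor = "start_to_start"`) selects the
   start-to-start variant, since the two conventions differ only by the
   anchor width and the source material uses both descriptions. Ties for
   the modal spacing resolve to the smallest absolute distance, then the
   more upstream value.

4. **Expression integration.** Replicates are averaged on the log2 scale
   before fold changes (a deliberate simplification of a moderated-t
   pipeline; we filter on mean fold change only). "At least twofold" is
   inclusive: `|log2fc| >= 1` at the default threshold. Gene-profile
   clustering uses Lloyd's k-means (Euclidean distance, best of 10
   restarts by within-cluster sum of squares; k = 7 for bound-gene
   clustering, k = 15 for differential-gene clustering), with an option
   to standardise rows first, which makes Euclidean distance equivalent
   to centered-correlation distance up to a monotone transform. We call
   `stats::kmeans` rather than re-implementing Lloyd's algorithm; its
   empty-cluster handling (drop with a warning) differs from
   re-initialising to the farthest point, but with 10 restarts at the
   package's problem sizes empty clusters do not occur. Per-class
   expression shifts are tested with a two-sided Wilcoxon rank-sum test
   of each class against the pooled rest, exact when both group sizes
   are at most 12.

# The synthetic landscape and what it does (not) emulate

`landscape_spec()` + the three `simulate_*()` stages generate a complete
landscape with planted ground truth, so every stage of the pipeline is
testable without external data. The defaults are the study conditions
the pipeline is designed to recover:

| parameter | default | meaning |
|---|---|---|
| `n_peaks`, `tags_per_peak` | 1000, 200 | peaks and expected tags/peak/condition |
| `class_proportions` | 0.30/0.65/0.05 | lost/shared/gained mix |
| `class_log2fc` | -3/0/+3 | planted rate multipliers (log2) |
| `tag_sd` | 150 bp | Gaussian tag spread around the summit |
| `plant_probs` | AP-1: lost only (0.9); TEAD: all classes (0.9) | class-specific motif planting |
| `composite_spacing`, `spacing_noise` | 7 bp, ±1 | oriented TEAD→AP-1 spacer |
| `n_footprints_fg`, `n_footprints_bg` | 500, 10000 | region pools for the bootstrap |
| `region_width`, `motif_prob` | 500 bp, 0.3 | DHS-like regions and occupancy fraction |
| `expr_k`, `dox_effect`, `noise_sd` | 7, -1.5, 0.25 | expression clusters, perturbation effect, replicate noise |

Generator design choices worth knowing about:

* **Consensus instances.** Planted motif instances carry the consensus
  sequence; the count matrix's softness affects scoring only. Sampling
  instance bases from the PWM columns would make single mismatches (15%
  per base at the shipped matrices) drop below any useful scan
  threshold, so planted presence structure would be unrecoverable — a
  property of threshold scanning, not of the data model we want to test.

* **Spacer jitter.** "±1 bp noise" is triangular (0.15/0.70/0.15 over
  -1/0/+1), so the planted spacing is the unambiguous histogram mode;
  uniform jitter would make the mode a three-way coin flip.

* **Balanced occupancy.** Each motif occupies an exact `motif_prob`
  fraction of each region pool (membership random). With independent
  Bernoulli inclusion, the pool-level motif-count fluctuations are
  invisible to a null that resamples regions, and the across-pair mean
  of null z-scores drifts by ±0.2 or more between landscape
  realisations. With balanced occupancy the foreground totals are fixed
  and subsample counts are, if anything, slightly over-dispersed, so the
  bootstrap z is conservatively calibrated by construction.

* **Background pool 10x the subsample.** Equally sized
  without-replacement draws from a pool only a few times larger than the
  draw understate the foreground's sampling variance by the
  finite-population factor `1 - n/N`; at `n/N = 0.05` the residual
  inflation of z is under 5%.

* **One footprint per foreground region** (the padded span of its
  occupied instances, or the whole region when it has none), so a
  background draw of `|fg|` regions is exchangeable with the foreground
  under the null — emitting one footprint per instance would make the
  draw size incomparable.

* **Gene placement.** Each gene's TSS sits 500 bp from its peak's
  summit, half the inter-peak spacing, so nearest-TSS annotation
  recovers the planted peak–gene link deterministically.

What the generator does **not** emulate: mappability and GC biases,
duplicate reads and fragment-length effects, overlapping/nested peaks,
motif degeneracy at planted sites, correlated motif occupancy,
chromatin-state-dependent backgrounds, and probe-level microarray noise.
Passing the planted-truth suite therefore demonstrates the correctness
of the computations, not robustness to every artefact of real ChIP-seq
or DNaseI-seq data.

# Numerical conventions

* Coordinates are 0-based half-open (BED) at every interface; GRanges
  (1-based) only internally.
* Bins are half-open, so a tag exactly at the summit falls in the
  center-right bin.
* A hit counts as present in a region only when fully contained (flush
  edges count); a hit is "occupied" when its match merely overlaps a
  footprint.
* `sd = 0` in the bootstrap with `obs == mean` gives `z = 0`; with
  `obs != mean` the z is flagged infinite rather than invented. For the
  clustered ordering of the z matrix (average-linkage hierarchical
  clustering, Euclidean distance), infinite entries are capped at twice
  the largest finite magnitude — the cap affects ordering only, never
  reported values.
* All randomness flows from a single integer seed; the three simulation
  stages use `seed`, `seed + 1`, `seed + 2` so stages can be re-run in
  isolation. Identical spec + seed gives byte-identical output files.
* An undefined spacing mode (no pair in range) is reported as `NA` with
  an explicit flag, never as 0.

# Problem sizes used in the shipped checks

The test suite exercises the full default landscape (1000 peaks at 200
expected tags, 500 foreground vs 10,000 background regions, 15 motif
families = 105 motif pairs, 1000 subsamples, 350 genes x 28 samples)
once, and smaller landscapes (about 100 peaks, 60/400 regions) for
per-module properties. These sizes give the planted effects comfortable
detection margins (classification accuracy ~100%, planted-pair z in the
hundreds, cluster recovery ARI 1.0) while each property remains cheap to
recompute.

# Known limitations

* The hypergeometric overlap test treats regions as exchangeable balls;
  it ignores interval lengths and clustering, as does the upstream
  convention it follows.
* The co-occurrence statistic counts hit pairs, not footprints; two
  dense clusters of hits inflate the count quadratically. The
  within-50-bp pairing of the source analysis is ambiguous on this
  point; pair counting is our declared convention.
* The twofold expression filter on replicate means is not a moderated
  test; at duplicate-level replication its false-discovery behaviour is
  that of a fold-change filter, nothing stronger.
* Scanning with a fixed fraction-of-maximum threshold does not model
  binding-energy distributions; thresholds are comparable within a PWM
  but not across PWMs of different information content.
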