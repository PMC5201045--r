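# peakgrammar

Differential ChIP-seq binding classes and regulatory motif grammar, for
researchers studying how transcription-factor occupancy reorganises under
a perturbation — here modelled on AP-1 (FOS/JUN) and TEAD4 in hemogenic
endothelium, where blocking AP-1 DNA binding removes a defined class of
TEAD4 sites and the genes they drive.

The package covers four linked analyses:

1. **Lost/shared/gained peak classification.** Tags are counted in
   ±1000 bp summit-centered windows, normalised to tags per 10 million,
   and peaks are ranked by `log2(B/A)` with a pseudocount. Classes are
   cut at ±1 log2 unit:
   class 1 *lost* (`log2FC ≤ −1`), class 2 *shared*, class 3 *gained*
   (`log2FC ≥ +1`), with class-average signal profiles.
2. **Peak-to-gene annotation and overlap statistics.** Nearest-TSS
   assignment with signed distances, 2–3-way Venn partitions, and
   hypergeometric overlap p-values `P(X ≥ k)` for
   `X ~ Hypergeom(N, K=|a|, n=|b|)`.
3. **Motif grammar.** PWM log-odds scanning on both strands
   (`score ≥ 0.8 × max`), motif-presence matrices, co-occurrence of
   footprinted motifs within 50 bp scored as a bootstrap Z against 1000
   equally sized without-replacement subsamples of background regions
   (`z = (obs − mean)/sd`), and oriented composite-motif spacing
   histograms (anchor end → partner start in the anchor's reading
   direction) whose mode recovers fixed spacers such as the 7 bp
   TEAD–AP-1 arrangement.
4. **Expression integration.** Inclusive "at least twofold" filters on
   mean log2 fold changes, k-means clustering of gene profiles (Lloyd,
   k = 7 or 15), and per-peak-class expression shifts tested by Wilcoxon
   rank-sum against the pooled rest.

A first-class synthetic-landscape generator (`landscape_spec()`,
`simulate_regulatory_landscape()`, `simulate_footprints()`,
`simulate_expression()`) plants ground-truth peak classes, motif
co-occurrence, a spaced composite motif and expression effects, emitting
exactly the FASTA/BED/TSV formats the analysis consumes plus a JSON
ground-truth sidecar — so the whole pipeline is testable end to end
without external data.

## Worked example

```r
library(peakgrammar)

cfg <- analysis_config(seed = 7, outdir = "demo_out")
run_pipeline(cfg, "all")   # simulate + classify + annotate + scan +
                           # cooccur + spacing + cluster-expr + report
```

`demo_out/report.txt` then reads:

```
peaks: 1000
class counts (lost/shared/gained): 298/637/65
class fractions: 29.8%/63.7%/6.5%
top co-occurring pair: AP1-TEAD (z = 143.09)
modal composite spacing: 7 bp
per-class expression fold change (median [Q1, Q3], p vs rest):
  gained: 0.01 [-0.03, 0.08], p = 0.00754
  lost: -1.49 [-1.56, -1.43], p = 4.31e-43
  shared: -0.00 [-0.07, 0.06], p = 7.54e-31
```

Reading this: the generator planted 30%/65%/5% lost/shared/gained peaks
and the classifier recovers 29.8/63.7/6.5; the planted AP-1–TEAD
co-occurrence dominates the bootstrap Z matrix (z ≈ 143 against a null of
1000 background subsamples); the planted 7 bp oriented spacer is the
modal spacing; and only genes linked to *lost* peaks show the planted
−1.5 log2 expression drop (median −1.49, rank-sum p ≈ 4e−43 — the small
p-values of the other classes reflect their medians differing from the
pooled rest, which contains the shifted lost class).

Individual stages are plain functions (`summit_matrix()`,
`fold_change_classify()`, `annotate_nearest_gene()`, `scan_sequence()`,
`cooccurrence_zscores()`, `spacing_distribution()`, `diff_genes()`,
`kmeans_cluster()`, `class_expression_test()`), and a thin CLI wrapper
ships in `inst/scripts/peakgrammar`
(`peakgrammar <mode> --config FILE --seed N --outdir DIR`).

## Methods

See the methods vignette, `vignettes/regulatory-grammar.Rmd`, for the
model, parameter meanings and defaults, the generator's design choices,
numerical conventions, and known limitations.
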