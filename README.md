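# posmap

Positional RNA-binding-protein motif maps around differentially used exons.

## The problem

Splicing factors such as QKI bind short degenerate RNA elements (for QKI the
ACUAAY element, `Y = C/U`) in the introns flanking cassette exons, and the
*side* of binding determines the outcome: motifs concentrated downstream of
an exon mark exons the factor **activates** (they are skipped when the factor
is lost), motifs upstream mark exons the factor **represses** (they are
included when the factor is lost). `posmap` implements the desk-scale
workflow a transcriptomics group uses to establish such a positional map
from exon-bin count data, and bundles a fully seeded simulator with planted
ground truth so every stage is testable without downloads.

The package is aimed at analysts studying splicing regulators in bulk
RNA-seq designs (e.g. knockout vs wild type), and at methodologists who need
a transparent, calibrated reference implementation of the positional-map
analysis.

## What it computes

**Differential exon usage.** For exon *i* of gene *g*, usage in a group is
the pooled exon count over the pooled gene count, `u = a / n`. Each exon is
tested with a two-sided 2×2 exact test of (exon vs rest-of-gene) × (group),
and the usage change is the ε-shrunk log fold change

```
LFC_i = log2( (u_KO + ε_KO) / (u_WT + ε_WT) ),   ε = 0.5 / pooled gene count.
```

Exons with host-gene TPM ≥ 0.5, |LFC| ≥ 1 and BH-adjusted p ≤ 0.05 are
called differentially used; `LFC < 0` ⇒ regulator-activated, `LFC > 0` ⇒
regulator-repressed.

**Windowed motif enrichment.** Around each significant exon (and an equal
number of expressed, non-significant background exons) the package extracts
four transcript-sense windows — 200 nt of each flanking intron plus 10 nt
inside each exon edge — and scans an ATtRACT-style IUPAC motif collection.
Each motif gets a one-sided 2×2 exact test of per-exon presence
(foreground vs background), a Haldane-corrected odds ratio, BH adjustment
and a rank.

**Positional mode.** For each exon class the per-exon normalized motif count
upstream (`U`) and downstream (`D`) yields the asymmetry index

```
A = (D − U) / (D + U)
```

with `A > τ` the activator pattern, `A < −τ` the repressor pattern
(default τ = 0.2).

**Isoform dynamics.** Utilities compare two analyses (gene-set overlap,
fold-change correlation and slope, per-cohort z-scoring) and detect exons
that *revert* to a reference (embryonic) usage state after regulator loss.

## Worked example

The demo pipeline simulates 60 five-exon genes (3 vs 3 samples, usage effect
2, ACUAAY planted downstream of activated and upstream of repressed exons)
and analyses them against 50 decoy motifs:

```r
library(posmap)
man <- run_pipeline(pipeline_config(outdir = "demo_out", seed = 1))
pipeline_report(man)
```

```
posmap pipeline summary (seed 1)
  exons tested: 300 | significant: 144 (activated 88, repressed 56)
  top enriched motifs:
   rank rbp_name  iupac  odds_ratio      p_value         padj
1     1      QKI ACUAAY 1041.317460 1.054622e-51 5.378570e-50
2     2 DECOY016  TCRAD    6.907973 4.622175e-07 1.178655e-05
...
  positional mode calls:
        class   upstream downstream  asymmetry              mode flagged
1   activated 0.09090909 1.32954545  0.8720000 activator-pattern   FALSE
2   repressed 1.41071429 0.12500000 -0.8372093 repressor-pattern   FALSE
3 independent 0.13888889 0.08333333 -0.2500000 repressor-pattern   FALSE
```

Reading the output: all 144 planted exons pass the thresholds; the planted
QKI element is the top-ranked motif by a wide margin (odds ratio ~1000 vs
< 7 for the best decoy); and the asymmetry indices recover the positional
logic — motifs pile up downstream of activated exons (A = +0.87) and
upstream of repressed exons (A = −0.84). The independent (background) class
has only chance hits; its weak asymmetry illustrates why the τ threshold
exists. The same run is available from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml \
    --outdir demo_out --seed 1 --report
```

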