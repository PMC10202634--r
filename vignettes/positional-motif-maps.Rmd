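---
title: "Positional motif maps of splicing regulators: models and design"
author: "posmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional motif maps of splicing regulators: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posmap)
```

## The scientific question

Many RNA-binding proteins regulate cassette-exon inclusion in a
position-dependent way: the same factor acts as an activator when bound on
one side of an exon and as a repressor when bound on the other. For the
STAR-family factor QKI, whose binding element is ACUAAY, motifs downstream
of an exon are associated with activation (the exon is skipped when the
factor is removed) and motifs upstream with repression (the exon is included
upon removal). `posmap` implements the analysis that establishes such a map
from exon-bin counts: differential exon usage, classification into
activated/repressed sets, windowed motif enrichment against a matched
background, and an upstream/downstream asymmetry statistic that names the
mode. A bundled simulator with planted truth makes every stage falsifiable.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_dataset()` is
deterministic given the configuration.

**Genome and annotation.** Each gene occupies its own chromosome (100 nt
pads), with exon and intron lengths drawn uniformly from configured ranges
and strands alternating so that strand handling is exercised everywhere.
Background sequence is i.i.d. with configurable GC (default 0.42, a typical
mammalian intron value). Chance motif hits therefore occur at the background
rate — tests must compare planted against background rates, never assert
zero background.

**Planted truth.** A fraction (default 0.8) of internal exons receives a
usage shift plus one concrete realization of the IUPAC motif (realization
chosen uniformly among expansions, so degenerate matching is exercised),
written transcript-sense at a fixed offset (default 50 nt) into the flanking
intron. The side follows the positional rule: usage-down exons
(regulator-activated) plant downstream, usage-up exons (repressed) plant
upstream. On minus strands the reverse complement is written at the mirrored
genomic locus.

**Counts.** Per gene and sample a negative-binomial total (mean 5000,
dispersion 0.05 — values typical of a deeply sequenced bulk design with
moderate biological replication) is split across exon bins by a multinomial
draw. This construction makes "usage" well defined and exactly recoverable:
the group-specific share of a planted exon is `u0 * 2^(±effect/2)` with
`u0 = min(0.12, 0.3 * 2^(-effect/2))`, so the group-2/group-1 usage ratio is
`2^(-effect)` for direction *down* and its reciprocal for *up*, while both
shares stay safely inside the simplex. Unplanted exons split the remaining
mass evenly. Planted directions alternate within a gene so the planted usage
mass stays balanced between groups and compensatory shifts on unplanted
exons remain small; the generator refuses configurations whose planted mass
would exceed 0.9 of a gene. Library-size heterogeneity is limited to a
uniform per-sample scale factor (0.9–1.1); usage is scale-free, so this only
perturbs TPM mildly.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: read-level effects (mappability, positional
coverage bias), multi-isoform gene structure and overlapping exon bins,
within-gene overdispersion beyond the multinomial, splice-site strength,
clustered or co-occurring motifs, and conservation. Results on real data
additionally depend on the upstream quantification pipeline.

## The differential exon-usage statistic

The usage test is intentionally a transparent stand-in for a full GLM
package: counts are pooled within each group and each exon is tested with a
two-sided 2×2 exact test of (exon vs rest-of-gene) × (group). Conditional on
the pooled gene totals the null distribution of the exon count is
hypergeometric, so p-values are exact; on simulated null data (no planting)
the p-value distribution is near-uniform (KS distance about 0.01 at 10,000
exons) and BH control behaves as expected. Pooling sacrifices
between-replicate variance modelling — at the simulator's dispersion and
sample sizes this costs little, but on real data a dedicated DEU package is
the right tool; `posmap` accepts any table with the same columns.

The log2 usage fold change is shrunk with `ε = 0.5 / pooled gene count` per
group, which keeps zero-count exons finite while shifting well-covered exons
negligibly (< 0.1 at gene totals of 200). Thresholds default to host-gene
TPM ≥ 0.5, |LFC| ≥ 1, BH-adjusted p ≤ 0.05, all boundaries inclusive. BH is
applied once across all tested exons.

**Background exons** are sampled uniformly (seeded, without replacement)
from expressed, non-significant exons, matching the "equal number of
non-differentially-spliced exons" design. No length/GC matching is applied
by default — uniform sampling is the simplest defensible reading, and the
region extractor already equalizes the sequence space examined per exon;
`enrich_motifs(unit = "hits")` offers a length-sensitive alternative when
truncation differs systematically between sets.

## Proximal windows

`window_spec()` defaults to 200 nt of each flanking intron and 10 nt inside
each exon edge. The exonic windows are placed at *both* edges (two regions),
since both splice sites are analysed; a single-edge mode
(`exon_edges = "start_only"`) is available for the narrower reading.
Windows truncate — never extend — at the neighbouring exon; terminal exons
yield an empty, flagged region on the missing-intron side, and empty regions
are kept so denominators stay well defined. Exons shorter than twice the
exon window are split at the transcript-sense midpoint (5′ half rounds up),
so the two exonic windows never overlap and the extraction is exactly
strand-symmetric: reverse-complementing the genome and flipping the
annotation reproduces every region sequence byte for byte, a property the
test suite checks on a 50-gene genome.

Internally all coordinates are 0-based half-open; GTF I/O converts at the
boundary (1-based inclusive), the single conversion point in the package.
Genome sequence is restricted to ACGTN at read time so scanner semantics
stay simple.

## Motif scanning and enrichment

The scanner matches IUPAC classes position by position, reports *all*
overlapping occurrences as 0-based offsets, and treats N in the genome as
matching nothing (an unknown base is not evidence), including against motif
N. It is implemented as a zero-width lookahead regular expression and is
verified against a brute-force oracle over random sequence/motif pairs.

Enrichment uses the exon as the unit: an exon "has" a motif if any of its
four regions contains a hit. Presence/absence is robust to per-exon
differences in truncated region length; a raw-hit mode is available. Each
motif gets a one-sided exact test (the analysis asks for enrichment only), a
Haldane-corrected odds ratio `((a+½)(d+½))/((b+½)(c+½))`, BH adjustment
across motifs, and a rank (ascending p, ties by descending odds ratio).
One-sided exact tests on discrete presence counts are conservative, so the
null false-positive rate sits below, not at, the nominal level — the
calibration test asserts the nominal rate as an upper bound.

The positional profile normalizes hit counts per exon (hits divided by
class size), with upstream = upstream intron + exon-start window and
downstream = exon-end + downstream intron. Per-exon normalization keeps the
two sides comparable when classes differ in size; truncation can in
principle bias sides differently, which is why the per-offset density table
is also emitted and a hit-based enrichment mode exists. The asymmetry index
`A = (D − U)/(D + U)` is classified with τ = 0.2: small classes make A
noisy, and ±0.2 is conservative against, e.g., the ±0.25 swings that a
handful of chance hits produce in a background class of ~150 exons (visible
in the demo run). A zero denominator (no hits at all) is an ambiguous,
flagged call rather than a number.

## Isoform dynamics and reversion

`zscore_by_cohort()` standardizes each feature within each cohort separately
(n−1 denominator; zero-variance cells are zeroed and flagged), the
convention used when visualizing two cohorts whose effect sizes differ.
`lfc_correlation()` joins two analyses on exon keys, restricted to exons
significant in either (union) or both (intersection); the b-on-a slope
documents magnitude asymmetry between cohorts.

"Reverting to the embryonic state" has no canonical quantitative
definition, so the package operationalizes it with a sign-and-distance rule:
an adult-significant exon reverts when the knockout moves its usage toward
the embryonic wild-type value and ends up closer to it than the adult wild
type was, and when a developmental difference of at least `min_move = 0.1`
absolute usage exists to revert across. The minimum-movement guard keeps
measurement noise around developmentally static exons from being called
reversion; 0.1 is about twice the usage s.e. at the simulator's coverage.
A gene reverts when at least one exon does. On constructed three-condition
data the rule recovers a known reverted fraction within binomial error.

## Determinism and problem sizes

Every stochastic step takes its stream from a single integer seed
(simulation sub-stages use fixed offsets of it), and the pipeline manifest
records an MD5 hash per output file: identical configuration and seed imply
identical hashes. The test suite exercises the workflow at the sizes the
package treats as its reference conditions: 60 genes × 5 exons for
planted-recovery runs (20 seeds), 10,000 exon bins for null p-value
calibration, 200 simulated datasets for enrichment calibration, and 400
exons for reversion recovery — sizes chosen so the full suite documents
calibration, power, direction accuracy and positional-mode recovery while
remaining quick to run on a laptop.

## Known limitations

* The usage test ignores replicate-level variance by pooling; it is a
  calibrated stand-in, not a replacement for GLM-based DEU tools on real
  data.
* Single-isoform, disjoint exon bins are assumed; flattening multi-isoform
  annotation is out of scope.
* Background sampling does not match length or GC; planted and background
  regions are construction-matched in the simulator, but real-data users
  may want the hit-based enrichment mode as a sensitivity check.
* The reversion rule is an operationalization; its threshold (`min_move`)
  should be tuned to the coverage of the data at hand.
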