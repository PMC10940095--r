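---
title: "Single-cell karyotypes and chromosomal mosaicism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell karyotypes and chromosomal mosaicism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyomosaic)
```

## The problem

Human preimplantation embryos frequently carry chromosomal abnormalities.
Errors in meiosis produce gametes with a wrong chromosome set, so every cell
of the resulting embryo shares the same abnormality. Errors in the mitotic
cleavage divisions after fertilization affect only the descendants of the
cell that missegregated, producing *chromosomal mosaicism*: two or more
cytogenetically distinct cell populations within one embryo. Clinical
aneuploidy screening (PGT-A) samples a multicellular trophectoderm (TE)
biopsy and sequences it in bulk, which can only register a *net* average gain
or loss of DNA above roughly 20--30% of the sampled cells — low-level
mosaicism, and reciprocal gain/loss populations that cancel on average, are
invisible.

`karyomosaic` implements the single-cell alternative as a tested pipeline:
per-cell binned read counts are quality-controlled and segmented into integer
copy-number profiles; each cell's deviations from its baseline ploidy become
typed abnormalities; embryo-level rules classify mosaicism, attribute each
abnormality to a meiotic or mitotic origin, group mitotic products into
segregation-error events with timing and mechanism labels; and a pseudo-bulk
re-analysis quantifies what a bulk biopsy of the same cells would have
detected. Because single-cell data from human embryos are controlled-access,
a blastocyst simulator with explicit division trees and ground-truth event
logs is a first-class part of the package: every inference stage is validated
by recovery against simulated truth.

## The simulator

`simulate_embryo()` grows a synchronous binary division tree of depth
`ceiling(log2(n_cells))`; the `n_cells` cells present at biopsy are sampled
uniformly from the leaves, which stands in for division asynchrony and cell
loss (no explicit cell-cycle model is attempted). Meiotic events are applied
to the zygote and hence all cells. A mitotic event at division *d* picks a
dividing cell whose daughters both have surviving descendants, and the two
daughter sublineages receive complementary products:

* `reciprocal_whole` / `reciprocal_segmental` — one daughter gains and the
  other loses the identical span, conserving total copy number (the
  single-missegregation signature);
* `whole_plus_partial_loss` — whole-chromosome loss in one daughter, a
  terminal loss distal to a shared proximal point in the other (progressive
  loss of a damaged chromosome);
* `pericentromeric_retention` — loss of a chromosome except a retained
  segment overlapping the centromere;
* `nonreciprocal_gain` / `nonreciprocal_loss` — one-sided products (e.g. a
  lost chromosome ending up in a micronucleus);
* `genome_wide_ploidy` — one sublineage becomes fully polyploid, yielding a
  mixoploid embryo.

Lineages are labeled at a configurable *specification division* (default 3,
the 8-cell stage): each subtree rooted there is assigned TE or ICM, with a
mixing probability (default 0) letting single cells take the other lineage.
The number of ICM subtrees follows the configured ICM fraction (default 0.2,
matching the roughly 5:1 TE:ICM cell ratio of a blastocyst). This subtree
model has a closed form for the probability that a pre-specification event's
products end up in a single lineage (`prob_restricted_one_lineage()`), which
the test suite verifies by enumeration and Monte Carlo — and which quantifies
the known caveat that such events are then indistinguishable from
post-specification ones.

Cohort defaults (`cohort_config()`) encode the study conditions this package
is designed around: 55 embryos of 20--80 cells; category mix 6 : 4 : 32 : 13
(normal : uniformly abnormal : diploid-aneuploid mosaic : aneuploid mosaic);
1 + Poisson(1.2) mitotic events per mosaic embryo, so about 70% of mosaic
embryos carry more than one event; 55% per-cell karyotyping dropout (45%
success); event chromosomes drawn uniformly over the autosomes, each event on
a distinct chromosome; pattern weights favoring reciprocal segmental over
reciprocal whole and whole-plus-partial events (0.34 / 0.22 / 0.16, the
ranking observed in real embryos), with small mass on one-sided events,
pericentromeric retention (restricted to chromosomes with both arms at least
30 Mb so both flanking losses stay reportable) and mixoploidy. The division
index of a mitotic event is drawn uniformly over rounds; we also examined
weighting rounds by their number of dividing cells, but that concentrates
events so late that the simulated timing split and clone sizes no longer
resemble reported blastocyst data — uniform rounds reproduce both (roughly a
quarter of events before lineage specification, and a mean of about 60%
normal cells in diploid-aneuploid mosaics), consistent with cleavage
divisions being especially error-prone.

Read counts (`simulate_binned_counts()`) are negative-binomial with expected
count proportional to copy number times bin length (variance
$\mu + \phi\mu^2$; `dispersion` $\phi = 0$ is the Poisson limit). Default
depth is 300,000 reads per cell. Simulated breakpoints land on a 1 Mb
lattice, aligned with the default binning.

What the simulator does **not** emulate: GC and mappability bias, replication
timing (S-phase) artifacts, chromosome-specific error propensities (event
chromosomes are uniform, so per-chromosome frequencies are flat and the
gene-density correlation of numerical abnormalities is expected to be ~0 in
simulation), whole-genome amplification artifacts, and biased dropout.
Passing recovery tests therefore demonstrate the correctness of the
inference rules, not robustness to every artifact of real scKaryo-Seq data.

## QC and copy-number calling

Counts are normalized by bin length times genome-wide read density
(`normalize_counts()`), making values proportional to copy number and
invariant to sequencing depth. Three QC metrics gate each cell
(`qc_evaluate()`), with the thresholds used for scKaryo-Seq data: minimum
15,000 total reads; maximum *spikiness* 0.25, where spikiness is
$\sum_i |c_{i+1}-c_i| / \sum_i c_i$ over consecutive bins; and minimum
*Bhattacharyya distance* 0.65 between Gaussian fits $(\mu_k, \sigma_k)$ of
the normalized counts of the two CN states occupying the most bins,

$$BD = \tfrac14 \ln\!\Big(\tfrac14\big(\tfrac{\sigma_1^2}{\sigma_2^2} +
\tfrac{\sigma_2^2}{\sigma_1^2} + 2\big)\Big) +
\tfrac14 \frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2}.$$

All comparisons are inclusive (a spikiness of exactly 0.25 passes); states
with fewer than 3 bins are skipped, and a single-state (e.g. fully diploid)
cell has an undefined score and passes with a flag. A `manual_override`
argument stands in for visual inspection of borderline profiles; it replaces
the automatic verdict and is always logged.

`call_copy_number()` is a divisive caller. Per chromosome it recursively
splits the normalized series at the breakpoint maximizing
$|\bar x_L - \bar x_R|\sqrt{n_L n_R / n}$, stopping when the statistic falls
below `split_threshold` (default 1.5, in approximate per-copy units) or a
segment would drop below `min_segment_bins` (default 5 bins, i.e. ~5 Mb at
the default fixed 1 Mb bins — below the smallest segmental events this assay
reports, so no reportable event is filtered). A global scale factor then maps
segment means to integers, chosen over a grid such that the modal segment
(most genomic material) lands on CN 1--4, minimizing the length-weighted
squared residual *measured in pre-scaling copy units* (residuals divided by
the scale): without that division the loss shrinks with the scale and noisy
diploid profiles would systematically be called haploid. Near-ties (within
5%) resolve toward the diploid interpretation, encoding the biological prior
that the dominant state is diploid. A consequence worth stating plainly:
read depth fixes only *relative* copy number, so a uniformly triploid cell is
indistinguishable from a diploid one from counts alone; mixoploidy detection
rests on the segment-table route, and the bundled fixed-width binning
replaces reference-derived variable bins (which need external diploid
reference cells).

## Abnormality catalog and embryo-level inference

A cell's baseline ploidy is its length-weighted modal autosomal CN; a
non-diploid baseline marks the cell as a genome-wide ploidy deviant, recorded
as a *single* abnormality (not 22), with remaining chromosomes called against
that modal baseline. Every maximal deviant autosomal segment of at least
`min_report_mb` (default 5 Mb, a guard against binning noise) becomes one
abnormality: gain or loss, numerical if it covers at least `whole_fraction`
(default 0.9) of the chromosome, else structural. Cells with more than 4
abnormalities are complex abnormal (the threshold is strict: 4 is still
"abnormal"). Sex chromosomes are called but excluded from all cohort-level
chromosome statistics.

Across the QC-passed cells of an embryo, abnormalities are matched
(`match_abnormalities()`): same chromosome and direction with reciprocal span
overlap of at least 0.8 and breakpoints within 2 bins is *same*; opposite
direction under the same span criteria is *reciprocal*; whole-chromosome
calls match each other regardless of bin jitter; and a whole-chromosome loss
matches a partial loss of that chromosome as a same-event candidate
(containment), one defensible reading of how progressive loss products should
be merged. The every-cell rule assigns origin: a signature cluster present in
every QC-passed cell is meiotic, anything else mitotic (single-cell embryos
give low-confidence meiotic calls; single-cell-supported clusters are kept
but flagged). Embryo categories follow the cell-status mixture: only normal
cells → *normal*; all abnormal with pairwise identical catalogs (the same
matcher, so bin jitter cannot fake mosaicism) → *uniformly abnormal*; normal
and abnormal cells → *diploid-aneuploid mosaic*; all abnormal,
cytogenetically different → *aneuploid mosaic*.

Mitotic abnormalities are grouped into events (`group_events()`) as connected
components of the match graph, with one addition to the pairwise matcher:
abnormalities of one cell on the same chromosome are joined, since one
damaged chromosome's products (e.g. the two losses flanking a retained
pericentromeric segment) belong to one error event. Timing is
`pre_specification` if an event's member cells span both lineages,
`post_specification` if confined to one, `unassessable` if the embryo lacks
both lineages — with the quantified caveat above. Mechanisms are labeled by
strict priority (genome-wide mixoploid, reciprocal whole, reciprocal
segmental, whole plus partial loss, pericentromeric retention, else
unclassified), making classification deterministic where the underlying
patterns are presented in the literature as illustrative.

## Pseudo-bulk detection

`net_affected_fraction()` computes, over a lineage's QC-passed cells, the
absolute mean copy-number deviation from the lineage baseline on an
abnormality's span — the net single-copy-equivalent fraction a bulk
measurement sees. The measure is copy-weighted (a two-copy gain in 10% of
cells equals a one-copy gain in 20%), which is the only reading consistent
with both "percent of affected cells" and "copy-number states compensate";
the raw carrier fraction is reported alongside. Equinumerous reciprocal
products cancel exactly. `cohort_bulk_detection()` applies the inclusive
detection threshold (default 0.20, the sensitive end of the PGT-A range,
validated to (0,1)) per mitotic abnormality in the TE, excluding complex
abnormal cells, and reports the detected fraction; the lineage baseline is
the modal cell ploidy, so a minority polyploid clone is assessed against the
diploid majority.

## Statistics layer

`fisher_exact_2x2()` (two-sided, probability-mass definition — the dominant
convention, verified in tests against exhaustive hypergeometric enumeration),
`pearson_correlation()`, `linear_regression()` (OLS with slope t-test), and
`expansion_rate()` for hourly blastocyst surface-area series: area at the
first attainment of the maximum minus initial area, divided by the number of
measurement intervals between them (first attainment is our tie rule; a
series whose maximum comes first gets rate 0 with a flag).
`chromosome_event_frequencies()` compares per-autosome event percentages with
the uniform 100/22 = 4.55% chance by exact binomial tests. The hg38 table
shipped in `inst/extdata/` carries exact chromosome lengths plus approximate
centromere midpoints and protein-coding gene counts (provenance in the file
header; the gene counts feed the gene-density correlation and can be swapped
by supplying a custom `genome_spec`).

## Numerical choices and degenerate inputs

Zero-total counts, empty binnings, empty segment tables, embryos without
QC-passed cells and losses from CN=0 are rejected with errors; degenerate
2×2 margins give p = 1; zero-variance inputs to correlation/regression are
rejected. Segment tables are kept canonical (sorted, adjacent equal-CN runs
merged) and always tile the binned genome; `segment_profile()` /
`expand_profile()` round-trip exactly. Event grouping and embryo
classification are invariant under cell reordering (union-find over an
order-independent edge set).

## Problem sizes used in validation

The test suite validates recovery on a 200-embryo noise-free cohort
(categories, event counts, origins, timing, mechanisms: 100% recovery
required), caller exactness on dispersion-0 counts at 2M reads/cell with
breakpoint recovery within ±2 bins in ≥95% of 200 noisy replicates
(300k reads, dispersion 0.01), the compensation property on 100 seeded
embryos, oracle equivalence on 500 random Fisher tables and 500 random
grouping instances, and the timing-caveat rate on 1,000 embryos against the
allocation model's closed form within 3 Monte-Carlo standard errors. These
sizes give stable Monte-Carlo assertions at desk scale.

## Known limitations

Cohort-level percentages from real embryo cohorts depend on biology the
simulator parameterizes only coarsely (clone-size distributions, selection
against abnormal cells, chromosome-specific propensities), so simulated
cohort summaries track reported values only approximately — the
bulk-detectable fraction is the most sensitive to the clone-size
distribution. Uniparental disomy and SNP-based origin assignment are out of
scope; the origin rule is the every-cell heuristic, whose failure modes under
dropout (a mitotic clone that happens to survive dropout in every karyotyped
cell) and for whole-plus-partial products spanning all cells are explicit,
simulated, and annotated in the truth log rather than hidden.
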