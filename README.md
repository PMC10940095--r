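# karyomosaic

Single-cell karyotype analysis and chromosomal mosaicism inference for human
blastocysts.

## What this is for

Chromosomal abnormalities are the leading cause of implantation failure and
early pregnancy loss. Meiotic errors make every embryonic cell abnormal in
the same way; mitotic (post-zygotic) errors create *chromosomal mosaicism* —
two or more cytogenetically distinct cell populations in one embryo. Clinical
aneuploidy screening (PGT-A) sequences a multicellular trophectoderm (TE)
biopsy in bulk and only registers a net DNA gain or loss present in at least
~20–30% of the sampled cells, so low-level mosaicism and reciprocal
gain/loss populations (which cancel on average) go undetected.

`karyomosaic` is an R package for researchers analyzing single-cell
whole-genome sequencing of embryos (scKaryo-Seq-style data). It provides:

* **QC and copy-number calling** from per-cell binned read counts: read-depth
  / spikiness / Bhattacharyya quality gates (defaults 15,000 reads,
  spikiness ≤ 0.25, Bhattacharyya ≥ 0.65) and a divisive segmentation caller
  mapping segment means to integer copy numbers, `call_cells()`.
* **Abnormality cataloguing**: per-cell baseline ploidy, typed abnormalities
  (numerical/structural × gain/loss, genome-wide ploidy deviations), complex
  abnormal cells (> 4 abnormalities), `extract_abnormalities()`.
* **Embryo-level inference**: the every-cell rule for meiotic vs mitotic
  origin, embryo categories (normal / uniformly abnormal / diploid-aneuploid
  mosaic / aneuploid mosaic), grouping of same/reciprocal/containment-matched
  abnormalities into mitotic error events with timing relative to TE/ICM
  lineage specification and mechanism labels (reciprocal whole or segmental,
  whole + partial loss, pericentromeric retention, mixoploid),
  `classify_embryo()`.
* **In-silico bulk DNA-Seq**: copy-weighted net affected fractions with
  reciprocal cancellation and the ≥ 20% detection rule, quantifying what a
  bulk TE biopsy would have found, `cohort_bulk_detection()`.
* **A blastocyst simulator** with explicit division trees, meiotic/mitotic
  event injection, TE/ICM allocation, dropout, and negative-binomial count
  emulation — every inference stage is validated by recovery against its
  ground-truth event logs, `simulate_embryo()` / `simulate_cohort()`.
* **The statistics layer** used for cohort reports: two-sided Fisher's exact
  test, Pearson correlation, OLS regression, blastocyst expansion rate,
  per-chromosome event frequencies vs the uniform 1-of-22 (4.55%) chance,
  `analyze_cohort()` / `build_report()`.

The central copy-number model: for cell $c$ and bin $i$, counts are
$n_{ci} \sim \mathrm{NB}(\mu_{ci}, \phi)$ with
$\mu_{ci} \propto \mathrm{CN}_{ci} \cdot \ell_i$; segmentation maximizes the
between-segment mean difference statistic $|\bar x_L - \bar x_R|\sqrt{n_L
n_R/n}$ recursively, and a global scale maps segment means to integers. The
bulk model: an abnormality with span $S$ is bulk-detectable iff
$\left|\tfrac1{|C|}\sum_{c \in C} (\mathrm{CN}_{cS} - b)\right| \ge 0.20$
over the biopsied cells $C$ with lineage baseline $b$ — reciprocal products
cancel, single cells never do.

## Worked example

Simulate one embryo carrying a meiotic trisomy 16 and a reciprocal
whole-chromosome 21 missegregation at the second cleavage division, then run
the embryo-level inference and the pseudo-bulk comparison:

```r
library(karyomosaic)
genome <- default_genome("female")

emb <- simulate_embryo("E1", n_cells = 24,
  events = list(
    error_event("meiotic", "nonreciprocal_gain", "chr16"),
    error_event("mitotic", "reciprocal_whole", "chr21", division = 2)),
  genome = genome, dropout = 0, seed = 7)

cls <- classify_embryo(emb$cells)
cls
#> <embryo_classification> E1: aneuploid_mosaic (24 cells, 0% normal, 1 mitotic events)

ev <- cls$events[[1]]
sprintf("event on %s: mechanism=%s, timing=%s, cells=%d",
        ev$chrom, ev$mechanism, ev$timing, ev$n_cells)
#> "event on chr21: mechanism=reciprocal_whole, timing=pre_specification, cells=11"

te <- Filter(function(cell) cell$lineage == "TE", emb$cells)
naf <- net_affected_fraction(list(chrom = "chr21", start = 0, end = 46709983),
                             te, genome)
sprintf("chr21 in TE: raw %.0f%% of cells, net fraction %.2f -> bulk-detectable: %s",
        100 * naf$raw_percent_cells, naf$net_fraction,
        is_bulk_detectable(naf$net_fraction))
#> "chr21 in TE: raw 44% of cells, net fraction 0.11 -> bulk-detectable: FALSE"
```

Reading this: every cell carries the trisomy 16 (meiotic, so the embryo is
uniformly abnormal at baseline), and the chromosome-21 gain and loss products
mark one mitotic event whose daughters ended up in both lineages (it predates
lineage specification). Although 44% of TE cells are affected on chr21, the
gains and losses nearly cancel: the net fraction 0.11 is below the 20% bulk
detection threshold, so a bulk TE biopsy would miss the event that the
single-cell analysis resolves — the package's core point in one embryo.

The statistics layer reproduces published worked examples, e.g. the TE vs
ICM complex-cell contingency (58/812 vs 4/160):

```r
fisher_exact_2x2(matrix(c(58, 754, 4, 156), 2, 2, byrow = TRUE))
#> 0.0318  (prints as P = 0.03)
```

File-based workflows use `read_counts_tsv()` / `read_bins_bed()` /
`read_segments()` and friends; a thin command-line wrapper over the same
functions is in `inst/cli/karyomosaic.R`.

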