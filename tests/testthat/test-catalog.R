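g_hs <- default_genome("female")

test_that("baseline ploidy is the length-weighted autosomal mode", {
  expect_equal(as.integer(infer_baseline_ploidy(make_cell("c", genome = g_hs),
                                                g_hs)), 2L)
  tri <- make_cell("c", lapply(autosomes(g_hs), function(ch)
    list(ch, 0, g_hs$length[g_hs$chrom == ch], 1)), genome = g_hs)
  b <- infer_baseline_ploidy(tri, g_hs)
  expect_equal(as.integer(b), 3L)
  expect_true(attr(b, "genome_wide"))

  # 20 diploid autosomes dominate 2 trisomic ones
  two_tri <- make_cell("c", list(list("chr1", 0, 248956422, 1),
                                 list("chr2", 0, 242193529, 1)), genome = g_hs)
  expect_equal(as.integer(infer_baseline_ploidy(two_tri, g_hs)), 2L)
  empty <- make_cell("c", genome = g_hs)
  empty$segments <- empty$segments[0, ]
  expect_error(infer_baseline_ploidy(empty, g_hs), "empty")
})

test_that("abnormality extraction types, filters and fractions are correct", {
  # whole-chromosome monosomy 21: one numerical loss
  mono <- make_cell("c", list(list("chr21", 0, 46709983, -1)), genome = g_hs)
  ab <- extract_abnormalities(mono, genome = g_hs)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$kind, "numerical")
  expect_equal(ab$direction, "loss")
  expect_equal(ab$delta, -1L)
  expect_equal(ab$chrom_fraction, 1)

  # 30 Mb gain on chr20: structural, fraction = 30e6 / chr20 length
  seg <- make_cell("c", list(list("chr20", 30e6, 60e6, 1)), genome = g_hs)
  ab <- extract_abnormalities(seg, genome = g_hs)
  expect_equal(ab$kind, "structural")
  expect_equal(ab$chrom_fraction, 30e6 / 64444167)

  # 4 Mb deviation is below the 5 Mb reporting floor
  tiny <- make_cell("c", list(list("chr20", 30e6, 34e6, 1)), genome = g_hs)
  expect_equal(nrow(extract_abnormalities(tiny, genome = g_hs)), 0)

  # genome-wide ploidy deviation is one abnormality, not 22
  tri <- make_cell("c", lapply(autosomes(g_hs), function(ch)
    list(ch, 0, g_hs$length[g_hs$chrom == ch], 1)), genome = g_hs)
  ab <- extract_abnormalities(tri, genome = g_hs)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$kind, "genome_wide")
  expect_equal(ab$direction, "gain")
})

test_that("extraction is idempotent and monotone in the reporting floor", {
  cell <- make_cell("c", list(list("chr3", 0, 198295559, -1),
                              list("chr11", 60e6, 67e6, 1)), genome = g_hs)
  a1 <- extract_abnormalities(cell, genome = g_hs)
  a2 <- extract_abnormalities(cell, genome = g_hs)
  expect_identical(a1, a2)
  for (mb in c(0, 5, 8, 50, 500)) {
    ab <- extract_abnormalities(cell, catalog_params(min_report_mb = mb),
                                g_hs)
    if (mb > 0)
      expect_lte(nrow(ab),
                 nrow(extract_abnormalities(cell,
                        catalog_params(min_report_mb = 0), g_hs)))
  }
  expect_equal(nrow(extract_abnormalities(cell,
                      catalog_params(min_report_mb = 8), g_hs)), 1)
})

test_that("cell status uses the strict more-than-4 complex rule", {
  mk <- function(n) {
    if (n == 0) return(karyomosaic:::empty_abnormalities())
    abn_row(rep("c", n), paste0("chr", seq_len(n)), 0, 10e6, "loss")
  }
  expect_equal(classify_cell(mk(0))$label, "normal")
  expect_equal(classify_cell(mk(1))$label, "abnormal")
  expect_equal(classify_cell(mk(4))$label, "abnormal")
  expect_equal(classify_cell(mk(5))$label, "complex_abnormal")
})

test_that("dispersion-0 catalogs equal the injected events", {
  set.seed(37)
  bins <- make_bins(g_hs)
  emb <- simulate_embryo("E1", 8,
    list(error_event("mitotic", "reciprocal_segmental", "chr6", division = 1),
         error_event("mitotic", "nonreciprocal_loss", "chr13", division = 2)),
    g_hs, dropout = 0)
  for (cell in emb$cells) {
    cnt <- simulate_binned_counts(cell, bins, 2e6, 0)
    called <- cell_karyotype(cell$cell_id, "E1",
                             segment_profile(call_copy_number(cnt, bins)$cn,
                                             bins), cell$lineage)
    ab_called <- extract_abnormalities(called, genome = g_hs)
    ab_truth <- extract_abnormalities(cell, genome = g_hs)
    expect_equal(nrow(ab_called), nrow(ab_truth))
    if (nrow(ab_truth) > 0) {
      o1 <- order(ab_called$chrom, ab_called$start)
      o2 <- order(ab_truth$chrom, ab_truth$start)
      expect_equal(ab_called$chrom[o1], ab_truth$chrom[o2])
      expect_equal(ab_called$delta[o1], ab_truth$delta[o2])
      expect_true(all(abs(ab_called$start[o1] - ab_truth$start[o2]) <= 1e6))
      expect_true(all(abs(ab_called$end[o1] - ab_truth$end[o2]) <= 1e6))
    }
  }
})
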