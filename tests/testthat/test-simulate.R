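g_hs <- default_genome("female")

test_that("meiotic events reach every cell; no events means all-diploid", {
  emb <- simulate_embryo("E1", 16,
                         list(error_event("meiotic", "nonreciprocal_gain",
                                          "chr16")),
                         g_hs, dropout = 0, seed = 11)
  cn16 <- vapply(emb$cells, function(cell)
    cell$segments$cn[cell$segments$chrom == "chr16"], integer(1))
  expect_true(all(cn16 == 3L))

  emb0 <- simulate_embryo("E0", 12, list(), g_hs, dropout = 0, seed = 12)
  expect_true(all(vapply(emb0$cells, function(cell)
    all(cell$segments$cn == 2L), logical(1))))
})

test_that("a division-2 reciprocal event splits cells 1:2:1, matching an exhaustive tree walk", {
  emb <- simulate_embryo("E1", 16,
                         list(error_event("mitotic", "reciprocal_whole",
                                          "chr21", division = 2)),
                         g_hs, dropout = 0, seed = 13)
  cn21 <- vapply(emb$cells, function(cell)
    cell$segments$cn[cell$segments$chrom == "chr21"], integer(1))
  # oracle: full binary tree, depth 4; the division-2 parent has 2 daughters
  # covering 4 leaves each
  ev <- emb$truth_events[[1]]
  depth <- emb$tree$depth
  leaves_under <- function(node, level)
    which(karyomosaic:::ancestor_at(seq_len(2^depth), depth, level) == node)
  expect_equal(sort(unname(which(cn21 == 3))),
               sort(match(ev$carriers_A, names(emb$cells))))
  expect_equal(length(ev$carriers_A), 4)
  expect_equal(length(ev$carriers_B), 4)
  expect_equal(sum(cn21 == 3), 4)
  expect_equal(sum(cn21 == 1), 4)
  expect_equal(sum(cn21 == 2), 8)
  expect_setequal(leaves_under(2L * ev$parent - 1L, ev$division),
                  match(ev$carriers_A, names(emb$cells)))
})

test_that("apply_mitotic_error conserves copy number for reciprocal patterns", {
  parent <- make_cell("p", genome = g_hs)
  for (pat in c("reciprocal_whole", "reciprocal_segmental")) {
    for (rep in 1:5) {
      ev <- error_event("mitotic", pat, "chr20", division = 3)
      d <- apply_mitotic_error(parent, ev, g_hs)
      sp <- d$spans
      cnA <- karyomosaic:::span_mean_cn(d$A$segments, sp$chrom[1], sp$start[1],
                                        sp$end[1])
      cnB <- karyomosaic:::span_mean_cn(d$B$segments, sp$chrom[1], sp$start[1],
                                        sp$end[1])
      expect_equal(cnA + cnB, 4)   # 2 x parent copies on the span
      expect_equal(cnA, 3)
      expect_equal(cnB, 1)
    }
  }
})

test_that("losses from a CN=0 span are rejected", {
  parent <- make_cell("p", list(list("chr21", 0, 46709983, -2)), genome = g_hs)
  ev <- error_event("mitotic", "nonreciprocal_loss", "chr21", division = 2)
  expect_error(apply_mitotic_error(parent, ev, g_hs), "CN=0")
})

test_that("pericentromeric retention spares a centromere-overlapping span", {
  parent <- make_cell("p", genome = g_hs)
  ev <- error_event("mitotic", "pericentromeric_retention", "chr5",
                    division = 2)
  d <- apply_mitotic_error(parent, ev, g_hs)
  cen <- g_hs$centromere[g_hs$chrom == "chr5"]
  s <- d$A$segments[d$A$segments$chrom == "chr5", ]
  retained <- s[s$cn == 2, ]
  expect_equal(nrow(retained), 1)
  expect_true(retained$start < cen && retained$end > cen)
  expect_true(all(s$cn[s$end <= retained$start | s$start >= retained$end] == 1))
})

test_that("identical config and seed give identical truth logs", {
  ev <- list(error_event("mitotic", "reciprocal_segmental", "chr7",
                         division = 3))
  e1 <- simulate_embryo("E", 24, ev, g_hs, dropout = 0.3, seed = 99)
  e2 <- simulate_embryo("E", 24, ev, g_hs, dropout = 0.3, seed = 99)
  expect_identical(e1$truth_events, e2$truth_events)
  expect_identical(e1$dropout_mask, e2$dropout_mask)
  expect_identical(lapply(e1$cells, `[[`, "segments"),
                   lapply(e2$cells, `[[`, "segments"))
})

test_that("realized dropout matches the configured rate within 3 SE", {
  set.seed(21)
  p <- 0.55
  dropped <- unlist(lapply(1:40, function(i) {
    emb <- simulate_embryo(paste0("E", i), 32, list(), g_hs, dropout = p)
    emb$dropout_mask
  }))
  n <- length(dropped)
  expect_gt(n, 1000)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(dropped) - p), 3 * se)
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulate_embryo("E", 1, list(), g_hs), "at least 2")
  expect_error(simulate_embryo("E", 8,
    list(error_event("mitotic", "reciprocal_whole", "chr1", division = 9)),
    g_hs, seed = 1), "deeper than tree")
  expect_error(allocate_lineages(1:8, 3, spec_division = 5), "beyond tree depth")
  expect_error(error_event("meiotic", "reciprocal_whole", "chr1"))
  expect_error(error_event("mitotic", "reciprocal_whole", "chr1"))
})

test_that("lineage restriction of pre-specification events follows the allocation model", {
  # closed form against direct enumeration over ICM-subtree choices
  combs <- utils::combn(8, 2)
  enum <- mean(apply(combs, 2, function(icm) {
    lab <- rep("TE", 8); lab[icm] <- "ICM"
    length(unique(lab[1:4])) == 1
  }))
  expect_equal(prob_restricted_one_lineage(8, 2, 4), enum)
  expect_equal(prob_restricted_one_lineage(8, 2, 4), 6 / 28)

  # Monte Carlo over full trees: division-2 event occupies 4 of 8 subtrees
  set.seed(31)
  n_emb <- 400
  restricted <- vapply(seq_len(n_emb), function(i) {
    emb <- simulate_embryo(paste0("E", i), 32,
      list(error_event("mitotic", "reciprocal_whole", "chr21", division = 2)),
      g_hs, spec_division = 3, icm_fraction = 0.25, mixing = 0, dropout = 0)
    length(emb$truth_events[[1]]$lineages_truth) == 1
  }, logical(1))
  p_hat <- mean(restricted)
  p_exp <- prob_restricted_one_lineage(8, 2, 4)
  se <- sqrt(p_exp * (1 - p_exp) / n_emb)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("simulated counts follow the copy-number-weighted expectation", {
  bins <- make_bins(g_hs)
  set.seed(41)
  cell <- make_cell("c", list(list("chr1", 0, 248956422, 1)), genome = g_hs)
  cnt <- simulate_binned_counts(cell, bins, 2e6, 0)
  norm <- normalize_counts(cnt, bins)
  is1 <- bins$chrom == "chr1"
  other <- bins$chrom %in% setdiff(autosomes(g_hs), "chr1")
  expect_equal(mean(norm[is1]) / mean(norm[other]), 1.5, tolerance = 0.01)

  # boundary-depth fixture: total lands near the requested 15,000 reads
  totals <- replicate(30, simulate_binned_counts(cell, bins, 15000,
                                                 0)$total_reads)
  expect_lt(abs(mean(totals) - 15000), 3 * sqrt(15000 / 30))
  expect_error(simulate_binned_counts(cell, bins[0, ], 1000, 0))
})

test_that("cohort simulation respects its configured truth mix", {
  coh <- simulate_cohort(cohort_config(n_embryos = 20, seed = 5))
  expect_length(coh, 20)
  cats <- vapply(coh, `[[`, character(1), "category_truth")
  expect_true(all(cats %in% c("normal", "uniformly_abnormal",
                              "diploid_aneuploid_mosaic", "aneuploid_mosaic")))
  for (emb in coh) {
    expect_equal(karyomosaic:::implied_truth_category(emb), emb$category_truth)
    for (ev in emb$truth_events)
      expect_true(all(ev$carriers %in% names(emb$cells)))
  }
})
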