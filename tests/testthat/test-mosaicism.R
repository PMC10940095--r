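g_hs <- default_genome("female")
L21 <- g_hs$length[g_hs$chrom == "chr21"]
L19 <- g_hs$length[g_hs$chrom == "chr19"]

test_that("pairwise matching follows the same/reciprocal/containment rules", {
  w_gain <- abn_row("c1", "chr21", 0, L21, "gain", kind = "numerical", frac = 1)
  w_loss <- abn_row("c2", "chr21", 0, L21, "loss", kind = "numerical",
                    delta = -1L, frac = 1)
  expect_equal(match_abnormalities(w_gain, w_loss)$relation, "reciprocal")

  wl19 <- abn_row("c1", "chr19", 0, L19, "loss", kind = "numerical", frac = 1)
  pl19 <- abn_row("c2", "chr19", 30e6, L19, "loss")
  m <- match_abnormalities(wl19, pl19)
  expect_equal(m$relation, "same")
  expect_true(m$containment)

  expect_equal(match_abnormalities(
    abn_row("c1", "chr4", 0, 50e6, "gain"),
    abn_row("c2", "chr7", 0, 50e6, "loss"))$relation, "unrelated")

  # segmental matching honors overlap fraction and breakpoint tolerance
  a <- abn_row("c1", "chr2", 100e6, 140e6, "loss")
  near <- abn_row("c2", "chr2", 101e6, 141e6, "loss")
  far <- abn_row("c2", "chr2", 104e6, 144e6, "loss")
  small <- abn_row("c2", "chr2", 100e6, 110e6, "loss")
  expect_equal(match_abnormalities(a, near)$relation, "same")
  expect_equal(match_abnormalities(a, far)$relation, "unrelated")
  expect_equal(match_abnormalities(a, small)$relation, "unrelated")
  opp <- abn_row("c2", "chr2", 100e6, 140e6, "gain")
  expect_equal(match_abnormalities(a, opp)$relation, "reciprocal")
})

test_that("the vectorized relation matrix agrees with the pairwise matcher", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    tab <- do.call(rbind, lapply(seq_len(n), function(i) {
      ch <- sample(c("chr1", "chr2", "chr21"), 1)
      L <- g_hs$length[g_hs$chrom == ch]
      whole <- runif(1) < 0.4
      st <- if (whole) 0 else sample(0:60, 1) * 1e6
      en <- if (whole) L else st + sample(10:40, 1) * 1e6
      abn_row(sample(paste0("c", 1:4), 1), ch, st, min(en, L),
              sample(c("gain", "loss"), 1),
              kind = if (whole) "numerical" else "structural",
              frac = if (whole) 1 else 0.3)
    }))
    rm_ <- karyomosaic:::relation_matrix(tab)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      expect_equal(rm_$relation[i, j],
                   match_abnormalities(tab[i, ], tab[j, ])$relation)
    }
  }
})

test_that("origin calls implement the every-cell rule", {
  tri <- list(list("chr16", 0, 90338345, 1))
  cells10 <- lapply(1:10, function(i) make_cell(paste0("c", i), tri,
                                                genome = g_hs))
  res <- classify_origin(cells10)
  expect_length(res$calls, 1)
  expect_equal(res$calls[[1]]$origin, "meiotic")

  cells9 <- c(cells10[1:9], list(make_cell("c10", genome = g_hs)))
  res9 <- classify_origin(cells9)
  expect_equal(res9$calls[[1]]$origin, "mitotic")
  expect_equal(res9$calls[[1]]$n_cells, 9)

  # single-cell embryos: meiotic with a low-confidence flag
  res1 <- classify_origin(cells10[1])
  expect_equal(res1$calls[[1]]$origin, "meiotic")
  expect_true(res1$calls[[1]]$low_confidence)
  expect_error(classify_origin(list()), "QC-passed")
})

test_that("embryo categories follow the cell-status mixture rules", {
  normal <- lapply(1:10, function(i) make_cell(paste0("c", i), genome = g_hs))
  expect_equal(classify_embryo(normal)$category, "normal")

  tri <- list(list("chr16", 0, 90338345, 1))
  uniform <- lapply(1:8, function(i) make_cell(paste0("c", i), tri,
                                               genome = g_hs))
  expect_equal(classify_embryo(uniform)$category, "uniformly_abnormal")

  mixed <- c(normal[1:5], uniform[6:8])
  cls <- classify_embryo(mixed)
  expect_equal(cls$category, "diploid_aneuploid_mosaic")
  expect_equal(cls$percent_normal_cells, 62.5)

  aneu <- c(uniform[1:4],
            lapply(5:8, function(i) make_cell(paste0("c", i),
              c(tri, list(list("chr9", 0, 50e6, -1))), genome = g_hs)))
  expect_equal(classify_embryo(aneu)$category, "aneuploid_mosaic")
})

test_that("same, reciprocal and containment products group into one event", {
  cells <- list(
    make_cell("c1", list(list("chr21", 0, L21, 1)), genome = g_hs),
    make_cell("c2", list(list("chr21", 0, L21, -1)), genome = g_hs),
    make_cell("c3", list(list("chr21", 0, L21, -1)), genome = g_hs),
    make_cell("c4", genome = g_hs))
  cls <- classify_embryo(cells)
  expect_equal(cls$n_mitotic_events, 1)
  expect_true(cls$events[[1]]$reciprocal)
  expect_equal(cls$events[[1]]$mechanism, "reciprocal_whole")

  L8 <- g_hs$length[g_hs$chrom == "chr8"]
  cells8 <- list(
    make_cell("c1", list(list("chr8", 0, L8, -1)), genome = g_hs),
    make_cell("c2", list(list("chr8", 60e6, L8, -1)), genome = g_hs),
    make_cell("c3", list(list("chr8", 80e6, L8, -1)), genome = g_hs),
    make_cell("c4", genome = g_hs))
  cls8 <- classify_embryo(cells8)
  expect_equal(cls8$n_mitotic_events, 1)
  expect_equal(cls8$events[[1]]$mechanism, "whole_plus_partial_loss")
})

test_that("event grouping equals the brute-force transitive closure", {
  set.seed(53)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    tab <- do.call(rbind, lapply(seq_len(n), function(i) {
      ch <- sample(c("chr1", "chr2", "chr3"), 1)
      L <- g_hs$length[g_hs$chrom == ch]
      whole <- runif(1) < 0.3
      st <- if (whole) 0 else sample(0:80, 1) * 1e6
      en <- if (whole) L else min(st + sample(8:50, 1) * 1e6, L)
      abn_row(sample(paste0("c", 1:4), 1), ch, st, en,
              sample(c("gain", "loss"), 1),
              kind = if (whole) "numerical" else "structural",
              frac = if (whole) 1 else 0.3)
    }))
    events <- group_events(tab)
    got <- integer(n)
    for (k in seq_along(events)) {
      idx <- as.integer(rownames(events[[k]]$members))
      got[idx] <- k
    }
    expect_true(same_partition(got, closure_components(tab)))
  }
})

test_that("timing reflects member lineages and lineage availability", {
  mk <- function(id, lineage, abn = TRUE)
    make_cell(id, if (abn) list(list("chr21", 0, L21, 1)) else list(),
              genome = g_hs, lineage = lineage)
  te_only_members <- list(mk("c1", "TE"), mk("c2", "TE"),
                          mk("c3", "ICM", abn = FALSE))
  cls <- classify_embryo(te_only_members)
  expect_equal(cls$events[[1]]$timing, "post_specification")

  shared <- list(mk("c1", "TE"), mk("c2", "ICM"), mk("c3", "TE", abn = FALSE))
  cls2 <- classify_embryo(shared)
  expect_equal(cls2$events[[1]]$timing, "pre_specification")

  te_embryo <- list(mk("c1", "TE"), mk("c2", "TE"), mk("c3", "TE", abn = FALSE))
  cls3 <- classify_embryo(te_embryo)
  expect_equal(cls3$events[[1]]$timing, "unassessable")
})

test_that("mechanism labels follow the priority rules", {
  # reciprocal segmental on chr20
  cells <- list(
    make_cell("c1", list(list("chr20", 34e6, 64444167, 1)), genome = g_hs),
    make_cell("c2", list(list("chr20", 34e6, 64444167, -1)), genome = g_hs),
    make_cell("c3", genome = g_hs))
  cls <- classify_embryo(cells)
  expect_equal(cls$events[[1]]$mechanism, "reciprocal_segmental")

  # chr5 lost except the pericentromeric region
  cen5 <- g_hs$centromere[g_hs$chrom == "chr5"]
  L5 <- g_hs$length[g_hs$chrom == "chr5"]
  peri <- list(
    make_cell("c1", list(list("chr5", 0, cen5 - 5e6, -1),
                         list("chr5", cen5 + 5e6, L5, -1)), genome = g_hs),
    make_cell("c2", genome = g_hs))
  clsP <- classify_embryo(peri)
  expect_equal(clsP$n_mitotic_events, 1)
  expect_equal(clsP$events[[1]]$mechanism, "pericentromeric_retention")

  # diploid cells next to fully triploid cells
  tri_mods <- lapply(autosomes(g_hs), function(ch)
    list(ch, 0, g_hs$length[g_hs$chrom == ch], 1))
  mixo <- c(lapply(1:3, function(i) make_cell(paste0("t", i), tri_mods,
                                              genome = g_hs)),
            lapply(4:6, function(i) make_cell(paste0("d", i), genome = g_hs)))
  clsM <- classify_embryo(mixo)
  expect_equal(clsM$events[[1]]$mechanism, "genome_wide_mixoploid")

  # a lone one-sided whole gain stays unclassified
  lone <- list(make_cell("c1", list(list("chr15", 0, 101991189, 1)),
                         genome = g_hs),
               make_cell("c2", genome = g_hs))
  expect_equal(classify_embryo(lone)$events[[1]]$mechanism, "unclassified")
})

test_that("classification is invariant under cell reordering", {
  set.seed(61)
  emb <- simulate_embryo("E1", 24,
    list(error_event("mitotic", "reciprocal_whole", "chr21", division = 2),
         error_event("mitotic", "nonreciprocal_loss", "chr7", division = 3)),
    g_hs, dropout = 0)
  cls1 <- classify_embryo(emb$cells)
  cls2 <- classify_embryo(rev(emb$cells))
  expect_equal(cls1$category, cls2$category)
  expect_equal(cls1$n_mitotic_events, cls2$n_mitotic_events)
  expect_equal(sort(vapply(cls1$events, `[[`, character(1), "mechanism")),
               sort(vapply(cls2$events, `[[`, character(1), "mechanism")))
  expect_equal(cls1$percent_normal_cells, cls2$percent_normal_cells)
})
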