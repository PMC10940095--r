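# Small fixtures built in code. The toy genome keeps segment-level tests fast;
# tests of the full pipeline use default_genome().

toy_genome <- function() {
  genome_spec(c("chrA", "chrB", "chrC"),
              length = c(100e6, 80e6, 60e6),
              centromere = c(50e6, 40e6, 30e6),
              genes = c(500L, 300L, 100L))
}

# build a cell from a diploid baseline plus (chrom, start, end, delta) edits
make_cell <- function(id, mods = list(), genome = toy_genome(),
                      lineage = "TE", embryo = "E1", qc_pass = TRUE) {
  s <- karyomosaic:::baseline_segments(genome)
  for (m in mods)
    s <- karyomosaic:::modify_cn(s, m[[1]], as.numeric(m[[2]]),
                                 as.numeric(m[[3]]), as.numeric(m[[4]]))
  cell <- cell_karyotype(id, embryo, s, lineage)
  cell$qc <- list(passed = qc_pass)
  cell
}

# a single abnormality row in the catalog's format, for matcher tests
abn_row <- function(cell_id, chrom, start, end, direction,
                    kind = "structural", delta = if (direction == "gain") 1L else -1L,
                    frac = 0.5) {
  data.frame(cell_id = cell_id, chrom = chrom, start = start, end = end,
             direction = direction, delta = delta, kind = kind,
             chrom_fraction = frac, stringsAsFactors = FALSE)
}

# deterministic "counts" at the expected value of the count model (no noise),
# for exactness and scale-invariance tests
expected_counts <- function(cell, binning, reads_total = 1e6) {
  cn <- karyomosaic:::segments_to_bins(cell$segments, binning)
  cn[is.na(cn)] <- 0
  w <- cn * (binning$end - binning$start)
  binned_counts(cell$cell_id, reads_total * w / sum(w))
}

# brute-force transitive closure of pairwise matches (independent oracle for
# event grouping): returns component labels
closure_components <- function(tab, params = match_params()) {
  n <- nrow(tab)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (tab$cell_id[i] == tab$cell_id[j]) {
      adj[i, j] <- tab$chrom[i] == tab$chrom[j]
    } else {
      adj[i, j] <- match_abnormalities(tab[i, ], tab[j, ],
                                       params)$relation != "unrelated"
    }
  }
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
    }
  }
  comp
}

# partition comparison independent of label numbering
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

expected_mechanism <- function(pattern) {
  switch(pattern,
         reciprocal_whole = "reciprocal_whole",
         reciprocal_segmental = "reciprocal_segmental",
         whole_plus_partial_loss = "whole_plus_partial_loss",
         pericentromeric_retention = "pericentromeric_retention",
         genome_wide_ploidy = "genome_wide_mixoploid",
         "unclassified")
}

# compare an embryo's inferred classification against its simulator truth log;
# returns a character vector of discrepancies (empty = full recovery)
check_recovery <- function(emb, cls) {
  probs <- character(0)
  if (cls$category != emb$category_truth)
    probs <- c(probs, paste("category", cls$category, "vs", emb$category_truth))
  oo <- vapply(emb$truth_events, `[[`, character(1), "origin_observable")
  tm <- emb$truth_events[oo == "mitotic"]
  if (cls$n_mitotic_events != length(tm))
    probs <- c(probs, paste("events", cls$n_mitotic_events, "vs", length(tm)))
  mei_truth <- sort(as.character(unlist(lapply(emb$truth_events[oo == "meiotic"],
    function(e) if (is.null(e$chromosome)) "genome" else e$chromosome))))
  mei_inf <- sort(as.character(unlist(lapply(cls$meiotic, `[[`, "chrom"))))
  if (!identical(mei_truth, mei_inf))
    probs <- c(probs, paste("meiotic calls:", paste(mei_inf, collapse = ","),
                            "vs", paste(mei_truth, collapse = ",")))
  for (e in tm) {
    ch <- if (e$pattern == "genome_wide_ploidy") "genome" else e$chromosome
    hit <- Filter(function(ev) ev$chrom == ch, cls$events)
    if (length(hit) != 1) {
      probs <- c(probs, paste("no unique event on", ch)); next
    }
    if (hit[[1]]$timing != e$timing_observable)
      probs <- c(probs, paste("timing", ch, hit[[1]]$timing, "vs",
                              e$timing_observable))
    if (hit[[1]]$mechanism != expected_mechanism(e$pattern))
      probs <- c(probs, paste("mechanism", ch, hit[[1]]$mechanism, "vs",
                              expected_mechanism(e$pattern)))
  }
  probs
}
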