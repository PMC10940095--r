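#' Specify a chromosome segregation error event
#'
#' An error event is either meiotic (inherited from the gamete, present in
#' every embryonic cell) or mitotic (occurring at a given cleavage division,
#' affecting only the descendants of that division). Mitotic patterns follow
#' the classes seen in single-cell embryo data: reciprocal whole-chromosome
#' gain/loss, reciprocal segmental gain/loss, one-sided gains/losses, whole
#' plus partial loss of the same chromosome, pericentromeric retention, and
#' genome-wide ploidy change (mixoploidy).
#'
#' @param origin \code{"meiotic"} or \code{"mitotic"}.
#' @param pattern event pattern; see Details.
#' @param chromosome chromosome name the event targets (ignored for
#'   \code{genome_wide_ploidy}).
#' @param division cleavage division index (>= 1) at which a mitotic event
#'   occurs; must be \code{NULL} for meiotic events.
#' @param span optional \code{c(start, end)} in bp for segmental patterns;
#'   \code{NULL} means whole chromosome or drawn at simulation time.
#' @param colocate optional label; mitotic events at the same division sharing
#'   a label hit the same dividing cell (used to build complex-cell clones).
#' @return An \code{error_event} object.
#' @export
error_event <- function(origin = c("mitotic", "meiotic"),
                        pattern = c("reciprocal_whole", "reciprocal_segmental",
                                    "nonreciprocal_gain", "nonreciprocal_loss",
                                    "whole_plus_partial_loss",
                                    "pericentromeric_retention",
                                    "genome_wide_ploidy"),
                        chromosome = NULL, division = NULL, span = NULL,
                        colocate = NULL) {
  origin <- match.arg(origin)
  pattern <- match.arg(pattern)
  if (origin == "meiotic") {
    if (!is.null(division)) stop("meiotic events have no division index")
    if (!pattern %in% c("nonreciprocal_gain", "nonreciprocal_loss"))
      stop("meiotic events are modeled as whole-chromosome gains or losses")
  } else {
    if (is.null(division) || division < 1) stop("mitotic events need division >= 1")
  }
  if (!is.null(span) && span[2] <= span[1]) stop("invalid span")
  structure(list(origin = origin, pattern = pattern, chromosome = chromosome,
                 division = division, span = span, colocate = colocate),
            class = "error_event")
}

# Draw any unspecified breakpoints and turn an event into concrete copy-number
# modifications for the two daughter sublineages. Breakpoints land on a
# `quantum` lattice so default 1 Mb bins see clean segment edges.
# Returns list(mods_A, mods_B, spans) where mods_* are data.frames
# (chrom, start, end, delta) and spans the truth-log affected spans.
realize_event <- function(event, genome, quantum = 1e6) {
  mods <- function(chrom, start, end, delta)
    data.frame(chrom = chrom, start = start, end = end, delta = delta,
               stringsAsFactors = FALSE)
  lattice <- function(lo, hi) {
    ticks <- seq(ceiling(lo / quantum), floor(hi / quantum)) * quantum
    if (length(ticks) == 0) return((lo + hi) / 2)
    ticks[sample.int(length(ticks), 1)]
  }
  if (event$pattern == "genome_wide_ploidy") {
    return(list(mods_A = mods(genome$chrom, 0, genome$length, 1L),
                mods_B = NULL,
                spans = data.frame(chrom = "genome", start = 0, end = 0,
                                   delta = 1L)))
  }
  chrom <- event$chromosome
  i <- match(chrom, genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  L <- genome$length[i]
  cen <- genome$centromere[i]
  span <- event$span
  switch(event$pattern,
    reciprocal_whole = {
      list(mods_A = mods(chrom, 0, L, 1L), mods_B = mods(chrom, 0, L, -1L),
           spans = mods(chrom, 0, L, 1L))
    },
    reciprocal_segmental = {
      if (is.null(span)) {
        # terminal segment of one arm, 10 Mb up to ~80% of the chromosome
        q_arm <- stats::runif(1) < 0.5
        lo <- max(0.2 * L, 10e6); hi <- L - 10e6
        bp <- lattice(min(lo, hi), max(lo, hi))
        span <- if (q_arm) c(bp, L) else c(0, L - bp)
      }
      list(mods_A = mods(chrom, span[1], span[2], 1L),
           mods_B = mods(chrom, span[1], span[2], -1L),
           spans = mods(chrom, span[1], span[2], 1L))
    },
    nonreciprocal_gain = {
      if (is.null(span)) span <- c(0, L)
      list(mods_A = mods(chrom, span[1], span[2], 1L), mods_B = NULL,
           spans = mods(chrom, span[1], span[2], 1L))
    },
    nonreciprocal_loss = {
      if (is.null(span)) span <- c(0, L)
      list(mods_A = mods(chrom, span[1], span[2], -1L), mods_B = NULL,
           spans = mods(chrom, span[1], span[2], -1L))
    },
    whole_plus_partial_loss = {
      # daughter A loses the whole chromosome; daughter B a terminal segment
      # distal to a shared proximal point (kept >= 6 Mb so it stays reportable)
      p0 <- lattice(0.2 * L, min(0.6 * L, L - 12e6))
      bp <- lattice(p0, min(0.9 * L, L - 6e6))
      list(mods_A = mods(chrom, 0, L, -1L),
           mods_B = mods(chrom, bp, L, -1L),
           spans = rbind(mods(chrom, 0, L, -1L), mods(chrom, bp, L, -1L)))
    },
    pericentromeric_retention = {
      w <- lattice(2e6, 10e6)  # retained half-width around the centromere
      a <- rbind(mods(chrom, 0, max(0, cen - w), -1L),
                 mods(chrom, min(L, cen + w), L, -1L))
      list(mods_A = a, mods_B = NULL, spans = a)
    }
  )
}

apply_mods <- function(segments, m) {
  if (is.null(m)) return(segments)
  for (j in seq_len(nrow(m)))
    segments <- modify_cn(segments, m$chrom[j], m$start[j], m$end[j], m$delta[j])
  segments
}

#' Apply a mitotic segregation error to a parent cell
#'
#' Produces the two daughter karyotypes. For reciprocal patterns one daughter
#' gains and the other loses the identical span, so the total copy number over
#' both daughters on that span is conserved (2x the parent's).
#'
#' @param parent a \code{cell_karyotype}.
#' @param event a mitotic \code{error_event}.
#' @param genome a \code{genome_spec}.
#' @return list with elements \code{A} and \code{B}, the daughter
#'   \code{cell_karyotype}s (\code{A} carries the gain for reciprocal
#'   patterns), plus \code{spans}, the affected spans.
#' @export
apply_mitotic_error <- function(parent, event, genome) {
  stopifnot(inherits(parent, "cell_karyotype"), inherits(event, "error_event"))
  if (event$origin != "mitotic") stop("event is not mitotic")
  r <- realize_event(event, genome)
  for (m in list(r$mods_A, r$mods_B)) {
    if (is.null(m)) next
    losses <- m[m$delta < 0, , drop = FALSE]
    for (j in seq_len(nrow(losses))) {
      cn <- span_mean_cn(parent$segments, losses$chrom[j], losses$start[j],
                         losses$end[j])
      if (!is.na(cn) && cn < 1) stop("cannot lose copies from CN=0 span")
    }
  }
  A <- cell_karyotype(paste0(parent$cell_id, ".A"), parent$embryo_id,
                      apply_mods(parent$segments, r$mods_A), parent$lineage)
  B <- cell_karyotype(paste0(parent$cell_id, ".B"), parent$embryo_id,
                      apply_mods(parent$segments, r$mods_B), parent$lineage)
  list(A = A, B = B, spans = r$spans)
}

# ancestor index (1-based) at `level` of leaf `idx` at depth `depth`
ancestor_at <- function(idx, depth, level) {
  ((idx - 1L) %/% (2L^(depth - level))) + 1L
}

#' Assign TE/ICM lineage labels over a division tree
#'
#' Lineage specification is modeled at a fixed division: each subtree rooted
#' at \code{spec_division} is assigned one lineage, with \code{n_icm} of the
#' \code{2^spec_division} subtrees drawn uniformly as ICM. A mixing
#' probability lets individual cells take the other lineage, so descendants
#' of one subtree can split across lineages.
#'
#' @param leaf_idx integer leaf positions (1-based) at tree depth \code{depth}.
#' @param depth tree depth (leaves live at \code{2^depth} positions).
#' @param spec_division division at which lineages are specified (default 3,
#'   the 8-cell stage); must not exceed \code{depth}.
#' @param n_icm number of ICM subtrees among \code{2^spec_division}.
#' @param mixing per-cell probability of taking the other lineage.
#' @return character vector of \code{"TE"}/\code{"ICM"} labels, one per leaf,
#'   with the subtree assignment in attribute \code{"subtree_lineage"}.
#' @export
allocate_lineages <- function(leaf_idx, depth, spec_division = 3, n_icm = 2,
                              mixing = 0) {
  if (spec_division > depth) stop("specification division beyond tree depth")
  m <- 2L^spec_division
  stopifnot(n_icm >= 0, n_icm <= m)
  subtree <- rep("TE", m)
  if (n_icm > 0) subtree[sample.int(m, n_icm)] <- "ICM"
  lab <- subtree[ancestor_at(leaf_idx, depth, spec_division)]
  if (mixing > 0) {
    flip <- stats::runif(length(lab)) < mixing
    lab[flip] <- ifelse(lab[flip] == "TE", "ICM", "TE")
  }
  attr(lab, "subtree_lineage") <- subtree
  lab
}

#' Probability that a pre-specification event is confined to one lineage
#'
#' Under the subtree allocation model with zero mixing: an event whose
#' products occupy \code{n_event} of the \code{n_total} specification-level
#' subtrees is restricted to a single lineage exactly when all those subtrees
#' drew the same label. Closed form over the uniform choice of \code{n_icm}
#' ICM subtrees.
#'
#' @param n_total total subtrees at the specification division (2^division).
#' @param n_icm number of ICM subtrees.
#' @param n_event number of subtrees carrying event products.
#' @return probability in [0, 1].
#' @export
prob_restricted_one_lineage <- function(n_total, n_icm, n_event) {
  stopifnot(n_event >= 1, n_event <= n_total, n_icm >= 0, n_icm <= n_total)
  all_te <- if (n_icm <= n_total - n_event)
    choose(n_total - n_event, n_icm) / choose(n_total, n_icm) else 0
  all_icm <- if (n_icm >= n_event)
    choose(n_total - n_event, n_icm - n_event) / choose(n_total, n_icm) else 0
  all_te + all_icm
}

#' Simulate one blastocyst-like embryo with a known error history
#'
#' Cells arise on a synchronous binary division tree of depth
#' \code{ceiling(log2(n_cells))}; the \code{n_cells} sampled leaves stand for
#' the cells present at biopsy. Meiotic events are applied to the zygote and
#' therefore to every cell. Each mitotic event is placed at its division on a
#' parent whose daughters both have surviving descendants, and the two
#' daughter sublineages receive the event's complementary products. Lineages
#' are labeled at a specification division, and a dropout mask marks which
#' cells were successfully karyotyped.
#'
#' @param embryo_id identifier.
#' @param n_cells number of cells (>= 2).
#' @param events list of \code{error_event}s.
#' @param genome a \code{genome_spec}; default female hg38 (autosomes + XX).
#' @param spec_division lineage specification division (default 3).
#' @param icm_fraction target ICM fraction, converted to a number of
#'   specification-level subtrees (at least 1 unless 0).
#' @param mixing lineage mixing probability (see
#'   \code{\link{allocate_lineages}}).
#' @param dropout probability that a cell fails karyotyping.
#' @param seed optional integer seed.
#' @param category optional truth category label stored in the truth log.
#' @return A \code{simulated_embryo}: list with \code{cells} (list of
#'   \code{cell_karyotype}, QC pass mirroring the dropout mask),
#'   \code{truth_events}, \code{dropout_mask}, and \code{tree} bookkeeping.
#' @export
simulate_embryo <- function(embryo_id = "E1", n_cells = 40, events = list(),
                            genome = default_genome("female"),
                            spec_division = 3, icm_fraction = 0.2,
                            mixing = 0, dropout = 0, seed = NULL,
                            category = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cells < 2) stop("need at least 2 cells")
  depth <- max(ceiling(log2(n_cells)), spec_division)
  n_leaves <- 2L^depth
  leaf_idx <- if (n_cells == n_leaves) seq_len(n_leaves)
              else sort(sample.int(n_leaves, n_cells))
  cell_ids <- sprintf("%s_c%03d", embryo_id, seq_len(n_cells))

  base <- baseline_segments(genome)
  truth <- list()
  for (ev in events) {
    if (ev$origin != "meiotic") next
    r <- realize_event(ev, genome)
    base <- apply_mods(base, r$mods_A)
    truth[[length(truth) + 1]] <- list(
      event_id = sprintf("%s_ev%02d", embryo_id, length(truth) + 1L),
      origin = "meiotic", pattern = ev$pattern, chromosome = ev$chromosome,
      division = NA_integer_, spans = r$spans,
      carriers = cell_ids, carriers_A = cell_ids, carriers_B = character(0))
  }

  seg_list <- rep(list(base), n_cells)
  mitotic <- Filter(function(e) e$origin == "mitotic", events)
  if (length(mitotic) > 0) {
    ord <- order(vapply(mitotic, `[[`, numeric(1), "division"))
    colocated <- list()
    for (ev in mitotic[ord]) {
      d <- ev$division
      if (d > depth) stop("event division deeper than tree")
      parents <- unique(ancestor_at(leaf_idx, depth, d - 1L))
      both <- parents[vapply(parents, function(p) {
        kids <- ancestor_at(leaf_idx, depth, d)
        any(kids == 2L * p - 1L) && any(kids == 2L * p)
      }, logical(1))]
      if (length(both) == 0) stop("no division-", d,
                                  " parent with two surviving daughters")
      key <- if (is.null(ev$colocate)) NULL else paste(d, ev$colocate)
      p <- if (!is.null(key) && !is.null(colocated[[key]])) colocated[[key]]
           else both[sample.int(length(both), 1)]
      if (!is.null(key)) colocated[[key]] <- p
      kids <- ancestor_at(leaf_idx, depth, d)
      in_A <- kids == 2L * p - 1L
      in_B <- kids == 2L * p
      r <- realize_event(ev, genome)
      for (k in which(in_A)) seg_list[[k]] <- apply_mods(seg_list[[k]], r$mods_A)
      for (k in which(in_B)) seg_list[[k]] <- apply_mods(seg_list[[k]], r$mods_B)
      carriers_A <- cell_ids[in_A]
      carriers_B <- if (is.null(r$mods_B)) character(0) else cell_ids[in_B]
      truth[[length(truth) + 1]] <- list(
        event_id = sprintf("%s_ev%02d", embryo_id, length(truth) + 1L),
        origin = "mitotic", pattern = ev$pattern, chromosome = ev$chromosome,
        division = d, parent = p, spans = r$spans,
        carriers = c(carriers_A, carriers_B),
        carriers_A = carriers_A, carriers_B = carriers_B,
        timing_truth = if (d <= spec_division) "pre_specification"
                       else "post_specification")
    }
  }

  m <- 2L^spec_division
  n_icm <- if (icm_fraction <= 0) 0L else max(1L, round(m * icm_fraction))
  lineage <- allocate_lineages(leaf_idx, depth, spec_division, n_icm, mixing)
  dropped <- stats::runif(n_cells) < dropout

  cells <- lapply(seq_len(n_cells), function(k) {
    cell <- cell_karyotype(cell_ids[k], embryo_id, seg_list[[k]], lineage[k])
    cell$qc <- list(passed = !dropped[k], dropout = dropped[k])
    cell
  })
  names(cells) <- cell_ids

  # annotate each truth event with the lineages its carriers landed in --
  # the recoverable notion of timing (a pre-specification event whose
  # products all drifted into one lineage is observationally post)
  both_lineages <- length(unique(lineage)) == 2
  truth <- lapply(truth, function(e) {
    lin <- unique(lineage[match(e$carriers, cell_ids)])
    e$lineages_truth <- sort(lin)
    e$timing_observable <- if (!both_lineages) "unassessable"
      else if (length(lin) == 2) "pre_specification" else "post_specification"
    # a mitotic event is indistinguishable from a meiotic one (every-cell
    # rule) when one product signature -- or the same-matched union of its
    # whole+partial loss products -- reaches every cell
    covers_all <- length(e$carriers_A) == n_cells ||
      length(e$carriers_B) == n_cells ||
      (identical(e$pattern, "whole_plus_partial_loss") &&
         length(e$carriers) == n_cells)
    e$origin_observable <- if (e$origin == "mitotic" && covers_all) "meiotic"
                           else e$origin
    e
  })
  structure(list(
    embryo_id = embryo_id, cells = cells, truth_events = truth,
    dropout_mask = stats::setNames(dropped, cell_ids),
    category_truth = category,
    tree = list(depth = depth, leaf_idx = leaf_idx,
                spec_division = spec_division,
                subtree_lineage = attr(lineage, "subtree_lineage"))),
    class = "simulated_embryo")
}

#' @export
print.simulated_embryo <- function(x, ...) {
  cat(sprintf("<simulated_embryo> %s: %d cells (%d karyotyped), %d truth events\n",
              x$embryo_id, length(x$cells), sum(!x$dropout_mask),
              length(x$truth_events)))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study conditions: 55 embryos of 20-80 cells, ~20% ICM,
#' 55% karyotyping dropout, embryo category mix 6:4:32:13 (normal : uniformly
#' abnormal : diploid-aneuploid mosaic : aneuploid mosaic), and 1 + Poisson(1.2)
#' mitotic events per mosaic embryo so ~70% of mosaic embryos carry more than
#' one event.
#'
#' @param n_embryos number of embryos.
#' @param cells_range min/max cells per embryo (drawn uniformly).
#' @param category_probs named probabilities over \code{normal},
#'   \code{uniformly_abnormal}, \code{diploid_aneuploid_mosaic},
#'   \code{aneuploid_mosaic}; must sum to 1.
#' @param events_lambda Poisson mean of extra mitotic events per mosaic embryo.
#' @param pattern_weights named weights over mitotic event patterns.
#' @param complex_prob probability a mosaic embryo carries a burst of 5
#'   co-lineage one-sided events, yielding complex (>4 abnormalities) cells.
#' @param mixoploid_prob probability an aneuploid-mosaic embryo is mixoploid
#'   (genome-wide ploidy event) instead of meiotic + mitotic.
#' @param dropout per-cell karyotyping failure probability.
#' @param icm_fraction,spec_division,mixing lineage model parameters.
#' @param reads_per_cell,dispersion,bin_size count-simulation parameters.
#' @param seed integer seed recorded in all outputs.
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(n_embryos = 55, cells_range = c(20, 80),
                          category_probs = c(normal = 6, uniformly_abnormal = 4,
                                             diploid_aneuploid_mosaic = 32,
                                             aneuploid_mosaic = 13) / 55,
                          events_lambda = 1.2,
                          pattern_weights = c(reciprocal_whole = 0.22,
                                              reciprocal_segmental = 0.34,
                                              whole_plus_partial_loss = 0.16,
                                              nonreciprocal_gain = 0.10,
                                              nonreciprocal_loss = 0.12,
                                              pericentromeric_retention = 0.06),
                          complex_prob = 0.15, mixoploid_prob = 0.08,
                          dropout = 0.55, icm_fraction = 0.2,
                          spec_division = 3, mixing = 0,
                          reads_per_cell = 3e5, dispersion = 0.01,
                          bin_size = 1e6, seed = 1L) {
  stopifnot(abs(sum(category_probs) - 1) < 1e-8,
            all(cells_range >= 2), cells_range[1] <= cells_range[2])
  structure(as.list(environment()), class = "cohort_config")
}

# Draw the error events for one embryo of a given truth category.
draw_embryo_events <- function(category, config, genome, depth) {
  auto <- autosomes(genome)
  used <- character(0)
  pick_chrom <- function(from = auto) {
    pool <- setdiff(from, used)
    if (length(pool) == 0) pool <- setdiff(auto, used)
    ch <- pool[sample.int(length(pool), 1)]
    used <<- c(used, ch)
    ch
  }
  # pericentromeric retention needs sizeable arms on both sides so that both
  # flanking losses clear the reporting filter
  metacentric <- genome$chrom[genome$centromere >= 30e6 &
                              genome$length - genome$centromere >= 30e6]
  metacentric <- intersect(metacentric, auto)
  ev <- list()
  n_mitotic <- 0L
  if (category %in% c("uniformly_abnormal", "aneuploid_mosaic")) {
    dir <- sample(c("nonreciprocal_gain", "nonreciprocal_loss"), 1,
                  prob = c(0.45, 0.55))
    ev <- c(ev, list(error_event("meiotic", dir, pick_chrom())))
  }
  if (category %in% c("diploid_aneuploid_mosaic", "aneuploid_mosaic")) {
    n_mitotic <- 1L + stats::rpois(1, config$events_lambda)
    for (k in seq_len(n_mitotic)) {
      pat <- sample(names(config$pattern_weights), 1,
                    prob = config$pattern_weights)
      # division drawn uniformly over rounds: reproduces the reported balance
      # of pre- vs post-specification events (early rounds are error-prone
      # despite having fewer dividing cells)
      d <- sample.int(depth, 1)
      ch <- if (pat == "pericentromeric_retention") pick_chrom(metacentric)
            else pick_chrom()
      ev <- c(ev, list(error_event("mitotic", pat, ch, division = d)))
    }
    if (stats::runif(1) < config$complex_prob && length(used) + 5 <= length(auto)) {
      # a burst of co-located one-sided errors: one sublineage accumulates
      # >4 abnormalities and its cells become complex abnormal
      d <- max(2L, depth - 1L)
      for (k in 1:5)
        ev <- c(ev, list(error_event("mitotic",
                                     sample(c("nonreciprocal_gain",
                                              "nonreciprocal_loss"), 1),
                                     pick_chrom(), division = d,
                                     colocate = "complex_burst")))
    }
  }
  ev
}

#' Simulate a cohort of blastocysts
#'
#' Draws each embryo's truth category from the configured mix, injects the
#' corresponding meiotic/mitotic events (each on a distinct autosome), and
#' retries embryos whose realized cell-level statuses do not reproduce the
#' intended category (e.g. a division-1 reciprocal event leaving no normal
#' cell in an intended diploid-aneuploid mosaic). Aneuploid-mosaic embryos are
#' occasionally realized as mixoploid (diploid next to fully triploid cells).
#'
#' @param config a \code{cohort_config}.
#' @param genome a \code{genome_spec}.
#' @return list of \code{simulated_embryo} objects; the config is attached as
#'   attribute \code{"config"}.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            genome = default_genome("female")) {
  set.seed(config$seed)
  cats <- names(config$category_probs)
  embryos <- vector("list", config$n_embryos)
  for (i in seq_len(config$n_embryos)) {
    category <- sample(cats, 1, prob = config$category_probs)
    n_cells <- sample(seq(config$cells_range[1], config$cells_range[2]), 1)
    depth <- max(ceiling(log2(n_cells)), config$spec_division)
    for (try in 1:25) {
      if (category == "aneuploid_mosaic" &&
          stats::runif(1) < config$mixoploid_prob) {
        # mixoploid realization: a meiotic trisomy in every cell plus a
        # genome-wide ploidy change in one sublineage, so all cells are
        # abnormal but cytogenetically different
        auto <- autosomes(genome)
        ev <- list(error_event("meiotic", "nonreciprocal_gain", sample(auto, 1)),
                   error_event("mitotic", "genome_wide_ploidy",
                               division = sample.int(2, 1)))
      } else {
        ev <- draw_embryo_events(category, config, genome, depth)
      }
      emb <- simulate_embryo(sprintf("E%02d", i), n_cells, ev, genome,
                             config$spec_division, config$icm_fraction,
                             config$mixing, config$dropout,
                             category = category)
      if (realized_category_ok(emb, category)) break
    }
    embryos[[i]] <- emb
  }
  attr(embryos, "config") <- config
  embryos
}

# Truth category implied by which cells carry event products (pre-dropout),
# by the same definitional rules the classifier uses.
implied_truth_category <- function(embryo) {
  origins <- vapply(embryo$truth_events, `[[`, character(1), "origin")
  has_mei <- any(origins == "meiotic")
  has_mit <- any(origins == "mitotic")
  mit_carriers <- unique(unlist(lapply(
    embryo$truth_events[origins == "mitotic"], `[[`, "carriers")))
  n <- length(embryo$cells)
  if (!has_mei && !has_mit) return("normal")
  if (has_mei && !has_mit) return("uniformly_abnormal")
  if (has_mei) return("aneuploid_mosaic")
  if (length(mit_carriers) == n) "aneuploid_mosaic" else "diploid_aneuploid_mosaic"
}

realized_category_ok <- function(embryo, category) {
  implied_truth_category(embryo) == category &&
    all(vapply(embryo$truth_events, function(e) length(e$carriers) > 0,
               logical(1)))
}

#' Simulate binned sequencing counts for one cell
#'
#' Expected count per bin is proportional to bin copy number times bin length;
#' counts are negative-binomial with the given dispersion (Poisson in the
#' dispersion-0 limit), so the emitted total is within sampling tolerance of
#' \code{reads_total}.
#'
#' @param cell a \code{cell_karyotype}.
#' @param binning a \code{genome_binning}.
#' @param reads_total target total read count.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @return A \code{binned_counts} list: \code{cell_id}, integer \code{counts}
#'   per bin, \code{total_reads}.
#' @export
simulate_binned_counts <- function(cell, binning, reads_total = 3e5,
                                   dispersion = 0.01) {
  stopifnot(reads_total > 0, dispersion >= 0, nrow(binning) >= 1)
  cn <- segments_to_bins(cell$segments, binning)
  cn[is.na(cn)] <- 0
  w <- cn * (binning$end - binning$start)
  if (sum(w) <= 0) stop("cell has no genomic material in the binning")
  mu <- reads_total * w / sum(w)
  counts <- if (dispersion == 0) stats::rpois(length(mu), mu)
            else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  binned_counts(cell$cell_id, counts)
}

#' Binned counts container
#'
#' @param cell_id identifier.
#' @param counts nonnegative integer vector, one count per bin.
#' @return A \code{binned_counts} list with \code{total_reads = sum(counts)}.
#' @export
binned_counts <- function(cell_id, counts) {
  stopifnot(all(counts >= 0))
  structure(list(cell_id = cell_id, counts = as.numeric(counts),
                 total_reads = sum(counts)),
            class = "binned_counts")
}
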