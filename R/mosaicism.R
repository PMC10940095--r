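#' Abnormality matching parameters
#'
#' @param tolerance_bins breakpoint tolerance, in bins (default 2).
#' @param min_overlap minimum reciprocal span-overlap fraction (default 0.8).
#' @param bin_size bin width in bp used to convert the tolerance.
#' @return A \code{match_params} list.
#' @export
match_params <- function(tolerance_bins = 2, min_overlap = 0.8,
                         bin_size = 1e6) {
  stopifnot(tolerance_bins >= 0, min_overlap > 0, min_overlap <= 1)
  structure(list(tolerance_bins = tolerance_bins, min_overlap = min_overlap,
                 bin_size = bin_size, tolerance_bp = tolerance_bins * bin_size),
            class = "match_params")
}

#' Compare two abnormalities from different cells
#'
#' Two abnormalities are the \emph{same} when they affect the same chromosome
#' in the same direction with spans that reciprocally overlap at least
#' \code{min_overlap} and breakpoints within tolerance; \emph{reciprocal}
#' when the direction is opposite under the same span criteria.
#' Whole-chromosome (numerical) calls match each other regardless of bin
#' jitter. A whole-chromosome loss also matches a partial loss of the same
#' chromosome as a same-event candidate (returned as same with a containment
#' flag), reflecting progressive loss of a damaged chromosome. Genome-wide
#' ploidy anomalies match each other by direction.
#'
#' @param a,b single abnormality rows (one-row data.frames or lists) as
#'   produced by \code{\link{extract_abnormalities}}.
#' @param params a \code{match_params}.
#' @return list with \code{relation} (\code{"same"}, \code{"reciprocal"},
#'   \code{"unrelated"}) and logical \code{containment}.
#' @export
match_abnormalities <- function(a, b, params = match_params()) {
  res <- function(rel, cont = FALSE) list(relation = rel, containment = cont)
  if (a$kind == "genome_wide" || b$kind == "genome_wide") {
    if (a$kind == b$kind && a$direction == b$direction) return(res("same"))
    return(res("unrelated"))
  }
  if (a$chrom != b$chrom) return(res("unrelated"))
  whole_a <- a$kind == "numerical"; whole_b <- b$kind == "numerical"
  if (whole_a && whole_b)
    return(res(if (a$direction == b$direction) "same" else "reciprocal"))
  if (xor(whole_a, whole_b)) {
    # whole-chromosome loss vs partial loss: same-event candidate
    if (a$direction == "loss" && b$direction == "loss")
      return(res("same", cont = TRUE))
    return(res("unrelated"))
  }
  ov <- min(a$end, b$end) - max(a$start, b$start)
  len_a <- a$end - a$start; len_b <- b$end - b$start
  span_ok <- ov > 0 && ov / len_a >= params$min_overlap &&
    ov / len_b >= params$min_overlap &&
    abs(a$start - b$start) <= params$tolerance_bp &&
    abs(a$end - b$end) <= params$tolerance_bp
  if (!span_ok) return(res("unrelated"))
  res(if (a$direction == b$direction) "same" else "reciprocal")
}

# Vectorized pairwise relations over an abnormality table: n x n character
# matrix of "same"/"reciprocal"/"unrelated" plus a containment indicator.
# Must agree with match_abnormalities() pair by pair (property-tested).
relation_matrix <- function(tab, params = match_params()) {
  n <- nrow(tab)
  rel <- matrix("unrelated", n, n)
  cont <- matrix(FALSE, n, n)
  if (n == 0) return(list(relation = rel, containment = cont))
  gw <- tab$kind == "genome_wide"
  whole <- tab$kind == "numerical"
  loss <- tab$direction == "loss"
  dir_eq <- outer(tab$direction, tab$direction, "==")
  chrom_eq <- outer(tab$chrom, tab$chrom, "==")
  both_gw <- outer(gw, gw, "&")
  rel[both_gw & dir_eq] <- "same"
  base <- chrom_eq & !outer(gw, gw, "|")
  wb <- outer(whole, whole, "&") & base
  rel[wb & dir_eq] <- "same"
  rel[wb & !dir_eq] <- "reciprocal"
  mixed <- base & outer(whole, whole, "!=") & outer(loss, loss, "&")
  rel[mixed] <- "same"
  cont[mixed] <- TRUE
  len <- tab$end - tab$start
  ov <- outer(tab$end, tab$end, pmin) - outer(tab$start, tab$start, pmax)
  span_ok <- ov > 0 &
    ov / matrix(len, n, n) >= params$min_overlap &
    ov / matrix(len, n, n, byrow = TRUE) >= params$min_overlap &
    abs(outer(tab$start, tab$start, "-")) <= params$tolerance_bp &
    abs(outer(tab$end, tab$end, "-")) <= params$tolerance_bp
  pb <- outer(!whole & !gw, !whole & !gw, "&") & base & span_ok
  rel[pb & dir_eq] <- "same"
  rel[pb & !dir_eq] <- "reciprocal"
  diag(rel) <- "unrelated"
  list(relation = rel, containment = cont)
}

# minimal union-find over 1..n given an edge matrix (2 columns)
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (length(edges) > 0)
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

embryo_abnormality_table <- function(cells, catalog = catalog_params(),
                                     genome = default_genome("female")) {
  cells <- Filter(cell_qc_passed, cells)
  if (length(cells) == 0) stop("no QC-passed cells in embryo")
  tab <- do.call(rbind, lapply(cells, extract_abnormalities, params = catalog,
                               genome = genome))
  list(cells = cells, abnormalities = tab)
}

#' Classify the origin of each distinct abnormality in an embryo
#'
#' Abnormality signatures are clustered across QC-passed cells (transitive
#' closure of the same-relation, including whole/partial containment). A
#' cluster present in every QC-passed cell is meiotic; anything else is
#' mitotic. Single-cell embryos yield meiotic calls flagged low-confidence;
#' clusters supported by one cell are flagged low-support.
#'
#' @param cells list of \code{cell_karyotype}s of one embryo.
#' @param params a \code{match_params}.
#' @param catalog a \code{catalog_params}.
#' @param genome a \code{genome_spec}.
#' @return list with \code{calls} (one entry per cluster: chrom, span,
#'   direction, kind, origin, supporting cell ids, flags) and
#'   \code{abnormalities}, the per-cell table annotated with \code{cluster}
#'   and \code{origin} columns.
#' @export
classify_origin <- function(cells, params = match_params(),
                            catalog = catalog_params(),
                            genome = default_genome("female")) {
  et <- embryo_abnormality_table(cells, catalog, genome)
  tab <- et$abnormalities
  n_cells <- length(et$cells)
  if (nrow(tab) == 0)
    return(list(calls = list(), abnormalities = cbind(tab, cluster = integer(0),
                                                      origin = character(0))))
  n <- nrow(tab)
  rm_ <- relation_matrix(tab, params)
  adj <- rm_$relation == "same" &
    outer(tab$cell_id, tab$cell_id, "!=")
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  cl <- uf_components(n, edges)
  tab$cluster <- cl
  calls <- lapply(sort(unique(cl)), function(k) {
    m <- tab[cl == k, , drop = FALSE]
    supp <- unique(m$cell_id)
    origin <- if (length(supp) == n_cells) "meiotic" else "mitotic"
    list(cluster = k, chrom = m$chrom[1],
         start = min(m$start), end = max(m$end),
         direction = m$direction[1], kind = m$kind[1], origin = origin,
         cells = supp, n_cells = length(supp),
         low_confidence = n_cells == 1, low_support = length(supp) == 1)
  })
  origin_by_cluster <- vapply(calls, `[[`, character(1), "origin")
  tab$origin <- origin_by_cluster[cl]
  list(calls = calls, abnormalities = tab)
}

#' Group mitotic abnormalities into segregation-error events
#'
#' Builds a graph over (cell, abnormality) nodes with edges for same,
#' reciprocal and containment matches between cells, plus edges between
#' abnormalities of one cell on the same chromosome (one damaged chromosome's
#' products). Connected components are events; the per-embryo mitotic event
#' count is the number of components. The result is invariant to input
#' ordering.
#'
#' @param abnormalities annotated abnormality table (the mitotic rows of
#'   \code{\link{classify_origin}}'s output).
#' @param params a \code{match_params}.
#' @return list of \code{mitotic_event} objects: \code{event_id},
#'   \code{members} (abnormality rows), \code{chrom}, unified \code{span},
#'   \code{reciprocal} flag, \code{n_cells}.
#' @export
group_events <- function(abnormalities, params = match_params()) {
  tab <- abnormalities
  if (nrow(tab) == 0) return(list())
  n <- nrow(tab)
  rm_ <- relation_matrix(tab, params)
  same_cell <- outer(tab$cell_id, tab$cell_id, "==")
  same_chrom <- outer(tab$chrom, tab$chrom, "==")
  adj <- (!same_cell & rm_$relation != "unrelated") |
    (same_cell & same_chrom)
  diag(adj) <- FALSE
  recip <- !same_cell & rm_$relation == "reciprocal"
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  comp <- uf_components(n, edges)
  lapply(sort(unique(comp)), function(k) {
    idx <- which(comp == k)
    m <- tab[idx, , drop = FALSE]
    structure(list(
      event_id = k, members = m,
      chrom = if (any(m$kind == "genome_wide")) "genome" else m$chrom[1],
      span = c(min(m$start), max(m$end)),
      reciprocal = any(recip[idx, idx]),
      n_cells = length(unique(m$cell_id)),
      low_support = length(unique(m$cell_id)) == 1),
      class = "mitotic_event")
  })
}

#' Timing of a mitotic event relative to lineage specification
#'
#' An event whose member cells sit in both TE and ICM must have occurred
#' before lineage specification; members confined to one lineage are labeled
#' post-specification (with the caveat that pre-specification products can end
#' up in one lineage by chance). Embryos lacking QC-passed cells in both
#' lineages are unassessable.
#'
#' @param event a \code{mitotic_event}.
#' @param cells the embryo's cells (for lineage lookup).
#' @return \code{"pre_specification"}, \code{"post_specification"} or
#'   \code{"unassessable"}.
#' @export
infer_event_timing <- function(event, cells) {
  cells <- Filter(cell_qc_passed, cells)
  lin <- vapply(cells, `[[`, character(1), "lineage")
  names(lin) <- vapply(cells, `[[`, character(1), "cell_id")
  if (length(unique(lin[lin %in% c("TE", "ICM")])) < 2) return("unassessable")
  member_lin <- unique(lin[unique(event$members$cell_id)])
  if (all(c("TE", "ICM") %in% member_lin)) "pre_specification"
  else "post_specification"
}

#' Mechanism label for a mitotic event
#'
#' Priority-ordered: genome-wide mixoploidy; reciprocal whole-chromosome
#' gain+loss; reciprocal segmental gain+loss; whole plus partial loss of one
#' chromosome; pericentromeric retention (losses flanking but sparing the
#' centromere); otherwise unclassified.
#'
#' @param event a \code{mitotic_event}.
#' @param genome a \code{genome_spec} (for centromere positions).
#' @param params a \code{match_params}.
#' @return mechanism label string.
#' @export
classify_mechanism <- function(event, genome = default_genome("female"),
                               params = match_params()) {
  m <- event$members
  if (any(m$kind == "genome_wide")) return("genome_wide_mixoploid")
  num_gain <- any(m$kind == "numerical" & m$direction == "gain")
  num_loss <- any(m$kind == "numerical" & m$direction == "loss")
  str_gain <- any(m$kind == "structural" & m$direction == "gain")
  str_loss <- any(m$kind == "structural" & m$direction == "loss")
  if (num_gain && num_loss) return("reciprocal_whole")
  if (str_gain && str_loss) {
    gains <- m[m$kind == "structural" & m$direction == "gain", , drop = FALSE]
    losses <- m[m$kind == "structural" & m$direction == "loss", , drop = FALSE]
    for (i in seq_len(nrow(gains))) for (j in seq_len(nrow(losses)))
      if (match_abnormalities(gains[i, ], losses[j, ],
                              params)$relation == "reciprocal")
        return("reciprocal_segmental")
  }
  if (num_loss && str_loss) return("whole_plus_partial_loss")
  if (all(m$direction == "loss") && nrow(m) >= 2) {
    cen <- genome$centromere[match(m$chrom[1], genome$chrom)]
    spares_cen <- all(m$end <= cen | m$start >= cen)
    both_sides <- any(m$end <= cen) && any(m$start >= cen)
    if (spares_cen && both_sides) return("pericentromeric_retention")
  }
  "unclassified"
}

#' Classify an embryo from its cells' karyotypes
#'
#' Runs the full embryo-level inference: per-cell abnormality catalogs and
#' statuses, origin calls, mitotic event grouping with timing and mechanism,
#' and the embryo category -- normal (only normal cells), uniformly abnormal
#' (all cells abnormal with identical catalogs), diploid-aneuploid mosaic
#' (normal and abnormal cells), or aneuploid mosaic (all abnormal,
#' cytogenetically different).
#'
#' @param cells list of \code{cell_karyotype}s of one embryo.
#' @param params a \code{match_params}.
#' @param catalog a \code{catalog_params}.
#' @param genome a \code{genome_spec}.
#' @return An \code{embryo_classification} list: \code{category},
#'   \code{percent_normal_cells}, per-lineage tallies, \code{origin} (calls +
#'   annotated abnormalities), \code{events} (with \code{timing} and
#'   \code{mechanism}), \code{n_mitotic_events}, \code{meiotic} calls.
#' @export
classify_embryo <- function(cells, params = match_params(),
                            catalog = catalog_params(),
                            genome = default_genome("female")) {
  qc_cells <- Filter(cell_qc_passed, cells)
  if (length(qc_cells) == 0) stop("no QC-passed cells in embryo")
  origin <- classify_origin(qc_cells, params, catalog, genome)
  tab <- origin$abnormalities

  status <- vapply(qc_cells, function(cell) {
    ab <- tab[tab$cell_id == cell$cell_id, , drop = FALSE]
    classify_cell(ab, catalog)$label
  }, character(1))
  names(status) <- vapply(qc_cells, `[[`, character(1), "cell_id")

  n_normal <- sum(status == "normal")
  all_abn <- n_normal == 0
  category <- if (all(status == "normal")) "normal"
    else if (!all_abn) "diploid_aneuploid_mosaic"
    else if (identical_catalogs(qc_cells, tab, params)) "uniformly_abnormal"
    else "aneuploid_mosaic"

  mito <- tab[tab$origin == "mitotic", , drop = FALSE]
  events <- group_events(mito, params)
  events <- lapply(events, function(ev) {
    ev$timing <- infer_event_timing(ev, qc_cells)
    ev$mechanism <- classify_mechanism(ev, genome, params)
    ev
  })

  lineage <- vapply(qc_cells, `[[`, character(1), "lineage")
  tallies <- table(factor(lineage, levels = c("TE", "ICM", "UNKNOWN")),
                   factor(status, levels = c("normal", "abnormal",
                                             "complex_abnormal")))
  structure(list(
    embryo_id = qc_cells[[1]]$embryo_id, category = category,
    n_cells = length(qc_cells),
    percent_normal_cells = 100 * n_normal / length(qc_cells),
    cell_status = status, lineage_tallies = tallies,
    origin = origin,
    meiotic = Filter(function(cl) cl$origin == "meiotic", origin$calls),
    events = events, n_mitotic_events = length(events)),
    class = "embryo_classification")
}

# all QC-passed cells pairwise share the same abnormality catalog (bijective
# same-matching), so bin jitter does not spuriously create mosaicism
identical_catalogs <- function(cells, tab, params) {
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  by_cell <- lapply(ids, function(id) tab[tab$cell_id == id, , drop = FALSE])
  n_ab <- vapply(by_cell, nrow, integer(1))
  if (length(unique(n_ab)) > 1) return(FALSE)
  ref <- by_cell[[1]]
  for (k in seq_along(by_cell)[-1]) {
    other <- by_cell[[k]]
    used <- rep(FALSE, nrow(other))
    for (i in seq_len(nrow(ref))) {
      hit <- FALSE
      for (j in seq_len(nrow(other))) {
        if (used[j]) next
        if (match_abnormalities(ref[i, ], other[j, ],
                                params)$relation == "same") {
          used[j] <- TRUE; hit <- TRUE; break
        }
      }
      if (!hit) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.embryo_classification <- function(x, ...) {
  cat(sprintf("<embryo_classification> %s: %s (%d cells, %.0f%% normal, %d mitotic events)\n",
              x$embryo_id, x$category, x$n_cells, x$percent_normal_cells,
              x$n_mitotic_events))
  invisible(x)
}
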