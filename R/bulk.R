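#' Bulk-detection configuration
#'
#' @param detection_threshold net affected fraction at or above which a bulk
#'   DNA-Seq assay is assumed to call the abnormality; default 0.20, the most
#'   sensitive end of the 20-30\% range quoted for PGT-A platforms.
#' @param lineage which lineage a bulk biopsy samples (default TE).
#' @return A \code{bulk_config} list.
#' @export
bulk_config <- function(detection_threshold = 0.20, lineage = "TE") {
  stopifnot(detection_threshold > 0, detection_threshold < 1)
  structure(list(detection_threshold = detection_threshold, lineage = lineage),
            class = "bulk_config")
}

#' Pseudo-bulk copy-number profile of a lineage
#'
#' The arithmetic mean of integer copy number per bin across the QC-passed
#' cells of one lineage -- what a bulk biopsy of those cells would measure.
#' Reciprocal daughter populations of equal size average out exactly.
#'
#' @param cells list of \code{cell_karyotype}s.
#' @param binning a \code{genome_binning}.
#' @param lineage lineage to aggregate (\code{NULL} for all cells).
#' @return numeric vector of mean CN per bin.
#' @export
pseudo_bulk_profile <- function(cells, binning, lineage = "TE") {
  cells <- Filter(cell_qc_passed, cells)
  if (!is.null(lineage))
    cells <- Filter(function(cell) cell$lineage == lineage, cells)
  if (length(cells) == 0) stop("no QC-passed cells in lineage")
  profs <- vapply(cells, function(cell)
    segments_to_bins(cell$segments, binning), numeric(nrow(binning)))
  rowMeans(profs)
}

# modal cell ploidy of a cell set, so a minority polyploid clone is assessed
# against the majority baseline
lineage_baseline <- function(cells, genome) {
  pl <- vapply(cells, function(cell)
    as.integer(infer_baseline_ploidy(cell, genome)), integer(1))
  as.integer(names(sort(table(pl), decreasing = TRUE))[1])
}

#' Net affected fraction of an abnormality in a cell population
#'
#' The absolute mean copy-number deviation from the lineage baseline over the
#' signature span -- the net single-copy-equivalent fraction a bulk measurement
#' sees after reciprocal products cancel. Copy-weighted: a two-copy gain in
#' 10\% of cells equals a one-copy gain in 20\%. Also reports
#' \code{raw_percent_cells}, the fraction of cells carrying any deviation on
#' the span.
#'
#' @param signature list or row with \code{chrom}, \code{start}, \code{end}
#'   (\code{chrom = "genome"} for genome-wide ploidy anomalies).
#' @param cells the lineage's QC-passed cells.
#' @param genome a \code{genome_spec}.
#' @param baseline lineage baseline CN; default the modal cell ploidy.
#' @return list with \code{net_fraction} and \code{raw_percent_cells}.
#' @export
net_affected_fraction <- function(signature, cells,
                                  genome = default_genome("female"),
                                  baseline = NULL) {
  stopifnot(length(cells) >= 1)
  if (is.null(baseline)) baseline <- lineage_baseline(cells, genome)
  dev <- vapply(cells, function(cell) {
    if (identical(signature$chrom, "genome"))
      return(as.integer(infer_baseline_ploidy(cell, genome)) - baseline)
    cn <- span_mean_cn(cell$segments, signature$chrom, signature$start,
                       signature$end)
    if (is.na(cn)) 0 else cn - baseline
  }, numeric(1))
  list(net_fraction = abs(mean(dev)),
       raw_percent_cells = mean(abs(dev) > 1e-9))
}

#' Would a bulk assay detect this net fraction?
#'
#' Inclusive threshold: a net fraction exactly at the detection threshold is
#' detectable.
#'
#' @param net_fraction numeric in [0, 1+].
#' @param config a \code{bulk_config}.
#' @return logical.
#' @export
is_bulk_detectable <- function(net_fraction, config = bulk_config()) {
  net_fraction >= config$detection_threshold
}

#' In-silico bulk DNA-Seq over a cohort
#'
#' For every mosaic embryo with QC-passed cells in the configured lineage,
#' each mitotic abnormality (cluster of same-matched per-cell abnormalities)
#' is scored by its net affected fraction in that lineage, after excluding
#' complex abnormal cells, and marked detectable against the threshold. The
#' cohort summary gives the fraction of mitotic abnormalities a bulk biopsy
#' would have found.
#'
#' @param cohort list of embryos: \code{simulated_embryo} objects or plain
#'   lists of \code{cell_karyotype}s.
#' @param config a \code{bulk_config}.
#' @param params a \code{match_params}.
#' @param catalog a \code{catalog_params}.
#' @param genome a \code{genome_spec}.
#' @return A \code{bulk_report}: list with \code{rows} (one per abnormality:
#'   embryo, signature, raw percent cells, net fraction, detectable) and
#'   \code{summary} (n detected / n total / fraction).
#' @export
cohort_bulk_detection <- function(cohort, config = bulk_config(),
                                  params = match_params(),
                                  catalog = catalog_params(),
                                  genome = default_genome("female")) {
  rows <- list()
  for (embryo in cohort) {
    cells <- embryo_cells(embryo)
    qc <- Filter(cell_qc_passed, cells)
    if (length(qc) == 0) next
    origin <- classify_origin(qc, params, catalog, genome)
    tab <- origin$abnormalities
    lin <- Filter(function(cell) cell$lineage == config$lineage, qc)
    if (length(lin) == 0) next
    # complex abnormal cells are excluded from the bulk view
    lin <- Filter(function(cell) {
      ab <- tab[tab$cell_id == cell$cell_id, , drop = FALSE]
      classify_cell(ab, catalog)$label != "complex_abnormal"
    }, lin)
    if (length(lin) == 0) next
    lin_ids <- vapply(lin, `[[`, character(1), "cell_id")
    for (cl in Filter(function(cl) cl$origin == "mitotic", origin$calls)) {
      members <- tab[tab$cluster == cl$cluster &
                     tab$cell_id %in% lin_ids, , drop = FALSE]
      if (nrow(members) == 0) next
      sig <- list(chrom = cl$chrom,
                  start = stats::median(members$start),
                  end = stats::median(members$end))
      naf <- net_affected_fraction(sig, lin, genome)
      rows[[length(rows) + 1]] <- data.frame(
        embryo_id = embryo_id_of(embryo), chrom = sig$chrom,
        start = sig$start, end = sig$end, direction = cl$direction,
        n_cells_lineage = length(lin),
        raw_percent_cells = naf$raw_percent_cells,
        net_fraction = naf$net_fraction,
        detectable = is_bulk_detectable(naf$net_fraction, config),
        stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(embryo_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), direction = character(0),
               n_cells_lineage = integer(0), raw_percent_cells = numeric(0),
               net_fraction = numeric(0), detectable = logical(0))
  structure(list(
    rows = rows,
    summary = list(n_detected = sum(rows$detectable), n_total = nrow(rows),
                   fraction_detected = if (nrow(rows) > 0)
                     mean(rows$detectable) else NA_real_,
                   detection_threshold = config$detection_threshold,
                   lineage = config$lineage)),
    class = "bulk_report")
}

embryo_cells <- function(embryo) {
  if (inherits(embryo, "simulated_embryo")) embryo$cells else embryo
}

embryo_id_of <- function(embryo) {
  cells <- embryo_cells(embryo)
  if (inherits(embryo, "simulated_embryo")) embryo$embryo_id
  else cells[[1]]$embryo_id
}
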