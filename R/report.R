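#' Analyze a cohort of embryos
#'
#' Runs the embryo-level classification on every embryo and assembles the
#' cohort-level summaries: category percentages, percent-normal distribution
#' over mosaic embryos, mitotic events per embryo, TE vs ICM cell tallies with
#' the complex-cell contingency test, per-chromosome event frequencies,
#' abnormality type tallies (numerical/structural x gain/loss x origin), the
#' gene-density correlation of numerical abnormalities, and the in-silico bulk
#' detection summary.
#'
#' @param cohort list of embryos (\code{simulated_embryo}s or lists of
#'   \code{cell_karyotype}s).
#' @param params a \code{match_params}.
#' @param catalog a \code{catalog_params}.
#' @param genome a \code{genome_spec}.
#' @param bulk a \code{bulk_config}.
#' @return A \code{cohort_report} list; see \code{\link{build_report}} for
#'   serialization.
#' @export
analyze_cohort <- function(cohort, params = match_params(),
                           catalog = catalog_params(),
                           genome = default_genome("female"),
                           bulk = bulk_config()) {
  classified <- lapply(cohort, function(embryo) {
    cells <- embryo_cells(embryo)
    if (!any(vapply(cells, cell_qc_passed, logical(1)))) return(NULL)
    classify_embryo(cells, params, catalog, genome)
  })
  keep <- !vapply(classified, is.null, logical(1))
  classified <- classified[keep]
  n <- length(classified)
  if (n == 0) stop("no embryo with QC-passed cells")

  categories <- vapply(classified, `[[`, character(1), "category")
  cat_levels <- c("normal", "uniformly_abnormal", "diploid_aneuploid_mosaic",
                  "aneuploid_mosaic")
  cat_pct <- 100 * table(factor(categories, levels = cat_levels)) / n

  mosaic <- categories %in% c("diploid_aneuploid_mosaic", "aneuploid_mosaic")
  pct_normal_mosaic <- vapply(classified[mosaic], `[[`, numeric(1),
                              "percent_normal_cells")
  events_per_embryo <- vapply(classified, `[[`, integer(1), "n_mitotic_events")

  # lineage tallies summed over embryos; complex-cell 2x2: TE vs ICM,
  # complex vs non-complex
  tallies <- Reduce(`+`, lapply(classified, `[[`, "lineage_tallies"))
  complex_tab <- matrix(c(tallies["TE", "complex_abnormal"],
                          sum(tallies["TE", ]) - tallies["TE", "complex_abnormal"],
                          tallies["ICM", "complex_abnormal"],
                          sum(tallies["ICM", ]) - tallies["ICM", "complex_abnormal"]),
                        2, 2, byrow = TRUE,
                        dimnames = list(c("TE", "ICM"),
                                        c("complex", "other")))
  complex_p <- fisher_exact_2x2(complex_tab)

  # events: chromosomes, timing, mechanisms (genome-wide flagged separately)
  all_events <- unlist(lapply(classified, `[[`, "events"), recursive = FALSE)
  event_chroms <- vapply(all_events, `[[`, character(1), "chrom")
  timing <- vapply(all_events, `[[`, character(1), "timing")
  mechanisms <- vapply(all_events, `[[`, character(1), "mechanism")
  meiotic_chroms <- unlist(lapply(classified, function(cls)
    vapply(cls$meiotic, `[[`, character(1), "chrom")))
  freq <- if (length(c(event_chroms, meiotic_chroms)) > 0)
    tryCatch(chromosome_event_frequencies(c(event_chroms, meiotic_chroms),
                                          genome),
             error = function(e) NULL) else NULL

  # abnormality-type tallies at the distinct-signature (cluster) level
  calls <- unlist(lapply(classified, function(cls) cls$origin$calls),
                  recursive = FALSE)
  type_tab <- if (length(calls) > 0) {
    df <- data.frame(origin = vapply(calls, `[[`, character(1), "origin"),
                     kind = vapply(calls, `[[`, character(1), "kind"),
                     direction = vapply(calls, `[[`, character(1), "direction"),
                     chrom = vapply(calls, `[[`, character(1), "chrom"),
                     stringsAsFactors = FALSE)
    df[df$kind != "genome_wide", , drop = FALSE]
  } else NULL

  gene_cor <- NULL
  if (!is.null(type_tab) && sum(type_tab$kind == "numerical") >= 3) {
    auto <- autosomes(genome)
    num <- table(factor(type_tab$chrom[type_tab$kind == "numerical"],
                        levels = auto))
    pct <- 100 * as.integer(num) / sum(num)
    genes <- genome$genes[match(auto, genome$chrom)]
    if (stats::var(pct) > 0)
      gene_cor <- pearson_correlation(genes, pct)
  }

  bulk_report <- cohort_bulk_detection(cohort[keep], bulk, params, catalog,
                                       genome)

  structure(list(
    n_embryos = n, classified = classified,
    category_percent = as.list(cat_pct),
    percent_mosaic = unname(sum(cat_pct[c("diploid_aneuploid_mosaic",
                                          "aneuploid_mosaic")])),
    percent_normal_per_mosaic_embryo = pct_normal_mosaic,
    events_per_embryo = events_per_embryo,
    lineage_tallies = tallies, complex_table = complex_tab,
    complex_fisher_p = complex_p,
    timing = table(factor(timing, levels = c("pre_specification",
                                             "post_specification",
                                             "unassessable"))),
    mechanisms = table(mechanisms),
    chromosome_frequencies = freq,
    abnormality_types = type_tab,
    gene_count_correlation = gene_cor,
    bulk = bulk_report), class = "cohort_report")
}

#' Serialize a cohort report
#'
#' Writes the cohort JSON (category percentages, timing and mechanism tallies,
#' bulk summary, correlation, seed) and TSVs with stable column order for the
#' per-embryo table, per-chromosome frequencies and bulk rows. Missing stages
#' are written as explicit nulls rather than dropped.
#'
#' @param report a \code{cohort_report} from \code{\link{analyze_cohort}}.
#' @param dir output directory (created if needed).
#' @param seed seed to echo into the report.
#' @return invisibly, the paths written.
#' @export
build_report <- function(report, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_embryo <- data.frame(
    embryo_id = vapply(report$classified, `[[`, character(1), "embryo_id"),
    category = vapply(report$classified, `[[`, character(1), "category"),
    n_cells = vapply(report$classified, `[[`, integer(1), "n_cells"),
    percent_normal = vapply(report$classified, `[[`, numeric(1),
                            "percent_normal_cells"),
    n_mitotic_events = vapply(report$classified, `[[`, integer(1),
                              "n_mitotic_events"),
    stringsAsFactors = FALSE)
  paths <- character(0)
  p <- file.path(dir, "embryos.tsv")
  utils::write.table(per_embryo, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$chromosome_frequencies)) {
    p <- file.path(dir, "chromosome_frequencies.tsv")
    utils::write.table(report$chromosome_frequencies, p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (nrow(report$bulk$rows) > 0) {
    p <- file.path(dir, "bulk_rows.tsv")
    utils::write.table(report$bulk$rows, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  json <- list(
    seed = seed, n_embryos = report$n_embryos,
    category_percent = report$category_percent,
    percent_mosaic = report$percent_mosaic,
    events_per_embryo = as.list(table(report$events_per_embryo)),
    timing = as.list(report$timing),
    mechanisms = as.list(report$mechanisms),
    complex_table = as.vector(report$complex_table),
    complex_fisher_p = report$complex_fisher_p,
    gene_count_correlation = report$gene_count_correlation,
    bulk_summary = report$bulk$summary)
  p <- file.path(dir, "cohort_report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(c(paths, p))
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d embryos; %.0f%% mosaic; bulk detects %s/%s mitotic abnormalities\n",
              x$n_embryos, x$percent_mosaic,
              x$bulk$summary$n_detected, x$bulk$summary$n_total))
  invisible(x)
}
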