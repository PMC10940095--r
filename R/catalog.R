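#' Abnormality catalog parameters
#'
#' @param whole_fraction fraction of a chromosome an abnormality must cover to
#'   count as numerical (whole-chromosome) rather than structural; default 0.9.
#' @param complex_threshold a cell with more than this many abnormalities is
#'   complex abnormal; default 4.
#' @param min_report_mb smallest deviant segment reported, in Mb (default 5;
#'   guards against binning noise).
#' @return A \code{catalog_params} list.
#' @export
catalog_params <- function(whole_fraction = 0.9, complex_threshold = 4,
                           min_report_mb = 5) {
  stopifnot(whole_fraction > 0, whole_fraction <= 1, complex_threshold >= 0,
            min_report_mb >= 0)
  structure(list(whole_fraction = whole_fraction,
                 complex_threshold = complex_threshold,
                 min_report_mb = min_report_mb),
            class = "catalog_params")
}

#' Baseline ploidy of a cell
#'
#' The length-weighted modal copy number across autosomes. A baseline other
#' than 2 marks the cell as a genome-wide ploidy deviant (mixoploid
#' candidate); its per-chromosome abnormalities are then called against that
#' modal baseline, so a triploid cell with one extra tetrasomic chromosome
#' yields one genome-wide anomaly plus one gain.
#'
#' @param cell a \code{cell_karyotype}.
#' @param genome a \code{genome_spec}.
#' @return integer baseline ploidy with logical attribute
#'   \code{"genome_wide"}.
#' @export
infer_baseline_ploidy <- function(cell, genome = default_genome("female")) {
  s <- cell$segments[cell$segments$chrom %in% autosomes(genome), , drop = FALSE]
  if (nrow(s) == 0) stop("empty segment table")
  w <- tapply(s$end - s$start, s$cn, sum)
  baseline <- as.integer(names(w)[which.max(w)])
  structure(baseline, genome_wide = baseline != 2L)
}

#' Extract typed abnormalities from a cell's segment table
#'
#' Every maximal autosomal segment whose copy number deviates from the cell's
#' baseline ploidy and is at least \code{min_report_mb} long becomes one
#' abnormality, typed numerical (chromosome fraction >=
#' \code{whole_fraction}) or structural, gain or loss, with \code{delta} = CN
#' minus baseline. A non-diploid baseline is emitted as a single genome-wide
#' abnormality rather than 22 per-chromosome ones.
#'
#' @param cell a \code{cell_karyotype}.
#' @param params a \code{catalog_params}.
#' @param genome a \code{genome_spec}.
#' @return data.frame with columns \code{cell_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{direction}, \code{delta}, \code{kind},
#'   \code{chrom_fraction} (zero rows for a normal cell).
#' @export
extract_abnormalities <- function(cell, params = catalog_params(),
                                  genome = default_genome("female")) {
  baseline <- infer_baseline_ploidy(cell, genome)
  auto <- autosomes(genome)
  s <- cell$segments
  s <- s[s$chrom %in% auto & s$cn != as.integer(baseline), , drop = FALSE]
  s <- s[(s$end - s$start) >= params$min_report_mb * 1e6, , drop = FALSE]
  out <- if (nrow(s) == 0) empty_abnormalities(cell$cell_id) else {
    chrom_len <- genome$length[match(s$chrom, genome$chrom)]
    frac <- (s$end - s$start) / chrom_len
    delta <- s$cn - as.integer(baseline)
    data.frame(cell_id = cell$cell_id, chrom = s$chrom, start = s$start,
               end = s$end,
               direction = ifelse(delta > 0, "gain", "loss"),
               delta = as.integer(delta),
               kind = ifelse(frac >= params$whole_fraction, "numerical",
                             "structural"),
               chrom_fraction = frac, stringsAsFactors = FALSE)
  }
  if (attr(baseline, "genome_wide")) {
    gw <- data.frame(cell_id = cell$cell_id, chrom = "genome", start = 0,
                     end = 0,
                     direction = if (baseline > 2) "gain" else "loss",
                     delta = as.integer(baseline - 2L), kind = "genome_wide",
                     chrom_fraction = 1, stringsAsFactors = FALSE)
    out <- rbind(gw, out)
  }
  rownames(out) <- NULL
  out
}

empty_abnormalities <- function(cell_id = character(0)) {
  data.frame(cell_id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), direction = character(0), delta = integer(0),
             kind = character(0), chrom_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Classify a cell by its abnormality count
#'
#' 0 abnormalities: normal; 1 to \code{complex_threshold}: abnormal; more
#' than \code{complex_threshold} (default 4): complex abnormal. A genome-wide
#' ploidy anomaly counts as one abnormality.
#'
#' @param abnormalities data.frame from \code{\link{extract_abnormalities}}.
#' @param params a \code{catalog_params}.
#' @return list with \code{label} (\code{"normal"}, \code{"abnormal"},
#'   \code{"complex_abnormal"}) and \code{n_abnormalities}.
#' @export
classify_cell <- function(abnormalities, params = catalog_params()) {
  n <- nrow(abnormalities)
  label <- if (n == 0) "normal"
           else if (n > params$complex_threshold) "complex_abnormal"
           else "abnormal"
  list(label = label, n_abnormalities = n)
}

#' Write an abnormality table to TSV
#'
#' @param abnormalities data.frame of abnormalities (possibly several cells).
#' @param path output path.
#' @export
write_abnormalities <- function(abnormalities, path) {
  utils::write.table(abnormalities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
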