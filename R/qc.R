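#' Normalize binned counts to copy-number-proportional values
#'
#' Each bin's count is divided by bin length times the genome-wide read
#' density, so values are proportional to the underlying copy number and the
#' length-weighted genome average is 1 regardless of sequencing depth
#' (multiplying all counts by a constant leaves the result unchanged).
#'
#' @param counts a \code{binned_counts}.
#' @param binning a \code{genome_binning} with one row per count.
#' @return numeric vector of normalized values, one per bin.
#' @export
normalize_counts <- function(counts, binning) {
  stopifnot(length(counts$counts) == nrow(binning))
  if (counts$total_reads <= 0) stop("zero total read count")
  len <- binning$end - binning$start
  density <- counts$total_reads / sum(len)
  counts$counts / (len * density)
}

#' Spikiness of a count profile
#'
#' Bin-to-bin variability: the sum of absolute differences between consecutive
#' bins divided by the total count, computed genome-wide over the bin order.
#' Constant profiles score 0; heavily oscillating profiles score up to 2.
#'
#' @param counts a \code{binned_counts} (>= 2 bins).
#' @return nonnegative numeric, or \code{NA} for an all-zero profile.
#' @export
compute_spikiness <- function(counts) {
  c <- counts$counts
  stopifnot(length(c) >= 2)
  tot <- sum(c)
  if (tot == 0) return(NA_real_)
  sum(abs(diff(c))) / tot
}

#' Bhattacharyya separation between the two dominant copy-number states
#'
#' Gaussian distributions are fitted (mean, sd of normalized counts) to the
#' two CN states occupying the most bins; states with fewer than 3 bins are
#' skipped. The Bhattacharyya distance
#' \deqn{BD = \frac14 \ln\left(\frac14\left(\frac{\sigma_1^2}{\sigma_2^2} +
#'   \frac{\sigma_2^2}{\sigma_1^2} + 2\right)\right) +
#'   \frac14 \frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2}}
#' measures how cleanly the caller separated the states; low values flag noisy
#' profiles whose state clouds overlap.
#'
#' @param counts a \code{binned_counts}.
#' @param profile a \code{cn_profile} for the same cell (or integer per-bin
#'   states).
#' @param binning the \code{genome_binning}.
#' @return numeric distance, or \code{NA} when fewer than two usable states
#'   exist (single-state profiles; treated as a QC pass with a flag).
#' @export
compute_bhattacharyya <- function(counts, profile, binning) {
  states <- if (inherits(profile, "cn_profile")) profile$cn else profile
  stopifnot(length(states) == length(counts$counts))
  x <- normalize_counts(counts, binning)
  tab <- sort(table(states), decreasing = TRUE)
  tab <- tab[tab >= 3]
  if (length(tab) < 2) return(NA_real_)
  top <- as.integer(names(tab)[1:2])
  m <- vapply(top, function(s) mean(x[states == s]), numeric(1))
  v <- vapply(top, function(s) stats::var(x[states == s]), numeric(1))
  if (any(v == 0)) return(if (m[1] == m[2]) 0 else Inf)
  0.25 * log(0.25 * (v[1] / v[2] + v[2] / v[1] + 2)) +
    0.25 * (m[1] - m[2])^2 / (v[1] + v[2])
}

#' Quality-control thresholds
#'
#' Defaults: minimum 15,000 total reads, maximum spikiness 0.25, minimum
#' Bhattacharyya score 0.65. All comparisons are inclusive.
#'
#' @param min_reads,max_spikiness,min_bhattacharyya positive thresholds.
#' @return A \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(min_reads = 15000, max_spikiness = 0.25,
                          min_bhattacharyya = 0.65) {
  stopifnot(min_reads > 0, max_spikiness > 0, min_bhattacharyya > 0)
  structure(list(min_reads = min_reads, max_spikiness = max_spikiness,
                 min_bhattacharyya = min_bhattacharyya),
            class = "qc_thresholds")
}

#' Evaluate quality control for one cell
#'
#' A cell passes when total reads >= \code{min_reads}, spikiness <=
#' \code{max_spikiness}, and the Bhattacharyya score is >=
#' \code{min_bhattacharyya} or undefined (single-state profiles pass with a
#' flag). A manual override, standing in for visual inspection of borderline
#' profiles, replaces the automatic verdict and is recorded and logged.
#'
#' @param counts a \code{binned_counts}.
#' @param profile a \code{cn_profile} (or per-bin states) for the cell.
#' @param binning the \code{genome_binning}.
#' @param thresholds a \code{qc_thresholds}.
#' @param manual_override optional logical replacing the automatic decision.
#' @return A \code{qc_metrics} list: \code{total_reads}, \code{spikiness},
#'   \code{bhattacharyya}, \code{bhattacharyya_undefined}, \code{auto_passed},
#'   \code{passed}, \code{manual_override}.
#' @export
qc_evaluate <- function(counts, profile, binning, thresholds = qc_thresholds(),
                        manual_override = NULL) {
  spik <- compute_spikiness(counts)
  bd <- compute_bhattacharyya(counts, profile, binning)
  bd_ok <- is.na(bd) || bd >= thresholds$min_bhattacharyya
  auto <- counts$total_reads >= thresholds$min_reads &&
    !is.na(spik) && spik <= thresholds$max_spikiness && bd_ok
  passed <- auto
  if (!is.null(manual_override)) {
    passed <- isTRUE(manual_override)
    message(sprintf("qc manual override for %s: auto=%s -> passed=%s",
                    counts$cell_id, auto, passed))
  }
  structure(list(total_reads = counts$total_reads, spikiness = spik,
                 bhattacharyya = bd, bhattacharyya_undefined = is.na(bd),
                 auto_passed = auto, passed = passed,
                 manual_override = manual_override),
            class = "qc_metrics")
}
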