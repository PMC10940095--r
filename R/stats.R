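#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value under the probability-mass definition: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's. Degenerate margins give
#' p = 1.
#'
#' @param tab 2x2 matrix of nonnegative counts (rows = groups, columns =
#'   outcome/complement), or a length-4 vector \code{c(a, b, c, d)} filled by
#'   row.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with \code{r} and two-sided \code{p}.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance in x.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared} and the
#'   slope's two-sided \code{p}.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]))
}

#' Blastocyst expansion rate from an hourly surface-area series
#'
#' The surface area at the first attainment of the maximum minus the initial
#' area, divided by the number of hourly measurements between those two
#' points. A series whose maximum is the first measurement gets rate 0 with a
#' flag.
#'
#' @param areas surface areas in square micrometers, ordered from the first
#'   blastocoel-formation frame; >= 2 positive values.
#' @return list with \code{rate} (area units per measurement interval),
#'   \code{n_intervals}, and logical \code{flagged}.
#' @export
expansion_rate <- function(areas) {
  stopifnot(length(areas) >= 2, all(areas > 0))
  imax <- which.max(areas)            # first attainment of the maximum
  if (imax == 1)
    return(list(rate = 0, n_intervals = 0L, flagged = TRUE))
  list(rate = (areas[imax] - areas[1]) / (imax - 1),
       n_intervals = imax - 1L, flagged = FALSE)
}

#' Per-chromosome event frequencies against a uniform expectation
#'
#' Tallies error events per autosome as percentages and compares each against
#' the uniform chance of random involvement (100 / number of autosomes, i.e.
#' 4.54\% for 22) with an exact binomial test.
#'
#' @param event_chroms character vector: the chromosome of each event
#'   (non-autosomal and genome-wide entries are dropped).
#' @param genome a \code{genome_spec}.
#' @return data.frame with \code{chrom}, \code{n_events}, \code{percent},
#'   \code{expected_percent}, \code{p_binomial}.
#' @export
chromosome_event_frequencies <- function(event_chroms,
                                         genome = default_genome("female")) {
  auto <- autosomes(genome)
  event_chroms <- event_chroms[event_chroms %in% auto]
  if (length(event_chroms) == 0) stop("no autosomal events")
  n <- length(event_chroms)
  counts <- table(factor(event_chroms, levels = auto))
  expected <- 100 / length(auto)
  p <- vapply(as.integer(counts), function(k)
    stats::binom.test(k, n, p = 1 / length(auto))$p.value, numeric(1))
  data.frame(chrom = auto, n_events = as.integer(counts),
             percent = 100 * as.integer(counts) / n,
             expected_percent = expected, p_binomial = p,
             stringsAsFactors = FALSE)
}
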