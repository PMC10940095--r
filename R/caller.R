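#' Copy-number caller parameters
#'
#' @param min_segment_bins smallest segment the divisive search may create
#'   (default 5, i.e. ~5 Mb at 1 Mb bins -- below the smallest segmental
#'   events this assay is expected to report).
#' @param split_threshold minimum value of the standardized between-segment
#'   mean-difference statistic for a split to be accepted, in per-copy units.
#' @param modal_cn_range integer CN values the modal (most genomic material)
#'   level may map to; the scale search is restricted to these.
#' @param scale_grid relative grid refined around each candidate scale.
#' @return A \code{caller_params} list.
#' @export
caller_params <- function(min_segment_bins = 5, split_threshold = 1.5,
                          modal_cn_range = 1:4,
                          scale_grid = seq(0.9, 1.1, by = 0.002)) {
  stopifnot(min_segment_bins >= 1, split_threshold > 0)
  structure(list(min_segment_bins = min_segment_bins,
                 split_threshold = split_threshold,
                 modal_cn_range = modal_cn_range, scale_grid = scale_grid),
            class = "caller_params")
}

# Recursive divisive segmentation of one chromosome's values: at each step the
# breakpoint maximizing |mean(left) - mean(right)| * sqrt(nl*nr/(nl+nr)) is
# taken if the statistic clears the threshold and both sides keep at least
# min_segment_bins bins. Returns sorted segment start indices.
divisive_breakpoints <- function(x, min_bins, threshold) {
  n <- length(x)
  starts <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_bins) return()
    xs <- x[lo:hi]
    cs <- cumsum(xs)
    k <- min_bins:(len - min_bins)       # left part sizes
    ml <- cs[k] / k
    mr <- (cs[len] - cs[k]) / (len - k)
    stat <- abs(ml - mr) * sqrt(k * (len - k) / len)
    best <- which.max(stat)
    if (stat[best] < threshold) return()
    cut <- lo + k[best] - 1              # last index of left part
    starts <<- c(starts, cut + 1L)
    recurse(lo, cut)
    recurse(cut + 1L, hi)
  }
  recurse(1L, n)
  sort(starts)
}

#' Call integer copy numbers from binned counts
#'
#' A divisive (recursive binary splitting) caller: counts are normalized to
#' copy-number-proportional values and rescaled so one copy is roughly one
#' unit; each chromosome is segmented by recursively splitting at the
#' breakpoint maximizing the standardized between-segment mean difference;
#' finally a global scale factor is chosen over a grid to minimize the
#' length-weighted squared distance of scaled segment means from integers,
#' with the modal segment level constrained to a small CN range and ties
#' broken toward the diploid interpretation (modal CN = 2).
#'
#' Read depth alone fixes only relative copy number, so a uniformly polyploid
#' cell is indistinguishable from a diploid one; the diploid tie-break encodes
#' that the dominant state in this assay is diploid.
#'
#' @param counts a \code{binned_counts}.
#' @param binning a \code{genome_binning}.
#' @param params a \code{caller_params}.
#' @return A \code{cn_profile}: list with \code{cell_id}, integer \code{cn}
#'   per bin, the fitted \code{scale}, and per-bin \code{normalized} values.
#' @export
call_copy_number <- function(counts, binning, params = caller_params()) {
  stopifnot(length(counts$counts) == nrow(binning))
  norm <- normalize_counts(counts, binning)
  len <- binning$end - binning$start
  wmed <- weighted_median(norm, len)
  x <- norm / wmed * 2                    # one copy ~ one unit near diploid

  chroms <- unique(binning$chrom)
  seg_id <- integer(nrow(binning))
  nseg <- 0L
  for (ch in chroms) {
    idx <- which(binning$chrom == ch)
    bp <- divisive_breakpoints(x[idx], params$min_segment_bins,
                               params$split_threshold)
    lab <- cumsum(seq_along(idx) %in% bp) + 1L
    seg_id[idx] <- lab + nseg
    nseg <- nseg + max(lab)
  }
  seg_mean <- tapply(x * len, seg_id, sum) / tapply(len, seg_id, sum)
  seg_len <- as.numeric(tapply(len, seg_id, sum))

  # global scale: modal level -> each candidate CN, refined on a local grid.
  # Residuals are divided by s (measured in pre-scaling copy units) so that
  # candidate scales are comparable; the raw residual shrinks with s and would
  # otherwise always favor the smallest ploidy on noisy data. Near-ties go to
  # the diploid interpretation.
  modal_level <- seg_mean[which.max(seg_len)]
  per_k <- lapply(params$modal_cn_range, function(k) {
    ss <- (k / modal_level) * params$scale_grid
    losses <- vapply(ss, function(s)
      sum(seg_len * ((seg_mean * s - round(seg_mean * s)) / s)^2), numeric(1))
    list(k = k, s = ss[which.min(losses)], loss = min(losses))
  })
  min_loss <- min(vapply(per_k, `[[`, numeric(1), "loss"))
  pref <- order(abs(params$modal_cn_range - 2), params$modal_cn_range)
  best <- NULL
  for (cand in per_k[pref]) {
    if (cand$loss <= min_loss * 1.05 + 1e-12) { best <- cand; break }
  }
  states <- pmax(0L, as.integer(round(seg_mean[as.character(seg_id)] * best$s)))
  structure(list(cell_id = counts$cell_id, cn = states, scale = best$s,
                 normalized = x), class = "cn_profile")
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s: %d bins, states %s, scale %.3f\n", x$cell_id,
              length(x$cn), paste(sort(unique(x$cn)), collapse = "/"), x$scale))
  invisible(x)
}
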