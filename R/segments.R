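#' Cell karyotype container
#'
#' The pipeline's atomic record: one cell's integer copy-number segments plus
#' lineage label and QC status.
#'
#' @param cell_id,embryo_id identifiers.
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, 0-based half-open) and integer \code{cn}; maximal runs of
#'   constant copy number per chromosome.
#' @param lineage one of \code{"TE"}, \code{"ICM"}, \code{"UNKNOWN"}.
#' @param qc optional \code{qc_metrics} list; \code{NULL} means not evaluated.
#' @return A \code{cell_karyotype} object.
#' @export
cell_karyotype <- function(cell_id, embryo_id = NA_character_, segments,
                           lineage = c("UNKNOWN", "TE", "ICM"), qc = NULL) {
  lineage <- match.arg(lineage)
  segments <- normalize_segments(segments)
  structure(
    list(cell_id = cell_id, embryo_id = embryo_id, lineage = lineage,
         segments = segments, qc = qc),
    class = "cell_karyotype"
  )
}

#' @export
print.cell_karyotype <- function(x, ...) {
  dev <- sum(x$segments$cn != 2)
  cat(sprintf("<cell_karyotype> %s (%s, %s): %d segments, %d non-diploid\n",
              x$cell_id, x$embryo_id, x$lineage, nrow(x$segments), dev))
  invisible(x)
}

cell_qc_passed <- function(cell) {
  is.null(cell$qc) || isTRUE(cell$qc$passed)
}

# Canonical form: sorted within chromosome, adjacent equal-CN runs merged.
# Vectorized; this sits on the simulator's hot path.
normalize_segments <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "cn") %in% names(segments)),
            all(segments$end > segments$start),
            all(segments$cn >= 0))
  chrom <- as.character(segments$chrom)
  ord <- order(match(chrom, unique(chrom)), segments$start)
  chrom <- chrom[ord]
  start <- segments$start[ord]
  end <- segments$end[ord]
  cn <- as.integer(round(segments$cn[ord]))
  n <- length(chrom)
  if (n > 1) {
    new_chrom <- chrom[-1] != chrom[-n]
    if (any(!new_chrom & start[-1] != end[-n]))
      stop("segments do not tile chromosome ",
           chrom[-1][!new_chrom & start[-1] != end[-n]][1])
    keep <- c(TRUE, new_chrom | cn[-1] != cn[-n])
  } else keep <- TRUE
  last <- c(which(keep)[-1] - 1L, n)
  data.frame(chrom = chrom[keep], start = start[keep], end = end[last],
             cn = cn[keep], stringsAsFactors = FALSE)
}

# Flat diploid (or other ploidy) segment table over a genome.
baseline_segments <- function(genome, cn = 2L) {
  data.frame(chrom = genome$chrom, start = 0, end = genome$length,
             cn = as.integer(cn), stringsAsFactors = FALSE)
}

# Add `delta` copies on [start, end) of `chrom`, splitting rows as needed.
# Copy number is floored at 0.
modify_cn <- function(segments, chrom, start, end, delta) {
  hit <- segments$chrom == chrom & segments$end > start & segments$start < end
  if (!any(hit)) return(segments)
  rows <- which(hit)
  pieces <- lapply(rows, function(i) {
    s <- segments[i, ]
    parts <- list()
    if (s$start < start)
      parts <- c(parts, list(data.frame(chrom = chrom, start = s$start,
                                        end = start, cn = s$cn)))
    ov_s <- max(s$start, start); ov_e <- min(s$end, end)
    parts <- c(parts, list(data.frame(chrom = chrom, start = ov_s, end = ov_e,
                                      cn = max(0L, s$cn + as.integer(delta)))))
    if (s$end > end)
      parts <- c(parts, list(data.frame(chrom = chrom, start = end,
                                        end = s$end, cn = s$cn)))
    do.call(rbind, parts)
  })
  normalize_segments(rbind(segments[-rows, ], do.call(rbind, pieces)))
}

# Mean copy number over [start, end) of `chrom`, length-weighted.
span_mean_cn <- function(segments, chrom, start, end) {
  s <- segments[segments$chrom == chrom & segments$end > start &
                segments$start < end, , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  w <- pmin(s$end, end) - pmax(s$start, start)
  sum(w * s$cn) / sum(w)
}

# Per-bin copy number of a segment table: length-weighted mean CN in each bin
# (fractional only where a breakpoint falls inside a bin).
segments_to_bins <- function(segments, binning) {
  vapply(seq_len(nrow(binning)), function(i) {
    span_mean_cn(segments, binning$chrom[i], binning$start[i], binning$end[i])
  }, numeric(1))
}

#' Collapse a per-bin copy-number profile into a segment table
#'
#' Maximal constant-CN runs per chromosome; the round trip through
#' \code{\link{expand_profile}} is the identity.
#'
#' @param profile integer copy-number state per bin.
#' @param binning the \code{genome_binning} the profile is indexed by.
#' @return Segment data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{cn}).
#' @export
segment_profile <- function(profile, binning) {
  stopifnot(length(profile) == nrow(binning))
  out <- lapply(unique(binning$chrom), function(ch) {
    idx <- which(binning$chrom == ch)
    p <- profile[idx]
    keep <- c(TRUE, p[-1] != p[-length(p)])
    run <- cumsum(keep)
    data.frame(chrom = ch,
               start = tapply(binning$start[idx], run, min),
               end = tapply(binning$end[idx], run, max),
               cn = as.integer(p[keep]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand a segment table to per-bin copy-number states
#'
#' Inverse of \code{\link{segment_profile}} for segment tables aligned to the
#' binning (bin values are rounded length-weighted means otherwise).
#'
#' @param segments segment data.frame.
#' @param binning a \code{genome_binning}.
#' @return Integer vector, one CN state per bin.
#' @export
expand_profile <- function(segments, binning) {
  as.integer(round(segments_to_bins(segments, binning)))
}

#' Read / write per-cell segment tables
#'
#' TSV with header \code{cell_id}, \code{chrom}, \code{start}, \code{end},
#' \code{cn} and optional \code{embryo_id}, \code{lineage} columns.
#'
#' @param path file path.
#' @return \code{read_segments}: a list of \code{cell_karyotype} objects.
#' @export
read_segments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "chrom", "start", "end", "cn") %in% names(tab)))
  lapply(split(tab, tab$cell_id), function(s) {
    cell_karyotype(
      cell_id = s$cell_id[1],
      embryo_id = if ("embryo_id" %in% names(s)) s$embryo_id[1] else NA_character_,
      segments = s[, c("chrom", "start", "end", "cn")],
      lineage = if ("lineage" %in% names(s)) s$lineage[1] else "UNKNOWN"
    )
  })
}

#' @param cells list of \code{cell_karyotype} objects.
#' @rdname read_segments
#' @export
write_segments <- function(cells, path) {
  tab <- do.call(rbind, lapply(cells, function(cell) {
    s <- cell$segments
    data.frame(cell_id = cell$cell_id, embryo_id = cell$embryo_id,
               lineage = cell$lineage, s, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
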