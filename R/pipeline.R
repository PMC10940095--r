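#' Read binned counts
#'
#' \code{read_counts_tsv} expects a bins x cells TSV whose first columns are
#' \code{chrom}, \code{start}, \code{end} followed by one column per cell.
#' \code{read_counts_triplets} expects columns \code{bin_index} (1-based),
#' \code{cell_id}, \code{count}.
#'
#' @param path file path.
#' @param binning for triplets, the \code{genome_binning} defining bin count.
#' @return list of \code{binned_counts}, plus (for the TSV form) the binning
#'   in attribute \code{"binning"}.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
  binning <- tab[, c("chrom", "start", "end")]
  class(binning) <- c("genome_binning", "data.frame")
  cells <- setdiff(names(tab), c("chrom", "start", "end"))
  out <- lapply(cells, function(id) binned_counts(id, tab[[id]]))
  names(out) <- cells
  attr(out, "binning") <- binning
  out
}

#' @rdname read_counts_tsv
#' @export
read_counts_triplets <- function(path, binning) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bin_index", "cell_id", "count") %in% names(tab)),
            all(tab$bin_index >= 1), all(tab$bin_index <= nrow(binning)))
  out <- lapply(split(tab, tab$cell_id), function(s) {
    counts <- numeric(nrow(binning))
    counts[s$bin_index] <- s$count
    binned_counts(s$cell_id[1], counts)
  })
  out
}

#' @param counts_list list of \code{binned_counts}.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts_list, binning, path) {
  tab <- data.frame(binning[, c("chrom", "start", "end")],
                    stringsAsFactors = FALSE)
  for (counts in counts_list) tab[[counts$cell_id]] <- counts$counts
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call karyotypes for a set of cells from binned counts
#'
#' The scKaryo-Seq analysis layer in one call: per cell, copy numbers are
#' called with the divisive caller, QC is evaluated, and the per-bin profile
#' is collapsed into a segment table.
#'
#' @param counts_list list of \code{binned_counts}.
#' @param binning a \code{genome_binning}.
#' @param thresholds a \code{qc_thresholds}.
#' @param params a \code{caller_params}.
#' @param embryo_id,lineages optional metadata; \code{lineages} is a named
#'   vector (cell_id -> \code{"TE"}/\code{"ICM"}).
#' @return list of \code{cell_karyotype} objects with \code{qc} filled in.
#' @export
call_cells <- function(counts_list, binning, thresholds = qc_thresholds(),
                       params = caller_params(), embryo_id = NA_character_,
                       lineages = NULL) {
  validate_binning(binning)
  lapply(counts_list, function(counts) {
    profile <- call_copy_number(counts, binning, params)
    qc <- qc_evaluate(counts, profile, binning, thresholds)
    lineage <- if (!is.null(lineages) && counts$cell_id %in% names(lineages))
      lineages[[counts$cell_id]] else "UNKNOWN"
    cell <- cell_karyotype(counts$cell_id, embryo_id,
                           segment_profile(profile$cn, binning), lineage)
    cell$qc <- qc
    cell
  })
}
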