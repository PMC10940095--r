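#' Genome specification
#'
#' A genome specification is a data.frame with one row per chromosome and
#' columns \code{chrom}, \code{length} (bp), \code{centromere} (bp midpoint)
#' and \code{genes} (protein-coding gene count). It parameterises the
#' simulator, the abnormality catalog (chromosome fractions, pericentromeric
#' logic) and the gene-density correlation.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive chromosome lengths in bp.
#' @param centromere centromere midpoints, strictly inside (0, length).
#' @param genes nonnegative integer gene counts.
#' @return A \code{genome_spec} data.frame.
#' @export
genome_spec <- function(chrom, length, centromere, genes = rep(0L, base::length(chrom))) {
  stopifnot(
    base::length(chrom) >= 1,
    !anyDuplicated(chrom),
    base::length(length) == base::length(chrom),
    base::length(centromere) == base::length(chrom),
    all(length > 0),
    all(centromere > 0 & centromere < length),
    all(genes >= 0)
  )
  g <- data.frame(
    chrom = as.character(chrom), length = as.numeric(length),
    centromere = as.numeric(centromere), genes = as.integer(genes),
    stringsAsFactors = FALSE
  )
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Default human genome (hg38)
#'
#' Reads the bundled hg38 table: exact chromosome lengths, approximate
#' centromere midpoints and per-chromosome protein-coding gene counts
#' (provenance stated in the file header).
#'
#' @param chroms which chromosomes to keep: \code{"autosomes"} (chr1-chr22),
#'   \code{"female"} (autosomes + chrX) or \code{"all"}.
#' @return A \code{genome_spec} data.frame.
#' @export
default_genome <- function(chroms = c("autosomes", "female", "all")) {
  chroms <- match.arg(chroms)
  path <- system.file("extdata", "genome_hg38.tsv", package = "karyomosaic")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  keep <- switch(chroms,
    autosomes = paste0("chr", 1:22),
    female = paste0("chr", c(1:22, "X")),
    all = tab$chrom
  )
  tab <- tab[match(keep, tab$chrom), ]
  genome_spec(tab$chrom, tab$length, tab$centromere, tab$genes)
}

#' Autosome names of a genome
#'
#' Sex chromosomes (chrX/chrY, X/Y) are excluded; all cohort-level chromosome
#' statistics are computed over autosomes only.
#' @param genome a \code{genome_spec}.
#' @return character vector of autosome names.
#' @export
autosomes <- function(genome) {
  setdiff(genome$chrom, c("chrX", "chrY", "X", "Y"))
}

#' Tile a genome into fixed-width bins
#'
#' Produces a BED3-style bin table (0-based, half-open). The last bin of each
#' chromosome is truncated at the chromosome end; a trailing remnant shorter
#' than half a bin is merged into the previous bin so no tiny bins inflate
#' count noise.
#'
#' @param genome a \code{genome_spec}.
#' @param bin_size bin width in bp (default 1 Mb).
#' @return A \code{genome_binning}: data.frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @export
make_bins <- function(genome, bin_size = 1e6) {
  stopifnot(inherits(genome, "genome_spec"), bin_size > 0)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    n <- length(starts)
    if (n > 1 && (ends[n] - starts[n]) < bin_size / 2) {
      ends[n - 1] <- ends[n]
      starts <- starts[-n]; ends <- ends[-n]
      n <- n - 1
    }
    data.frame(chrom = rep(genome$chrom[i], n), start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, out)
  rownames(b) <- NULL
  class(b) <- c("genome_binning", "data.frame")
  b
}

validate_binning <- function(binning) {
  stopifnot(is.data.frame(binning),
            all(c("chrom", "start", "end") %in% names(binning)),
            nrow(binning) >= 1,
            all(binning$end > binning$start))
  for (ch in unique(binning$chrom)) {
    b <- binning[binning$chrom == ch, ]
    if (is.unsorted(b$start)) stop("bins not sorted on ", ch)
    if (any(b$start[-1] < b$end[-nrow(b)])) stop("overlapping bins on ", ch)
  }
  invisible(binning)
}

#' Read a BED3 bin table
#'
#' @param path path to a 3-column BED file (chrom, start, end; 0-based
#'   half-open), no header, tab-separated.
#' @return A \code{genome_binning} data.frame.
#' @export
read_bins_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)[, 1:3]
  names(b) <- c("chrom", "start", "end")
  validate_binning(b)
  class(b) <- c("genome_binning", "data.frame")
  b
}
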