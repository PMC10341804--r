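#' Genome layout
#'
#' A genome layout records the chromosomes of an allopolyploid assembly, their
#' lengths and the subgenome (\code{"A"} or \code{"D"}) each belongs to. All
#' coordinates in the package are 0-based, half-open (BED convention); every
#' interval must lie within \code{[0, length)} of its chromosome.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bases (> 0).
#' @param subgenome character vector of subgenome labels, one of
#'   \code{"A"} or \code{"D"}.
#' @return A \code{GenomeLayout}: a data.frame with columns \code{chrom},
#'   \code{length}, \code{subgenome}.
#' @examples
#' genome_layout(c("A01", "D01"), c(1e6, 5e5), c("A", "D"))
#' @export
genome_layout <- function(chrom, length, subgenome) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  subgenome <- as.character(subgenome)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (!all(subgenome %in% c("A", "D"))) {
    stop("subgenome labels must be 'A' or 'D'")
  }
  if (stats::var(c(base::length(chrom), base::length(length),
                   base::length(subgenome))) != 0) {
    stop("chrom, length and subgenome must have equal length")
  }
  out <- data.frame(chrom = chrom, length = length, subgenome = subgenome,
                    stringsAsFactors = FALSE)
  class(out) <- c("GenomeLayout", "data.frame")
  out
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosomes, %.0f bases (A: %.0f, D: %.0f)\n",
              nrow(x), sum(x$length),
              sum(x$length[x$subgenome == "A"]),
              sum(x$length[x$subgenome == "D"])))
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

n_bins <- function(layout, bin_width) {
  setNames(as.integer(ceiling(layout$length / bin_width)), layout$chrom)
}

#' Validate intervals against a genome layout
#'
#' Checks the 0-based half-open convention: \code{0 <= start < end <= length}.
#' Called internally by most operations; exported because input sanitisation
#' is useful on its own.
#'
#' @param x data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @param layout a [genome_layout()].
#' @return \code{x}, invisibly, if valid; otherwise an error naming the first
#'   offending interval.
#' @export
check_intervals <- function(x, layout) {
  if (nrow(x) == 0) return(invisible(x))
  len <- chrom_length(layout, x$chrom)
  bad <- which(x$start < 0 | x$start >= x$end | x$end > len)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("interval %s:%d-%d outside layout (chrom length %d)",
                 x$chrom[i], x$start[i], x$end[i], as.integer(len[i])))
  }
  invisible(x)
}

# intervals (0-based half-open) -> IRanges per the 1-based closed convention
as_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

iranges_to_df <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

# reduce intervals (collapse overlaps) within each chromosome
reduce_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  parts <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(as_iranges(d$start, d$end))
    iranges_to_df(ir, d$chrom[1])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# total bases covered by intervals after collapsing overlaps
covered_bases <- function(x) {
  if (nrow(x) == 0) return(0)
  r <- reduce_intervals(x)
  sum(r$end - r$start)
}

#' Transcription start sites
#'
#' TSS of each gene under the strand convention: \code{start} for \code{+}
#' genes, \code{end - 1} for \code{-} genes (0-based).
#'
#' @param genes gene model data.frame (columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}).
#' @return integer vector of 0-based TSS positions.
#' @export
tss_positions <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1L, genes$start)
}

#' Promoter intervals
#'
#' The promoter is the \code{promoter_len} bases immediately upstream of the
#' TSS, strand-aware, clamped at chromosome boundaries (a promoter may be
#' shorter than \code{promoter_len} near an edge, or empty for a TSS at the
#' boundary).
#'
#' @param genes gene model data.frame.
#' @param layout a [genome_layout()].
#' @param promoter_len promoter length in bases upstream of the TSS
#'   (default 500).
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{gene_id}; zero-length promoters have \code{start == end}.
#' @export
promoter_intervals <- function(genes, layout, promoter_len = 500L) {
  tss <- tss_positions(genes)
  len <- chrom_length(layout, genes$chrom)
  minus <- genes$strand == "-"
  start <- ifelse(minus, tss + 1L, pmax(0L, tss - promoter_len))
  end <- ifelse(minus, pmin(len, tss + 1L + promoter_len), tss)
  data.frame(chrom = genes$chrom, start = as.numeric(start),
             end = as.numeric(end), strand = genes$strand,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}
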