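#' Binned signal track
#'
#' A \code{BinnedTrack} holds fixed-width per-bin fragment counts for one mark
#' (histone modification, DNase or Mock control), one condition and one
#' replicate, across all chromosomes of a layout. The number of bins on each
#' chromosome is \code{ceiling(length / bin_width)}; the last bin may be
#' shorter than \code{bin_width}.
#'
#' @param counts named list (one element per layout chromosome, in layout
#'   order) of non-negative integer vectors.
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bases.
#' @param mark mark label (e.g. \code{"H3K4me3"}, \code{"DNase"},
#'   \code{"Mock"}).
#' @param condition condition label.
#' @param replicate replicate number.
#' @return A \code{BinnedTrack} object.
#' @export
binned_track <- function(counts, layout, bin_width, mark = "signal",
                         condition = "cond1", replicate = 1L) {
  nb <- n_bins(layout, bin_width)
  if (!identical(names(counts), layout$chrom)) {
    counts <- counts[layout$chrom]
  }
  for (ch in layout$chrom) {
    v <- counts[[ch]]
    if (is.null(v) || length(v) != nb[[ch]]) {
      stop(sprintf("counts for %s must have %d bins", ch, nb[[ch]]))
    }
    if (any(v < 0)) stop("counts must be non-negative")
  }
  structure(list(mark = mark, condition = condition,
                 replicate = as.integer(replicate),
                 bin_width = as.integer(bin_width),
                 counts = counts, layout = layout),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack %s/%s rep%d: %d chroms, bin %d bp, %.0f fragments\n",
              x$mark, x$condition, x$replicate, length(x$counts),
              x$bin_width, sum(unlist(x$counts))))
  invisible(x)
}

total_fragments <- function(track) sum(vapply(track$counts, sum, numeric(1)))

check_same_layout <- function(a, b) {
  if (!identical(a$layout, b$layout) || a$bin_width != b$bin_width) {
    stop("tracks must share the same layout and bin width")
  }
}

#' Bin sequenced fragments by midpoint
#'
#' Assigns each fragment to the single bin containing its midpoint
#' (\code{floor((start + end) / 2) \%/\% bin_width}), so the total count over
#' all bins equals the number of fragments exactly.
#'
#' @param fragments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bases (default 200, the resolution used for
#'   chromatin-state analysis).
#' @inheritParams binned_track
#' @return A [binned_track()].
#' @examples
#' lay <- genome_layout("chr1", 1000, "A")
#' fr <- data.frame(chrom = "chr1", start = 190, end = 410)
#' bin_fragments(fr, lay, 200)$counts$chr1  # midpoint 300 -> bin 2 of 5
#' @export
bin_fragments <- function(fragments, layout, bin_width = 200L,
                          mark = "signal", condition = "cond1",
                          replicate = 1L) {
  check_intervals(fragments, layout)
  nb <- n_bins(layout, bin_width)
  counts <- lapply(layout$chrom, function(ch) integer(nb[[ch]]))
  names(counts) <- layout$chrom
  if (nrow(fragments) > 0) {
    mid <- (fragments$start + fragments$end) %/% 2
    bin <- mid %/% bin_width
    for (ch in unique(fragments$chrom)) {
      sel <- fragments$chrom == ch
      counts[[ch]] <- counts[[ch]] +
        tabulate(bin[sel] + 1L, nbins = nb[[ch]])
    }
  }
  binned_track(counts, layout, bin_width, mark, condition, replicate)
}

#' Pool replicate tracks
#'
#' Sums per-bin counts across tracks of the same mark/condition (replicates
#' are pooled before binarization to maximise depth).
#'
#' @param tracks list of [binned_track()]s on one layout and bin width.
#' @return A [binned_track()] with summed counts and \code{replicate = 0}.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  for (t in tracks[-1]) check_same_layout(tracks[[1]], t)
  counts <- tracks[[1]]$counts
  for (t in tracks[-1]) {
    for (ch in names(counts)) counts[[ch]] <- counts[[ch]] + t$counts[[ch]]
  }
  binned_track(counts, tracks[[1]]$layout, tracks[[1]]$bin_width,
               tracks[[1]]$mark, tracks[[1]]$condition, 0L)
}

#' RPKM-normalize a binned track
#'
#' Reads (fragments) per kilobase of bin per million mapped fragments:
#' \code{count * 1e9 / (total_fragments * bin_width)}. The nominal
#' \code{bin_width} is used for every bin, including a shorter terminal bin.
#'
#' @param track a [binned_track()].
#' @param total_fragments library size; defaults to the track's own total.
#' @return Named list of per-chromosome numeric vectors with attributes
#'   \code{bin_width} and \code{layout}.
#' @export
rpkm_normalize <- function(track, total_fragments = NULL) {
  if (is.null(total_fragments)) total_fragments <- total_fragments(track)
  if (!is.numeric(total_fragments) || total_fragments <= 0) {
    stop("total_fragments must be > 0")
  }
  f <- 1e9 / (total_fragments * track$bin_width)
  out <- lapply(track$counts, function(v) v * f)
  attr(out, "bin_width") <- track$bin_width
  attr(out, "layout") <- track$layout
  out
}

#' Pearson correlation between replicate tracks
#'
#' Standard Pearson correlation of per-bin counts across all bins of the
#' genome; the usual replicate-QC statistic (replicates with r >= 0.95 are
#' considered concordant).
#'
#' @param a,b two [binned_track()]s on the same layout and bin width.
#' @return Pearson r.
#' @export
replicate_correlation <- function(a, b) {
  check_same_layout(a, b)
  x <- unlist(a$counts, use.names = FALSE)
  y <- unlist(b$counts, use.names = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("replicate_correlation undefined: zero variance in a track")
  }
  stats::cor(x, y)
}

#' Strand-aware metagene profile around TSSs
#'
#' Averages normalized signal over genes, anchored at the TSS, from
#' \code{-flank} to \code{+flank} at \code{n_points} equally spaced offsets.
#' Minus-strand genes are flipped so that positive offsets always point into
#' the gene body. Offsets falling outside a chromosome are dropped from the
#' mean at that position; a position with no usable gene is \code{NaN}.
#'
#' @param signal normalized signal as returned by [rpkm_normalize()].
#' @param anchors gene model data.frame (\code{chrom}, \code{start},
#'   \code{end}, \code{strand}).
#' @param flank flank size in bases on each side of the TSS (default 2000).
#' @param n_points number of points in the profile (default
#'   \code{2 * flank / bin_width + 1}, i.e. one per bin).
#' @return numeric vector of length \code{n_points} with attribute
#'   \code{offsets} (base offsets relative to the TSS, 5' to 3').
#' @export
metagene_profile <- function(signal, anchors, flank = 2000L, n_points = NULL) {
  if (nrow(anchors) == 0) stop("anchors must be non-empty")
  bw <- attr(signal, "bin_width")
  layout <- attr(signal, "layout")
  if (is.null(n_points)) n_points <- as.integer(2 * flank / bw + 1)
  offsets <- round(seq(-flank, flank, length.out = n_points))
  tss <- tss_positions(anchors)
  len <- chrom_length(layout, anchors$chrom)
  acc <- numeric(n_points)
  nn <- integer(n_points)
  for (i in seq_len(nrow(anchors))) {
    dir <- if (anchors$strand[i] == "-") -1 else 1
    pos <- tss[i] + dir * offsets
    ok <- pos >= 0 & pos < len[i]
    if (!any(ok)) next
    bins <- pos[ok] %/% bw + 1L
    vals <- signal[[anchors$chrom[i]]][bins]
    acc[ok] <- acc[ok] + vals
    nn[ok] <- nn[ok] + 1L
  }
  out <- acc / nn  # positions never covered -> NaN by 0/0
  attr(out, "offsets") <- offsets
  out
}
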