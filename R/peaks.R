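#' Call broad peaks with a per-bin Poisson enrichment test
#'
#' A deliberately simple broad-peak caller for binned ChIP signal against a
#' Mock control. For each bin the expected rate is
#' \code{lambda = max(control scaled to ChIP depth, global ChIP mean)}; a bin
#' is enriched when the Poisson upper tail \code{P(X >= c | lambda)} falls
#' below \code{p_cut} and the fold ratio \code{c / lambda} exceeds
#' \code{fc_cut}. Runs of enriched bins separated by at most
#' \code{merge_gap} bases are merged into one peak; the peak's
#' \code{p_value} is the minimum bin p and \code{fold_change} the maximum bin
#' ratio.
#'
#' @param chip,control [binned_track()]s on the same layout; a control with
#'   zero total counts falls back to the global ChIP mean alone.
#' @param p_cut Poisson tail cutoff (default \code{1e-10}).
#' @param fc_cut fold-change cutoff (default 5).
#' @param merge_gap maximum gap in bases between merged enriched bins
#'   (default 0: only adjacent bins merge).
#' @return data.frame of peaks: \code{chrom}, \code{start}, \code{end},
#'   \code{mark}, \code{p_value}, \code{fold_change}.
#' @export
call_broad_peaks <- function(chip, control, p_cut = 1e-10, fc_cut = 5,
                             merge_gap = 0L) {
  check_same_layout(chip, control)
  bw <- chip$bin_width
  chip_tot <- total_fragments(chip)
  ctrl_tot <- total_fragments(control)
  global_mean <- chip_tot / sum(vapply(chip$counts, length, numeric(1)))
  scale <- if (ctrl_tot > 0) chip_tot / ctrl_tot else 0
  peaks <- list()
  for (ch in chip$layout$chrom) {
    c_chip <- chip$counts[[ch]]
    lambda <- pmax(control$counts[[ch]] * scale, global_mean)
    p <- stats::ppois(c_chip - 1, lambda, lower.tail = FALSE)
    ratio <- c_chip / lambda
    enr <- which(p < p_cut & ratio > fc_cut)
    if (!length(enr)) next
    # merge enriched bins whose inter-bin gap (bases) <= merge_gap
    grp <- cumsum(c(1L, (diff(enr) - 1L) * bw > merge_gap))
    for (g in split(enr, grp)) {
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch,
        start = (min(g) - 1L) * bw,
        end = min(max(g) * bw, chrom_length(chip$layout, ch)),
        mark = chip$mark,
        p_value = max(min(p[g]), .Machine$double.xmin),
        fold_change = max(ratio[g]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(peaks)) return(empty_peaks(chip$mark))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

empty_peaks <- function(mark = character(0)) {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             mark = character(0), p_value = numeric(0),
             fold_change = numeric(0), stringsAsFactors = FALSE)
}

#' Replicate-consensus peaks
#'
#' Retains each replicate-1 peak that overlaps a replicate-2 peak by at least
#' one base, widening its interval to the union of itself and all overlapping
#' replicate-2 peaks (the union is contiguous since every contributing peak
#' overlaps the anchor). \code{p_value} is the minimum and
#' \code{fold_change} the maximum over the contributing peaks.
#'
#' @param rep1,rep2 peak data.frames from [call_broad_peaks()].
#' @return consensus peak data.frame.
#' @export
consensus_peaks <- function(rep1, rep2) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) return(empty_peaks())
  out <- rep1[0, , drop = FALSE]
  for (ch in unique(rep1$chrom)) {
    a <- rep1[rep1$chrom == ch, , drop = FALSE]
    b <- rep2[rep2$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) next
    hits <- IRanges::findOverlaps(as_iranges(a$start, a$end),
                                  as_iranges(b$start, b$end))
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      js <- sh[qh == i]
      row <- a[i, , drop = FALSE]
      row$start <- min(a$start[i], b$start[js])
      row$end <- max(a$end[i], b$end[js])
      row$p_value <- min(a$p_value[i], b$p_value[js])
      row$fold_change <- max(a$fold_change[i], b$fold_change[js])
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Fraction of peaks substantially covered by another peak set
#'
#' For each peak in \code{peaks_a}, computes the bases covered by the union
#' of \code{peaks_b}; the peak counts as overlapped when that coverage is at
#' least \code{min_fraction} of its own length (boundary inclusive).
#'
#' @param peaks_a,peaks_b peak data.frames.
#' @param min_fraction required covered fraction (default 0.5).
#' @return fraction of \code{peaks_a} counted as overlapped.
#' @export
peak_overlap_fraction <- function(peaks_a, peaks_b, min_fraction = 0.5) {
  if (nrow(peaks_a) == 0) stop("peak_overlap_fraction undefined for empty A")
  covered <- numeric(nrow(peaks_a))
  if (nrow(peaks_b) > 0) {
    bred <- reduce_intervals(peaks_b)
    for (ch in unique(peaks_a$chrom)) {
      ai <- which(peaks_a$chrom == ch)
      b <- bred[bred$chrom == ch, , drop = FALSE]
      if (nrow(b) == 0) next
      a_ir <- as_iranges(peaks_a$start[ai], peaks_a$end[ai])
      b_ir <- as_iranges(b$start, b$end)
      hits <- IRanges::findOverlaps(a_ir, b_ir)
      if (!length(hits)) next
      ov <- IRanges::width(IRanges::pintersect(
        a_ir[S4Vectors::queryHits(hits)], b_ir[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
      covered[ai[as.integer(names(agg))]] <- agg
    }
  }
  mean(covered >= min_fraction * (peaks_a$end - peaks_a$start))
}

#' Genome coverage of peak sets
#'
#' Bases (self-overlaps collapsed) and genome fraction covered by each peak
#' set, plus the union across all sets (the fraction of the genome carrying
#' at least one mark).
#'
#' @param peak_sets named list of peak data.frames.
#' @param layout a [genome_layout()].
#' @return data.frame with one row per set plus a \code{"union"} row:
#'   \code{set}, \code{bases}, \code{fraction}.
#' @export
genome_coverage <- function(peak_sets, layout) {
  total <- sum(layout$length)
  for (p in peak_sets) if (nrow(p)) check_intervals(p, layout)
  bases <- vapply(peak_sets, covered_bases, numeric(1))
  union_bases <- covered_bases(
    do.call(rbind, lapply(peak_sets, function(p) p[, c("chrom", "start", "end")])))
  out <- data.frame(set = c(names(peak_sets), "union"),
                    bases = c(bases, union_bases),
                    stringsAsFactors = FALSE)
  out$fraction <- out$bases / total
  out
}

#' Annotate peaks by midpoint location
#'
#' Assigns each peak to \code{genic}, \code{TE} or \code{intergenic} by the
#' genomic position of its midpoint (\code{floor((start + end) / 2)}), with
#' precedence gene body > TE > intergenic when features overlap. The three
#' categories partition the peak set.
#'
#' @param peaks peak data.frame.
#' @param genes gene model data.frame.
#' @param tes TE interval data.frame (\code{chrom}, \code{start}, \code{end}).
#' @return \code{peaks} with a \code{category} column added.
#' @export
annotate_by_midpoint <- function(peaks, genes, tes) {
  mid <- (peaks$start + peaks$end) %/% 2
  point_in <- function(feat) {
    hit <- logical(nrow(peaks))
    if (is.null(feat) || nrow(feat) == 0) return(hit)
    for (ch in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == ch)
      f <- feat[feat$chrom == ch, , drop = FALSE]
      if (nrow(f) == 0) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(start = mid[pi] + 1L, width = 1L),
        as_iranges(f$start, f$end))
      hit[pi] <- ov > 0
    }
    hit
  }
  in_gene <- point_in(genes)
  in_te <- point_in(tes)
  peaks$category <- ifelse(in_gene, "genic", ifelse(in_te, "TE", "intergenic"))
  peaks
}

#' Write / read peaks in a broadPeak-style BED6+ dialect
#'
#' Columns: chrom, start, end, name (mark), score (0), strand (.),
#' fold_change, -log10 p-value.
#'
#' @param peaks peak data.frame.
#' @param path file path.
#' @return \code{path} / the peak data.frame.
#' @export
write_broadpeak <- function(peaks, path) {
  out <- data.frame(chrom = peaks$chrom, start = as.integer(peaks$start),
                    end = as.integer(peaks$end), name = peaks$mark,
                    score = 0L, strand = ".",
                    fold_change = peaks$fold_change,
                    neglog10_p = -log10(peaks$p_value))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_broadpeak
#' @export
read_broadpeak <- function(path) {
  d <- data.table::fread(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand", "fold_change",
                                       "neglog10_p"))
  data.frame(chrom = d$chrom, start = d$start, end = d$end, mark = d$name,
             p_value = 10^(-d$neglog10_p), fold_change = d$fold_change,
             stringsAsFactors = FALSE)
}
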