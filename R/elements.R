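#' Partition the genome into genomic elements
#'
#' Builds a disjoint map of \code{promoter}, \code{exon}, \code{intron} and
#' \code{intergenic} intervals covering every base exactly once. The promoter
#' is the \code{promoter_len} bases immediately upstream of each TSS
#' (strand-aware, clamped at chromosome boundaries); base-level precedence on
#' overlaps is promoter > exon > intron > intergenic.
#'
#' @param genes gene model data.frame.
#' @param exons exon data.frame (\code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}); when \code{NULL}, each gene body is a single exon.
#' @param layout a [genome_layout()].
#' @param promoter_len promoter length in bases (default 500).
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{element}
#'   partitioning the genome.
#' @export
build_element_map <- function(genes, exons = NULL, layout,
                              promoter_len = 500L) {
  check_intervals(genes, layout)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  }
  prom <- promoter_intervals(genes, layout, promoter_len)
  prom <- prom[prom$end > prom$start, , drop = FALSE]
  parts <- lapply(layout$chrom, function(ch) {
    len <- chrom_length(layout, ch)
    whole <- IRanges::IRanges(1L, len)
    sel_ir <- function(d) {
      d <- d[d$chrom == ch, , drop = FALSE]
      if (nrow(d) == 0) IRanges::IRanges() else
        IRanges::reduce(as_iranges(d$start, d$end))
    }
    p_ir <- sel_ir(prom)
    e_ir <- IRanges::setdiff(sel_ir(exons), p_ir)
    body_ir <- sel_ir(genes)
    i_ir <- IRanges::setdiff(IRanges::setdiff(body_ir, p_ir), sel_ir(exons))
    g_ir <- IRanges::setdiff(IRanges::setdiff(whole, p_ir), body_ir)
    part <- function(ir, el) {
      d <- iranges_to_df(ir, ch)
      d$element <- rep(el, nrow(d))
      d
    }
    rbind(part(p_ir, "promoter"), part(e_ir, "exon"),
          part(i_ir, "intron"), part(g_ir, "intergenic"))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

element_levels <- c("promoter", "exon", "intron", "intergenic")

# base-overlap matrix between two interval partitions/sets with labels
overlap_base_matrix <- function(a, a_label, b, b_label,
                                a_levels, b_levels) {
  m <- matrix(0, length(a_levels), length(b_levels),
              dimnames = list(a_levels, b_levels))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    a_ir <- as_iranges(ai$start, ai$end)
    b_ir <- as_iranges(bi$start, bi$end)
    hits <- IRanges::findOverlaps(a_ir, b_ir)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(a_ir[qh], b_ir[sh]))
    dt <- data.table::data.table(r = ai[[a_label]][qh],
                                 c = bi[[b_label]][sh], w = w)
    agg <- dt[, list(w = sum(w)), by = c("r", "c")]
    m[cbind(match(agg$r, a_levels), match(agg$c, b_levels))] <-
      m[cbind(match(agg$r, a_levels), match(agg$c, b_levels))] + agg$w
  }
  m
}

normalize_rows <- function(m) {
  rs <- rowSums(m)
  sweep(m, 1, ifelse(rs > 0, rs, 1), "/")
}
normalize_cols <- function(m) t(normalize_rows(t(m)))

#' Chromatin state by genomic element
#'
#' Base-overlap counts of each state against each element class, with both
#' normalized views: within-state element proportions (rows; with a
#' \code{Background} row giving whole-genome element proportions) and
#' within-element state proportions (columns).
#'
#' @param seg a \code{Segmentation}.
#' @param elements element map from [build_element_map()].
#' @return list with \code{bases} (state x element counts),
#'   \code{by_state} (row-normalized, + Background row), \code{by_element}
#'   (column-normalized).
#' @export
state_by_element <- function(seg, elements) {
  iv <- state_intervals(seg)
  states <- paste0("S", seq_len(seg$K))
  m <- overlap_base_matrix(iv, "state", elements, "element",
                           states, element_levels)
  bg <- vapply(element_levels, function(e) {
    sum(elements$end[elements$element == e] -
          elements$start[elements$element == e])
  }, numeric(1))
  by_state <- rbind(normalize_rows(m), Background = bg / sum(bg))
  list(bases = m, by_state = by_state, by_element = normalize_cols(m))
}

#' Chromatin state by TE class
#'
#' Two views of the TE landscape across states: a count view assigning each
#' TE to the state covering its midpoint, and a base view apportioning each
#' TE's bases over the states it spans. Background gives each class's share
#' of TE bases genome-wide.
#'
#' @param seg a \code{Segmentation}.
#' @param tes TE data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{te_class}).
#' @return list with \code{te_counts} and \code{bases} (state x class
#'   matrices), their row-normalized views \code{counts_by_state} /
#'   \code{bases_by_state} (+ Background row on the base view), and
#'   column-normalized \code{by_class}.
#' @export
state_by_te <- function(seg, tes) {
  states <- paste0("S", seq_len(seg$K))
  classes <- sort(unique(tes$te_class))
  iv <- state_intervals(seg)
  counts <- matrix(0, length(states), length(classes),
                   dimnames = list(states, classes))
  if (nrow(tes) > 0) {
    mid <- (tes$start + tes$end) %/% 2
    mid_state <- character(nrow(tes))
    for (ch in unique(tes$chrom)) {
      ti <- which(tes$chrom == ch)
      si <- iv[iv$chrom == ch, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(mid[ti] + 1L, width = 1L),
        as_iranges(si$start, si$end), select = "first")
      mid_state[ti] <- si$state[hits]
    }
    tab <- table(factor(mid_state, states), factor(tes$te_class, classes))
    counts <- counts + unclass(tab)
  }
  bases <- overlap_base_matrix(iv, "state", tes, "te_class", states, classes)
  bg <- vapply(classes, function(cl) {
    sum(tes$end[tes$te_class == cl] - tes$start[tes$te_class == cl])
  }, numeric(1))
  bg <- if (sum(bg) > 0) bg / sum(bg) else bg
  list(te_counts = counts, bases = bases,
       counts_by_state = normalize_rows(counts),
       bases_by_state = rbind(normalize_rows(bases), Background = bg),
       by_class = normalize_cols(bases))
}
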