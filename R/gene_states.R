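#' Assign each gene a chromatin state from its promoter
#'
#' A gene's state is the state covering the most bases of its promoter (the
#' \code{promoter_len} bases upstream of the TSS). When two states tie, the
#' state of the segment overlapping the promoter's 5'-most base (the end
#' farthest upstream in transcription orientation) wins. Genes whose
#' promoter is empty after clamping at a chromosome boundary are assigned
#' \code{"unsegmented"}.
#'
#' @param genes gene model data.frame.
#' @param seg a \code{Segmentation} covering the genes' chromosomes.
#' @param promoter_len promoter length in bases (default 500).
#' @param condition condition label recorded in the output.
#' @return data.frame \code{gene_id}, \code{condition}, \code{state}.
#' @export
assign_gene_state <- function(genes, seg, promoter_len = 500L,
                              condition = "cond1") {
  prom <- promoter_intervals(genes, seg$layout, promoter_len)
  bw <- seg$bin_width
  state <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- prom$start[i]; e <- prom$end[i]
    if (e <= s) { state[i] <- "unsegmented"; next }
    sv <- seg$states[[prom$chrom[i]]]
    b0 <- s %/% bw
    b1 <- (e - 1) %/% bw
    bins <- b0:b1
    ov <- pmin(e, (bins + 1) * bw) - pmax(s, bins * bw)
    st <- sv[bins + 1L]
    bases <- tapply(ov, st, sum)
    best <- names(bases)[bases == max(bases)]
    if (length(best) > 1) {
      five_prime <- if (prom$strand[i] == "-") e - 1 else s
      best <- as.character(sv[five_prime %/% bw + 1L])
    }
    state[i] <- paste0("S", best)
  }
  data.frame(gene_id = genes$gene_id, condition = condition, state = state,
             stringsAsFactors = FALSE)
}

#' Cross-condition chromatin-state transition ledger
#'
#' Pairs each gene's state in two conditions; a transition is a gene whose
#' promoter state differs between them. Genes absent from either assignment,
#' or unsegmented in either, are excluded from the K x K matrix (reported in
#' \code{excluded}).
#'
#' @param assign_a,assign_b assignments from [assign_gene_state()] for the
#'   two conditions.
#' @param K number of states (default: inferred from the labels present).
#' @return list with \code{ledger} (data.frame \code{gene_id},
#'   \code{state_from}, \code{state_to}, \code{is_transition}),
#'   \code{matrix} (K x K gene counts, rows = condition-1 state),
#'   \code{transition_fraction} (share of assignable genes with a
#'   transition) and \code{excluded} (gene ids dropped).
#' @export
build_transition_ledger <- function(assign_a, assign_b, K = NULL) {
  m <- merge(assign_a[, c("gene_id", "state")],
             assign_b[, c("gene_id", "state")],
             by = "gene_id", suffixes = c("_from", "_to"))
  dropped <- union(setdiff(assign_a$gene_id, m$gene_id),
                   setdiff(assign_b$gene_id, m$gene_id))
  unseg <- m$state_from == "unsegmented" | m$state_to == "unsegmented"
  excluded <- c(dropped, m$gene_id[unseg])
  m <- m[!unseg, , drop = FALSE]
  m$is_transition <- m$state_from != m$state_to
  if (is.null(K)) {
    K <- max(as.integer(sub("^S", "", c(m$state_from, m$state_to))))
  }
  states <- paste0("S", seq_len(K))
  mat <- unclass(table(factor(m$state_from, states),
                       factor(m$state_to, states)))
  names(dimnames(mat)) <- NULL
  rownames(m) <- NULL
  list(ledger = m, matrix = mat,
       transition_fraction = mean(m$is_transition),
       excluded = excluded)
}

#' Chromatin-state transition x differential-expression enrichment
#'
#' Tests whether genes undergoing a promoter state transition are enriched
#' for differential expression. Always reports the overall 2x2
#' (transition vs no transition x DEG vs non-DEG); with
#' \code{by_group = TRUE} additionally tests each transition group (ordered
#' from-to pair) against the chosen DEG direction. P-values are two-sided
#' Fisher exact tests; each result carries the background DEG fraction for
#' comparison.
#'
#' @param ledger output of [build_transition_ledger()].
#' @param de a [nb_de_test()]-style data.frame (\code{gene_id},
#'   \code{call}).
#' @param direction which DEGs to count: \code{"any"}, \code{"up"} or
#'   \code{"down"}.
#' @param by_group also test each transition group (default TRUE).
#' @param min_group_size groups smaller than this are skipped (default 5).
#' @return data.frame with one row per test: \code{group}, \code{direction},
#'   \code{n_group}, \code{n_deg_in_group}, \code{deg_fraction},
#'   \code{background_fraction}, \code{odds_ratio}, \code{p_value}.
#' @export
transition_deg_enrichment <- function(ledger, de,
                                      direction = c("any", "up", "down"),
                                      by_group = TRUE, min_group_size = 5L) {
  direction <- match.arg(direction)
  led <- ledger$ledger
  led <- merge(led, de[, c("gene_id", "call")], by = "gene_id")
  is_deg <- if (direction == "any") led$call %in% c("up", "down")
            else led$call == direction
  res <- list()
  add_test <- function(group, in_group) {
    a <- sum(in_group & is_deg); b <- sum(in_group & !is_deg)
    c_ <- sum(!in_group & is_deg); d <- sum(!in_group & !is_deg)
    ft <- fisher_exact(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
    data.frame(group = group, direction = direction,
               n_group = a + b, n_deg_in_group = a,
               deg_fraction = if (a + b > 0) a / (a + b) else NA_real_,
               background_fraction = mean(is_deg),
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  }
  res[["overall"]] <- add_test("transition", led$is_transition)
  if (by_group) {
    groups <- unique(led[led$is_transition,
                         c("state_from", "state_to"), drop = FALSE])
    groups <- groups[order(groups$state_from, groups$state_to), , drop = FALSE]
    for (i in seq_len(nrow(groups))) {
      in_g <- led$state_from == groups$state_from[i] &
        led$state_to == groups$state_to[i]
      if (sum(in_g) < min_group_size) next
      res[[length(res) + 1L]] <-
        add_test(paste0(groups$state_from[i], "-", groups$state_to[i]), in_g)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
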