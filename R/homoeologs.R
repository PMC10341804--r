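#' Reciprocal-best-hit homoeolog pairing
#'
#' Identifies homoeologous gene pairs between the A and D subgenomes from
#' all-vs-all protein similarity tables. Each query's best hit is its
#' lowest-E-value hit (ties: highest identity, then lexicographically
#' smallest target id); a pair (a, d) is kept when a's best hit is d, d's
#' best hit is a, and both hits pass all three cuts. A gene whose every
#' cross-subgenome hit fails the similarity cuts (coverage or identity below
#' threshold), or that has no hit at all, is subgenome-unique. Genes that
#' are neither (e.g. a passing hit without reciprocity) form an unclassified
#' remainder.
#'
#' @param hits_ad,hits_da similarity tables (data.frames with
#'   \code{query_id}, \code{target_id}, \code{e_value}, \code{coverage},
#'   \code{identity}; coverage/identity in percent) for A-vs-D and D-vs-A
#'   searches.
#' @param a_genes,d_genes full gene-id universes per subgenome (genes with no
#'   hits are invisible in the tables); default: ids seen in the tables.
#' @param e_cut E-value cut (default \code{1e-5}).
#' @param cov_cut,id_cut coverage / identity cuts in percent (default 50).
#' @return list with \code{pairs} (data.frame \code{a_gene}, \code{d_gene}),
#'   \code{a_unique}, \code{d_unique}, \code{a_other}, \code{d_other}
#'   (character vectors).
#' @export
reciprocal_best_hits <- function(hits_ad, hits_da,
                                 a_genes = NULL, d_genes = NULL,
                                 e_cut = 1e-5, cov_cut = 50, id_cut = 50) {
  clean <- function(h) {
    dt <- data.table::as.data.table(h)
    if (anyDuplicated(dt[, c("query_id", "target_id")])) {
      warning("duplicate (query, target) rows: keeping the best")
      data.table::setorder(dt, e_value, -identity)
      dt <- dt[!duplicated(dt[, c("query_id", "target_id")]), ]
    }
    dt
  }
  best_hit <- function(dt) {
    data.table::setorder(dt, query_id, e_value, -identity, target_id)
    dt[!duplicated(dt$query_id), ]
  }
  ad <- clean(hits_ad); da <- clean(hits_da)
  if (is.null(a_genes)) a_genes <- sort(unique(c(ad$query_id, da$target_id)))
  if (is.null(d_genes)) d_genes <- sort(unique(c(da$query_id, ad$target_id)))
  ba <- best_hit(ad); bd <- best_hit(da)
  passes <- function(dt) dt$e_value < e_cut & dt$coverage >= cov_cut &
    dt$identity >= id_cut
  ba_pass <- ba[passes(ba), ]
  bd_pass <- bd[passes(bd), ]
  bd_map <- setNames(bd_pass$target_id, bd_pass$query_id)
  mutual <- !is.na(bd_map[ba_pass$target_id]) &
    bd_map[ba_pass$target_id] == ba_pass$query_id
  pairs <- data.frame(a_gene = ba_pass$query_id[mutual],
                      d_gene = ba_pass$target_id[mutual],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$a_gene), , drop = FALSE]
  rownames(pairs) <- NULL
  # unique = every cross-subgenome hit is weak (cov or id below cut), or none
  similar <- function(dt) dt$coverage >= cov_cut & dt$identity >= id_cut
  has_similar_a <- unique(ad$query_id[similar(ad)])
  has_similar_d <- unique(da$query_id[similar(da)])
  a_unique <- setdiff(a_genes, has_similar_a)
  d_unique <- setdiff(d_genes, has_similar_d)
  list(pairs = pairs,
       a_unique = sort(a_unique), d_unique = sort(d_unique),
       a_other = sort(setdiff(a_genes, c(pairs$a_gene, a_unique))),
       d_other = sort(setdiff(d_genes, c(pairs$d_gene, d_unique))))
}

#' Categorise homoeolog pairs by expression bias
#'
#' Treats the two members of each pair as pseudo-conditions across RNA-seq
#' replicates and runs the NB test ([nb_de_test()]) per pair at the usual
#' thresholds (fold change >= 2, FDR <= 0.05). Pairs where the A member is
#' significantly higher are \code{"A>D"}, lower \code{"A<D"}, otherwise
#' \code{"A=D"}; a pair with a member missing from the count matrix is
#' \code{"A=D"} (logged via attribute \code{missing}).
#'
#' @param homoeologs a [reciprocal_best_hits()] result.
#' @param counts gene x sample count matrix (one condition's replicates).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_cut log2 fold-change threshold (default 1).
#' @return data.frame \code{a_gene}, \code{d_gene}, \code{log2_fold_change}
#'   (A over D), \code{fdr}, \code{category}; attribute \code{summary} holds
#'   the category counts and biased percentage (see [bias_summary()]).
#' @export
categorize_bias <- function(homoeologs, counts, alpha = 0.05, lfc_cut = 1) {
  pairs <- homoeologs$pairs
  present <- pairs$a_gene %in% rownames(counts) &
    pairs$d_gene %in% rownames(counts)
  category <- rep("A=D", nrow(pairs))
  lfc <- rep(NA_real_, nrow(pairs))
  fdr <- rep(NA_real_, nrow(pairs))
  if (any(present)) {
    p <- pairs[present, , drop = FALSE]
    nrep <- ncol(counts)
    # pair-level matrix: D-member replicates then A-member replicates
    pm <- cbind(counts[p$d_gene, , drop = FALSE],
                counts[p$a_gene, , drop = FALSE])
    rownames(pm) <- paste(p$a_gene, p$d_gene, sep = "|")
    cond <- rep(c("D", "A"), each = nrep)
    de <- nb_de_test(pm, cond, "D", "A", alpha = alpha, lfc_cut = lfc_cut)
    category[present] <- c(ns = "A=D", up = "A>D", down = "A<D")[de$call]
    lfc[present] <- de$log2_fold_change
    fdr[present] <- de$fdr
  }
  out <- data.frame(a_gene = pairs$a_gene, d_gene = pairs$d_gene,
                    log2_fold_change = lfc, fdr = fdr, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- bias_summary(sum(category == "A>D"),
                                       sum(category == "A<D"), nrow(pairs))
  attr(out, "missing") <- pairs$a_gene[!present]
  out
}

#' Summarise homoeolog expression-bias counts
#'
#' @param n_a_gt number of A > D pairs.
#' @param n_a_lt number of A < D pairs.
#' @param n_pairs total pairs.
#' @return list with the counts, \code{n_balanced}, \code{n_biased} and
#'   \code{biased_percent} = 100 * (A>D + A<D) / total.
#' @examples
#' bias_summary(2879, 3114, 26340)$biased_percent  # 22.8
#' @export
bias_summary <- function(n_a_gt, n_a_lt, n_pairs) {
  n_biased <- n_a_gt + n_a_lt
  list(n_a_gt = n_a_gt, n_a_lt = n_a_lt, n_pairs = n_pairs,
       n_balanced = n_pairs - n_biased, n_biased = n_biased,
       biased_percent = 100 * n_biased / n_pairs)
}

#' Compare mark or expression levels between gene groups
#'
#' Per-mark group means plus a two-sided Wilcoxon rank-sum p-value
#' ([wilcoxon_rank_sum()]) for every unordered pair of groups.
#'
#' @param signal gene x mark numeric matrix (row names = gene ids); a plain
#'   numeric named vector is treated as a one-column matrix.
#' @param groups named list of gene-id vectors.
#' @return list with \code{means} (group x mark) and \code{tests}
#'   (data.frame \code{mark}, \code{group1}, \code{group2}, \code{p_value}).
#' @export
mark_level_compare <- function(signal, groups) {
  if (is.null(dim(signal))) {
    signal <- matrix(signal, ncol = 1,
                     dimnames = list(names(signal), "signal"))
  }
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  marks <- colnames(signal)
  gn <- names(groups)
  means <- matrix(NA_real_, length(groups), length(marks),
                  dimnames = list(gn, marks))
  for (i in seq_along(groups)) {
    means[i, ] <- colMeans(
      signal[intersect(groups[[i]], rownames(signal)), , drop = FALSE])
  }
  tests <- list()
  for (mk in marks) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      x <- signal[intersect(groups[[i]], rownames(signal)), mk]
      y <- signal[intersect(groups[[j]], rownames(signal)), mk]
      w <- wilcoxon_rank_sum(x, y)
      tests[[length(tests) + 1L]] <-
        data.frame(mark = mk, group1 = gn[i], group2 = gn[j],
                   p_value = w$p_value, stringsAsFactors = FALSE)
    }
  }
  list(means = means, tests = do.call(rbind, tests))
}
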