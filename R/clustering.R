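#' Gene-body mean signal matrix
#'
#' Mean normalized signal (RPKM) over each gene body, per mark — the feature
#' matrix for histone-combination clustering of genes.
#'
#' @param signals named list (one per mark) of normalized signals from
#'   [rpkm_normalize()].
#' @param genes gene model data.frame.
#' @return gene x mark numeric matrix.
#' @export
gene_signal_matrix <- function(signals, genes) {
  marks <- names(signals)
  out <- matrix(0, nrow(genes), length(marks),
                dimnames = list(genes$gene_id, marks))
  bw <- attr(signals[[1]], "bin_width")
  b0 <- genes$start %/% bw + 1L
  b1 <- (genes$end - 1L) %/% bw + 1L
  for (m in marks) {
    sig <- signals[[m]]
    for (i in seq_len(nrow(genes))) {
      out[i, m] <- mean(sig[[genes$chrom[i]]][b0[i]:b1[i]])
    }
  }
  out
}

# deterministic k-means++ seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    prob <- d2 / sum(d2)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster genes by histone-mark signal
#'
#' K-means (Lloyd iterations via \code{stats::kmeans}) on per-mark z-scored
#' gene signal, with seeded k-means++ initial centers so that the labelling
#' is deterministic given \code{seed}. Cluster labels are renumbered by
#' descending cluster size (C1 = largest). Genes are typically pre-filtered
#' to those carrying at least one histone peak in the gene body (see
#' \code{genes_with_body_peaks()}).
#'
#' @param signal gene x mark matrix from [gene_signal_matrix()].
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @return list with \code{labels} (named integer vector, 1..k),
#'   \code{centers} (cluster x mark means on the original signal scale) and
#'   \code{sizes}.
#' @export
kmeans_gene_clusters <- function(signal, k = 5L, seed = 1L) {
  if (k > nrow(signal)) stop("k exceeds the number of genes")
  z <- scale(signal)
  z[, attr(z, "scaled:scale") == 0] <- 0
  set.seed(seed)
  init <- kmeanspp_centers(z, k)
  km <- stats::kmeans(z, centers = init, iter.max = 100,
                      algorithm = "Lloyd")
  sizes <- tabulate(km$cluster, k)
  relab <- order(-sizes, seq_len(k))      # new label c = old cluster relab[c]
  newlab <- integer(k)
  newlab[relab] <- seq_len(k)             # old -> new
  labels <- setNames(newlab[km$cluster], rownames(signal))
  centers <- matrix(0, k, ncol(signal),
                    dimnames = list(paste0("C", seq_len(k)),
                                    colnames(signal)))
  for (cl in seq_len(k)) {
    centers[cl, ] <- colMeans(signal[labels == cl, , drop = FALSE])
  }
  list(labels = labels, centers = centers, sizes = tabulate(labels, k))
}

#' Genes carrying at least one histone peak in the gene body
#'
#' @param genes gene model data.frame.
#' @param peak_sets list of peak data.frames (histone marks only).
#' @return character vector of gene ids.
#' @export
genes_with_body_peaks <- function(genes, peak_sets) {
  all_peaks <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  hit <- logical(nrow(genes))
  if (!is.null(all_peaks) && nrow(all_peaks) > 0) {
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      p <- all_peaks[all_peaks$chrom == ch, , drop = FALSE]
      if (nrow(p) == 0) next
      ov <- IRanges::countOverlaps(as_iranges(genes$start[gi], genes$end[gi]),
                                   as_iranges(p$start, p$end))
      hit[gi] <- ov > 0
    }
  }
  genes$gene_id[hit]
}

#' New-gene enrichment per cluster
#'
#' For each cluster, a two-sided Fisher exact test of the 2x2 table
#' \{new, not new\} x \{in cluster, not in cluster\}, with the cluster's
#' background share of all genes reported alongside (as in comparisons of
#' polyploidy-derived new genes against the genome background).
#'
#' @param labels cluster labels from [kmeans_gene_clusters()].
#' @param new_genes character vector of new-gene ids (subset of
#'   \code{names(labels)}).
#' @return data.frame \code{cluster}, \code{n_cluster}, \code{n_new_in},
#'   \code{new_fraction} (share of new genes in the cluster),
#'   \code{background_fraction} (cluster share of all genes),
#'   \code{odds_ratio}, \code{p_value}.
#' @export
newgene_cluster_enrichment <- function(labels, new_genes) {
  if (length(new_genes) == 0) stop("new_genes must be non-empty")
  is_new <- names(labels) %in% new_genes
  k <- max(labels)
  out <- lapply(seq_len(k), function(cl) {
    in_cl <- labels == cl
    ft <- fisher_exact(matrix(c(sum(is_new & in_cl), sum(is_new & !in_cl),
                                sum(!is_new & in_cl), sum(!is_new & !in_cl)),
                              2, 2, byrow = TRUE))
    data.frame(cluster = paste0("C", cl), n_cluster = sum(in_cl),
               n_new_in = sum(is_new & in_cl),
               new_fraction = sum(is_new & in_cl) / sum(is_new),
               background_fraction = mean(in_cl),
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
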