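#' FPKM from a fragment count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \code{count * 1e9 / (column total * transcript length)}. Transcript length
#' is the summed exon length of each gene.
#'
#' @param counts gene x sample matrix of non-negative integer fragment
#'   counts (row names = gene ids).
#' @param genes gene model data.frame.
#' @param exons exon data.frame; when \code{NULL} the gene body length is
#'   used.
#' @return matrix of FPKM values, same shape as \code{counts}.
#' @export
fpkm <- function(counts, genes, exons = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lens <- if (is.null(exons)) {
    setNames(genes$end - genes$start, genes$gene_id)
  } else {
    dt <- data.table::as.data.table(exons)
    agg <- dt[, list(len = sum(end - start)), by = "gene_id"]
    setNames(agg$len, agg$gene_id)
  }
  glen <- lens[rownames(counts)]
  if (anyNA(glen) || any(glen <= 0)) stop("missing or zero gene length")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total fragments")
  sweep(counts / glen, 2, totals, "/") * 1e9
}

#' Negative-binomial differential expression test
#'
#' A transparent DESeq2-style workflow: median-of-ratios library-size
#' normalization, per-gene method-of-moments NB dispersion from the pooled
#' within-group variance, moderated by taking the maximum of the gene-wise
#' estimate and the common (across-genes) dispersion — with few replicates
#' the gene-wise estimate alone is far too noisy — and a Wald test of the
#' log2 ratio of normalized group means under the NB variance model
#' \code{Var(X) = mu + disp * mu^2}; p-values are BH-adjusted. A gene is
#' called \code{up} (\code{down}) when \code{fdr <= alpha} and
#' \code{log2FC > lfc_cut} (\code{< -lfc_cut}); \code{log2FC} is
#' \code{cond_b} over \code{cond_a}.
#'
#' @param counts gene x sample count matrix.
#' @param conditions condition label per column of \code{counts}.
#' @param cond_a,cond_b the two condition labels to compare (each needs >= 2
#'   replicates).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_cut absolute log2 fold-change threshold (default 1, i.e.
#'   two-fold).
#' @param disp_floor dispersion floor (default \code{1e-8}).
#' @return data.frame \code{gene_id}, \code{base_mean},
#'   \code{log2_fold_change}, \code{raw_p}, \code{fdr}, \code{call}.
#' @export
nb_de_test <- function(counts, conditions, cond_a, cond_b, alpha = 0.05,
                       lfc_cut = 1, disp_floor = 1e-8) {
  counts <- as.matrix(counts)
  sel <- conditions %in% c(cond_a, cond_b)
  counts <- counts[, sel, drop = FALSE]
  conditions <- conditions[sel]
  ia <- which(conditions == cond_a)
  ib <- which(conditions == cond_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need >= 2 replicates per condition")
  }
  sf <- median_of_ratios(counts)
  y <- sweep(counts, 2, sf, "/")
  mu_a <- rowMeans(y[, ia, drop = FALSE])
  mu_b <- rowMeans(y[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  s2a <- apply(y[, ia, drop = FALSE], 1, stats::var)
  s2b <- apply(y[, ib, drop = FALSE], 1, stats::var)
  s2 <- ((na - 1) * s2a + (nb - 1) * s2b) / (na + nb - 2)
  mu <- (na * mu_a + nb * mu_b) / (na + nb)
  disp_g <- pmax((s2 - mu) / mu^2, 0)
  disp_g[!is.finite(disp_g)] <- 0
  expressed <- mu > 1
  common <- if (any(expressed)) {
    mean(disp_g[expressed], trim = 0.1)
  } else 0
  disp <- pmax(disp_g, common, disp_floor)
  pseudo <- 0.5
  lfc <- log2((mu_b + pseudo) / (mu_a + pseudo))
  # Var(log2 mean_g) ~ (1/(n mu) + disp/n) / ln(2)^2 under the NB model
  v <- (1 / (na * pmax(mu_a, pseudo)) + disp / na +
          1 / (nb * pmax(mu_b, pseudo)) + disp / nb) / log(2)^2
  z <- lfc / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  zero <- mu_a + mu_b == 0
  p[zero] <- 1
  lfc[zero] <- 0
  fdr <- benjamini_hochberg(p)
  fdr[zero] <- 1
  call <- rep("ns", nrow(counts))
  call[fdr <= alpha & lfc > lfc_cut] <- "up"
  call[fdr <= alpha & lfc < -lfc_cut] <- "down"
  data.frame(gene_id = rownames(counts), base_mean = mu,
             log2_fold_change = lfc, raw_p = p, fdr = fdr, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

# DESeq2-style median-of-ratios size factors; genes with any zero count are
# excluded from the geometric-mean reference
median_of_ratios <- function(counts) {
  logc <- log(counts)
  ref <- rowMeans(logc)
  use <- is.finite(ref)
  if (!any(use)) return(colSums(counts) / mean(colSums(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col[col > 0]) - ref[use][col > 0]))
  })
  sf
}

#' Summarise differential-expression calls
#'
#' @param de a [nb_de_test()] result.
#' @return list with \code{n_up}, \code{n_down}, \code{n_deg},
#'   \code{deg_fraction}.
#' @export
deg_summary <- function(de) {
  n_up <- sum(de$call == "up")
  n_down <- sum(de$call == "down")
  list(n_up = n_up, n_down = n_down, n_deg = n_up + n_down,
       deg_fraction = (n_up + n_down) / nrow(de))
}

#' Derive up/down/ns calls from an external DE table
#'
#' Lets an externally produced differential-expression table (columns
#' \code{gene_id}, \code{log2_fold_change}, \code{fdr}) bypass the built-in
#' test while keeping the downstream enrichment machinery.
#'
#' @param de data.frame with \code{gene_id}, \code{log2_fold_change},
#'   \code{fdr}.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @return \code{de} with a \code{call} column added.
#' @export
de_calls <- function(de, alpha = 0.05, lfc_cut = 1) {
  call <- rep("ns", nrow(de))
  call[de$fdr <= alpha & de$log2_fold_change > lfc_cut] <- "up"
  call[de$fdr <= alpha & de$log2_fold_change < -lfc_cut] <- "down"
  de$call <- call
  de
}
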