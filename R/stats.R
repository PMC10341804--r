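#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional on the table margins, sums the hypergeometric probabilities of
#' every table as or less probable than the observed one (the standard
#' two-sided definition). The odds ratio reported is the sample odds ratio
#' \code{(a*d)/(b*c)}.
#'
#' @param tab 2x2 integer matrix (or \code{c(a, b, c, d)} row-wise).
#' @return list with \code{p_value}, \code{odds_ratio} and the table.
#' @examples
#' fisher_exact(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 margin (white balls)
  n <- sum(tab[2, ])   # row-2 margin (black balls)
  k <- sum(tab[, 1])   # column-1 margin (draws)
  lo <- max(0, k - n)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or, table = tab)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by complete enumeration of all rank splits when both groups have
#' at most \code{exact_max} observations (ties handled naturally by
#' enumeration); otherwise the normal approximation with tie-corrected
#' variance (no continuity correction). The two-sided exact p is the
#' probability of a rank sum at least as far from its null expectation as
#' observed.
#'
#' @param x,y numeric samples.
#' @param exact_max per-group size limit for exact enumeration (default 10).
#' @return list with \code{p_value}, \code{W} (rank sum of \code{x} minus its
#'   minimum, the Mann-Whitney U), and \code{method}.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  ew <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[splits], nrow = n1))
    p <- mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    n <- n1 + n2
    varw <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w_obs - ew) / sqrt(varw)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(p_value = min(p, 1), W = w_obs - n1 * (n1 + 1) / 2, method = method)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (via \code{stats::p.adjust}), order-preserving
#' with respect to the input.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
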