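# Independent brute-force oracles used against the package implementations.

# exhaustive-path HMM log-likelihood: sum over all K^T state paths
brute_loglik <- function(model, obs) {
  K <- model$K
  T_ <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    p <- model$initial[s[1]]
    if (T_ > 1) for (t in 2:T_) p <- p * model$transition[s[t - 1], s[t]]
    for (t in seq_len(T_)) {
      e <- model$emission[s[t], ]
      p <- p * prod(e^obs[t, ] * (1 - e)^(1 - obs[t, ]))
    }
    total <- total + p
  }
  log(total)
}

# exhaustive-path Viterbi: argmax over all K^T paths
brute_viterbi <- function(model, obs) {
  K <- model$K
  T_ <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  best <- -Inf
  best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    lp <- log(model$initial[s[1]])
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(model$transition[s[t - 1], s[t]])
    for (t in seq_len(T_)) {
      e <- model$emission[s[t], ]
      lp <- lp + sum(obs[t, ] * log(e) + (1 - obs[t, ]) * log(1 - e))
    }
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(logprob = best, path = unname(best_path))
}

# two-sided Fisher exact p by explicit enumeration over all feasible tables
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  ks <- max(0, k - n):min(k, m)
  probs <- vapply(ks, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  p_obs <- probs[match(a, ks)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact Wilcoxon rank-sum p by explicit split enumeration
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  ew <- n1 * (length(r) + 1) / 2
  splits <- utils::combn(length(r), n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# random small HMM instance for oracle comparisons
random_small_hmm <- function(K, M) {
  emission <- matrix(runif(K * M, 0.1, 0.9), K, M)
  transition <- matrix(runif(K * K, 0.1, 1), K, K)
  transition <- transition / rowSums(transition)
  initial <- runif(K, 0.1, 1)
  initial <- initial / sum(initial)
  chromatin_hmm(emission, transition, initial,
                paste0("m", seq_len(M)))
}

random_obs <- function(T_, M) {
  matrix(rbinom(T_ * M, 1, 0.5), T_, M,
         dimnames = list(NULL, paste0("m", seq_len(M))))
}

# wrap a single observation matrix as a one-chromosome BinaryMatrix
obs_as_binary_matrix <- function(obs, bin_width = 200L) {
  layout <- genome_layout("chr1", nrow(obs) * bin_width, "A")
  binarized <- lapply(seq_len(ncol(obs)), function(m) list(chr1 = obs[, m]))
  names(binarized) <- colnames(obs)
  binary_matrix(binarized, layout, bin_width)
}

tiny_layout <- function(len = 10000, n = 1) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n),
                rep(c("A", "D"), length.out = n))
}

# constant-count track helper
track_from_counts <- function(counts, layout, bin_width = 200L, ...) {
  binned_track(counts, layout, bin_width, ...)
}
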