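#' Binarize a ChIP track against its control
#'
#' ChromHMM-style presence/absence call per 200-bp bin: the expected rate in
#' bin i is the control count scaled to ChIP depth, floored at the global
#' ChIP mean; the bin is called 1 when the Poisson upper tail
#' \code{P(X >= c | lambda)} is at most \code{p_threshold}.
#'
#' @param chip a [binned_track()] (replicates pooled beforehand, see
#'   [pool_tracks()]).
#' @param control matching Mock [binned_track()], or \code{NULL} to use the
#'   global ChIP mean alone.
#' @param p_threshold Poisson tail threshold (default \code{1e-4}).
#' @return named list of per-chromosome integer 0/1 vectors.
#' @export
binarize <- function(chip, control = NULL, p_threshold = 1e-4) {
  if (!is.null(control)) check_same_layout(chip, control)
  chip_tot <- total_fragments(chip)
  nbins_tot <- sum(vapply(chip$counts, length, numeric(1)))
  global_mean <- chip_tot / nbins_tot
  ctrl_tot <- if (is.null(control)) 0 else total_fragments(control)
  scale <- if (ctrl_tot > 0) chip_tot / ctrl_tot else 0
  out <- lapply(chip$layout$chrom, function(ch) {
    cc <- chip$counts[[ch]]
    if (any(cc < 0)) stop("negative counts in chip track")
    lambda <- if (!is.null(control) && ctrl_tot > 0) {
      pmax(control$counts[[ch]] * scale, global_mean)
    } else rep(global_mean, length(cc))
    p <- stats::ppois(cc - 1, lambda, lower.tail = FALSE)
    as.integer(p <= p_threshold)
  })
  names(out) <- chip$layout$chrom
  out
}

#' Multi-mark binary observation matrix
#'
#' Stacks binarized tracks for M marks into per-chromosome T x M 0/1
#' matrices — the observation sequences for the chromatin-state HMM.
#'
#' @param binarized named list (one element per mark, in the desired mark
#'   order) of [binarize()] outputs.
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bases (default 200).
#' @return A \code{BinaryMatrix} object.
#' @export
binary_matrix <- function(binarized, layout, bin_width = 200L) {
  marks <- names(binarized)
  if (is.null(marks) || any(marks == "")) stop("binarized must be a named list")
  nb <- n_bins(layout, bin_width)
  bins <- lapply(layout$chrom, function(ch) {
    m <- do.call(cbind, lapply(binarized, function(b) b[[ch]]))
    if (nrow(m) != nb[[ch]]) stop("bin count mismatch on ", ch)
    if (!all(m %in% c(0L, 1L))) stop("entries must be 0/1")
    colnames(m) <- marks
    m
  })
  names(bins) <- layout$chrom
  structure(list(marks = marks, bins = bins,
                 bin_width = as.integer(bin_width), layout = layout),
            class = "BinaryMatrix")
}

#' @export
print.BinaryMatrix <- function(x, ...) {
  cat(sprintf("BinaryMatrix: %d marks (%s), %d bins @ %d bp\n",
              length(x$marks), paste(x$marks, collapse = ", "),
              sum(vapply(x$bins, nrow, numeric(1))), x$bin_width))
  invisible(x)
}

#' Chromatin-state hidden Markov model
#'
#' A K-state multivariate HMM with independent Bernoulli emissions per mark:
#' in state k, mark m is observed (binarized 1) with probability
#' \code{emission[k, m]} — the "enrichment probability" displayed in
#' emission heatmaps.
#'
#' @param emission K x M matrix of Bernoulli success probabilities in [0,1];
#'   column names are the mark labels.
#' @param transition K x K row-stochastic matrix.
#' @param initial length-K probability vector.
#' @param marks mark labels (defaults to \code{colnames(emission)}).
#' @return A \code{ChromatinHMM} object.
#' @export
chromatin_hmm <- function(emission, transition, initial, marks = NULL) {
  emission <- as.matrix(emission)
  transition <- as.matrix(transition)
  K <- nrow(emission)
  if (is.null(marks)) marks <- colnames(emission)
  if (is.null(marks)) marks <- paste0("mark", seq_len(ncol(emission)))
  if (any(emission < 0 | emission > 1)) stop("emission entries must be in [0,1]")
  if (nrow(transition) != K || ncol(transition) != K) {
    stop("transition must be K x K")
  }
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  if (length(initial) != K || abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a length-K probability vector")
  }
  dimnames(emission) <- list(paste0("S", seq_len(K)), marks)
  dimnames(transition) <- list(paste0("S", seq_len(K)), paste0("S", seq_len(K)))
  structure(list(K = K, marks = marks, emission = emission,
                 transition = transition, initial = as.numeric(initial)),
            class = "ChromatinHMM")
}

#' @export
print.ChromatinHMM <- function(x, ...) {
  cat(sprintf("ChromatinHMM: %d states x %d marks\nEmission probabilities:\n",
              x$K, length(x$marks)))
  print(round(x$emission, 3))
  invisible(x)
}

# per-chromosome T x K log emission probability matrices
emission_logprob <- function(model, data) {
  logp <- log(pmax(model$emission, 1e-300))
  log1mp <- log(pmax(1 - model$emission, 1e-300))
  lapply(data$bins, function(o) {
    o %*% t(logp) + (1 - o) %*% t(log1mp)
  })
}

#' Log-likelihood of binarized data under a chromatin-state HMM
#'
#' Scaled forward algorithm; chromosomes are independent sequences, each
#' started from the model's initial distribution.
#'
#' @param model a [chromatin_hmm()].
#' @param data a [binary_matrix()] with the model's marks.
#' @return total log-likelihood.
#' @export
log_likelihood <- function(model, data) {
  if (!identical(model$marks, data$marks)) {
    stop("model and data mark sets differ")
  }
  logB <- emission_logprob(model, data)
  sum(vapply(logB, hmm_forward_loglik_cpp, numeric(1),
             init = model$initial, trans = model$transition))
}

random_hmm_init <- function(K, M, marks) {
  emission <- matrix(stats::runif(K * M, 0.05, 0.95), K, M)
  transition <- matrix(stats::rgamma(K * K, shape = 1) +
                         diag(K) * K, K, K)
  transition <- transition / rowSums(transition)
  initial <- stats::rgamma(K, shape = 1)
  initial <- initial / sum(initial)
  chromatin_hmm(emission, transition, initial, marks)
}

#' Fit a chromatin-state HMM by Baum-Welch EM
#'
#' Expectation-maximisation with the scaled forward-backward E-step and
#' closed-form M-step. Within a restart the log-likelihood is non-decreasing
#' at every iteration; the best of \code{n_restarts} random initialisations
#' (seed-derived substreams, fully deterministic given \code{seed}) is
#' returned. Emission probabilities are floored at \code{1e-6} (and capped at
#' \code{1 - 1e-6}) to avoid degenerate zeros.
#'
#' @param data a [binary_matrix()].
#' @param K number of chromatin states (default 6).
#' @param n_restarts random restarts (default 10).
#' @param seed RNG seed.
#' @param tol convergence threshold on the log-likelihood improvement
#'   (default \code{1e-4}).
#' @param max_iter maximum EM iterations per restart (default 200).
#' @param init optional [chromatin_hmm()] used as the single starting point
#'   (overrides restarts).
#' @return the best-likelihood [chromatin_hmm()], with attributes
#'   \code{loglik} (final log-likelihood) and \code{loglik_trace} (list of
#'   per-restart log-likelihood sequences).
#' @export
baum_welch <- function(data, K = 6L, n_restarts = 10L, seed = 1L,
                       tol = 1e-4, max_iter = 200L, init = NULL) {
  total_bins <- sum(vapply(data$bins, nrow, numeric(1)))
  if (K < 1) stop("K must be >= 1")
  if (K > total_bins) stop("K exceeds the number of bins")
  M <- length(data$marks)
  obs <- data$bins
  best <- NULL
  best_ll <- -Inf
  traces <- vector("list", n_restarts)
  if (!is.null(init)) n_restarts <- 1L
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    model <- if (!is.null(init)) init else random_hmm_init(K, M, data$marks)
    trace <- numeric(0)
    ll_prev <- -Inf
    for (iter in seq_len(max_iter)) {
      logB <- emission_logprob(model, data)
      e <- lapply(logB, hmm_forward_backward_cpp,
                  init = model$initial, trans = model$transition)
      ll <- sum(vapply(e, `[[`, numeric(1), "loglik"))
      trace <- c(trace, ll)
      # M-step
      gamma0 <- Reduce(`+`, lapply(e, function(x) x$gamma[1, ]))
      xi <- Reduce(`+`, lapply(e, `[[`, "xi_sum"))
      gsum <- Reduce(`+`, lapply(e, function(x) colSums(x$gamma)))
      gobs <- Reduce(`+`, Map(function(x, o) t(x$gamma) %*% o, e, obs))
      emission <- gobs / gsum
      emission <- pmin(pmax(emission, 1e-6), 1 - 1e-6)
      rs <- rowSums(xi)
      transition <- xi / ifelse(rs > 0, rs, 1)
      transition[rs == 0, ] <- 1 / K
      transition <- transition / rowSums(transition)
      initial <- gamma0 / sum(gamma0)
      model <- chromatin_hmm(emission, transition, initial, data$marks)
      if (is.finite(ll_prev) && ll - ll_prev < tol) break
      ll_prev <- ll
    }
    ll_final <- log_likelihood(model, data)
    traces[[r]] <- c(trace, ll_final)
    if (ll_final > best_ll) {
      best_ll <- ll_final
      best <- model
    }
  }
  attr(best, "loglik") <- best_ll
  attr(best, "loglik_trace") <- traces
  best
}

#' Decode a genome segmentation from a fitted model
#'
#' Viterbi (joint MAP path) or posterior (per-bin marginal argmax) decoding
#' of each chromosome, producing a segmentation that labels every bin with
#' exactly one state.
#'
#' @param model a [chromatin_hmm()].
#' @param data a [binary_matrix()].
#' @param method \code{"viterbi"} (default) or \code{"posterior"}.
#' @return A \code{Segmentation}: list with per-chromosome integer state
#'   vectors (\code{states}), \code{K}, \code{bin_width}, \code{layout}.
#' @export
decode <- function(model, data, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  if (!identical(model$marks, data$marks)) stop("mark sets differ")
  logB <- emission_logprob(model, data)
  states <- if (method == "viterbi") {
    log_init <- log(pmax(model$initial, 1e-300))
    log_trans <- log(pmax(model$transition, 1e-300))
    lapply(logB, hmm_viterbi_cpp, log_init = log_init, log_trans = log_trans)
  } else {
    lapply(logB, function(lb) {
      e <- hmm_forward_backward_cpp(lb, model$initial, model$transition)
      max.col(e$gamma, ties.method = "first")
    })
  }
  names(states) <- names(data$bins)
  structure(list(states = states, K = model$K, bin_width = data$bin_width,
                 layout = data$layout),
            class = "Segmentation")
}

#' @export
print.Segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d states over %d bins @ %d bp\n", x$K,
              sum(vapply(x$states, length, numeric(1))), x$bin_width))
  invisible(x)
}

#' Merge a segmentation into state intervals
#'
#' Maximal runs of equal state become one interval; intervals partition the
#' genome exactly (the terminal interval is clamped to the chromosome
#' length).
#'
#' @param seg a \code{Segmentation} from [decode()].
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{state}
#'   (labels \code{"S1"}..\code{"SK"}).
#' @export
state_intervals <- function(seg) {
  bw <- seg$bin_width
  parts <- lapply(names(seg$states), function(ch) {
    r <- rle(seg$states[[ch]])
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    data.frame(chrom = ch, start = starts_bin * bw,
               end = pmin(ends_bin * bw, chrom_length(seg$layout, ch)),
               state = paste0("S", r$values), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Canonically relabel HMM states
#'
#' EM state indices are arbitrary; this orders states by lexicographic
#' descending sort of their emission vectors under \code{signature_order}
#' (ties broken by original index) and applies the permutation consistently
#' to the model and, optionally, a segmentation. Idempotent.
#'
#' @param model a [chromatin_hmm()].
#' @param seg optional \code{Segmentation} to relabel alongside.
#' @param signature_order mark labels defining sort priority (default: the
#'   model's mark order).
#' @return \code{list(model, seg)} with canonical state ids.
#' @export
relabel_states <- function(model, seg = NULL, signature_order = NULL) {
  if (is.null(signature_order)) signature_order <- model$marks
  em <- model$emission[, signature_order, drop = FALSE]
  keys <- c(lapply(seq_len(ncol(em)), function(j) -em[, j]),
            list(seq_len(model$K)))
  perm <- do.call(order, keys)  # perm[new] = old
  new_model <- chromatin_hmm(model$emission[perm, , drop = FALSE],
                             model$transition[perm, perm, drop = FALSE],
                             model$initial[perm], model$marks)
  new_seg <- seg
  if (!is.null(seg)) {
    inv <- integer(model$K)
    inv[perm] <- seq_len(model$K)  # old -> new
    new_seg$states <- lapply(seg$states, function(s) inv[s])
  }
  list(model = new_model, seg = new_seg)
}

#' Match learned states to a reference emission matrix
#'
#' Greedy minimal total-variation assignment of each learned state to a
#' reference state (used to compare independently trained models, or to map
#' learned states onto planted simulation states).
#'
#' @param model a [chromatin_hmm()].
#' @param reference_emission K x M reference emission matrix (same marks).
#' @return integer vector \code{map} such that learned state k corresponds
#'   to reference state \code{map[k]}.
#' @export
match_states <- function(model, reference_emission) {
  K <- model$K
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    cost[i, j] <- sum(abs(model$emission[i, ] - reference_emission[j, ])) / 2
  }
  map <- integer(K)
  used <- logical(K)
  for (step in seq_len(K)) {
    c2 <- cost
    c2[map != 0, ] <- Inf
    c2[, used] <- Inf
    idx <- arrayInd(which.min(c2), dim(c2))
    map[idx[1]] <- idx[2]
    used[idx[2]] <- TRUE
  }
  map
}

#' Genome coverage of each chromatin state
#'
#' Bases and genome fraction per state, for the whole genome and (optionally)
#' per subgenome; fractions sum to 1 within each scope.
#'
#' @param seg a \code{Segmentation}.
#' @param layout a [genome_layout()] (defaults to the segmentation's own).
#' @param by_subgenome also break coverage down by A/D subgenome.
#' @return data.frame \code{scope}, \code{state}, \code{bases},
#'   \code{fraction}.
#' @export
state_coverage <- function(seg, layout = NULL, by_subgenome = FALSE) {
  if (is.null(layout)) layout <- seg$layout
  iv <- state_intervals(seg)
  iv$width <- iv$end - iv$start
  scopes <- list(genome = layout$chrom)
  if (by_subgenome) {
    scopes$A <- layout$chrom[layout$subgenome == "A"]
    scopes$D <- layout$chrom[layout$subgenome == "D"]
  }
  states <- paste0("S", seq_len(seg$K))
  out <- do.call(rbind, lapply(names(scopes), function(sc) {
    sel <- iv[iv$chrom %in% scopes[[sc]], ]
    bases <- vapply(states, function(s) sum(sel$width[sel$state == s]),
                    numeric(1))
    data.frame(scope = sc, state = states, bases = bases,
               fraction = bases / sum(bases), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a chromatin-state model as JSON
#'
#' @param model a [chromatin_hmm()].
#' @param path JSON path.
#' @return \code{path} / the model.
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(list(K = model$K, marks = model$marks,
                            emission = model$emission,
                            transition = model$transition,
                            initial = model$initial),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chromatin_hmm(x$emission, x$transition, x$initial, x$marks)
}

#' Write a segmentation as a dense BED
#'
#' @param seg a \code{Segmentation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_segmentation_bed <- function(seg, path) {
  iv <- state_intervals(seg)
  iv$name <- iv$state
  write_bed(iv, path)
}

#' Write / read ChromHMM-style binary mark files
#'
#' One text file per chromosome: a header line \code{<genome>\t<chrom>}, a
#' line of mark names, then tab-separated 0/1 rows (one per bin).
#'
#' @param data a [binary_matrix()].
#' @param dir output directory.
#' @param genome genome label for the header (default "genome").
#' @return vector of written paths.
#' @export
write_binary_files <- function(data, dir, genome = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(names(data$bins), function(ch) {
    path <- file.path(dir, paste0(genome, "_", ch, "_binary.txt"))
    con <- file(path, "w")
    writeLines(c(paste(genome, ch, sep = "\t"),
                 paste(data$marks, collapse = "\t")), con)
    utils::write.table(data$bins[[ch]], con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    close(con)
    path
  }, character(1))
}

#' @rdname write_binary_files
#' @param paths files written by [write_binary_files()], in layout order.
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bases (default 200).
#' @export
read_binary_files <- function(paths, layout, bin_width = 200L) {
  per_chrom <- list()
  marks <- NULL
  for (p in paths) {
    hdr <- readLines(p, n = 2)
    ch <- strsplit(hdr[1], "\t")[[1]][2]
    marks <- strsplit(hdr[2], "\t")[[1]]
    m <- as.matrix(data.table::fread(p, skip = 2, header = FALSE))
    colnames(m) <- marks
    per_chrom[[ch]] <- m
  }
  binarized <- lapply(setNames(marks, marks), function(mk) {
    lapply(per_chrom, function(m) as.integer(m[, mk]))
  })
  binary_matrix(binarized, layout, bin_width)
}
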