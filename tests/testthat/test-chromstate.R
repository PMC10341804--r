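test_that("binarize applies the Poisson upper-tail rule", {
  # 20 bins with mean exactly 1 and no control: lambda = 1 everywhere
  counts <- c(10L, 3L, rep(1L, 7), rep(0L, 11))
  lay <- genome_layout("chr1", 20 * 200, "A")
  chip <- binned_track(list(chr1 = counts), lay, 200)
  stopifnot(mean(counts) == 1)
  b <- binarize(chip, control = NULL, p_threshold = 1e-4)$chr1
  expect_equal(b[1], 1L)  # P(X >= 10 | 1) ~ 1.1e-7 <= 1e-4
  expect_equal(b[2], 0L)  # P(X >= 3 | 1) ~ 0.080 > 1e-4
  expect_true(all(b[counts == 0] == 0L))  # P(X >= 0) = 1
})

test_that("forward log-likelihood matches closed form and path enumeration", {
  # K = 1, single mark with p = 0.5: loglik = T * log(0.5)
  m1 <- chromatin_hmm(matrix(0.5, 1, 1), matrix(1, 1, 1), 1, "m1")
  obs <- random_obs(40, 1)
  expect_equal(log_likelihood(m1, obs_as_binary_matrix(obs)),
               40 * log(0.5))

  set.seed(11)
  for (i in 1:25) {
    K <- sample(2:3, 1); M <- sample(1:2, 1); T_ <- sample(2:8, 1)
    model <- random_small_hmm(K, M)
    obs <- random_obs(T_, M)
    expect_equal(log_likelihood(model, obs_as_binary_matrix(obs)),
                 brute_loglik(model, obs), tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant to state relabelling", {
  set.seed(4)
  model <- random_small_hmm(3, 2)
  obs <- random_obs(30, 2)
  perm <- c(3, 1, 2)
  permuted <- chromatin_hmm(model$emission[perm, ],
                            model$transition[perm, perm],
                            model$initial[perm], model$marks)
  bm <- obs_as_binary_matrix(obs)
  expect_equal(log_likelihood(model, bm), log_likelihood(permuted, bm))
})

test_that("Viterbi decoding matches exhaustive-path argmax", {
  set.seed(21)
  for (i in 1:25) {
    K <- sample(2:3, 1); M <- sample(1:2, 1); T_ <- sample(2:8, 1)
    model <- random_small_hmm(K, M)
    obs <- random_obs(T_, M)
    seg <- decode(model, obs_as_binary_matrix(obs), method = "viterbi")
    expect_equal(seg$states$chr1, brute_viterbi(model, obs)$path)
  }
})

test_that("posterior and Viterbi agree under near-deterministic emissions", {
  em <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2, byrow = TRUE)
  tr <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  model <- chromatin_hmm(em, tr, c(0.5, 0.5), c("m1", "m2"))
  sim <- simulate_binary_from_hmm(model, genome_layout("chr1", 4e4, "A"),
                                  200, seed = 9)
  v <- decode(model, sim$data, "viterbi")
  p <- decode(model, sim$data, "posterior")
  expect_equal(v$states$chr1, p$states$chr1)
  expect_equal(v$states$chr1, sim$states$chr1)  # separation recovers truth
})

test_that("decode with K = 1 labels every bin state 1 and partitions", {
  m1 <- chromatin_hmm(matrix(0.3, 1, 1), matrix(1, 1, 1), 1, "m1")
  bm <- obs_as_binary_matrix(random_obs(17, 1))
  seg <- decode(m1, bm)
  expect_true(all(seg$states$chr1 == 1))
  iv <- state_intervals(seg)
  expect_equal(sum(iv$end - iv$start), sum(bm$layout$length))
})

test_that("Baum-Welch log-likelihood is monotone and seed-deterministic", {
  set.seed(5)
  truth <- chromatin_hmm(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
                         matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE),
                         c(0.5, 0.5), c("m1", "m2"))
  sim <- simulate_binary_from_hmm(truth, genome_layout("chr1", 3e5, "A"),
                                  200, seed = 2)
  fit <- baum_welch(sim$data, K = 2, n_restarts = 4, seed = 10,
                    max_iter = 50)
  for (trace in attr(fit, "loglik_trace")) {
    expect_true(all(diff(trace) > -1e-6))
  }
  fit2 <- baum_welch(sim$data, K = 2, n_restarts = 4, seed = 10,
                     max_iter = 50)
  a1 <- fit; a2 <- fit2
  attributes(a1) <- attributes(a2) <- NULL
  expect_identical(a1, a2)
})

test_that("Baum-Welch recovers a planted 2-state model", {
  truth <- chromatin_hmm(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
                         matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE),
                         c(0.5, 0.5), c("m1", "m2"))
  sim <- simulate_binary_from_hmm(truth, genome_layout("chr1", 1e7, "A"),
                                  200, seed = 2)  # 50k bins
  fit <- baum_welch(sim$data, K = 2, n_restarts = 3, seed = 1)
  map <- match_states(fit, truth$emission)
  expect_lt(max(abs(fit$emission[order(map), ] - truth$emission)), 0.05)
})

test_that("EM started at a deterministic-emission truth is a fixed point", {
  em <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  tr <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  truth <- chromatin_hmm(em, tr, c(0.5, 0.5), c("m1", "m2"))
  sim <- simulate_binary_from_hmm(truth, genome_layout("chr1", 2e6, "A"),
                                  200, seed = 6)
  start <- chromatin_hmm(pmin(pmax(em, 1e-6), 1 - 1e-6), tr, c(0.5, 0.5),
                         c("m1", "m2"))
  fit <- baum_welch(sim$data, K = 2, max_iter = 1, init = start, seed = 1)
  expect_equal(fit$emission, start$emission, tolerance = 1e-3)
  expect_equal(fit$transition, start$transition, tolerance = 2e-2)
})

test_that("relabel_states sorts canonically, idempotently, symmetrically", {
  em <- rbind(c(0.2, 0.9), c(0.9, 0.1), c(0.2, 0.3))
  colnames(em) <- c("m1", "m2")
  tr <- matrix(1 / 3, 3, 3)
  model <- chromatin_hmm(em, tr, rep(1 / 3, 3))
  rel <- relabel_states(model)$model
  # hand sort: descending by m1 then m2 -> rows 2, 1, 3
  expect_equal(unname(rel$emission), unname(em[c(2, 1, 3), ]))
  expect_equal(relabel_states(rel)$model$emission, rel$emission)
  perm <- c(2, 3, 1)
  swapped <- chromatin_hmm(em[perm, ], tr[perm, perm], rep(1 / 3, 3)[perm],
                           c("m1", "m2"))
  expect_equal(relabel_states(swapped)$model$emission, rel$emission)
})

test_that("relabel_states remaps segmentations consistently", {
  em <- rbind(c(0.1, 0.1), c(0.9, 0.9))
  colnames(em) <- c("m1", "m2")
  model <- chromatin_hmm(em, matrix(0.5, 2, 2), c(0.5, 0.5))
  bm <- obs_as_binary_matrix(random_obs(10, 2))
  seg <- decode(model, bm)
  rel <- relabel_states(model, seg)
  # state 2 (high emissions) becomes S1 after relabelling
  expect_equal(rel$seg$states$chr1, 3L - seg$states$chr1)
})

test_that("state_coverage fractions partition to one, also by subgenome", {
  lay <- genome_layout(c("a1", "d1"), c(2000, 2000), c("A", "D"))
  seg <- structure(list(states = list(a1 = rep(1:2, 5), d1 = rep(2L, 10)),
                        K = 2, bin_width = 200L, layout = lay),
                   class = "Segmentation")
  cov <- state_coverage(seg, by_subgenome = TRUE)
  for (sc in unique(cov$scope)) {
    expect_equal(sum(cov$fraction[cov$scope == sc]), 1, tolerance = 1e-9)
  }
  expect_equal(cov$fraction[cov$scope == "A"], c(0.5, 0.5))
  expect_equal(cov$fraction[cov$scope == "D"], c(0, 1))
})

test_that("model JSON and segmentation BED round-trip", {
  tmp <- withr::local_tempdir()
  set.seed(8)
  model <- random_small_hmm(3, 2)
  path <- file.path(tmp, "model.json")
  write_hmm_json(model, path)
  back <- read_hmm_json(path)
  expect_equal(back$emission, model$emission)
  expect_equal(back$transition, model$transition)
  expect_equal(back$initial, model$initial)
})
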