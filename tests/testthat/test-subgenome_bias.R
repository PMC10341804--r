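hit_row <- function(q, t, e = 1e-20, cov = 90, id = 80) {
  data.frame(query_id = q, target_id = t, e_value = e, coverage = cov,
             identity = id, stringsAsFactors = FALSE)
}

test_that("reciprocal_best_hits traces pairs, uniques and the remainder", {
  ad <- rbind(hit_row("A1", "D1"),
              hit_row("A2", "D1", e = 1e-10, cov = 60, id = 55),
              hit_row("A3", "D2", cov = 30))
  da <- rbind(hit_row("D1", "A1"),
              hit_row("D2", "A1", e = 1e-8, cov = 70, id = 60))
  rbh <- reciprocal_best_hits(ad, da, a_genes = c("A1", "A2", "A3"),
                              d_genes = c("D1", "D2"))
  expect_equal(rbh$pairs, data.frame(a_gene = "A1", d_gene = "D1"))
  # A2's best is D1 but D1's best is A1; A2 still has a passing hit -> other
  expect_true("A2" %in% rbh$a_other)
  # A3's only hit has 30% coverage -> subgenome-unique
  expect_equal(rbh$a_unique, "A3")
  # D2's best hit passes but is non-reciprocal -> other
  expect_equal(rbh$d_other, "D2")
})

test_that("reciprocal_best_hits is symmetric in the subgenome roles", {
  set.seed(41)
  a <- paste0("A", 1:12); d <- paste0("D", 1:12)
  ad <- hit_row(a, sample(d), e = 10^runif(12, -40, -8),
                cov = runif(12, 40, 100), id = runif(12, 40, 100))
  da <- hit_row(d, sample(a), e = 10^runif(12, -40, -8),
                cov = runif(12, 40, 100), id = runif(12, 40, 100))
  fwd <- reciprocal_best_hits(ad, da, a_genes = a, d_genes = d)
  rev <- reciprocal_best_hits(da, ad, a_genes = d, d_genes = a)
  expect_equal(sort(paste(fwd$pairs$a_gene, fwd$pairs$d_gene)),
               sort(paste(rev$pairs$d_gene, rev$pairs$a_gene)))
  expect_equal(sort(fwd$a_unique), sort(rev$d_unique))
  expect_equal(sort(fwd$d_unique), sort(rev$a_unique))
})

test_that("duplicate hit rows are deduplicated with a warning", {
  ad <- rbind(hit_row("A1", "D1", e = 1e-30),
              hit_row("A1", "D1", e = 1e-10))
  da <- hit_row("D1", "A1")
  expect_warning(rbh <- reciprocal_best_hits(ad, da, a_genes = "A1",
                                             d_genes = "D1"),
                 "duplicate")
  expect_equal(nrow(rbh$pairs), 1)
})

test_that("categorize_bias flags planted directional pairs and summarises", {
  set.seed(6)
  n <- 60
  a <- paste0("A", seq_len(n)); d <- paste0("D", seq_len(n))
  rbh <- list(pairs = data.frame(a_gene = a, d_gene = d,
                                 stringsAsFactors = FALSE))
  mu <- rep(300, n)
  cnt <- rbind(
    matrix(rnbinom(3 * n, mu = c(rep(3000, 10), rep(300, n - 10)),
                   size = 50), n, 3, dimnames = list(a, NULL)),
    matrix(rnbinom(3 * n, mu = mu, size = 50), n, 3,
           dimnames = list(d, NULL)))
  colnames(cnt) <- paste0("rep", 1:3)
  bias <- categorize_bias(rbh, cnt)
  expect_true(all(bias$category[1:10] == "A>D"))
  s <- attr(bias, "summary")
  expect_equal(s$n_a_gt + s$n_a_lt + s$n_balanced, n)
  # worked example on published pair counts
  expect_equal(round(bias_summary(2879, 3114, 26340)$biased_percent, 1),
               22.8)
})

test_that("mark_level_compare reports group means and Wilcoxon p-values", {
  sig <- matrix(c(1:6, 6:1), 6, 2,
                dimnames = list(paste0("g", 1:6), c("mk1", "mk2")))
  groups <- list(lo = paste0("g", 1:3), hi = paste0("g", 4:6))
  mc <- mark_level_compare(sig, groups)
  expect_equal(mc$means["lo", "mk1"], 2)
  expect_equal(mc$means["hi", "mk1"], 5)
  expect_equal(mc$tests$p_value[mc$tests$mark == "mk1"], 0.1)
  expect_equal(mc$tests$p_value[mc$tests$mark == "mk2"], 0.1)
  expect_error(mark_level_compare(sig, list(a = character(0), b = "g1")),
               "non-empty")
})

test_that("kmeans_gene_clusters recovers planted blobs deterministically", {
  set.seed(13)
  x <- rbind(matrix(rnorm(60 * 3, mean = 0), 60, 3),
             matrix(rnorm(40 * 3, mean = 8), 40, 3))
  rownames(x) <- paste0("g", 1:100)
  colnames(x) <- paste0("mk", 1:3)
  cl <- kmeans_gene_clusters(x, k = 2, seed = 7)
  # labels ordered by size: C1 = the 60-gene blob
  expect_equal(unname(cl$labels[1:60]), rep(1L, 60))
  expect_equal(unname(cl$labels[61:100]), rep(2L, 40))
  cl2 <- kmeans_gene_clusters(x, k = 2, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  # k = 1: centroid is the column means
  c1 <- kmeans_gene_clusters(x, k = 1, seed = 7)
  expect_equal(unname(c1$centers["C1", ]), unname(colMeans(x)))
  expect_error(kmeans_gene_clusters(x[1:3, ], k = 5), "exceeds")
})

test_that("newgene_cluster_enrichment matches hypergeometric tails", {
  labels <- setNames(rep(1:2, c(30, 30)), paste0("g", 1:60))
  new_genes <- paste0("g", 1:10)  # all new genes in cluster 1
  enr <- newgene_cluster_enrichment(labels, new_genes)
  tab <- matrix(c(10, 0, 20, 30), 2, 2, byrow = TRUE)
  expect_equal(enr$p_value[enr$cluster == "C1"], enum_fisher_p(tab),
               tolerance = 1e-10)
  expect_equal(enr$new_fraction[enr$cluster == "C1"], 1)
  expect_equal(enr$background_fraction[enr$cluster == "C1"], 0.5)
  # proportional allocation shows no enrichment
  prop <- setNames(rep(1:2, 30), paste0("g", 1:60))
  enr2 <- newgene_cluster_enrichment(prop, paste0("g", 1:10))
  expect_true(all(enr2$p_value > 0.5))
  expect_error(newgene_cluster_enrichment(labels, character(0)), "non-empty")
})

test_that("gene_signal_matrix averages gene-body bins per mark", {
  lay <- genome_layout("chr1", 2000, "A")
  sig <- list(chr1 = as.numeric(1:10))
  attr(sig, "bin_width") <- 200L
  attr(sig, "layout") <- lay
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(0, 800), end = c(400, 1400), strand = "+")
  m <- gene_signal_matrix(list(mk = sig), genes)
  expect_equal(unname(m["g1", "mk"]), mean(1:2))
  expect_equal(unname(m["g2", "mk"]), mean(5:7))
})
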