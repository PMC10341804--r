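test_that("bin_fragments assigns by midpoint and conserves counts", {
  lay <- genome_layout("chr1", 1000, "A")
  t1 <- bin_fragments(data.frame(chrom = "chr1", start = 0, end = 100),
                      lay, 200)
  expect_equal(t1$counts$chr1, c(1L, 0L, 0L, 0L, 0L))

  # fragment [190,410) has midpoint 300, which lies in bin [200,400)
  t2 <- bin_fragments(data.frame(chrom = "chr1", start = 190, end = 410),
                      lay, 200)
  expect_equal(t2$counts$chr1, c(0L, 1L, 0L, 0L, 0L))

  set.seed(7)
  lay2 <- tiny_layout(1e5, 2)
  st <- floor(runif(10000, 0, 99000))
  fr <- data.frame(chrom = sample(lay2$chrom, 10000, TRUE),
                   start = st, end = st + sample(50:500, 10000, TRUE))
  tr <- bin_fragments(fr, lay2, 200)
  expect_equal(sum(unlist(tr$counts)), 10000)

  expect_error(
    bin_fragments(data.frame(chrom = "chr1", start = 900, end = 1100),
                  lay, 200),
    "outside layout")
})

test_that("rpkm_normalize follows the RPKM formula and scaling laws", {
  lay <- genome_layout("chr1", 100, "A")
  tr <- binned_track(list(chr1 = c(1L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)),
                     lay, 10)
  v <- rpkm_normalize(tr, total_fragments = 1e6)
  expect_equal(v$chr1[1], 100)   # 1 * 1e9 / (1e6 * 10)
  expect_equal(v$chr1[2], 0)
  v2 <- rpkm_normalize(tr, total_fragments = 2e6)
  expect_equal(unlist(v2), unlist(v) / 2, ignore_attr = TRUE)
  expect_error(rpkm_normalize(tr, total_fragments = 0), "> 0")
})

test_that("rpkm_normalize commutes with chromosome concatenation", {
  lay2 <- tiny_layout(2000, 2)
  cnt <- list(chr1 = c(3L, 0L, 1L, 5L, 0L, 0L, 2L, 0L, 0L, 1L),
              chr2 = c(0L, 7L, 0L, 0L, 2L, 0L, 0L, 0L, 4L, 0L))
  tr <- binned_track(cnt, lay2, 200)
  joint <- rpkm_normalize(tr, 1e5)
  lay1 <- genome_layout("chr1", 4000, "A")
  tr1 <- binned_track(list(chr1 = c(cnt$chr1, cnt$chr2)), lay1, 200)
  expect_equal(unname(c(joint$chr1, joint$chr2)),
               unname(rpkm_normalize(tr1, 1e5)$chr1))
})

test_that("replicate_correlation is textbook Pearson", {
  lay <- genome_layout("chr1", 600, "A")
  mk <- function(v) binned_track(list(chr1 = as.integer(v)), lay, 200)
  expect_equal(replicate_correlation(mk(c(1, 2, 3)), mk(c(1, 2, 3))), 1)
  expect_equal(replicate_correlation(mk(c(1, 2, 3)), mk(c(3, 2, 1))), -1)
  lay4 <- genome_layout("chr1", 800, "A")
  mk4 <- function(v) binned_track(list(chr1 = as.integer(v)), lay4, 200)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(replicate_correlation(mk4(x), mk4(y)), r_hand)
  expect_error(replicate_correlation(mk(c(2, 2, 2)), mk(c(1, 2, 3))),
               "zero variance")
})

test_that("metagene_profile is strand-aware and averages correctly", {
  lay <- genome_layout("chr1", 10000, "A")
  bw <- 100L
  sig <- list(chr1 = rep(2, 100))
  attr(sig, "bin_width") <- bw; attr(sig, "layout") <- lay

  g <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000, end = 6000,
                  strand = "+")
  prof <- metagene_profile(sig, g, flank = 1000, n_points = 21)
  expect_equal(unname(prof), rep(2, 21), ignore_attr = TRUE)

  # + gene with spike one bin downstream of TSS vs - gene with the mirror
  # spike: identical profiles after orientation
  spike_plus <- sig; spike_plus$chr1 <- rep(0, 100)
  spike_plus$chr1[52] <- 5    # TSS 5000 -> bin 51; +100 -> bin 52
  gp <- data.frame(gene_id = "p", chrom = "chr1", start = 5000, end = 6000,
                   strand = "+")
  spike_minus <- sig; spike_minus$chr1 <- rep(0, 100)
  spike_minus$chr1[50] <- 5   # TSS 5999 -> bin 60 ... spike upstream in + coords
  gm <- data.frame(gene_id = "m", chrom = "chr1", start = 4000, end = 5000,
                   strand = "-")
  # - gene TSS = 4999 (bin 50); one bin downstream in gene orientation is
  # bin 49 (coordinate-decreasing)
  spike_minus$chr1 <- rep(0, 100); spike_minus$chr1[49] <- 5
  pp <- metagene_profile(spike_plus, gp, flank = 500, n_points = 11)
  pm <- metagene_profile(spike_minus, gm, flank = 500, n_points = 11)
  expect_equal(unname(pp), unname(pm))

  # two + genes with spikes at TSS+0 and TSS+2 bins -> mean 0.5 at both
  s2 <- sig; s2$chr1 <- rep(0, 100)
  s2$chr1[11] <- 1   # TSS 1000 of g1 -> bin 11
  s2$chr1[33] <- 1   # TSS 3000 of g2 -> bin 31; +2 bins -> bin 33
  gg <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(1000, 3000), end = c(2000, 4000), strand = "+")
  p2 <- metagene_profile(s2, gg, flank = 500, n_points = 11)
  off <- attr(p2, "offsets")
  expect_equal(unname(p2[off == 0]), 0.5)
  expect_equal(unname(p2[off == 200]), 0.5)
  # order invariance
  p2r <- metagene_profile(s2, gg[2:1, ], flank = 500, n_points = 11)
  expect_equal(unname(p2), unname(p2r))
})

test_that("BED, GFF3, bedGraph and binary files round-trip", {
  tmp <- withr::local_tempdir()
  lay <- tiny_layout(4000, 2)
  iv <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 600L),
                   end = c(400L, 1200L), name = c("a", "b"),
                   score = c(1, 2), strand = c("+", "-"))
  bed <- file.path(tmp, "x.bed")
  write_bed(iv, bed)
  back <- read_bed(bed)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$strand, iv$strand)

  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
                      start = c(1000L, 500L), end = c(2000L, 1500L),
                      strand = c("+", "-"), subgenome = c("A", "D"),
                      is_new_gene = c(TRUE, FALSE))
  exons <- data.frame(gene_id = c("gA", "gA", "gB"), chrom = c("chr1", "chr1", "chr2"),
                      start = c(1000L, 1600L, 500L), end = c(1400L, 2000L, 1500L))
  gff <- file.path(tmp, "g.gff3")
  write_gff3_genes(genes, exons, gff)
  gm <- read_gff3_genes(gff)
  expect_equal(gm$genes[order(gm$genes$gene_id), ]$start, genes$start)
  expect_equal(gm$genes$is_new_gene[match(c("gA", "gB"), gm$genes$gene_id)],
               c(TRUE, FALSE))
  expect_equal(nrow(gm$exons), 3)
  expect_equal(sort(gm$exons$start), sort(exons$start))

  tr <- binned_track(list(chr1 = as.integer(c(1, 0, 3, 0, 0, 0, 0, 2, 0, 0,
                                              0, 0, 0, 0, 0, 0, 0, 0, 0, 1)),
                          chr2 = integer(20)), lay, 200)
  sig <- rpkm_normalize(tr, 100)
  bg <- file.path(tmp, "x.bedGraph")
  write_bedgraph(sig, bg)
  sig2 <- read_bedgraph(bg, lay, 200)
  expect_equal(sig2$chr1, sig$chr1)

  bm <- obs_as_binary_matrix(random_obs(25, 3))
  paths <- write_binary_files(bm, file.path(tmp, "bin"))
  bm2 <- read_binary_files(paths, bm$layout, bm$bin_width)
  expect_equal(bm2$bins, bm$bins, ignore_attr = TRUE)
})
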