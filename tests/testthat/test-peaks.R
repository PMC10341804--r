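make_track <- function(counts, lay, mark = "H3K4me3") {
  binned_track(list(chr1 = as.integer(counts)), lay, 200, mark = mark)
}

test_that("call_broad_peaks finds Poisson-enriched runs and merges by gap", {
  lay <- genome_layout("chr1", 20 * 200, "A")
  base <- rep(1L, 20)
  ctrl <- make_track(base, lay, "Mock")

  expect_equal(nrow(call_broad_peaks(make_track(base, lay), ctrl)), 0)

  # one bin at 50 vs lambda 1: P(X >= 50 | 1) << 1e-10 and ratio 50 > 5
  spike <- base; spike[5] <- 50L
  pk <- call_broad_peaks(make_track(spike, lay), ctrl)
  # control is rescaled to chip depth so lambda ~= (sum chip)/(sum ctrl) > 1;
  # the call survives because the tail is still astronomically small
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 800)
  expect_equal(pk$end, 1000)
  expect_lt(pk$p_value, 1e-10)

  two <- base; two[c(5, 7)] <- 50L
  expect_equal(nrow(call_broad_peaks(make_track(two, lay), ctrl,
                                     merge_gap = 0)), 2)
  merged <- call_broad_peaks(make_track(two, lay), ctrl, merge_gap = 200)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(800, 1400))
})

test_that("consensus_peaks keeps rep1 peaks supported by rep2, union-widened", {
  p <- function(chrom, start, end, pv = 1e-20, fc = 10)
    data.frame(chrom = chrom, start = start, end = end, mark = "H3K4me3",
               p_value = pv, fold_change = fc, stringsAsFactors = FALSE)
  a <- p("chr1", 0, 100)
  b <- p("chr1", 50, 150)
  cons <- consensus_peaks(a, b)
  expect_equal(c(cons$start, cons$end), c(0, 150))
  same <- rbind(p("chr1", 0, 100), p("chr1", 500, 700))
  expect_equal(consensus_peaks(same, same)[, c("start", "end")],
               same[, c("start", "end")])
  expect_equal(nrow(consensus_peaks(a, a[0, ])), 0)
  # every output peak overlaps both replicates
  set.seed(3)
  r1 <- p("chr1", seq(0, 9000, 1000), seq(0, 9000, 1000) + 300)
  r2 <- p("chr1", seq(150, 9150, 1500), seq(150, 9150, 1500) + 400)
  out <- consensus_peaks(r1, r2)
  for (i in seq_len(nrow(out))) {
    ov1 <- any(pmin(out$end[i], r1$end) - pmax(out$start[i], r1$start) > 0)
    ov2 <- any(pmin(out$end[i], r2$end) - pmax(out$start[i], r2$start) > 0)
    expect_true(ov1 && ov2)
  }
})

test_that("peak_overlap_fraction uses the at-least-50%-of-bases rule", {
  p <- function(start, end) data.frame(chrom = "chr1", start = start,
                                       end = end)
  expect_equal(peak_overlap_fraction(p(0, 100), p(50, 150)), 1)   # exactly 50%
  expect_equal(peak_overlap_fraction(p(0, 100), p(60, 150)), 0)   # 40%
  expect_equal(peak_overlap_fraction(p(0, 100), p(0, 100)), 1)
  expect_error(peak_overlap_fraction(p(0, 100)[0, ], p(0, 100)), "empty")
  # coverage accumulates across several B peaks
  expect_equal(peak_overlap_fraction(p(0, 100),
                                     rbind(p(0, 30), p(60, 90))), 1)
})

test_that("genome_coverage collapses overlaps and reports the union", {
  lay <- genome_layout("chr1", 1000, "A")
  p1 <- data.frame(chrom = "chr1", start = 0, end = 100)
  cov1 <- genome_coverage(list(m1 = p1), lay)
  expect_equal(cov1$bases, c(100, 100))
  expect_equal(cov1$fraction, c(0.1, 0.1))
  p2 <- data.frame(chrom = "chr1", start = 50, end = 150)
  cov2 <- genome_coverage(list(m1 = p1, m2 = p2), lay)
  expect_equal(cov2$bases[cov2$set == "union"], 150)
  expect_lte(cov2$bases[cov2$set == "union"],
             sum(cov2$bases[cov2$set != "union"]))
  # order invariance of the union
  cov2r <- genome_coverage(list(m2 = p2, m1 = p1), lay)
  expect_equal(cov2$bases[cov2$set == "union"],
               cov2r$bases[cov2r$set == "union"])
  expect_equal(genome_coverage(list(m1 = p1[0, ]), lay)$bases, c(0, 0))
})

test_that("annotate_by_midpoint partitions peaks with gene > TE precedence", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 120, end = 400,
                      strand = "+")
  tes <- data.frame(chrom = "chr1", start = 100, end = 300)
  pk <- data.frame(chrom = "chr1",
                   start = c(100, 90, 600), end = c(200, 110, 700),
                   mark = "x", p_value = 1e-12, fold_change = 6)
  ann <- annotate_by_midpoint(pk, genes, tes)
  expect_equal(ann$category, c("genic", "TE", "intergenic"))
  expect_equal(sum(table(ann$category)), nrow(pk))
})

test_that("broadPeak-style files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".broadPeak")
  pk <- data.frame(chrom = "chr1", start = c(0L, 800L), end = c(400L, 1000L),
                   mark = "H3K27me3", p_value = c(1e-20, 1e-12),
                   fold_change = c(8.5, 6))
  write_broadpeak(pk, tmp)
  back <- read_broadpeak(tmp)
  expect_equal(back$start, pk$start)
  expect_equal(back$p_value, pk$p_value, tolerance = 1e-12)
  expect_equal(back$fold_change, pk$fold_change)
})
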