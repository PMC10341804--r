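test_that("build_element_map partitions the genome with stated precedence", {
  lay <- genome_layout("chr1", 2000, "A")
  # + strand gene, TSS 1000, single exon = body
  g <- data.frame(gene_id = "g", chrom = "chr1", start = 1000, end = 1600,
                  strand = "+")
  em <- build_element_map(g, NULL, lay)
  get <- function(el) em[em$element == el, c("start", "end")]
  expect_equal(unlist(get("promoter"), use.names = FALSE), c(500, 1000))
  expect_equal(unlist(get("exon"), use.names = FALSE), c(1000, 1600))
  expect_equal(sum(em$end - em$start), 2000)

  # - strand gene body [0,1000): promoter [1000,1500)
  gm <- data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 1000,
                   strand = "-")
  emm <- build_element_map(gm, NULL, lay)
  expect_equal(unlist(emm[emm$element == "promoter", c("start", "end")],
                      use.names = FALSE), c(1000, 1500))

  # TSS at 300: promoter clamps to [0,300)
  g3 <- data.frame(gene_id = "g", chrom = "chr1", start = 300, end = 900,
                   strand = "+")
  em3 <- build_element_map(g3, NULL, lay)
  expect_equal(unlist(em3[em3$element == "promoter", c("start", "end")],
                      use.names = FALSE), c(0, 300))

  # introns are gene body minus exons minus promoter-claimed bases
  g4 <- data.frame(gene_id = "g", chrom = "chr1", start = 1000, end = 1600,
                   strand = "+")
  ex4 <- data.frame(gene_id = "g", chrom = "chr1",
                    start = c(1000, 1400), end = c(1200, 1600))
  em4 <- build_element_map(g4, ex4, lay)
  expect_equal(unlist(em4[em4$element == "intron", c("start", "end")],
                      use.names = FALSE), c(1200, 1400))
  expect_equal(sum(em4$end - em4$start), 2000)
})

test_that("element map partitions on a busy synthetic genome", {
  cfg <- simulation_config(seed = 3, n_chroms = c(A = 1L, D = 1L),
                           chrom_length = c(A = 2e5, D = 1e5),
                           n_genes = c(A = 80L, D = 40L), n_tes = 60L)
  gen <- simulate_genome(cfg)
  em <- build_element_map(gen$genes, gen$exons, gen$layout)
  expect_equal(sum(em$end - em$start), sum(gen$layout$length))
  # no overlaps within the map
  by_ch <- split(em, em$chrom)
  for (d in by_ch) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("state_by_element marginals and normalizations are consistent", {
  lay <- genome_layout("chr1", 3000, "A")
  g <- data.frame(gene_id = "g", chrom = "chr1", start = 1000, end = 1600,
                  strand = "+")
  em <- build_element_map(g, NULL, lay)
  # S3 exactly covers the promoter [500,1000), S1 the rest (bins of 100)
  sv <- rep(1L, 30); sv[6:10] <- 3L
  seg <- structure(list(states = list(chr1 = sv), K = 3, bin_width = 100L,
                        layout = lay), class = "Segmentation")
  se <- state_by_element(seg, em)
  expect_equal(se$by_element["S3", "promoter"], 1)
  expect_equal(sum(se$bases), 3000)
  # row marginals equal state coverage, column marginals element totals
  cov <- state_coverage(seg)
  expect_equal(unname(rowSums(se$bases)),
               cov$bases[cov$scope == "genome"])
  expect_equal(unname(colSums(se$bases)),
               unname(vapply(c("promoter", "exon", "intron", "intergenic"),
                             function(e) sum(em$end[em$element == e] -
                                               em$start[em$element == e]),
                             numeric(1))))
  # normalized views sum to 1 over every state/element actually present
  used_state <- rowSums(se$bases) > 0
  expect_equal(unname(rowSums(se$by_state)[c(used_state, TRUE)]),
               rep(1, sum(used_state) + 1))  # + Background row
  nonzero <- colSums(se$bases) > 0  # the toy genome has no intron bases
  expect_equal(unname(colSums(se$by_element)[nonzero]),
               rep(1, sum(nonzero)))
  # single-state segmentation: element mix equals the Background row
  seg1 <- structure(list(states = list(chr1 = rep(1L, 30)), K = 1,
                         bin_width = 100L, layout = lay),
                    class = "Segmentation")
  se1 <- state_by_element(seg1, em)
  expect_equal(unname(se1$by_state["S1", ]),
               unname(se1$by_state["Background", ]))
})

test_that("state_by_te splits counts by midpoint and bases by overlap", {
  lay <- genome_layout("chr1", 1000, "A")
  sv <- c(rep(1L, 4), rep(2L, 6))  # S1 on [0,400), S2 on [400,1000)
  seg <- structure(list(states = list(chr1 = sv), K = 2, bin_width = 100L,
                        layout = lay), class = "Segmentation")
  tes <- data.frame(chrom = "chr1", start = 0, end = 100,
                    te_class = "Gypsy")
  st <- state_by_te(seg, tes)
  expect_equal(st$te_counts["S1", "Gypsy"], 1)
  expect_equal(st$bases["S1", "Gypsy"], 100)

  # TE [360,460): midpoint 410 -> S2 count; bases split 40/60
  tes2 <- data.frame(chrom = "chr1", start = 360, end = 460,
                     te_class = "Copia")
  st2 <- state_by_te(seg, tes2)
  expect_equal(st2$te_counts["S2", "Copia"], 1)
  expect_equal(st2$te_counts["S1", "Copia"], 0)
  expect_equal(st2$bases["S1", "Copia"], 40)
  expect_equal(st2$bases["S2", "Copia"], 60)

  empty <- state_by_te(seg, tes[0, ])
  expect_true(all(empty$te_counts == 0))
})
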