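one_call <- function() {
  data.frame(chrom = "chrT", start_a = 25000, end_a = 50000,
             start_b = 150000, end_b = 175000, score = 0.4,
             distance = 125000)
}

test_that("intersect_pairs pairs features across the two anchors", {
  snp <- data.frame(chrom = "chrT", start = 30100, end = 30101, name = "rs1")
  prom <- data.frame(chrom = "chrT", start = 160000, end = 161000,
                     name = "GENE1")
  hits <- intersect_pairs(one_call(), snp, prom)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$left_features, "rs1")
  expect_equal(hits$right_features, "GENE1")
  expect_equal(hits$orientation, "left_a")

  # both features in the same bin with no spanning call: no hit
  prom_same <- data.frame(chrom = "chrT", start = 30500, end = 31000,
                          name = "G2")
  expect_equal(nrow(intersect_pairs(one_call(), snp, prom_same)), 0L)

  # different chromosome: no hit
  snp_chr <- data.frame(chrom = "chr9", start = 30100, end = 30101,
                        name = "rs2")
  expect_equal(nrow(intersect_pairs(one_call(), snp_chr, prom)), 0L)
})

test_that("intersect_pairs is symmetric under swapping left/right", {
  set.seed(17)
  calls <- data.frame(chrom = "chrT",
                      start_a = c(0, 50000), end_a = c(25000, 75000),
                      start_b = c(100000, 200000), end_b = c(125000, 225000),
                      score = 0.3, distance = c(100000, 150000))
  a <- data.frame(chrom = "chrT", start = c(5000, 210000),
                  end = c(5500, 210500), name = c("A1", "A2"))
  b <- data.frame(chrom = "chrT", start = c(110000, 60000),
                  end = c(110400, 60400), name = c("B1", "B2"))
  h1 <- intersect_pairs(calls, a, b)
  h2 <- intersect_pairs(calls, b, a)
  expect_equal(nrow(h1), nrow(h2))
  expect_setequal(paste(h1$start_a, h1$start_b),
                  paste(h2$start_a, h2$start_b))
})

test_that("long_range_hits filters by distance and stays a subset", {
  hits <- data.frame(distance = c(600001, 400000, 500000))
  lr <- long_range_hits(hits)
  expect_equal(lr$distance, 600001)
  expect_equal(nrow(long_range_hits(hits[0, , drop = FALSE])), 0L)
  expect_true(all(lr$distance %in% hits$distance))
})

test_that("promoter_connectivity counts anchor overlaps per gene", {
  prom <- data.frame(chrom = "chrT", start = 26000, end = 27000,
                     name = "G1")
  calls <- rbind(one_call(), one_call(), one_call())
  expect_equal(unname(promoter_connectivity(calls, prom)["G1"]), 3L)
  expect_equal(unname(promoter_connectivity(calls[0, ], prom)["G1"]), 0L)

  # relative connectivity across two cell types
  two <- promoter_connectivity(list(ct1 = rbind(calls, one_call()),
                                    ct2 = calls[1:2, ]), prom)
  expect_equal(unname(two$counts["G1", ]), c(4L, 2L))
  expect_equal(unname(two$relative["G1", ]), c(1, -1))

  dup <- rbind(prom, data.frame(chrom = "chrT", start = 160500, end = 160900,
                                name = "G1"))
  expect_warning(cc <- promoter_connectivity(calls, dup), "duplicate")
  expect_equal(unname(cc["G1"]), 6L)   # both promoters merged
})

test_that("two-proportion z-test matches the pooled-proportion hand formula", {
  # 30/100 vs 10/100: pooled p = 0.2, se = sqrt(0.2*0.8*(2/100))
  r <- enrichment_two_proportion(30, 100, 10, 100)
  se <- sqrt(0.2 * 0.8 * (1 / 100 + 1 / 100))
  expect_equal(r$z, (0.3 - 0.1) / se, tolerance = 1e-12)
  expect_equal(r$z, 3.5355339, tolerance = 1e-6)
  expect_lt(r$p, 0.001)
  expect_equal(r$enrichment, 3)

  eq <- enrichment_two_proportion(10, 50, 20, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$enrichment, 1)

  expect_warning(s <- enrichment_two_proportion(100, 100, 0, 100),
                 "undefined")
  expect_true(is.na(s$enrichment))
  expect_true(is.finite(s$z))

  expect_error(enrichment_two_proportion(5, 0, 1, 10), "positive")
  expect_error(enrichment_two_proportion(11, 10, 1, 10), "exceed")
})

test_that("bh_adjust returns raw p alongside BH q-values", {
  p <- c(0.001, 0.02, 0.04, 0.8)
  out <- bh_adjust(p)
  expect_equal(out$p, p)
  expect_equal(out$q, p.adjust(p, "BH"))
  expect_true(all(out$q >= out$p))
})
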