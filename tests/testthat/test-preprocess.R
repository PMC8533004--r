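test_that("bin_genome tiles chromosomes and truncates the last bin", {
  b <- bin_genome(c(chrT = 100000), bin_size = 25000)
  expect_equal(nrow(b), 4L)
  expect_equal(b$start, c(0, 25000, 50000, 75000))
  expect_equal(b$end, c(25000, 50000, 75000, 100000))
  expect_equal(b$index, 0:3)

  b2 <- bin_genome(c(chrT = 60000), bin_size = 25000)
  expect_equal(nrow(b2), 3L)
  expect_equal(b2$end[3], 60000)
  expect_equal(b2$end[3] - b2$start[3], 10000)

  # default bin size is 25 kbp
  expect_equal(formals(bin_genome)$bin_size, 25000L)

  # multiple chromosomes, data.frame input
  b3 <- bin_genome(data.frame(chrom = c("a", "b"), len = c(50000, 25000)),
                   bin_size = 25000)
  expect_equal(table(b3$chrom)[["a"]], 2L)

  expect_error(bin_genome(c(chrT = 1000), bin_size = 0), "positive")
  expect_error(bin_genome(c(chrT = -5), bin_size = 100), "positive")
})

test_that("merge_peaks_into_bins sums counts by midpoint bin", {
  bins <- bin_genome(c(chrT = 125000), 25000)
  # two peaks in bin 3 (index 3: [75000,100000)), counts 3 and 5
  peaks <- data.frame(chrom = "chrT",
                      start = c(76000, 90000, 10000),
                      end   = c(76500, 90500, 10500))
  counts <- matrix(c(3, 5, 2), nrow = 1)
  m <- merge_peaks_into_bins(counts, peaks, bins)
  expect_equal(ncol(m$counts), 2L)          # empty bins dropped
  expect_equal(m$bins$index, c(0L, 3L))     # genomic order
  expect_equal(unname(m$counts[1, ]), c(2, 8))

  # one peak per bin: identity on occupied bins
  peaks1 <- data.frame(chrom = "chrT", start = c(1000, 30000),
                       end = c(1400, 30400))
  c1 <- matrix(c(7, 9), nrow = 1)
  m1 <- merge_peaks_into_bins(c1, peaks1, bins)
  expect_equal(unname(m1$counts[1, ]), c(7, 9))

  # midpoint rule at the boundary: midpoint 24999 -> bin 0
  pk <- data.frame(chrom = "chrT", start = 24749, end = 25250) # mid 24999
  mb <- merge_peaks_into_bins(matrix(1, 1, 1), pk, bins)
  expect_equal(mb$bins$index, 0L)
  # midpoint 25000 -> bin 1
  pk2 <- data.frame(chrom = "chrT", start = 24750, end = 25251)
  mb2 <- merge_peaks_into_bins(matrix(1, 1, 1), pk2, bins)
  expect_equal(mb2$bins$index, 1L)

  # peak on unknown chromosome: warning + skip
  pk3 <- rbind(peaks, data.frame(chrom = "chrX", start = 0, end = 100))
  expect_warning(
    m3 <- merge_peaks_into_bins(cbind(counts, 4), pk3, bins),
    "skipping 1 peak")
  expect_equal(sum(m3$counts), sum(counts))

  expect_error(merge_peaks_into_bins(matrix(-1, 1, 1),
                                     peaks[1, ], bins), "non-negative")
})

test_that("merge conserves reads and commutes with peak reordering", {
  set.seed(11)
  bins <- bin_genome(c(chrT = 250000), 25000)
  n_pk <- 12
  peaks <- data.frame(chrom = "chrT",
                      start = sort(sample(0:249000, n_pk)))
  peaks$end <- peaks$start + 800
  counts <- matrix(rpois(5 * n_pk, 3), nrow = 5)
  m <- merge_peaks_into_bins(counts, peaks, bins)
  expect_equal(rowSums(m$counts), rowSums(counts))  # conservation per cell

  perm <- sample(n_pk)
  m2 <- merge_peaks_into_bins(counts[, perm], peaks[perm, ], bins)
  expect_equal(log_transform(m2$counts), log_transform(m$counts),
               ignore_attr = TRUE)
})

test_that("log_transform is natural log1p, monotone, rejects negatives", {
  expect_equal(log_transform(matrix(0))[1, 1], 0)
  expect_equal(log_transform(matrix(1))[1, 1], log(2))
  expect_equal(log_transform(matrix(exp(1) - 1))[1, 1], 1)
  x <- matrix(c(0, 1, 5, 50), 2)
  expect_true(all(diff(sort(log_transform(x))) > 0))
  expect_error(log_transform(matrix(-0.5)), "non-negative")
})

test_that("preprocess_chromosome restricts to one chromosome", {
  bins <- bin_genome(c(A = 50000, B = 50000), 25000)
  peaks <- data.frame(chrom = c("A", "A", "B"),
                      start = c(1000, 30000, 2000),
                      end = c(1500, 30500, 2500))
  counts <- matrix(c(1, 2, 3), nrow = 1)
  bm <- preprocess_chromosome(counts, peaks, bins, "A")
  expect_s3_class(bm, "binned_matrix")
  expect_equal(ncol(bm$values), 2L)
  expect_equal(bm$chrom, "A")
  expect_equal(bm$values[1, ], log1p(c(1, 2)), ignore_attr = TRUE)
})

test_that("read_peak_matrix handles dense TSV and matrix-market input", {
  dir <- withr::local_tempdir()
  mat <- matrix(c(0, 2, 1, 3), 2, 2)
  peaks <- data.frame(chrom = "chrT", start = c(100, 30100),
                      end = c(600, 30600))
  nm <- sprintf("chrT:%d-%d", peaks$start, peaks$end)
  df <- data.frame(cell = c("c1", "c2"), mat)
  names(df)[2:3] <- nm
  p_tsv <- file.path(dir, "m.tsv")
  data.table::fwrite(df, p_tsv, sep = "\t")
  got <- read_peak_matrix(p_tsv)
  expect_equal(unname(got$counts), mat)
  expect_equal(got$peaks$start, peaks$start)

  p_mtx <- file.path(dir, "m.mtx")
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), p_mtx)
  p_bed <- file.path(dir, "p.bed")
  write.table(peaks, p_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  got2 <- read_peak_matrix(p_mtx, peaks_bed = p_bed)
  expect_equal(unname(got2$counts), mat)

  # peaks-as-rows orientation
  p_t <- file.path(dir, "t.tsv")
  data.table::fwrite(data.frame(peak = nm, t(mat)), p_t, sep = "\t")
  got3 <- read_peak_matrix(p_t, peaks_bed = p_bed, peaks_as = "rows")
  expect_equal(unname(got3$counts), mat)
})
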