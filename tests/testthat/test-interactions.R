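toy_fit <- function(pcor) {
  structure(list(pcor = pcor, theta = pcor), class = "precision_fit")
}

toy_bins <- function(n, bin_size = 25000) {
  data.frame(chrom = "chrT", start = (0:(n - 1)) * bin_size,
             end = (1:n) * bin_size, index = 0:(n - 1))
}

test_that("call_interactions thresholds and orders deterministically", {
  pc <- diag(8)
  expect_equal(nrow(call_interactions(toy_fit(pc), toy_bins(8))), 0L)

  pc[2, 7] <- pc[7, 2] <- 0.4
  calls <- call_interactions(toy_fit(pc), toy_bins(8), min_abs_score = 0.1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$distance, 5 * 25000)
  expect_equal(calls$score, 0.4)

  expect_equal(nrow(call_interactions(toy_fit(pc), toy_bins(8),
                                      min_abs_score = 0.5)), 0L)
})

test_that("sign modes and distance cap", {
  pc <- diag(6)
  pc[1, 2] <- pc[2, 1] <- 0.3
  pc[1, 6] <- pc[6, 1] <- -0.4
  pos <- call_interactions(toy_fit(pc), toy_bins(6))
  expect_equal(nrow(pos), 1L)
  expect_true(all(pos$score > 0))
  both <- call_interactions(toy_fit(pc), toy_bins(6), sign_mode = "both")
  expect_equal(nrow(both), 2L)
  expect_setequal(both$score, c(0.3, -0.4))
  capped <- call_interactions(toy_fit(pc), toy_bins(6), sign_mode = "both",
                              max_distance = 100000)
  expect_equal(nrow(capped), 1L)
})

test_that("raising the threshold never adds calls; no self/duplicate pairs", {
  set.seed(15)
  p <- 10
  pc <- matrix(runif(p * p, -1, 1), p); pc <- (pc + t(pc)) / 2; diag(pc) <- 1
  counts <- sapply(seq(0, 0.9, by = 0.15), function(th)
    nrow(call_interactions(toy_fit(pc), toy_bins(p), min_abs_score = th,
                           sign_mode = "both")))
  expect_true(all(diff(counts) <= 0))
  calls <- call_interactions(toy_fit(pc), toy_bins(p), sign_mode = "both")
  expect_true(all(calls$start_a < calls$start_b))
  expect_false(anyDuplicated(paste(calls$start_a, calls$start_b)) > 0)
})

test_that("distance_stratified_counts partitions calls", {
  calls <- data.frame(distance = c(1e5, 6e5, 9e5))
  ct <- distance_stratified_counts(calls, boundaries = 5e5)
  expect_equal(unname(as.integer(ct)), c(1L, 2L))

  expect_equal(sum(distance_stratified_counts(calls[0, , drop = FALSE])), 0L)

  ct4 <- distance_stratified_counts(calls, boundaries = c(2.5e5, 5e5, 1e6))
  expect_equal(length(ct4), 4L)
  expect_equal(sum(ct4), nrow(calls))
  expect_error(distance_stratified_counts(calls, boundaries = c(5e5, 5e5)),
               "increasing")
})

test_that("BEDPE write/read round trip is exact", {
  pc <- diag(8)
  pc[1, 7] <- pc[7, 1] <- 0.42
  pc[2, 4] <- pc[4, 2] <- -0.137
  calls <- call_interactions(toy_fit(pc), toy_bins(8), sign_mode = "both")
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(calls, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "#"))
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_length(fields, 10L)
  expect_equal(fields[c(1, 2, 3, 4, 5, 6)],
               c("chrT", "0", "25000", "chrT", "150000", "175000"))
  expect_equal(fields[9:10], c(".", "."))

  back <- read_bedpe(path)
  expect_equal(back$start_a, calls$start_a)
  expect_equal(back$score, calls$score)       # exact: 17 sig digits
  expect_equal(back$distance, calls$distance)
})

test_that("empty calls produce header-only files", {
  empty <- call_interactions(toy_fit(diag(4)), toy_bins(4))
  p1 <- tempfile(); p2 <- tempfile()
  write_bedpe(empty, p1)
  expect_length(readLines(p1), 1L)
  write_ucsc_track(empty, p2)
  l2 <- readLines(p2)
  expect_length(l2, 1L)
  expect_match(l2[1], "^track type=interact")
  expect_equal(nrow(read_bedpe(p1)), 0L)
})

test_that("UCSC track rescales |score| to 0-1000", {
  pc <- diag(5); pc[1, 3] <- pc[3, 1] <- 0.42
  calls <- call_interactions(toy_fit(pc), toy_bins(5))
  p <- tempfile()
  write_ucsc_track(calls, p, track_name = "t")
  row <- strsplit(readLines(p)[2], "\t")[[1]]
  expect_equal(as.integer(row[5]), 420L)
  expect_equal(as.numeric(row[6]), 0.42)
})
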