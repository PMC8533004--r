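#' Define a synthetic benchmark scenario
#'
#' Describes a single-chromosome world with planted ground truth: a sparse
#' positive-definite precision matrix over genomic bins (a mix of short- and
#' long-range edges), single cells sampled from the implied covariance with
#' dropout, and a noisy Hi-C-like prior correlated with the planted edges.
#' Defaults are the standard benchmark: 200 bins of 25 kbp, 400 cells, 100
#' edges of which 30% span more than 500 kbp, 30% dropout, prior fidelity
#' 0.8 with 50 noise pairs.
#'
#' @param n_bins,n_cells,bin_size,chrom world geometry.
#' @param n_edges number of planted precision edges.
#' @param short_long_mix fraction of planted edges with genomic distance
#'   greater than 500 kbp.
#' @param dropout_rate probability that an observed count is zeroed.
#' @param prior_fidelity probability that a planted edge appears enriched in
#'   the synthetic Hi-C prior.
#' @param noise_edges number of non-planted pairs enriched in the prior.
#' @param seed integer seed; every generator below is deterministic given it.
#' @return list of class `scenario`.
#' @export
make_scenario <- function(n_bins = 200L, n_cells = 400L, bin_size = 25000L,
                          chrom = "chrS", n_edges = 100L,
                          short_long_mix = 0.3, dropout_rate = 0.3,
                          prior_fidelity = 0.8, noise_edges = 50L,
                          seed = 1L) {
  stopifnot(short_long_mix >= 0, short_long_mix <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            prior_fidelity >= 0, prior_fidelity <= 1)
  structure(list(n_bins = as.integer(n_bins), n_cells = as.integer(n_cells),
                 bin_size = as.integer(bin_size), chrom = chrom,
                 n_edges = as.integer(n_edges), short_long_mix = short_long_mix,
                 dropout_rate = dropout_rate, prior_fidelity = prior_fidelity,
                 noise_edges = as.integer(noise_edges), seed = as.integer(seed)),
            class = "scenario")
}

#' Planted sparse precision matrix
#'
#' Builds a symmetric positive-definite precision matrix whose off-diagonal
#' nonzeros sit exactly at the planted edges. Edge weights are negative
#' (negative precision entries give positive partial correlations, the
#' co-accessibility sign); positive definiteness is enforced by diagonal
#' dominance, and if planted magnitudes still break it the off-diagonal is
#' rescaled with a warning.
#'
#' @param scenario a `scenario`.
#' @return list: `theta` (n_bins x n_bins), `edges` (data.frame `i`, `j`,
#'   1-based, i < j, with `distance` in bp), `pcor_true`.
#' @export
make_precision <- function(scenario) {
  set.seed(scenario$seed)
  p <- scenario$n_bins
  long_gap <- ceiling(5e5 / scenario$bin_size)   # > 500 kbp in bins
  n_long <- round(scenario$n_edges * scenario$short_long_mix)
  n_short <- scenario$n_edges - n_long

  pick_pairs <- function(n, gap_min, gap_max, taken) {
    out <- matrix(integer(), 0, 2)
    guard <- 0L
    while (nrow(out) < n && guard < 50000L) {
      guard <- guard + 1L
      gap <- sample(seq(gap_min, gap_max), 1L)
      i <- sample(seq_len(p - gap), 1L)
      key <- paste(i, i + gap)
      if (!key %in% taken) {
        out <- rbind(out, c(i, i + gap))
        taken <- c(taken, key)
      }
    }
    list(pairs = out, taken = taken)
  }
  sh <- pick_pairs(n_short, 1L, min(long_gap, p - 1L), character())
  lo <- pick_pairs(n_long, min(long_gap + 1L, p - 1L), p - 1L, sh$taken)
  edges <- rbind(sh$pairs, lo$pairs)
  theta <- diag(p)
  if (nrow(edges)) {
    w <- -runif(nrow(edges), 0.15, 0.35)
    theta[edges] <- w
    theta[edges[, c(2, 1), drop = FALSE]] <- w
    # diagonal dominance with margin keeps it PD and pcors moderate
    diag(theta) <- 0.05 + 1 + (rowSums(abs(theta)) - 1)
  }
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    warnf("planted magnitudes break positive definiteness; rescaling")
    off <- theta; diag(off) <- 0
    theta <- diag(diag(theta)) + 0.5 * off
  }
  edges_df <- data.frame(i = pmin(edges[, 1], edges[, 2]),
                         j = pmax(edges[, 1], edges[, 2]))
  edges_df <- edges_df[order(edges_df$i, edges_df$j), , drop = FALSE]
  rownames(edges_df) <- NULL
  edges_df$distance <- (edges_df$j - edges_df$i) * scenario$bin_size
  list(theta = theta, edges = edges_df,
       pcor_true = partial_correlations(theta))
}

#' Sample single-cell counts from a planted precision matrix
#'
#' Latent accessibility vectors are zero-mean Gaussian with covariance
#' `solve(precision)`; they are mapped to counts by
#' `max(0, round(exp(mu + z) - 1))` with a fixed location `mu` on the log
#' scale (default 2), so the log1p transform of the counts approximately
#' recovers `mu + z` and hence the latent covariance. Dropout then zeroes
#' entries independently.
#'
#' @param precision positive-definite matrix.
#' @param n_cells number of cells (rows).
#' @param dropout_rate probability in \[0,1\].
#' @param seed integer seed.
#' @param mu latent log-scale mean (default 2).
#' @return n_cells x n_bins integer count matrix.
#' @export
sample_cells <- function(precision, n_cells, dropout_rate = 0, seed = 1L,
                         mu = 2) {
  set.seed(seed)
  p <- nrow(precision)
  sigma <- solve(precision)
  ch <- chol(0.5 * (sigma + t(sigma)))
  z <- matrix(rnorm(n_cells * p), n_cells, p) %*% ch
  counts <- pmax(round(exp(mu + z) - 1), 0)
  if (dropout_rate > 0) {
    drop <- matrix(runif(n_cells * p) < dropout_rate, n_cells, p)
    counts[drop] <- 0
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Synthetic Hi-C-like prior correlated with the planted edges
#'
#' Each planted edge appears as an enriched contact with probability
#' `prior_fidelity`; `noise_edges` random non-planted pairs are enriched
#' too. Enrichment values are lognormal around 10 (a typical enriched
#' contact count at 25 kbp). The map is written in the juicer-dump
#' three-column dialect so it round-trips through [load_contact_text()].
#'
#' @param edges data.frame `i`, `j` (1-based bins) of planted edges.
#' @param n_bins number of bins in the world.
#' @param prior_fidelity,noise_edges see [make_scenario()].
#' @param seed integer seed.
#' @param path output text file; a tempfile by default.
#' @param resolution bin width bp. @param chrom chromosome name.
#' @return list: `path`, `map` (the `contact_map`), `kept` (logical per
#'   planted edge: present in the prior).
#' @export
make_prior <- function(edges, n_bins, prior_fidelity = 0.8, noise_edges = 50L,
                       seed = 1L, path = tempfile(fileext = ".txt"),
                       resolution = 25000L, chrom = "chrS") {
  set.seed(seed + 1L)
  kept <- runif(nrow(edges)) < prior_fidelity
  ei <- edges$i[kept]; ej <- edges$j[kept]
  planted_key <- paste(edges$i, edges$j)
  ni <- nj <- integer(0)
  guard <- 0L
  while (length(ni) < noise_edges && guard < 50000L) {
    guard <- guard + 1L
    a <- sample.int(n_bins, 1L); b <- sample.int(n_bins, 1L)
    if (a == b) next
    i <- min(a, b); j <- max(a, b)
    if (paste(i, j) %in% c(planted_key, paste(ni, nj))) next
    ni <- c(ni, i); nj <- c(nj, j)
  }
  i <- c(ei, ni); j <- c(ej, nj)
  value <- exp(rnorm(length(i), log(10), 0.25))
  # 0-based starts in the dump
  lines <- sprintf("%d\t%d\t%.17g", (i - 1L) * resolution,
                   (j - 1L) * resolution, value)
  writeLines(lines, path)
  map <- contact_map(chrom, resolution,
                     data.frame(i = i - 1L, j = j - 1L, value = value))
  list(path = path, map = map, kept = kept)
}

#' Generate a complete synthetic input set on disk
#'
#' Materializes a scenario as the files the pipeline consumes: a cells x
#' peaks count matrix (TSV, peak names `chr:start-end` in the header), a
#' peak BED, a chrom.sizes file and a Hi-C-like prior dump. Each bin's
#' counts are split across one or two peaks inside the bin, so peak merging
#' is exercised and reconstructs the bin totals exactly.
#'
#' @param scenario a `scenario`.
#' @param dir output directory (created if needed).
#' @return list with file `paths` (matrix, peaks, chrom_sizes, prior) and
#'   the `truth` (`theta`, `edges`, `pcor_true`, `counts`, `prior_kept`).
#' @export
simulate_scenario <- function(scenario, dir = tempfile("scenario")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- make_precision(scenario)
  counts <- sample_cells(pr$theta, scenario$n_cells, scenario$dropout_rate,
                         seed = scenario$seed)
  prior <- make_prior(pr$edges, scenario$n_bins, scenario$prior_fidelity,
                      scenario$noise_edges, seed = scenario$seed,
                      path = file.path(dir, "prior.txt"),
                      resolution = scenario$bin_size, chrom = scenario$chrom)
  bs <- scenario$bin_size
  set.seed(scenario$seed + 2L)
  # split each bin into 1-2 peaks; peak midpoints stay inside the bin
  peak_rows <- list(); cols <- list()
  for (b in seq_len(scenario$n_bins)) {
    start <- (b - 1L) * bs
    n_pk <- sample(1:2, 1L)
    if (n_pk == 1L) {
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(chrom = scenario$chrom, start = start + bs %/% 4L,
                   end = start + bs %/% 4L + 500L)
      cols[[length(cols) + 1L]] <- counts[, b]
    } else {
      split <- rbinom(scenario$n_cells, counts[, b], 0.5)
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(chrom = scenario$chrom, start = start + bs %/% 5L,
                   end = start + bs %/% 5L + 500L)
      cols[[length(cols) + 1L]] <- split
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(chrom = scenario$chrom, start = start + (3L * bs) %/% 5L,
                   end = start + (3L * bs) %/% 5L + 500L)
      cols[[length(cols) + 1L]] <- counts[, b] - split
    }
  }
  peaks <- do.call(rbind, peak_rows)
  peaks$name <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  mat <- do.call(cbind, cols)
  colnames(mat) <- peaks$name
  rownames(mat) <- sprintf("cell_%d", seq_len(nrow(mat)))

  p_matrix <- file.path(dir, "counts.tsv")
  p_peaks <- file.path(dir, "peaks.bed")
  p_sizes <- file.path(dir, "chrom.sizes")
  data.table::fwrite(data.table::data.table(cell = rownames(mat), mat),
                     p_matrix, sep = "\t")
  utils::write.table(peaks, p_peaks, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("%s\t%d", scenario$chrom, scenario$n_bins * bs), p_sizes)
  list(paths = list(matrix = p_matrix, peaks = p_peaks,
                    chrom_sizes = p_sizes, prior = prior$path),
       truth = list(theta = pr$theta, edges = pr$edges,
                    pcor_true = pr$pcor_true, counts = counts,
                    prior_kept = prior$kept))
}
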