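#' Divide a genome into fixed-width bins
#'
#' Tiles each chromosome with consecutive bins of width `bin_size` (default
#' 25 kbp). The last bin of a chromosome is truncated at the chromosome end.
#' Coordinates are 0-based half-open throughout the package.
#'
#' @param chrom_sizes named numeric vector or two-column data.frame
#'   (chrom, length) as in a standard `chrom.sizes` file.
#' @param bin_size bin width in bp; default 25000.
#' @return data.frame with columns `chrom`, `start`, `end`, `index`
#'   (0-based ordinal within the chromosome).
#' @examples
#' bin_genome(c(chrT = 60000), bin_size = 25000)
#' @export
bin_genome <- function(chrom_sizes, bin_size = 25000L) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stopf("bin_size must be a positive number, got %s", format(bin_size))
  if (any(chrom_sizes <= 0))
    stopf("chromosome lengths must be positive")
  bin_size <- as.integer(bin_size)
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    n <- as.integer(ceiling(len / bin_size))
    idx <- seq_len(n) - 1L
    data.frame(chrom = ch,
               start = idx * bin_size,
               end   = pmin((idx + 1L) * bin_size, len),
               index = idx,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stopf("chrom sizes data.frame needs two columns")
    out <- as.numeric(x[[2L]]); names(out) <- as.character(x[[1L]])
    return(out)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stopf("chrom_sizes must be named by chromosome")
  x
}

#' Read a chrom.sizes file
#'
#' @param path two-column whitespace-separated text (chrom, length).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("chrom", "len"))
  out <- as.numeric(dt$len); names(out) <- as.character(dt$chrom)
  out
}

#' Merge peak-level counts into genomic bins
#'
#' Assigns every peak to the bin containing its midpoint and sums the read
#' counts of peaks that fall in the same bin, per cell. Bins containing no
#' peak are dropped; columns come out in genomic order. Peaks on chromosomes
#' absent from `bins` are skipped with a warning.
#'
#' @param counts cells x peaks matrix of non-negative read counts.
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per column of `counts`.
#' @param bins output of [bin_genome()] restricted to one or more chromosomes.
#' @return list with `counts` (cells x occupied-bins integer matrix) and
#'   `bins` (data.frame of the occupied bins, genomic order).
#' @export
merge_peaks_into_bins <- function(counts, peaks, bins) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("peak counts must be non-negative")
  if (nrow(peaks) != ncol(counts))
    stopf("number of peak records (%d) must equal number of count columns (%d)",
          nrow(peaks), ncol(counts))
  if (any(peaks$start >= peaks$end)) stopf("invalid peak interval (start >= end)")
  known <- peaks$chrom %in% unique(bins$chrom)
  if (!all(known)) {
    warnf("skipping %d peak(s) on chromosomes absent from bins", sum(!known))
    peaks <- peaks[known, , drop = FALSE]
    counts <- counts[, known, drop = FALSE]
  }
  bin_size <- max(bins$end - bins$start)
  mid <- floor((peaks$start + peaks$end) / 2)
  key_bin  <- paste0(bins$chrom, ":", bins$index)
  key_peak <- paste0(peaks$chrom, ":", mid %/% bin_size)
  j <- match(key_peak, key_bin)
  if (anyNA(j)) {
    warnf("skipping %d peak(s) whose midpoint falls outside the binned genome",
          sum(is.na(j)))
    keep <- !is.na(j)
    counts <- counts[, keep, drop = FALSE]
    j <- j[keep]
  }
  occ <- sort(unique(j))
  # cells x occupied bins: sum peak columns sharing a bin
  agg <- matrix(0, nrow(counts), length(occ))
  jj <- match(j, occ)
  for (k in seq_along(jj)) agg[, jj[k]] <- agg[, jj[k]] + counts[, k]
  storage.mode(agg) <- "double"
  occupied <- bins[occ, , drop = FALSE]
  rownames(occupied) <- NULL
  colnames(agg) <- paste0(occupied$chrom, ":", occupied$start, "-", occupied$end)
  rownames(agg) <- rownames(counts)
  list(counts = agg, bins = occupied)
}

#' Log-transform a binned count matrix
#'
#' Elementwise natural log of (count + 1), the variance-stabilizing transform
#' applied to the merged bin counts before covariance estimation.
#'
#' @param counts non-negative matrix.
#' @return matrix of the same shape, `log(counts + 1)`.
#' @export
log_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("log_transform requires non-negative input")
  log1p(counts)
}

#' Bin and log-transform a peak-count matrix for one chromosome
#'
#' Convenience wrapper: [merge_peaks_into_bins()] followed by
#' [log_transform()], restricted to a single chromosome.
#'
#' @inheritParams merge_peaks_into_bins
#' @param chrom chromosome to process.
#' @return list of class `binned_matrix` with `values` (cells x occupied
#'   bins, natural-log scale), `bins`, `chrom`, and `log_base = "natural"`.
#' @export
preprocess_chromosome <- function(counts, peaks, bins, chrom) {
  bins_c <- bins[bins$chrom == chrom, , drop = FALSE]
  on_chrom <- peaks$chrom == chrom
  merged <- suppressWarnings(merge_peaks_into_bins(
    counts[, on_chrom, drop = FALSE],
    peaks[on_chrom, , drop = FALSE], bins_c))
  structure(list(values = log_transform(merged$counts),
                 bins = merged$bins, chrom = chrom, log_base = "natural"),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %s: %d cells x %d occupied bins (log scale)\n",
              x$chrom, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a peak-level count matrix
#'
#' Accepts either a delimited dense text matrix (with `peaks_as` indicating
#' whether rows or columns are peaks) or matrix-market triplets plus a BED
#' peak file and a cell-id list.
#'
#' @param path dense delimited matrix, or a `.mtx` file.
#' @param peaks_bed BED file of peak coordinates (required for `.mtx`; for
#'   dense input peak names of the form `chr:start-end` are parsed from the
#'   header when `peaks_bed` is NULL).
#' @param cells path to a one-column cell-id list (mtx input), or NULL.
#' @param peaks_as "columns" (cells x peaks, default) or "rows".
#' @return list with `counts` (cells x peaks matrix) and `peaks` data.frame.
#' @export
read_peak_matrix <- function(path, peaks_bed = NULL, cells = NULL,
                             peaks_as = c("columns", "rows")) {
  peaks_as <- match.arg(peaks_as)
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(peaks_bed)) stopf("matrix-market input requires peaks_bed")
    peaks <- read_bed(peaks_bed)
    if (peaks_as == "rows") m <- t(m)
    if (!is.null(cells)) rownames(m) <- readLines(cells)[seq_len(nrow(m))]
  } else {
    dt <- data.table::fread(path, header = TRUE)
    rn <- NULL
    if (!is.numeric(dt[[1L]])) { rn <- as.character(dt[[1L]]); dt <- dt[, -1L] }
    m <- as.matrix(dt)
    if (peaks_as == "rows") { cn <- rn; m <- t(m); rownames(m) <- NULL
                              colnames(m) <- cn %||% colnames(m) }
    else rownames(m) <- rn
    if (is.null(peaks_bed)) {
      peaks <- parse_peak_names(colnames(m))
    } else peaks <- read_bed(peaks_bed)
  }
  if (nrow(peaks) != ncol(m))
    stopf("peak annotation (%d) does not match matrix columns (%d)",
          nrow(peaks), ncol(m))
  list(counts = m, peaks = peaks)
}

parse_peak_names <- function(x) {
  if (is.null(x)) stopf("cannot infer peak coordinates: no header and no BED")
  ok <- grepl("^[^:]+:[0-9]+-[0-9]+$", x)
  if (!all(ok)) stopf("peak names must look like chr:start-end (offender: %s)",
                      x[which(!ok)[1L]])
  chrom <- sub(":.*$", "", x)
  rng <- sub("^[^:]+:", "", x)
  start <- as.integer(sub("-.*$", "", rng))
  end <- as.integer(sub("^.*-", "", rng))
  data.frame(chrom = chrom, start = start, end = end, id = x,
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' Minimal BED reader: first three columns are chrom/start/end (0-based
#' half-open); a fourth column, when present, becomes `name`.
#'
#' @param path BED path (gzip transparent).
#' @return data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  out <- data.frame(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]),
                    end   = as.integer(dt[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) out$name <- as.character(dt[[4L]])
  out
}
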