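#' Load a Hi-C contact map from juicer-style text
#'
#' Reads a per-chromosome plain-text Hi-C dump (three whitespace/tab
#' separated columns: start1, start2, value at a fixed resolution) into a
#' sparse upper-triangular contact map keyed by bin index. Non-finite or
#' negative values are skipped with a message; starts must be multiples of
#' the resolution.
#'
#' @param path text dump (gzip transparent).
#' @param resolution bin width in bp of the dump.
#' @param chrom chromosome name to record (dumps are per-chromosome and
#'   carry no name themselves).
#' @return object of class `contact_map`: list with `chrom`, `resolution`,
#'   and `entries` (data.frame `i`, `j`, `value` with `i <= j`, bin indices).
#' @export
load_contact_text <- function(path, resolution, chrom = "chr") {
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE,
                        col.names = c("s1", "s2", "value"))),
    error = function(e) stopf("cannot parse contact dump %s: %s", path,
                              conditionMessage(e)))
  if (nrow(dt) == 0L) {
    warnf("empty contact dump: %s", path)
    return(contact_map(chrom, resolution,
                       data.frame(i = integer(), j = integer(),
                                  value = numeric())))
  }
  if (!is.numeric(dt$s1) || !is.numeric(dt$s2) || !is.numeric(dt$value)) {
    bad <- which(!grepl("^\\s*[0-9.eE+-]+", readLines(path)))[1]
    stopf("malformed contact dump %s (line %s)", path,
          if (is.na(bad)) "?" else bad)
  }
  off <- which(dt$s1 %% resolution != 0 | dt$s2 %% resolution != 0)
  if (length(off))
    stopf("start %s (line %d of %s) is not a multiple of resolution %d",
          format(dt$s1[off[1]]), off[1], path, resolution)
  keep <- is.finite(dt$value) & dt$value >= 0
  if (any(!keep)) {
    message(sprintf("load_contact_text: skipped %d non-finite/negative value(s)",
                    sum(!keep)))
    dt <- dt[keep]
  }
  i <- as.integer(dt$s1 %/% resolution)
  j <- as.integer(dt$s2 %/% resolution)
  contact_map(chrom, resolution,
              data.frame(i = pmin(i, j), j = pmax(i, j), value = dt$value))
}

contact_map <- function(chrom, resolution, entries) {
  # canonicalize: i <= j, unique keys (duplicates: last wins is arbitrary --
  # sum them, the convention for re-binned dumps)
  if (nrow(entries)) {
    key <- paste(entries$i, entries$j)
    if (anyDuplicated(key)) {
      agg <- tapply(entries$value, key, sum)
      ij <- do.call(rbind, strsplit(names(agg), " "))
      entries <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                            value = as.numeric(agg))
    }
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(chrom = chrom, resolution = resolution, entries = entries),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s @ %d bp, %d entries\n",
              x$chrom, x$resolution, nrow(x$entries)))
  invisible(x)
}

#' Average several contact maps entrywise
#'
#' Entrywise mean over the union of bin pairs; a pair missing from a map
#' contributes 0 for that map (absence of evidence counts as no contact).
#' All maps must share chromosome and resolution.
#'
#' @param maps list of `contact_map` objects.
#' @return a `contact_map` with the averaged entries.
#' @export
average_contacts <- function(maps) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  res <- unique(vapply(maps, function(m) m$resolution, numeric(1)))
  if (length(res) != 1L) stopf("contact maps have mixed resolutions")
  ch <- unique(vapply(maps, function(m) m$chrom, character(1)))
  if (length(ch) != 1L) stopf("contact maps cover different chromosomes")
  all_e <- do.call(rbind, lapply(maps, function(m) m$entries))
  if (nrow(all_e) == 0L) return(contact_map(ch, res, all_e))
  key <- paste(all_e$i, all_e$j)
  tot <- tapply(all_e$value, key, sum)
  ij <- do.call(rbind, strsplit(names(tot), " "))
  contact_map(ch, res,
              data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                         value = as.numeric(tot) / length(maps)))
}

#' Build the elementwise L1 penalty from a contact map
#'
#' For occupied model bins i, j the penalty is `rho_ij = delta / (h_ij +
#' eps)`, where `h_ij` is the (averaged) Hi-C enrichment between the bins.
#' Pairs without prior contact get the maximal finite penalty `delta / eps`;
#' the diagonal is never penalized (set to 0). `delta` is the sensitivity
#' knob: larger `delta` penalizes more and yields fewer predicted
#' interactions; `eps` is a pseudo-count keeping the penalty finite where no
#' contact was observed.
#'
#' @param h `contact_map` whose resolution matches the model bin size.
#' @param bins occupied-bin data.frame (from [merge_peaks_into_bins()]).
#' @param delta,eps positive constants; defaults 1 and 1.
#' @param log_scale_h if TRUE, use `log1p(h)` in place of raw enrichment
#'   (raw Hi-C counts span orders of magnitude).
#' @return object of class `penalty_matrix`: list with dense symmetric
#'   `rho`, `delta`, `eps`, `mode = "hic-prior"`.
#' @export
build_penalty <- function(h, bins, delta = 1, eps = 1, log_scale_h = FALSE) {
  if (eps <= 0) stopf("eps must be > 0 (eps = 0 would allow infinite penalty)")
  if (delta <= 0) stopf("delta must be > 0")
  p <- nrow(bins)
  H <- matrix(0, p, p)
  if (nrow(h$entries)) {
    idx <- match(h$entries$i, bins$index)
    jdx <- match(h$entries$j, bins$index)
    keep <- !is.na(idx) & !is.na(jdx)
    v <- h$entries$value[keep]
    if (log_scale_h) v <- log1p(v)
    H[cbind(idx[keep], jdx[keep])] <- v
    H[cbind(jdx[keep], idx[keep])] <- v
  }
  rho <- delta / (H + eps)
  diag(rho) <- 0
  structure(list(rho = rho, delta = delta, eps = eps, mode = "hic-prior"),
            class = "penalty_matrix")
}

#' Constant-penalty baseline
#'
#' All off-diagonal penalties equal `rho0` (default 0.01, the constant-rho
#' baseline); the diagonal is unpenalized.
#'
#' @param bins occupied-bin data.frame (or an integer bin count).
#' @param rho0 non-negative scalar penalty; default 0.01.
#' @return `penalty_matrix` with `mode = "constant"`.
#' @export
constant_penalty <- function(bins, rho0 = 0.01) {
  if (rho0 < 0) stopf("rho0 must be >= 0")
  p <- if (is.data.frame(bins)) nrow(bins) else as.integer(bins)
  rho <- matrix(rho0, p, p)
  diag(rho) <- 0
  structure(list(rho = rho, delta = NA_real_, eps = NA_real_,
                 mode = "constant"),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat(sprintf("<penalty_matrix> %d x %d, mode=%s%s\n",
              nrow(x$rho), ncol(x$rho), x$mode,
              if (x$mode == "hic-prior")
                sprintf(" (delta=%g, eps=%g)", x$delta, x$eps) else ""))
  invisible(x)
}
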