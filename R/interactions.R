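#' Convert a precision fit into interaction calls
#'
#' One call per off-diagonal bin pair whose partial correlation passes the
#' score filter. By default only positive partial correlations are reported
#' (co-accessibility is a positive-association concept); `sign_mode =
#' "both"` keeps negative ones with signed scores. Calls are sorted by
#' (bin_a, bin_b) and deterministic.
#'
#' @param fit a `precision_fit`.
#' @param bins occupied-bin data.frame matching the fit's variables.
#' @param min_abs_score report pairs with `|pcor| >` this (default 0: every
#'   exact nonzero of the precision matrix is a call; sparsity is controlled
#'   primarily by the penalty scale delta).
#' @param sign_mode "positive" (default) or "both".
#' @param max_distance optional bp cap on the anchor distance (emulates
#'   fixed-window methods; default `Inf`, no cap).
#' @return data.frame of class `interaction_calls` with columns `chrom`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `score`, `distance`.
#' @export
call_interactions <- function(fit, bins, min_abs_score = 0,
                              sign_mode = c("positive", "both"),
                              max_distance = Inf) {
  sign_mode <- match.arg(sign_mode)
  if (min_abs_score < 0) stopf("min_abs_score must be >= 0")
  pc <- fit$pcor
  p <- nrow(pc)
  if (nrow(bins) != p) stopf("bins (%d) do not match fit dimension (%d)",
                             nrow(bins), p)
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  sc <- pc[ut]
  keep <- abs(sc) > min_abs_score
  if (sign_mode == "positive") keep <- keep & sc > 0
  ia <- ut[keep, 1L]; ib <- ut[keep, 2L]; sc <- sc[keep]
  dist <- bins$start[ib] - bins$start[ia]
  keep2 <- dist <= max_distance
  out <- data.frame(chrom = bins$chrom[ia][keep2],
                    start_a = bins$start[ia][keep2],
                    end_a = bins$end[ia][keep2],
                    start_b = bins$start[ib][keep2],
                    end_b = bins$end[ib][keep2],
                    score = sc[keep2],
                    distance = dist[keep2],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_calls", "data.frame")
  out
}

#' Count calls per genomic-distance class
#'
#' Partitions calls into half-open distance classes `[0, b1), [b1, b2), ...,
#' [bk, Inf)` defined by strictly increasing bp boundaries, e.g.
#' `boundaries = 5e5` separates short-range from long-range (>500 kbp)
#' calls.
#'
#' @param calls `interaction_calls` data.frame.
#' @param boundaries strictly increasing bp cutoffs.
#' @return named integer vector of counts, one per class; sums to
#'   `nrow(calls)`.
#' @export
distance_stratified_counts <- function(calls, boundaries = 5e5) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stopf("boundaries must be strictly increasing")
  brk <- c(0, boundaries, Inf)
  cls <- cut(calls$distance, breaks = brk, right = FALSE,
             labels = paste0("[", format(brk[-length(brk)], scientific = FALSE,
                                         trim = TRUE), ",",
                             format(brk[-1], scientific = FALSE, trim = TRUE),
                             ")"))
  table(cls)
}

bedpe_header <- function(extra = NULL) {
  paste0("# chromglasso ", as.character(utils::packageVersion("chromglasso")),
         if (!is.null(extra)) paste0(" ", extra) else "")
}

#' Write interaction calls as BEDPE
#'
#' Ten-column BEDPE (chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2, strands "."), preceded by a `#` metadata line. Reads
#' back with [read_bedpe()].
#'
#' @param calls `interaction_calls` data.frame.
#' @param path output file.
#' @param metadata optional string appended to the header line (e.g. a
#'   config hash).
#' @export
write_bedpe <- function(calls, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(bedpe_header(metadata), con)
  if (nrow(calls)) {
    df <- data.frame(calls$chrom, calls$start_a, calls$end_a,
                     calls$chrom, calls$start_b, calls$end_b,
                     name = sprintf("interaction_%d", seq_len(nrow(calls))),
                     score = sprintf("%.17g", calls$score),
                     s1 = ".", s2 = ".")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#'
#' @param path BEDPE path.
#' @return `interaction_calls` data.frame.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), score = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("interaction_calls", "data.frame")
    return(out)
  }
  dt <- data.table::fread(text = lines, header = FALSE)
  out <- data.frame(chrom = as.character(dt[[1L]]),
                    start_a = as.integer(dt[[2L]]), end_a = as.integer(dt[[3L]]),
                    start_b = as.integer(dt[[5L]]), end_b = as.integer(dt[[6L]]),
                    score = as.numeric(dt[[8L]]),
                    stringsAsFactors = FALSE)
  out$distance <- out$start_b - out$start_a
  class(out) <- c("interaction_calls", "data.frame")
  out
}

#' Write interaction calls as a UCSC interact track
#'
#' Emits a `track type=interact` header followed by one interact-format row
#' per call. The track score is `|pcor|` mapped linearly from \[0, 1\] to
#' \[0, 1000\] and rounded (stated in the header); the signed partial
#' correlation is kept in the `value` column.
#'
#' @param calls `interaction_calls` data.frame.
#' @param path output file.
#' @param track_name name shown in the browser.
#' @export
write_ucsc_track <- function(calls, path, track_name = "chromglasso") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    paste0("track type=interact name=\"%s\" ",
           "description=\"predicted chromatin interactions; ",
           "score=round(1000*|partial correlation|)\" useScore=on"),
    track_name), con)
  if (nrow(calls)) {
    df <- data.frame(calls$chrom, calls$start_a, calls$end_b,
                     name = sprintf("interaction_%d", seq_len(nrow(calls))),
                     score = pmin(1000L, as.integer(round(1000 * abs(calls$score)))),
                     value = sprintf("%.6g", calls$score),
                     exp = ".", color = "0",
                     chrom1 = calls$chrom, start1 = calls$start_a,
                     end1 = calls$end_a, name1 = ".", strand1 = ".",
                     chrom2 = calls$chrom, start2 = calls$start_b,
                     end2 = calls$end_b, name2 = ".", strand2 = ".")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
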