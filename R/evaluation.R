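#' Top-N positive set from a Hi-C contact map
#'
#' Selects the `n` most enriched bin pairs of a contact map as the positive
#' set for evaluation (default n = 60000 per chromosome). Diagonal pairs are
#' excluded (self-pairs are never predicted). Ties at the cutoff are broken
#' deterministically by (value desc, bin_i asc, bin_j asc); if fewer than
#' `n` entries exist, all are taken.
#'
#' @param cm `contact_map`.
#' @param n number of pairs requested (default 60000).
#' @return object of class `positive_set`: list with `chrom`, `pairs`
#'   (data.frame `i`, `j`, i < j), `scheme`, `n_requested`, `n_selected`.
#' @export
top_n_positive <- function(cm, n = 60000L) {
  if (n <= 0) stopf("n must be positive")
  e <- cm$entries
  e <- e[e$i != e$j, , drop = FALSE]
  o <- order(-e$value, e$i, e$j)
  e <- e[o, , drop = FALSE]
  sel <- utils::head(e, n)
  structure(list(chrom = cm$chrom,
                 pairs = data.frame(i = sel$i, j = sel$j),
                 scheme = "per-chromosome-topN",
                 n_requested = as.integer(n),
                 n_selected = nrow(sel)),
            class = "positive_set")
}

#' Chromosome-proportional allocation of positive-set sizes
#'
#' Allocates the number of top Hi-C pairs per chromosome proportionally to
#' chromosome length, with the longest chromosome getting exactly `n_max`
#' (default 60000).
#'
#' @param chrom_sizes named lengths (or two-column data.frame).
#' @param n_max pairs for the longest chromosome.
#' @return named integer vector chrom -> n.
#' @export
proportional_n <- function(chrom_sizes, n_max = 60000L) {
  if (n_max <= 0) stopf("n_max must be positive")
  cs <- as_chrom_sizes(chrom_sizes)
  out <- as.integer(round(n_max * cs / max(cs)))
  names(out) <- names(cs)
  out
}

#' Fraction of predicted interactions supported by the Hi-C positive set
#'
#' A call matches a positive iff its two anchors are exactly the positive
#' pair's bins at the shared resolution (bin-exact matching; `slack_bins`
#' allows a +/- k bin window for robustness studies, default 0).
#'
#' @param calls `interaction_calls` on the same chromosome/resolution as
#'   `pos`.
#' @param pos `positive_set` from [top_n_positive()].
#' @param resolution bin width used to convert call coordinates to bin
#'   indices.
#' @param slack_bins match within this many bins on each anchor (default 0).
#' @return list: `accuracy` (fraction in \[0,1\], or `NA` with a warning if
#'   there are no calls), `n_matched`, `n_calls`, `n_positives`.
#' @export
overlap_accuracy <- function(calls, pos, resolution, slack_bins = 0L) {
  n_calls <- nrow(calls)
  if (n_calls == 0L) {
    warnf("no predicted interactions: accuracy undefined")
    return(list(accuracy = NA_real_, n_matched = 0L, n_calls = 0L,
                n_positives = nrow(pos$pairs)))
  }
  ci <- calls$start_a %/% resolution
  cj <- calls$start_b %/% resolution
  if (slack_bins == 0L) {
    key_pos <- paste(pos$pairs$i, pos$pairs$j)
    hit <- paste(pmin(ci, cj), pmax(ci, cj)) %in% key_pos
  } else {
    hit <- logical(n_calls)
    for (k in seq_len(n_calls)) {
      hit[k] <- any(abs(pos$pairs$i - ci[k]) <= slack_bins &
                    abs(pos$pairs$j - cj[k]) <= slack_bins)
    }
  }
  list(accuracy = sum(hit) / n_calls, n_matched = sum(hit),
       n_calls = n_calls, n_positives = nrow(pos$pairs))
}
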