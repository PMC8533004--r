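#' Paired intersection of interaction calls with two feature sets
#'
#' Emits a hit when one anchor bin of a call overlaps at least one `left`
#' feature and the other anchor overlaps at least one `right` feature, in
#' either orientation (e.g. left = GWAS SNPs, right = gene promoters: a gene
#' is labelled a target when the bin containing its promoter interacts with
#' the bin containing the mutation). Overlap is a nonempty interval
#' intersection with the full anchor bin.
#'
#' @param calls `interaction_calls`.
#' @param left,right data.frames with `chrom`, `start`, `end` and optional
#'   `name` (0-based half-open).
#' @return data.frame with one row per hit: the call columns plus
#'   `left_features`, `right_features` (comma-separated names or
#'   coordinates) and `orientation` ("left_a" if the left features overlap
#'   anchor a, else "left_b").
#' @export
intersect_pairs <- function(calls, left, right) {
  hits <- lapply(seq_len(nrow(calls)), function(k) {
    cl <- calls[k, ]
    la <- feat_overlap(left, cl$chrom, cl$start_a, cl$end_a)
    lb <- feat_overlap(left, cl$chrom, cl$start_b, cl$end_b)
    ra <- feat_overlap(right, cl$chrom, cl$start_a, cl$end_a)
    rb <- feat_overlap(right, cl$chrom, cl$start_b, cl$end_b)
    out <- NULL
    if (length(la) && length(rb))
      out <- rbind(out, cbind(cl, left_features = feat_names(left, la),
                              right_features = feat_names(right, rb),
                              orientation = "left_a"))
    if (length(lb) && length(ra))
      out <- rbind(out, cbind(cl, left_features = feat_names(left, lb),
                              right_features = feat_names(right, ra),
                              orientation = "left_b"))
    out
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- cbind(calls[0, ], left_features = character(),
                 right_features = character(), orientation = character())
  rownames(out) <- NULL
  out
}

feat_overlap <- function(feat, chrom, start, end) {
  which(feat$chrom == chrom & feat$start < end & feat$end > start)
}

feat_names <- function(feat, idx) {
  nm <- if (!is.null(feat$name)) feat$name[idx]
        else sprintf("%s:%d-%d", feat$chrom[idx], feat$start[idx], feat$end[idx])
  paste(nm, collapse = ",")
}

#' Keep only long-range hits
#'
#' @param hits output of [intersect_pairs()] (any data.frame with a
#'   `distance` column).
#' @param cutoff bp; keep hits with `distance > cutoff` (default 500 kbp).
#' @return the filtered subset.
#' @export
long_range_hits <- function(hits, cutoff = 5e5) {
  hits[hits$distance > cutoff, , drop = FALSE]
}

#' Promoter connectivity per gene
#'
#' Counts, for each gene, the interaction calls with at least one anchor
#' overlapping the gene's promoter. With a list of per-cell-type call sets,
#' also reports the relative connectivity (count minus the across-cell-type
#' mean), the quantity used to rank cell-type-specific promoter activity.
#'
#' @param calls `interaction_calls`, or a named list of them (one per cell
#'   type).
#' @param promoters data.frame with `chrom`, `start`, `end`, `name` (gene).
#' @return single call set: named integer vector gene -> count. List input:
#'   list with `counts` (genes x cell-types matrix) and `relative`
#'   (mean-centered across cell types).
#' @export
promoter_connectivity <- function(calls, promoters) {
  if (is.null(promoters$name)) stopf("promoters must carry gene names")
  if (anyDuplicated(promoters$name))
    warnf("duplicate gene names in promoters: counts merged per gene")
  genes <- unique(promoters$name)
  count_one <- function(cl) {
    vapply(genes, function(g) {
      pr <- promoters[promoters$name == g, , drop = FALSE]
      n <- 0L
      for (q in seq_len(nrow(pr))) {
        hit_a <- cl$chrom == pr$chrom[q] &
          cl$start_a < pr$end[q] & cl$end_a > pr$start[q]
        hit_b <- cl$chrom == pr$chrom[q] &
          cl$start_b < pr$end[q] & cl$end_b > pr$start[q]
        n <- n + sum(hit_a | hit_b)
      }
      n
    }, integer(1))
  }
  if (is.data.frame(calls)) return(count_one(calls))
  counts <- vapply(calls, count_one, integer(length(genes)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(genes),
                                             dimnames = list(genes, names(calls)))
  list(counts = counts, relative = counts - rowMeans(counts))
}

#' Two-proportion z-test enrichment
#'
#' Compares the hit fraction in a case set against a null set: enrichment is
#' the ratio of fractions, the z statistic uses the pooled proportion, and
#' the p-value is the two-sided normal tail.
#'
#' @param hits_case,total_case,hits_null,total_null counts, hits <= totals,
#'   totals > 0.
#' @return list: `enrichment`, `z`, `p` (two-sided). A zero null fraction
#'   gives `enrichment = NA` with a warning (flagged sentinel), while `z`
#'   and `p` are still defined by the pooled statistic unless both
#'   fractions are degenerate.
#' @export
enrichment_two_proportion <- function(hits_case, total_case,
                                      hits_null, total_null) {
  if (total_case <= 0 || total_null <= 0) stopf("totals must be positive")
  if (hits_case > total_case || hits_null > total_null)
    stopf("hits cannot exceed totals")
  p1 <- hits_case / total_case
  p0 <- hits_null / total_null
  enr <- if (p0 == 0) { warnf("null fraction is 0: enrichment undefined"); NA_real_ }
         else p1 / p0
  pp <- (hits_case + hits_null) / (total_case + total_null)
  se <- sqrt(pp * (1 - pp) * (1 / total_case + 1 / total_null))
  z <- if (se == 0) 0 else (p1 - p0) / se
  list(enrichment = enr, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment for a set of enrichment tests
#'
#' Convenience wrapper labelled as an extension of the per-test p < 0.05
#' convention: returns the raw p-values alongside BH q-values.
#'
#' @param p numeric vector of raw p-values.
#' @return data.frame with `p` and `q`.
#' @export
bh_adjust <- function(p) data.frame(p = p, q = stats::p.adjust(p, "BH"))
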