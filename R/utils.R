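stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Area under the precision-recall curve
#'
#' Step-function AUPRC for a binary labelling ranked by a continuous score.
#' Ties are handled by grouping: all items with the same score enter the
#' curve together, so the result does not depend on the order of tied items.
#'
#' @param score numeric vector of scores (higher = more confident).
#' @param label logical or 0/1 vector, same length, TRUE for positives.
#' @return scalar AUPRC in \[0, 1\]; `NA` if there are no positives.
#' @export
auprc <- function(score, label) {
  label <- as.logical(label)
  if (length(score) != length(label)) stopf("score/label length mismatch")
  P <- sum(label)
  if (P == 0L) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- label[o]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  n  <- tapply(y, grp, length)
  ctp <- cumsum(tp); cn <- cumsum(n)
  prec <- ctp / cn
  rec  <- ctp / P
  # trapezoid-free "average precision" over the step curve: interpolate
  # linearly within a tie group (standard AP with tie grouping)
  prev_rec <- c(0, rec[-length(rec)])
  sum((rec - prev_rec) * prec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
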