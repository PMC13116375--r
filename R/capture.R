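# Significance and differential calling on Capture Hi-C interaction score
# tables (confidence scores are consumed, not computed).

#' Flag high-confidence interactions
#'
#' An interaction is significant in a condition when its score is at least
#' `threshold` (inclusive, default 3).
#'
#' @param rows Tibble with one or more `score_*` columns (or a single
#'   `score` column).
#' @param threshold Significance cutoff.
#' @return `rows` with a logical `sig_*` column per score column.
#' @export
call_significant <- function(rows, threshold = 3) {
  score_cols <- grep("^score", names(rows), value = TRUE)
  if (!length(score_cols)) abort("no score column found")
  for (sc in score_cols) {
    rows[[sub("^score", "sig", sc)]] <- rows[[sc]] >= threshold
  }
  rows
}

#' Call differential WT/MT interactions
#'
#' MT-enhanced: significant in MT (score >= `sig`), non-significant in WT
#' (score < `sig`), and MT - WT difference strictly greater than `delta`.
#' WT-enhanced is the mirror image; everything else is `none`.
#'
#' @param rows Tibble with `score_wt` and `score_mt` columns.
#' @param sig Significance cutoff (inclusive, default 3).
#' @param delta Minimum score difference (strict, default 3).
#' @return `rows` with a `diff_label` factor
#'   (MT_enhanced/WT_enhanced/none).
#' @export
differential_interactions <- function(rows, sig = 3, delta = 3) {
  if (!all(c("score_wt", "score_mt") %in% names(rows))) {
    abort("need score_wt and score_mt columns")
  }
  d <- rows$score_mt - rows$score_wt
  lab <- ifelse(rows$score_mt >= sig & rows$score_wt < sig & d > delta,
                "MT_enhanced",
                ifelse(rows$score_wt >= sig & rows$score_mt < sig &
                         -d > delta, "WT_enhanced", "none"))
  rows$diff_label <- factor(lab, levels = c("MT_enhanced", "WT_enhanced",
                                            "none"))
  rows
}
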