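## Ingestion and summarization of external cytokine-induction predictions
## (IL-4, IFN-gamma, IL-10) and bioactivity annotations. Predictor outputs
## are opaque evidence: scores are validated, stored and aggregated, never
## recomputed.

#' Enumerate sliding windows of a sequence
#'
#' @param sequence amino-acid string.
#' @param window_length window size `w >= 1`.
#' @return Data.frame with `offset` (1-based start) and `window`; `max(0,
#'   L - w + 1)` rows at consecutive offsets. A window longer than the
#'   sequence yields zero rows (not an error).
#' @export
#' @examples
#' nrow(enumerate_windows("SDIPNPIGSENSEK", 9))  # 6
enumerate_windows <- function(sequence, window_length) {
  stopifnot(window_length >= 1L)
  L <- nchar(sequence)
  n <- max(0L, L - as.integer(window_length) + 1L)
  if (n == 0L) {
    return(data.frame(offset = integer(0), window = character(0),
                      stringsAsFactors = FALSE))
  }
  offsets <- seq_len(n)
  data.frame(offset = offsets,
             window = substring(sequence, offsets, offsets + window_length - 1L),
             stringsAsFactors = FALSE)
}

#' Summarize per-window predictor scores into a cytokine record
#'
#' A window is inducing when its score is strictly greater than the
#' threshold; the score range is reported over inducing windows only. The
#' summary is invariant to window order.
#'
#' @param window_scores numeric vector of finite per-window SVM scores.
#' @param threshold inducing threshold (default 0.2).
#' @return List with `n_inducing`, `score_min`, `score_max` (the latter two
#'   `NA` when nothing induces).
#' @export
#' @examples
#' summarize_scores(c(0.5, -0.1, 0.3))   # n_inducing 2, range 0.3-0.5
summarize_scores <- function(window_scores, threshold = 0.2) {
  stopifnot(all(is.finite(window_scores)))
  inducing <- window_scores[window_scores > threshold]
  list(n_inducing = length(inducing),
       score_min = if (length(inducing)) min(inducing) else NA_real_,
       score_max = if (length(inducing)) max(inducing) else NA_real_)
}

#' Consistency check of an ingested cytokine summary table
#'
#' Flags rows whose reported number of inducing windows exceeds the number
#' of windows of the stated length that fit in the peptide, and rows with
#' `score_min > score_max`. Published summary tables contain such rows, so
#' anomalies are reported, never rejected.
#'
#' @param cytokines data.frame with `peptide_id`, `cytokine`, `n_inducing`,
#'   `score_min`, `score_max`, `window_length`; `peptide_id` must hold the
#'   peptide sequence (windows are counted from it).
#' @return Data.frame of flagged rows with a `flag` message column (zero
#'   rows when clean).
#' @export
check_cytokine_consistency <- function(cytokines) {
  flags <- lapply(seq_len(nrow(cytokines)), function(i) {
    r <- cytokines[i, ]
    avail <- max(0L, nchar(r$peptide_id) - as.integer(r$window_length) + 1L)
    msg <- character(0)
    if (r$n_inducing > avail) {
      msg <- c(msg, sprintf("n_inducing %d exceeds the %d windows of length %d",
                            r$n_inducing, avail, r$window_length))
    }
    if (!is.na(r$score_min) && !is.na(r$score_max) && r$score_min > r$score_max) {
      msg <- c(msg, "score_min exceeds score_max")
    }
    if (length(msg) == 0L) return(NULL)
    cbind(r, flag = paste(msg, collapse = "; "), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, flags)
  if (is.null(out)) {
    out <- cbind(cytokines[0, , drop = FALSE], flag = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Count distinct peptides carrying a bioactivity function
#'
#' @param tags bioactivity table with `peptide_id`, `function` and
#'   optionally `source`.
#' @param fun one of `"immunomodulatory"`, `"antimicrobial"`,
#'   `"anti_inflammatory"`, `"il10_inducer"`.
#' @param source optional source filter (`"IS"` or `"IV"`).
#' @return Integer count of distinct peptides.
#' @export
#' @examples
#' tags <- data.frame(peptide_id = c("A", "A"), "function" = "il10_inducer",
#'                    check.names = FALSE)
#' count_by_function(tags, "il10_inducer")   # 1 (distinct peptides)
count_by_function <- function(tags, fun, source = NULL) {
  sel <- tags[["function"]] == fun
  if (!is.null(source) && "source" %in% names(tags)) {
    sel <- sel & tags$source == source
  }
  length(unique(tags$peptide_id[sel]))
}
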