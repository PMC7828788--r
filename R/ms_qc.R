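## Mass-spectrometry identification summaries: score filtering and the
## replicate-homogeneity check.

#' Filter MS identifications by score
#'
#' Retains rows whose score reaches the cutoff (inclusive: "threshold
#' cut-off" with significance at the threshold, the conventional Mascot
#' reading).
#'
#' @param identifications data.frame with a `score` column.
#' @param cutoff minimum score retained (default 32).
#' @return The retained rows.
#' @export
#' @examples
#' filter_identifications(data.frame(score = c(31, 32, 40)))  # 2 rows
filter_identifications <- function(identifications, cutoff = 32) {
  if (!"score" %in% names(identifications)) {
    stop("identification table lacks a 'score' column")
  }
  out <- identifications[identifications$score >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate homogeneity by Manhattan distance
#'
#' For every key (protein accession or peptide) present in all replicates,
#' computes the pairwise Manhattan distance between replicates in the
#' two-dimensional space of identification score and abundance index
#' (emPAI/PAI): `d(a, b) = |score_a - score_b| + |abund_a - abund_b|`.
#' Because the two dimensions live on incomparable scales, each dimension
#' is by default divided by its pooled standard deviation before the
#' distance is taken (`mode = "raw"` skips this). Keys absent from any
#' replicate are excluded and listed.
#'
#' @param replicates list of >= 2 data.frames, each with columns `key` (or
#'   `accession`), `score` and `abundance` (or `pai` / `empai`).
#' @param mode `"standardized"` (default) or `"raw"`.
#' @param flag_threshold per-key minimum pairwise distance above which the
#'   key is flagged heterogeneous; the default flags keys above the batch
#'   mean + 2 standard deviations of the per-key minima.
#' @return List with `distances` (key, replicate pair, distance),
#'   `per_key` (key, min/max/mean distance, heterogeneous flag), `summary`
#'   (min/max/mean over all pairs) and `excluded_keys`.
#' @export
manhattan_homogeneity <- function(replicates, mode = c("standardized", "raw"),
                                  flag_threshold = NULL) {
  mode <- match.arg(mode)
  if (length(replicates) < 2L) stop("at least two replicates are required")
  canon <- function(df) {
    key <- if ("key" %in% names(df)) df$key else df$accession
    abund <- if ("abundance" %in% names(df)) df$abundance
      else if ("empai" %in% names(df)) df$empai else df$pai
    if (is.null(key) || is.null(abund) || is.null(df$score)) {
      stop("each replicate needs key/accession, score and abundance (empai/pai) columns")
    }
    data.frame(key = key, score = df$score, abundance = abund,
               stringsAsFactors = FALSE)
  }
  reps <- lapply(replicates, canon)
  common <- Reduce(intersect, lapply(reps, `[[`, "key"))
  all_keys <- unique(unlist(lapply(reps, `[[`, "key")))
  excluded <- setdiff(all_keys, common)
  if (length(common) == 0L) {
    stop("no key is present in every replicate")
  }
  pooled <- do.call(rbind, reps)
  scale_score <- if (mode == "standardized") stats::sd(pooled$score) else 1
  scale_abund <- if (mode == "standardized") stats::sd(pooled$abundance) else 1
  if (is.na(scale_score) || scale_score == 0) scale_score <- 1
  if (is.na(scale_abund) || scale_abund == 0) scale_abund <- 1
  pairs <- utils::combn(length(reps), 2L)
  dist_rows <- list()
  for (key in common) {
    pts <- lapply(reps, function(r) r[match(key, r$key), ])
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      d <- abs(pts[[i]]$score - pts[[j]]$score) / scale_score +
           abs(pts[[i]]$abundance - pts[[j]]$abundance) / scale_abund
      dist_rows[[length(dist_rows) + 1L]] <-
        data.frame(key = key, rep_a = i, rep_b = j, distance = d,
                   stringsAsFactors = FALSE)
    }
  }
  distances <- do.call(rbind, dist_rows)
  per_key <- do.call(rbind, lapply(split(distances, distances$key), function(d) {
    data.frame(key = d$key[1],
               min_distance = min(d$distance),
               max_distance = max(d$distance),
               mean_distance = mean(d$distance),
               stringsAsFactors = FALSE)
  }))
  rownames(per_key) <- NULL
  if (is.null(flag_threshold)) {
    mu <- mean(per_key$min_distance)
    sdev <- stats::sd(per_key$min_distance)
    flag_threshold <- mu + 2 * (if (is.na(sdev)) 0 else sdev)
  }
  per_key$heterogeneous <- per_key$min_distance > flag_threshold
  list(distances = distances,
       per_key = per_key,
       summary = c(min = min(distances$distance),
                   max = max(distances$distance),
                   mean = mean(distances$distance)),
       excluded_keys = excluded)
}
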