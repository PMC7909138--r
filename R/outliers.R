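#' Remove outlier scanpaths with a boxplot rule on DTW dissimilarity
#'
#' Scores every subject by the mean DTW distance from their scanpath to all
#' other scanpaths in the set, then applies Tukey fences to the scores:
#' quartiles by linear interpolation (quantile type 7), fences
#' `Q1 - k*IQR` and `Q3 + k*IQR`. Removal is one-sided — only scanpaths
#' *above* the upper fence are dropped, since unusually low dissimilarity
#' indicates conformity with the group, not anomaly. A single pass is made.
#'
#' @param sps A `scanpath_set` with at least 2 scanpaths. With fewer than 3
#'   scanpaths the fences are undefined, so everything is kept with a
#'   warning.
#' @param k Fence multiplier on the interquartile range (default 1.5).
#' @return An object of class `outlier_report`: list with `kept` (a
#'   `scanpath_set`), `removed` (data.frame `subject_id`, `score`), `scores`
#'   (named numeric, all subjects) and `fences` (`lower`, `upper`).
#' @export
remove_outliers <- function(sps, k = 1.5) {
  stopifnot(inherits(sps, "scanpath_set"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` must be a positive scalar")
  n <- n_scanpaths(sps)
  if (n < 2L) stop("outlier removal needs at least 2 scanpaths (aggregation undefined)")
  seqs <- set_xy(sps)
  ids <- subject_ids(sps)
  dmat <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- cpp_dtw_dist(seqs[[i]], seqs[[j]])
    dmat[i, j] <- d; dmat[j, i] <- d
  }
  scores <- rowSums(dmat) / (n - 1L)
  if (n < 3L) {
    warning("fewer than 3 scanpaths: boxplot fences undefined, keeping all")
    return(new_outlier_report(sps, character(0), scores, c(-Inf, Inf), k))
  }
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  drop <- ids[scores > fences["upper"]]
  if (length(drop) >= n - 1L) {
    warning("boxplot rule would leave fewer than 2 scanpaths; keeping all")
    drop <- character(0)
  }
  kept <- scanpath_set(sps$stimulus_id, sps$scanpaths[setdiff(ids, drop)],
                       width = sps$width, height = sps$height)
  new_outlier_report(kept, drop, scores, fences, k)
}

new_outlier_report <- function(kept, drop, scores, fences, k) {
  structure(
    list(kept = kept,
         removed = data.frame(subject_id = drop,
                              score = unname(scores[drop])),
         scores = scores,
         fences = c(lower = unname(fences[1]), upper = unname(fences[2])),
         k = k),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", n_scanpaths(x$kept), " kept, ",
      nrow(x$removed), " removed (k = ", x$k, ")\n", sep = "")
  cat("  score range [", format(min(x$scores), digits = 4), ", ",
      format(max(x$scores), digits = 4), "], upper fence ",
      format(x$fences["upper"], digits = 4), "\n", sep = "")
  if (nrow(x$removed))
    cat("  removed:", paste0(x$removed$subject_id, " (",
        format(x$removed$score, digits = 4), ")", collapse = ", "), "\n")
  invisible(x)
}
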