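#' Pool visit durations by AOI occurrence
#'
#' When analyzing gaze duration, an AOI appearing more than once within a
#' sequence is treated as distinct occurrences, keyed by appearance order:
#' the key of a visit is `(aoi_id, occurrence)` where `occurrence` counts
#' how many times that AOI has appeared so far in the same sequence.
#' Durations are pooled across subjects per key.
#'
#' @param seqs `aoi_sequences` from [to_aoi_sequences()].
#' @return An object of class `occurrence_durations`: list with `values`
#'   (named list, key `"<aoi_id>#<occurrence>"`, each a numeric vector of
#'   pooled durations in ms), `table` (data.frame `aoi_id`, `occurrence`,
#'   `n`, `mean_ms`, `sd_ms`) and `n_subjects`.
#' @export
occurrence_durations <- function(seqs) {
  if (length(seqs) == 0L) stop("no AOI sequences")
  values <- list()
  for (s in seqs) {
    ids <- if (is.data.frame(s)) s$aoi_id else stop("sequences must be data.frames")
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    keys <- paste0(ids, "#", occ)
    for (v in seq_along(keys))
      values[[keys[v]]] <- c(values[[keys[v]]], s$duration_ms[v])
  }
  keys <- names(values)
  split_at <- regexpr("#[0-9]+$", keys)
  tab <- data.frame(
    aoi_id = substr(keys, 1L, split_at - 1L),
    occurrence = as.integer(substring(keys, split_at + 1L)),
    n = lengths(values),
    mean_ms = vapply(values, mean, numeric(1)),
    sd_ms = vapply(values, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                   numeric(1)),
    row.names = NULL
  )
  tab <- tab[order(tab$aoi_id, tab$occurrence), ]
  rownames(tab) <- NULL
  structure(list(values = values, table = tab, n_subjects = length(seqs)),
            class = "occurrence_durations")
}

#' @export
print.occurrence_durations <- function(x, ...) {
  cat("<occurrence_durations> ", nrow(x$table), " (AOI, occurrence) keys over ",
      x$n_subjects, " subjects\n", sep = "")
  print(x$table, digits = 5)
  invisible(x)
}

#' Attach gaze durations to a representative scanpath
#'
#' Walks the representative's visits tracking the running occurrence count
#' per AOI and sets each visit's duration to the average of the pooled
#' durations for its `(aoi_id, occurrence)` key. By default the average is
#' taken over the subjects that actually contain the occurrence
#' (`denominator = "observed"`); `"all-subjects"` divides the pooled sum by
#' the total subject count instead (implicit zero for subjects without the
#' occurrence).
#'
#' A representative occurrence never observed in any individual sequence
#' (possible after CDBA edits) falls back to the statistic over *all*
#' occurrences of that AOI; an AOI never visited at all falls back to the
#' grand mean visit duration. The source of each value is recorded in the
#' `duration_source` column (`"occurrence"`, `"aoi"` or `"grand"`). Visit
#' order and AOI identity are never altered.
#'
#' @param rep A `representative_scanpath`.
#' @param pooled An `occurrence_durations` object.
#' @param stat `"mean"` (default) or `"median"`.
#' @param denominator `"observed"` (default) or `"all-subjects"` (only
#'   meaningful with `stat = "mean"`).
#' @return The `representative_scanpath` with `duration_ms` and
#'   `duration_source` filled in.
#' @export
assign_durations <- function(rep, pooled, stat = c("mean", "median"),
                             denominator = c("observed", "all-subjects")) {
  stopifnot(inherits(rep, "representative_scanpath"),
            inherits(pooled, "occurrence_durations"))
  stat <- match.arg(stat)
  denominator <- match.arg(denominator)
  agg <- function(v) {
    if (denominator == "all-subjects" && stat == "mean")
      return(sum(v) / pooled$n_subjects)
    if (stat == "mean") mean(v) else stats::median(v)
  }
  ids <- rep$visits$aoi_id
  occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  all_by_aoi <- split(unlist(pooled$values, use.names = FALSE),
                      rep(sub("#[0-9]+$", "", names(pooled$values)),
                          lengths(pooled$values)))
  grand <- unlist(pooled$values, use.names = FALSE)
  dur <- numeric(length(ids))
  src <- character(length(ids))
  for (v in seq_along(ids)) {
    key <- paste0(ids[v], "#", occ[v])
    if (!is.null(pooled$values[[key]])) {
      dur[v] <- agg(pooled$values[[key]]); src[v] <- "occurrence"
    } else if (!is.null(all_by_aoi[[ids[v]]])) {
      dur[v] <- agg(all_by_aoi[[ids[v]]]); src[v] <- "aoi"
    } else {
      dur[v] <- mean(grand); src[v] <- "grand"
    }
  }
  rep$visits$duration_ms <- dur
  rep$visits$duration_source <- src
  rep$params$duration_stat <- stat
  rep$params$duration_denominator <- denominator
  rep
}
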