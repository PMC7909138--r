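#' Run the full representative-scanpath pipeline
#'
#' Chains the three stages on each stimulus: (1) preprocessing — boxplot
#' outlier removal on pairwise DTW, density-peaks AOI extraction and
#' random-walk center identification; (2) scanpath aggregation under the
#' contiguity and occurrence constraints by the chosen method; (3) gaze
#' duration analysis attaching per-occurrence average durations to the
#' aggregated scanpath. When the input holds several stimuli each is
#' processed independently; a failure on one stimulus is reported and the
#' others continue.
#'
#' @param x Input: a file path (CSV/JSON, see [read_scanpaths()]), a
#'   `scanpath_set`, or a list of `scanpath_set`s.
#' @param method Aggregation method: `"heuristic"`, `"cdba"` or `"ioc"`.
#' @param n_max Heuristic enumeration depth.
#' @param iqr_k Boxplot fence multiplier.
#' @param d_c,sigma,gamma_mean AOI-extraction controls (see
#'   [extract_aois()]).
#' @param cdba_init,max_iter CDBA controls (see [cdba_aggregate()]).
#' @param duration_stat,duration_denominator Duration controls (see
#'   [assign_durations()]).
#' @param normalize_dtw Report the objective normalized by path length.
#' @param seed Seed recorded in provenance and used by any stochastic
#'   option (`cdba_init = "random"`).
#' @param out Optional directory; when given, each stimulus's
#'   representative is written there as `<stimulus_id>_representative.json`
#'   and the outlier report as `<stimulus_id>_outliers.json`.
#' @return Named list (by stimulus) of pipeline results, class
#'   `gazerep_result`: each element has `representative`, `outliers`
#'   (an `outlier_report`), `aois` (`aoi_model`), `sequences`, `durations`
#'   and `provenance`; failed stimuli carry an `error` element instead.
#' @export
run_pipeline <- function(x, method = c("heuristic", "cdba", "ioc"),
                         n_max = 8L, iqr_k = 1.5, d_c = "auto",
                         sigma = "auto", gamma_mean = "gap",
                         cdba_init = "ioc", max_iter = 50L,
                         duration_stat = "mean",
                         duration_denominator = "observed",
                         normalize_dtw = FALSE, seed = NULL, out = NULL) {
  method <- match.arg(method)
  sets <- if (is.character(x)) read_scanpaths(x)
          else if (inherits(x, "scanpath_set")) stats::setNames(list(x), x$stimulus_id)
          else x
  results <- lapply(sets, function(sps) {
    tryCatch(
      pipeline_one(sps, method, n_max, iqr_k, d_c, sigma, gamma_mean,
                   cdba_init, max_iter, duration_stat, duration_denominator,
                   normalize_dtw, seed, out),
      error = function(e)
        list(stimulus_id = sps$stimulus_id,
             error = conditionMessage(e))
    )
  })
  structure(results, class = "gazerep_result")
}

pipeline_one <- function(sps, method, n_max, iqr_k, d_c, sigma, gamma_mean,
                         cdba_init, max_iter, duration_stat,
                         duration_denominator, normalize_dtw, seed, out) {
  if (n_scanpaths(sps) < 2L)
    stop("stimulus '", sps$stimulus_id, "': aggregation undefined with ",
         n_scanpaths(sps), " scanpath(s)")
  rep_outliers <- remove_outliers(sps, k = iqr_k)
  kept <- rep_outliers$kept
  aois <- extract_aois(kept, d_c = d_c, sigma = sigma, gamma_mean = gamma_mean)
  seqs <- to_aoi_sequences(kept, aois)
  graph <- build_candidate_graph(seqs)
  rep <- switch(method,
    heuristic = heuristic_aggregate(kept, graph, aois, n_max = n_max),
    cdba = cdba_aggregate(kept, graph, aois, seqs, init = cdba_init,
                          max_iter = max_iter, seed = seed),
    ioc = ioc_select(kept, seqs, aois))
  if (normalize_dtw)
    rep$objective <- average_dtw(cbind(x = rep$visits$cx, y = rep$visits$cy),
                                 kept, normalize = TRUE)
  pooled <- occurrence_durations(seqs)
  rep <- assign_durations(rep, pooled, stat = duration_stat,
                          denominator = duration_denominator)
  rep$seed <- seed
  rep$params <- c(rep$params,
                  list(iqr_k = iqr_k, d_c = aois$params$d_c,
                       sigma = aois$params$sigma, gamma_mean = gamma_mean,
                       normalize_dtw = normalize_dtw))
  prov <- list(
    package_version = as.character(utils::packageVersion("gazerep")),
    stimulus_id = sps$stimulus_id,
    n_scanpaths_in = n_scanpaths(sps),
    n_removed = nrow(rep_outliers$removed),
    n_aois = nrow(aois$aois),
    method = method, seed = seed
  )
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_representative(rep, file.path(out, paste0(sps$stimulus_id,
                                                    "_representative.json")))
    jsonlite::write_json(
      list(fences = as.list(rep_outliers$fences),
           scores = as.list(rep_outliers$scores),
           removed = rep_outliers$removed,
           provenance = prov),
      file.path(out, paste0(sps$stimulus_id, "_outliers.json")),
      auto_unbox = TRUE, digits = NA)
  }
  list(stimulus_id = sps$stimulus_id, representative = rep,
       outliers = rep_outliers, aois = aois, sequences = seqs,
       graph = graph, durations = pooled, provenance = prov)
}

#' @export
print.gazerep_result <- function(x, ...) {
  cat("<gazerep_result> ", length(x), " stimulus/stimuli\n", sep = "")
  for (r in x) {
    if (!is.null(r$error)) {
      cat("  '", r$stimulus_id, "': ERROR: ", r$error, "\n", sep = "")
    } else {
      cat("  '", r$stimulus_id, "': ", nrow(r$representative$visits),
          " visits (", r$representative$method, "), objective ",
          format(r$representative$objective, digits = 6),
          ", ", r$provenance$n_removed, " outlier(s) removed, ",
          r$provenance$n_aois, " AOIs\n", sep = "")
    }
  }
  invisible(x)
}
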