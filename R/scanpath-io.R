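#' Read scanpaths from CSV or JSON
#'
#' The CSV layout has one fixation per row with columns `stimulus_id`,
#' `subject_id`, `index`, `x`, `y`, `duration_ms` (header required, UTF-8);
#' one file may hold many stimuli, grouped by `stimulus_id`. The JSON layout
#' holds one stimulus: `{stimulus_id, width, height, scanpaths: [{subject_id,
#' fixations: [{x, y, duration_ms}]}]}`.
#'
#' Fixations are sorted by their `index` within each subject and re-indexed
#' 0..n-1 (0- and 1-based exports are both accepted). Validation errors name
#' the offending record.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by file extension), `"csv"` or `"json"`.
#' @param width,height Stimulus dimensions in pixels for CSV input (the CSV
#'   layout carries none); ignored for JSON.
#' @return A named list of [scanpath_set()] objects, one per stimulus.
#' @export
read_scanpaths <- function(path, format = c("auto", "csv", "json"),
                           width = NA_real_, height = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = \"csv\" or \"json\""))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_scanpaths_csv(path, width, height)
  else read_scanpaths_json(path)
}

read_scanpaths_csv <- function(path, width, height) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("stimulus_id", "subject_id", "index", "x", "y", "duration_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$stimulus_id, df$subject_id, df$index, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (stimulus_id, subject_id, index) record: (",
         df$stimulus_id[dup[1]], ", ", df$subject_id[dup[1]], ", ",
         df$index[dup[1]], ")")
  sets <- lapply(split(df, factor(df$stimulus_id, unique(df$stimulus_id))),
                 function(g) {
    paths <- lapply(split(g, factor(g$subject_id, unique(g$subject_id))),
                    function(s) {
      s <- s[order(s$index), c("x", "y", "duration_ms")]
      s
    })
    scanpath_set(g$stimulus_id[1], paths, width = width, height = height)
  })
  names(sets) <- vapply(sets, `[[`, "", "stimulus_id")
  sets
}

read_scanpaths_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$stimulus_id)) stop("JSON lacks required field 'stimulus_id'")
  if (is.null(obj$scanpaths) || length(obj$scanpaths) == 0L)
    stop("JSON lacks a non-empty 'scanpaths' array")
  paths <- list()
  for (sp in obj$scanpaths) {
    if (is.null(sp$subject_id)) stop("scanpath record lacks 'subject_id'")
    fx <- do.call(rbind, lapply(sp$fixations, function(f)
      data.frame(x = as.numeric(f$x), y = as.numeric(f$y),
                 duration_ms = as.numeric(f$duration_ms))))
    paths[[as.character(sp$subject_id)]] <- fx
  }
  set <- scanpath_set(as.character(obj$stimulus_id), paths,
                      width = if (is.null(obj$width)) NA_real_ else as.numeric(obj$width),
                      height = if (is.null(obj$height)) NA_real_ else as.numeric(obj$height))
  out <- list(set)
  names(out) <- set$stimulus_id
  out
}

#' Write a scanpath set
#'
#' Inverse of [read_scanpaths()]: `format = "json"` writes the single-stimulus
#' JSON layout, `format = "csv"` appends/overwrites the tabular layout (one
#' fixation per row).
#'
#' @param sps A `scanpath_set`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_scanpaths <- function(sps, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(sps, "scanpath_set"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), csv = "csv", json = "json",
                     stop("cannot infer format for '", path, "'"))
  if (format == "csv") {
    df <- pool_fixations(sps)
    df <- cbind(stimulus_id = sps$stimulus_id, df)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      stimulus_id = sps$stimulus_id,
      width = if (is.finite(sps$width)) sps$width else NULL,
      height = if (is.finite(sps$height)) sps$height else NULL,
      scanpaths = lapply(names(sps$scanpaths), function(id) {
        fx <- sps$scanpaths[[id]]
        list(subject_id = id,
             fixations = lapply(seq_len(nrow(fx)), function(i)
               list(x = fx$x[i], y = fx$y[i], duration_ms = fx$duration_ms[i])))
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Write a representative scanpath to JSON
#'
#' The output records the ordered AOI visits (id, center, mean duration), the
#' average-DTW objective, and provenance: the method name, its parameter
#' record and the seed (when one was used).
#'
#' @param rep A `representative_scanpath` (see [heuristic_aggregate()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_representative <- function(rep, path) {
  stopifnot(inherits(rep, "representative_scanpath"))
  if (nrow(rep$visits) == 0L) stop("representative scanpath has no visits")
  v <- rep$visits
  obj <- list(
    stimulus_id = rep$stimulus_id,
    method = rep$method,
    params = rep$params,
    seed = rep$seed,
    objective_dtw = rep$objective,
    visits = lapply(seq_len(nrow(v)), function(i)
      list(aoi_id = v$aoi_id[i], cx = v$cx[i], cy = v$cy[i],
           duration_ms = v$duration_ms[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a representative scanpath written by [write_representative()]
#'
#' @param path Path to the JSON file.
#' @return A `representative_scanpath`.
#' @export
read_representative <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  visits <- do.call(rbind, lapply(obj$visits, function(v)
    data.frame(aoi_id = as.character(v$aoi_id), cx = as.numeric(v$cx),
               cy = as.numeric(v$cy),
               duration_ms = if (is.null(v$duration_ms)) NA_real_
                             else as.numeric(v$duration_ms))))
  new_representative(
    visits = visits,
    objective = as.numeric(obj$objective_dtw),
    method = as.character(obj$method),
    params = obj$params,
    seed = if (is.null(obj$seed)) NULL else obj$seed,
    stimulus_id = if (is.null(obj$stimulus_id)) NA_character_
                  else as.character(obj$stimulus_id)
  )
}
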