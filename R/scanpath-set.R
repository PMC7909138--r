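#' Construct a scanpath set
#'
#' A scanpath set holds all individual scanpaths recorded on one stimulus:
#' one ordered fixation sequence per subject, plus the stimulus dimensions
#' when known. It is the unit every pipeline stage operates on.
#'
#' @param stimulus_id Label of the stimulus (character scalar).
#' @param scanpaths Named list, one element per subject (names are the
#'   subject ids). Each element is a data.frame with columns `x`, `y`
#'   (pixels, origin top-left, y downward) and `duration_ms` (> 0), one row
#'   per fixation in viewing order.
#' @param width,height Stimulus dimensions in pixels, or `NA` when unknown.
#'   When given, fixation coordinates are validated against them.
#'
#' @return An object of class `scanpath_set`.
#' @export
#' @examples
#' sp <- data.frame(x = c(10, 50), y = c(20, 60), duration_ms = c(150, 200))
#' scanpath_set("img1", list(s1 = sp, s2 = sp + 5))
scanpath_set <- function(stimulus_id, scanpaths, width = NA_real_, height = NA_real_) {
  stopifnot(is.character(stimulus_id), length(stimulus_id) == 1L)
  if (!is.list(scanpaths) || length(scanpaths) == 0L)
    stop("`scanpaths` must be a non-empty named list of fixation data.frames")
  ids <- names(scanpaths)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every scanpath must be named by its subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject_id in scanpath set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  scanpaths <- lapply(ids, function(id) {
    fx <- as.data.frame(scanpaths[[id]])
    validate_fixations(fx, subject_id = id, width = width, height = height)
  })
  names(scanpaths) <- ids
  structure(
    list(stimulus_id = stimulus_id, width = as.numeric(width),
         height = as.numeric(height), scanpaths = scanpaths),
    class = "scanpath_set"
  )
}

validate_fixations <- function(fx, subject_id, width = NA, height = NA) {
  need <- c("x", "y", "duration_ms")
  miss <- setdiff(need, names(fx))
  if (length(miss))
    stop("scanpath of subject '", subject_id, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(fx) == 0L)
    stop("scanpath of subject '", subject_id, "' is empty")
  for (col in need) fx[[col]] <- as.numeric(fx[[col]])
  bad <- which(!is.finite(fx$x) | !is.finite(fx$y) | !is.finite(fx$duration_ms))
  if (length(bad))
    stop("subject '", subject_id, "', fixation ", bad[1] - 1L,
         ": non-finite value")
  bad <- which(fx$duration_ms <= 0)
  if (length(bad))
    stop("subject '", subject_id, "', fixation ", bad[1] - 1L,
         ": duration_ms must be > 0 (got ", fx$duration_ms[bad[1]], ")")
  if (is.finite(width) && is.finite(height)) {
    bad <- which(fx$x < 0 | fx$y < 0 | fx$x > width | fx$y > height)
    if (length(bad))
      stop("subject '", subject_id, "', fixation ", bad[1] - 1L,
           ": coordinates (", fx$x[bad[1]], ", ", fx$y[bad[1]],
           ") outside stimulus ", width, "x", height)
  }
  fx$index <- seq_len(nrow(fx)) - 1L
  rownames(fx) <- NULL
  fx[c("index", "x", "y", "duration_ms")]
}

#' @export
print.scanpath_set <- function(x, ...) {
  nfix <- vapply(x$scanpaths, nrow, integer(1))
  dims <- if (is.finite(x$width)) paste0(x$width, "x", x$height, " px") else "unknown size"
  cat("<scanpath_set> stimulus '", x$stimulus_id, "' (", dims, ")\n", sep = "")
  cat("  ", length(x$scanpaths), " scanpaths, ", sum(nfix),
      " fixations (", min(nfix), "-", max(nfix), " per subject)\n", sep = "")
  invisible(x)
}

#' Number of scanpaths in a set
#' @param x A `scanpath_set`.
#' @export
n_scanpaths <- function(x) {
  stopifnot(inherits(x, "scanpath_set"))
  length(x$scanpaths)
}

#' Subject ids of a scanpath set
#' @param x A `scanpath_set`.
#' @export
subject_ids <- function(x) {
  stopifnot(inherits(x, "scanpath_set"))
  names(x$scanpaths)
}

#' Pool all fixations of a set into one table
#'
#' @param x A `scanpath_set`.
#' @return A data.frame with columns `subject_id`, `index`, `x`, `y`,
#'   `duration_ms`, one row per fixation, subjects in set order.
#' @export
pool_fixations <- function(x) {
  stopifnot(inherits(x, "scanpath_set"))
  out <- do.call(rbind, lapply(names(x$scanpaths), function(id) {
    fx <- x$scanpaths[[id]]
    cbind(subject_id = id, fx)
  }))
  rownames(out) <- NULL
  out
}

# n x 2 coordinate matrix from a fixation data.frame (or passthrough).
as_xy <- function(s) {
  if (is.matrix(s)) {
    storage.mode(s) <- "double"
    return(s[, 1:2, drop = FALSE])
  }
  if (is.data.frame(s)) return(cbind(x = as.numeric(s$x), y = as.numeric(s$y)))
  stop("cannot interpret object of class ", paste(class(s), collapse = "/"),
       " as a coordinate sequence")
}

# list of n x 2 matrices for every scanpath in a set
set_xy <- function(sps) lapply(sps$scanpaths, as_xy)
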