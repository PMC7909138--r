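#' Dynamic time warping between two fixation sequences
#'
#' Computes the DTW dissimilarity between two coordinate sequences with
#' Euclidean local cost on (x, y): the accumulated cost
#' `D(i, j) = d(a_i, b_j) + min(D(i-1, j), D(i, j-1), D(i-1, j-1))` with
#' `D(0, 0) = 0` and infinite borders. Gaze durations never enter the
#' distance; DTW measures spatial shape only. The distance is the
#' accumulated cost at `(m, n)`, unnormalized by default.
#'
#' The optimal alignment path is recovered by backtracking with the fixed
#' tie order diagonal, then up (advance in A), then left (advance in B), so
#' the alignment used downstream by CDBA is deterministic.
#'
#' @param a,b Coordinate sequences: an `n x 2` matrix, a fixation data.frame
#'   with `x`/`y` columns, or a `scanpath_set` element.
#' @param normalize If `TRUE`, divide the distance by the alignment path
#'   length. Off by default; reported group dissimilarities are accumulated
#'   pixel costs.
#' @return An object of class `dtw_result`: list with `distance`, `matrix`
#'   (the `(m+1) x (n+1)` accumulation grid; row/column 1 are the borders)
#'   and `path` (`k x 2` matrix of 1-based index pairs into `a` and `b`,
#'   from `(1, 1)` to `(m, n)`).
#' @export
#' @examples
#' dtw_scanpaths(cbind(0, 0), cbind(3, 4))$distance  # 5
dtw_scanpaths <- function(a, b, normalize = FALSE) {
  A <- as_xy(a); B <- as_xy(b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("DTW requires non-empty sequences")
  D <- cpp_dtw_matrix(A, B)
  path <- dtw_backtrack(D)
  dist <- D[nrow(D), ncol(D)]
  if (normalize) dist <- dist / nrow(path)
  structure(list(distance = dist, matrix = D, path = path,
                 normalized = normalize),
            class = "dtw_result")
}

# Backtrack from (m, n) to (1, 1) through the accumulation grid.
# Tie order: diagonal > up > left.
dtw_backtrack <- function(D) {
  i <- nrow(D) - 1L; j <- ncol(D) - 1L
  path <- matrix(NA_integer_, i + j, 2L)
  k <- 0L
  while (i >= 1L && j >= 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    # grid indices are offset by 1 (border row/col)
    diag <- D[i, j]; up <- D[i, j + 1L]; left <- D[i + 1L, j]
    best <- min(diag, up, left)
    if (diag <= best) { i <- i - 1L; j <- j - 1L }
    else if (up <= best) i <- i - 1L
    else j <- j - 1L
  }
  path[k:1, , drop = FALSE]
}

#' @export
print.dtw_result <- function(x, ...) {
  cat("<dtw_result> distance ", format(x$distance), " (",
      nrow(x$matrix) - 1L, " x ", ncol(x$matrix) - 1L, " points, path length ",
      nrow(x$path), if (x$normalized) ", normalized" else "", ")\n", sep = "")
  invisible(x)
}

#' Average DTW dissimilarity of a candidate sequence to a scanpath set
#'
#' The aggregation objective: the arithmetic mean of the DTW distances from
#' `candidate` to every individual scanpath in the set. The representative
#' scanpath is the constraint-valid candidate minimizing this quantity.
#'
#' @param candidate Coordinate sequence (matrix or fixation data.frame).
#' @param sps A `scanpath_set`, or a list of coordinate sequences.
#' @param normalize Divide each pairwise distance by its path length.
#' @return Non-negative scalar (pixels).
#' @export
average_dtw <- function(candidate, sps, normalize = FALSE) {
  cand <- as_xy(candidate)
  if (nrow(cand) == 0L) stop("candidate sequence is empty")
  seqs <- if (inherits(sps, "scanpath_set")) set_xy(sps) else lapply(sps, as_xy)
  if (length(seqs) == 0L) stop("scanpath set is empty")
  if (!normalize) return(cpp_avg_dtw(cand, seqs))
  mean(vapply(seqs, function(s) dtw_scanpaths(cand, s, normalize = TRUE)$distance,
              numeric(1)))
}
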