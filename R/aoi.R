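#' Density-peaks statistics for pooled fixations
#'
#' For every fixation computes the local density
#' `rho_i = sum_{j != i} exp(-(d_ij / d_c)^2)` (Gaussian kernel) and the
#' separation `delta_i`, the distance to the nearest fixation of higher
#' density; the global density maximum takes `delta = max_j d_ij`. The
#' exemplar score is `gamma = rho * delta`: cluster exemplars are dense
#' *and* far from anything denser. Density ties are broken by fixation
#' enumeration order (the earlier fixation counts as denser), which makes
#' `delta` and the cluster assignment deterministic.
#'
#' @param points Pooled fixations: an `n x 2` matrix or a data.frame with
#'   `x`/`y` columns (see [pool_fixations()]); `n >= 2`.
#' @param d_c Kernel cutoff distance in pixels, or `"auto"`: the 2nd
#'   percentile of all pairwise distances (rule of thumb of the original
#'   density-peaks method). When every pairwise distance is zero the points
#'   are fully degenerate and a unit cutoff is used (all `gamma` are then 0
#'   and a single AOI results downstream).
#' @return An object of class `density_peaks`: list with `rho`, `delta`,
#'   `gamma`, `nneigh` (index of the nearest higher-density fixation, `NA`
#'   for the density maximum), `d_c`, and the input coordinates `xy`.
#' @export
compute_density_peaks <- function(points, d_c = "auto") {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n < 2L) stop("density-peaks clustering needs at least 2 fixations")
  dvec <- stats::dist(xy)
  if (identical(d_c, "auto")) {
    pos <- dvec[dvec > 0]
    d_c <- if (length(pos)) max(stats::quantile(dvec, 0.02, type = 7, names = FALSE),
                                min(pos)) else 1
  }
  if (!is.numeric(d_c) || d_c <= 0) stop("`d_c` must be a positive distance or \"auto\"")
  dmat <- as.matrix(dvec)
  rho <- rowSums(exp(-(dmat / d_c)^2)) - 1  # subtract the j == i term
  ord <- order(-rho, seq_len(n))            # ties: earlier fixation is denser
  delta <- numeric(n)
  nneigh <- rep(NA_integer_, n)
  delta[ord[1]] <- max(dmat[ord[1], ])
  for (k in seq2(2L, n)) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1L)]
    j <- higher[which.min(dmat[i, higher])]
    delta[i] <- dmat[i, j]
    nneigh[i] <- j
  }
  structure(list(rho = rho, delta = delta, gamma = rho * delta,
                 nneigh = nneigh, d_c = d_c, xy = xy),
            class = "density_peaks")
}

seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

#' @export
print.density_peaks <- function(x, ...) {
  cat("<density_peaks> ", nrow(x$xy), " fixations, d_c = ",
      format(x$d_c, digits = 4), "\n", sep = "")
  cat("  gamma: max ", format(max(x$gamma), digits = 4), ", median ",
      format(stats::median(x$gamma), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Select cluster exemplars by a gamma threshold
#'
#' The number of AOIs is decided by thresholding the exemplar scores
#' `gamma = rho * delta`: fixations with `gamma` strictly above the
#' threshold become exemplars, one AOI each. The threshold is a weighted
#' geometric mean of the scores that puts more emphasis on larger `gamma`
#' than the plain geometric mean, and so yields fewer, less overlapping
#' clusters.
#'
#' The default weighting (`"gap"`) concentrates the weight on the two
#' scores flanking the spectrum's exemplar/tail boundary, so the threshold
#' is the geometric mean `sqrt(g_K * g_(K+1))` of the scores around the
#' cut. The cut index is located on whichever spectrum shows it most
#' sharply: when the separations `delta` are supplied (as [extract_aois()]
#' does), the widest multiplicative gap of the ordered `delta` spectrum —
#' cluster peaks have `delta` at the between-cluster scale while everything
#' else sits at the within-cluster neighbor spacing, so this gap is
#' structurally wide however many clusters there are and however unevenly
#' occupied — otherwise the widest multiplicative gap of the `gamma`
#' spectrum itself, restricted to splits above the plain geometric mean.
#' `"self-weighted"` (weights = `gamma` itself), `"geometric"` and
#' `"arithmetic"` are offered as empirical alternatives.
#'
#' @param gamma Non-negative exemplar scores (any order).
#' @param method `"gap"` (default), `"self-weighted"`, `"geometric"` or
#'   `"arithmetic"`.
#' @param delta Optional per-fixation separations (same order as `gamma`),
#'   used by `"gap"` to locate the exemplar/tail boundary.
#' @return List with `threshold`, `exemplars` (indices into `gamma`,
#'   ordered by decreasing score) and `method`. When no score strictly
#'   exceeds the threshold (all scores equal, e.g. fully degenerate input)
#'   a single exemplar — the score maximum — is returned with a warning.
#' @export
select_exemplars <- function(gamma, method = c("gap", "self-weighted", "geometric", "arithmetic"),
                             delta = NULL) {
  method <- match.arg(method)
  if (any(gamma < 0)) stop("gamma scores must be non-negative")
  if (!is.null(delta)) stopifnot(length(delta) == length(gamma))
  g <- gamma[gamma > 0]
  threshold <- if (length(g) == 0L) 0 else switch(method,
    "gap"           = gap_threshold(g, delta),
    "self-weighted" = exp(sum(g * log(g)) / sum(g)),
    "geometric"     = exp(mean(log(g))),
    "arithmetic"    = mean(gamma))
  ex <- which(gamma > threshold)
  if (length(ex) == 0L) {
    warning("no gamma strictly exceeds the threshold; falling back to a single exemplar")
    ex <- which.max(gamma)
  }
  ex <- ex[order(-gamma[ex], ex)]
  list(threshold = threshold, exemplars = ex, method = method)
}

# Geometric mean of the two gamma values flanking the exemplar/tail
# boundary. The cut index comes from the widest log-gap of a spectrum,
# restricted to splits whose lower flank is >= the spectrum's plain
# geometric mean (which keeps near-zero tail values from producing huge
# relative gaps). delta, when available, locates the cut more sharply than
# gamma: peak delta sits at the between-cluster scale, tail delta at the
# within-cluster neighbor spacing, while gamma also varies between peaks
# with cluster occupancy.
gap_threshold <- function(g, delta = NULL) {
  gs <- sort(g, decreasing = TRUE)
  if (length(gs) == 1L) return(gs)
  k <- NULL
  if (!is.null(delta)) {
    d <- sort(delta[delta > 0], decreasing = TRUE)
    if (length(d) >= 2L) {
      # coincident duplicates carry delta 0; represent that mass by one
      # pseudo-tail entry so the boundary above it remains visible
      if (any(delta == 0)) d <- c(d, d[length(d)] / 10)
      k <- widest_gap_index(d)
    }
  }
  if (is.null(k)) k <- widest_gap_index(gs)
  if (k >= length(gs)) return(0)  # every positive-score fixation sticks out
  sqrt(gs[k] * gs[k + 1L])
}

# index of the widest log-gap in a decreasing positive spectrum, among
# splits whose upper flank is at least the spectrum's geometric mean (the
# guard keeps near-zero deep-tail values, whose relative gaps explode,
# from capturing the split)
widest_gap_index <- function(vs) {
  v0 <- exp(mean(log(vs)))
  cand <- which(vs[-length(vs)] >= v0)
  gaps <- log(vs[cand]) - log(vs[cand + 1L])
  cand[which.max(gaps)]
}

#' Assign every fixation to an AOI
#'
#' Non-exemplar fixations inherit, in decreasing density order, the cluster
#' of their nearest neighbor among higher-density fixations (the neighbor
#' that realized `delta`). Exemplars seed the clusters, numbered by
#' decreasing `gamma`.
#'
#' @param peaks A `density_peaks` object.
#' @param exemplars Indices of the exemplar fixations (see
#'   [select_exemplars()]).
#' @return Integer vector of cluster labels `1..K`, one per fixation;
#'   label `k` belongs to the exemplar with the k-th largest `gamma`.
#' @export
assign_clusters <- function(peaks, exemplars) {
  stopifnot(inherits(peaks, "density_peaks"), length(exemplars) >= 1L)
  n <- length(peaks$rho)
  labels <- rep(NA_integer_, n)
  ex <- exemplars[order(-peaks$gamma[exemplars], exemplars)]
  labels[ex] <- seq_along(ex)
  ord <- order(-peaks$rho, seq_len(n))
  for (i in ord) {
    if (!is.na(labels[i])) next
    labels[i] <- labels[peaks$nneigh[i]]
  }
  labels
}

#' Random-walk center of an AOI
#'
#' Locates the AOI center as a density-seeded random-walk equilibrium over
#' the member fixations, which is less sensitive to edge points than the
#' arithmetic mean. Transition probabilities are a Gaussian affinity,
#' `q(j, i) = exp(-D(j, i)^2 / (2 sigma^2))` normalized so each column
#' (moves out of fixation `i`) sums to one; the weight vector starts at the
#' within-AOI-normalized densities `w` and is iterated `l <- Q l`
#' (renormalized) to its fixed point; the iteration is accelerated by
#' operator squaring so it converges even when a small `sigma` makes the
#' chain's spectral gap vanish. The center is the `l`-weighted mean of the
#' member coordinates.
#'
#' @param xy Member coordinates, `n x 2` matrix or data.frame.
#' @param rho Member local densities (same length); used as the initial
#'   weights. Defaults to uniform.
#' @param sigma Gaussian bandwidth in pixels (> 0); it shifts the center
#'   distribution only subtly and defaults to the clustering cutoff `d_c`
#'   in [extract_aois()].
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Iteration cap.
#' @return List with `center` (length-2 numeric), `weights` (the converged
#'   `l`, summing to 1), `iterations` and `converged`.
#' @export
random_walk_center <- function(xy, rho = NULL, sigma, tol = 1e-8, max_iter = 1000L) {
  xy <- as_xy(xy)
  n <- nrow(xy)
  if (n == 0L) stop("AOI has no member fixations")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a positive bandwidth in pixels")
  if (is.null(rho)) rho <- rep(1, n)
  stopifnot(length(rho) == n, all(rho >= 0))
  if (n == 1L)
    return(list(center = c(x = xy[1, 1], y = xy[1, 2]),
                weights = 1, iterations = 0L, converged = TRUE))
  D2 <- as.matrix(stats::dist(xy))^2
  Q <- exp(-D2 / (2 * sigma^2))
  Q <- sweep(Q, 2L, colSums(Q), "/")          # column-stochastic
  l <- if (sum(rho) > 0) rho / sum(rho) else rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  # power iteration accelerated by operator squaring: update k applies
  # Q^(2^(k-1)), so a vanishing spectral gap (small sigma) still converges
  # in a handful of updates
  while (iter < max_iter) {
    iter <- iter + 1L
    l_new <- as.vector(Q %*% l)
    l_new <- l_new / sum(l_new)
    if (max(abs(l_new - l)) < tol) { l <- l_new; converged <- TRUE; break }
    l <- l_new
    Q <- Q %*% Q
    Q <- sweep(Q, 2L, colSums(Q), "/")
  }
  list(center = c(x = sum(l * xy[, 1]), y = sum(l * xy[, 2])),
       weights = l, iterations = iter, converged = converged)
}

#' Extract AOIs from a scanpath set
#'
#' Runs the full AOI stage on the pooled fixations of one (outlier-cleaned)
#' scanpath set: density-peaks clustering, gamma-threshold exemplar
#' selection, cluster assignment, and a random-walk center per AOI. AOI ids
#' are `"A01"`, `"A02"`, ... in decreasing exemplar `gamma`.
#'
#' @param sps A `scanpath_set`.
#' @param d_c Cutoff distance in pixels or `"auto"` (see
#'   [compute_density_peaks()]).
#' @param sigma Random-walk bandwidth in pixels or `"auto"` (= the `d_c`
#'   actually used).
#' @param gamma_mean Threshold variant, see [select_exemplars()].
#' @param tol,max_iter Random-walk convergence controls.
#' @return An object of class `aoi_model`: list with `aois` (data.frame
#'   `aoi_id`, `cx`, `cy`, `n_members`, `gamma`), `assignment` (data.frame
#'   `subject_id`, `index`, `aoi_id`, one row per pooled fixation),
#'   `peaks` (the `density_peaks`), `exemplars`, `centers` (matrix with
#'   rownames `aoi_id`) and `params`.
#' @export
extract_aois <- function(sps, d_c = "auto", sigma = "auto",
                         gamma_mean = "gap",
                         tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(sps, "scanpath_set"))
  pooled <- pool_fixations(sps)
  peaks <- compute_density_peaks(pooled[c("x", "y")], d_c = d_c)
  if (identical(sigma, "auto")) sigma <- peaks$d_c
  sel <- select_exemplars(peaks$gamma, method = gamma_mean,
                          delta = peaks$delta)
  labels <- assign_clusters(peaks, sel$exemplars)
  K <- length(sel$exemplars)
  aoi_ids <- sprintf("A%02d", seq_len(K))
  centers <- matrix(NA_real_, K, 2, dimnames = list(aoi_ids, c("x", "y")))
  rw <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    rw[[k]] <- random_walk_center(peaks$xy[idx, , drop = FALSE],
                                  rho = peaks$rho[idx], sigma = sigma,
                                  tol = tol, max_iter = max_iter)
    centers[k, ] <- rw[[k]]$center
  }
  aois <- data.frame(
    aoi_id = aoi_ids,
    cx = centers[, 1], cy = centers[, 2],
    n_members = as.integer(tabulate(labels, K)),
    gamma = peaks$gamma[sel$exemplars],
    row.names = NULL
  )
  assignment <- data.frame(subject_id = pooled$subject_id,
                           index = pooled$index,
                           aoi_id = aoi_ids[labels])
  structure(
    list(aois = aois, assignment = assignment, peaks = peaks,
         exemplars = sel$exemplars, centers = centers, walks = rw,
         params = list(d_c = peaks$d_c, sigma = sigma,
                       gamma_mean = gamma_mean, threshold = sel$threshold,
                       tol = tol, max_iter = max_iter)),
    class = "aoi_model"
  )
}

#' @export
print.aoi_model <- function(x, ...) {
  cat("<aoi_model> ", nrow(x$aois), " AOIs from ", nrow(x$assignment),
      " fixations (d_c = ", format(x$params$d_c, digits = 4),
      ", gamma threshold = ", format(x$params$threshold, digits = 4), ")\n",
      sep = "")
  print(x$aois, digits = 4)
  invisible(x)
}
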