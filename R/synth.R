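#' Configuration for the synthetic scanpath generator
#'
#' Describes a group viewing experiment with known ground truth: K true
#' AOIs on a stimulus, a consensus visit order (the template), per-subject
#' deviations (visit skips and adjacent swaps), isotropic Gaussian fixation
#' scatter around each AOI center, lognormal visit durations, and
#' optionally a number of far-outlier subjects whose whole scanpath is a
#' rigidly translated template copy.
#'
#' Defaults emulate the free-viewing conditions typical of saliency
#' datasets: an 800 x 600 px stimulus viewed by 15 subjects, fixation
#' scatter of 15 px around each center, mean visit duration 250 ms
#' (right-skewed), and mild idiosyncrasy (10% skip and swap rates).
#'
#' @param width,height Stimulus size in pixels.
#' @param K Number of true AOIs.
#' @param centers `K x 2` matrix of true centers, or `NULL` to sample them
#'   with pairwise separation at least `8 * spread` (guaranteeing
#'   recoverability) inside an inner margin of the frame.
#' @param spread Within-AOI fixation standard deviation (pixels); may be 0
#'   for the noise-free limit (requires explicit `centers` when 0 and
#'   `K > 1` only in the sense that separation checks still apply).
#' @param template Consensus AOI visit order: integer vector of center
#'   indices (repeats allowed, no immediate repeats), or `NULL` for a
#'   random no-immediate-repeat walk of length `max(template_len, K)` that
#'   visits every AOI at least once (so the planted layout is recoverable
#'   from the fixations).
#' @param template_len Length of the auto-generated template (floored at
#'   `K`).
#' @param n_subjects Number of conforming subjects.
#' @param p_skip Per-visit deletion probability.
#' @param p_swap Per-adjacent-pair transposition probability (single left
#'   to right pass).
#' @param duration_mean,duration_sd Mean and sd of the lognormal visit
#'   duration (ms).
#' @param fix_per_visit Integer range of fixations drawn per visit
#'   (uniform), default 1:3; the visit duration is split across them.
#' @param outliers Count of injected outlier subjects.
#' @param seed Integer RNG seed; the same config and seed reproduce the
#'   set bit for bit.
#' @return A `synth_config` list.
#' @export
synth_config <- function(width = 800, height = 600, K = 3, centers = NULL,
                         spread = 15, template = NULL, template_len = 5L,
                         n_subjects = 15L, p_skip = 0.1, p_swap = 0.1,
                         duration_mean = 250, duration_sd = 100,
                         fix_per_visit = 1:3, outliers = 0L, seed = 1L) {
  stopifnot(width > 0, height > 0, K >= 1, spread >= 0,
            p_skip >= 0, p_skip <= 1, p_swap >= 0, p_swap <= 1,
            n_subjects >= 1, outliers >= 0,
            duration_mean > 0, duration_sd >= 0,
            all(fix_per_visit >= 1))
  if (!is.null(centers)) {
    centers <- as_xy(centers)
    if (nrow(centers) != K) stop("`centers` must have K rows")
  }
  if (!is.null(template)) {
    template <- as.integer(template)
    if (any(template < 1 | template > K)) stop("template indices must be in 1..K")
    if (length(template) >= 2L && any(diff(template) == 0))
      stop("template may not repeat an AOI immediately")
  }
  structure(list(width = width, height = height, K = as.integer(K),
                 centers = centers, spread = spread, template = template,
                 template_len = as.integer(template_len),
                 n_subjects = as.integer(n_subjects),
                 p_skip = p_skip, p_swap = p_swap,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 fix_per_visit = as.integer(fix_per_visit),
                 outliers = as.integer(outliers), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic scanpath set with known ground truth
#'
#' Per conforming subject: copy the template, delete each visit with
#' probability `p_skip` (at least one visit always survives), transpose
#' adjacent visits with probability `p_swap` in one pass, then realize each
#' visit as 1-3 fixations drawn from an isotropic Gaussian at the visit's
#' true center with sd `spread`, with a lognormal visit duration split
#' across the fixations. Outlier subjects are an unedited template copy
#' rigidly translated toward the frame corner farthest from the AOI
#' layout; the translation magnitude must reach at least `10 * spread`
#' (else the configuration is rejected as infeasible).
#'
#' @param config A [synth_config()].
#' @return List with `set` (a `scanpath_set`) and `truth`: `centers` (K x 2
#'   matrix), `template` (integer center indices), `sequences` (per-subject
#'   realized center-index visit orders, consecutive duplicates merged),
#'   `outlier_subjects` (character ids) and `offsets` (per-outlier
#'   translation vectors).
#' @export
generate_scanpaths <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  cfg <- config
  margin <- max(3 * cfg$spread, 0.05 * min(cfg$width, cfg$height))
  if (cfg$outliers > 0) margin <- margin + 10 * cfg$spread
  centers <- cfg$centers
  if (is.null(centers))
    centers <- sample_separated_centers(cfg$K, cfg$width, cfg$height,
                                        margin, 8 * cfg$spread)
  template <- cfg$template
  if (is.null(template)) template <- random_template(cfg$K, cfg$template_len)

  meanlog <- log(cfg$duration_mean) -
    0.5 * log(1 + (cfg$duration_sd / cfg$duration_mean)^2)
  sdlog <- sqrt(log(1 + (cfg$duration_sd / cfg$duration_mean)^2))

  realize <- function(visit_idx, offset = c(0, 0)) {
    rows <- lapply(visit_idx, function(k) {
      nf <- if (length(cfg$fix_per_visit) == 1L) cfg$fix_per_visit
            else sample(cfg$fix_per_visit, 1L)
      pts <- matrix(rnorm(2 * nf, sd = cfg$spread), nf, 2)
      pts <- sweep(pts, 2L, centers[k, ] + offset, "+")
      vdur <- if (cfg$duration_sd == 0) cfg$duration_mean
              else rlnorm(1, meanlog, sdlog)
      prop <- if (nf == 1L) 1 else { u <- runif(nf); u / sum(u) }
      data.frame(x = pts[, 1], y = pts[, 2], duration_ms = vdur * prop)
    })
    fx <- do.call(rbind, rows)
    fx$x <- pmin(pmax(fx$x, 0), cfg$width)
    fx$y <- pmin(pmax(fx$y, 0), cfg$height)
    fx
  }

  sequences <- list()
  paths <- list()
  for (s in seq_len(cfg$n_subjects)) {
    vis <- template
    if (cfg$p_skip > 0 && length(vis) > 1L) {
      keep <- runif(length(vis)) >= cfg$p_skip
      if (!any(keep)) keep[sample.int(length(vis), 1L)] <- TRUE
      vis <- vis[keep]
    }
    if (cfg$p_swap > 0 && length(vis) > 1L) {
      for (t in seq_len(length(vis) - 1L))
        if (runif(1) < cfg$p_swap) vis[c(t, t + 1L)] <- vis[c(t + 1L, t)]
    }
    id <- sprintf("s%02d", s)
    sequences[[id]] <- merge_consecutive(vis)
    paths[[id]] <- realize(vis)
  }

  outlier_ids <- character(0)
  offsets <- list()
  if (cfg$outliers > 0) {
    diam <- if (cfg$K > 1) max(stats::dist(centers)) else 0
    for (o in seq_len(cfg$outliers)) {
      id <- sprintf("out%02d", o)
      fx <- realize(template)
      off <- corner_translation(fx, cfg$width, cfg$height, pad = 1)
      if (sqrt(sum(off^2)) < 10 * cfg$spread)
        stop("infeasible config: outlier translation (",
             round(sqrt(sum(off^2)), 1), " px) below 10 * spread")
      fx$x <- fx$x + off[1]; fx$y <- fx$y + off[2]
      paths[[id]] <- fx
      sequences[[id]] <- merge_consecutive(template)
      outlier_ids <- c(outlier_ids, id)
      offsets[[id]] <- off
    }
  }

  set <- scanpath_set(sprintf("synth_seed%d", cfg$seed), paths,
                      width = cfg$width, height = cfg$height)
  list(set = set,
       truth = list(centers = centers, template = template,
                    sequences = sequences, outlier_subjects = outlier_ids,
                    offsets = offsets, config = cfg))
}

# rejection-sample K centers with pairwise separation >= min_sep inside the
# margin-inset frame
sample_separated_centers <- function(K, width, height, margin, min_sep) {
  lo <- c(margin, margin); hi <- c(width - margin, height - margin)
  if (any(hi <= lo)) stop("infeasible config: margin exceeds frame")
  for (attempt in seq_len(2000L)) {
    pts <- cbind(runif(K, lo[1], hi[1]), runif(K, lo[2], hi[2]))
    if (K == 1L || min(stats::dist(pts)) >= min_sep) return(pts)
  }
  stop("infeasible config: cannot place ", K,
       " centers with separation ", min_sep, " in the frame")
}

# consensus order covering every AOI: a random permutation of 1..K extended
# to the requested length by no-immediate-repeat draws
random_template <- function(K, len) {
  if (K == 1L) return(1L)
  out <- sample.int(K)
  while (length(out) < len) {
    pool <- setdiff(seq_len(K), out[length(out)])
    out <- c(out, pool[sample.int(length(pool), 1L)])
  }
  out
}

merge_consecutive <- function(v) v[c(TRUE, diff(v) != 0)]

# rigid translation moving the fixation bounding box into the frame corner
# farthest from its centroid
corner_translation <- function(fx, width, height, pad = 1) {
  cx <- mean(fx$x); cy <- mean(fx$y)
  corners <- rbind(c(0, 0), c(width, 0), c(0, height), c(width, height))
  far <- corners[which.max((corners[, 1] - cx)^2 + (corners[, 2] - cy)^2), ]
  tx <- if (far[1] == 0) pad - min(fx$x) else (width - pad) - max(fx$x)
  ty <- if (far[2] == 0) pad - min(fx$y) else (height - pad) - max(fx$y)
  c(tx, ty)
}
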