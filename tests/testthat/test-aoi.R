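two_cluster_points <- function(sep = 400, n = 10, sd = 3, seed = 9) {
  set.seed(seed)
  rbind(cbind(rnorm(n, 100, sd), rnorm(n, 100, sd)),
        cbind(rnorm(n, 100 + sep, sd), rnorm(n, 100, sd)))
}

test_that("two well-separated clusters put their density maxima on top of gamma", {
  xy <- two_cluster_points()
  pk <- compute_density_peaks(xy)
  expect_equal(pk$gamma, pk$rho * pk$delta)
  top2 <- order(-pk$gamma)[1:2]
  expect_setequal((top2 > 10), c(TRUE, FALSE))      # one per cluster
  # each top fixation is its cluster's density maximum
  expect_equal(sort(top2), unname(sort(c(which.max(pk$rho[1:10]),
                                         10 + which.max(pk$rho[11:20])))))
  sel <- select_exemplars(pk$gamma)
  expect_length(sel$exemplars, 2)
  labels <- assign_clusters(pk, sel$exemplars)
  expect_equal(length(unique(labels)), 2)
  expect_equal(length(unique(labels[1:10])), 1)     # purity 100%
  expect_equal(length(unique(labels[11:20])), 1)
  expect_false(labels[1] == labels[11])
})

test_that("gamma threshold variants behave as specified", {
  expect_equal(suppressWarnings(
    select_exemplars(base::rep(3.5, 6), "geometric"))$threshold, 3.5)
  expect_warning(sel <- select_exemplars(base::rep(3.5, 6)), "single exemplar")
  expect_length(sel$exemplars, 1)
  g <- c(100, 1, 1, 1)
  sw <- select_exemplars(g, "self-weighted")$threshold
  geo <- select_exemplars(g, "geometric")$threshold
  expect_gt(sw, geo)                                # emphasis on large gamma
  expect_equal(geo, exp(mean(log(g))), tolerance = 1e-12)
  expect_equal(sw, exp(sum(g * log(g)) / sum(g)), tolerance = 1e-12)
  expect_error(select_exemplars(c(-1, 2)), "non-negative")
})

test_that("coincident fixations collapse to one AOI", {
  xy <- matrix(5, 7, 2)
  pk <- compute_density_peaks(xy)
  expect_warning(sel <- select_exemplars(pk$gamma), "single exemplar")
  labels <- assign_clusters(pk, sel$exemplars)
  expect_equal(unique(labels), 1L)
})

test_that("random-walk center handles the symmetric and degenerate cases", {
  expect_equal(unname(random_walk_center(cbind(7, 9), sigma = 10)$center), c(7, 9))
  sq <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  rw <- random_walk_center(sq, rho = base::rep(1, 4), sigma = 5)
  expect_true(rw$converged)
  expect_equal(unname(rw$center), c(5, 5), tolerance = 1e-6)
  expect_equal(sum(rw$weights), 1, tolerance = 1e-12)
  expect_error(random_walk_center(sq, sigma = 0), "positive")
})

test_that("random-walk center resists an edge point better than the mean", {
  set.seed(21)
  core <- cbind(rnorm(20, 50, 4), rnorm(20, 50, 4))
  edge <- c(50 + 40 * 10 / 10, 50)                  # 10x core radius away
  pts <- rbind(core, matrix(edge, 1))
  pk <- compute_density_peaks(pts)
  rw <- random_walk_center(pts, rho = pk$rho, sigma = pk$d_c)
  core_centroid <- colMeans(core)
  d_rw <- sqrt(sum((rw$center - core_centroid)^2))
  d_mean <- sqrt(sum((colMeans(pts) - core_centroid)^2))
  expect_lt(d_rw, d_mean)
  expect_true(rw$converged)
})

test_that("AOI extraction is equivariant under rigid translation", {
  g <- generate_scanpaths(synth_config(K = 3, n_subjects = 8, seed = 14))
  sps <- g$set
  m1 <- extract_aois(sps)
  shifted <- lapply(sps$scanpaths, function(fx) { fx$x <- fx$x + 50; fx$y <- fx$y + 20; fx })
  m2 <- extract_aois(scanpath_set(sps$stimulus_id, shifted))
  expect_identical(m1$assignment$aoi_id, m2$assignment$aoi_id)
  expect_equal(unname(m2$centers), unname(sweep(m1$centers, 2, c(50, 20), "+")),
               tolerance = 1e-6)
})

test_that("AOI extraction recovers planted clusters and their centers", {
  for (seed in 1:5) {
    K <- 1 + (seed %% 3) + 1                        # K in 2..4
    g <- generate_scanpaths(synth_config(K = K, n_subjects = 12, seed = seed,
                                         p_skip = 0, p_swap = 0))
    model <- extract_aois(g$set)
    expect_equal(nrow(model$aois), K, info = paste("seed", seed))
    mapping <- match_centers(model, g$truth$centers)
    expect_equal(sort(unique(mapping)), seq_len(K))
    err <- sqrt(rowSums((model$centers - g$truth$centers[mapping, ])^2))
    expect_true(all(err < 0.5 * g$truth$config$spread),
                info = paste("seed", seed))
    # every random walk converged
    expect_true(all(vapply(model$walks, `[[`, TRUE, "converged")))
  }
})
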