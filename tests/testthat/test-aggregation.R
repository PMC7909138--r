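test_that("consecutive same-AOI fixations merge into visits with summed durations", {
  model <- fake_aoi_model(list(A = c(0, 0), B = c(100, 0)),
                          list(s1 = c("A", "A", "B", "B", "A")))
  sps <- scanpath_set("toy", list(
    s1 = fix_df(c(0, 0, 1, 1, 100, 0, 101, 1, 0, 0),
                dur = c(100, 100, 200, 100, 300))))
  seqs <- to_aoi_sequences(sps, model)
  expect_equal(seqs$s1$aoi_id, c("A", "B", "A"))
  expect_equal(seqs$s1$duration_ms, c(200, 300, 300))
  # all fixations in one AOI -> one visit with the total duration
  model1 <- fake_aoi_model(list(A = c(0, 0)), list(s1 = base::rep("A", 4)))
  sps1 <- scanpath_set("toy", list(s1 = fix_df(base::rep(c(0, 0), 4), dur = 50)))
  expect_equal(to_aoi_sequences(sps1, model1)$s1,
               data.frame(aoi_id = "A", duration_ms = 200))
})

test_that("candidate graph reads successors and occurrence maxima off the sequences", {
  g <- build_candidate_graph(list(c("A", "B", "C"), c("A", "C")))
  expect_equal(g$successors$A, c("B", "C"))
  expect_equal(g$successors$B, "C")
  expect_equal(g$successors$C, character(0))        # terminal dead end
  expect_equal(unname(g$max_count[c("A", "B", "C")]), c(1L, 1L, 1L))
  g2 <- build_candidate_graph(list(c("A", "B", "A")))
  expect_equal(unname(g2$max_count["A"]), 2L)
})

test_that("constraint validation flags exactly the stated violations", {
  g <- build_candidate_graph(list(c("A", "B", "C")))
  expect_true(validate_constraints(c("A", "B", "C"), g)$valid)
  v <- validate_constraints(c("A", "C"), g)
  expect_false(v$valid)
  expect_match(v$violations, "\\(A,C\\)")
  v2 <- validate_constraints(c("A", "B", "A"), g)   # needs count(A)=2 and (B,A)
  expect_false(v2$valid)
  expect_true(any(grepl("count\\(A\\)", v2$violations)))
  v3 <- validate_constraints(c("A", "Z"), g)
  expect_true(any(grepl("unknown AOI 'Z'", v3$violations)))
})

test_that("heuristic equals the identical consensus when all subjects agree", {
  centers <- list(A = c(0, 0), B = c(200, 0), C = c(100, 150))
  inst <- toy_instance(base::rep(list(c("A", "B", "C")), 4), centers)
  rep <- heuristic_aggregate(inst$sps, inst$graph, inst$model, n_max = 5)
  expect_equal(rep$visits$aoi_id, c("A", "B", "C"))
  expect_equal(rep$objective, 0)
  expect_true(validate_constraints(rep, inst$graph)$valid)
})

test_that("heuristic matches the independent brute-force optimum on the toy instance", {
  centers <- list(A = c(0, 0), B = c(200, 0), C = c(100, 150))
  seq_list <- list(c("A", "B", "C"), c("A", "C"), c("B", "C"))
  inst <- toy_instance(seq_list, centers)
  cmat <- inst$model$centers
  rep <- heuristic_aggregate(inst$sps, inst$graph, inst$model, n_max = 3)
  oracle <- oracle_best_representative(seq_list, cmat, inst$sps, 3)
  expect_equal(rep$objective, oracle$objective, tolerance = 1e-9)
  expect_identical(rep$visits$aoi_id, oracle$ids)
  # n_max = 1 reduces to the best single AOI center
  rep1 <- heuristic_aggregate(inst$sps, inst$graph, inst$model, n_max = 1)
  singles <- vapply(rownames(cmat), function(a)
    average_dtw(cmat[a, , drop = FALSE], inst$sps), numeric(1))
  expect_equal(rep1$objective, min(singles), tolerance = 1e-12)
})

test_that("heuristic matches brute force on random toy instances", {
  set.seed(91)
  for (i in 1:20) {
    K <- sample(2:4, 1)
    ids <- LETTERS[1:K]
    centers <- lapply(stats::setNames(seq_len(K), ids), function(k)
      runif(2, 0, 300))
    seq_list <- lapply(seq_len(sample(2:4, 1)), function(s) {
      len <- sample(2:4, 1)
      v <- character(len)
      v[1] <- sample(ids, 1)
      for (t in 2:len) v[t] <- sample(setdiff(ids, v[t - 1]), 1)
      v
    })
    inst <- toy_instance(seq_list, centers)
    n_max <- sample(2:5, 1)
    rep <- heuristic_aggregate(inst$sps, inst$graph, inst$model, n_max = n_max)
    oracle <- oracle_best_representative(seq_list, inst$model$centers,
                                         inst$sps, n_max)
    expect_equal(rep$objective, oracle$objective, tolerance = 1e-9,
                 info = paste("instance", i))
    expect_true(validate_constraints(rep, inst$graph)$valid)
  }
})

test_that("heuristic objective is non-increasing in n_max", {
  g <- generate_scanpaths(synth_config(K = 3, n_subjects = 8, seed = 55))
  res <- run_pipeline(g$set, method = "ioc")[[1]]
  obj <- vapply(1:6, function(n)
    heuristic_aggregate(res$outliers$kept, res$graph, res$aois,
                        n_max = n)$objective, numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
})

test_that("IOC picks the member with minimal average DTW, from the member set", {
  centers <- list(A = c(0, 0), B = c(200, 0), C = c(100, 150))
  seq_list <- list(c("A", "B", "C"), c("A", "C"), c("B", "C"))
  inst <- toy_instance(seq_list, centers)
  rep <- ioc_select(inst$sps, inst$seqs, inst$model)
  objs <- vapply(seq_list, function(ids)
    average_dtw(inst$model$centers[ids, , drop = FALSE], inst$sps), numeric(1))
  expect_equal(rep$objective, min(objs), tolerance = 1e-12)
  expect_true(any(vapply(seq_list, identical, TRUE, rep$visits$aoi_id)))
  # single subject: that subject's sequence
  inst1 <- toy_instance(seq_list[2], centers)
  rep1 <- ioc_select(inst1$sps, inst1$seqs, inst1$model)
  expect_identical(rep1$visits$aoi_id, c("A", "C"))
})

test_that("CDBA is a fixed point on unanimous input and at the heuristic optimum", {
  centers <- list(A = c(0, 0), B = c(200, 0), C = c(100, 150))
  inst <- toy_instance(base::rep(list(c("A", "B", "C")), 3), centers)
  rep <- cdba_aggregate(inst$sps, inst$graph, inst$model, inst$seqs)
  expect_identical(rep$visits$aoi_id, c("A", "B", "C"))
  expect_lte(rep$params$iterations, 1)
  # starting from the heuristic optimum, the update changes nothing
  seq_list <- list(c("A", "B", "C"), c("A", "C"), c("B", "C"))
  inst2 <- toy_instance(seq_list, centers)
  h <- heuristic_aggregate(inst2$sps, inst2$graph, inst2$model, n_max = 3)
  c2 <- cdba_aggregate(inst2$sps, inst2$graph, inst2$model, inst2$seqs, init = h)
  expect_identical(c2$visits$aoi_id, h$visits$aoi_id)
  expect_equal(c2$objective, h$objective, tolerance = 1e-12)
})

test_that("objective ordering heuristic <= CDBA <= IOC holds with IOC init", {
  for (seed in c(3, 17, 29)) {
    g <- generate_scanpaths(synth_config(K = 3, n_subjects = 10, seed = seed))
    kept <- remove_outliers(g$set)$kept
    aois <- extract_aois(kept)
    seqs <- to_aoi_sequences(kept, aois)
    graph <- build_candidate_graph(seqs)
    h <- heuristic_aggregate(kept, graph, aois, n_max = 8)
    cd <- cdba_aggregate(kept, graph, aois, seqs, init = "ioc")
    io <- ioc_select(kept, seqs, aois)
    expect_lte(h$objective, cd$objective + 1e-9)
    expect_lte(cd$objective, io$objective + 1e-9)
    expect_true(all(diff(cd$params$objective_trace) <= 1e-9))
    expect_true(validate_constraints(cd, graph)$valid)
    expect_true(validate_constraints(h, graph)$valid)
  }
})

test_that("alternative CDBA initializations stay constraint-valid", {
  g <- generate_scanpaths(synth_config(K = 3, n_subjects = 8, seed = 77))
  kept <- remove_outliers(g$set)$kept
  aois <- extract_aois(kept)
  seqs <- to_aoi_sequences(kept, aois)
  graph <- build_candidate_graph(seqs)
  for (init in c("medoid", "random")) {
    cd <- cdba_aggregate(kept, graph, aois, seqs, init = init, seed = 4)
    expect_true(validate_constraints(cd, graph)$valid)
    expect_true(all(diff(cd$params$objective_trace) <= 1e-9))
  }
})
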