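test_that("CSV with two subjects parses into one set of two scanpaths", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "stimulus_id,subject_id,index,x,y,duration_ms",
    "img1,s1,0,10,20,150", "img1,s1,1,30,40,200", "img1,s1,2,50,60,120",
    "img1,s2,0,12,22,180", "img1,s2,1,33,44,210", "img1,s2,2,55,66,130"), f)
  sets <- read_scanpaths(f)
  expect_length(sets, 1)
  sps <- sets[["img1"]]
  expect_s3_class(sps, "scanpath_set")
  expect_equal(subject_ids(sps), c("s1", "s2"))
  expect_equal(vapply(sps$scanpaths, nrow, integer(1)),
               c(s1 = 3L, s2 = 3L))
  expect_equal(sps$scanpaths$s1$x, c(10, 30, 50))
})

test_that("CSV fixations are sorted by index and 1-based indices are re-based", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "stimulus_id,subject_id,index,x,y,duration_ms",
    "img1,s1,2,50,60,120", "img1,s1,1,30,40,200", "img1,s1,3,70,80,100"), f)
  sps <- read_scanpaths(f)[["img1"]]
  expect_equal(sps$scanpaths$s1$x, c(30, 50, 70))
  expect_equal(sps$scanpaths$s1$index, 0:2)
})

test_that("reader rejects invalid records and names the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stimulus_id,subject_id,index,x,y",
               "img1,s1,0,10,20"), f)
  expect_error(read_scanpaths(f), "duration_ms")
  writeLines(c("stimulus_id,subject_id,index,x,y,duration_ms",
               "img1,s1,0,10,20,0", "img1,s1,1,30,40,100"), f)
  expect_error(read_scanpaths(f), "subject 's1'.*duration_ms must be > 0")
  writeLines(c("stimulus_id,subject_id,index,x,y,duration_ms",
               "img1,s1,0,10,20,100", "img1,s1,0,30,40,100"), f)
  expect_error(read_scanpaths(f), "duplicate.*s1.*0")
  writeLines(c("stimulus_id,subject_id,index,x,y,duration_ms",
               "img1,s1,0,900,20,100"), f)
  expect_error(read_scanpaths(f, width = 800, height = 600),
               "outside stimulus")
})

test_that("scanpath set JSON survives a write/read round trip", {
  sps <- scanpath_set("img7", list(
    a = fix_df(c(10.5, 20.25, 300.125, 400), dur = c(111.5, 222)),
    b = fix_df(c(1, 2, 3, 4, 5, 6), dur = c(10, 20, 30))),
    width = 800, height = 600)
  f <- withr::local_tempfile(fileext = ".json")
  write_scanpaths(sps, f)
  back <- read_scanpaths(f)[["img7"]]
  expect_identical(back$stimulus_id, sps$stimulus_id)
  expect_identical(subject_ids(back), subject_ids(sps))
  expect_equal(back$width, 800)
  for (id in subject_ids(sps)) {
    expect_equal(back$scanpaths[[id]]$x, sps$scanpaths[[id]]$x, tolerance = 1e-9)
    expect_equal(back$scanpaths[[id]]$y, sps$scanpaths[[id]]$y, tolerance = 1e-9)
    expect_equal(back$scanpaths[[id]]$duration_ms,
                 sps$scanpaths[[id]]$duration_ms, tolerance = 1e-9)
  }
})

test_that("CSV round trip preserves a multi-stimulus file", {
  g1 <- generate_scanpaths(synth_config(K = 2, n_subjects = 3, seed = 11))
  g2 <- generate_scanpaths(synth_config(K = 3, n_subjects = 4, seed = 12))
  f <- withr::local_tempfile(fileext = ".csv")
  df1 <- cbind(stimulus_id = "one", pool_fixations(g1$set))
  df2 <- cbind(stimulus_id = "two", pool_fixations(g2$set))
  utils::write.csv(rbind(df1, df2), f, row.names = FALSE, quote = FALSE)
  sets <- read_scanpaths(f)
  expect_named(sets, c("one", "two"))
  expect_equal(n_scanpaths(sets$one), 3)
  expect_equal(n_scanpaths(sets$two), 4)
  expect_equal(sets$two$scanpaths[[2]]$x, g2$set$scanpaths[[2]]$x,
               tolerance = 1e-9)
})

test_that("representative JSON round trip preserves visits and provenance", {
  inst <- toy_instance(list(c("A", "B"), c("A", "B", "A")),
                       list(A = c(0, 0), B = c(100, 0)))
  rep <- heuristic_aggregate(inst$sps, inst$graph, inst$model, n_max = 3)
  rep <- assign_durations(rep, occurrence_durations(inst$seqs))
  f <- withr::local_tempfile(fileext = ".json")
  write_representative(rep, f)
  back <- read_representative(f)
  expect_identical(back$visits$aoi_id, rep$visits$aoi_id)
  expect_equal(back$visits$cx, rep$visits$cx, tolerance = 1e-9)
  expect_equal(back$visits$duration_ms, rep$visits$duration_ms, tolerance = 1e-9)
  expect_equal(back$objective, rep$objective, tolerance = 1e-9)
  expect_identical(back$method, "heuristic")
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(scanpath_set("x", list()), "non-empty")
  expect_error(scanpath_set("x", list(a = fix_df(c(1, 2)),
                                      a = fix_df(c(3, 4)))), "duplicate subject_id")
  inst <- toy_instance(list(c("A", "B"), c("B", "A")),
                       list(A = c(0, 0), B = c(100, 0)))
  rep <- ioc_select(inst$sps, inst$seqs, inst$model)
  rep$visits <- rep$visits[0, ]
  f <- withr::local_tempfile(fileext = ".json")
  expect_error(write_representative(rep, f), "no visits")
})
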