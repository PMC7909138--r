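# Small in-code fixtures shared across test files.

fix_df <- function(xy, dur = 100) {
  xy <- matrix(xy, ncol = 2, byrow = TRUE)
  data.frame(x = xy[, 1], y = xy[, 2],
             duration_ms = base::rep(dur, length.out = nrow(xy)))
}

# scanpath set in which every subject visits the same few anchor points,
# jittered by `jitter` px
toy_set <- function(anchors, n_subjects = 3, jitter = 0, seed = 1,
                    stimulus_id = "toy") {
  set.seed(seed)
  paths <- lapply(seq_len(n_subjects), function(s) {
    xy <- anchors + matrix(rnorm(length(anchors), sd = jitter),
                           nrow(anchors), 2)
    data.frame(x = xy[, 1], y = xy[, 2], duration_ms = 100)
  })
  names(paths) <- sprintf("s%02d", seq_len(n_subjects))
  scanpath_set(stimulus_id, paths)
}

# hand-built aoi_model: centers is a named list aoi_id -> c(x, y);
# assignment_list is a named (by subject) list of per-fixation aoi_id
# vectors, in fixation order
fake_aoi_model <- function(centers, assignment_list) {
  ids <- names(centers)
  cmat <- do.call(rbind, centers)
  rownames(cmat) <- ids
  colnames(cmat) <- c("x", "y")
  assignment <- do.call(rbind, lapply(names(assignment_list), function(s)
    data.frame(subject_id = s,
               index = seq_along(assignment_list[[s]]) - 1L,
               aoi_id = assignment_list[[s]])))
  structure(list(
    aois = data.frame(aoi_id = ids, cx = cmat[, 1], cy = cmat[, 2],
                      n_members = NA_integer_, gamma = NA_real_),
    assignment = assignment, centers = cmat,
    params = list()), class = "aoi_model")
}

# scanpath set realizing given AOI-id visit sequences at fixed centers
# (one fixation per visit), plus the matching aoi_model
toy_instance <- function(seq_list, centers, dur = 100) {
  paths <- lapply(seq_list, function(ids) {
    xy <- do.call(rbind, centers[ids])
    data.frame(x = xy[, 1], y = xy[, 2],
               duration_ms = base::rep(dur, length.out = nrow(xy)))
  })
  names(paths) <- sprintf("s%02d", seq_along(seq_list))
  sps <- scanpath_set("toy", paths)
  model <- fake_aoi_model(centers, stats::setNames(seq_list, names(paths)))
  list(sps = sps, model = model,
       seqs = to_aoi_sequences(sps, model),
       graph = build_candidate_graph(lapply(seq_list, identity)))
}

# bare representative with given visit order (centers irrelevant)
new_rep_for_test <- function(ids) {
  structure(list(visits = data.frame(aoi_id = ids, cx = 0, cy = 0,
                                     duration_ms = NA_real_),
                 objective = NA_real_, method = "test", params = list(),
                 seed = NULL, stimulus_id = "toy"),
            class = "representative_scanpath")
}

# map recovered AOI ids to true center indices by nearest true center
match_centers <- function(aoi_model, true_centers) {
  apply(aoi_model$centers, 1, function(p)
    which.min(colSums((t(true_centers) - p)^2)))
}
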