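#' Transform scanpaths into AOI visit sequences
#'
#' Maps each subject's fixations to their AOIs and merges consecutive
#' same-AOI fixations into one visit whose duration is the sum of the
#' merged fixations' durations. No two consecutive visits share an AOI.
#'
#' @param sps A `scanpath_set` (the kept set the AOIs were extracted from).
#' @param aois An `aoi_model` from [extract_aois()].
#' @return Named list (by subject) of data.frames with columns `aoi_id`,
#'   `duration_ms`, class `aoi_sequences`.
#' @export
to_aoi_sequences <- function(sps, aois) {
  stopifnot(inherits(sps, "scanpath_set"), inherits(aois, "aoi_model"))
  amap <- aois$assignment
  out <- lapply(names(sps$scanpaths), function(id) {
    fx <- sps$scanpaths[[id]]
    rows <- amap[amap$subject_id == id, ]
    lab <- rows$aoi_id[match(fx$index, rows$index)]
    if (anyNA(lab))
      stop("subject '", id, "' has fixations without an AOI assignment")
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(aoi_id = r$values,
               duration_ms = vapply(seq_along(starts), function(v)
                 sum(fx$duration_ms[starts[v]:ends[v]]), numeric(1)))
  })
  names(out) <- names(sps$scanpaths)
  structure(out, class = "aoi_sequences")
}

#' Build the candidate-successor graph from AOI sequences
#'
#' For each AOI, the candidate set contains the AOIs observed to follow it
#' immediately in at least one individual sequence; `max_count` records the
#' maximum number of times each AOI occurs within any single sequence. Both
#' feed the contiguity and occurrence constraints of the aggregation.
#'
#' @param seqs `aoi_sequences` (or a plain list of data.frames / character
#'   vectors of AOI ids).
#' @return An object of class `candidate_graph`: list with `successors`
#'   (named list of sorted character vectors) and `max_count` (named
#'   integer over every AOI that appears).
#' @export
build_candidate_graph <- function(seqs) {
  ids_list <- lapply(seqs, function(s) if (is.data.frame(s)) s$aoi_id else as.character(s))
  if (length(ids_list) == 0L) stop("no AOI sequences given")
  universe <- sort(unique(unlist(ids_list)))
  succ <- stats::setNames(vector("list", length(universe)), universe)
  for (a in universe) succ[[a]] <- character(0)
  max_count <- stats::setNames(integer(length(universe)), universe)
  for (s in ids_list) {
    if (length(s) >= 2L)
      for (t in seq_len(length(s) - 1L))
        succ[[s[t]]] <- union(succ[[s[t]]], s[t + 1L])
    cnt <- table(s)
    max_count[names(cnt)] <- pmax(max_count[names(cnt)], as.integer(cnt))
  }
  succ <- lapply(succ, sort)
  structure(list(successors = succ, max_count = max_count),
            class = "candidate_graph")
}

#' @export
print.candidate_graph <- function(x, ...) {
  cat("<candidate_graph> ", length(x$max_count), " AOIs, ",
      sum(lengths(x$successors)), " observed transitions\n", sep = "")
  invisible(x)
}

#' Check a visit sequence against the aggregation constraints
#'
#' A representative scanpath must (1) be composed of known AOIs, (2) have
#' every adjacent pair contiguous in at least one individual sequence
#' (successor constraint), and (3) use each AOI no more often than its
#' maximum occurrence count over the individual sequences.
#'
#' @param visits Character vector of AOI ids (or a
#'   `representative_scanpath`).
#' @param graph A `candidate_graph`.
#' @return List with `valid` (logical) and `violations` (character vector
#'   describing each failed check).
#' @export
validate_constraints <- function(visits, graph) {
  stopifnot(inherits(graph, "candidate_graph"))
  if (inherits(visits, "representative_scanpath")) visits <- visits$visits$aoi_id
  visits <- as.character(visits)
  viol <- character(0)
  universe <- names(graph$max_count)
  unknown <- setdiff(unique(visits), universe)
  if (length(unknown))
    viol <- c(viol, paste0("unknown AOI '", unknown, "'"))
  if (length(visits) >= 2L) {
    for (t in seq_len(length(visits) - 1L)) {
      u <- visits[t]; v <- visits[t + 1L]
      if (u %in% universe && !(v %in% graph$successors[[u]]))
        viol <- c(viol, paste0("(", u, ",", v, ") contiguous in no individual sequence"))
    }
  }
  cnt <- table(visits)
  over <- names(cnt)[cnt > graph$max_count[names(cnt)] & names(cnt) %in% universe]
  if (length(over))
    viol <- c(viol, paste0("count(", over, ")=", as.integer(cnt[over]),
                           " exceeds max ", graph$max_count[over]))
  list(valid = length(viol) == 0L, violations = viol)
}

new_representative <- function(visits, objective, method, params,
                               seed = NULL, stimulus_id = NA_character_) {
  if (!all(c("aoi_id", "cx", "cy") %in% names(visits)))
    stop("visits must have aoi_id, cx, cy")
  if (is.null(visits$duration_ms)) visits$duration_ms <- NA_real_
  rownames(visits) <- NULL
  structure(list(visits = visits, objective = objective, method = method,
                 params = params, seed = seed, stimulus_id = stimulus_id),
            class = "representative_scanpath")
}

#' @export
print.representative_scanpath <- function(x, ...) {
  cat("<representative_scanpath> method '", x$method, "', ",
      nrow(x$visits), " visits, average DTW ",
      format(x$objective, digits = 6), "\n", sep = "")
  print(x$visits, digits = 4)
  invisible(x)
}

# centers lookup matrix (rownames aoi_id) from an aoi_model or data.frame
aoi_center_matrix <- function(aois) {
  if (inherits(aois, "aoi_model")) return(aois$centers)
  if (is.data.frame(aois)) {
    m <- cbind(x = aois$cx, y = aois$cy)
    rownames(m) <- aois$aoi_id
    return(m)
  }
  if (is.matrix(aois) && !is.null(rownames(aois))) return(aois)
  stop("`aois` must be an aoi_model, a data.frame with aoi_id/cx/cy, or a named matrix")
}

rep_visits <- function(ids, centers) {
  data.frame(aoi_id = ids,
             cx = centers[ids, 1], cy = centers[ids, 2],
             duration_ms = NA_real_)
}

#' Exhaustive heuristic aggregation
#'
#' Enumerates every constraint-valid AOI sequence of length 1 to `n_max` by
#' depth-first extension through the candidate-successor graph (pruning
#' AOIs that have reached their maximum occurrence count) and returns the
#' sequence of AOI centers minimizing the average DTW to the individual
#' scanpaths. For `n_max` large enough this is the exact optimum of the
#' constrained aggregation objective. Ties are broken by shorter length,
#' then lexicographic AOI-id order.
#'
#' @param sps The kept `scanpath_set` (objective is measured against its
#'   fixation sequences).
#' @param graph A `candidate_graph`.
#' @param aois An `aoi_model` (or centers data.frame/matrix).
#' @param n_max Maximum sequence length to enumerate (default 8; past the
#'   typical individual sequence length the objective saturates).
#' @param start_observed If `TRUE`, restrict starting AOIs to those opening
#'   at least one individual sequence; by default any AOI may start.
#' @param seqs The individual `aoi_sequences`; only needed when
#'   `start_observed = TRUE`.
#' @return A `representative_scanpath` with `method = "heuristic"`.
#' @export
heuristic_aggregate <- function(sps, graph, aois, n_max = 8L,
                                start_observed = FALSE, seqs = NULL) {
  stopifnot(inherits(graph, "candidate_graph"), n_max >= 1L)
  centers <- aoi_center_matrix(aois)
  universe <- names(graph$max_count)
  if (length(universe) == 0L) stop("candidate graph is empty: no valid sequence exists")
  starts <- universe
  if (start_observed) {
    if (is.null(seqs)) stop("start_observed = TRUE requires `seqs`")
    starts <- sort(unique(vapply(seqs, function(s)
      (if (is.data.frame(s)) s$aoi_id else s)[1], character(1))))
  }
  seqs_xy <- set_xy(sps)

  store <- new.env(parent = emptyenv())
  store$paths <- vector("list", 1024L)
  store$n <- 0L
  push <- function(ids) {
    store$n <- store$n + 1L
    if (store$n > length(store$paths))
      store$paths <- c(store$paths, vector("list", length(store$paths)))
    store$paths[[store$n]] <- ids
  }
  counts0 <- stats::setNames(integer(length(universe)), universe)
  extend <- function(ids, counts) {
    push(ids)
    if (length(ids) >= n_max) return(invisible())
    for (nxt in graph$successors[[ids[length(ids)]]]) {
      if (counts[nxt] < graph$max_count[nxt]) {
        counts[nxt] <- counts[nxt] + 1L
        extend(c(ids, nxt), counts)
        counts[nxt] <- counts[nxt] - 1L
      }
    }
  }
  for (a in starts) {
    counts <- counts0; counts[a] <- 1L
    extend(a, counts)
  }
  paths <- store$paths[seq_len(store$n)]
  obj <- vapply(paths, function(ids)
    cpp_avg_dtw(centers[ids, , drop = FALSE], seqs_xy), numeric(1))
  best <- which(obj == min(obj))
  if (length(best) > 1L) {
    key_len <- lengths(paths[best])
    key_lex <- vapply(paths[best], paste, "", collapse = "\r")
    best <- best[order(key_len, key_lex)]
  }
  ids <- paths[[best[1]]]
  new_representative(
    rep_visits(ids, centers), objective = obj[best[1]][[1]],
    method = "heuristic",
    params = list(n_max = as.integer(n_max), start_observed = start_observed,
                  n_enumerated = store$n),
    stimulus_id = sps$stimulus_id
  )
}

#' Inter-observer-consistency (IOC) selection
#'
#' Selects, among the individual AOI sequences themselves (rendered as AOI
#' center sequences), the one with the smallest average DTW to the group's
#' scanpaths. Ties are broken by subject enumeration order. The output is
#' always one of the transformed individual sequences, and therefore
#' constraint-valid by construction.
#'
#' @inheritParams heuristic_aggregate
#' @param seqs The individual `aoi_sequences` from [to_aoi_sequences()].
#' @return A `representative_scanpath` with `method = "ioc"`.
#' @export
ioc_select <- function(sps, seqs, aois) {
  if (length(seqs) == 0L) stop("no AOI sequences to select from")
  centers <- aoi_center_matrix(aois)
  seqs_xy <- set_xy(sps)
  ids_list <- lapply(seqs, function(s) if (is.data.frame(s)) s$aoi_id else as.character(s))
  obj <- vapply(ids_list, function(ids)
    cpp_avg_dtw(centers[ids, , drop = FALSE], seqs_xy), numeric(1))
  k <- which.min(obj)
  new_representative(
    rep_visits(ids_list[[k]], centers), objective = obj[[k]], method = "ioc",
    params = list(selected_subject = names(seqs)[k]),
    stimulus_id = sps$stimulus_id
  )
}

#' Candidate-constrained DTW barycenter averaging (CDBA)
#'
#' Iteratively refines a reference AOI sequence: each iteration (a) aligns
#' every individual scanpath to the reference's center sequence via the
#' optimal DTW path, then (b) replaces each reference component, left to
#' right, by its *constrained barycenter* — the AOI, among those keeping
#' the whole sequence constraint-valid when substituted at that position,
#' whose center minimizes the summed Euclidean distance to all fixations
#' aligned to the component. Cost ties keep the incumbent AOI, then fall
#' back to lexicographic AOI-id order. The reference length is fixed at the
#' initial reference's length (components are replaced, never inserted or
#' deleted). Iteration stops when the reference no longer changes or
#' `max_iter` is reached; the average-DTW objective is non-increasing
#' across iterations by construction.
#'
#' @inheritParams heuristic_aggregate
#' @param seqs The individual `aoi_sequences` (needed for initialization).
#' @param init `"ioc"` (default: initialize from [ioc_select()], which
#'   bounds the CDBA objective by the IOC objective), `"medoid"` (the
#'   individual sequence minimizing total DTW to the other individual
#'   sequences), `"random"` (a random individual sequence; uses `seed`), or
#'   a `representative_scanpath` to start from.
#' @param max_iter Iteration cap (default 50).
#' @param seed RNG seed for `init = "random"`.
#' @return A `representative_scanpath` with `method = "cdba"`; its
#'   `params$objective_trace` records the objective after each iteration.
#' @export
cdba_aggregate <- function(sps, graph, aois, seqs, init = "ioc",
                           max_iter = 50L, seed = NULL) {
  stopifnot(inherits(graph, "candidate_graph"))
  centers <- aoi_center_matrix(aois)
  seqs_xy <- set_xy(sps)
  universe <- names(graph$max_count)

  ref <- cdba_init(sps, seqs, aois, init, seed)
  chk <- validate_constraints(ref, graph)
  if (!chk$valid)
    stop("initial reference scanpath violates constraints: ",
         paste(chk$violations, collapse = "; "))
  trace <- cpp_avg_dtw(centers[ref, , drop = FALSE], seqs_xy)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # (a) align every scanpath to the current reference
    aligned <- vector("list", length(ref))
    ref_xy <- centers[ref, , drop = FALSE]
    for (s in seqs_xy) {
      path <- dtw_scanpaths(ref_xy, s)$path
      for (r in seq_len(nrow(path)))
        aligned[[path[r, 1]]] <- rbind(aligned[[path[r, 1]]],
                                       s[path[r, 2], , drop = FALSE])
    }
    # (b) constrained barycenter update, left to right
    new_ref <- ref
    for (t in seq_along(new_ref)) {
      cand <- vapply(universe, function(a) {
        trial <- new_ref; trial[t] <- a
        validate_constraints(trial, graph)$valid
      }, logical(1))
      cand_ids <- universe[cand]
      pts <- aligned[[t]]
      cost <- vapply(cand_ids, function(a)
        sum(sqrt((pts[, 1] - centers[a, 1])^2 + (pts[, 2] - centers[a, 2])^2)),
        numeric(1))
      best <- cand_ids[cost == min(cost)]
      new_ref[t] <- if (new_ref[t] %in% best) new_ref[t] else sort(best)[1]
    }
    trace <- c(trace, cpp_avg_dtw(centers[new_ref, , drop = FALSE], seqs_xy))
    if (identical(new_ref, ref)) break
    ref <- new_ref
  }
  new_representative(
    rep_visits(ref, centers), objective = trace[length(trace)],
    method = "cdba",
    params = list(init = if (is.character(init)) init else "given",
                  max_iter = as.integer(max_iter), iterations = iter,
                  objective_trace = trace),
    seed = seed, stimulus_id = sps$stimulus_id
  )
}

cdba_init <- function(sps, seqs, aois, init, seed) {
  if (inherits(init, "representative_scanpath")) return(init$visits$aoi_id)
  ids_list <- lapply(seqs, function(s) if (is.data.frame(s)) s$aoi_id else as.character(s))
  switch(init,
    ioc = ioc_select(sps, seqs, aois)$visits$aoi_id,
    medoid = {
      centers <- aoi_center_matrix(aois)
      xs <- lapply(ids_list, function(ids) centers[ids, , drop = FALSE])
      n <- length(xs)
      tot <- numeric(n)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        tot[i] <- tot[i] + cpp_dtw_dist(xs[[i]], xs[[j]])
      ids_list[[which.min(tot)]]
    },
    random = {
      if (!is.null(seed)) set.seed(seed)
      ids_list[[sample.int(length(ids_list), 1L)]]
    },
    stop("unknown CDBA init '", init, "'")
  )
}
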