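# Independent oracles: these deliberately avoid the package's DP/C++ code
# paths and recompute the same quantities by explicit enumeration.

# DTW by exhaustive minimization over all monotone alignments: walk every
# lattice path from (1,1) to (m,n) with steps {down, right, diagonal},
# accumulating Euclidean costs (branch-and-bound pruning keeps it exact).
oracle_dtw <- function(A, B) {
  m <- nrow(A); n <- nrow(B)
  dloc <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + dloc(i, j)
    if (acc > best) return(invisible())
    if (i == m && j == n) { best <<- acc; return(invisible()) }
    if (i < m && j < n) walk(i + 1, j + 1, acc)
    if (i < m) walk(i + 1, j, acc)
    if (j < n) walk(i, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# All constraint-valid AOI-id sequences of length 1..n_max, enumerated from
# first principles (bigram and count checks scan the individual sequences
# directly; no candidate_graph involved).
oracle_valid_sequences <- function(ids_list, n_max) {
  universe <- sort(unique(unlist(ids_list)))
  has_bigram <- function(u, v)
    any(vapply(ids_list, function(s)
      length(s) >= 2 && any(s[-length(s)] == u & s[-1] == v), logical(1)))
  max_count <- vapply(universe, function(a)
    max(vapply(ids_list, function(s) sum(s == a), integer(1))), integer(1))
  names(max_count) <- universe
  out <- list()
  gen <- function(prefix) {
    out[[length(out) + 1L]] <<- prefix
    if (length(prefix) == n_max) return(invisible())
    for (a in universe) {
      if (!has_bigram(prefix[length(prefix)], a)) next
      if (sum(prefix == a) + 1L > max_count[a]) next
      gen(c(prefix, a))
    }
  }
  for (a in universe) gen(a)
  out
}

# Brute-force optimum of the aggregation objective: evaluate every valid
# sequence and return the minimum average DTW (ties: shorter, then lex).
oracle_best_representative <- function(ids_list, centers, sps, n_max) {
  cand <- oracle_valid_sequences(ids_list, n_max)
  obj <- vapply(cand, function(ids)
    average_dtw(centers[ids, , drop = FALSE], sps), numeric(1))
  best <- which(obj == min(obj))
  if (length(best) > 1L)
    best <- best[order(lengths(cand[best]),
                       vapply(cand[best], paste, "", collapse = "\r"))]
  list(ids = cand[[best[1]]], objective = obj[best[1]][[1]])
}

random_xy_seq <- function(n, lim = 100) matrix(runif(2 * n, 0, lim), n, 2)
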