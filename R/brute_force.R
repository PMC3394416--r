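# Energy of a structure when the per-pair shears are imposed (exhaustive
# branching). shears is the barrel-position-order vector (pair p joins
# positions p and p+1, pair n wraps); loops use the composed shear along
# the direct barrel arc of the imposed values.
score_with_shears <- function(graph, vids, sigma, shears, closed = TRUE) {
  n <- length(vids)
  n_pairs <- if (closed) n else n - 1L
  E <- sum(vapply(vids, function(v) e_intr(graph, v), numeric(1L))) +
    e_loop(graph, 0L, vids[1L]) + e_loop(graph, vids[n], 0L)
  for (p in seq_len(n_pairs)) {
    a <- vids[sigma$sigma[p]]
    b <- vids[sigma$sigma[if (p == n) 1L else p + 1L]]
    ea <- e_adj(graph, a, b, shears[p])
    if (!is.finite(ea)) return(Inf)
    E <- E + ea
  }
  for (i in seq_len(n - 1L)) {
    a <- sigma$inv[i]; b <- sigma$inv[i + 1L]
    dir <- sign(b - a)
    # composed shear along the direct barrel arc: stepping from position p
    # to p+1 adds +shears[p], stepping from p to p-1 adds -shears[p-1]
    scomp <- 0L
    p <- a
    while (p != b) {
      if (dir > 0L) { scomp <- scomp + shears[p]; p <- p + 1L }
      else { scomp <- scomp - shears[p - 1L]; p <- p - 1L }
    }
    E <- E + e_loop(graph, vids[i], vids[i + 1L],
                    abs(sigma$inv[i + 1L] - sigma$inv[i]), scomp, n)
  }
  E
}

# All sequence-ordered, edge-connected vertex tuples of length n from
# admissible start vertices to admissible end vertices, in lexicographic
# order.
enumerate_paths <- function(graph, n) {
  out <- list()
  walk <- function(path) {
    k <- length(path)
    if (k == n) {
      if (graph$end_ok[path[n]]) out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in sort(graph$succ[[path[k]]])) walk(c(path, w))
  }
  for (v in sort(which(graph$start_ok))) walk(v)
  out
}

#' Exhaustive-enumeration folding oracle
#'
#' Enumerates every sequence-ordered n-tuple of vertices that forms an
#' edge-connected path with admissible leader and trailer, evaluates the
#' full objective under sigma (closure included for barrels) subject to
#' the shear constraint, and returns the maximum-criterion structure. The
#' objective definition is shared with the solvers, so agreement is exact.
#' Guarded to small graphs; intended as the independent test oracle.
#'
#' @inheritParams fold_barrel_permuted
#' @param closed TRUE for a barrel, FALSE for an open sheet.
#' @param guard Maximum number of graph vertices accepted.
#' @return A \code{barrel_structure}.
#' @export
brute_force_fold <- function(graph, n, S, sigma = NULL, closed = TRUE,
                             guard = 16L) {
  if (graph$n_vert > guard) {
    stop("brute_force_fold guard exceeded (", graph$n_vert, " > ", guard,
         " vertices)")
  }
  stopifnot(n >= 2L)
  sigma <- if (is.null(sigma)) identity_permutation(n)
    else as_permutation(sigma)
  exh <- isTRUE(graph$config$exhaustive_shear)
  paths <- enumerate_paths(graph, n)
  best <- NULL
  n_pairs <- if (closed) n else n - 1L
  sg <- shear_grid(graph)
  if (exh && length(sg)^n_pairs > 2e5) {
    stop("exhaustive shear enumeration too large for the oracle")
  }
  for (vids in paths) {
    if (exh) {
      grids <- rep(list(sg), n_pairs)
      combos <- as.matrix(do.call(expand.grid, grids))
      for (ci in seq_len(nrow(combos))) {
        shears <- as.integer(combos[ci, ])
        if (sum(shears) != S) next
        E <- score_with_shears(graph, vids, sigma, shears, closed)
        if (is.finite(E) && (is.null(best) || -E > best$criterion)) {
          best <- list(vids = vids, shears = shears, criterion = -E,
                       energy = E)
        }
      }
    } else {
      sc <- score_structure(graph, vids, S, sigma, closed)
      if (isTRUE(sc$feasible) && (is.null(best) ||
                                    sc$criterion > best$criterion)) {
        best <- list(vids = vids, shears = sc$shears,
                     criterion = sc$criterion, energy = sc$energy)
      }
    }
  }
  if (is.null(best)) return(no_solution("no feasible tuple"))
  barrel_structure(graph, best$vids, n, S, sigma, best$shears, best$energy,
                   closed = closed)
}
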