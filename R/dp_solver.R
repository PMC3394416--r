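# Precompute, for every graph edge (u, w), the transition cost and shear
# branches. Fixed-shear mode uses the per-pair optimum s_adj(u, w); the
# exhaustive mode branches over the whole shear grid. Returns a data.frame
# with one row per (edge, shear branch).
edge_branches <- function(graph, exhaustive = FALSE) {
  rows <- vector("list", 0L)
  for (u in seq_len(graph$n_vert)) {
    for (w in graph$succ[[u]]) {
      if (exhaustive) {
        for (s in shear_grid(graph)) {
          ea <- e_adj(graph, u, w, s)
          if (!is.finite(ea)) next
          rows[[length(rows) + 1L]] <-
            list(u = u, w = w, s = s,
                 cost = e_intr(graph, w) + ea + e_loop(graph, u, w, 1L, s))
        }
      } else {
        opt <- e_adj_opt(graph, u, w)
        if (!is.finite(opt$energy)) next
        rows[[length(rows) + 1L]] <-
          list(u = u, w = w, s = opt$s,
               cost = e_intr(graph, w) + opt$energy +
                 e_loop(graph, u, w, 1L, opt$s))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(u = integer(0), w = integer(0), s = integer(0),
                      cost = numeric(0)))
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# Shear accumulator window for a solve with n_pairs adjacency terms whose
# per-pair shear lies in [s_lo, s_hi].
shear_window <- function(n_pairs, s_lo, s_hi) {
  lo <- min(0L, n_pairs * s_lo)
  hi <- max(0L, n_pairs * s_hi)
  list(lo = lo, hi = hi, H = hi - lo + 1L, off = 1L - lo)
}

#' Fold an open beta-sheet of n strands with shear number S
#'
#' Solves the constrained longest-path problem on the fold graph: among all
#' paths of exactly n strand vertices whose consecutive relative shears sum
#' to S, maximizes the criterion C = -E. The per-pair shear is the pair
#' optimum s_adj(u, v) unless the configuration requests the exhaustive
#' shear branching.
#'
#' @param graph A [build_fold_graph()] or [make_random_graph()] object.
#' @param n Number of strands, >= 2.
#' @param S Required shear number (sum of the n - 1 consecutive shears).
#' @return A \code{barrel_structure} (open, \code{closed = FALSE});
#'   \code{feasible = FALSE} when no path attains (n, S).
#' @export
fold_sheet <- function(graph, n, S) {
  stopifnot(n >= 2L)
  M <- graph$n_vert
  if (M == 0L) return(no_solution("empty graph"))
  exh <- isTRUE(graph$config$exhaustive_shear)
  eb <- edge_branches(graph, exh)
  if (nrow(eb) == 0L) return(no_solution("no edges"))
  win <- shear_window(n - 1L, min(eb$s), max(eb$s))
  H <- win$H
  C <- matrix(-Inf, M, H)
  start <- which(graph$start_ok)
  C[cbind(start, win$off)] <-
    -graph$vertices$e_intr[start] - vapply(start, function(v)
      e_loop(graph, 0L, v), numeric(1L))
  BU <- vector("list", n) # back pointers: predecessor vertex
  BS <- vector("list", n) # back pointers: shear used
  for (k in 2:n) {
    Cn <- matrix(-Inf, M, H)
    bu <- matrix(NA_integer_, M, H)
    bs <- matrix(NA_integer_, M, H)
    for (r in seq_len(nrow(eb))) {
      u <- eb$u[r]; w <- eb$w[r]; s <- eb$s[r]
      cols <- max(1L, 1L - s):min(H, H - s)
      src <- C[u, cols]
      fin <- which(is.finite(src))
      if (length(fin) == 0L) next
      cols <- cols[fin]
      cand <- src[fin] - eb$cost[r]
      tgt <- cols + s
      better <- cand > Cn[w, tgt]
      if (any(better)) {
        idx <- tgt[better]
        Cn[w, idx] <- cand[better]
        bu[w, idx] <- u
        bs[w, idx] <- s
      }
    }
    C <- Cn
    BU[[k]] <- bu
    BS[[k]] <- bs
  }
  colS <- S + win$off
  if (colS < 1L || colS > H) return(no_solution("shear out of range"))
  final <- C[, colS]
  final[!graph$end_ok] <- -Inf
  final <- final - vapply(seq_len(M), function(v) e_loop(graph, v, 0L),
                          numeric(1L))
  final[!is.finite(C[, colS])] <- -Inf
  if (!any(is.finite(final))) return(no_solution("no path attains (n, S)"))
  v <- which.max(final)
  vids <- integer(n)
  shears <- integer(n - 1L)
  col <- colS
  vids[n] <- v
  for (k in n:2) {
    u <- BU[[k]][v, col]
    s <- BS[[k]][v, col]
    shears[k - 1L] <- s
    col <- col - s
    v <- u
    vids[k - 1L] <- v
  }
  barrel_structure(graph, vids, n, S, identity_permutation(n), shears,
                   -final[vids[n]], closed = FALSE)
}

#' Fold a closed barrel of n strands with shear number S (identity order)
#'
#' As [fold_sheet()], but the last strand is additionally adjacent to the
#' first, so the solver tracks the first vertex of every partial path and
#' applies a closing step: the wrap pair contributes its interaction energy
#' and relative shear, and the shear constraint runs over all n pairs.
#'
#' @inheritParams fold_sheet
#' @return A \code{barrel_structure} (closed).
#' @export
fold_barrel <- function(graph, n, S) {
  fold_barrel_scan(graph, n, S)[[1L]]
}

#' Fold closed barrels of n strands for several shear numbers at once
#'
#' The level recursion of the barrel solver does not depend on S; only the
#' closing step does. This runs the levels once and closes at each
#' requested shear number, which is how the (n, S) couples of a
#' classification scan are solved efficiently.
#'
#' @inheritParams fold_sheet
#' @param S_values Integer vector of shear numbers.
#' @return A list of \code{barrel_structure} objects, one per shear
#'   number, in order.
#' @export
fold_barrel_scan <- function(graph, n, S_values) {
  stopifnot(n >= 2L)
  S_values <- as.integer(S_values)
  M <- graph$n_vert
  if (M == 0L) return(rep(list(no_solution("empty graph")),
                          length(S_values)))
  exh <- isTRUE(graph$config$exhaustive_shear)
  eb <- edge_branches(graph, exh)
  if (nrow(eb) == 0L) return(rep(list(no_solution("no edges")),
                                 length(S_values)))
  sg <- shear_grid(graph)
  win <- shear_window(n, min(c(eb$s, sg)), max(c(eb$s, sg)))
  H <- win$H
  fverts <- which(graph$start_ok)
  FN <- length(fverts)
  if (FN == 0L) return(no_solution("no admissible first strand"))
  mk <- function(fill) lapply(seq_len(M), function(w) matrix(fill, FN, H))
  C <- mk(-Inf)
  for (fi in seq_len(FN)) {
    v <- fverts[fi]
    C[[v]][fi, win$off] <- -graph$vertices$e_intr[v] - e_loop(graph, 0L, v)
  }
  BU <- vector("list", n)
  BS <- vector("list", n)
  for (k in 2:n) {
    Cn <- mk(-Inf)
    bu <- mk(NA_integer_)
    bs <- mk(NA_integer_)
    for (r in seq_len(nrow(eb))) {
      u <- eb$u[r]; w <- eb$w[r]; s <- eb$s[r]
      src <- C[[u]]
      if (all(!is.finite(src))) next
      cols <- max(1L, 1L - s):min(H, H - s)
      cand <- src[, cols, drop = FALSE] - eb$cost[r]
      tgt <- cols + s
      cur <- Cn[[w]][, tgt, drop = FALSE]
      better <- cand > cur
      if (any(better)) {
        cur[better] <- cand[better]
        Cn[[w]][, tgt] <- cur
        bmat <- bu[[w]][, tgt, drop = FALSE]
        bmat[better] <- u
        bu[[w]][, tgt] <- bmat
        smat <- bs[[w]][, tgt, drop = FALSE]
        smat[better] <- s
        bs[[w]][, tgt] <- smat
      }
    }
    C <- Cn
    BU[[k]] <- bu
    BS[[k]] <- bs
  }
  # closing step: wrap adjacency between the last strand u and the first f
  closures <- list()
  for (u in which(graph$end_ok)) {
    src <- C[[u]]
    if (all(!is.finite(src))) next
    for (fi in seq_len(FN)) {
      f <- fverts[fi]
      if (f == u) next
      close_opts <- if (exh) {
        lapply(sg, function(s) list(energy = e_adj(graph, u, f, s), s = s))
      } else list(e_adj_opt(graph, u, f))
      for (opt in close_opts) {
        if (!is.finite(opt$energy)) next
        closures[[length(closures) + 1L]] <- list(
          u = u, fi = fi, s = opt$s,
          cost = opt$energy + e_loop(graph, u, 0L))
      }
    }
  }
  lapply(S_values, function(S) {
    colS <- S + win$off
    if (colS < 1L || colS > H) return(no_solution("shear out of range"))
    best <- -Inf; best_fi <- NA_integer_; best_u <- NA_integer_
    best_s <- NA_integer_
    for (cl in closures) {
      col0 <- colS - cl$s
      if (col0 < 1L || col0 > H) next
      val <- C[[cl$u]][cl$fi, col0] - cl$cost
      if (is.finite(val) && val > best) {
        best <- val; best_fi <- cl$fi; best_u <- cl$u; best_s <- cl$s
      }
    }
    if (!is.finite(best)) return(no_solution("no path attains (n, S)"))
    vids <- integer(n)
    shears <- integer(n)
    shears[n] <- best_s # wrap pair (position n -> 1)
    v <- best_u
    col <- colS - best_s
    vids[n] <- v
    for (k in n:2) {
      u <- BU[[k]][[v]][best_fi, col]
      s <- BS[[k]][[v]][best_fi, col]
      shears[k - 1L] <- s
      col <- col - s
      v <- u
      vids[k - 1L] <- v
    }
    stopifnot(vids[1L] == fverts[best_fi])
    barrel_structure(graph, vids, n, S, identity_permutation(n), shears,
                     -best, closed = TRUE)
  })
}
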