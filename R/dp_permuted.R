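#' Fold a permuted barrel of n strands with shear number S
#'
#' General solver for circle-attached paths: the k-th strand along the
#' sequence is inserted at barrel position sigma^-1(k), between the strands
#' of ranks left_k and right_k. Partial solutions are indexed by the tuple
#' of vertices at the active ranks and by the accumulated shear h over the
#' barrel adjacencies realized so far; each pair interaction enters exactly
#' once, at the level of its later strand, and each turn/loop energy enters
#' at the level where the interleaving adjacencies first determine its
#' composed relative shear. The optimum is read at level n, h = S.
#'
#' @inheritParams fold_sheet
#' @param sigma A [barrel_permutation()] (or plain vector) with
#'   \code{sigma(1) = 1} and length n.
#' @return A \code{barrel_structure} (closed). The attribute
#'   \code{"max_states"} records the largest number of distinct active
#'   vertex tuples held at any level (the shear dimension not counted).
#' @export
fold_barrel_permuted <- function(graph, n, S, sigma) {
  sigma <- as_permutation(sigma)
  if (sigma$n != n) stop("sigma length must equal n")
  stopifnot(n >= 3L)
  M <- graph$n_vert
  if (M == 0L) return(no_solution("empty graph"))
  exh <- isTRUE(graph$config$exhaustive_shear)
  sg <- shear_grid(graph)
  acts <- lapply(seq_len(n), function(k) active_set(sigma, k))
  lrs <- lapply(seq_len(n), function(k) left_right(sigma, k))
  dAs <- lapply(seq_len(n), function(k) adjacency_closure(sigma, k)$delta)
  t_loop <- abs(sigma$inv[2:n] - sigma$inv[1:(n - 1L)])
  max_states <- 0L

  state_key <- function(assign, h) paste(c(assign, h), collapse = "|")
  count_tuples <- function(env) {
    keys <- ls(env)
    length(unique(sub("\\|[^|]*$", "", keys)))
  }
  states <- new.env(parent = emptyenv())
  for (v in which(graph$start_ok)) {
    a <- c("1" = v)
    states[[state_key(a, 0L)]] <- list(
      C = -graph$vertices$e_intr[v] - e_loop(graph, 0L, v),
      assign = a, h = 0L, path = v,
      shears = rep(NA_integer_, n))
  }
  max_states <- max(max_states, count_tuples(states))

  for (k in 2:n) {
    nxt <- new.env(parent = emptyenv())
    lr <- lrs[[k]]
    left <- lr[["left"]]; right <- lr[["right"]]
    p_k <- sigma$inv[k]
    act_k <- as.character(acts[[k]])
    dA <- dAs[[k]]
    for (key in sort(ls(states))) {
      y <- states[[key]]
      u <- y$assign[[as.character(k - 1L)]]
      for (w in graph$succ[[u]]) {
        if (k == n && !graph$end_ok[w]) next
        # branches over the relative shears of the adjacencies realized
        # by inserting strand k
        optL <- if (left < k) {
          vl <- y$assign[[as.character(left)]]
          if (exh) lapply(sg, function(s)
            list(energy = e_adj(graph, vl, w, s), s = s))
          else list(e_adj_opt(graph, vl, w))
        } else list(NULL)
        optR <- if (right < k) {
          vr <- y$assign[[as.character(right)]]
          if (exh) lapply(sg, function(s)
            list(energy = e_adj(graph, w, vr, s), s = s))
          else list(e_adj_opt(graph, w, vr))
        } else list(NULL)
        # deferred loop terms resolved at this level
        loop_E <- 0
        if (length(dA) > 0L) {
          by_rank <- rep(NA_integer_, n)
          by_rank[as.integer(names(y$assign))] <- y$assign
          by_rank[k] <- w
          for (i in dA) {
            vi <- by_rank[i]; vj <- by_rank[i + 1L]
            if (is.na(vi) || is.na(vj)) {
              stop("internal error: deferred loop endpoints not active")
            }
            loop_E <- loop_E +
              e_loop(graph, vi, vj, t_loop[i],
                     compose_shear(graph, by_rank, sigma, i), n)
          }
        }
        base <- y$C - graph$vertices$e_intr[w] - loop_E -
          (if (k == n) e_loop(graph, w, 0L) else 0)
        for (oL in optL) {
          if (!is.null(oL) && !is.finite(oL$energy)) next
          for (oR in optR) {
            if (!is.null(oR) && !is.finite(oR$energy)) next
            val <- base
            h <- y$h
            sh <- y$shears
            if (!is.null(oL)) {
              val <- val - oL$energy
              h <- h + oL$s
              sh[if (p_k == 1L) n else p_k - 1L] <- oL$s
            }
            if (!is.null(oR)) {
              val <- val - oR$energy
              h <- h + oR$s
              sh[if (p_k == n) n else p_k] <- oR$s
            }
            assign <- c(y$assign, stats::setNames(w, as.character(k)))
            assign <- assign[act_k]
            names(assign) <- act_k
            nk <- state_key(assign, h)
            old <- nxt[[nk]]
            if (is.null(old) || val > old$C) {
              nxt[[nk]] <- list(C = val, assign = assign, h = h,
                                path = c(y$path, w), shears = sh)
            }
          }
        }
      }
    }
    states <- nxt
    max_states <- max(max_states, count_tuples(states))
  }

  best <- NULL
  for (key in sort(ls(states))) {
    st <- states[[key]]
    if (st$h == S && (is.null(best) || st$C > best$C)) best <- st
  }
  if (is.null(best)) {
    out <- no_solution("no path attains (n, S) under sigma")
  } else {
    out <- barrel_structure(graph, best$path, n, S, sigma, best$shears,
                            -best$C, closed = TRUE)
  }
  attr(out, "max_states") <- max_states
  out
}
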