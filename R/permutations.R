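#' Barrel permutation
#'
#' A circular permutation sigma on 1..n describing the strand order around
#' the barrel: barrel position p holds the sigma(p)-th strand in sequence
#' order. The reference position is fixed by sigma(1) = 1.
#'
#' @param sigma Integer vector: a bijection of 1..n with \code{sigma[1] == 1}.
#' @return A list of class \code{"barrel_permutation"} with \code{n},
#'   \code{sigma} and the cached inverse \code{inv} (\code{inv[k]} is the
#'   barrel position of the k-th sequence strand).
#' @examples
#' barrel_permutation(c(1, 2, 5, 4, 3, 6))
#' @export
barrel_permutation <- function(sigma) {
  sigma <- as.integer(sigma)
  n <- length(sigma)
  if (n < 2L || !identical(sort(sigma), seq_len(n))) {
    stop("sigma must be a bijection of 1..n, n >= 2")
  }
  if (sigma[1L] != 1L) stop("sigma(1) must equal 1 (reference position)")
  inv <- integer(n)
  inv[sigma] <- seq_len(n)
  structure(list(n = n, sigma = sigma, inv = inv),
            class = "barrel_permutation")
}

#' @export
print.barrel_permutation <- function(x, ...) {
  cat("<barrel_permutation> (", paste(x$sigma, collapse = " "), ")\n",
      sep = "")
  invisible(x)
}

as_permutation <- function(sigma) {
  if (inherits(sigma, "barrel_permutation")) sigma
  else barrel_permutation(sigma)
}

#' Ranks of the barrel neighbors of the k-th strand
#'
#' When the k-th strand (in sequence order) is inserted into the barrel it
#' sits between the strands of sequence ranks left_k and right_k:
#' left_k = sigma(sigma^-1(k) - 1) (wrapping to sigma(n)) and
#' right_k = sigma(sigma^-1(k) + 1) (wrapping to 1).
#'
#' @param sigma A [barrel_permutation()] (or plain vector).
#' @param k Sequence rank, 1..n.
#' @return Named integer vector \code{c(left =, right =)}.
#' @examples
#' left_right(c(1, 2, 5, 4, 3, 6), 3) # left = 4, right = 6
#' @export
left_right <- function(sigma, k) {
  sigma <- as_permutation(sigma)
  n <- sigma$n
  if (k < 1L || k > n) stop("k out of 1..n")
  p <- sigma$inv[k]
  left <- if (p > 1L) sigma$sigma[p - 1L] else sigma$sigma[n]
  right <- if (p < n) sigma$sigma[p + 1L] else 1L
  c(left = left, right = right)
}

# TRUE iff sequence ranks i and j occupy neighboring barrel positions
# (including the wrap that closes the barrel).
ranks_adjacent <- function(sigma, i, j) {
  d <- abs(sigma$inv[i] - sigma$inv[j])
  d == 1L | d == sigma$n - 1L
}

#' Active index set at construction level k
#'
#' conf_k holds k itself plus every earlier rank that still has a barrel
#' neighbor among the strands not yet placed: those ranks remain degrees of
#' freedom of the partial solution.
#'
#' @param sigma A [barrel_permutation()] (or plain vector).
#' @param k Construction level, 1..n.
#' @return Sorted integer vector of active ranks.
#' @examples
#' conf_set(c(1, 2, 5, 4, 3, 6), 5) # {1, 3, 5}
#' @export
conf_set <- function(sigma, k) {
  sigma <- as_permutation(sigma)
  n <- sigma$n
  if (k < 1L || k > n) stop("k out of 1..n")
  k <- as.integer(k)
  if (k == 1L || k == n) return(k)
  # the barrel neighbors of rank i are the ranks at the two adjacent
  # positions (wrap included); i stays active while one of them is > k
  pos <- sigma$inv
  nbr_max <- pmax(sigma$sigma[ifelse(pos == 1L, n, pos - 1L)],
                  sigma$sigma[ifelse(pos == n, 1L, pos + 1L)])
  earlier <- seq_len(k - 1L)
  sort(c(earlier[nbr_max[earlier] > k], k))
}

# Connected components of the realized-adjacency relation A_k: ranks
# i, j <= k are related when their barrel positions are neighbors. Returns
# a component label per rank 1..k.
adjacency_components <- function(sigma, k) {
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  if (k >= 2L) {
    for (i in 1L:(k - 1L)) {
      for (j in (i + 1L):k) {
        if (ranks_adjacent(sigma, i, j)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  vapply(seq_len(k), find, integer(1L))
}

#' Realized sequence-consecutive adjacencies at level k
#'
#' A_k lists the ranks i < k whose loop to strand i + 1 is geometrically
#' determined once the first k strands are laid: i and i + 1 are linked
#' through the transitive closure of realized barrel adjacencies.
#' delta_A_k = A_k - A_(k-1) marks the loops whose energy (and composed
#' relative shear) becomes computable exactly at level k.
#'
#' @param sigma A [barrel_permutation()] (or plain vector).
#' @param k Construction level, 1..n.
#' @return A list with \code{A} (sorted ranks of A_k) and \code{delta}
#'   (sorted ranks of delta_A_k; equal to A for k = 1).
#' @examples
#' adjacency_closure(c(1, 2, 5, 4, 3, 6), 5)$delta # {2, 4}
#' @export
adjacency_closure <- function(sigma, k) {
  sigma <- as_permutation(sigma)
  if (k < 1L || k > sigma$n) stop("k out of 1..n")
  A_of <- function(kk) {
    if (kk < 2L) return(integer(0))
    comp <- adjacency_components(sigma, kk)
    which(comp[seq_len(kk - 1L)] == comp[2L:kk])
  }
  A <- A_of(k)
  prev <- if (k > 1L) A_of(k - 1L) else integer(0)
  list(A = A, delta = setdiff(A, prev))
}

# Augmented active set actually indexed by the permuted DP state: Prop-6
# conf_k plus any earlier rank whose loop to a sequence neighbor is still
# unresolved (needed so deferred E_loop terms can always be evaluated).
active_set <- function(sigma, k) {
  base <- conf_set(sigma, k)
  if (k == sigma$n) return(base)
  A <- adjacency_closure(sigma, k)$A
  extra <- integer(0)
  if (k >= 2L) {
    for (i in 1L:(k - 1L)) {
      if (!(i %in% A) || (i > 1L && !((i - 1L) %in% A))) {
        extra <- c(extra, i)
      }
    }
  }
  sort(unique(c(base, extra)))
}

#' Enumerate all circular permutations of n strands
#'
#' Yields the (n-1)! bijections of 1..n with sigma(1) = 1, in deterministic
#' lexicographic order of the remaining ranks.
#'
#' @param n Number of strands, >= 2.
#' @return A list of [barrel_permutation()] objects.
#' @examples
#' length(enumerate_circular_permutations(5)) # 24
#' @export
enumerate_circular_permutations <- function(n) {
  stopifnot(n >= 2L)
  rest <- permute_all(seq(2L, n))
  lapply(rest, function(p) barrel_permutation(c(1L, p)))
}

# All permutations of a vector, lexicographic, plain recursion.
permute_all <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in permute_all(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], tail)
    }
  }
  out
}

#' Permutations built from disjoint Greek key motifs
#'
#' Starting from the identity, a Greek key motif replaces four consecutive
#' ranks i+1..i+4 by one of the two canonical strand orders
#' (i+3, i+2, i+1, i+4) or (i+1, i+4, i+3, i+2). Motifs must not overlap,
#' and sigma(1) = 1 restricts the first form to i >= 1. Enumerates every
#' such permutation for a given n (the identity itself included).
#'
#' @param n Number of strands, >= 2.
#' @return A list of [barrel_permutation()] objects, deterministic order.
#' @examples
#' gk <- greek_key_permutations(6)
#' any(vapply(gk, function(p) identical(p$sigma, c(1L,2L,5L,4L,3L,6L)),
#'            logical(1)))
#' @export
greek_key_permutations <- function(n) {
  stopifnot(n >= 2L)
  motif <- function(i, form) {
    if (form == 1L) c(i + 3L, i + 2L, i + 1L, i + 4L)
    else c(i + 1L, i + 4L, i + 3L, i + 2L)
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  emit <- function(sigma) {
    key <- paste(sigma, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <<- barrel_permutation(sigma)
    }
  }
  place <- function(sigma, from) {
    emit(sigma)
    if (from > n - 4L) return(invisible())
    for (i in from:(n - 4L)) {
      for (form in 1:2) {
        if (form == 1L && i == 0L) next # would break sigma(1) = 1
        s2 <- sigma
        s2[(i + 1L):(i + 4L)] <- motif(i, form)
        place(s2, i + 4L)
      }
    }
  }
  place(seq_len(n), 0L)
  out
}
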