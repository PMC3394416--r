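identity_permutation <- function(n) barrel_permutation(seq_len(n))

# Composed relative shear across the loop from sequence strand i to i + 1:
# the sum of per-pair optimal shears along the direct barrel arc between
# their positions. NA when some interior strand assignment is missing.
compose_shear <- function(graph, vids_by_rank, sigma, i) {
  a <- sigma$inv[i]
  b <- sigma$inv[i + 1L]
  dir <- sign(b - a)
  s <- 0L
  for (p in seq(a, b - dir, by = dir)) {
    va <- vids_by_rank[sigma$sigma[p]]
    vb <- vids_by_rank[sigma$sigma[p + dir]]
    if (is.na(va) || is.na(vb)) return(NA_integer_)
    s <- s + e_adj_opt(graph, va, vb)$s
  }
  s
}

#' Score a candidate structure against the full objective
#'
#' Recomputes, from the graph alone, the pseudo-energy
#' \eqn{E = \sum E_{intr}(v) + \sum E_{loop}(v, w) + \sum E_{adj}(v, w)}
#' of a sequence-ordered vertex tuple arranged on the barrel according to
#' sigma, together with the realized relative shears. Used by the
#' brute-force oracle and to verify solver tracebacks.
#'
#' @param graph A fold graph.
#' @param vids Integer vector of n vertex indices in sequence order.
#' @param S Required shear number; the structure is infeasible when the
#'   realized shears do not sum to S.
#' @param sigma A [barrel_permutation()] or NULL for the identity.
#' @param closed TRUE for a barrel (n adjacent pairs, wrap included),
#'   FALSE for an open sheet (n - 1 pairs, identity order only).
#' @return A list with \code{feasible}, \code{energy}, \code{criterion},
#'   \code{shears} (barrel-position order) and \code{reason} when
#'   infeasible.
#' @export
score_structure <- function(graph, vids, S, sigma = NULL, closed = TRUE) {
  n <- length(vids)
  if (n < 2L) return(list(feasible = FALSE, reason = "fewer than 2 strands"))
  sigma <- if (is.null(sigma)) identity_permutation(n) else as_permutation(sigma)
  if (sigma$n != n) stop("sigma length does not match number of strands")
  if (!closed && !identical(sigma$sigma, seq_len(n))) {
    stop("open sheets require the identity permutation")
  }
  if (any(diff(vids) <= 0L)) {
    return(list(feasible = FALSE, reason = "vertices not sequence-ordered"))
  }
  for (i in seq_len(n - 1L)) {
    if (!(vids[i + 1L] %in% graph$succ[[vids[i]]])) {
      return(list(feasible = FALSE,
                  reason = sprintf("no edge between strands %d and %d", i,
                                   i + 1L)))
    }
  }
  if (!graph$start_ok[vids[1L]] || !graph$end_ok[vids[n]]) {
    return(list(feasible = FALSE, reason = "leader or trailer too long"))
  }
  n_pairs <- if (closed) n else n - 1L
  shears <- integer(n_pairs)
  e_pairs <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- vids[sigma$sigma[p]]
    b <- vids[sigma$sigma[if (p == n) 1L else p + 1L]]
    opt <- e_adj_opt(graph, a, b)
    if (!is.finite(opt$energy)) {
      return(list(feasible = FALSE,
                  reason = sprintf("unusable strand pair at barrel position %d",
                                   p)))
    }
    shears[p] <- opt$s
    e_pairs[p] <- opt$energy
  }
  if (sum(shears) != S) {
    return(list(feasible = FALSE, reason = "shear constraint unmet",
                shears = shears))
  }
  vr <- vids # rank -> vertex
  e_loops <- vapply(seq_len(n - 1L), function(i) {
    t_i <- abs(sigma$inv[i + 1L] - sigma$inv[i])
    e_loop(graph, vids[i], vids[i + 1L], t_i,
           compose_shear(graph, vr, sigma, i), n)
  }, numeric(1L))
  E <- sum(vapply(vids, function(v) e_intr(graph, v), numeric(1L))) +
    e_loop(graph, 0L, vids[1L]) + e_loop(graph, vids[n], 0L) +
    sum(e_loops) + sum(e_pairs)
  list(feasible = TRUE, energy = E, criterion = -E, shears = shears)
}

# Construct the solver result object. vids in sequence order; shears in
# barrel-position order (pair p joins positions p and p+1; for closed
# structures pair n wraps to position 1).
barrel_structure <- function(graph, vids, n, S, sigma, shears, energy,
                             closed = TRUE) {
  structure(list(
    feasible = TRUE, n = n, S = S,
    sigma = sigma$sigma, sigma_inv = sigma$inv,
    vids = vids,
    strands = graph$vertices[vids, , drop = FALSE],
    relative_shears = shears,
    energy = energy, criterion = -energy,
    closed = closed,
    seq = graph$seq
  ), class = "barrel_structure")
}

no_solution <- function(reason) {
  structure(list(feasible = FALSE, reason = reason),
            class = "barrel_structure")
}

#' @export
print.barrel_structure <- function(x, ...) {
  if (!x$feasible) {
    cat("<barrel_structure> infeasible:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<barrel_structure> %s n=%d S=%d E=%.3f C=%.3f\n",
              if (x$closed) "barrel" else "sheet", x$n, x$S, x$energy,
              x$criterion))
  cat("  sigma: (", paste(x$sigma, collapse = " "), ")\n", sep = "")
  df <- x$strands
  cat(sprintf("  strand %d: %d-%d %s %s\n", seq_len(x$n), df$nu, df$kappa,
              df$dir, df$facing), sep = "")
  invisible(x)
}

#' Per-residue states implied by a structure
#'
#' @param structure A feasible [fold_barrel()]-style result.
#' @param N Sequence length (defaults to the structure's own sequence).
#' @return Character vector over \code{{"S", "L"}} of length N.
#' @export
structure_states <- function(structure, N = NULL) {
  stopifnot(inherits(structure, "barrel_structure"), structure$feasible)
  if (is.null(N)) {
    if (is.null(structure$seq)) stop("structure carries no sequence; give N")
    N <- structure$seq$N
  }
  states <- rep("L", N)
  for (i in seq_len(nrow(structure$strands))) {
    states[structure$strands$nu[i]:structure$strands$kappa[i]] <- "S"
  }
  states
}

#' Write a predicted structure to disk
#'
#' Produces two text files: \code{<path>.ann}, the per-residue strand
#' annotation (readable back with [read_annotation()]), and
#' \code{<path>.tsv}, a strand table (sequence index, bounds, barrel
#' position, direction, facing, relative shear to the next barrel
#' neighbor) preceded by header lines with n, S, sigma and the total
#' pseudo-energy.
#'
#' @param structure A feasible \code{barrel_structure} holding its
#'   sequence.
#' @param path Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "barrel_structure"))
  if (!structure$feasible) stop("cannot write an infeasible structure")
  if (is.null(structure$seq)) stop("structure carries no sequence")
  ann <- paste0(path, ".ann")
  tsv <- paste0(path, ".tsv")
  lab <- labeled_structure(structure$seq, structure_states(structure))
  write_annotation(lab, ann)
  con <- file(tsv, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n=%d S=%d energy=%.6f", structure$n, structure$S,
            structure$energy),
    sprintf("# sigma=%s", paste(structure$sigma, collapse = ",")),
    "strand\tstart\tend\tbarrel_position\tdirection\tfacing\tshear_to_next"
  ), con)
  df <- structure$strands
  n_sh <- length(structure$relative_shears)
  for (i in seq_len(structure$n)) {
    pos <- structure$sigma_inv[i]
    shear <- if (pos <= n_sh) structure$relative_shears[pos] else NA_integer_
    writeLines(sprintf("%d\t%d\t%d\t%d\t%s\t%s\t%s", i, df$nu[i],
                       df$kappa[i], pos, df$dir[i], df$facing[i],
                       as.character(shear)), con)
  }
  invisible(c(ann, tsv))
}
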