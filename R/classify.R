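#' Classify a sequence as TMB or non-TMB
#'
#' Runs the full pipeline: strand filtering, graph construction, and
#' closed-barrel folding over every admissible (n, S) couple. The sequence
#' is accepted as a transmembrane beta-barrel when some couple admits a
#' feasible structure whose per-strand criterion C/n reaches the
#' configured threshold; sequences whose filter output cannot support any
#' barrel are rejected outright.
#'
#' @param seq A [protein_sequence()].
#' @param table A [train_block_table()].
#' @param config A [run_config()] list.
#' @return A list of class \code{"classification_result"} with elements
#'   \code{decision} ("TMB"/"non-TMB"), \code{best_structure} (a
#'   \code{barrel_structure} or NULL), \code{per_strand_criterion} and
#'   \code{scanned} (data.frame of n, S, criterion; NA when infeasible).
#' @export
classify <- function(seq, table, config = run_config()) {
  pairs <- enumerate_nS(seq$N, config)
  scanned <- cbind(pairs, criterion = rep(NA_real_, nrow(pairs)))
  result <- function(best, crit) {
    structure(list(
      decision = if (!is.null(best) &&
                       isTRUE(crit >= config$classify_threshold)) "TMB"
        else "non-TMB",
      best_structure = best,
      per_strand_criterion = crit,
      scanned = scanned
    ), class = "classification_result")
  }
  if (nrow(pairs) == 0L) return(result(NULL, NA_real_))
  candidates <- candidate_segments(seq, table, config)
  if (nrow(candidates) < min(pairs$n)) return(result(NULL, NA_real_))
  graph <- build_fold_graph(seq, table, config, candidates = candidates)
  best <- NULL
  for (n in unique(pairs$n)) {
    rows <- which(pairs$n == n)
    sts <- fold_barrel_scan(graph, n, pairs$S[rows])
    for (i in seq_along(rows)) {
      st <- sts[[i]]
      if (st$feasible) {
        scanned$criterion[rows[i]] <- st$criterion
        if (is.null(best) || st$criterion > best$criterion) best <- st
      }
    }
  }
  crit <- if (is.null(best)) NA_real_ else best$criterion / best$n
  result(best, crit)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (per-strand criterion: %s)\n",
              x$decision,
              if (is.na(x$per_strand_criterion)) "none"
              else sprintf("%.3f", x$per_strand_criterion)))
  invisible(x)
}

#' Energy landscape over barrel permutations
#'
#' Folds the same graph under each supplied permutation at fixed (n, S)
#' and reports the pseudo-energy per permutation, flagging the low-energy
#' set within a fractional window above the minimum (the candidate set a
#' screening study would retain).
#'
#' @param graph A fold graph.
#' @param n,S Barrel size and shear number.
#' @param permutations List of [barrel_permutation()] objects (e.g. from
#'   [enumerate_circular_permutations()]).
#' @param window Fraction of |min energy| defining the low-energy window;
#'   0 keeps only the global minimizer(s).
#' @return A data.frame with columns \code{sigma} (comma-joined ranks),
#'   \code{energy} (NA when infeasible) and \code{in_window}.
#' @export
permutation_landscape <- function(graph, n, S, permutations,
                                  window = 0.02) {
  energy <- vapply(permutations, function(p) {
    st <- fold_barrel_permuted(graph, n, S, p)
    if (st$feasible) st$energy else NA_real_
  }, numeric(1L))
  sig <- vapply(permutations, function(p) paste(p$sigma, collapse = ","),
                character(1L))
  in_window <- rep(FALSE, length(energy))
  if (any(!is.na(energy))) {
    emin <- min(energy, na.rm = TRUE)
    cutoff <- emin + window * abs(emin)
    in_window <- !is.na(energy) & energy <= cutoff
  }
  data.frame(sigma = sig, energy = energy, in_window = in_window,
             stringsAsFactors = FALSE)
}
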