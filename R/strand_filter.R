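CONFORMATIONS <- c("strand", "other")

other_conf <- function(tau) if (tau == "strand") "other" else "strand"

#' Train the block-frequency table of the information filter
#'
#' Counts every length-l window that lies fully inside a single
#' conformation run of the training structures. Laplace smoothing over the
#' 20^l block space is applied lazily per queried cell, so unseen blocks
#' never yield infinite log scores while the stored table stays sparse.
#'
#' @param training Non-empty list of [labeled_structure()] objects.
#' @param l Block length in residues.
#' @param pseudocount Smoothing constant added to every cell.
#' @return A list of class \code{"block_table"} with per-conformation
#'   named count vectors and smoothed marginals.
#' @export
train_block_table <- function(training, l = 3L, pseudocount = 1) {
  if (length(training) == 0L) stop("empty training set")
  if (l < 1L) stop("block length must be >= 1")
  counts <- list(strand = list(), other = list())
  env <- list(strand = new.env(parent = emptyenv()),
              other = new.env(parent = emptyenv()))
  for (lab in training) {
    stopifnot(inherits(lab, "labeled_structure"))
    r <- rle(lab$states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    str <- seq_string(lab$sequence)
    for (k in seq_along(r$values)) {
      run_len <- r$lengths[k]
      if (run_len < l) next
      tau <- if (r$values[k] == "S") "strand" else "other"
      e <- env[[tau]]
      for (i in starts[k]:(ends[k] - l + 1L)) {
        block <- substr(str, i, i + l - 1L)
        e[[block]] <- (if (is.null(e[[block]])) 0 else e[[block]]) + 1
      }
    }
  }
  cnt <- lapply(env, function(e) {
    v <- unlist(as.list(e))
    if (is.null(v)) v <- numeric(0)
    v[order(names(v))]
  })
  n_blocks <- 20^l
  raw_tot <- vapply(cnt, sum, numeric(1L))
  structure(list(
    l = as.integer(l),
    pseudocount = pseudocount,
    counts = cnt,
    # smoothed marginals: every one of the 20^l cells carries +pseudocount
    f_tau = raw_tot + pseudocount * n_blocks,
    n_blocks = n_blocks
  ), class = "block_table")
}

#' @export
print.block_table <- function(x, ...) {
  cat(sprintf(
    "<block_table> l=%d, %d strand / %d other blocks observed, pseudocount=%g\n",
    x$l, length(x$counts$strand), length(x$counts$other), x$pseudocount))
  invisible(x)
}

# Smoothed cell frequency f_{tau,r}; r may be a vector of blocks.
block_count <- function(table, tau, r) {
  v <- table$counts[[tau]][r]
  v[is.na(v)] <- 0
  unname(v) + table$pseudocount
}

#' Information carried by a block about a conformation
#'
#' Computes \eqn{I(\tau; r) = \log[(f_{\tau,r}/f_{\cdot,r}) \cdot
#' (f_{\cdot,\cdot}/f_{\tau,\cdot})]} from the smoothed table. Zero means
#' the block carries no information about the conformation; positive values
#' favor it.
#'
#' @param table A [train_block_table()] result.
#' @param tau \code{"strand"} or \code{"other"}.
#' @param r Block string(s) of length \code{table$l}.
#' @return Numeric vector in natural-log units.
#' @export
block_info <- function(table, tau, r) {
  stopifnot(tau %in% CONFORMATIONS)
  f_tr <- block_count(table, tau, r)
  f_dr <- block_count(table, "strand", r) + block_count(table, "other", r)
  f_t <- table$f_tau[[tau]]
  f_dd <- sum(table$f_tau)
  log((f_tr / f_dr) * (f_dd / f_t))
}

#' Preference of a block for one conformation over the other
#'
#' \eqn{I(\tau:\bar\tau; r) = I(\tau;r) - I(\bar\tau;r) =
#' \log[(f_{\tau,r}/f_{\tau,\cdot}) / (f_{\bar\tau,r}/f_{\bar\tau,\cdot})]},
#' antisymmetric in the two conformations.
#'
#' @inheritParams block_info
#' @return Numeric vector in natural-log units.
#' @export
block_preference <- function(table, r, tau = "strand") {
  stopifnot(tau %in% CONFORMATIONS)
  taub <- other_conf(tau)
  log((block_count(table, tau, r) / table$f_tau[[tau]]) /
        (block_count(table, taub, r) / table$f_tau[[taub]]))
}

segment_blocks <- function(segment, l) {
  p <- nchar(segment)
  substring(segment, 1:(p - l + 1L), l:p)
}

#' Segment score of the information filter
#'
#' Sums the block preferences over every length-l block of the segment and
#' charges \eqn{-\log\rho} per block:
#' \eqn{\tilde I = \sum_i I(\tau:\bar\tau; r_i..r_{i+l-1}) -
#' \log\rho \cdot (p-l+1)}. The segment is a candidate for \code{tau} when
#' the score is positive.
#'
#' @param table A [train_block_table()] result.
#' @param segment Residue string of length p >= l.
#' @param rho Threshold \eqn{\rho}; values below 1 turn the per-block
#'   charge into a bonus, loosening the filter.
#' @param tau Conformation scored in the numerator.
#' @return The scalar score \eqn{\tilde I}.
#' @export
segment_score <- function(table, segment, rho = 2 / 3, tau = "strand") {
  l <- table$l
  p <- nchar(segment)
  if (p < l) stop("segment shorter than block length (", p, " < ", l, ")")
  blocks <- segment_blocks(segment, l)
  sum(block_preference(table, blocks, tau)) - log(rho) * length(blocks)
}

#' Side-averaged hydrophobicities of a segment
#'
#' A beta-strand directs side chains alternately to its two faces, so the
#' residues at even and odd absolute sequence positions of a segment form
#' its two sides. Returns the Kyte-Doolittle means of both.
#'
#' @param seq A [protein_sequence()].
#' @param i,j Segment bounds, 1-based inclusive, \code{j > i}.
#' @return Named numeric vector \code{c(H_even =, H_odd =)}.
#' @export
side_averages <- function(seq, i, j) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (i < 1L || j > seq$N || i > j) stop("invalid segment bounds")
  if (i == j) stop("single-residue segment has an empty side")
  pos <- i:j
  H <- hydropathy(seq$residues[pos])
  even <- pos %% 2L == 0L
  c(H_even = mean(H[even]), H_odd = mean(H[!even]))
}

#' Enumerate candidate membrane-spanning strand segments
#'
#' Scans all segments whose length lies within the configured bounds and
#' keeps those that satisfy both amphipathicity constraints
#' (\eqn{\max\{H^e, H^o\} > \zeta^-} and \eqn{\min\{H^e, H^o\} < \zeta^+})
#' and a positive information score for the strand conformation. The facing
#' is \code{odd_inward} when the odd side is the hydrophilic one; on an
#' exact tie both orientations are emitted.
#'
#' @param seq A [protein_sequence()].
#' @param table A [train_block_table()] result.
#' @param config A [run_config()] list.
#' @return A data.frame with columns \code{start}, \code{end},
#'   \code{facing}, \code{H_even}, \code{H_odd}, \code{score}, sorted by
#'   (start, end).
#' @export
candidate_segments <- function(seq, table, config = run_config()) {
  stopifnot(inherits(seq, "protein_sequence"))
  N <- seq$N
  lmin <- max(config$strand_len_bounds[1L], table$l, 2L)
  lmax <- config$strand_len_bounds[2L]
  H <- hydropathy(seq$residues, unknown = config$unknown_hydropathy)
  str <- seq_string(seq)
  pref <- local({
    # per-position block preference, precomputed once
    if (N < table$l) numeric(0) else {
      blocks <- substring(str, 1:(N - table$l + 1L),
                          table$l:N)
      block_preference(table, blocks, "strand")
    }
  })
  cpref <- c(0, cumsum(pref))
  ceven <- c(0, cumsum(H * (seq_len(N) %% 2L == 0L)))
  codd <- c(0, cumsum(H * (seq_len(N) %% 2L == 1L)))
  neven <- c(0, cumsum(seq_len(N) %% 2L == 0L))
  rows <- list()
  for (i in seq_len(N)) {
    for (len in lmin:lmax) {
      j <- i + len - 1L
      if (j > N) break
      n_even <- neven[j + 1L] - neven[i]
      n_odd <- len - n_even
      if (n_even == 0L || n_odd == 0L) next
      H_even <- (ceven[j + 1L] - ceven[i]) / n_even
      H_odd <- (codd[j + 1L] - codd[i]) / n_odd
      if (!(max(H_even, H_odd) > config$zeta_minus &&
              min(H_even, H_odd) < config$zeta_plus)) next
      nb <- len - table$l + 1L
      score <- (cpref[i + nb] - cpref[i]) - log(config$rho) * nb
      if (score <= 0) next
      facing <- if (H_odd < H_even) "odd_inward"
        else if (H_even < H_odd) "odd_outward"
        else c("odd_inward", "odd_outward")
      for (f in facing) {
        rows[[length(rows) + 1L]] <- list(
          start = i, end = j, facing = f,
          H_even = H_even, H_odd = H_odd, score = score)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      facing = character(0), H_even = numeric(0),
                      H_odd = numeric(0), score = numeric(0)))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$start, out$end, out$facing), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a block table as TSV
#'
#' Columns: conformation, block, raw count; a header comment records the
#' block length and pseudocount. Rows are ordered deterministically.
#'
#' @param table A [train_block_table()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_block_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# l=%d pseudocount=%g", table$l, table$pseudocount),
             con)
  writeLines("conformation\tblock\tcount", con)
  for (tau in CONFORMATIONS) {
    v <- table$counts[[tau]]
    if (length(v) > 0L) {
      writeLines(sprintf("%s\t%s\t%g", tau, names(v), v), con)
    }
  }
  invisible(path)
}

#' Read a block table written by [write_block_table()]
#'
#' @param path Input path.
#' @return A \code{"block_table"} list.
#' @export
read_block_table <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
                  regexec("^# l=(\\d+) pseudocount=([0-9.eE+-]+)", first))[[1L]]
  if (length(m) != 3L) stop("malformed block table header: ", first)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  l <- as.integer(m[2L])
  pc <- as.numeric(m[3L])
  cnt <- lapply(CONFORMATIONS, function(tau) {
    sub <- df[df$conformation == tau, , drop = FALSE]
    v <- sub$count
    names(v) <- sub$block
    v[order(names(v))]
  })
  names(cnt) <- CONFORMATIONS
  n_blocks <- 20^l
  structure(list(l = l, pseudocount = pc, counts = cnt,
                 f_tau = vapply(cnt, sum, numeric(1L)) + pc * n_blocks,
                 n_blocks = n_blocks),
            class = "block_table")
}
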