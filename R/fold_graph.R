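DIRECTIONS <- c("down", "up")
FACINGS <- c("odd_inward", "odd_outward")

#' Build oriented strand-candidate vertices
#'
#' Each filtered segment yields one vertex per direction (upward /
#' downward); the facing degree of freedom is fixed by the filter unless
#' the two side averages tied, in which case both facings already appear
#' as separate candidate rows. Vertices are returned in canonical
#' lexicographic order on (start, end, direction, facing), which is also a
#' topological order of the fold graph.
#'
#' @param seq A [protein_sequence()].
#' @param candidates A [candidate_segments()] data.frame.
#' @param config A [run_config()] list.
#' @return A data.frame of vertices with columns \code{nu}, \code{kappa},
#'   \code{dir}, \code{facing}, \code{e_intr}.
#' @export
build_vertices <- function(seq, candidates, config = run_config()) {
  if (nrow(candidates) == 0L) {
    return(data.frame(nu = integer(0), kappa = integer(0),
                      dir = character(0), facing = character(0),
                      e_intr = numeric(0)))
  }
  v <- expand.grid(row = seq_len(nrow(candidates)), dir = DIRECTIONS,
                   stringsAsFactors = FALSE)
  out <- data.frame(
    nu = candidates$start[v$row],
    kappa = candidates$end[v$row],
    dir = v$dir,
    facing = candidates$facing[v$row],
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$nu, out$kappa, out$dir, out$facing), , drop = FALSE]
  rownames(out) <- NULL
  H <- hydropathy(seq$residues, unknown = config$unknown_hydropathy)
  out$e_intr <- vapply(seq_len(nrow(out)), function(i) {
    intrinsic_energy(H, out$nu[i], out$kappa[i], out$facing[i], config)
  }, numeric(1L))
  # conformational admissibility: a membrane-spanning strand must be
  # intrinsically favorable in its orientation, per residue
  out <- out[out$e_intr / (out$kappa - out$nu + 1L) < config$e_intr_max, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Lipid-facing mask for absolute positions `pos` of a strand with the given
# facing: odd_outward strands expose their odd-indexed residues to the
# bilayer.
lipid_mask <- function(pos, facing) {
  odd <- pos %% 2L == 1L
  if (facing == "odd_outward") odd else !odd
}

# Intrinsic pseudo-energy of an oriented strand. Lipid-facing residues
# contribute -H (hydrophobic burial rewarded, exposed hydrophilics
# penalized); channel-facing hydrophobics are penalized at unit weight and
# channel-facing hydrophilics rewarded at channel_weight; residues beyond
# the nominal membrane span pay the excess penalty. Independent of
# up/down.
intrinsic_energy <- function(H, nu, kappa, facing, config) {
  pos <- nu:kappa
  lip <- lipid_mask(pos, facing)
  Hc <- H[pos][!lip]
  -sum(H[pos][lip]) + sum(pmax(Hc, 0)) -
    config$channel_weight * sum(pmax(-Hc, 0)) +
    config$strand_excess_penalty *
      max(0L, length(pos) - config$min_span_residues)
}

#' Build the edge structure over strand vertices
#'
#' An edge (v, w) stands for a feasible turn/loop between two strands that
#' are consecutive along the sequence: the gap from kappa_v + 1 to
#' nu_w - 1 must hold at least 2 residues (kappa_v < nu_w - 2), fall within
#' the configured loop-length bounds, score as a turn/loop under the
#' information filter when a table is supplied, and the two strands must
#' alternate direction (antiparallel barrel). Start (top) and end (bottom)
#' attachments are controlled by the leader/trailer length limits.
#'
#' @param seq A [protein_sequence()].
#' @param vertices A [build_vertices()] data.frame in canonical order.
#' @param config A [run_config()] list.
#' @param table Optional [train_block_table()]; when given, gaps must
#'   satisfy the turn/loop information score.
#' @return A list with \code{succ} (per-vertex integer vectors of
#'   successors), \code{start_ok} and \code{end_ok} logical vectors.
#' @export
build_edges <- function(seq, vertices, config = run_config(), table = NULL) {
  M <- nrow(vertices)
  succ <- vector("list", M)
  str <- seq_string(seq)
  lmin <- config$loop_len_bounds[1L]
  lmax <- config$loop_len_bounds[2L]
  gap_ok <- new.env(parent = emptyenv())
  gap_pass <- function(a, b) { # gap interval [a, b]
    key <- paste0(a, ":", b)
    val <- gap_ok[[key]]
    if (!is.null(val)) return(val)
    len <- b - a + 1L
    ok <- len >= lmin && len <= lmax
    if (ok && !is.null(table) && len >= table$l) {
      ok <- segment_score(table, substr(str, a, b), config$rho,
                          tau = "other") > 0
    }
    gap_ok[[key]] <- ok
    ok
  }
  for (v in seq_len(M)) {
    kv <- vertices$kappa[v]
    cand <- which(vertices$nu > kv + 2L & vertices$dir != vertices$dir[v])
    if (length(cand) > 0L) {
      keep <- vapply(cand, function(w) gap_pass(kv + 1L, vertices$nu[w] - 1L),
                     logical(1L))
      succ[[v]] <- cand[keep]
    } else {
      succ[[v]] <- integer(0)
    }
  }
  list(
    succ = succ,
    start_ok = (vertices$nu - 1L) <= config$max_leader,
    end_ok = (seq$N - vertices$kappa) <= config$max_trailer
  )
}

#' Assemble the weighted fold graph for a sequence
#'
#' Runs the candidate filter, builds oriented vertices and edges, and
#' attaches the pseudo-energy callbacks. The returned object is the input
#' of every solver.
#'
#' @param seq A [protein_sequence()].
#' @param table A [train_block_table()] used by the strand filter and the
#'   turn/loop screen; may be NULL to skip information filtering of loops
#'   (the strand filter then still requires a table, so `candidates` must
#'   be supplied).
#' @param config A [run_config()] list.
#' @param candidates Optional precomputed [candidate_segments()] output.
#' @return A list of class \code{"fold_graph"}.
#' @export
build_fold_graph <- function(seq, table, config = run_config(),
                             candidates = NULL) {
  if (is.null(candidates)) {
    candidates <- candidate_segments(seq, table, config)
  }
  vertices <- build_vertices(seq, candidates, config)
  edges <- build_edges(seq, vertices, config, table)
  structure(list(
    kind = "sequence",
    seq = seq,
    H = hydropathy(seq$residues, unknown = config$unknown_hydropathy),
    vertices = vertices,
    n_vert = nrow(vertices),
    succ = edges$succ,
    start_ok = edges$start_ok,
    end_ok = edges$end_ok,
    config = config,
    cache = new.env(parent = emptyenv())
  ), class = "fold_graph")
}

#' @export
print.fold_graph <- function(x, ...) {
  cat(sprintf("<fold_graph> %d vertices, %d edges (%s)\n", x$n_vert,
              sum(lengths(x$succ)), x$kind))
  invisible(x)
}

#' Intrinsic energy of a vertex
#'
#' Default simplified potential: over the strand, lipid-facing residues
#' reward burial of hydrophobicity (-sum of positive-part hydropathy),
#' channel-facing hydrophobicity is penalized symmetrically, and each
#' residue beyond the nominal membrane span costs the configured excess
#' penalty. Lower is better; the dummy terminals have energy 0.
#'
#' @param graph A [build_fold_graph()] object.
#' @param v Vertex index, or 0 for the dummy terminals (energy 0).
#' @return Scalar energy.
#' @export
e_intr <- function(graph, v) {
  if (v == 0L) return(0)
  graph$vertices$e_intr[v]
}

# Axis coordinate -> absolute residue position for vertex v. Coordinate 1
# is the N-terminal end for upward strands and the C-terminal end for
# downward strands, so antiparallel neighbors meet head-to-tail.
axis_positions <- function(graph, v, coords) {
  nu <- graph$vertices$nu[v]
  len <- graph$vertices$kappa[v] - nu + 1L
  if (graph$vertices$dir[v] == "up") nu + coords - 1L else nu + len - coords
}

#' Pair interaction energy at a given relative shear
#'
#' The default simplified potential lays the two strands side by side: axis
#' coordinate q of `w` pairs with coordinate q + s of `v`. Each aligned
#' pair earns the backbone hydrogen-bond reward; pairs whose residues both
#' face the bilayer additionally earn a hydrophobic-packing term
#' proportional to the product of their (positive-part) hydropathies. An
#' empty overlap yields +Inf (the pair is unusable at that shear).
#' By construction \code{e_adj(w, v, -s) == e_adj(v, w, s)}.
#'
#' @param graph A fold graph.
#' @param v,w Vertex indices (0 denotes a dummy terminal: energy 0).
#' @param s Integer relative shear.
#' @return Scalar energy (possibly +Inf).
#' @export
e_adj <- function(graph, v, w, s) {
  if (v == 0L || w == 0L) return(0)
  if (graph$kind == "synthetic") {
    si <- match(s, graph$s_values)
    if (is.na(si)) return(Inf)
    return(graph$e_adj_cube[v, w, si])
  }
  cfg <- graph$config
  len_v <- graph$vertices$kappa[v] - graph$vertices$nu[v] + 1L
  len_w <- graph$vertices$kappa[w] - graph$vertices$nu[w] + 1L
  lo <- max(1L, 1L - s)
  hi <- min(len_w, len_v - s)
  if (lo > hi) return(Inf)
  q <- lo:hi
  pv <- axis_positions(graph, v, q + s)
  pw <- axis_positions(graph, w, q)
  lip <- lipid_mask(pv, graph$vertices$facing[v]) &
    lipid_mask(pw, graph$vertices$facing[w])
  Hv <- pmax(graph$H[pv], 0)
  Hw <- pmax(graph$H[pw], 0)
  -cfg$hb_reward * min(length(q), cfg$min_span_residues) -
    cfg$pair_scale * sum(Hv[lip] * Hw[lip]) +
    cfg$shear_weight * (abs(s) - cfg$shear_pref)^2
}

#' Optimal pair interaction and its relative shear
#'
#' Scans the shear grid \code{-shear_max..shear_max} and returns the
#' minimum energy with its argmin. The scan is performed once per
#' unordered pair: the reversed pair reuses the same energy with the shear
#' negated, which keeps \code{s_adj(w, v) == -s_adj(v, w)} exact even under
#' ties (ties resolve to the smallest shear of the canonically ordered
#' pair).
#'
#' @param graph A fold graph.
#' @param v,w Vertex indices (0 denotes a dummy terminal).
#' @return A list with \code{energy} and \code{s}.
#' @export
e_adj_opt <- function(graph, v, w) {
  if (v == 0L || w == 0L) return(list(energy = 0, s = 0L))
  flip <- v > w
  a <- min(v, w); b <- max(v, w)
  key <- paste0(a, ",", b)
  hit <- graph$cache[[key]]
  if (is.null(hit)) {
    grid <- shear_grid(graph)
    en <- vapply(grid, function(s) e_adj(graph, a, b, s), numeric(1L))
    i <- which.min(en) # ties: first, i.e. smallest shear
    hit <- list(energy = en[i], s = grid[i])
    if (!is.finite(hit$energy)) hit$s <- 0L
    graph$cache[[key]] <- hit
  }
  if (flip) list(energy = hit$energy, s = -hit$s) else hit
}

shear_grid <- function(graph) {
  if (graph$kind == "synthetic") graph$s_values
  else seq(-graph$config$shear_max, graph$config$shear_max)
}

#' Turn/loop energy between consecutive strands
#'
#' The gap residues between kappa_v and nu_w must be able to bridge t
#' barrel positions (length at least \code{loop_span_factor * t}) and must
#' not be majority-hydrophobic; a violation costs the configured penalty.
#' Feasible loops contribute their mean hydropathy, a weak term compared
#' with the pair energies. The relative shear \code{s} is accepted for
#' interface compatibility; the default potential does not use it.
#'
#' @param graph A fold graph.
#' @param v,w Vertex indices with v preceding w along the sequence; 0
#'   denotes a dummy terminal, whose outer-fragment energy is 0.
#' @param t Barrel-position distance between the strands, in 1..n-1.
#' @param s Relative shear across the loop (unused by the default
#'   potential).
#' @param n Optional strand count used to validate \code{t}.
#' @return Scalar energy.
#' @export
e_loop <- function(graph, v, w, t = 1L, s = NA_integer_, n = NULL) {
  if (t < 1L) stop("loop distance t must be >= 1")
  if (!is.null(n) && t > n - 1L) stop("loop distance t must be <= n - 1")
  if (v == 0L || w == 0L) return(0)
  if (graph$kind == "synthetic") {
    return(graph$e_loop_arr[v, w, min(t, dim(graph$e_loop_arr)[3L])])
  }
  cfg <- graph$config
  a <- graph$vertices$kappa[v] + 1L
  b <- graph$vertices$nu[w] - 1L
  len <- b - a + 1L
  if (len < 1L) return(cfg$loop_penalty)
  H <- graph$H[a:b]
  min_len <- max(cfg$loop_len_bounds[1L], ceiling(cfg$loop_span_factor * t))
  if (len < min_len) return(cfg$loop_penalty)
  if (sum(H > 0) > len / 2) return(cfg$loop_penalty) # hydrophobic majority
  cfg$loop_weight * mean(H)
}

#' Dump a fold graph as TSV tables
#'
#' Writes a vertex table and an edge table (with the optimal pair energy
#' and shear per edge) for inspection.
#'
#' @param graph A fold graph.
#' @param path Output path prefix; \code{<path>.vertices.tsv} and
#'   \code{<path>.edges.tsv} are written.
#' @return Invisibly, the two paths.
#' @export
write_graph <- function(graph, path) {
  vp <- paste0(path, ".vertices.tsv")
  ep <- paste0(path, ".edges.tsv")
  utils::write.table(graph$vertices, vp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rows <- list()
  for (v in seq_len(graph$n_vert)) {
    for (w in graph$succ[[v]]) {
      opt <- e_adj_opt(graph, v, w)
      rows[[length(rows) + 1L]] <- data.frame(
        from = v, to = w, e_adj = opt$energy, s_adj = opt$s,
        e_loop = e_loop(graph, v, w, 1L))
    }
  }
  edges <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(from = integer(0), to = integer(0), e_adj = numeric(0),
               s_adj = integer(0), e_loop = numeric(0))
  utils::write.table(edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vp, ep))
}
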