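#' Specification of a synthetic barrel fixture
#'
#' Describes a fully determined amphipathic barrel sequence: n strands of
#' equal length, separated by polar loops, flanked by loop-like termini.
#' Strand faces alternate hydrophobic (bilayer) and hydrophilic (channel)
#' residues; the hydrophobic face carries a period-4 two-residue registry
#' pattern whose phase advances by the planted relative shear from strand
#' to strand, so that the default pair potential recovers the planted
#' shears (exactly so for uniform shear 1 and n divisible by 4).
#'
#' @param n_strands Number of strands.
#' @param strand_len Strand length in residues (odd lengths give the
#'   cleanest pair registry; default 9, about one membrane span).
#' @param loop_len Loop length in residues.
#' @param termini Length of the leader and trailer (drawn from the loop
#'   alphabet).
#' @param relative_shears Planted per-pair relative shears, length
#'   \code{n_strands} (the last entry closes the barrel). Default uniform
#'   1, giving shear number S = n.
#' @param seed Integer seed; fixtures are bit-reproducible given
#'   (spec, seed).
#' @param hydrophobic,hydrophilic,loop_alphabet Residue alphabets for the
#'   bilayer face, the channel face, and the loops/termini.
#' @return A list of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(n_strands = 8L, strand_len = 9L, loop_len = 4L,
                         termini = 5L,
                         relative_shears = rep(1L, n_strands),
                         seed = 1L,
                         hydrophobic = c("I", "V"),
                         hydrophilic = c("D", "E", "N", "Q"),
                         loop_alphabet = c("G", "S", "P")) {
  stopifnot(n_strands >= 2L, strand_len >= 4L,
            loop_len >= 1L, termini >= 0L,
            length(relative_shears) == n_strands,
            length(intersect(hydrophobic, hydrophilic)) == 0L,
            length(intersect(hydrophobic, loop_alphabet)) == 0L)
  structure(list(n_strands = as.integer(n_strands),
                 strand_len = as.integer(strand_len),
                 loop_len = as.integer(loop_len),
                 termini = as.integer(termini),
                 relative_shears = as.integer(relative_shears),
                 seed = as.integer(seed),
                 hydrophobic = hydrophobic, hydrophilic = hydrophilic,
                 loop_alphabet = loop_alphabet),
            class = "fixture_spec")
}

#' Generate a synthetic amphipathic barrel with known structure
#'
#' Builds the sequence and its per-residue strand/loop labels. Strand i is
#' upward for odd i and downward for even i; its hydrophobic face parity
#' follows the planted shears so that adjacent faces are in registry at
#' the planted relative shear.
#'
#' @param spec A [fixture_spec()].
#' @param id Identifier of the generated record.
#' @return A [labeled_structure()]. The attribute \code{"truth"} records
#'   the planted n, S, strand intervals, directions and facings.
#' @export
make_barrel_fixture <- function(spec = fixture_spec(), id = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_strands
  L <- spec$strand_len
  # lipid-face axis-coordinate parity per strand: advancing one position
  # around the barrel shifts the face registry by the planted shear
  qlip <- (1L - cumsum(c(0L, spec$relative_shears[-n]))) %% 2L
  phase <- cumsum(c(1L, spec$relative_shears[-n])) %% 4L
  res <- character(0)
  states <- character(0)
  truth <- data.frame(start = integer(n), end = integer(n),
                      dir = character(n), facing = character(n),
                      stringsAsFactors = FALSE)
  lead <- sample(spec$loop_alphabet, spec$termini, replace = TRUE)
  res <- c(res, lead)
  states <- c(states, rep("L", spec$termini))
  for (i in seq_len(n)) {
    if (i > 1L) {
      loop <- sample(spec$loop_alphabet, spec$loop_len, replace = TRUE)
      res <- c(res, loop)
      states <- c(states, rep("L", spec$loop_len))
    }
    nu <- length(res) + 1L
    up <- i %% 2L == 1L
    strand <- character(L)
    for (t in seq_len(L)) {
      q <- if (up) t else L - t + 1L
      if (q %% 2L == qlip[i]) {
        # bilayer face: two-level registry pattern, period 4 in the axis
        # coordinate, phase advancing with the planted shears
        strand[t] <- if ((q + phase[i]) %% 4L == 0L) spec$hydrophobic[1L]
          else spec$hydrophobic[length(spec$hydrophobic)]
      } else {
        strand[t] <- sample(spec$hydrophilic, 1L)
      }
    }
    res <- c(res, strand)
    states <- c(states, rep("S", L))
    # facing: the label under which the lipid coordinates face the bilayer
    q0 <- if (qlip[i] == 1L) 1L else 2L # a lipid axis coordinate
    p_lip <- if (up) nu + q0 - 1L else nu + L - q0
    facing <- if (p_lip %% 2L == 1L) "odd_outward" else "odd_inward"
    truth[i, ] <- list(nu, nu + L - 1L, if (up) "up" else "down", facing)
  }
  trail <- sample(spec$loop_alphabet, spec$termini, replace = TRUE)
  res <- c(res, trail)
  states <- c(states, rep("L", spec$termini))
  lab <- labeled_structure(
    protein_sequence(id, paste(res, collapse = "")), states)
  attr(lab, "truth") <- list(n = n, S = sum(spec$relative_shears),
                             strands = truth)
  lab
}

#' Generate a labeled training set of synthetic barrels
#'
#' Draws \code{count} fixtures with varied strand counts and lengths under
#' a single seed; used to train the block-frequency filter without any
#' external data.
#'
#' @param count Number of structures, >= 1.
#' @param seed Integer seed.
#' @param base_spec Template [fixture_spec()]; its alphabets and termini
#'   are kept, sizes are varied.
#' @return A list of [labeled_structure()] objects.
#' @export
make_training_set <- function(count = 10L, seed = 1L,
                              base_spec = fixture_spec()) {
  stopifnot(count >= 1L)
  set.seed(seed)
  draws <- data.frame(
    n = sample(c(8L, 10L, 12L), count, replace = TRUE),
    len = sample(c(9L, 11L), count, replace = TRUE),
    loop = sample(3:6, count, replace = TRUE),
    sub_seed = sample.int(.Machine$integer.max %/% 2L, count)
  )
  lapply(seq_len(count), function(i) {
    sp <- fixture_spec(
      n_strands = draws$n[i], strand_len = draws$len[i],
      loop_len = draws$loop[i], termini = base_spec$termini,
      relative_shears = rep(1L, draws$n[i]), seed = draws$sub_seed[i],
      hydrophobic = base_spec$hydrophobic,
      hydrophilic = base_spec$hydrophilic,
      loop_alphabet = base_spec$loop_alphabet)
    make_barrel_fixture(sp, id = sprintf("fixture_%03d", i))
  })
}

#' Generate a small random fold graph for oracle testing
#'
#' Synthetic vertices carry random non-overlapping-capable intervals and
#' random energies; the pair-energy cube respects the antisymmetry
#' \code{e_adj(w, v, -s) == e_adj(v, w, s)} and contains occasional +Inf
#' sentinels (unusable pairs). Deterministic given the seed.
#'
#' @param num_vertices Number of strand vertices, <= 16.
#' @param seed Integer seed.
#' @param s_values Symmetric integer shear grid.
#' @param t_max Largest barrel-position distance with a stored loop term.
#' @param p_edge Probability that an interval-compatible pair is an edge.
#' @param exhaustive_shear Propagated to the graph configuration.
#' @return A list of class \code{"fold_graph"} (kind \code{"synthetic"}).
#' @export
make_random_graph <- function(num_vertices, seed = 1L, s_values = -3:3,
                              t_max = 11L, p_edge = 0.85,
                              exhaustive_shear = FALSE) {
  stopifnot(num_vertices <= 16L, identical(sort(-s_values), sort(s_values)))
  set.seed(seed)
  M <- num_vertices
  nu <- integer(M); kappa <- integer(M)
  pos <- 1L
  for (v in seq_len(M)) {
    pos <- pos + sample(3:6, 1L)
    nu[v] <- pos
    kappa[v] <- pos + sample(4:8, 1L)
    pos <- kappa[v]
  }
  vertices <- data.frame(
    nu = nu, kappa = kappa,
    dir = sample(DIRECTIONS, M, replace = TRUE),
    facing = sample(FACINGS, M, replace = TRUE),
    e_intr = round(stats::runif(M, -5, 0), 3),
    stringsAsFactors = FALSE)
  succ <- lapply(seq_len(M), function(v) {
    cand <- which(nu > kappa[v] + 2L)
    cand[stats::runif(length(cand)) < p_edge]
  })
  n_s <- length(s_values)
  cube <- array(0, dim = c(M, M, n_s))
  for (v in seq_len(M)) {
    for (w in seq_len(M)) {
      if (w <= v) next
      en <- round(stats::runif(n_s, -6, 0), 3)
      en[stats::runif(n_s) < 0.1] <- Inf
      cube[v, w, ] <- en
      cube[w, v, rev(seq_len(n_s))] <- en # antisymmetric shear mirror
    }
  }
  loops <- array(round(stats::runif(M * M * t_max, -1, 1), 3),
                 dim = c(M, M, t_max))
  loops[stats::runif(length(loops)) < 0.1] <- 50
  structure(list(
    kind = "synthetic",
    seq = NULL,
    vertices = vertices,
    n_vert = M,
    succ = succ,
    start_ok = stats::runif(M) < 0.9,
    end_ok = stats::runif(M) < 0.9,
    s_values = as.integer(s_values),
    e_adj_cube = cube,
    e_loop_arr = loops,
    config = list(exhaustive_shear = isTRUE(exhaustive_shear)),
    cache = new.env(parent = emptyenv())
  ), class = "fold_graph")
}
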