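#' Run configuration for barrel recognition and folding
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults reflect the geometry of bacterial outer-membrane barrels: a 30 A
#' membrane, a 3.3 A rise per residue along a strand, a 4.4 A inter-strand
#' distance, even strand counts n in 8..22 and even shear numbers S in
#' [n, 2n].
#'
#' @param rho Filter threshold \eqn{\rho} of the block-information screen
#'   (dimensionless). Each length-l block is charged \eqn{-\log\rho}; with
#'   the default 2/3 a block is accepted for a conformation even when its
#'   propensity is up to 1.5 times lower than for the alternative.
#' @param zeta_minus Lower bound \eqn{\zeta^-} for the hydrophobic side
#'   average (Kyte-Doolittle units).
#' @param zeta_plus Upper bound \eqn{\zeta^+} for the hydrophilic side
#'   average (Kyte-Doolittle units).
#' @param membrane_thickness Membrane thickness in Angstrom.
#' @param h Rise per residue along a strand, Angstrom.
#' @param d Mean distance between adjacent strands, Angstrom.
#' @param n_range Even integers: admissible strand counts.
#' @param block_len Block length l of the information filter (residues).
#' @param strand_len_bounds Length-2 integer vector: admissible strand
#'   candidate lengths (residues).
#' @param loop_len_bounds Length-2 integer vector: admissible turn/loop
#'   lengths between consecutive strands (residues).
#' @param classify_threshold Per-strand criterion cutoff for the TMB
#'   decision (criterion units per strand).
#' @param min_span_residues Nominal number of residues needed to cross the
#'   membrane; also the length of the central window used by the intrinsic
#'   strand energy.
#' @param shear_max Maximum relative-shear magnitude scanned when optimizing
#'   a strand pair; the scan grid is \code{-shear_max..shear_max}.
#' @param pseudocount Laplace smoothing constant of the block table.
#' @param hb_reward Backbone hydrogen-bond reward per aligned residue pair
#'   (energy units, subtracted).
#' @param pair_scale Scale of the hydrophobic side-chain pair term.
#' @param channel_weight Weight of the reward for hydrophilic side chains
#'   facing the aqueous channel, relative to the (unit-weight) penalty for
#'   hydrophobic ones.
#' @param loop_weight Scale of the feasible-loop energy (mean gap
#'   hydropathy); kept weak relative to the pair terms.
#' @param shear_weight Optional quadratic penalty weight pulling the
#'   per-pair shear toward \code{shear_pref} (0 disables).
#' @param shear_pref Preferred per-pair relative shear when
#'   \code{shear_weight > 0}.
#' @param strand_excess_penalty Intrinsic-energy cost per strand residue
#'   beyond the nominal membrane span (disfavors overlong candidates
#'   whose ends leave the bilayer).
#' @param e_intr_max Admissibility cut on the intrinsic strand energy: a
#'   candidate orientation is kept as a vertex only when its intrinsic
#'   energy per residue is below this value (a membrane-spanning strand
#'   must be intrinsically favorable). The default is calibrated to the
#'   simplified hydropathy potential; \code{Inf} disables the cut.
#' @param loop_penalty Energy charged to an infeasible turn/loop.
#' @param loop_span_factor A loop bridging t barrel positions must contain
#'   at least \code{loop_span_factor * t} residues.
#' @param max_leader,max_trailer Maximum length of the substring before the
#'   first strand / after the last strand (residues; \code{Inf} to disable).
#' @param exhaustive_shear If TRUE the solvers branch over the full shear
#'   grid per pair instead of fixing the per-pair optimum s_adj. Slower, but
#'   can reach (n, S) combinations the fixed-shear scheme misses.
#' @param unknown_hydropathy Hydropathy assigned to non-standard residue
#'   codes (B, Z, X, U, ...).
#' @return A list of class \code{"bf_config"}.
#' @examples
#' cfg <- run_config()
#' cfg$rho
#' @export
run_config <- function(rho = 2 / 3,
                       zeta_minus = -1,
                       zeta_plus = 1,
                       membrane_thickness = 30,
                       h = 3.3,
                       d = 4.4,
                       n_range = seq(8L, 22L, by = 2L),
                       block_len = 3L,
                       strand_len_bounds = c(6L, 22L),
                       loop_len_bounds = c(2L, 25L),
                       classify_threshold = 0.85,
                       min_span_residues = 8L,
                       shear_max = 4L,
                       pseudocount = 1,
                       hb_reward = 1,
                       pair_scale = 0.25,
                       channel_weight = 0.4,
                       loop_weight = 0.25,
                       shear_weight = 0,
                       shear_pref = 1L,
                       strand_excess_penalty = 1,
                       e_intr_max = -2.2,
                       loop_penalty = 1000,
                       loop_span_factor = 2,
                       max_leader = 30L,
                       max_trailer = 30L,
                       exhaustive_shear = FALSE,
                       unknown_hydropathy = 0) {
  cfg <- list(
    rho = rho, zeta_minus = zeta_minus, zeta_plus = zeta_plus,
    membrane_thickness = membrane_thickness, h = h, d = d,
    n_range = as.integer(n_range), block_len = as.integer(block_len),
    strand_len_bounds = as.integer(strand_len_bounds),
    loop_len_bounds = as.integer(loop_len_bounds),
    classify_threshold = classify_threshold,
    min_span_residues = as.integer(min_span_residues),
    shear_max = as.integer(shear_max), pseudocount = pseudocount,
    hb_reward = hb_reward, pair_scale = pair_scale,
    channel_weight = channel_weight, loop_weight = loop_weight,
    shear_weight = shear_weight, shear_pref = as.integer(shear_pref),
    strand_excess_penalty = strand_excess_penalty,
    e_intr_max = e_intr_max,
    loop_penalty = loop_penalty, loop_span_factor = loop_span_factor,
    max_leader = max_leader, max_trailer = max_trailer,
    exhaustive_shear = isTRUE(exhaustive_shear),
    unknown_hydropathy = unknown_hydropathy
  )
  class(cfg) <- "bf_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$rho > 0,
    cfg$h > 0, cfg$d > 0, cfg$membrane_thickness > 0,
    cfg$block_len >= 1L,
    length(cfg$strand_len_bounds) == 2L,
    cfg$strand_len_bounds[1L] >= 2L,
    cfg$strand_len_bounds[1L] <= cfg$strand_len_bounds[2L],
    length(cfg$loop_len_bounds) == 2L,
    cfg$loop_len_bounds[1L] >= 0L,
    cfg$loop_len_bounds[1L] <= cfg$loop_len_bounds[2L],
    cfg$shear_max >= 0L,
    cfg$pseudocount > 0,
    cfg$loop_penalty > 0
  )
  if (length(cfg$n_range) > 0L) {
    if (any(cfg$n_range %% 2L != 0L)) {
      stop("n_range must contain even integers only")
    }
    if (any(cfg$n_range < 8L | cfg$n_range > 22L)) {
      stop("n_range must lie within [8, 22]")
    }
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments.
#' @return A \code{"bf_config"} list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(run_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0L) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Admissible (n, S) couples for a sequence
#'
#' Enumerates even strand counts n from the configured range and even shear
#' numbers S in [n, 2n], keeping only the n for which the sequence is long
#' enough to host n minimal strands separated by minimal loops.
#'
#' @param N Sequence length in residues.
#' @param config A [run_config()] list.
#' @return A data.frame with integer columns \code{n} and \code{S}, sorted
#'   by (n, S). May have zero rows for short sequences.
#' @examples
#' subset(enumerate_nS(200, run_config()), n == 8)
#' @export
enumerate_nS <- function(N, config = run_config()) {
  min_unit <- config$strand_len_bounds[1L] + config$loop_len_bounds[1L]
  ns <- config$n_range[config$n_range * min_unit <= N]
  if (length(ns) == 0L) {
    return(data.frame(n = integer(0), S = integer(0)))
  }
  out <- do.call(rbind, lapply(ns, function(n) {
    S <- seq(n, 2L * n, by = 2L)
    data.frame(n = rep.int(n, length(S)), S = S)
  }))
  out[order(out$n, out$S), , drop = FALSE]
}
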