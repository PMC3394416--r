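---
title: "Recognizing and folding transmembrane beta-barrels by constrained longest paths"
author: "barrelfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and folding transmembrane beta-barrels by constrained longest paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelfold)
```

## The problem

Transmembrane beta-barrel (TMB) proteins cross the outer membrane of
Gram-negative bacteria (and of mitochondria and chloroplasts) as a closed
cylinder of antiparallel beta-strands. A regular barrel is described by
two integers: the number of strands $n$ and the shear number $S$, the
ordinal offset accumulated along one hydrogen-bonded turn around the
barrel. Together with the rise per residue $h \approx 3.3$ Å and the
inter-strand distance $d \approx 4.4$ Å they fix the strand tilt against
the barrel axis,

$$\tan\theta = \frac{hS}{dn},$$

and, with the membrane thickness, the number of residues a strand needs
to span the bilayer. `barrelfold` predicts the super-secondary structure
of a TMB — which segments are membrane-spanning strands, in which order
they sit around the barrel, and with which per-pair relative shears — and
classifies sequences as TMB or non-TMB, all from the sequence alone.

## Pipeline

1. **Strand filtering.** Candidate membrane-spanning strands must be
   amphipathic: the mean Kyte–Doolittle hydropathy of one face (residues
   at even absolute positions vs odd) must exceed $\zeta^- = -1$ while
   the other face stays below $\zeta^+ = +1$. A block-frequency model
   trained on labeled structures adds an information score: for blocks of
   $l = 3$ residues, the preference of block $r$ for the strand
   conformation is the log-ratio of its smoothed relative frequencies in
   the two conformations, and a segment is accepted when the sum of its
   block preferences exceeds $\log\rho$ per block ($\rho = 2/3$ by
   default; values below 1 deliberately loosen the screen to limit
   dependence on the small training set).

2. **Graph construction.** Each accepted segment becomes up to four
   vertices (upward/downward orientation times inward/outward facing,
   the latter usually fixed by the filter). An edge $(v, w)$ states that
   the gap between the two strands can form a turn or loop: at least two
   residues ($\kappa_v < \nu_w - 2$), within configurable length bounds,
   not majority-hydrophobic, scoring as turn/loop under the block model,
   and with alternating strand direction. The graph is a DAG; the
   canonical vertex order (start, end, direction, facing) is topological.

3. **Constrained longest paths.** With pseudo-energies attached
   (below), folding is the search for the $\top \to \bot$ path with
   exactly $n$ strand vertices that maximizes the criterion $C = -E$
   subject to the shear constraint $\sum s_{adj} = S$. Open sheets track
   one active vertex; closed barrels also track the first vertex so the
   wrap pair (last strand, first strand) can be scored at closing;
   permuted barrels (Greek key / Jelly roll strand orders, given as a
   circular permutation $\sigma$ with $\sigma(1)=1$) track the tuple of
   *active* ranks — strands whose barrel neighbors are not all placed
   yet — with per-level costs added exactly when the corresponding
   adjacency or loop becomes determined.

## The simplified pseudo-energy

The published atomistic terms for this family of models (rotamer
libraries, force-field partial charges) are not reproducible from the
literature values alone, so `barrelfold` ships a pluggable simplified
potential in plain Kyte–Doolittle units. It was calibrated once against
the synthetic fixtures (below) so that a noiseless planted barrel is the
strict global optimum, and then frozen:

* **Intrinsic strand energy** `e_intr`: over the strand,
  lipid-facing residues contribute $-H(r)$ (burial of hydrophobics is
  favorable, exposing hydrophilics to the bilayer is penalized);
  channel-facing hydrophobics are penalized at unit weight and
  channel-facing hydrophilics rewarded at `channel_weight` = 0.4; every
  residue beyond the nominal membrane span (`min_span_residues` = 8)
  costs `strand_excess_penalty` = 1. The per-residue value also acts as
  a vertex admissibility cut (`e_intr_max` = -2.2): windows that are not
  clearly amphipathic in registry never enter the graph, which keeps
  $|V|$ linear in $N$ with a small constant.
* **Pair energy** `e_adj(v, w, s)`: the strands are laid side by side
  with relative shear $s$; every aligned residue pair earns the backbone
  hydrogen-bond reward `hb_reward` = 1 (capped at `min_span_residues`
  pairs, since contacts outside the membrane span do not stabilize the
  barrel), and pairs with both residues lipid-facing earn
  $-\mathrm{pair\_scale} \cdot H^+(a) H^+(b)$ with $H^+ = \max(H, 0)$
  and `pair_scale` = 0.25. An empty overlap yields $+\infty$ (the pair
  is unusable). `e_adj_opt` scans the symmetric grid
  $s \in -\mathrm{shear\_max} .. \mathrm{shear\_max}$ once per unordered
  pair, which keeps $s_{adj}(w,v) = -s_{adj}(v,w)$ exact even under
  ties. The grid is symmetric because the wrap pair of a closed barrel
  is traversed against the canonical order; the realized barrel-direction
  shears remain small non-negative integers for right-tilted barrels.
* **Loop energy** `e_loop(v, w, t, s)`: a loop bridging $t$ barrel
  positions must contain at least $\max(2, 2t)$ residues and must not be
  majority-hydrophobic, else it costs `loop_penalty` = 1000; feasible
  loops contribute `loop_weight` = 0.25 times their mean hydropathy, a
  deliberately weak term. The relative shear argument is accepted for
  interface compatibility but unused by the default potential — this is
  also why the permuted solver can defer loop terms without enlarging
  its state space (see below). Leading and trailing fragments are free
  (energy 0) but bounded in length by `max_leader` / `max_trailer`.

Every term is a plain R function of the graph, so a richer potential can
be substituted without touching the solvers.

## The permuted dynamic program

Level $k$ places the $k$-th strand (in sequence order) at barrel
position $\sigma^{-1}(k)$, between the ranks `left_k` and `right_k`.
Shear bookkeeping differs superficially from the textbook presentation
of such recurrences: the accumulator $h$ collects $s_{adj}$ only for
adjacencies *realized* at level $k$ (those with `left_k` < k and/or
`right_k` < k), exactly mirroring how each pair energy is counted once
at the level of its later strand. At $k = n$ the accumulator equals the
full barrel sum, so reading the optimum at $h = S$ enforces the shear
constraint without any provisional correction terms for not-yet-adjacent
pairs.

The state tuple is indexed by an *augmented* active set: the classical
active ranks (those with a barrel neighbor still unplaced) plus any rank
whose loop to a sequence neighbor is not yet determined by the realized
adjacencies. For the identity and for single Greek key motifs the two
sets coincide, and the tested state counts respect the
$O(N^{\max_k \lVert conf_k \rVert})$ bound. For some permutations with
two adjacent motifs — e.g. $\sigma = (1,4,3,2,7,6,5,8)$ — a deferred
loop's endpoint has left the classical active set before the loop
resolves, and the augmented set keeps one extra rank; the solver stays
exact at the cost of one power of $N$ in the worst case. Composed loop
shears are evaluated from the currently active assignment along the
direct barrel arc; since the default loop potential ignores the shear,
states never need to be split by it.

Ties between equal-criterion solutions are broken deterministically: the
solvers scan predecessors in canonical order and replace only on strict
improvement, and the exhaustive oracle enumerates paths
lexicographically, so repeated runs return identical structures.

## Classification

`classify()` runs the pipeline over every admissible couple: $n$ even in
8..22 and $S$ even in $[n, 2n]$, restricted to $n$ small enough for the
sequence to host $n$ minimal strands and loops. The level recursion of
the barrel solver is independent of $S$, so all shear numbers of one $n$
are solved with a single pass plus cheap closing steps
(`fold_barrel_scan()`). A sequence is called TMB when some couple admits
a feasible barrel whose per-strand criterion $C/n$ reaches
`classify_threshold`. The threshold's published nominal value (0.85) is
tied to an energy scale this package does not reproduce; with the
simplified potential any feasible fixture barrel clears it by a wide
margin, and the parameter chiefly serves the monotonicity contract:
raising it can only flip decisions from TMB to non-TMB.

By default the solvers fix each pair at its optimal shear
$s_{adj}(v, w)$, following the recurrences as published; this scheme can
miss couples $(n, S)$ that are only attainable with suboptimal per-pair
shears. `exhaustive_shear = TRUE` branches over the whole grid instead,
at a factor $|{\rm grid}|$ in time, and is the honest fallback when a
specific $S$ must be enforced.

## Synthetic fixtures

`make_barrel_fixture()` builds fully determined barrel sequences:
$n$ strands (default 8) of `strand_len` = 9 residues, alternating
hydrophobic ({I, V}) and hydrophilic ({D, E, N, Q}) faces, separated by
`loop_len` = 4 residues from {G, S, P} and flanked by 5-residue termini
drawn from the same loop alphabet. The hydrophobic face carries a
period-4 two-level registry pattern (I peaks on a V background) whose
phase advances by the planted relative shear from strand to strand, so
the pair potential's optimum reproduces the planted shears. Three
choices matter and are deliberate:

* *Uniform planted shear 1 (S = n).* The registry pattern closes
  consistently around the barrel exactly when $S \equiv 0 \pmod 4$, so
  the default 8-strand fixture uses uniform shear 1; recovery is
  guaranteed for $n$ divisible by 4. Other shear vectors can be planted
  (they appear in the labels and the truth attribute) but are not
  energy-recoverable ground truth.
* *Odd strand length.* With an even length the number of lipid-lipid
  contacts differs between shears $+1$ and $-1$, and the contact count
  overwhelms the registry signal; odd lengths make the two shifts
  symmetric so the registry decides.
* *Loop-like termini.* Strong hydrophilics immediately flanking a
  strand are indistinguishable from channel-facing strand extensions
  under a hydropathy-only potential, so termini are drawn from the loop
  alphabet.

What the fixtures do *not* emulate: real membrane strands have noisy,
overlapping hydropathy distributions; loops contain hydrophobic
residues; strand lengths vary within one protein; barrels have
broken strands and domains outside the membrane. Passing the planted
recovery suite therefore demonstrates that the machinery — filter,
graph, constrained DP, traceback, metrics — is internally correct, not
that the simplified potential folds real proteins at the accuracy the
published atomistic variants report.

## Study sizes and numerical choices

The end-to-end tests use 8-strand fixtures (sequence length ~107), a
training set of 10 labeled fixtures for the block table (Laplace
pseudocount 1 over the $20^3$ block space; natural logarithms — only the
sign of the segment score matters), and oracle suites of 100 random
graphs with up to 12 vertices, where `brute_force_fold()` enumerates
every edge-connected $n$-tuple and, in exhaustive-shear mode, every
shear assignment. These sizes keep a full run in a few minutes on one
core while covering all three solvers, both printed Greek key motif
forms, and all circular permutations up to $n = 9$ for the active-set
bounds. Degenerate inputs are explicit: infeasible $(n, S)$ returns a
no-solution object rather than an error; empty filter output classifies
as non-TMB; unknown residue codes get neutral hydropathy with a warning.

## Evaluation conventions

Residue-level reports use strand as the positive class, with
"specificity" meaning precision TP/(TP+FP) — the convention that makes
the reported F-score the harmonic mean of the specificity and
sensitivity columns — and the Matthews correlation set to 0 when a
marginal vanishes. Strand-level matching declares a predicted strand
correct when it overlaps an unmatched true strand by at least half the
shorter of the two; since true negatives do not exist at segment level,
the strand-level MCC slot reports $\sqrt{\mathrm{precision} \cdot
\mathrm{recall}}$ (the Fowlkes–Mallows index, the TN-to-infinity limit
of MCC). Loop-mutation experiments (`mutate_loops()`) substitute up to a
given fraction of loop residues with PAM250-odds-weighted replacements,
never touching strands, and are reproducible under a seed.

## Known limitations

* The default potential is a calibrated toy: it shares the structure,
  not the accuracy, of atomistic pseudo-energies. Classification
  thresholds must be recalibrated for any substituted potential.
* The fixed-shear scheme can declare an $(n, S)$ infeasible that the
  exhaustive mode solves; this mirrors the published recurrences and is
  surfaced, not hidden.
* Barrels with broken strands, multiple domains, or non-regular
  geometry are out of scope, as are alpha-helical membrane proteins.
* The permuted solver requires $\sigma(1) = 1$ and $n \ge 3$; scanning
  all $(n-1)!$ permutations of a real-size barrel is supported by the
  API but computationally meaningful only for small windows of
  candidate permutations.
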