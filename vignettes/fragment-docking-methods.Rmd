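---
title: "Fragment-based ssRNA docking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based ssRNA docking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rnafragdock)
```

## The problem and the approach

Single-stranded RNA (ssRNA) is so flexible that rigid-body docking of a
whole RNA onto a protein is hopeless when no bound conformation is known:
the unbound molecule often has no defined structure at all, yet the ssRNA
stretch usually carries the specificity of recognition (canonically by RNA
recognition motifs, RRMs). `rnafragdock` implements the fragment-based
alternative: cut the RNA sequence into overlapping trinucleotides,
represent each trinucleotide by an ensemble of conformers harvested from
protein-bound RNA crystal structures, dock every conformer rigidly all
around the protein, and reconstruct the chain by connecting poses whose
shared nucleotides superpose. The key observation the pipeline exploits is
that single wrong poses are abundant but wrong poses that can *chain* into
a full-length ssRNA are vanishingly rare, so a pose's propensity to
participate in chains is a powerful filter.

The pipeline has five stages, each an exported function family:

1. **Library** — `extract_trinucleotides()`, `canonicalize()`,
   `deduplicate_library()`: sliding 3-mer windows over protein-bound RNA
   chains, pooled per sequence class. All-pyrimidine fragments are
   re-typed to UUU and all-purine to AAA without moving an atom: the
   stacking geometry of a trinucleotide depends on its ring systems, not
   on the exocyclic substituents, so pyrimidine (purine) conformers are
   interchangeable within the class.
2. **Docking** — `generate_starts()`, `build_grid()`, `minimize_pose()`,
   `rescore()`, `deduplicate_poses()`, `select_top()`, or the wrapper
   `dock()`.
3. **Top-fraction selection** — 20% per conformer (5% when a full library
   multiplies the pose count by three orders of magnitude).
4. **Chain-propensity filter** — `build_graph()`, `count_chains()`,
   `propensity_filter()`, with `iterative_assembly()` as the
   memory-bounded variant.
5. **Clustering, chain building, ranking, evaluation** —
   `cluster_poses()`, `sequential_cluster()`, `assemble_clustered()`,
   `enumerate_chains()`, `score_poses()`, `score_chains()`,
   `evaluate_pool()`.

## Coarse-grained model

Nucleotides map to 6 (pyrimidine) or 7 (purine) beads: a phosphate bead
(P, OP1, OP2, O5'), two sugar/backbone beads (C5'+C4' and C3'+C2'+C1')
and 3–4 base beads partitioning the ring and substituent heavy atoms;
amino acids map to 3–4 beads. Every bead sits at the unweighted center of
mass of its source atoms. The exact base partition of the original
coarse-grained force field is not published, so the shipped mapping
(`inst/extdata/cg_mapping.tsv`) is a documented, editable approximation
that preserves the published bead counts and the phosphate/backbone/base
roles. Guanine's extra substituents (O6, N2) are merged into the
shared-scaffold beads so guanine and adenine carry the same four base
beads; purine canonicalization is therefore a pure re-typing, and the
invariant "canonicalize never moves a bead" holds exactly.

## Energy model and docking

Pair energies use the 8-6 potential
$\varepsilon[(R/r)^8 - (R/r)^6]$ (for attractive type pairs; the two terms
add for repulsive pairs) plus Coulomb electrostatics
$332.0636\,q_iq_j/(\epsilon(r)\,r)$ with the distance-dependent
$\epsilon(r)=r$ as default. The attractive pair minimum is at
$r^\ast = R\sqrt{4/3}$ with depth $27\varepsilon/256$; the tests pin both.
The published parameter values are external to this package: parameters
load from a pair table (`read_forcefield()`), and a toy table ships for
the synthetic benchmark.

Docking follows the published protocol: center-of-mass starts equidistant
on a sphere (Fibonacci lattice; 75 Å radius and 30,000 starts are the
published defaults, the toy scenario uses 30 Å and ~2,000), orientations
uniform over SO(3) from a seeded generator, a harmonic restraint of
0.0015 kcal/mol/Å² pulling the fragment COM toward the protein COM (the
source prints the unit as kcal/mol/Å; a harmonic constant must be per Å²,
and this reading is fixed here), up to 1000 minimization steps on a
precomputed receptor grid, grid-free re-scoring without the restraint,
and removal of poses within 0.05 Å of a better-scored pose of the same
conformer.

Numerical choices:

* **Minimizer.** Rigid-body adaptive-step gradient descent over the six
  degrees of freedom, rotations applied about the fragment COM so
  translation and torque decouple, with a monotone backtracking
  acceptance rule (energy never increases) and early exit at a scaled
  gradient norm below 1e-4. A quasi-Newton scheme would converge in fewer
  iterations but the descent scheme is simple, robust to the grid's
  interpolation noise, and exactly reproducible.
* **Receptor grid.** Per probe-type potential plus analytic gradient
  tabulated on a regular lattice (receptor bounding box + padding),
  trilinear interpolation (exact at nodes), plus one per-unit-charge
  electrostatic grid. Points outside the grid evaluate to zero — the COM
  restraint steers distant poses back inside. Interpolation error scales
  as $h^2\lvert V''\rvert$: for mild fields it is below 0.5 kcal/mol at
  1.0 Å spacing 3 Å away from beads, while in the steep wells of the toy
  scenario the 1.0 Å grid is a minimization guide only and final energies
  always come from the grid-free rescore.
* **Rescoring cutoff.** The protocol prescribes a cutoff on "a squared
  distance of 50 Å", which cannot be disambiguated; the literal reading
  (50 Å², i.e. ~7.07 Å separation) is the default and
  `cutoff_mode = "plain"` selects the 50 Å distance reading.

## Overlap, chains, and the propensity filter

Two poses are connectable (i → j, "j continues i toward 3'") when the
flat-bottom harmonic violation energy between the shared nucleotides
(nt 2–3 of i against nt 1–2 of j; margins 2.3 Å for
backbone/sugar/phosphate and 2.8 Å for base beads, k = 100 kcal/mol/Å²)
totals at most 2 kcal/mol. The margins are deliberately loose: a later
refinement must still be able to close the backbone covalently. Chain
counting is the forward–backward dynamic program: the forward pass counts
walks of each length ending at a pose, the backward pass walks starting
there, and their position-wise products give the number of length-N
chains through each pose, with the identity
$\sum_v c_v = N\,T$ enforced in tests. The filter keeps poses present in
at least 1 chain in 10,000.

In single-pool mode (the mode the published protocol settled on) the DP
counts *walks*, so a pose may in principle occupy several positions of
one counted chain; forbidding repeats would make counting #P-hard and the
described forward–backward procedure counts walks as stated.
`enumerate_chains()` drops pose-repeating walks before reporting and logs
how many were dropped; on the benchmark-like graphs we see the two
numbers coincide, because pose repetition requires tight spatial cycles.

Default chain length is N = 5 for library docking (terminal fragments
sample worst, so demanding all six is counter-productive — with bound
conformers and N = 6, position-agnostic chaining can produce no chain at
all) and N = 6 for position-specific bound docking.

## Clustering and hierarchical assembly

`cluster_poses()` is greedy leader clustering in rank order (deterministic
because ranks are unique); `sequential_cluster()` applies it at 2, then
3, then 4 Å on the surviving representatives. `assemble_clustered()`
reproduces the published cluster-level assembly: 3 Å clusters, uniform
5 Å margins, *no* violation allowed. For `hierarchical_assembly()` the
source gives no margin schedule; the package takes a user schedule (one
`overlap_params` per level, loosest at the coarsest level) and the
one-level degenerate schedule provably equals the direct graph build.
The alternate printed constants 2.23/2.83 Å are treated as the same
parameters as 2.3/2.8 Å; the config defaults to the latter.

## Ranking

$S_{poses} = \ln(\text{chain-propensity})/\text{rank}$, natural log
(the printed equation does not fix the base; the base rescales scores
within equal ranks but the ordering across ranks depends on it, so it is
fixed and documented), propensity as a fraction in (0, 1], larger is
better, zero-propensity poses excluded. The chain score's typography is
ambiguous between a product and a ratio of the junction-overlap sum and
the normalized sum of squared member ranks; the product (both factors are
penalties, smaller is better) is the default and the ratio is selectable
(`score_chains(mode = "ratio")`), with the chosen reading recorded in the
result. Enrichment of hits among top-ranked poses is assessed with the
exact hypergeometric upper tail; the source does not name its test, so
its printed p-values are not asserted anywhere.

## The synthetic benchmark (toybench)

`make_scenario()` builds the world every end-to-end test runs in: an
8-nucleotide coarse-grained chain along a planar path with fixed
per-nucleotide jitter, its 6 overlapping trinucleotide fragments (the
planted chain; consecutive planted poses share nucleotides exactly, so
their junction violation is exactly 0), a receptor bed of type-matched
attractive partner beads placed at the pair-potential minimum distance
straight below every chain bead, a repulsive core wall 4.5 Å deeper, a
library of the 6 planted conformers plus noise-perturbed decoy conformers,
and 200 far-away decoy poses that provably cannot continue any pose (a
deterministic repair loop pushes any connectable decoy outward until the
whole set has zero chain propensity by construction).

Design notes, recorded because the first constructions violated the
scenario's own invariants:

* Bead types cycle with period 3 nucleotides (18 types). With one type
  set per nucleotide, a homopolymer groove lets a pose bridge two
  same-type partner beads 5.9 Å apart, or slide registration by one
  nucleotide, and such poses *beat* the planted one. With period-3
  cycling, same-type partners are ~18 Å apart and the planted
  registrations are the deep minima.
* The chain is planar and each groove partner sits exactly
  $r^\ast$ = 4 Å below its bead, so a mismatched bead–partner distance is
  at least 4 Å by construction and relaxation from a planted pose drifts
  < 0.5 Å.
* The fixed jitter table makes the six fragment windows mutually distinct
  (pairwise superposed RMSD ≥ 1 Å, actual minimum ≈ 2 Å), so each
  conformer fits its own site best and "recovery" is well defined.
* The matched-pair well depth (ε = 5 kcal/mol) was set during
  construction so basin capture at the stated ~2,000 starts is reliable;
  at shallower wells recovery of the chain-end sites depends on start-set
  luck. The recovery criterion itself (< 2 Å, top 20%, fixed seed) was
  never adjusted.

What a green toybench run does establish: the full pipeline — starts,
grid minimization, rescoring, dedup, top-fraction, overlap graph, DP
counting, filtering, clustering, enumeration, evaluation — is wired
correctly, deterministic under a fixed seed, and the propensity filter
separates chainable from unchainable poses perfectly in a world where
that separation is true by construction. What it does not establish:
anything about real protein energetics, real RNA conformational
diversity, electrostatics at charged interfaces (toy charges are zero;
the Coulomb path is unit-tested separately), receptor flexibility, ions,
or the transferability of the published statistics — those numbers
(Pearson r = 0.72 between library fit quality and docking accuracy, 75%
of fragments approximated within 1 Å, ≥ 81% hit retention by the
single-pool filter) are recomputed by `scripts/acceptance.R` from the
published per-fragment tables shipped as data, not re-derived from
structures.

## Known limitations

* PDB/mmCIF parsing is minimal (standard dialects, first altloc, no
  symmetry expansion, no hydrogens); unknown residues are skipped, never
  guessed.
* Libraries are homopolymer-class only (UUU, AAA); heteropolymer classes
  are out of scope, as is all-atom reconstruction and covalent closure of
  assembled chains.
* The greedy dedup and leader clustering are order-dependent by
  definition; order is fixed (energy rank), so results are reproducible
  but not order-free.
* Single-pool chain counts are walk counts (see above); treat propensity
  values near the threshold accordingly.
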