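# rnafragdock

Fragment-based docking of single-stranded RNA (ssRNA) onto protein
receptors, in coarse-grained representation.

Unbound ssRNA usually has no defined structure, so whole-molecule
rigid-body docking cannot work; yet the single-stranded stretches carry
the specificity of most protein–RNA recognition (canonically by RNA
recognition motifs). This package implements the fragment-based
alternative for people who model protein–RNA complexes: cut the RNA
sequence into overlapping trinucleotides, represent each trinucleotide by
a conformer ensemble harvested from protein-bound RNA structures, dock
every conformer rigidly all around the protein, and reconstruct the bound
chain by connecting poses whose shared nucleotides superpose.

## The method in brief

* **Coarse graining.** 6 beads per pyrimidine, 7 per purine (phosphate,
  two sugar/backbone beads, 3–4 base beads at heavy-atom centers of
  mass), 3–4 beads per amino acid; editable mapping table.
* **Energy.** Pairwise 8–6 potential ε[(R/r)⁸ − (R/r)⁶] plus Coulomb
  q_iq_j·332.0636/(ε(r)·r); the attractive-pair minimum is at
  r\* = R·√(4/3). Parameters load from a text pair table.
* **Docking.** Center-of-mass starts on a sphere (Fibonacci lattice,
  uniform random orientations, seeded), 6-DOF rigid minimization on a
  precomputed receptor grid with a 0.0015 kcal/mol/Å² COM restraint,
  grid-free rescoring (cutoff on squared distance, 50 Å² default),
  0.05 Å redundancy removal, top-20% selection.
* **Chain-propensity filter.** Poses i → j are connectable when the
  flat-bottom harmonic violation between their shared nucleotides
  (margins 2.3/2.8 Å, k = 100 kcal/mol/Å²) is ≤ 2 kcal/mol. A
  forward–backward dynamic program counts, for every pose, the number of
  length-N chains it participates in (c_v, with Σ_v c_v = N·T); poses in
  fewer than 1/10,000 of all chains are discarded.
* **Clustering and chains.** Greedy leader clustering at 2/3/4 Å,
  cluster-level assembly with 5 Å hard margins, deterministic chain
  enumeration, pose score S = ln(propensity)/rank and a junction-overlap ×
  rank² chain score, hit/near-hit/close-hit classification at 2/5/6 Å
  ligand-RMSD (no re-superposition), hypergeometric enrichment.

## Worked example

The package ships a deterministic synthetic benchmark: a planted
6-fragment chain in a groove whose beads attract matching fragment beads,
plus decoy poses that provably cannot form chains.

```r
library(rnafragdock)
sc  <- make_scenario(seed = 1, n_decoy_poses = 50)
cfg <- pipeline_config(nstarts = 200, start_radius = 30, steps = 300,
                       seed = 1)
res <- run_pipeline(sc, cfg)
print(res)
```

```
pipeline_result
             stage n_in n_out
           library   16     6
           docking 1200  1200
      top_fraction 1200   240
     assembly_pool  240   296
 propensity_filter  296     7
            chains    7     3
  chains: 3
  best chain geometric-mean RMSD: 0.00 A
```

1200 docked poses (6 conformers × 200 starts) are cut to the top 20%,
merged with the scenario's planted and decoy poses (296 total), and the
chain-propensity filter keeps 7 poses — the 6 planted ones plus one
docked recovery — while removing all 50 unchainable decoys. The planted
chain is found with geometric-mean RMSD 0 (the planted poses are exact).
The evaluation report shows each reference fragment recovered (min RMSD
0.00 Å) and the binding site delineated: 100% of filtered poses within
10 Å of the true chain, worst pose 1.3 Å.

```r
print(res$report)
#>   binding site: 100%<10 A, 100%<15 A; worst pose 1.3 A
head(score_poses(res$filtered, res$counts), 3)
#>         pose_id propensity rank s_poses
#> 1 planted_frag5          1    3       0
#> 2 planted_frag2          1    4       0
#> 3 planted_frag4          1    6       0
```

A propensity of 1 means the pose takes part in every enumerated chain;
S_poses = ln(propensity)/rank is 0 for such poses — the best possible
score.

Real structures enter through `load_structure()` (PDB/mmCIF) +
`coarse_grain()`, libraries through `extract_trinucleotides()`,
`canonicalize()` and `deduplicate_library()`.

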