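# cgkit

Coarse-grained protein interaction scaling and dimerization free-energy
analysis for Martini-style force fields.

## The problem

The Martini coarse-grained force field describes nonbonded interactions
between its bead types with a tabulated matrix of Lennard-Jones well depths —
nine discrete levels with ε between 2.0 and 5.6 kJ/mol (σ = 0.47 nm, or
0.62 nm for the super-repulsive pairs; small ring beads use σ = 0.43 nm with
ε reduced by 25%). With the standard table, transmembrane helices dimerize
far too strongly: simulated dimerization free energies exceed FRET-derived
values by tens of kJ/mol, and membrane proteins collapse into irreversible
aggregates that never re-sample their dimerization interfaces.

A pragmatic remedy is to scale every protein–protein well depth toward the
repulsive floor,

&emsp; ε_scaled = ε_repulsive + (1 − α) (ε_original − ε_repulsive),

with ε_repulsive = 2.0 kJ/mol, so that α = 0 leaves the force field
untouched and α = 1 flattens all chemical specificity onto the floor. A
mild uniform scaling (α ≈ 0.1 over all protein bead types, "U-0.1") brings
transmembrane-dimer free energies into the experimental range without
touching protein–lipid or protein–water interactions, which is achieved by
duplicating the protein bead types and rewriting only their mutual pairs.
The package implements this rewriting (strategy **U**, uniform over all
protein beads, and strategy **W**, restricted to residues with more water
than lipid contacts within 0.6 nm), plus the analysis stack around it:

* **WHAM** — self-consistent reweighting of umbrella-sampling histograms
  into a potential of mean force G(r) along the peptide–peptide
  centre-of-mass distance, with Bayesian-bootstrap error bars
  (`wham()`, `bootstrap_pmf()`).
* **Dimerization free energy** — K_a = π ∫₀^rmax r exp(−G(r)/RT) dr and
  ΔG_DIM = −RT ln(K_a/A₀) at the FRET standard state A₀ = 1 nm² per
  receptor, with profiles shifted to zero at 2.75 nm and r_max = 2.0 nm
  (`association_constant()`, `dimerization_free_energy()`,
  `dgdim_with_error()`).
* **Dimer structure metrics** — backbone-bead RMSD after joint Kabsch
  superposition, helix crossing angles from SVD principal axes folded into
  [0°, 90°], and inter-peptide backbone contacts at 0.8 nm
  (`backbone_rmsd()`, `crossing_angle()`, `interpeptide_contacts()`,
  `dimer_deviation_summary()`).
* **Oligomer statistics** — single-linkage clustering of peptide COMs at
  2.5 nm under the minimum-image convention, average-oligomer-size time
  series and trailing-window size histograms
  (`single_linkage_clusters()`, `cluster_size_stats()`).
* **IO** — GROMACS-dialect `[ atomtypes ]`/`[ nonbond_params ]` tables in
  σ–ε or C6/C12 form, GRO/PDB coordinates (nm everywhere), XVG time
  series.
* **Synthetic fixtures** — a Martini-like 9-level matrix, ideal helices
  and crossed dimers with exact geometry, Metropolis-sampled umbrella
  windows from a known PMF, and COM configurations with a known cluster
  partition, all seedable (`martini_like_matrix()`, `ideal_helix()`,
  `make_crossed_dimer()`, `metropolis_umbrella_sampler()`,
  `make_oligomer_config()`).

## Worked example

```r
library(cgkit)

## rescale the protein block of a Martini-like matrix by 10% (U-0.1)
mat <- martini_like_matrix()
ff  <- apply_uniform_scaling(mat, c("P5", "P4", "Qa", "Qd"), alpha = 0.1)
ff
#> scaled_forcefield: strategy U, alpha = 0.1, floor = 2 kJ/mol
#>   4 type(s) duplicated, 10 pair(s) rescaled
head(ff$audit, 3)
#>   type_i type_j eps_original eps_scaled sigma
#> 1   P4_s   P4_s          3.5       3.35  0.47
#> 2   P4_s   P5_s          5.0       4.70  0.47
#> 3   P4_s   Qa_s          3.1       2.99  0.47

## umbrella sampling -> WHAM -> dimerization free energy, on synthetic
## windows drawn from a known double-well PMF
pmf     <- make_double_well_pmf()
windows <- metropolis_umbrella_sampler(pmf, seq(0.6, 2.8, by = 0.2),
                                       k = 400, n_samples = 20000, seed = 11)
profile <- bootstrap_pmf(windows, n_boot = 100, seed = 7)
dgdim_with_error(profile)
#> dG_dim = -7.49 +/- 0.18 kJ/mol  (K_a = 19.5 nm^2, T = 303 K, r_max = 2 nm, A0 = 1 nm^2)
#>   100 bootstrap replicates (0 excluded)
```

The audit rows show each duplicated pair moving one tenth of the way to
the 2.0 kJ/mol floor (5.0 → 4.70, 3.5 → 3.35). The recovered −7.49 ±
0.18 kJ/mol agrees with the exact value for this synthetic double well
(−7.56 kJ/mol by direct quadrature of the generating curve) within the
bootstrap error.

A command-line front end wrapping the same functions is installed at
`system.file("exec", "cgkit", package = "cgkit")`, with subcommands
`convert-ff`, `scale-ff`, `classify-water`, `wham`, `dgdim`,
`dimer-metrics`, `clustersize` and `make-fixtures`.

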