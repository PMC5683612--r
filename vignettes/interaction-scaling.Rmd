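---
title: "Scaling protein-protein interactions in coarse-grained membrane simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling protein-protein interactions in coarse-grained membrane simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgkit)
```

## The model

Martini-style coarse-grained force fields tabulate the Lennard-Jones well
depth $\epsilon_{ij}$ for every pair of bead types instead of deriving it
from combination rules. The standard table uses nine interaction levels
between 2.0 and 5.6 kJ/mol, with the interaction distance $\sigma =
0.47$ nm for all pairs except the super-repulsive charged–apolar ones
($\sigma = 0.62$ nm); small ring beads use $\sigma = 0.43$ nm with
$\epsilon$ reduced by 25%. Because the protein–protein entries of this
table were never calibrated against protein association data, simulated
transmembrane dimers bind far too strongly, and crowded membranes collapse
into effectively irreversible aggregates.

cgkit implements the interaction-rescaling remedy. Every targeted
protein–protein pair is moved toward the repulsive floor:

$$\epsilon_\mathrm{scaled} \;=\; \epsilon_\mathrm{repulsive} +
  (1-\alpha)\,(\epsilon_\mathrm{original} - \epsilon_\mathrm{repulsive}),$$

with $\epsilon_\mathrm{repulsive} = 2.0$ kJ/mol, the weakest level of the
standard ladder. The map has three properties the tests pin down exactly:
it is the identity at $\alpha = 0$; no scaled value ever drops below the
floor, and at $\alpha = 1$ every pair sits exactly on it; and the spread
of the ladder contracts linearly, $\max - \min = (1-\alpha)\times 3.6$
kJ/mol, so at $\alpha = 0.9$ only a 0.36 kJ/mol window of chemical
specificity remains (2.0 vs 2.36 kJ/mol for the extreme levels).

Two selection strategies are provided. **U** (uniform) duplicates every
bead type used by the protein — explicitly including the polar and charged
types P4, Qa and Qd — and rescales the mutual pairs of the duplicates;
every pair involving a non-duplicated type is copied bitwise, so lipid,
water and ion interactions are untouched. **W** (water-contacting)
restricts the duplication to the bead types of residues that have strictly
more water than lipid contacts within 0.6 nm; interactions between scaled
and unscaled protein beads remain at their standard values. Duplicated
types get a deterministic suffix (default `_s`); a collision with an
existing name is an error, never a silent rename.

### Decisions where the procedure was underdetermined

* **Tie rule.** A residue with equal water and lipid contact counts is
  *not* rescaled; "more contacts with water" is read strictly.
* **Contact counting.** Counts are summed bead–bead events over the
  retained frames, not per-frame booleans, which makes the classification
  robust to the number of frames analysed. The default equilibration skip
  is the leading 5% of frames, configurable.
* **Sub-floor pairs.** Small-bead pairs start 25% below the normal ladder,
  so some sit below the 2.0 kJ/mol floor. `scale_epsilon()` keeps its
  strict precondition ($\epsilon \ge \epsilon_\mathrm{repulsive}$: scaling
  must never *increase* attraction), while the table rewriters use a
  per-pair floor of $\min(\epsilon, \epsilon_\mathrm{repulsive})$, making
  sub-floor pairs fixed points. The floor itself is exposed as an argument
  for tables with a different weakest level.

## Umbrella sampling to free energies

`wham()` iterates the standard self-consistency equations on per-window
histograms: with window biases $c_i(r) = \tfrac{k}{2}(r - r_i)^2$
evaluated at bin centres and per-window constants $f_i$,

$$p_b \propto \frac{\sum_i n_{ib}}{\sum_i N_i\, e^{(f_i - c_{ib})/RT}},
  \qquad
  e^{-f_i/RT} = \sum_b e^{-c_{ib}/RT}\, p_b,$$

until $\max_i |\Delta f_i| / RT < 10^{-7}$ (cap $10^5$ iterations;
non-convergence is an error carrying the last residual). $G(r) = -RT\ln
p_b$ is reported up to an additive constant and only on bins with at least
one sample; empty bins propagate as `NA`, never $\pm\infty$. The default
bin width is 0.01 nm. No radial Jacobian is applied to $G(r)$: the
two-dimensional geometry of association in the membrane plane enters
once, through the explicit $\pi\int r\,\mathrm{d}r$ below.

**Bootstrap.** Samples within a window are autocorrelated, so resampling
individual observations would understate the error. `bootstrap_pmf()`
instead draws Bayesian-bootstrap weights (one $\mathrm{Exp}(1)$ draw per
*complete window histogram*, normalized to preserve the total count) and
re-solves WHAM per replicate, warm-started from the full-data constants.
Replicates are shift-aligned to the full-data profile by their mean offset
over commonly defined bins before the per-bin standard deviation is taken,
which makes the reported spread independent of the additive convention.
The default is 100 replicates; a single replicate reports zero spread by
convention, and non-converged replicates are excluded with a warning.

**Free energies.** Profiles are shifted to zero at $r_\mathrm{ref} =
2.75$ nm (a distance at which dimerization profiles have plateaued), then

$$K_a = \pi \int_0^{r_\mathrm{max}} r\, e^{-G(r)/RT}\, \mathrm{d}r,
  \qquad
  \Delta G_\mathrm{DIM} = -RT \ln (K_a / A_0),$$

with $r_\mathrm{max} = 2.0$ nm, $T = 303$ K and the FRET standard state
$A_0 = 1$ nm$^2$ per receptor (the standard-state area is where the
association constant's units cancel; it is exposed as an argument). The
error on $\Delta G_\mathrm{DIM}$ is the standard deviation over the
bootstrap replicates, each shifted at $r_\mathrm{ref}$ individually so the
result is convention-free.

**Quadrature.** $G$ is a binned, piecewise-constant object, so the
integral is evaluated by the midpoint rule per bin (with the boundary bin
truncated at $r_\mathrm{max}$). For a piecewise-constant $G$ the integrand
is linear in $r$ within each bin, making the midpoint rule *exact* there —
including across discontinuities that fall on bin edges, where any rule
interpolating across neighbouring centres would smear the step. This is
why midpoint was chosen over trapezoid on centres: on a square-well
profile the trapezoid's single straddling panel already errs by more than
the 0.1% the closed-form checks demand. Bins below the first sampled
distance contribute zero (the unsampled hard core has vanishing
$e^{-G/RT}$); an undefined bin *interior* to the defined region is an
error rather than a silent gap. Raising $r_\mathrm{max}$ above 2 nm
changes well-dominated profiles negligibly because the flat tail is
exponentially outweighed by the well; the tests assert this on a deep
(−20 kJ/mol) square well, where the effect is below 0.1 kJ/mol. For a
*shallow* or purely flat profile the tail contribution is geometric
($\pi r\,\mathrm{d}r$) and not negligible — the insensitivity is a
property of well-dominated profiles, not of the quadrature.

## Dimer structure metrics

Three criteria score a simulated dimer against a coarse-grained reference
structure (e.g. a C$\alpha$-mapped NMR model, one bead per residue):

* **Backbone RMSD** after least-squares (Kabsch) superposition of *both*
  peptides jointly, with the homodimer chain-pairing ambiguity resolved by
  taking the minimum over the two assignments. The proper-rotation sign
  correction is always applied, so reflections are never returned.
  Motif-anchored alignment (`motif_align()`), which fits only the
  dimerization-motif residues of peptide 1 and carries the whole dimer
  along, is kept as a separate operation for visual comparison of where
  the second peptide lands.
* **Crossing angle**: the angle between the first principal axes (SVD of
  the centred backbone beads) of the two contact-helix residue ranges,
  folded as $\arccos|u\cdot v|$ into $[0^\circ, 90^\circ]$ — handedness is
  deliberately discarded. Axis signs are fixed first-residue-to-last, so
  the absolute value is the only symmetrization. Using only the
  contact-helix ranges (not the full chains) keeps frayed termini out of
  the axis fit.
* **Inter-peptide contacts**: backbone bead pairs across the two peptides
  within 0.8 nm, minimum-image, with a *closed* boundary (a pair at
  exactly the cutoff counts — the convention had to be fixed one way and
  is documented here).

`dimer_deviation_summary()` evaluates the three per frame over the
trailing analysis window (default the last half of the trajectory, e.g.
the last 20 of 40 µs), reporting means and standard deviations; the
replica wrapper adds the across-replica mean. The rule-of-thumb acceptance
region — mean RMSD within 1 nm *and* mean absolute crossing-angle
deviation within 10° — is exposed as the pure threshold
`acceptable_dimer()`.

## Oligomer statistics

Peptide centres of mass are mass-weighted means taken after unwrapping
each peptide's beads by minimum image relative to its first bead (exact
whenever the peptide's diameter is below half the box). Oligomers are
single-linkage clusters: connected components of the graph joining COMs
within 2.5 nm, the distance at which peptide–peptide radial distribution
functions decay to zero; minimum image is applied in all three dimensions.
Labels are deterministic (lowest member index). The per-frame *average
oligomer size* is number-averaged (total peptides / number of clusters);
since the weight-averaged convention — the mean size of the cluster a
random peptide sits in — is equally defensible and differs for mixed
partitions, both are reported. Size histograms pool per-cluster sizes over
a trailing window (default the last quarter of frames, e.g. the last 10 of
40 µs) and are normalized to frequencies.

## What the synthetic fixtures emulate

The package generates every input its tests need:

* `martini_like_matrix()` — a completed 18-type table (nine normal types
  spanning protein/water/lipid/ion categories plus small twins) using the
  standard nine-level ladder 5.6, 5.0, 4.5, 4.0, 3.5, 3.1, 2.7, 2.3,
  2.0 kJ/mol. Only the printed anchors are treated as facts: the
  endpoints, $\sigma \in \{0.47, 0.62, 0.43\}$ nm, and the 25% small-bead
  reduction. The assignment of intermediate levels to pairs is a
  deterministic fixture invention, arranged so the protein–protein block
  covers all nine levels and therefore exercises the full ladder under
  scaling.
* `ideal_helix()` / `make_crossed_dimer()` — regular helices (0.15 nm
  rise, 100° twist, 0.23 nm radius: textbook α-helix values chosen for
  fixtures, not fitted to anything) that are de-tilted during construction
  so their principal axis equals the requested axis to machine precision;
  crossed dimers therefore have *exactly* the requested crossing angle,
  giving the angle code a zero-tolerance oracle.
* `metropolis_umbrella_sampler()` — random-walk Metropolis chains from the
  biased density $\propto e^{-(G_\mathrm{true}(r) + k(r-r_0)^2/2)/RT}$,
  step size auto-tuned to 30–60% acceptance, leading 10% discarded as
  burn-in, fully reproducible given a seed. Against a harmonic
  $G_\mathrm{true}$ the sampled variance matches $RT/(k_\mathrm{true} +
  k_\mathrm{bias})$, which the tests check across seeds.
* `make_double_well_pmf()` — a soft exponential wall, a deep contact well
  and a shallow secondary well, decaying to zero beyond 2 nm; its
  dimerization free energy is known by direct fine-grid quadrature,
  closing the sampler → WHAM → bootstrap → $\Delta G_\mathrm{DIM}$ loop
  end to end.
* `make_oligomer_config()` — chained clusters (member spacing 80% of the
  cutoff) on a grid with inter-cluster gaps of 150% of the cutoff and
  more than half a cutoff of clearance from every box face, so periodic
  images cannot bridge clusters and the intended partition is recovered
  by construction.

What passing these tests shows is that the *algorithms* are correct:
formats round-trip, the scaling rewrite touches exactly the intended
pairs, WHAM inverts known biased samplers, the geometry and clustering
codes agree with brute-force oracles. What it does not show is fidelity to
real membranes: the fixtures contain no lipid degrees of freedom, no
helix flexibility or tilt, no force-field accuracy beyond the scaling
formula itself. Transmembrane-dimer free energies of experimental scale
(tens of kJ/mol) require microsecond coarse-grained MD in an external
engine and are out of scope here; the conversion layer is validated on
closed forms and on the synthetic double well instead.

## Validation problem sizes

The recovery experiment uses 12 windows at centres 0.6–2.8 nm (0.2 nm
spacing), $k = 400$ kJ mol$^{-1}$ nm$^{-2}$, 20,000 retained samples per
window and 0.01 nm bins — enough sampling that the WHAM reconstruction
sits well inside the 0.3 kJ/mol RMS target over the window-anchored
region. The RMS comparison runs over defined bins between the outermost
window centres: bins in the exponential tails beyond them hold a handful
of samples each and carry pure shot noise, so including them would test
the Metropolis chain's tails, not WHAM. Property suites use 1000
randomized configurations for the contact and clustering oracles (n ≤ 30
beads, n ≤ 12 peptides) and 100 bootstrap replicates, matching the
analysis default.

## Known limitations

* Orthorhombic boxes only; triclinic input is rejected explicitly.
* Full topology parsing (bonds, angles, elastic networks) is out of
  scope; only the nonbonded sections are read and rewritten.
* The W-strategy classifier needs frames containing protein, water *and*
  lipid beads; classification is undefined otherwise and errors.
* WHAM here is the scalar-coordinate estimator; MBAR,
  autocorrelation-weighted variants and two-dimensional umbrella sampling
  (distance × crossing angle) are not implemented.
* Amino-acid-specific scaling — the direction the uniform strategy's
  structural shortcomings point to — is not attempted; the per-type
  duplication machinery is the natural extension point.
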