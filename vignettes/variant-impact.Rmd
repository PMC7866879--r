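---
title: "Multi-layer structural and dynamic assessment of missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer structural and dynamic assessment of missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynimpact)
```

## The problem and the approach

Sequence-based pathogenicity predictors miss missense variants whose damage
is mechanistic rather than positional: a substitution far from an enzyme's
active site can still distort local packing, shift the protonation
behaviour of catalytic residues, or loosen the collective dynamics that
substrate recognition depends on. `dynimpact` implements a multi-layer
assessment of such variants built around evidence layers that can each flag
a variant independently:

1. **Structure** — global and local backbone perturbation between
   energy-minimized wild-type and variant models. The local score selects
   every residue with a heavy atom within 10 Å of the mutated residue
   (the site itself excluded, since its side chain differs by construction)
   and measures the backbone RMSD over that shell.
2. **pKa shift** — per-residue pKa differences between wild type and
   variant over all titratable residues, summed in both directions:
   `total_abs = positive_sum + |negative_sum|`. Titratable residues lost or
   gained at the mutation site are excluded so a single substitution cannot
   dominate the global score; the variants-by-residues matrix exposes
   "weak-spot" residues that many variants perturb coherently.
3. **Dynamics** — replicate molecular-ensemble metrics: per-frame RMSD
   drift from the initial structure, summarized as the median over the
   production window and compared as *median difference* against the
   benign-control baseline, and per-residue RMSF compared as the *average
   absolute difference* per residue. These two summary statistics are used
   as the headline dynamics scores; the four other candidate comparisons
   (Pearson, Spearman, average difference, absolute residual sum) are
   always reported alongside.
4. **Interactions** — time-dependent nonbonded (Coulomb + Lennard-Jones)
   energies between the enzyme and named partner groups (substrate peptide,
   methylated lysine, cofactor, metal sites), reported as variant-minus-wild-type
   deltas. Only destabilization counts toward badness: stabilizing deltas
   map to zero.
5. **Sequence** — consumed as externally supplied labels (sequence
   predictors are not re-implemented).

Per metric, values are calibrated on the benign controls: anything at or
below the benign-control maximum "badness" is benign, at or below twice
that is a VUS, above it damaging. Layers take the worst severity of their
metrics, and a variant is overall damaging if *any* layer is damaging,
benign only if *every* layer is benign, VUS otherwise.

## Superposition, RMSF, and essential dynamics

All trajectory metrics share one superposition protocol: frames are
Kabsch-fitted (SVD with reflection correction via the sign of the smallest
singular value) onto the production-window mean structure over the backbone
selection, with one mean-refit iteration. Because a Kabsch fit is
independent of a frame's starting rigid placement, the stored reference can
be reused to place a *variant* ensemble into the wild-type frame, which is
what makes cross-projections onto the wild-type principal components
well-defined.

RMSF is the root mean squared deviation of an atom from its ensemble mean
position, averaged per residue over the Cα selection by default (a
heavy-atom option exists). It converts to a predicted crystallographic
temperature factor by B = (8π²/3)·RMSF², which the package uses to check
ensembles against crystal B-factors. Residues are classed *still* below
0.7 Å, *mobile* above 1.0 Å, *intermediate* between (boundaries inclusive
to intermediate).

Essential dynamics diagonalizes the covariance of the superposed coordinate
fluctuations, Λ = TᵀCT, with eigenvalues sorted descending and a
deterministic eigenvector sign convention (largest-magnitude component
positive) so runs are reproducible. Porcupine vectors average each
eigenvector's per-atom components over the residue and scale by √λ, giving
an RMS displacement along the mode in Å. The free-energy landscape is a
50×50 2-D histogram over the first two projections with
F = −ln(count/count_max) in kT; empty bins are masked, never extrapolated,
so the occupied minimum is exactly 0. Per-PC distribution shifts
(difference of medians plus an overlap coefficient) are reported for every
variant but deliberately *excluded from the classification layers*: on both
synthetic and published data this view is not congruent with the other
scores and is best read as an independent descriptive channel.

## Nonbonded energetics

Pair energies use E_elec = 332.0637·q₁q₂/(ε(r)·r) with the implicit
distance-dependent dielectric ε(r) = D·r (D = 80 by default; a constant
mode exists) and a 12-6 Lennard-Jones term with geometric-mean well depths
and summed r_min/2 radii, truncated plainly at 12 Å. The bundled parameter
table carries approximate charges and LJ parameters for backbone atoms,
common side-chain atoms, divalent metal centers and the cofactor; it is a
starting point for synthetic experiments and is fully overridable. Absolute
energies from this model are not comparable to any specific force-field
implementation — only variant-vs-wild-type deltas and orderings are
meaningful, and only those are tested and classified.

## Surface areas

SASA is numerical Shrake–Rupley over heavy atoms: 960 deterministic
golden-spiral points per probe-inflated sphere (1.4 Å probe), occlusion
tested against neighbours. Polar area sums N and O atoms; sulfur counts as
nonpolar (configurable). The bundled radii (C 1.70, N 1.55, O 1.52, S 1.80,
default 1.80) are overridable, since published buried-surface figures
rarely state their radii set. Buried surface is the ΔSASA decomposition
SASA(A)+SASA(B)−SASA(AB); because conventions differ across tools, both the
*per-side* (Δ/2, the default) and *total* conventions are emitted, and the
per-side value is what comparable published interface areas usually quote.

## What the synthetic generators emulate — and what they do not

The generators replace an MD engine and the external calculators with
distributionally matched stand-ins carrying known ground truth:

* **Ensembles**: reference backbone (ideal helix/strand/coil built from
  standard bond geometry) plus i.i.d. per-coordinate Gaussian noise
  (σ = 0.3 Å per coordinate by default, so per-residue RMSF → σ√3 ≈ 0.52 Å),
  optional low-rank collective modes (sinusoidal amplitude along a fixed
  direction over a residue window), constant mean-shift offsets for local
  perturbation, and inflated-σ outlier replicates. Defaults mirror a
  standard production protocol: 1000 frames at 10 ps, 10 replicates,
  the last 500 frames as the production window, at most 2 replicates
  excluded per set.
* **Variant effects** default to the magnitudes reported for real
  benign/damaging cohorts: global fluctuation elevation factors
  1.057–1.060 for benign controls versus 1.12–1.196 for damaging variants,
  local mean displacements of a few tenths of an Å, coordinated pKa
  weak-spot shifts of 0.5–1.5 pH units against 0.02 noise, and
  charge-scaling that destabilizes an attractive partner interaction.
* **Score tables** draw benign badness from a half-normal null; planted
  damaging rows receive, in one or two randomly chosen layers, a badness of
  `damaging_multiple` (default 3) times the *realized* benign-control
  maximum of that layer. Anchoring to the realized maximum is what makes
  the planted effect a guaranteed exceedance of the twice-benign-max
  threshold; anchoring to the null scale instead would make "planted
  damaging" fail calibration roughly a third of the time purely through
  the sampling variability of a 3-control maximum.

Because fluctuations are sampled independently per frame, the ensembles
have no autocorrelation, no anharmonicity and no solvent: the metrics the
package computes (RMSF, windowed median RMSD, covariance PCA, windowed
energy means) are distributional, so recovery tests on this data validate
the *estimators*, not the physics. Passing them says the pipeline measures
what was planted; it does not say a 10 ns trajectory of a real protein is
converged.

A quantitative caveat the synthetic experiments surfaced: with three benign
controls and five layers, a *null* query (one drawn from the same
distribution as the controls) exceeds twice the benign-control maximum in
at least one layer in roughly one table in five. That is the intrinsic
false-positive behaviour of max-of-controls calibration, not a bug, and it
is why the ledger always exposes per-layer labels and the calibration audit
trail rather than the overall call alone.

## Numerical choices and degenerate inputs

* Kabsch refuses fewer than 3 points or (near-)collinear configurations;
  the reflection case is corrected so det(R) = +1 always.
* Structure-vs-structure RMSD defaults to *no* superposition: minimized
  structures derived from one common starting model are already
  co-registered, and superposing would hide exactly the displacement being
  measured. A flag enables fitting.
* Atom matching is by residue key (author numbering, never renumbered) plus
  atom name; side chains of residues whose name differs between the two
  structures are auto-excluded, anything else unmatched is an error.
* Alternate locations resolve to the highest occupancy, first on ties.
* Outlier replicates: a replicate is excluded when its production-window
  median RMSD deviates from the median of replicate medians by more than
  2.5 consistency-scaled MADs (so the factor reads as a robust z-score),
  at most 2 per set, worst first; if everything is flagged the set is
  returned unchanged with a warning. With identical replicate medians the
  MAD is 0 and any deviation flags — matching the intent that only clear
  deviants leave.
* Calibration floors: a metric whose benign controls are all ~0 would make
  any noise damaging; its threshold is replaced by a configured absolute
  floor and flagged in the calibration table.
* Boundary labels are inclusive downward (≤ b_max benign, ≤ 2·b_max VUS) so
  a benign control always labels itself benign.
* FEL bins: 50×50, no pseudo-counts; temperature only enters the reported
  kT→kcal/mol factor (k_B = 0.0019872041 kcal/mol/K).

## Problem sizes

The demo cohort (`demo_config()`) runs 3 benign controls, 2 damaging
controls and 5 queries at 5 replicates × 300 frames over a 60-residue
backbone — sizes chosen so the complete end-to-end demo, including
replicate exclusion, PCA and all layers, finishes in about half a minute on
a single core while leaving every estimator comfortably inside its
validated regime (the σ√3 law is recovered within 5% at 500 frames; the
spectral identities are exact at any size). The generator defaults
themselves (1000 frames × 10 replicates) remain the full study conditions
and are what `ensemble_spec()` produces when you do not override them.

## Known limitations

* The pKa, folding-energy and sequence layers consume externally computed
  tables; the package aggregates and calibrates them but cannot create them
  from physics.
* The porcupine localization of a planted regional mode is attenuated by
  superposition: the rigid counter-motion of the fit spreads some apparent
  amplitude onto unaffected residues (in-window/outside magnitude ratio
  ≈ 1.7 rather than the naive ∞ at the default study conditions). The peak
  still sits inside the planted window.
* Nonbonded energetics use plain cutoff truncation and no bonded terms;
  they are a delta-measuring instrument, not a force field.
* The per-PC shift channel is reported but unclassified, as discussed
  above.
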