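---
title: "Methods: screening and characterising modulators of a dynamic PPI site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and characterising modulators of a dynamic PPI site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynappi)
```

`dynappi` implements an integrated computational workflow for finding and
characterising small-molecule modulators of the SxIP–EB1 protein–protein
interaction — a shallow, conformationally dynamic binding site on the
End-Binding homology (EBH) domain of EB1 that recruits +TIP proteins through
their Ser-x-Ile-Pro motif. The same machinery applies to any
pharmacophore-driven campaign against a dynamic interaction site. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the design was genuinely open.

## 1. Pharmacophore model and conformer matching

A pharmacophore model is an ordered list of typed interaction points
(hydrogen-bond **acceptor**, **donor**, **hydrophobic** centroid), each with
a Cartesian centre (Å), a spherical tolerance radius, an optional unit
direction vector and a provenance label. The shipped SxIP preset
(`sxip_preset()`) reads eight points off the peptide side of an EB1–peptide
complex:

* two acceptors in the Ser (position 1) hydroxyl region, which anchors a
  water-mediated hydrogen-bond network to Arg222, Glu225, Gln229 and Tyr247;
* three hydrophobic centroids over the Ile (position 3) side chain and the
  Pro (position 4) ring, which bury into the hydrophobic cavity;
* the Ile backbone amine typed as an acceptor, and the Ile/Pro carbonyl
  oxygens typed as donors.

The last assignment follows the source screening protocol as written. It is
chemically inverted relative to convention (an amide N–H donates; carbonyl
oxygens accept), so the preset has a `chemically_corrected` switch that
swaps the roles. The default keeps the protocol as stated; the switch makes
the conventional typing a one-argument choice rather than a fork of the
preset. The coordinated water in the binding site is not given a feature
point: whether it contributed one in the original model is not recorded, and
a water-mediated feature cannot be placed without it.

Feature radii default to 1.0 Å — the radii used by the original search
engine are not recorded, and 1.0 Å is the scale at which the 0.5 Å RMSD
acceptance threshold (below) remains meaningful. Direction vectors are
carried but not scored by default; when both sides of a match supply them, a
configurable angular tolerance (45°) can be enforced. No tolerance is
documented for the original model, so directional scoring is off unless
requested.

**Subset queries.** Requiring all eight points simultaneously is too strict
for any real library, so screening enumerates feature subsets. With eight
points and subset sizes 5–7 the unconstrained enumeration gives
C(8,5)+C(8,6)+C(8,7) = 56+28+8 = 92 queries. The original campaign reports
71 combinations of those sizes; whatever constraint removed the other 21 is
not stated. `enumerate_subsets()` therefore ships unconstrained and exposes
a predicate hook so any such constraint can be expressed when it is known.
Sizes below 3 are rejected: fewer than three points cannot fix a rigid
superposition.

**Matching.** A conformer is represented by its own ligand-side feature
points (`assign_ligand_features()` derives them from element/connectivity
rules: N/O accept, N–H/O–H donate, bonded carbon clusters contribute a
centroid at the mean of their heavy atoms). Matching a query against a
conformer searches every kind-compatible injection of query features into
conformer points and scores each correspondence by the RMSD after optimal
least-squares rigid superposition (closed-form, SVD-based, reflections
rejected). The search is exhaustive for queries of up to 12 features —
exactness and testability dominate at this scale — with an exact
branch-and-bound pruning: for any rigid motion the inter-point distance
mismatch bounds the achievable RMSD from below
(\(\sum_{i<j}(d^P_{ij}-d^Q_{ij})^2 \le 2n(n-1)\,\mathrm{RMSD}^2\)), so
partial correspondences that already exceed the current threshold are
discarded without a superposition. Only provably worse branches are pruned;
the returned minimum is identical to the naive enumeration, which the test
suite verifies against an independent quaternion-based oracle.

Conformers whose best RMSD exceeds `rmsd_max` (default 0.5 Å, the filter
used in the original campaign) are rejected. `screen_library()` keeps the
best accepted match per conformer and then deduplicates to one row per
molecule, keeping the lowest-RMSD conformer — multi-conformer libraries
report each unique compound once, which mirrors how duplicate conformers
were collapsed to unique compounds in the original screen. Ties between
queries at equal RMSD resolve toward the larger query.

## 2. Compound prioritisation

Docking engines are deliberately out of scope: scores enter as data
(`import_scores()`) or through a pluggable backend closure, and a
deterministic soft-sphere toy backend exists solely so end-to-end tests can
run without an external engine. On top of the score tables the package
provides:

* **Consensus scoring** (`consensus_top()`): the intersection over scoring
  functions of each function's top fraction. The fraction used originally is
  not stated; the default is 0.25, configurable — intersection semantics are
  preserved at any value, and the parameter is scale-free.
* **Ligand efficiency** (`ligand_efficiency()`): score divided by the
  number of atoms. Whether that meant heavy atoms or all atoms is not
  recorded; heavy atoms is the standard convention and is the default, with
  the count supplied by the caller so either interpretation is a data choice.
* **Lipinski profiling** (`lipinski_profile()`): MW ≤ 500, logP ≤ 5,
  HBD ≤ 5, HBA ≤ 10. All filters in the package treat boundaries
  inclusively (a compound at exactly the cutoff passes); the convention is
  stated once here and applied everywhere.
* **Solubility filter** (`solubility_filter()`): predicted aqueous
  solubility at or above 10⁻⁴ mol/L by default — the concentration scale
  required for NMR follow-up screening.
* **Pose consistency** (`pose_consistency()`): mean pairwise RMSD of a
  compound's docked poses, computed **without** superposition because docked
  poses already share the receptor frame; a tight bundle indicates a
  consistently predicted binding mode.
* **Pareto ranking** (`pareto_rank()`): non-dominated sorting. Compound A
  dominates B when A is no worse in every objective and strictly better in
  at least one, after aligning objective directions. Front 1 is the
  non-dominated set; successive fronts are obtained by peeling. Within a
  front, ordering uses a normalised rank-sum tie key (mean of per-objective
  ranks scaled to [0, 1]) rather than crowding distance: it is
  deterministic, trivially explained, and adequate for shortlisting.
  Truncation to a top-n cuts at front boundaries, breaking the boundary
  front by tie key then id. The exact objective columns used originally are
  not recorded; the default set is consensus score (max), ligand efficiency
  (max), MW, logP, HBD, HBA (min) and solubility (max), fully configurable.

The whole funnel is orchestrated by `run_selection()` /` run_pipeline()`,
which log entering/leaving compound counts per stage and write
content-hashed artifacts so identical configurations provably produce
identical outputs.

A small property utility, `monoisotopic_mass()`, sums principal-isotope
masses over a molecular formula (shipped table: C, H, N, O, S, P, F, Cl,
Br, I, Na, K, B, Si); synthesis-confirmation masses are conventionally
compared at two decimals.

## 3. Titration analysis and K_D fitting

Ligand binding is detected and quantified through amide chemical shift
perturbations (CSPs) in ¹H,¹⁵N correlation spectra. The combined CSP uses
the standard weighting
\[\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2},\qquad
\alpha = 0.14,\]
with α configurable; the exact combination used for the published
perturbation amplitudes is not recorded, so profiles may also be supplied
pre-combined and are then used as-is.

In the fast-exchange regime one population-weighted peak is observed, so
the perturbation of residue *r* at total ligand \(L_t\) is
\(\Delta\delta_r = \Delta\delta_{\max,r}\, f_b\), with the bound fraction
from the single-site mass-action quadratic
\[f_b = \frac{(P_t+L_t+K_D) - \sqrt{(P_t+L_t+K_D)^2 - 4P_tL_t}}{2P_t}.\]
The "minus" branch is the physical one — the other root exceeds the total
protein concentration. Concentrations are mM and shifts ppm throughout.

`fit_kd()` estimates \((K_D, \Delta\delta_{\max})\) by nonlinear least
squares (Levenberg–Marquardt), with:

* **K_D on the log scale**, which enforces positivity and makes the
  sampling distribution more symmetric;
* **multi-start** over \(K_D \in \{0.1, 1, 10, 100\}\) mM to avoid local
  minima — the global mode shares one K_D across residues with
  residue-specific amplitudes, the per-residue mode fits each residue
  independently;
* **amplitude-proportional weighting by default**: after an unweighted
  pass, residues are reweighted by the inverse of their fitted amplitude
  magnitude and the fit repeated (twice). This is the maximum-likelihood
  weighting when CSP measurement error scales with the perturbation
  amplitude — the error model the synthetic generator implements — and it
  is what makes the reported standard errors calibrated in the recovery
  studies below. When peak-position error is better described as constant
  in ppm, `weights = "uniform"` fits unweighted. The two coincide for
  single-residue data;
* **covariance-based standard errors** from the Gauss–Newton approximation
  at the optimum, with the free-protein point excluded from the
  residual-variance degrees of freedom (it is a structural zero — the
  reference spectrum — and carries no noise);
* **explicit failure modes**: fewer than four titration points and all-zero
  perturbations are errors; data without measurable curvature over the
  schedule (fitted K_D beyond 25 times the largest ligand concentration, or
  an exploding log-scale standard error) are flagged non-identifiable
  rather than silently returned, because on a linear response K_D and
  \(\Delta\delta_{\max}\) trade off freely.

The fit returns a classed model object with `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals` and `plot` methods.

`csp_profile_compare()` aligns two per-residue CSP profiles on their shared
residues (at least three required), reporting the difference vector and the
Spearman rank correlation — the tool used to ask whether a small molecule
perturbs the same surface as the natural SxIP peptide.

## 4. Ensemble docking analysis and pocket dynamics

Because the SxIP pocket is not preformed in solution — the Arg222 and
Tyr247 side-chains that form its walls are mobile in the free protein —
docking against a single structure is unreliable. `aggregate_ensemble_scores()`
averages a compound × receptor-conformation score matrix per compound
(mean, sd, min, max), ranks by ensemble mean, and excludes explicit
failed-docking sentinels (`NA`) from the aggregates with a logged count
rather than imputing them. `rank_agreement()` quantifies concordance with an
experimental affinity order by tie-corrected Kendall τ and Spearman ρ.

Pocket geometry is summarised by two **gate distances** — from the Tyr247
side-chain Cζ across the binding site to the Cα atoms of Leu221 and
Leu246 — computed per model of a multi-model ensemble
(`distance_series()`, `pocket_metrics()`). `classify_pocket()` labels each
model *closed* (both gates at or below `closed_max`), *open* (both at or
above `open_min`), *bound-like* (both within ±1.5 Å of reference distances
measured in a supplied bound-form structure) or *indeterminate*. No
numerical thresholds for these states are published — the states are
defined qualitatively — so thresholds are always explicit in configuration:
the bound-like window requires a reference structure, and the
closed/open partition is placed at the midpoint of the observed
gate-distance range when calibrated from data. Overlapping regions are a
configuration error, not a tie-break.

Per-atom RMSF uses an **iterated mean-structure superposition**: models are
least-squares fitted (on e.g. the Cα atoms of the stable helical regions,
residues 218–232 and 239–247) to the ensemble mean, the mean is recomputed,
and the procedure repeats (at least two iterations) to a 10⁻⁶ Å tolerance.
Fitting to the evolving mean rather than to the first model removes
reference bias; it is standard practice in trajectory analysis.

`formal_charge()` implements the integer ionisation model at pH 7 (Asp/Glu
−1, Lys/Arg +1, His 0 with its pKa ≈ 6, termini +1/−1 netting zero), and
`neutralizing_ions()` converts a multimer's total charge into a monovalent
counterion count for simulation setup. His protonation is a parameter for
work near its pKa.

## 5. Synthetic data: what it emulates, and what it does not

Every stage has a seeded generator with machine-readable ground truth, so
each claim in the test suite traces to a planted answer:

* `plant_conformer_library()` — hits are the model's feature points under a
  random rigid motion plus isotropic Gaussian jitter (σ default 0.05 Å);
  decoys are either single-kind point sets (no kind-compatible
  correspondence exists for any mixed-kind query) or geometry-randomised
  sets with the right kinds but uniform random coordinates.
* `simulate_titration()` — the fast-exchange forward model plus Gaussian
  noise with s.d. equal to `noise_fraction` × each residue's amplitude.
  The default protocol is 0.05 mM protein, 12 ligand points from 0 to
  40 mM, 2% noise: the protein concentration is the documented screening
  condition; the ligand schedule is not published, and 0–40 mM is a
  documented stand-in that spans the weak-binding K_D range (2–14 mM) up
  to several-fold ligand excess, which is where the curvature that
  identifies K_D lives. The free-protein point is exactly zero by
  construction.
* `make_toy_ensemble()` — a rigid scaffold with a gate pseudo-atom whose
  anchor distances are drawn in the closed (6.5 ± 0.4 Å) or open
  (12 ± 0.4 Å) region per model, Bernoulli-labelled with the requested
  closed fraction.
* `make_score_matrix()` — base scores strictly decreasing along a planted
  affinity order plus per-conformation Gaussian noise.

One global seed expands into per-generator child seeds through a fixed
polynomial hash of the stream name (`child_seed()`), so stages are
independently reproducible under a single knob and no two streams share a
generator state.

These generators validate the *machinery*, not the chemistry: planted
conformers are feature-point skeletons, not molecules; decoys are
geometrically, not chemically, realistic; the toy ensemble has a
caricatured gate; and synthetic titrations have exactly the noise model the
fitter assumes. Passing tests therefore demonstrate correctness of the
algorithms and calibration under the stated models — they say nothing about
hit rates or affinities on real libraries and spectra.

## 6. Reference values and study-scale choices

The package's acceptance checks re-derive, at desk scale, the quantities
the workflow is anchored to: the eight-point SxIP model with its 3/2/3
acceptor/donor/hydrophobic composition; the monoisotopic masses 289.18 and
303.18 Da of the two synthesis-confirmation formulas; median K_D recovery
at the three measured dissociation constants (SKIP peptide 14 mM, and the
two lead compounds at 10 and 6 mM) over 200 replicates of the synthetic
protocol, judged against the measured uncertainties (±1.9, ±3, ±1 mM); and
the ensemble-average score ranking (64/53/48/46 for the four tested
compounds) reproducing the experimental affinity order with τ = 1. The
published ensemble averages are engine-specific scores and are used as a
printed input table, not recomputed.

Recovery studies use 40–200 replicates per condition and libraries of tens
of conformers; these sizes give binomial/medians stable enough for the
stated tolerances while keeping the full suite interactive.

**Known limitation — charge bookkeeping.** For the EBH-domain construct
(UniProt Q15691, residues 191–260; sequence shipped as plain-text FASTA and
cross-checked against all residue identities the accompanying analyses
name), the integer model gives −12 per monomer: 7 Asp + 11 Glu + 3 Lys +
3 Arg, no His, termini netting zero. The published simulation setup states
−11 per monomer and 22 neutralising sodium ions for the dimer; that pair of
values is mutually consistent only at −11, which the sequence does not
support under this (or any standard integer) ionisation model. The package
reports the arithmetic consequence of its stated model (−12, hence 24
cations for the dimer); the corresponding acceptance check records the
discrepancy rather than papering over it.

## 7. Limitations

* Docking scores are consumed, never produced; conclusions about ranking
  quality are conditional on the supplied engine.
* The matcher is exhaustive by design and capped at 12 query features;
  database-scale indexed pharmacophore search is out of scope.
* Ligand feature typing uses element/connectivity rules, not a full
  chemical perception model (no aromaticity model, no charged-group
  typing); for real libraries, feature points are better imported from a
  cheminformatics pipeline.
* Lineshape analysis for slow/intermediate exchange is out of scope; the
  fitter assumes fast exchange throughout.
* Wald-type uncertainties from the covariance are accurate at the 2% noise
  level tested; at much higher noise or near non-identifiability, profile
  or bootstrap intervals should be preferred.
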