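# dynappi

Pharmacophore screening, NMR titration fitting and receptor-ensemble
analysis for **dynamic protein–protein interaction sites**, built around the
SxIP–EB1 system.

End-binding protein 1 (EB1) recruits +TIP proteins to growing microtubule
ends through a shallow pocket on its End-Binding homology (EBH) domain that
recognises the Ser-x-Ile-Pro (SxIP) motif. The pocket is not preformed in
solution — the Arg222 and Tyr247 side-chains that form its walls are mobile
in the free protein — which makes it a hard, and representative, target for
small-molecule modulation. `dynappi` packages the complete computational
workflow for such campaigns, for computational chemists and structural
biologists who want each stage reproducible and testable:

1. **Pharmacophore screening** — build a typed interaction-point model
   (acceptor / donor / hydrophobic) from a protein–peptide complex,
   enumerate feature-subset queries, and match conformers by exhaustive
   kind-compatible correspondence search with closed-form least-squares
   superposition. A conformer is a hit when its minimum feature RMSD
   satisfies

   `RMSD = sqrt( (1/n) Σᵢ ‖R xᵢ + t − qᵢ‖² ) ≤ 0.5 Å`

   minimised over correspondences and rigid motions (R, t), det R = +1.
2. **Multi-objective prioritisation** — consensus scoring across scoring
   functions, ligand efficiency (score per heavy atom), Lipinski rule-of-5
   profiling, a solubility cutoff (default 10⁻⁴ M), docking-pose
   consistency, and Pareto non-dominated sorting with deterministic
   tie-breaking.
3. **NMR titration analysis** — combined amide chemical-shift perturbations
   `Δδ = sqrt(ΔδH² + (0.14·ΔδN)²)` fitted to the two-state fast-exchange
   binding model

   `Δδᵣ(Lt) = Δδmax,ᵣ · fb`,  `fb = [(Pt+Lt+KD) − sqrt((Pt+Lt+KD)² − 4·Pt·Lt)] / (2·Pt)`

   by multi-start Levenberg–Marquardt (shared-K_D global mode or
   per-residue), with calibrated standard errors and explicit
   non-identifiability flags.
4. **Ensemble docking analysis & pocket dynamics** — per-compound
   aggregation of compound × receptor-conformation score matrices, rank
   concordance (Kendall τ, Spearman ρ) with experimental affinity order,
   gate-distance series (Tyr247 Cζ – Leu221/Leu246 Cα), per-atom RMSF after
   iterated mean-structure superposition, open/closed/bound-like pocket
   classification, and charge/counterion arithmetic for simulation setup.
5. **Seeded synthetic data** — planted conformer libraries, fast-exchange
   titrations, toy gate ensembles and score matrices, each with a
   machine-readable truth table, so the whole pipeline is testable
   end-to-end without external engines or spectrometers.

Standard formats are used throughout: SDF V2000 (conformer libraries),
multi-model PDB (ensembles), FASTA (sequences), documented CSV schemas
(shift tables, score matrices), JSON (fits, audit logs).

## Worked example

```r
library(dynappi)

## 1. the SxIP pharmacophore model (8 points: 3 acceptors, 2 donors,
##    3 hydrophobic centroids) from the shipped synthetic peptide fixture
model <- build_sxip_model(system.file("extdata", "sxip_peptide_synthetic.pdb",
                                      package = "dynappi"))
model
#> Pharmacophore model 'sxip' (8 features; source: residues 5477,5479,5480)
#>   kinds: acceptor 3, donor 2, hydrophobic 3

## 2. screen a planted library: 5 true hits (0.05 A jitter) among 20 decoys,
##    all 92 subset queries of sizes 5-7, 0.5 A RMSD filter
camp <- plant_conformer_library(model, n_hits = 5, n_decoys = 20,
                                jitter_sigma = 0.05, seed = 42)
hits <- screen_library(camp$library, model, sizes = c(5, 6, 7), rmsd_max = 0.5)
head(hits, 3)
#>   molecule_id conformer_id query_size query_indices     rmsd_A
#> 1      hit004    hit004_c1          5     2,4,5,6,7 0.03346568
#> 2      hit001    hit001_c1          5     1,2,3,4,8 0.03894671
#> 3      hit005    hit005_c1          5     1,3,6,7,8 0.04415886
nrow(hits)   # 5 -- every planted hit recovered, no decoy accepted

## 3. fit a dissociation constant from a synthetic fast-exchange titration
##    (0.05 mM protein, 12 points 0-40 mM ligand, 2% noise)
s <- simulate_titration(kd = 6, dmax = c(Y247 = 0.66, A248 = 0.4, T249 = 0.2),
                        noise_fraction = 0.02, seed = 42)
fit <- fit_kd(s, mode = "global")
fit
#> Two-state fast-exchange binding fit
#>   K_D  = 5.98 mM (se 0.31)
#>   dmax[Y247] = 0.662 ppm (se 0.0098)
#>   dmax[A248] = 0.4011 ppm (se 0.006)
#>   dmax[T249] = 0.2002 ppm (se 0.003)
#>   RSS 0.0034 over 3 residue(s) x 12 points; converged: TRUE

## 4. ensemble-average docking scores vs the experimental affinity order
printed <- matrix(c(64, 53, 48, 46), 4, 1,
                  dimnames = list(c("1d", "1a", "1c", "1b"), "ensemble_avg"))
aggregate_ensemble_scores(printed)$id
#> [1] "1d" "1a" "1c" "1b"
rank_agreement(setNames(printed[, 1], rownames(printed)),
               c("1d", "1a", "1c", "1b"))$tau
#> [1] 1
```

The fitted K_D of 5.98 ± 0.31 mM recovers the generating value (6 mM)
within one standard error; the screen recovers exactly the planted hit set;
and the ensemble-average score table ranks the four compounds in the
experimental affinity order with perfect concordance (τ = 1).

## Documentation

The methods vignette (`vignettes/dynamic-ppi-screening.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generators do and do not emulate, numerical
choices, and known limitations.
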