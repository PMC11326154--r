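# allomap

Inferring allosteric residue networks from perturbation experiments.

When a point mutation far from an enzyme's active site changes its
activity, the signal travels through a network of residues. **allomap**
maps that network from two complementary residue-resolved experiments
and quantifies how well it matches externally defined residue sets:

* **Isomorphous difference crystallography** — mutant and wild-type
  amplitudes are scaled together, combined into error-weighted
  difference structure factors
  `w = [1 + σΔ²/⟨σΔ²⟩ + α·ΔF²/⟨ΔF²⟩]⁻¹` (α = 0.05), phased with the
  reference model, and synthesized into a real-space Fo−Fo map by FFT.
  The map is reduced to per-residue **IADDAT** scores: |Δρ| above
  0.04 e⁻/Å³ within 1.5 Å of a protein heavy atom, summed and averaged
  per residue.
* **HDX-MS difference analysis** — peptide centroid masses become
  back-exchange-corrected %deuteration via fully-deuterated controls,
  mutant−WT Woods-plot differences are classified against a ±5
  percentage-point band, and a residue-level profile is built by
  inverse-amide-count weighted interpolation (optionally over a greedy
  short-peptide cover).
* **Michaelis–Menten kinetics** — v = V_max·S/(K_m+S) fitted to
  plate-reader velocities; k_cat = V_max/(ε·ℓ·E₀); mutant/WT ratios
  with replicate-level confidence intervals.
* **Network overlap** — residues with IADDAT > 0.3 or |Δ%D| > 7 are
  pooled by union into a combined network and compared with residue
  sectors via the Jaccard ratio J(X,Y) = |X∩Y|/|X∪Y| and the
  hypergeometric upper-tail test P(X ≥ k).

A synthetic-data module simulates all four input types (toy P1
crystals with direct-summation structure factors, peptide uptake
curves from per-residue protection factors, plate-reader kinetics,
residue sets with controlled overlap) with known ground truth — the
package's validation rests on recovering that truth.

## Worked example

Simulate a wild-type toy crystal and a mutant with a 1.5 Å side-chain
displacement at residue 15, add 5 % measurement noise, and run the
difference-map branch:

```r
library(allomap)

wt  <- make_toy_structure(30, seed = 1)
mut <- perturb_structure(wt, 15, displacement = 1.5, seed = 2)
f_wt  <- add_measurement_noise(simulate_structure_factors(wt,  d_min = 1.8), 0.05, seed = 3)
f_mut <- add_measurement_noise(simulate_structure_factors(mut, d_min = 1.8), 0.05, seed = 4)

scaled <- scale_to_reference(f_mut, f_wt)
attr(scaled, "scale")
#>          k          B
#>  1.0030184 -0.2084265

coef <- phase_from_model(weighted_differences(scaled, f_wt, alpha = 0.05), wt)
dmap <- synthesize_map(coef, grid_spacing = 0.5)
dmap
#> real_space_map: 37x37x111 grid, cell 18.1 18.13 55.24 90 90 90, rms 0.01017 e-/A^3

prof <- compute_iaddat(dmap, wt, threshold = 0.04, radius = 1.5)
head(prof[order(-prof$score), ], 3)
#>    resno chain      score n_atoms
#> 15    15     A 2.49589757       5
#> 18    18     A 0.08900163       5
#> 8      8     A 0.01661822       5
```

The scale fit is near-identity (k ≈ 1, |B| < 0.3 Å², as it should be
for the same model at the same nominal B), the difference map has low
RMS background, and the perturbed residue 15 carries an IADDAT score
~28× above the runner-up — the map localizes the perturbation.

Kinetics, from simulated quadruplicate data (true k_cat = 20 s⁻¹,
K_m = 5 mM, 5 % noise):

```r
fit <- fit_michaelis_menten(simulate_kinetics(k_cat = 20, K_m = 5, E0 = 125,
                                              rel_noise = 0.05, n_reps = 4, seed = 1))
fit
#> Michaelis-Menten fit (n = 48)
#>   Vmax = 1360 mAU/min  [1330, 1390]
#>   Km   = 4.982 mM  [4.63, 5.334]
#>   kcat = 20.15 1/s  [19.7, 20.6]
```

Both parameters are recovered within their confidence intervals.

For the full route — difference maps and HDX for several mutants,
pooled into a network and tested against sectors — see
`make_synthetic_fixture()` + `run_pipeline()`, and the methods
vignette (`vignettes/allomap-methods.Rmd`) for the science and the
design decisions.

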