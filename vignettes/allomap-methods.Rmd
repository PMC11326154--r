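---
title: "Mapping allosteric residue networks with allomap: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping allosteric residue networks with allomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomap)
```

## The problem

Point mutations distant from an enzyme's active site can perturb its
activity through allosteric networks — chains of residues whose
conformational ensemble or local dynamics shift together. Two
complementary experiments see these shifts at residue resolution:

* **Isomorphous difference crystallography.** Two crystals of the same
  form (mutant and wild type) diffract to similar resolution; the
  Fourier synthesis of their amplitude differences, phased with the
  reference model, shows where electron density has moved.
* **HDX-MS.** Backbone amides exchange hydrogen for deuterium at rates
  set by hydrogen bonding and solvent access; mutant-minus-wild-type
  differences in peptide deuteration localize changes in dynamics.

allomap implements the computational route from both raw inputs to a
pooled residue network, together with Michaelis–Menten kinetics for the
functional readout and overlap statistics against externally defined
residue sets (e.g. coevolving sectors from statistical coupling
analysis). A synthetic-data module generates all four input types with
known ground truth, which is how the package validates itself.

## Difference maps and IADDAT

### Scaling

Mutant amplitudes are first placed on the reference scale by least
squares over the common reflections, minimizing
$\sum_h \left(k\, e^{+B s^2/4} F_\mathrm{mut} - F_\mathrm{ref}\right)^2$
with $s = 1/d$. The reported $B$ is the *relative isotropic B-factor of
the mutant data*: positive $B$ means the mutant lattice is more smeared
and the correction $e^{+B s^2/4}$ sharpens it back. The fit is
Levenberg–Marquardt with an analytic Jacobian, seeded from a log-linear
(Wilson-style) regression; this survives degenerate inputs (exact scale
multiples, zero residuals) that break the usual `nls` machinery.

### Error weighting

Each common reflection yields $\Delta F = F_\mathrm{mut,scaled} -
F_\mathrm{ref}$ and $\sigma_\Delta^2 = \sigma_\mathrm{mut}^2 +
\sigma_\mathrm{ref}^2$. Before synthesis, coefficients are down-weighted
by the standard error/outlier weighting for Fo−Fo maps:

$$w_h = \left[\,1 + \frac{\sigma_{\Delta,h}^2}{\langle\sigma_\Delta^2\rangle}
 + \alpha\,\frac{\Delta F_h^2}{\langle\Delta F^2\rangle}\,\right]^{-1},
 \qquad \alpha = 0.05 .$$

$\alpha$ controls how aggressively large $|\Delta F|$ outliers are
suppressed; $0.05$ is the conventional default for mutant-vs-WT
difference maps and the package default. The normalizing means are
global by default; whether the original lineage of this weighting used
global or resolution-binned means is ambiguous in the literature, so
equal-population resolution bins are available via `n_bins` and the
choice is recorded in the output attributes.

### Synthesis and integration

Maps are synthesized by FFT on a grid obeying the sampling condition
(spacing $\le d_\mathrm{min}/2$; default 0.5 Å), with Hermitian
expansion of the Friedel-unique coefficients so the map is exactly
real, and F000 excluded so the map mean is zero. A direct-summation
evaluator (`map_value_direct`) provides the slow exact answer at
arbitrary fractional coordinates; the test suite holds the FFT to it at
randomly chosen points and checks Parseval's identity, both at 1e-6
relative.

IADDAT (integration of absolute difference density above a threshold)
then turns the map into a per-residue score: every grid point with
$|\Delta\rho| > 0.04\ e^-/\text{Å}^3$ (strict inequality) is assigned
to the nearest non-water heavy atom within 1.5 Å under minimum-image
periodic distances, and each residue's accumulated $|\Delta\rho|$ is
divided by its heavy-atom count. Two conventions were genuinely open:

* *Atom-averaged vs grid-point-averaged.* The per-atom division is the
  default because it makes residues of different size comparable
  (glycine vs tryptophan); `per_grid_point = TRUE` selects the
  alternative, and the normalization used is recorded in the profile.
* *Tie-breaking.* A grid point equidistant from atoms of two residues
  goes to the lowest (chain, residue, atom id) — determinism matters
  more than the physically arbitrary choice.

Scores are raw; `cap_for_display(profile, 0.3)` produces the capped
copy used for structure coloring without ever touching the raw values.

## HDX-MS difference analysis

### From centroids to percent deuteration

A peptide of length $L$ has $L-1$ backbone amides; prolines carry none,
and the amide adjacent to the N-terminal residue loses its label too
fast to measure. The exchangeable count is therefore
$N_\mathrm{ex} = L - 2 - \#\{\text{P at positions } 3..L\}$. Two
algebraically identical formulations of this rule are computed and
asserted against each other on every call.

With a fully-deuterated (FD) control the back-exchange-corrected
deuteration is $\%D = 100\,(m_t - m_0)/(m_{FD} - m_0)$; without one,
the theoretical maximum $N_\mathrm{ex}\, d_\mathrm{frac}\, m_D$
($m_D = 1.00628$ Da, $d_\mathrm{frac} = 0.90$) is the denominator.
Values are clipped to $[-5, 110]$: small negative values are tolerated
as noise, anything beyond is flagged. Replicates are averaged within
condition before differencing; missing replicates reduce n rather than
aborting.

### Differences and residue-level interpolation

Peptides are matched by (sequence, start, end) and classified against
the no-change band: protected if $\Delta\%D < -5$, deprotected if
$> +5$, strict at the boundaries. The band (5) and the network cutoff
(7) are distinct constants, both exposed in the configuration.

The residue-level profile is a transparent surrogate for the
proprietary smoothing used by acquisition software: each residue takes
the mean of its covering peptides' $\Delta\%D$, weighted by
$1/N_\mathrm{ex}$ so short, information-dense peptides dominate. The
`short-peptides` scheme first selects a greedy minimal-length cover
(the shortest peptide covering each yet-uncovered position, ties to the
smaller start) — prioritizing short peptides for closer comparison with
single-residue crystallographic scores. Note that this goal is *not*
minimum total length (a single long peptide would win that); it is
using the shortest available peptide everywhere. Residues with no
coverage are flagged `no_data`, never imputed as zero. The scheme used
is recorded in the output; no claim of bit-compatibility with any
vendor's smoothing is made.

## Michaelis–Menten kinetics

Initial velocities (OLS slopes of absorbance traces, mAU/min) are fit
to $v = V_\mathrm{max} S/(K_m + S)$ by nonlinear least squares on
replicate-level points (pooled residuals preserve degrees of freedom),
started from $V_\mathrm{max} = \max v$ and $K_m$ at half-max.
$k_\mathrm{cat} = V_\mathrm{max}/(\varepsilon \ell E_0)$ is reported
only when the molar absorptivity and path length are supplied —
$\varepsilon$ for para-nitrophenolate at 405 nm is buffer- and
pH-dependent, so the package refuses to guess (defaults in the
simulator: 18 AU mM$^{-1}$ cm$^{-1}$, 0.5 cm).

Fitting is on velocities, not a Lineweaver–Burk linearization, which
would bias the noise structure. Confidence intervals on the fit are
covariance-based with a $t$ quantile ($n-2$ df). For mutant-vs-WT
comparison, however, the ratio CI is built from *replicate-level*
parameter estimates (Welch interval on the log scale): under the
multiplicative noise typical of plate readers the pooled-fit covariance
understates $K_m$ uncertainty by roughly half, which would inflate
false "changed" calls, while replicate spread measures it directly.
With single-replicate data the delta method on the pooled-fit errors is
the fallback. A parameter is "unchanged" when the ratio CI contains 1;
a two-tailed one-sample $t$-test of the mutant's replicate-level
activity against the WT mean is reported alongside, mirroring common
practice.

The default simulated substrate series is 12 concentrations spanning
40 mM to 3.9 µM geometrically (dilution factor ≈ 2.3), bracketing
typical phosphatase $K_m$ values from both sides.

## Network pooling and overlap statistics

Residues exceeding the response cutoffs — IADDAT > 0.3, or
$|\Delta\%D| > 7$ (strict) — are pooled by union across mutants and
techniques into the combined network. Overlap with each externally
supplied sector is summarized by the Jaccard ratio
$J(X,Y) = |X \cap Y|/|X \cup Y|$ and the hypergeometric upper tail
$P(X \ge k)$, computed inclusively (the open "≥ vs >" question is
resolved to the inclusive convention, which is the standard enrichment
test) and evaluated in log space.

The universe matters. Whether $N$ counts all construct residues or
only crystallographically resolved ones materially changes the
p-values; the default is the residues present in the supplied model,
any override is echoed in every report, and no-data HDX residues join
the universe only on request.

Because the test statistic is discrete, its attainable size at nominal
0.05 depends on $(N, K, n)$. The calibration study in the test suite
uses $N = 321$ (a full-length catalytic construct), $K = 100$,
$n = 70$, a design whose exact attainable size — computed from the
null CDF before any simulation — is 0.0498, so the empirical type-I
error over seeded draws is expected at nominal level.

## The synthetic-data generators

The generators define the validation conditions; they emulate the
essential physics and nothing more.

* **Toy crystals.** A 5-atoms-per-residue poly-alanine chain on an
  idealized helical path, jittered by 0.05 Å, in a P1 box with a 5 Å
  solvent margin; B = 15 Å², occupancy 1. Structure factors come from
  direct summation with single-Gaussian per-element scattering factors
  (effective electron counts; widths crude but resolution-dependent).
  This is exact for the model — ideal for testing difference signals —
  but has no lattice packing, solvent, anomalous signal, or symmetry
  beyond P1, and is unusable for refinement questions. d_min defaults
  to 1.8 Å. A point mutation is emulated by displacing one residue's
  CB along a seeded random direction (1.5 Å by default), optionally
  with its backbone; measurement noise is proportional
  ($\sigma = 0.05\,F$ by default).
* **HDX uptake.** Per-residue single-exponential exchange
  $D_i(t) = d_\mathrm{frac}(1 - e^{-(k_{\mathrm{int},i}/PF_i)t})$ at
  the exchangeable positions, summed per peptide, back-exchange applied
  as a uniform factor, Gaussian centroid noise (0.05 Da). Intrinsic
  rates default to a single constant 1 s⁻¹ rather than
  sequence-dependent chemistry: ground-truth recovery needs
  controllable rates, and a hook accepts per-residue rates when realism
  matters. The baseline protection factor in the validation studies is
  700, placing the 300 s timepoint mid-transition so that a 10×
  protection produces a ≈30-point %D drop — a strong but realistic
  protection signal.
* **Kinetics.** Michaelis–Menten velocities converted to absorbance
  slopes, multiplicative N(1, 5%) replicate noise, quadruplicate.
* **Residue sets.** Pairs of sets with exact requested sizes and
  intersection, for overlap statistics with known truth.

What passing tests on these data do *not* show: robustness to
non-isomorphism between crystals, to peptide misassignment or spectral
overlap in HDX, to substrate depletion in kinetics, or to any of the
upstream processing (data reduction, refinement, centroiding) that real
inputs have already undergone.

## Problem sizes and numerical choices

The validation studies use sizes chosen to exercise every code path at
interactive speed: 8–10-residue crystals for oracle-equivalence checks
(the exhaustive grid scan is quadratic), a 30-residue crystal over 20
seeds for localization and null calibration, a 40-residue chain for
HDX recovery, 20 seeds for kinetic parameter recovery, 1000 draws for
type-I calibration, and a 60-residue three-mutant bundle for the
end-to-end run. Determinism is part of the contract: every generator
takes a seed, and the full pipeline rerun on identical inputs produces
byte-identical tables.

Other numerical choices worth knowing: strict inequalities at every
threshold (a value exactly at a cutoff never counts as a response);
duplicate reflections merge by inverse-variance weighted mean;
reflections present in only one dataset are dropped, never imputed;
grid dimensions satisfy both the spacing target and Nyquist bounds
($n_i \ge 2 h_{\max,i} + 2$); and the FD control scored against itself
is exactly 100%.

## Limitations

* Space-group support for synthetic data is P1 only; real data in
  higher symmetry must be expanded/merged upstream. Reflection exchange
  is CSV (h, k, l, F, SIGF); models are PDB with a CRYST1 record.
* The residue-level HDX profile is a documented surrogate, not a
  reconstruction of any vendor's deconvolution.
* No peak clustering or blob analysis on difference maps; no
  exchange-rate or ΔG fitting for HDX; no inhibition modeling in
  kinetics; no recomputation of coevolving sectors.
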