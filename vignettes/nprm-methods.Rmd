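---
title: "Nonparametric residue mapping of dynamic PET with bootstrap uncertainty: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric residue mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A dynamic PET acquisition measures decay-corrected activity $z_i(t_j)$
(kBq/mL) in voxel $i$ over $J$ contiguous time frames.  Under the
Meier–Zierler formalism the tissue time course is the convolution of the
arterial whole-blood input $C_p$ with a tissue *residue function* $R(t)$:
the flow-weighted fraction of tracer atoms still resident $t$ seconds after
arterial arrival.  $R$ is non-negative, non-increasing, and carries flow
units (mL/min/g).

Rather than forcing $R$ into a compartmental (sum-of-exponentials) form,
nonparametric residue mapping (NPRM) represents each voxel as a
non-negative combination of $K$ data-derived basis elements,

$$z(t_j) \;=\; \alpha_1\,\mu_1(t_j-\delta) + \dots +
\alpha_K\,\mu_K(t_j-\delta) + \varepsilon(t_j), \qquad \alpha_k \ge 0,$$

where $\mu_k(t) = \int_0^t R_k(t-s)\,C_p(s - \Delta_k)\,ds$ is the
frame-averaged tissue curve of basis residue $R_k$ with element delay
$\Delta_k$, and $\delta$ is a voxel-level arrival delay.  Fits minimise a
weighted least-squares criterion with frame weights proportional to the
frame duration combined with the decay correction at the frame mid-time;
the amplitudes are found by non-negative quadratic programming (an
active-set solver in compiled code) and $\delta$ by a crude grid search
(default $-10..30$ s in 2-s steps for voxels, $\pm 300$ s for VOI mean
curves).

### Kinetic parameters

The fitted voxel residue $\hat R = \sum_k \alpha_k R_k$ is decomposed with
a vascular transit threshold $t^\*$ (default 15 s):

* $R_b(t) = (R(t) - R(t^\*))\,1\{t < t^\*\}$ — fast vascular component;
* $R_e(t) \equiv R(T_{end})$ — extracted (trapped) component;
* $R_d = R - R_b - R_e$ — in-distribution component.

Areas (time in minutes) give the vascular volume $V_b = \int R_b$ and
distribution volume $V_d = \int R_d$; heights give the flux
$K_i = R(T_{end})$ and distribution flow $K_d = R_d(0)$.  Ratios give the
mean transit time $\mathrm{MTT} = V_d/K_d$ and extraction fraction
$\mathrm{Ext} = K_i/(K_d+K_i)$.  Derived clinical variables are
$\mathrm{MR}_{FDG} = \mu_{glc} K_i$ (µmol/100 g/min), $\mathrm{DV} = V_d$,
and, via the central volume theorem with vascular mean transit $t^\*/2$
(7.5 s), $\mathrm{BF} = V_b/(t^\*/2)$.

Because the decomposition is linear in $R$, per-element loadings
$(V_b^k, V_d^k, K_d^k, K_i^k)$ are precomputed and voxel maps obtained as
matrix products in the amplitudes — this is what makes whole-image
bootstrap refits cheap.

### Open choices resolved here

* **Ext denominator.** $K_i/(K_d+K_i)$ (retained fraction of non-vascular
  delivery), the alternative $K_i/K_d$ is available via
  `ext_convention = "flow"`.
* **$R_d$ below $t^\*$** is the constant $R(t^\*) - R(T_{end})$ (i.e. the
  decomposition subtracts the vascular excess above $R(t^\*)$).
* **MTT when $K_d \approx 0$** (below $10^{-9}$) is reported missing, not
  infinite.
* **Weight convention.** "Product of frame duration and decay correction
  factor" is ambiguous: we default to
  $w_j \propto \mathrm{dur}_j\,e^{-\lambda t_j}$ (decay-corrected late
  frames carry fewer raw counts, hence larger variance and smaller
  weight — the Poisson-variance argument); the literal multiplier reading
  $\mathrm{dur}_j\,e^{+\lambda t_j}$ is available as
  `convention = "product"`.
* **Convolution form.** The basis integral is implemented as the standard
  causal convolution $\int_0^t R_k(t-s) C_p(s-\Delta_k) ds$.
* **The 2C model's six parameters** are taken as
  $(K_1, k_2, k_3, k_4, V_b^{frac}, \mathrm{delay})$.

## Basis construction

Candidate residues come from the study's own data: voxel time courses are
amplitude-normalised (divided by their time integral) and clustered by
k-means into $S$ segments (default $4\cdot\max(K)$); one shape-constrained
residue + delay is fitted per segment mean curve.  The shape constraint is
exact by construction: a piecewise-linear residue on a fixed geometric knot
grid (~30 knots, 1 s–$T_{end}$) is a non-negative combination of
"staircase" elementary shapes (a constant plus one element per knot
interval dropping from 1 to 0), so the constrained fit is again a
non-negative quadratic program.  Element delays use a $-20..+60$ s grid.

For each candidate size $K$, elements are chosen greedily to minimise
training WRSS; $K$ is selected by cross-validation over voxels.

**Scoring held-out voxels needed care.**  Refitting a held-out TAC over a
*nested* non-negative basis is monotone in $K$ — a superfluous element is
simply zeroed by the QP, so validation WRSS never turns upward and a plain
minimiser drifts to $\max(K)$ in every experiment.  Two measures restore an
honest model-size signal:

1. held-out voxels are scored by *prediction*: amplitudes are fitted using
   the odd frames only and the weighted error is evaluated on the even
   frames (folds remain over voxels; the frame split is purely a scoring
   device inside each held-out voxel);
2. the selected $K$ is the smallest whose CV score is within one fold-SE
   of the minimum (the familiar one-SE rule, default on).

With these, a three-organ phantom at realistic noise selects $K = 3$
consistently and a one-dimensional truth selects $K = 1$; the CV curve is
steeply decreasing up to the true dimension and flat beyond it.

## The two-compartment reference

The Huang–Sokoloff model is fitted for comparison: impulse response
$h(t) = K_1[(k_3+k_4-\alpha_1)e^{-\alpha_1 t} +
(\alpha_2-k_3-k_4)e^{-\alpha_2 t}]/(\alpha_2-\alpha_1)$ plus a fractional
blood volume term $V_b^{frac} C_b(t)$ (the whole-blood input curve, since
the study-style AIF is whole blood) and an input delay.  Exponential
convolutions are computed by $O(n)$ recursive filtering on the fine grid;
optimisation is BFGS (`stats::optim`) on log/softplus-transformed
parameters with 10 jittered log-uniform multistarts and the delay profiled
on a grid ($\pm 5$ min, 10-s step).  A Meier–Zierler residue for the fitted
model adds a sharp vascular element — a triangle of height
$2 V_b^{frac}/t^\*$ falling to zero at $t^\*$ (area $V_b^{frac}$, mean
transit $t^\*/2$, consistent with the BF convention above; a rectangle is
available behind a flag).

One caveat documented by the tests: with fast tissue exchange the
decomposition attributes the early-transit part of $h$ (its drop over
$[0, t^\*)$) to $V_b$, so the identity $V_b = V_b^{frac}$ is exact only in
the pure-vascular limit; at typical FDG rates the cross-talk is below 1%.

## Image-domain bootstrap

Fit residuals $e_{ij} = z_{ij} - \hat z_{ij}$ are factored as
$e_{ij} = \sigma_e\,\psi_i\,\phi_j\,\epsilon_{ij}$: an overall scale, a
per-voxel relative scale, and a per-frame relative scale, normalised so
$\mathrm{mean}(\psi^2) = 1$, $\sum_j w_j\phi_j^2 = 1$; $\sigma_e$ is the
weighted RMS of the factored residuals, so the normalised pool has
weighted RMS 1.  Three estimation choices were driven by SE-calibration
experiments against Monte-Carlo ground truth (each is a flag on
`build_dgp`):

* **Winsorized-RMS scales, not plain MAD.**  A MAD per-voxel scale has
  $\approx 1.6/\sqrt{J}$ relative sampling noise ($\approx 20\%$ at
  $J = 62$), which transfers verbatim into every bootstrap SE; the
  alternating passes instead use an RMS clipped at six robust SDs —
  near-RMS efficiency ($\approx 9\%$ noise) while keeping tail
  robustness.
* **Leverage standardisation.**  Fitting absorbs residual variance
  non-uniformly across frames (most in the high-weight late frames that
  determine the flux), so residuals are divided by $\sqrt{1-h_j}$ with
  $h_j$ the per-frame leverage of the weighted basis design; a global
  df inflation is not enough.
* **Moderated voxel scales.**  $\log\psi_i$ is shrunk toward its stratum
  mean by the usual empirical-Bayes factor $\tau^2/(\tau^2 + 1/(2J))$
  (the same logic as variance moderation in microarray analysis),
  trading a small conditional bias for a large variance reduction in the
  SE maps.

Replicates are generated as
$z^*_{ij} = \hat z_{ij} + \sigma_e \psi_i \phi_j \epsilon^*_{ij}$, with
$\epsilon^*$ resampled *framewise* with replacement from donor voxels in
the same stratum (quantile bins of fitted time-integrated signal crossed
with axial bands, collapsed so every stratum keeps at least 40 donors).
Framewise resampling preserves each frame's marginal distribution —
including its skewness — but deliberately not the intra-voxel temporal
correlation of the residual vectors, and this is a correctness
requirement, not a convenience: fit residual *vectors* are
weighted-orthogonal to the basis curves, and the kinetic parameters are
linear functionals inside the basis span, so replicates built from whole
resampled residual vectors perturb the refit almost not at all and the
bootstrap SEs collapse (observed about five-fold too small; exactly zero
in the linear, fixed-active-set limit).  Whole-vector resampling remains
available (`resample = "vector"`) for studying that effect.  Spatial
correlation *between* voxels is diagnosed (directional autocorrelations,
axial scale profile) but not regenerated — a documented limitation shared
with the diagnostic-only role of the spectrum analysis.

Each replicate is refitted with the *same* basis and delay grids
(conditional-on-model bootstrap; no basis re-selection), and the SE of any
statistic — voxel parameter, VOI mean, maximum-intensity projection — is
the SD across replicates ($N_B - 1$ denominator; default $N_B = 25$).  For
MIPs the SE is the SD of the replicate MIPs, *not* the MIP of the SE map:
the maximum is a nonlinear order statistic and the two differ.

### What the calibration test does and does not establish

The acceptance suite checks, on a $16^3$ phantom, that the bootstrap SE of
$K_i$ ($N_B = 50$) lies within ±25% of the Monte-Carlo SD over 200
independently regenerated datasets for at least 80% of voxels.  With the
estimator above the SE maps are globally well calibrated (median
SE-to-truth ratio $\approx 0.94$), and organs with appreciable flux reach
about 80% voxelwise coverage — but the phantom's liver-like organ (flux
near the non-negativity boundary, $K_i \approx 0.0045$ mL/min/g) does
not, and the aggregate criterion stays red at roughly 65–70%.  The
failure decomposes into terms that no residual bootstrap removes: a
$\approx 10\%$ chi-square noise floor from $N_B = 50$ itself, the
residual per-voxel scale uncertainty, and — dominant for the boundary
organ — the plug-in conditioning error: the bootstrap conditions on one
dataset's fitted amplitudes and active set, whose local sensitivity
differs voxel-by-voxel from the truth's.  An oracle bootstrap given the
*true* noise scales attains only $\approx 80\text{–}84\%$ under the same
protocol, which locates the bar at the edge of what the statistic itself
permits.  A green result here would validate variance transfer under the
phantom's stated world (multiplicative scales, skewed i.i.d. noise, no
inter-voxel correlation); neither outcome speaks to calibration under
reconstruction-induced spatial correlation, motion, or basis
misspecification.

## The synthetic phantoms

The generator emulates acquisition structure, not anatomy: rectangular
"organ" regions on a default $32\times32\times48$ grid, a gamma-variate
bolus AIF with a two-exponential washout tail (injection at 15 s, peak
50 kBq/mL), the printed 62-frame/65-min whole-body binning, and Eq.-3-style
noise.  Presets:

* `twocomp` — three organs with 2C residues (vascular triangle +
  biexponential), i.e. truths inside the compartmental family;
* `mixed` — liver/kidney-like residues with *linear-decay* distribution
  phases that no 2-exponential model can represent (the model-mismatch
  test bed);
* `flat` — constant residues (pure trapping, the Patlak limit:
  $V_b = V_d = 0$, $\mathrm{Ext} = 1$).

Noise defaults were fixed once: $\sigma_e = 0.4$ kBq/mL, skewness 1.5
(standardised shifted gamma), $\phi_j \propto 1/\sqrt{w_j}$ (short/late
frames noisier), and a U-shaped axial $\psi$ profile (amplitude 0.5)
mimicking scanner-sensitivity structure.  This puts late-frame voxel
coefficients of variation at roughly 10–20%, typical of iteratively
reconstructed dynamic FDG voxels.  Real data differ in at least: spatial
noise correlation (~2–3 mm FWHM), motion, attenuation structure, and
anatomical heterogeneity within organs — a green phantom test therefore
validates the estimators' statistical machinery, not clinical accuracy.

## Numerical choices

* Fine evaluation grid: 1 s, cell-centred; frame averages are midpoint-rule
  means over the cells of each frame, used identically in simulation,
  basis construction and fitting (a shared convention matters more than
  the rule itself).
* Delays are applied as index shifts of fine-grid convolutions (shift
  equivariance of convolution), never by shifting frame bins.
* NNLS: Lawson–Hanson active set on the normal equations, gradient
  tolerance $10^{-10}$ (scaled), deterministic; verified against
  exhaustive active-set enumeration on 1000 random problems.
* Residue admissibility: violations beyond $10^{-8}$ (relative) raise;
  smaller ones are clipped by a running-maximum projection.
* Voxels with weighted total signal below 0.1% of the image maximum are
  skipped and flagged (maps show NA, not 0).
* A per-voxel scale estimated from $J \approx 62$ frames carries
  $\approx 1.6/\sqrt{J} \approx 20\%$ sampling noise; tests therefore
  assess the $\psi$ field through binned means and correlations rather
  than voxelwise equality (see the DGP acceptance test).

## Known limitations

* The bootstrap does not regenerate inter-voxel noise correlation; SEs of
  *spatially aggregated* statistics (large-VOI means) will be
  anti-conservative on data with strong reconstruction smoothing.
* Basis selection conditions on the segmentation; uncertainty in the
  segmentation itself is not propagated.
* The NIfTI reader/writer is minimal (single-file NIfTI-1, common dtypes,
  srow affine); it is not a general neuroimaging I/O library.
* 2C fitting is multistart BFGS on a nonconvex surface; with 10 starts the
  fits are reproducible (seeded) but global optimality is not guaranteed,
  particularly for very flat $k_4$ directions.
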