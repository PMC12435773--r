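---
title: "Methods: zoning, mobility, DIM detection and fluctuation analysis"
author: "nucleozone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zoning, mobility, DIM detection and fluctuation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleozone)
```

# Scope

`nucleozone` implements the quantitative analyses used to study the
relocation of damaged chromosomal loci to the nuclear periphery in budding
yeast: the three-zone subnuclear position assay, detection of fluorescent
foci, the spindle pole body (SPB) and damage-induced microtubules (DIMs) in
multi-channel 3D stacks, drift-corrected mean-squared-displacement (MSD)
analysis with radius-of-constraint estimation, and Luria–Delbrück
fluctuation analysis of chromosome-end-loss rates.  Because raw microscopy
for such experiments is rarely redistributable, the package includes a
ground-truthed synthetic-scene generator: every measurement chain can be
exercised end to end against planted truth.

All coordinates are micrometres, with 0-based voxel indices and
pixel-centre calibration (voxel *i* is centred at *i* × pixel size).

# The zoning assay

The nucleus in a cross-section is a disc of radius $R$ fitted to the
Nup49-marked envelope ring.  The disc is divided into three concentric
regions of **equal area**; the boundaries are therefore at
$\sqrt{1/3}\,R \approx 0.577R$ and $\sqrt{2/3}\,R \approx 0.816R$.  Zone 1
is the outermost ring — the nuclear periphery where the nuclear pore
complexes sit — and zone 3 the central disc.  A focus at normalised radius
$\rho = |x - c|/R$ is scored zone 1 if $\rho \ge \sqrt{2/3}$, zone 2 if
$\sqrt{1/3} \le \rho < \sqrt{2/3}$, zone 3 otherwise.  Under the null of a
uniformly positioned locus each zone receives exactly 1/3 of cells, which
is what makes the assay self-calibrating.

Conventions the implementation fixes (the underlying protocol is usually
described informally):

* **Ties assign outward**: $\rho$ exactly on a boundary scores the outer
  zone.  A fixed convention keeps results bit-reproducible.
* **Measurement plane**: the nuclear radius is measured in the focal plane
  of the scored focus (plane of maximal focus intensity), matching the
  established zoning protocol; 3D spherical-shell zoning is deliberately
  not used.
* **Clamping**: segmentation noise can place a focus marginally outside the
  fitted circle; $\rho \le 1.2$ clamps to zone 1, larger values reject the
  cell (logged as a status, never silently dropped into a zone).
* **Mid-stack gate**: only the middle two-thirds of the z stack is scored;
  the excluded sixth at each end is rounded up
  (`ceil(n_planes/6)`), so a 24-plane stack keeps exactly 16 planes.
* **Cell-cycle gate**: mid-to-late S-phase cells are selected by bud
  morphology — bud area between 15% and two-thirds of the mother area
  (inclusive at both ends); unbudded cells are G1, smaller buds early S,
  larger buds "other".

# The synthetic-scene generator

`make_cell()` draws one cell under a `scene_preset()`; `render()` turns it
into a multi-channel stack.  The generator emulates:

* a spherical nucleus (default radius 1.0 µm, typical of haploid yeast)
  whose envelope renders as a spherical shell with a Gaussian radial
  profile (the Nup49 ring);
* a diffraction-limited locus focus placed with a condition-dependent zone
  bias;
* an SPB embedded in the nuclear envelope at a preset mean 3D distance
  from the locus, with monopolar DIM line segments anchored at the SPB at a
  preset prevalence, aimed through the locus with the preset's
  colocalization probability and otherwise into a random inward direction;
* anisotropic Gaussian optics (lateral σ 0.11 µm, axial σ 0.27 µm,
  matching a high-NA oil objective) and Poisson photon noise about a
  constant background, scaled so that peak-signal over background-noise SD
  equals the preset SNR (default 10; `snr = Inf` renders noise-free).

Imaging geometry defaults follow the experimental setup the analyses are
designed for: 0.065 µm lateral pixels, 0.175 µm z-steps, 25 planes.

## Zone planting and the `zone1_weight` mixture

For weight $w \in [0, 1]$ the locus is planted uniformly in the zone-1
annulus of its cross-section with probability $w$ and uniformly in the
nuclear sphere otherwise.  Because the axial coordinate is drawn with the
uniform-in-sphere marginal in both branches, the expected zone-1 occupancy
is exactly $w + (1 - w)/3$ — the mixture arithmetic the recovery tests
verify.  Occupancies **below** the uniform null of 1/3, as observed in
repeat-free control strains (~31%), are unreachable by a nonnegative
mixture; `zone1_weight` therefore also accepts negative values: with
probability $|w|$ the locus is planted uniformly in zones 2–3, giving
occupancy $(1 - |w|)/3$.  The built-in `wt_cag0` preset uses $w = -0.07$
(31%) and `wt_cag130` uses $w = 0.22$ (48%).

## Condition presets

The shipped presets encode the study conditions the pipeline is validated
against: `wt_cag0` and `wt_cag130` (zone-1 occupancies 31% and 48%), `mms`
(DIMs in 62% of S-phase cells after alkylation damage), `mms_hu` (87% of
mid-to-late S cells under fork-collapsing treatment) and `spb_offset`
(mean SPB–locus distance 0.6 µm, SD 0.15 µm).  DIM colocalization
probabilities and the DIM prevalence of untreated strains are not reported
as precise numbers in the experimental literature; the presets fix
plausible values (e.g. 0.7 for the expanded-repeat strain, where most DIMs
colocalize with the locus) and expose them as parameters.

## What the generator does not emulate

No brightfield cell bodies (bud-size gating is exercised on tabulated
areas), no photobleaching, no chromatic aberration, no spatially varying
background, and the envelope shell ignores the axial PSF elongation so
that the in-plane ring radius stays geometrically exact — the quantity the
zoning protocol measures.  Passing recovery tests therefore demonstrate
correctness of the measurement chain under idealised optics, not
robustness to every artefact of real microscopes.

# Detection

* **Periphery**: ring pixels above `median + 3·MAD-SD` of the plane are
  fitted with an algebraic (Kasa) circle fit — first pass unweighted, then
  intensity-weighted with up to five rounds of outlier rejection at 2.5
  robust SDs of the radial residual.  Two bias corrections matter at this
  pixel size: intensity weighting centres the fit on the ring's (symmetric)
  radial profile rather than the asymmetric thresholded annulus, and the
  fitted radius is reduced by $\sigma^2/R$ (the mean radius of an annulus
  with radial spread $\sigma$ exceeds the circle radius because the area
  element grows with $r$).  Residual radius bias is ~0.005 µm (&lt; 0.1
  pixel).
* **Foci**: matched-filter blob detection — Gaussian smoothing at the PSF
  scale, 26-connected local maxima above `median + 8·MAD-SD` of the
  smoothed stack, sub-voxel refinement by background-subtracted intensity
  centroid.  Smoothing suppresses photon noise ~15-fold, so genuine foci at
  SNR 10 sit tens of SDs above this threshold while blank noise stays
  below it.
* **SPB**: the brightest focus in the tubulin channel; exact ties break
  toward the nucleus centre.
* **DIMs**: a DIM is a monopolar linear tubulin structure emanating from
  the SPB.  The detector subtracts the SPB's own PSF blob (amplitude
  estimated as the directional median at a fixed scaled radius, so a DIM
  arm cannot inflate it), then examines above-threshold voxels relative to
  the SPB: the axis is the direction of the farthest voxel refined once by
  the principal axis of the voxels within a 0.35 µm tube; the structure
  must form a gap-free chain (gap tolerance 0.25 µm, spanning the axial
  pitch) starting within `anchor_radius + gap_tol` of the SPB and
  extending at least `min_length` (0.5 µm) after subtracting the
  axis-projected PSF blur from the chain tip; a comparable chain within a
  30° cone on the opposite side is read as a bipolar spindle and vetoes
  the call.  On synthetic scenes at SNR 10 the detector reaches ~99%
  recall at 0–2% false positives, with length error under 20%.
* **Colocalization** follows the strict overlap rule: two above-threshold
  masks colocalize iff they share at least one voxel; edge- or
  corner-adjacent masks ("touching") do not.  The scoring is symmetric and
  monotone under dilation.

The thresholds (`k = 3` SDs for masks, `k = 8` on smoothed stacks for
detection, minimum DIM length 0.5 µm, anchor radius 0.25 µm, 30°
monopolarity cone) operationalise what was originally scored by eye; they
are explicit arguments everywhere, and their defaults are tuned only on
the synthetic renderer — real DIM brightness and thickness distributions
are unknown.

# Locus mobility

Trajectories carry a locus track and a nucleus-centre track at a fixed
frame interval (default 1.5 s, 200 frames ≈ 5 min).  `drift_correct()`
subtracts the nucleus track frame by frame, which removes *any* rigid
nuclear translation exactly — an invariance the tests assert to numerical
precision.  The MSD is time-averaged over all overlapping pairs,
$\mathrm{MSD}(k\Delta t) = \langle |x(t+k\Delta t)-x(t)|^2\rangle_t$, in
the two projected dimensions; pairs spanning gaps are dropped, and lags
averaged over fewer than 10 pairs are excluded from fits.

The plateau is estimated by nonlinear least squares of the saturating
model $P\,(1 - e^{-\Delta t/\tau})$ over the first 100 lags (falling back
to the mean of the last quartile of the window, flagged, if the fit fails)
and converted to the radius of constraint
$$R_c = \sqrt{\tfrac{5}{4}\,P},$$
the standard conversion for 2D-projected tracking: a locus occupying a
sphere of radius $R_c$ uniformly has projected-MSD plateau
$2 \times 2 \times \tfrac{1}{5}R_c^2 = \tfrac{4}{5}R_c^2$.  The saturating
model was chosen over a polynomial because confined diffusion has exactly
this asymptotic shape and the plateau then has a closed-form oracle; a
single 200-frame track is noisy at large lags, so ensemble averaging
across cells (`ensemble_msd()`) is the intended estimator.

The simulator implements confined diffusion as reflecting Brownian steps
(per-axis SD $\sqrt{2D\,dt}$) inside the confinement sphere, started from
the uniform stationary distribution; the default $D = 0.005$ µm²/s is
typical of interphase yeast chromatin (literature range roughly
$10^{-3}$–$10^{-2}$ µm²/s).  Ensembles of 50 such trajectories recover
$R_c \in \{0.3, 0.6, 0.9\}$ µm within 10%; the small negative bias of the
discrete reflection scheme shrinks with step size.

# Fluctuation analysis

Chromosome-end-loss rates are inferred from parallel-culture fluctuation
experiments under the Lea–Coulson formulation of the Luria–Delbrück model:
mutation events per culture are Poisson($m$), each event founds a clone
whose final size $j$ has $q_j = 1/(j(j+1))$, and the observed count is the
clone-size sum.  The count distribution is compound Poisson, so its pmf
follows the Ma–Sandri–Sarkar recursion (a Panjer recursion with kernel
$j\,q_j = 1/(j+1)$):
$$p_0 = e^{-m}, \qquad p_r = \frac{m}{r}\sum_{i=0}^{r-1}
\frac{p_i}{r-i+1}.$$
The implementation was validated against an independent route — direct
compound-Poisson simulation with clone sizes sampled as
$\lfloor 1/U \rfloor$ — by goodness of fit on $10^4$ cultures; the far
tail follows $p_r \sim m/(r(r+1))$ (jackpot cultures), which the
likelihood uses analytically for counts beyond 1000 instead of running
the $O(n^2)$ recursion out to a jackpot.

The MLE maximises the log likelihood by bracketed 1D search in $\log m$
(tolerance $10^{-6}$); the likelihood is unimodal in $m$ on every sample
tested, all-zero counts give the boundary solution $\hat m = 0$, and the
estimator agrees with the $P_0$ method ($\hat m = -\ln f_0$) within 25% on
simulated data at $m = 1$.  95% confidence intervals invert the likelihood
ratio (endpoints where the log likelihood drops by
$\chi^2_1(0.95)/2$); simulated coverage at $m = 1$ with 24 cultures is
~95–96%.  Two experiments are compared by the likelihood-ratio test (one
degree of freedom, separate vs pooled fits), whose type-I error at nominal
0.05 simulates to ~0.05.  Rates per cell divide $\hat m$ by the plated
cell count adjusted for dilution; no mutant-fitness or plating-efficiency
correction is applied (a dilution adjustment and an optional
plating-efficiency multiplier cover the common designs), matching the
defaults of the standard estimator this analysis re-implements.

# Shared statistics

Zone tallies are compared by 2×3 contingency chi-squared without
continuity correction (Yates matters only for 2×2); zones empty in both
conditions are dropped with a matching reduction in degrees of freedom and
a flag, as are expected counts below 5.  Time-course families use explicit
Bonferroni correction, $p_\mathrm{adj} = \min(1, p \cdot m)$ with $m$ the
number of time points.  SPB-distance samples are compared by Welch's
unequal-variance t test.  All three delegate to the standard R
implementations and are verified against hand-computed closed forms to
$10^{-8}$.

# Problem sizes and reproducibility

The validation suite uses the sizes at which the recovery claims are
stated: $10^4$ cells for the geometric zone null plus 400 rendered cells
end to end; 300 rendered cells per condition preset (200 for the
SPB-distance preset); 50 trajectories × 200 frames per confinement
radius; 500 simulations for CI coverage and 1000 for LRT size.  Every
stochastic routine takes an explicit `rng_seed`, and identical seeds
reproduce scenes, stacks, trajectories and counts exactly;
`run_pipeline()` records the seed and package version in its JSON report,
and re-running a config reproduces the report byte for byte.

# Known limitations

* Detection defaults are calibrated on the synthetic renderer; real images
  will need threshold adjustment and possibly deconvolution (out of
  scope).
* DIMs are modelled as single straight segments; curved or branched
  structures would be reported with the length of their dominant straight
  chain.
* Z-oriented DIMs shorter than ~0.5 µm are genuinely confounded with the
  axially elongated SPB blob at this optical anisotropy and are the main
  source of residual misses.
* The MSD module analyses 2D projections with the 5/4 plateau correction;
  no 3D MSD, anomalous-exponent fitting, or directed-motion segmentation
  is provided.
* The fluctuation model assumes equal mutant fitness and complete plating;
  differential fitness would need a different clone-size law.
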