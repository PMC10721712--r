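---
title: "Switching-diffusion segmentation and target-search statistics for single-particle tracking"
author: "TrackStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TrackStates methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrackStates)
```

# The scientific problem

Single-molecule localization microscopy of a nuclear transcription factor
yields tens of thousands of short trajectories per nucleus. A molecule's
motion switches as it binds chromatin, scans locally, and diffuses freely,
so a single diffusion coefficient misdescribes it. TrackStates implements
the statistical pipeline that turns such trajectory tables into
biologically interpretable quantities:

1. segmentation of jumps into discrete Brownian diffusive states with a
   hidden Markov model (HMM), giving per-state diffusion coefficients,
   state proportions, and per-jump labels;
2. a per-trajectory three-decision classification into Brownian,
   sub-diffusive and super-diffusive motion;
3. turning-angle statistics — the resultant vector and the fold-anisotropy
   metric f(180/0) — and its profile against displacement, the signature
   of molecules trapped in zones of a characteristic size;
4. enrichment of trajectories near a marked target locus segmented from a
   marker image;
5. clustering of bound-molecule barycentres by a two-component
   Poisson-process mixture over k-th nearest-neighbour distances, with a
   randomization control relating anisotropy to cluster proximity.

Every stage is paired with a ground-truthed simulator so that the whole
chain is verifiable by parameter recovery.

# The switching-diffusion HMM

Within a trajectory, the displacement between consecutive frames ("jump")
in state $s$ is modelled as isotropic bivariate Gaussian,
$\Delta x, \Delta y \sim N(0,\, 2 D_s \Delta t + 2\sigma_{loc}^2)$,
where $D_s$ is the state's diffusion coefficient and $\sigma_{loc}$ the
per-axis localization error (default 0.020 µm, the typical sub-pixel
precision of Gaussian-fit localization at 110 nm pixels). States follow a
first-order Markov chain over jumps with transition matrix $A$.

`fitHMM()` maximizes the likelihood by Baum–Welch EM, vectorized across
trajectories. The M-step solves $D_s$ in closed form from the posterior-
weighted mean squared jump, subtracts the noise term $2\sigma_{loc}^2$
and floors at zero; setting `sigmaLoc = 0` reproduces the uncorrected
variant. Numerical choices:

* **Initialization/restarts.** Initial $D$ values are spread quantiles of
  the per-jump naive estimates; five restarts are run for 30 iterations
  at a loose tolerance and the best is refined to convergence
  ($\Delta\log L < 10^{-6}$ nats or 500 iterations). This short-run
  strategy (as in mclust) buys restart robustness without quintupling the
  cost.
* **Model selection.** `selectModel()` fits $K = 1..K_{max}$ (ceiling 4)
  and maximizes $\log L - \tfrac{1}{2}(K^2 + K - 1)\log n_{jumps}$, the
  BIC approximation to the marginal-likelihood score used by
  variational-Bayes treatments; at these data sizes the two select
  identically in our recovery experiments.
* **Canonical order.** States are sorted by ascending $D$, so state 1 is
  the slowest ("bound") and state $K$ the fastest ("free").
* **Decoding.** Per-jump labels are posterior maxima (forward–backward);
  each trajectory receives the mode state of its jumps, ties broken
  toward the slower state (conservative for bound-fraction claims).
  Population proportions are computed over whole trajectories from mode
  states: fast molecules leave the detection slab sooner, so per-jump
  proportions over-weight slow states, while whole-trajectory summaries
  largely cancel the bias (the simulator reproduces this: with a 1 µm
  slab the per-jump fast fraction drops by >5 points while the
  mode-state fraction stays much closer to truth).
* **Known bias.** On tracks of ~8 jumps the mode-state fraction of the
  fastest state sits systematically ~1–2 points below the generator
  occupancy — finite windows plus the slower-state tie rule — which is
  well inside the 3-point recovery tolerance used in the tests.

No motion-blur (exposure-averaging) correction is applied; positions are
treated as sampled at frame instants.

# Motion-type classification

`estimateTrajDiffusion()` uses the lag-1 estimator
$\hat D = \max(0, \mathrm{MSD}_1/(4\Delta t) - \sigma_{loc}^2/\Delta t)$.
`threeDecisionTest()` computes the maximum excursion statistic
$T = \max_i \lVert X_i - X_0\rVert / \sqrt{\hat D\, n\, \Delta t}$ and
compares it against Monte-Carlo null quantiles tabulated per track length
from $10^5$ simulated Brownian tracks (all lengths calibrated in one
incremental pass under a fixed internal seed; a fine quantile grid is
cached, so reruns are bit-stable). $T$ below the $\alpha/2$ quantile means
the molecule explored less space than Brownian motion (sub-diffusive),
above $1-\alpha/2$ more (super-diffusive; drift). Inside the statistic,
$\hat D$ deliberately omits the noise subtraction so that data and null
are computed identically.

The test's type-I error is exact by construction (verified within
binomial error). Its power against confinement grows with track length:
wall-to-wall bouncing in a small domain shrinks the excursion and the
jump-variance normalizer together, so very short confined tracks are only
flagged in ~60–80% of cases at radius 0.05 µm, reaching >90% by ~40
frames. Super-diffusive drift is detected essentially always at moderate
drift speeds.

# Turning-angle machinery

The turning angle between successive jump vectors is signed via the 2D
cross product and mapped to $[0, 360)$: 0° is straight continuation,
180° a reversal. `foldAnisotropy()` computes
$f(180/0) = \#\{\theta \in 180 \pm 30\} / \#\{\theta \in 0 \pm 30\}$,
how many-fold more likely a backwards step is than a forwards one; 1
under isotropy. `anisotropyVsDisplacement()` bins angles by the mean of
their two adjacent jump lengths (the mean keeps the angle and its
displacement abscissa co-local) across 50–350 nm in
50 nm bins, restricted to angles whose two defining jumps both carry one
of the two fastest state labels — this keeps the displacements well above
the localization error. Per-bin spread is the SD over 50 bootstrap
subsamples of 50% of the bin's angles drawn with replacement; bins with
fewer than 30 angles are masked.

# The simulator as the verification instrument

`simulateSwitchingDiffusion()` generates the statistical structure the
analysis assumes: Markov state switching per jump, Gaussian increments,
localization noise on observed positions, geometric track lengths (mean
9 localizations = 8 jumps by default; the source imaging reports no
track-length law, so this is a package choice exposed in the config),
and optionally a hidden axial Brownian coordinate confined to a
detection slab (default 1 µm when enabled) that truncates and splits
observed tracks — reproducing defocalization bias without modelling
optics. `stickyTransitionMatrix()` builds
$A = a I + (1-a)\mathbf{1}\pi^\top$, which keeps the configured
occupancy $\pi$ exactly stationary while the effective self-transition
is $a + (1-a)\pi_i \ge a = 0.9$.

`presetConfig()` carries the published four-state conditions: $D$ =
0.006, 0.020, 0.078, 0.512 µm²/s with occupancies 5.7/18.7/27.5/48.1%
("Notch-Off") or with the free state at 32% and the remainder
redistributed proportionally ("Notch-On"), 50 ms frames, 20 nm
localization error.

`simulateTrappedMotion()` adds reflecting trap zones: inside a disc,
increments that would exit are reflected radially; each frame the
molecule escapes with a configured probability. Only molecules whose
state $D$ is below `trapDmax` interact with traps — fast free molecules
cross them unaffected. This matters for the displacement profile: a
single trapped population alone produces anisotropy that *rises*
monotonically with displacement (boundary-to-boundary reversal pairs
dominate the top bins); the published peak at the trap scale emerges
when fast isotropic jumps dominate the large-displacement bins.
`trapPreset()` therefore pairs a slow trappable population
(D = 0.1 µm²/s) with a fast free one (D = 0.512): with 125 nm traps the
profile peaks robustly in the 100–150 nm bin. The dense (40-trap)
preset is used for the profile; the sparse (8-trap) variant for the
cluster-control experiments, where shifted "fake" clusters must be able
to land away from every real trap.

`simulateBoundPattern()` superposes uniform points in cluster discs
(intensity $\lambda_1$) with window-wide clutter ($\lambda_2$), with
ground-truth flags.

What the simulator does **not** emulate: photophysics (blinking,
bleaching), motion blur within exposures, anisotropic or 3D PSFs,
chromatin polymer context, and detection/linking errors (unless the
rendered-movie front end is used). Passing recovery tests therefore
demonstrates correctness of the estimators under the model's
assumptions, not robustness to every artefact of real data.

# Locus enrichment

`detectLocus()` Gaussian-smooths the marker channel, applies Otsu's
threshold and keeps the largest connected component. A trajectory is
"near" if any localization comes within 550 nm of the mask (distance
transform lookup; inside = 0). The enrichment ratio
$(n_{near}/n_{tot}) \cdot (A_{nucleus}/A_{near})$ uses the area of the
550 nm-dilated near region as denominator, so the spatially uniform null
is exactly 1 (membership and area use the same pixel partition); the
nucleus area is the convex hull of the localizations. The any-localization
membership rule is the most sensitive reading of "trajectories localised
within" the threshold and is stated here as the package's rule.

# Cluster analysis of bound molecules

Bound (two slowest states by mode) trajectories are reduced to their
barycentres. For a homogeneous Poisson process of intensity $\lambda$ the
squared k-th nearest-neighbour distance follows
$D_k^2 \sim \Gamma(k, \lambda\pi)$; `fitKnnMixtureEM()` fits the
two-component mixture
$p\, g(d;\lambda_1) + (1-p)\, g(d;\lambda_2)$ by EM with closed-form
M-steps, initialized from the 25th/75th distance percentiles, converged
at $\Delta\log L < 10^{-8}$ (up to 1000 iterations), components ordered
$\lambda_1 > \lambda_2$, and points flagged clustered at posterior > 0.5.
k = 11 is the canonical neighbour order.

Two practical notes, both verified numerically and reflected in the
tests: (i) a forced two-component split of genuinely one-component data
settles near $\lambda_1/\lambda_2 \approx 2$, so the degenerate-fit flag
uses a ratio cutoff of 3 (true clusters live at ratios of 50+); (ii)
points near a cluster-disc edge see a truncated neighbourhood, biasing
$\hat\lambda_1$ downward for sparse discs — fraction and classification
recovery are unaffected, and intensity recovery within 10% holds for
dense discs.

`shiftedClusterControl()` implements the randomization control: all
clustered points are translated by one common random vector (the
translation target is uniform over the ROI bounding box), a translation
is accepted when ≥80% of shifted points stay inside the convex hull of
the diffusive jump starts, and the near-cluster anisotropic proportion is
recomputed; 100 attempted translations are made and both the attempt and
acceptance counts are reported ("repeated 100 times" is read as
attempts). A jump's position is its starting localization — the
localization shared by the two jumps that define the angle.

# Group statistics, density maps, pipeline

`groupStats()` follows the field's convention: Shapiro–Wilk at 0.05 per
sample; both normal → two-sample t (Welch if Bartlett rejects equal
variances), else Mann–Whitney U; paired → paired t or Wilcoxon
signed-rank; stars at 0.05/0.01/0.001. `densityMap()` smooths trajectory
barycentres with a 440 nm Gaussian kernel and reports trajectories per
0.0001 µm². `runPipeline()` chains all stages on one nucleus and writes
delimited tables plus a JSON manifest (config, seed, package version)
sufficient to reproduce every number; there is deliberately no shell
entry point — the functions and this document are the interface.

# Problem sizes and reproducibility

The recovery experiments use 5000 simulated trajectories (≈3500 after
the four-point filter) for the four-state presets, 2000 for the
defocalized mean-jump check, 1000 barycentres for the cluster mixture,
and 2500–3000 trajectories for the isotropy/trap property suites —
sizes at which the quantities of interest have standard errors well
inside their tolerances. All randomness flows through explicit seeds;
simulation, fitting and bootstrap functions restore the caller's RNG
state, and the Monte-Carlo null tables of the motion test are derived
from a fixed internal seed so classifications are bit-stable across
sessions.

# Known limitations

* The HMM assumes memoryless switching per jump and isotropic Gaussian
  jumps; anomalous-diffusion alternatives appear only through the
  three-decision test.
* No aggregated-state or per-state localization-error estimation; no
  gap closing or merge/split handling in the linker (densities where
  that matters need a multiple-hypothesis tracker).
* Confinement power of the excursion statistic is limited on very short
  tracks (see above).
* The locus near/away geometry is pixel-quantized at the marker image's
  resolution; at 110 nm pixels the quantization is ~10% of the 550 nm
  threshold and cancels in the enrichment null by construction.
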