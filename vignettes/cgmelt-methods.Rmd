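---
title: "Models and methods behind cgmelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgmelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmelt)
```

# Scope

cgmelt packages the analysis layer of a coarse-grained study of how a
peptide segment — the motivating case is the central region of
α-synuclein, residues 65–97, binding synaptic-like bilayers — interacts
with a lipid membrane in two conformational states, helical-locked and
extended-disordered.  Three model components carry the science:

1. **Conformational restraints.** Gaussian angle and dihedral potentials
   on consecutive backbone beads that pin the chain into one of the two
   states, with analytic Cartesian forces.
2. **Contact melting analysis.** Per-residue protein–phosphate contact
   indices, their average (the global contact index), its temperature
   dependence across a 310–450 K ladder, a logistic melting-temperature
   fit, and a three-segment convergence diagnostic.
3. **Umbrella-sampling analysis.** Histogramming of biased
   reaction-coordinate samples, the WHAM self-consistency solve, the
   potential of mean force, and the membrane-binding free energy.

Because μs-scale coarse-grained MD and multi-window all-atom umbrella
sampling are far beyond desk scale, the package ships a minimal
overdamped Langevin engine and synthetic-data generators with exact
ground truth, so every estimator can be validated end to end in minutes.

# The restraint model

For three consecutive backbone beads the angle
$\theta_{ijk} = \cos^{-1}(\hat u \cdot \hat v)$ is formed by the arms
$j\!\to\!i$ and $j\!\to\!k$; for four consecutive beads the dihedral
$\varphi_{ijkl}$ is computed with the four-quadrant inverse tangent of
its sine and cosine, giving values in $(-180°, 180°]$ with the polymer
convention (planar *cis* = 0°, planar *trans* = 180°, mirror images of
opposite sign).  The restraining potentials are inverted Gaussians,

$$V_\theta = -K\,e^{-(\theta - \theta_{min})^2/\sigma}, \qquad
  V_\varphi = -K\,e^{-(\varphi - \varphi_{min})^2/\sigma},$$

with the squared deviation divided by $\sigma$ itself, so $\sigma$
carries units of degrees².  We keep this literal form rather than the
more common $2\sigma^2$ convention for fidelity to the printed model.
Angles enter in degrees; the chain-rule factor $180/\pi$ converts the
radian-valued geometric gradients, and the dihedral deviation is wrapped
into $(-180°, 180°]$ before squaring so the potential is periodic with
no cliff at ±180°.  The arccos derivative is guarded by a $10^{-12}$
floor on $1-\cos^2\theta$ at collinear geometry.

Forces are the analytic gradients
$F = -\,dV/d\theta \cdot d\theta/d r$ (and likewise for $\varphi$); the
tests hold them to $<10^{-5}$ relative error against central finite
differences over hundreds of random geometries, and to exact
translation/rotation invariance.

**Parameter defaults.** The published model defers its numeric restraint
parameters to earlier parameterisation work, so the package ships
documented illustrative placeholders — helical $\theta_{min}=96°$,
$\varphi_{min}=-120°$; extended $\theta_{min}=127°$,
$\varphi_{min}=180°$; $K = 10$ kJ/mol and $\sigma = 200$ deg² for both
terms — all overridable through `restraintParams()` or the YAML
`restraints` block.  Whether the published parameterisation used
different $\sigma$ for angle and dihedral terms is unknown; we default
to a single value.

# The toy engine

The engine integrates overdamped (Brownian) dynamics,
$x \leftarrow x + F\,\Delta t/\zeta + \sqrt{2 k_B T \Delta t/\zeta}\,\eta$,
with drag $\zeta = m\gamma$ (bead mass 72 amu, one coarse backbone bead,
times the collision rate `friction` in 1/ps).  In amu–nm–ps units
1 kJ/mol equals 1 amu nm²/ps², so no further conversion is needed
($k_B = 0.0083145$ kJ/mol/K).  The choice of overdamped dynamics is
deliberate: the engine only has to produce Boltzmann-distributed
configurations, not realistic kinetics, so thermostats and barostats of
the original NPT protocol are out of scope.

The membrane is implicit: each bead feels a z-Gaussian well
$U(z) = -\varepsilon\,e^{-(z-z_0)^2/2w^2}$ centred on the phosphate
plane, while a static phosphate lattice at $z_0$ gives the contact
analysis the same data model as an explicit bilayer.  The box is
periodic in xy (entering only through minimum-image distances in the
contact analysis) with reflecting walls in z, which confine the unbound
state without biasing the binding equilibrium.

**Time step.** The Euler–Maruyama stationary variance of a harmonic mode
of stiffness $k$ is inflated by $\left(1-k\Delta t/2\zeta\right)^{-1}$.
With the default $\Delta t = 0.002$ ps, $\gamma = 1$/ps and the stiffest
default mode (bonds, $k = 2000$ kJ/mol/nm²) the inflation is below 3%,
and the single-bead calibration tests (variance of a $k=1000$ tether,
Kolmogorov–Smirnov distance to $e^{-U/k_BT}$ at $10^5$ samples) pass
comfortably.  Larger steps trade accuracy for speed visibly; the 0.01 ps
step inflates the tether variance by ~7%.

# Contact indices and melting curves

A residue is in contact when the minimum distance between its backbone
bead and any phosphate bead is below 1 nm (minimum image in xy, plain
distance in z, both leaflets included when present).  The contact index
is the fraction of frames in contact, averaged over the whole
trajectory by default (`burnIn` is available but 0, matching the
analysis of full trajectories); the global contact index is the
unweighted mean over residues, computed per residue first — for equal
frame counts the order of averaging is immaterial.  Backbone beads stand
in for Cα atoms, which is the natural reading in a model where one
backbone bead per residue sits at the Cα-dominated centroid.

The melting curve is the global contact index versus ladder temperature
(310–450 K in 10 K steps, 15 runs).  Since the original analysis reports
melting temperatures without stating the estimator, the package fits the
four-parameter logistic

$$c(T) = c_{low} + \frac{c_{high} - c_{low}}{1 + e^{(T - T_m)/w}}$$

by Levenberg–Marquardt (`minpack.lm::nlsLM`) and takes $T_m$ as the
inflection point, reporting the width, plateaus, RMS residual and the
standard error of $T_m$; curves spanning less than 0.2 in global index
are flagged low-confidence.  On clean logistic curves the fit recovers
midpoints to better than 0.1 K; under Gaussian noise of σ = 0.03 the
bias stays below 2 K across the ladder (both are asserted in the test
suite).  Convergence is assessed the way the study did: the trajectory
is cut into three consecutive equal segments (remainder frames dropped
from the end) and the maximum absolute per-residue deviation between
segment profiles is reported.

# Umbrella sampling and WHAM

Windows are harmonic, $w_i(\xi) = \tfrac12 k(\xi - \xi_i)^2$ with
$k = 1000$ kJ/mol/nm² on the protein–bilayer COM distance (we read the
printed "1,000 kJ/mol" force constant as kJ/mol/nm², the only
dimensionally consistent unit for a distance restraint).  Histograms
share a grid with default 0.02 nm bins, which resolves the ≈0.05 nm
thermal width of a $k=1000$ window at 300 K with more than two bins per
standard deviation.  The WHAM pair

$$p_b = \frac{\sum_i n_{ib}}{\sum_i N_i e^{(F_i - w_i(b))/k_BT}},\qquad
  F_i = -k_BT \ln \sum_b p_b\, e^{-w_i(b)/k_BT}$$

is iterated until the largest window shift changes by less than
$10^{-7} k_BT$, with log-sum-exp evaluation of the $F_i$ update for
numeric safety; empty bins stay undefined and are never interpolated,
adjacent-window overlaps below 5% raise a warning and fully disjoint
histogram support is an error naming the gap.  The PMF is
$G(\xi) = -k_BT\ln p(\xi)$, zeroed on a detached plateau — by default
the last 0.2 nm of the sampled path, the study's pull path ending
detached; the binding free energy is the plateau mean minus the bound
minimum, reported as a positive favourable depth in kcal/mol (4.184
kJ/kcal).  Minimum-to-plateau is the default convention; an integrated
bound-basin estimate was considered and rejected as the default because
the original work gives no basin bounds.  No Jacobian/entropic
correction is applied to the 1-D distance coordinate, mirroring the
standard g_wham behaviour; this is a known limitation.  Optional
bootstrap resampling (`bootstrapBindingFreeEnergy()`) attaches an
uncertainty the original analysis did not report.

# Synthetic ground truth

Each generator is a pure function of its seed and embeds its ground
truth in the object's provenance, so tests never re-derive it.

* `genMarkovBindingTrajectory()` — per-residue two-state Markov chains
  toggling between a bound height (0.5 nm above the phosphate plane,
  inside the 1 nm shell) and an unbound height (3 nm), initialised from
  the stationary law.  The default per-frame switching probability of
  0.5 keeps the autocorrelation time near two frames, so $10^4$ frames
  determine an occupancy to about ±0.01.
* `genMeltingEnsemble()` — occupancies following the logistic
  $1/(1+e^{(T-T_m)/w})$ across the 15-point ladder; defaults $T_m=372$ K
  and $w = 15$ K place the midpoint where the extended-state curve of
  the motivating study sits, with the transition comfortably inside the
  ladder.
* `genUmbrellaSamples()` — exact inverse-CDF draws from
  $e^{-(U+w_i)/k_BT}$ on a $10^{-4}$ nm grid.  Inverse-CDF rather than
  Metropolis sampling removes autocorrelation from the oracle, making
  WHAM recovery error purely statistical.
* `genBilayerPatch()` — 167 lipids per leaflet, DOPE:DOPS:DOPC
  84:50:33 (the 5:3:2 synaptic-vesicle mimic), phosphate beads exactly
  on the two leaflet planes with seeded xy jitter; lipid identity is a
  label only, since the contact analysis treats all phosphates
  identically.
* `genPeptideChain()` — 33 beads (residues 65–97) built by internal-
  coordinate (NeRF) placement with every angle and dihedral at the
  restraint minimum, so the chain is the exact global minimizer of the
  chain restraint energy; the centre of mass starts 4.0 nm above the
  phosphate plane, the study's initial geometry.

What the generators deliberately do not emulate: lipid diffusion and
packing, nonbonded coarse-grained energetics, realistic binding
kinetics, sequence-specific residue affinities.  Passing tests therefore
demonstrate estimator correctness on data of known structure — not that
the toy engine reproduces membrane biophysics.

# Designed end-to-end experiment

The strongest integration check couples the engine to the full
contacts → melting analysis.  Four unbonded beads (`bondK = 0`) in a
$4\times4\times28$ nm box feel a 14 kJ/mol, 0.3 nm membrane well at
$z_0 = 2$ nm; for independent beads the exact occupancy at any
temperature is a one-dimensional Boltzmann quadrature over the box,
combined with the geometric fraction of the xy lattice cell inside the
1 nm contact shell (`analyticContactOccupancy()`).  Two design rules
make the experiment statistically well-posed.  First, the ladder for
this system spans 260–560 K in 20 K steps: a single-bead well shallow
enough to bind and unbind hundreds of times at desk scale necessarily
melts over a broad temperature range, and a four-parameter logistic
fitted to a curve whose plateaus lie outside the sampled window is
unidentifiable — its midpoint wanders tens of kelvin under percent-level
noise.  Sampling both plateaus restores identifiability.  (Deeper wells
would sharpen the transition but require exponentially larger unbound
volumes and exponentially slower escape, which is exactly why the
original study needed microsecond simulations.)  Second, the predicted
melting temperature applies the *same* logistic estimator to the exact
occupancy curve (`analyticMeltingTemperature(method = "fit")`), so
simulation and prediction are compared estimator-to-estimator and the
comparison probes the engine and the contact pipeline rather than the
estimator's extrapolation behaviour.  The friction is lowered to
0.05/ps so binding and unbinding recur hundreds of times per
trajectory; equilibrium statistics are unaffected by the drag.  With
$4\times10^7$ steps per temperature the fitted midpoint lands within a
few kelvin of the prediction across seeds (tolerance 10 K); this stage
dominates the validation runtime (a few minutes).

# Degenerate inputs and tie-breaks

Coincident beads in an angle, or collinear central bonds in a dihedral,
raise degenerate-geometry errors naming the offending beads rather than
returning NaN.  Duplicate ladder temperatures are rejected as an
ambiguous ladder.  Histogram bins are right-open; samples falling
outside an explicit histogram range are dropped and counted.  Segment
splitting drops remainder frames from the end, never the start.  Window
free energies are reported relative to the first window.

# Known limitations

* The restraint parameter defaults are placeholders, not the published
  calibration; quantitative conformational equilibria depend on them.
* The implicit membrane has no lateral structure; per-residue contact
  profiles of engine trajectories are flat by construction, so
  sequence-resolved statements require real trajectories read through
  `readTrajectoryXYZ()`/`readGRO()`.
* WHAM assumes uncorrelated samples within windows; for correlated MD
  input the bootstrap uncertainty is optimistic unless samples are
  thinned first.
* The 1-D COM-distance PMF carries no volume-entropy correction.
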