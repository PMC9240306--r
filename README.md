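# cgmelt

Analysis toolkit for coarse-grained simulations of peptide–membrane
binding, built for the study design in which a short peptide segment —
the motivating system is the central region of α-synuclein (residues
65–97) against a synaptic-like DOPE:DOPS:DOPC bilayer — is simulated in
two conformational states, **helical-locked** and
**extended-disordered**, across a temperature ladder, and its membrane
affinity is read off a *melting curve* of contacts and an
umbrella-sampling free-energy profile.

It is aimed at structural/computational biophysicists who have (or want
to emulate) such trajectories and need the analysis layer as tested,
reusable code rather than one-off scripts.

## What it computes

**Conformational restraints.** Backbone angles
θ<sub>ijk</sub> = cos⁻¹(û·v̂) over consecutive bead triplets and
four-quadrant dihedrals φ<sub>ijkl</sub> = atan2(sin φ, cos φ) over
quadruplets, restrained by inverted Gaussians

&nbsp;&nbsp;&nbsp;&nbsp;V<sub>θ</sub> = −K·exp(−(θ−θ<sub>min</sub>)²/σ),&nbsp;&nbsp;
V<sub>φ</sub> = −K·exp(−(φ−φ<sub>min</sub>)²/σ)

(σ in degrees²), with analytic forces validated against finite
differences to <10⁻⁵ relative error.

**Contact melting curves.** A residue contacts the membrane when the
minimum distance between its backbone bead and any lipid phosphate bead
is under 1 nm; the contact index is the contact fraction over frames,
the global contact index its mean over residues, and the melting curve
its temperature dependence over the 310–450 K ladder.  The melting
temperature T<sub>m</sub> is the inflection point of a four-parameter
logistic c(T) = c<sub>low</sub> + (c<sub>high</sub>−c<sub>low</sub>)/(1+e^{(T−T_m)/w})
fitted by Levenberg–Marquardt.  A three-segment convergence diagnostic
reports the largest per-residue deviation between trajectory thirds.

**Umbrella sampling / WHAM.** Harmonic windows
w<sub>i</sub>(ξ) = ½k(ξ−ξ<sub>i</sub>)² (k = 1000 kJ/mol/nm²) on the
protein–bilayer COM distance are combined by the weighted histogram
analysis method into the unbiased distribution p(ξ); the potential of
mean force G(ξ) = −k<sub>B</sub>T ln p(ξ) is zeroed on the detached
plateau and the binding free energy ΔG (plateau mean minus bound
minimum, kcal/mol) is extracted, with optional bootstrap errors and
window-overlap diagnostics.

**Toy engine and ground-truth generators.** An overdamped Langevin
integrator (Rcpp) for a restrained bead chain over an implicit membrane
well, plus generators for two-state Markov contact trajectories, melting
ensembles with a prescribed midpoint, exact biased Boltzmann samples
from analytic PMFs, toy bilayer patches (167 lipids per leaflet,
DOPE:DOPS:DOPC 84:50:33) and ideal-geometry peptide chains — every
stage of the pipeline is testable against known truth without any
external MD engine.

## Worked example

Generate a melting ensemble whose true midpoint is 372 K, run the full
contact analysis, and fit the melting temperature:

```r
library(cgmelt)

ens   <- genMeltingEnsemble(Tm = 372, width = 15, nFrames = 20000, seed = 8)
profs <- lapply(ens, contactProfile)          # per-residue contact indices
curve <- fitMeltingTemperature(meltingCurve(profs))
curve
#> MeltingCurve: 15 temperatures, 310-450 K
#>   fitted Tm = 372.0 K (width 15.0 K)
```

The fitted midpoint lands within a fraction of a kelvin of the designed
372 K; `meltingFit(curve)` also returns the plateau levels, the RMS
residual and the standard error of T<sub>m</sub>.

Umbrella sampling against a known well of depth 7.5 kcal/mol:

```r
u    <- analyticPMF("morse_like", depth = 7.5, location = 1, width = 0.2,
                    domain = c(0.7, 2.4))
wins <- genUmbrellaSamples(u, nPerWindow = 20000, seed = 7)  # 11 windows, 1.2 nm
pmf  <- whamPMF(wins, temperature = 300, plateauWindow = c(2, 2.2))
bindingFreeEnergy(pmf, boundWindow = c(0.8, 1.4), plateauWindow = c(2, 2.2))
#> [1] 7.402414
```

The recovered ΔG of 7.40 kcal/mol sits within the statistical tolerance
of the designed 7.5; repeating with `depth = 11` recovers 10.85, so the
helical/extended free-energy difference ΔΔG ≈ 3.45 kcal/mol is also
preserved through the full histogram + WHAM chain.

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/cgmelt`:

```sh
cgmelt generate --scenario scenario.yaml --out-dir ens/
cgmelt contacts --traj ens/traj_T310.xyz --out T310
cgmelt melt     --traj-dir ens/ --out melt
cgmelt wham     --manifest umbrella/manifest.yaml --temp 300 --out pmf
cgmelt report   --melt melt_melt.json --pmf pmf_wham.json --out summary
```

All runs log to stderr, write results to TSV/JSON with provenance
headers (package version, config hash, seed), and are byte-reproducible
for a fixed config and seed.

## Trajectory file dialect

Multi-frame XYZ with a structured comment line; grammar:

```
file     := provenance* frame+
provenance := "#" text NL
frame    := natoms NL comment NL bead{natoms}
comment  := "frame=" int " temperature=" num " time=" num " box=" num "," num "," num
bead     := name SP resid SP x SP y SP z NL     ; coordinates in nm
name     := "BB" | "PO4"                        ; peptide bead / phosphate
```

Umbrella series are two-column text (time, ξ in nm) tolerating
XVG-style `#`/`@` comments; single frames use standard GRO.

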