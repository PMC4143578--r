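---
title: "Methods: THz-timescale protein and hydration-shell dynamics"
author: "thzdyn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: THz-timescale protein and hydration-shell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzdyn)
```

# Scope and units

`thzdyn` analyses picosecond protein and hydration-water dynamics from
molecular-dynamics trajectories in the far-infrared (THz) band, roughly
10–250 cm⁻¹.  It covers five connected analyses: velocity autocorrelation
spectra (a vibrational density of states proxy), hydrogen-bond occupancy
autocorrelation and exponential lifetimes, residue cross-correlation
matrices and their thresholded networks, essential-dynamics PCA of Cα
motion, and transmittance-to-absorbance conversion for experimental
spectra.  Running the MD engine itself is out of scope: trajectories are
opaque inputs (multi-model PDB or GRO series), and a synthetic generator
with analytic ground truth stands in for MD output during testing.

Units are fixed package-wide: Ångström, picoseconds, and cm⁻¹.  Readers
convert on ingestion (GRO nanometres are multiplied by 10).  Frame
spacing `dt` must always be supplied explicitly for formats that do not
encode time, because a silently defaulted `dt` corrupts every downstream
frequency axis; the wavenumber conversion uses the exact constant
1 ps⁻¹ = 1/(2.99792458×10⁻²) cm⁻¹ ≈ 33.3564 cm⁻¹.

# Autocorrelation conventions

All correlation functions are time-origin averages.  The estimator at
lag $k$ divides by the number of valid origins ($n-k$, the "unbiased"
form) rather than by $n$.  This choice is forced by the identities the
package guarantees: a constant series and a fixed inter-atom vector must
give $C(\tau)\equiv 1$ exactly, and the velocity autocorrelation of a
noiseless harmonic mode must equal $\cos(\omega\tau)$ to about 10⁻³ even
at lag fractions where the divide-by-$n$ taper alone is several percent.
The biased form remains available (`estimator = "biased"`); it trades
the taper for lower lag-to-lag variance.  Non-negativity of the power
spectrum does not depend on this choice here, because the spectrum is
defined as the squared magnitude of the transform.

The velocity autocorrelation (VACF) accumulates the 3-component
dot-product correlation per atom, normalizes by that atom's
$\langle|v|^2\rangle$, and averages the normalized curves over the
selection.  Atoms with zero velocity variance are excluded with a
warning rather than propagating NaN.  Mean removal is applied to generic
series before correlating (drift protection) but never to velocities,
whose mean is physically ~0.  The rotational autocorrelation of an
inter-atom unit vector supports Legendre orders 1 (default) and 2; the
order is a flag because published rotational correlation figures often
omit it, and the two orders differ only by the polynomial applied to the
dot product.

# Spectra

`spectrum_from_acf()` transforms the one-sided correlation function with
a real-input FFT after an optional Hann taper (cosine falling to zero at
the last lag) and zero padding.  Defaults: power spectrum (squared
magnitude), Hann window, 4× padding.  Published low-frequency spectra
rarely state whether they are amplitude or power, windowed or raw, so
both are supported and every `Spectrum` records its window, padding, bin
width and total power in metadata.  Peak positions are local maxima
filtered by prominence (height above the higher flanking valley,
expressed as a fraction of the band maximum) and refined by three-point
parabolic interpolation, with ties broken toward lower wavenumber.  With
the default conventions, a planted mode is recovered well within one bin
width of the padded grid.

A peak's temperature trend is classified by regressing position on
temperature: a fitted red-shift exceeding the tolerance (default
2 cm⁻¹ across the measured range) marks the motion as anharmonic-like,
the signature used to separate vibrational modes from fluctuations that
soften above the protein glass transition near 200 K.

# Hydrogen bonds

A bond D–H⋯A is counted when three strict inequalities hold
simultaneously: donor–acceptor heavy-atom distance < 3.5 Å,
hydrogen–acceptor distance < 2.6 Å, and the angle at the donor between
the D→H and D→A directions < 30°.  Two interpretation points were
genuinely open and are resolved as follows, with the alternatives kept
as options:

* the "heavy-atom" distance is measured between the donor and acceptor
  N/O atoms, not molecular centres of mass — a molecular COM is
  ill-defined for protein partners; a water–water COM mode is available
  (`heavy_mode = "water-com"`);
* the angular criterion is the acceptance-cone angle at the donor, which
  matches the 30° magnitude; the angle-at-hydrogen variant is available
  (`angle_at = "hydrogen"`).

Donors are N/O atoms with a hydrogen within 1.2 Å in the reference
frame (bond topology is assumed constant, as under constrained-bond MD);
acceptors are all N/O.  Bonds are classed protein–protein,
protein–water, or water–water by partner category, and the three classes
partition the unfiltered detections.  Interfacial water–water analyses
restrict both partners to the hydration shell, re-evaluated per frame;
the shell contains the water molecules whose oxygen lies within the
cutoff (3.8 Å for the first layer, 8.0 Å for a two-layer shell) of any
protein atom.  Membership is per molecule via the oxygen because shell
sizes are conventionally counted in water molecules; an any-atom mode
exists.  Minimum-image distances are used only when the trajectory
carries a box.

The occupancy autocorrelation uses the intermittent definition
$C(\tau)=\langle hb(t+\tau)\,hb(t)\rangle/\langle hb^2\rangle$: a broken
bond that reforms contributes again, which is the literal reading of the
correlation as printed with raw 0/1 states.  Each bond's curve is
normalized by its own occupancy before averaging over bonds (a pooled
variant is available, since the averaging convention is rarely stated).
A continuous variant treats the first rupture as absorbing, for
"survival"-style lifetimes.  Lifetimes come from a Levenberg–Marquardt
fit of $C(\tau)=c_\infty+(1-c_\infty)e^{-\tau/\tau_{hb}}$; the free
plateau absorbs the stationary occupancy that an intermittent two-state
correlation relaxes to, and can be pinned (e.g. to 0).  The default fit
window is 0.5–8 ps; analyses targeting slower kinetics scale the window
with the expected decay (the tests use 0.5–4τ).  An ACF with no decay
over the window is refused rather than fitted.

# Collective motion

Rigid-body motion is removed before correlation and PCA by default: each
frame is least-squares fitted (Kabsch/SVD, proper rotation enforced)
onto the mean structure, iterated once.  Without this, global rotation
dominates the apparent residue–residue correlation; because the
alternative is defensible when trajectories are pre-aligned, the flag
`superpose_first = FALSE` preserves it.

The cross-correlation matrix is
$C_{ij}=\langle\Delta r_i\cdot\Delta r_j\rangle/
(\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle)^{1/2}$ with
full 3-vector dot products in the numerator (not per-component
correlations averaged).  $C_{ij}=1$, $-1$ and $0$ mark completely
correlated, anti-correlated and uncorrelated motion.  Zero-variance
residues get zeroed correlations (diagonal kept at 1) with a warning —
NaNs would poison network construction downstream.

The network view keeps an edge where $|C_{ij}|$ reaches the threshold,
with the sign stored as an edge attribute and node sizes given by the
mean square fluctuation $\langle|\Delta r_i|^2\rangle$.  Two thresholds
are in common use for this analysis — 0.35 for a strict network and 0.25
for a permissive one — so both are first-class; neither is privileged,
and edges at 0.35 are always a subset of edges at 0.25.

PCA diagonalizes the $3N\times 3N$ covariance of superposed Cα
coordinates, unweighted (mass weighting is an option; Cα atoms are
near-identical in mass, and the analysis targets Cα geometry).  Square
fluctuations of mode $k$ are per-residue sums of squared mode components
scaled by the eigenvalue, so they sum to the mode variance and, over all
modes, to the per-residue variance (trace identity).  Projection
variance equals the eigenvalue by construction; both identities are
verified to 10⁻⁶ relative in the tests.

# The synthetic generators

Each generator produces data whose analysis result is known in closed
form, so every stage is testable without MD output:

* **Harmonic trajectories** — sums of cosine modes (reproducible
  per-atom phases) plus optional positional white noise; stored
  velocities are the analytic derivatives of the modes and exclude the
  noise, so a noise-free single mode has VACF exactly $\cos(\omega\tau)$.
  Mode wavenumbers must respect the Nyquist limit $1/(2\,dt)$.
* **Langevin (Ornstein–Uhlenbeck) baths** — exact-discretization OU
  velocities with stationary variance $\sigma^2/(2\theta)$ and VACF
  $e^{-\theta\tau}$, a broadband stand-in for solvent-coupled
  relaxation.
* **Two-state Markov hydrogen bonds** — per-step switching
  probabilities $1-e^{-k\,dt}$, initial states from stationarity
  $p=k_{on}/(k_{on}+k_{off})$; the intermittent ACF is the closed form
  $p+(1-p)e^{-(k_{on}+k_{off})\tau}$, so the fitted lifetime has the
  analytic truth $1/(k_{on}+k_{off})$.  Two-state kinetics is the
  simplest process with a closed-form intermittent ACF; published
  lifetime values rarely state their kinetic model, and when only a
  target lifetime is specified the package's convention is symmetric
  rates $k_{on}=k_{off}$.  Dwell times are simulated run-length-wise
  (geometric), which is exactly equivalent to the frame-by-frame chain.
* **Correlated Gaussian fields** — white noise coloured by the
  symmetric square root of a prescribed PSD correlation matrix, the same
  factor for x/y/z, so the sampled $C_{ij}$ converges to the target and
  equals it exactly for ±1 entries.
* **Toy hydrogen-bond geometries** — donor/hydrogen/acceptor placed at
  exact distances and angles, with the bond truth evaluated from the
  layout parameters, never from the detector.

All generators take explicit seeds (never global state), are
bit-reproducible, and restore the caller's RNG stream.

What the generators deliberately do **not** emulate: realistic water
structure or force-field energetics, anharmonic mode coupling,
non-exponential (stretched or multi-scale) hydrogen-bond kinetics, and
the actual geometry of a solvated protein.  Passing tests therefore
demonstrate that the analysis chain is correct and well-calibrated on
processes with known answers — not that any particular simulated protein
reproduces experimental THz spectra.  In particular, the two interfacial
water–water lifetimes that motivate the kinetics chain (2.9 ps for a
first-shell hydration and 2.6 ps for a two-layer shell) originate from
10 ns solvated-protein simulations; regenerating them requires an
external MD engine run, which this package scopes out.  The kinetics
chain is instead validated end-to-end on two-state ensembles whose
analytic lifetimes are set to those values, recovering them within the
stochastic tolerance.

# Numerical choices and problem sizes

* Autocovariance is computed via FFT with zero padding to the next power
  of two, identical to the double-loop definition to 10⁻¹⁰ (tested
  against a brute-force oracle up to length 512).
* Strict inequalities are used at all three hydrogen-bond thresholds;
  test grids straddle the boundaries by ≥0.05 Å / 0.1° so constructor
  and detector cannot disagree through floating-point ties.
* Parabolic peak refinement is clamped to ±half a bin; flat spectra
  yield an empty peak set, and an empty search band is an error.
* Transmittance above 100 % (possible in noisy measurements) produces a
  negative absorbance and a warning, never clamping — the round trip
  stays exact.  Non-positive transmittance is an error.
* Degenerate inputs fail loudly: empty atom selections, missing `dt`,
  frame-count mismatches (naming the frame), coincident atoms in the
  rotational ACF (naming the frame), non-PSD correlation targets
  (naming the most negative eigenvalue), and no-decay ACFs.
* Default test and acceptance problem sizes: 4096-frame harmonic
  trajectories (dt = 0.05 ps) for spectral recovery; 100-bond ×
  10⁵-frame Markov timelines (dt = 0.01 ps), 10 replicates per rate, for
  lifetime recovery; 100 random ≤300-atom frames for the detector
  oracle; 2×10⁴-frame fields for network recovery; 5×10³–10⁴-frame,
  10-residue systems for PCA.  These sizes put sampling error well
  inside each stated tolerance while keeping the whole suite quick on a
  laptop.

# Workflows

`run_protein_modes()`, `run_hydration_kinetics()` and `run_collective()`
chain the stages into the two study workflows (protein-mode spectra;
hydration-shell hydrogen-bond kinetics) plus the collective-motion
analysis.  Reports echo every parameter with units in the key names
(`shell_cutoff_angstrom`, `max_lag_ps`, …), record the package version,
and can write TSV tables, GraphML networks and a JSON summary to an
output directory; reruns with the same inputs are bit-identical.  YAML
configs are validated against a known-key list so typos never fall back
to defaults silently.

# Known limitations

* PDB parsing is delegated to `bio3d` and inherits its fixed-format
  assumptions; the GRO reader handles orthorhombic boxes only.
* Donor/hydrogen topology is taken from the reference frame; trajectories
  with reactive or exchanging hydrogens would need per-frame assignment.
* The lifetime model is single-exponential with a plateau.  Stretched or
  multi-exponential decays will fit poorly (watch `residual_rms`).
* Dipole autocorrelation / IR intensities and quantum corrections are
  intentionally absent, as are baseline correction of experimental
  spectra, community detection on networks, and molecular graphics.
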