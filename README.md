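# thzdyn

Analysis of picosecond protein and hydration-shell dynamics from
molecular-dynamics trajectories in the far-infrared (THz, ~10–250 cm⁻¹)
band, for structural-bioinformatics and biophysics users who have MD
output (multi-model PDB or GRO series) and want the standard
trajectory-side counterparts of THz spectroscopy:

* **Vibrational spectra** from the velocity autocorrelation function
  (VACF), `C_v(τ) = ⟨v_i(t+τ)·v_i(t)⟩ / ⟨|v_i|²⟩`, Fourier-transformed
  onto a wavenumber axis (1 ps⁻¹ = 33.3564 cm⁻¹), with peak detection
  and classification of peak temperature trends as harmonic-like
  (temperature-insensitive) or anharmonic-like (red-shifting).
* **Hydrogen-bond kinetics**: geometric bond detection (donor–acceptor
  < 3.5 Å, H⋯acceptor < 2.6 Å, donor angle < 30°), per-class occupancy
  timelines (protein–protein, protein–water, interfacial water–water
  within a hydration shell such as 3.8 Å or 8.0 Å), the intermittent
  occupancy autocorrelation `C_hb(τ) = ⟨hb_i(t+τ)·hb_i(t)⟩ / ⟨hb_i²⟩`,
  and exponential lifetime fits `C(τ) = c∞ + (1−c∞) e^(−τ/τ_hb)`.
* **Collective motion**: residue cross-correlation
  `C_ij = ⟨Δr_i·Δr_j⟩ / (⟨|Δr_i|²⟩⟨|Δr_j|²⟩)^{1/2}` after rigid-body
  superposition, thresholded correlation networks (0.35 strict / 0.25
  permissive), and essential-dynamics PCA of Cα motion with per-residue
  square fluctuations.
* **Absorbance conversion** for experimental spectra:
  `A = −log₁₀(%T/100)` with `%T = 100·I/I₀`.

A synthetic-trajectory generator (harmonic modes, Ornstein–Uhlenbeck
baths, two-state Markov hydrogen bonds, Gaussian fields with planted
cross-correlations, exact toy bond geometries) provides analytic ground
truth, so the whole pipeline is testable without running an MD engine.
See `vignettes/thzdyn-methods.Rmd` for the conventions and their
rationale.

## Worked example

Recover planted vibrational modes and a hydrogen-bond lifetime:

```r
library(thzdyn)

## two modes at 40 and 90 cm^-1 with a small positional noise floor
spec <- harmonic_spec(data.frame(wavenumber = c(40, 90), amplitude = c(1, 1)),
                      noise_sigma = 0.02, dt = 0.05, n_frames = 4096,
                      n_atoms = 4, seed = 1)
traj <- make_harmonic_trajectory(spec)
sp <- spectrum_from_acf(vacf(traj, max_lag = 25))
sp
#> spectrum (power): 0..333.6 cm^-1, bin width 0.3329 cm^-1 (window: hann, pad x4)
find_spectrum_peaks(sp, min_prominence = 0.02, band = c(10, 250))
#>   position     height prominence
#> 1 39.96747   446.5312   446.2221
#> 2 90.00310 10843.7934 10843.4793
```

Both planted wavenumbers are recovered within a tenth of the 0.33 cm⁻¹
bin; the 90 cm⁻¹ peak is ~24× taller because the VACF weights each mode
by amplitude²·ω² and the spectrum is a power spectrum.

```r
## two-state hydrogen-bond ensemble with analytic lifetime 2.9 ps
ms <- markov_hbond_spec(k_on = 1/5.8, k_off = 1/5.8, dt = 0.01,
                        n_frames = 1e5, n_bonds = 100, seed = 1)
tl <- make_markov_hbond_timeline(ms)
fit_hbond_lifetime(hbacf(tl, max_lag = 15), fit_window = c(0.5, 11.6))
#> H-bond lifetime fit: tau = 2.963 ps, plateau = 0.4921 (window 0.5-11.6 ps, residual rms 0.000773)

absorbance_from_transmittance(I = 25, I0 = 50)$absorbance
#> [1] 0.30103
```

The fitted lifetime (2.963 ps) recovers the analytic truth
1/(k_on+k_off) = 2.9 ps within ~2 %, and the fitted plateau matches the
stationary occupancy k_on/(k_on+k_off) = 0.5 of the intermittent
correlation.

For real trajectories the same chain starts from
`read_trajectory("traj.pdb", dt = ...)` followed by
`run_protein_modes()`, `run_hydration_kinetics()` (shell cutoff 3.8 Å by
default) or `run_collective()`, each of which writes TSV/GraphML tables
and a JSON run report when given `out_dir`.

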