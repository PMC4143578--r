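Package: thzdyn
Title: THz-Timescale Protein and Hydration-Shell Dynamics from Molecular
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of picosecond protein and hydration-shell dynamics
    from molecular dynamics trajectories in the far-infrared (THz) band.
    Computes velocity and hydrogen-bond autocorrelation functions and their
    wavenumber spectra, detects hydrogen bonds by a geometric criterion and
    fits exponential bond lifetimes, builds residue cross-correlation
    matrices and thresholded correlation networks, performs essential
    dynamics PCA of C-alpha motion, and converts transmittance to
    absorbance spectra.  A synthetic-trajectory generator with analytic
    ground truth (harmonic modes, Ornstein-Uhlenbeck baths, two-state
    Markov hydrogen-bond kinetics, Gaussian fields with prescribed
    cross-correlation) makes every stage testable without running a
    molecular dynamics engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
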