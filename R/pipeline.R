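# Workflow orchestration: the two analysis chains (protein-mode spectra;
# hydration-shell H-bond kinetics) plus the collective-motion chain, each
# returning a run report that echoes every parameter (no silent defaults -
# unit bugs are this domain's classic failure, so keys carry units) and
# can be written to disk as TSV tables plus a JSON report.

#' Load a pipeline configuration from a YAML key/value file
#'
#' Keys carry units in their names (e.g. \code{shell_cutoff_angstrom},
#' \code{max_lag_ps}); values are scalars.  Unknown keys are an error so
#' typos never silently fall back to defaults.
#'
#' @param path YAML file path.
#' @param known character vector of accepted keys.
#' @return named list.
#' @export
read_pipeline_config <- function(path, known = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(known)) {
    bad <- setdiff(names(cfg), known)
    if (length(bad) > 0) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
  }
  cfg
}

.report_skeleton <- function(stage, params) {
  list(stage = stage,
       package_version = as.character(utils::packageVersion("thzdyn")),
       parameters = params,
       outputs = list())
}

.write_report_json <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, paste0(report$stage, "_report.json"))
  slim <- report
  slim$vacf <- slim$hbacf <- slim$spectrum <- slim$pca <-
    slim$dccm <- slim$network <- slim$timeline <- NULL
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Protein-mode spectrum workflow
#'
#' Velocity autocorrelation of the configured selection (backbone by
#' default), its wavenumber spectrum, and a peak table; with a list of
#' per-temperature trajectories, peak positions are additionally
#' classified as harmonic- or anharmonic-like.
#'
#' @param traj a \code{\link{trajectory}} (velocities stored or
#'   derivable), or a named list of trajectories keyed by temperature in
#'   K for the trend analysis.
#' @param selection selection query passed to \code{\link{select_atoms}}.
#' @param max_lag_ps VACF maximum lag (ps).
#' @param window,zero_pad_factor,kind spectrum conventions
#'   (\code{\link{spectrum_from_acf}}).
#' @param peak_band_cm1 wavenumber window for peak detection (cm^-1).
#' @param min_prominence peak prominence threshold (fraction of band max).
#' @param shift_tolerance_cm1 red-shift tolerance for the temperature
#'   trend (cm^-1).
#' @param out_dir optional output directory for TSV tables and the JSON
#'   report.
#' @return run report list with \code{vacf}, \code{spectrum},
#'   \code{peaks} (and \code{trend} when temperatures were given).
#' @export
run_protein_modes <- function(traj, selection = "backbone",
                              max_lag_ps, window = "hann",
                              zero_pad_factor = 4L, kind = "power",
                              peak_band_cm1 = c(10, 250),
                              min_prominence = 0.05,
                              shift_tolerance_cm1 = 2,
                              out_dir = NULL) {
  multi <- is.list(traj) && !inherits(traj, "trajectory")
  trajs <- if (multi) traj else list(`NA` = traj)
  params <- list(selection = selection, max_lag_ps = max_lag_ps,
                 window = window, zero_pad_factor = zero_pad_factor,
                 kind = kind, peak_band_cm1 = peak_band_cm1,
                 min_prominence = min_prominence)
  report <- .report_skeleton("protein_modes", params)
  peak_rows <- list()
  for (nm in names(trajs)) {
    tr <- trajs[[nm]]
    sel <- select_atoms(tr, selection)
    cv <- tryCatch(vacf(tr, sel, max_lag = max_lag_ps),
                   error = function(e) {
                     stop("stage vacf: ", conditionMessage(e), call. = FALSE)
                   })
    sp <- spectrum_from_acf(cv, window = window,
                            zero_pad_factor = zero_pad_factor, kind = kind)
    pk <- find_spectrum_peaks(sp, min_prominence, band = peak_band_cm1)
    if (nm == names(trajs)[1]) {
      report$vacf <- cv
      report$spectrum <- sp
    }
    pk$temperature_K <- suppressWarnings(as.numeric(nm))
    peak_rows[[nm]] <- pk
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tag <- if (multi) paste0("_", nm, "K") else ""
      write_xy_tsv(cv$lags, cv$values,
                   file.path(out_dir, paste0("vacf", tag, ".tsv")),
                   meta = c(params["selection"], list(units = "ps, dimensionless")),
                   colnames = c("lag_ps", "C_v"))
      write_xy_tsv(sp$wavenumbers, sp$amplitude,
                   file.path(out_dir, paste0("vacf_spectrum", tag, ".tsv")),
                   meta = sp$metadata,
                   colnames = c("wavenumber_cm1", kind))
    }
  }
  report$peaks <- do.call(rbind, peak_rows)
  rownames(report$peaks) <- NULL
  if (multi && length(trajs) >= 2 && nrow(report$peaks) > 0) {
    # track the strongest peak per temperature
    best <- do.call(rbind, lapply(peak_rows, function(p) {
      p[which.max(p$height), , drop = FALSE]
    }))
    report$trend <- classify_peak_trend(best$temperature_K, best$position,
                                        shift_tolerance_cm1)
  }
  .write_report_json(report, out_dir)
  report
}

#' Hydration-shell hydrogen-bond kinetics workflow
#'
#' Interfacial water-water H-bond timeline inside the configured shell,
#' its intermittent autocorrelation, an exponential lifetime fit, and the
#' spectrum of the autocorrelation over a configurable band.
#'
#' @param traj a \code{\link{trajectory}} containing protein and water,
#'   or an \code{hbond_timeline} (the synthetic route, bypassing
#'   detection).
#' @param shell_cutoff_angstrom hydration-shell radius (3.8 for the first
#'   layer).
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param max_lag_ps HBACF maximum lag (ps).
#' @param fit_window_ps lifetime fit window (ps).
#' @param band_cm1 spectrum band for reporting (cm^-1).
#' @param out_dir optional output directory.
#' @return run report with \code{timeline} summary, \code{hbacf},
#'   \code{lifetime}, \code{spectrum}, and per-class bond counts.
#' @export
run_hydration_kinetics <- function(traj, shell_cutoff_angstrom = 3.8,
                                   criteria = hbond_criteria(),
                                   max_lag_ps, fit_window_ps = c(0.5, 8),
                                   band_cm1 = c(10, 160),
                                   out_dir = NULL) {
  params <- list(shell_cutoff_angstrom = shell_cutoff_angstrom,
                 max_heavy_distance_angstrom = criteria$max_heavy_distance,
                 max_oh_distance_angstrom = criteria$max_oh_distance,
                 max_angle_degrees = criteria$max_angle,
                 max_lag_ps = max_lag_ps, fit_window_ps = fit_window_ps,
                 band_cm1 = band_cm1)
  report <- .report_skeleton("hydration_kinetics", params)
  if (inherits(traj, "hbond_timeline")) {
    tl <- traj
    report$class_counts <- table(tl$bonds$class)
  } else {
    tl <- tryCatch(
      hbond_timeline(traj, criteria, scope = "water-water",
                     shell_cutoff = shell_cutoff_angstrom),
      error = function(e) stop("stage timeline: ", conditionMessage(e),
                               call. = FALSE))
    if (nrow(tl$occupancy) == 0L) {
      stop("stage timeline: no interfacial water-water bonds found; ",
           "check the shell cutoff (", shell_cutoff_angstrom,
           " A) and that the system contains shell waters")
    }
    # partition bookkeeping: unfiltered counts per class on frame 1
    det <- detect_hbonds_frame(traj, 1, criteria)
    report$class_counts <- table(det$class)
  }
  report$n_bonds <- nrow(tl$occupancy)
  ch <- hbacf(tl, max_lag = max_lag_ps)
  if (diff(range(ch$values)) < 1e-12) {
    report$degenerate <- TRUE
    warning("HBACF shows no decay (static hydrogen-bond network); ",
            "no lifetime fitted")
    report$hbacf <- ch
    .write_report_json(report, out_dir)
    return(report)
  }
  lt <- fit_hbond_lifetime(ch, fit_window = fit_window_ps)
  sp <- spectrum_from_acf(ch)
  report$hbacf <- ch
  report$lifetime <- list(tau_ps = lt$tau, plateau = lt$plateau,
                          residual_rms = lt$residual_rms)
  report$spectrum <- sp
  report$band_peaks <- find_spectrum_peaks(sp, band = band_cm1)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_xy_tsv(ch$lags, ch$values, file.path(out_dir, "hbacf.tsv"),
                 meta = params["shell_cutoff_angstrom"],
                 colnames = c("lag_ps", "C_hb"))
    write_xy_tsv(sp$wavenumbers, sp$amplitude,
                 file.path(out_dir, "hbacf_spectrum.tsv"),
                 meta = sp$metadata, colnames = c("wavenumber_cm1", sp$kind))
  }
  .write_report_json(report, out_dir)
  report
}

#' Collective-motion workflow
#'
#' Cross-correlation matrix of C-alpha displacements, the thresholded
#' correlation network, and PCA with the PC1 square-fluctuation profile.
#'
#' @param traj a \code{\link{trajectory}} with protein atoms, or a
#'   \code{displacement_field} (the synthetic route).
#' @param threshold correlation network threshold in (0, 1].
#' @param superpose_first remove rigid-body motion before the analysis.
#' @param out_dir optional output directory.
#' @return run report with \code{dccm}, \code{network},
#'   \code{network_summary}, \code{pca}, \code{pc1_square_fluctuations}.
#' @export
run_collective <- function(traj, threshold = 0.35, superpose_first = TRUE,
                           out_dir = NULL) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  params <- list(threshold = threshold, superpose_first = superpose_first)
  report <- .report_skeleton("collective", params)
  if (inherits(traj, "displacement_field")) {
    field <- traj
    pca <- NULL
  } else {
    if (n_frames(traj) < 100) {
      warning("fewer than 100 frames; correlation estimates will be noisy")
    }
    field <- displacement_field(traj, superpose_first = superpose_first)
    pca <- pca_modes(traj, superpose_first = superpose_first)
  }
  ccm <- cross_correlation_matrix(field)
  net <- build_network(ccm, threshold = threshold)
  report$dccm <- ccm
  report$network <- net
  report$network_summary <- list(
    n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
    threshold = threshold)
  if (!is.null(pca)) {
    report$pca <- pca
    report$pc1_square_fluctuations <- square_fluctuations(pca, 1)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_crosscorr_tsv(ccm, file.path(out_dir, "dccm.tsv"))
    write_network(net, file.path(out_dir, "network.graphml"), "graphml")
    write_network(net, file.path(out_dir, "network_edges.tsv"), "tsv")
    if (!is.null(pca)) {
      sf <- report$pc1_square_fluctuations
      write_xy_tsv(sf$residue, sf$square_fluctuation,
                   file.path(out_dir, "pc1_square_fluctuations.tsv"),
                   meta = list(units = "residue, Angstrom^2"),
                   colnames = c("residue", "square_fluctuation_A2"))
    }
  }
  .write_report_json(report, out_dir)
  report
}
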