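# Autocorrelation and spectral machinery shared by the velocity,
# hydrogen-bond and rotational analyses.  Conventions (recorded in every
# Spectrum's metadata): ACF = time-origin average over all valid origins
# (divide by n - lag; the biased divide-by-n variant is selectable), Hann
# window and 4x zero padding by default, power = squared magnitude of the
# real-input FFT (non-negative by construction), wavenumber axis
# nu[cm^-1] = f[ps^-1] / 2.99792458e-2.

#' Build a correlation-series container
#'
#' @param lags ascending lag grid in ps, starting at 0.
#' @param values correlation values (dimensionless).
#' @param normalized logical; if TRUE, \code{values[1]} must be 1.
#' @param n_samples number of time origins entering each lag.
#' @param dt lag spacing in ps.
#' @return object of class \code{correlation_series}.
#' @export
correlation_series <- function(lags, values, normalized = TRUE,
                               n_samples = NULL, dt = NULL) {
  stopifnot(length(lags) == length(values), lags[1] == 0,
            !is.unsorted(lags))
  if (is.null(dt)) dt <- if (length(lags) > 1) lags[2] - lags[1] else NA_real_
  if (normalized && abs(values[1] - 1) > 1e-12) {
    stop("normalized correlation series must start at 1 (got ",
         format(values[1]), ")")
  }
  structure(list(lags = lags, values = values, normalized = normalized,
                 n_samples = n_samples, dt = dt),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat("correlation series: ", length(x$lags), " lags, 0..",
      max(x$lags), " ps", if (x$normalized) ", normalized", "\n", sep = "")
  invisible(x)
}

# Autocovariance of a vector up to lag L via FFT.
# unbiased: r[k] = (1/(n-k)) sum_t x[t] x[t+k]  (average over valid origins)
# biased:   r[k] = (1/n)     sum_t x[t] x[t+k]
.acov_fft <- function(x, max_lag_frames, estimator = "unbiased") {
  n <- length(x)
  nfft <- stats::nextn(n + max_lag_frames + 1L, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  r <- Re(fft(X * Conj(X), inverse = TRUE)) / nfft
  r <- r[1:(max_lag_frames + 1L)]
  if (estimator == "unbiased") r / (n - 0:max_lag_frames) else r / n
}

#' Time-origin-averaged autocorrelation of a multichannel series
#'
#' Computes the biased estimator \eqn{C(\tau) = \langle s(t+\tau)
#' s(t)\rangle} averaged over all valid time origins, per channel, then
#' averaged over channels; when \code{normalize} is TRUE the result is
#' divided by its lag-0 value.  Channels are mean-removed first unless
#' \code{detrend = FALSE} (velocities should keep their raw zero mean).
#'
#' @param series numeric vector or frames x channels matrix.
#' @param dt sample spacing in ps.
#' @param max_lag maximum lag in ps; must be below the series duration.
#' @param normalize divide by the lag-0 value.
#' @param detrend subtract each channel's mean before correlating.
#' @param per_channel_normalize normalize each channel by its own lag-0
#'   value before averaging channels (used for per-atom VACF and per-bond
#'   HBACF averaging); otherwise channel covariances are pooled and
#'   normalized once.
#' @param estimator \code{"unbiased"} divides each lag by its number of
#'   valid time origins (default); \code{"biased"} divides by the full
#'   series length, trading a linear taper for lower lag-to-lag variance.
#' @return a \code{\link{correlation_series}}.
#' @export
autocorrelation <- function(series, dt, max_lag, normalize = TRUE,
                            detrend = TRUE, per_channel_normalize = FALSE,
                            estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  n <- nrow(series)
  L <- as.integer(round(max_lag / dt))
  if (L >= n) stop("max_lag (", max_lag, " ps) must be shorter than the ",
                   "series duration (", (n - 1) * dt, " ps)")
  if (L < 1L) stop("max_lag shorter than one frame spacing")
  if (detrend) series <- sweep(series, 2, colMeans(series))
  acc <- numeric(L + 1L)
  kept <- 0L
  for (ch in seq_len(ncol(series))) {
    r <- .acov_fft(series[, ch], L, estimator)
    if (per_channel_normalize) {
      if (r[1] <= 0) next  # zero-variance channel carries no signal
      r <- r / r[1]
    }
    acc <- acc + r
    kept <- kept + 1L
  }
  if (kept == 0L) stop("all channels have zero variance")
  acc <- acc / kept
  if (normalize && !per_channel_normalize) {
    if (acc[1] <= 0) stop("zero-variance series cannot be normalized")
    acc <- acc / acc[1]
  }
  correlation_series(lags = (0:L) * dt, values = acc,
                     normalized = normalize || per_channel_normalize,
                     n_samples = n - (0:L), dt = dt)
}

#' Velocity autocorrelation function
#'
#' Per selected atom, the dot-product correlation
#' \eqn{\langle v_i(t+\tau)\cdot v_i(0)\rangle} is accumulated over the
#' three Cartesian components, normalized by that atom's
#' \eqn{\langle |v_i(0)|^2\rangle}, and the normalized curves are averaged
#' over atoms.  Its Fourier transform approximates the vibrational density
#' of states of the selection.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param selection atom indices (e.g. from \code{\link{select_atoms}}).
#' @param max_lag maximum lag in ps.
#' @param derive if velocities are absent, derive them by
#'   \code{\link{finite_difference_velocities}} (TRUE) or fail (FALSE).
#' @param estimator lag normalization, as in \code{\link{autocorrelation}}.
#' @return a \code{\link{correlation_series}}.
#' @export
vacf <- function(traj, selection = NULL, max_lag, derive = TRUE,
                 estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("empty atom selection")
  if (is.null(traj$velocities)) {
    if (!derive) stop("trajectory has no velocities and derive = FALSE")
    traj <- finite_difference_velocities(traj)
  }
  dt <- traj$dt
  L <- as.integer(round(max_lag / dt))
  nf <- n_frames(traj)
  if (L >= nf) stop("max_lag exceeds trajectory duration")
  acc <- numeric(L + 1L)
  kept <- 0L
  dropped <- 0L
  for (a in selection) {
    r <- numeric(L + 1L)
    for (k in 1:3) r <- r + .acov_fft(traj$velocities[, a, k], L, estimator)
    if (r[1] <= .Machine$double.eps) { dropped <- dropped + 1L; next }
    acc <- acc + r / r[1]
    kept <- kept + 1L
  }
  if (dropped > 0L) {
    warning(dropped, " static atom(s) with zero velocity variance excluded")
  }
  if (kept == 0L) stop("no atom in the selection has nonzero velocities")
  correlation_series(lags = (0:L) * dt, values = acc / kept,
                     normalized = TRUE, n_samples = nf - (0:L), dt = dt)
}

#' Rotational autocorrelation of an inter-atom vector
#'
#' Follows the unit vector from \code{atom_a} to \code{atom_b} and returns
#' \eqn{\langle P_\ell(\hat u(t+\tau)\cdot\hat u(t))\rangle} over time
#' origins, with \eqn{P_1(x) = x} (default) or the second Legendre
#' polynomial \eqn{P_2(x) = (3x^2-1)/2}.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param atom_a,atom_b distinct atom indices.
#' @param max_lag maximum lag in ps.
#' @param order Legendre order, 1 or 2.
#' @return a \code{\link{correlation_series}}.
#' @export
rotational_acf <- function(traj, atom_a, atom_b, max_lag, order = 1L) {
  stopifnot(atom_a != atom_b, order %in% c(1L, 2L))
  u <- traj$coords[, atom_b, , drop = FALSE] - traj$coords[, atom_a, , drop = FALSE]
  u <- matrix(u, ncol = 3)
  nrm <- sqrt(rowSums(u * u))
  if (any(nrm < 1e-9)) {
    stop("atoms coincide at frame ", which(nrm < 1e-9)[1])
  }
  u <- u / nrm
  dt <- traj$dt
  L <- as.integer(round(max_lag / dt))
  if (L >= nrow(u)) stop("max_lag exceeds trajectory duration")
  if (order == 1L) {
    chans <- u
  } else {
    # P2 of the dot product via the symmetric outer-product embedding:
    # (u.u')^2 = q.q' with q = (xx, yy, zz, sqrt2*xy, sqrt2*xz, sqrt2*yz)
    s2 <- sqrt(2)
    chans <- cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
                   s2 * u[, 1] * u[, 2], s2 * u[, 1] * u[, 3],
                   s2 * u[, 2] * u[, 3])
  }
  r <- numeric(L + 1L)
  for (ch in seq_len(ncol(chans))) {
    r <- r + .acov_fft(chans[, ch], L, "unbiased")
  }
  # r[k] is <u(t+k).u(t)> (order 1) or <(u(t+k).u(t))^2> (order 2)
  vals <- if (order == 1L) r else (3 * r - 1) / 2
  correlation_series(lags = (0:L) * dt, values = vals / vals[1],
                     normalized = TRUE,
                     n_samples = nrow(u) - (0:L), dt = dt)
}

# ---------------------------------------------------------------------------
# Spectra

#' Fourier spectrum of a correlation function on a wavenumber axis
#'
#' The (optionally Hann-windowed, zero-padded) one-sided correlation
#' function is transformed with a real-input FFT; the frequency axis is
#' converted to wavenumber with the exact constant
#' \eqn{\tilde\nu\,[\mathrm{cm}^{-1}] = f\,[\mathrm{ps}^{-1}] /
#' 2.99792458\times 10^{-2}} (1 ps^-1 = 33.3564 cm^-1).
#'
#' @param acf a \code{\link{correlation_series}} on a uniform lag grid.
#' @param window \code{"hann"} (cosine taper to zero at the last lag) or
#'   \code{"none"}.
#' @param zero_pad_factor integer >= 1; the transform length is
#'   \code{zero_pad_factor * length(acf)}, interpolating the grid.
#' @param kind \code{"power"} (squared magnitude, default) or
#'   \code{"amplitude"} (magnitude).
#' @return object of class \code{spectrum_cm1}: ascending wavenumber grid
#'   (cm^-1) up to Nyquist, non-negative amplitude, and metadata recording
#'   window, padding, bin width and total power.
#' @export
spectrum_from_acf <- function(acf, window = c("hann", "none"),
                              zero_pad_factor = 4L,
                              kind = c("power", "amplitude")) {
  window <- match.arg(window)
  kind <- match.arg(kind)
  stopifnot(inherits(acf, "correlation_series"), zero_pad_factor >= 1)
  lagdiff <- diff(acf$lags)
  if (length(lagdiff) < 1L) stop("correlation series too short")
  if (max(abs(lagdiff - lagdiff[1])) > 1e-9 * lagdiff[1]) {
    stop("correlation series must be on a uniform lag grid")
  }
  dt <- lagdiff[1]
  y <- acf$values
  n <- length(y)
  w <- switch(window,
              none = rep(1, n),
              hann = 0.5 * (1 + cos(pi * (0:(n - 1)) / (n - 1))))
  yw <- y * w
  nfft <- as.integer(zero_pad_factor) * n
  X <- fft(c(yw, rep(0, nfft - n)))
  total_power <- sum(Mod(X)^2) / nfft
  half <- seq_len(floor(nfft / 2) + 1L)
  freq_ps <- (half - 1) / (nfft * dt)
  wavenumbers <- freq_ps / C_CM_PER_PS
  amp <- Mod(X[half])
  if (kind == "power") amp <- amp^2
  structure(list(wavenumbers = wavenumbers, amplitude = amp, kind = kind,
                 metadata = list(window = window,
                                 zero_pad_factor = as.integer(zero_pad_factor),
                                 dt = dt, n_lags = n,
                                 bin_width_cm1 = 1 / (nfft * dt) / C_CM_PER_PS,
                                 total_power = total_power)),
            class = "spectrum_cm1")
}

#' @export
print.spectrum_cm1 <- function(x, ...) {
  cat("spectrum (", x$kind, "): 0..",
      round(max(x$wavenumbers), 1), " cm^-1, bin width ",
      signif(x$metadata$bin_width_cm1, 4), " cm^-1 (window: ",
      x$metadata$window, ", pad x", x$metadata$zero_pad_factor, ")\n",
      sep = "")
  invisible(x)
}

#' Locate spectral peaks
#'
#' Local maxima whose prominence (height above the higher of the two
#' flanking minima, where a flanking minimum is the lowest point between
#' the peak and the nearest higher ground or band edge) exceeds
#' \code{min_prominence} times the band maximum.  Positions are refined by
#' 3-point parabolic interpolation; ties are broken toward lower
#' wavenumber.
#'
#' @param spec a \code{spectrum_cm1}.
#' @param min_prominence prominence threshold as a fraction of the band
#'   maximum.
#' @param band optional \code{c(lo, hi)} wavenumber window (cm^-1).
#' @return data.frame of class \code{peak_set} with columns
#'   \code{position}, \code{height}, \code{prominence}, sorted by position.
#' @export
find_spectrum_peaks <- function(spec, min_prominence = 0.05, band = NULL) {
  stopifnot(inherits(spec, "spectrum_cm1"))
  x <- spec$wavenumbers
  y <- spec$amplitude
  if (!is.null(band)) {
    keep <- x >= band[1] & x <= band[2]
    if (!any(keep)) stop("band [", band[1], ", ", band[2],
                         "] contains no spectrum points")
    x <- x[keep]; y <- y[keep]
  }
  n <- length(y)
  out <- data.frame(position = numeric(0), height = numeric(0),
                    prominence = numeric(0))
  if (n >= 3) {
    ymax <- max(y)
    cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                  y[2:(n - 1)] >= y[3:n]) + 1L
    for (i in cand) {
      # walk out to higher ground on each side, track lowest valley
      left_min <- y[i]; j <- i
      while (j > 1 && y[j] <= y[i]) { j <- j - 1; left_min <- min(left_min, y[j]) }
      right_min <- y[i]; j <- i
      while (j < n && y[j] <= y[i]) { j <- j + 1; right_min <- min(right_min, y[j]) }
      prom <- y[i] - max(left_min, right_min)
      if (prom >= min_prominence * ymax && prom > 0) {
        # parabolic refinement on the raw grid
        denom <- y[i - 1] - 2 * y[i] + y[i + 1]
        delta <- if (abs(denom) > 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
        delta <- max(min(delta, 0.5), -0.5)
        pos <- x[i] + delta * (x[2] - x[1])
        out <- rbind(out, data.frame(position = pos, height = y[i],
                                     prominence = prom))
      }
    }
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  attr(out, "min_prominence") <- min_prominence
  attr(out, "band") <- band
  out
}

#' Classify a peak's temperature trend as harmonic- or anharmonic-like
#'
#' A red-shift of a mode with rising temperature marks anharmonic motion;
#' a temperature-insensitive position marks a vibrational (harmonic) mode.
#' The call regresses position on temperature and labels the trend
#' anharmonic-like when the fitted slope is below
#' \eqn{-\mathrm{tol}/(T_{max}-T_{min})}, i.e. when the net fitted shift
#' across the measured range exceeds the tolerance toward the red.
#'
#' @param temperatures temperatures in K (at least 2, all distinct).
#' @param positions peak positions in cm^-1, same length.
#' @param shift_tolerance smallest red-shift (cm^-1) across the full
#'   temperature range counted as meaningful.
#' @return \code{"anharmonic-like"} or \code{"harmonic-like"}, with the
#'   fitted slope (cm^-1/K) as attribute \code{slope}.
#' @export
classify_peak_trend <- function(temperatures, positions,
                                shift_tolerance = 2) {
  stopifnot(length(temperatures) == length(positions),
            length(temperatures) >= 2)
  if (anyDuplicated(temperatures)) stop("duplicate temperatures")
  fit <- lm(positions ~ temperatures)
  slope <- unname(coef(fit)[2])
  span <- max(temperatures) - min(temperatures)
  label <- if (slope < -shift_tolerance / span) "anharmonic-like"
           else "harmonic-like"
  structure(label, slope = slope)
}

#' Convert transmittance to absorbance
#'
#' \eqn{A = -\log_{10}(\%T/100)} pointwise; with raw intensities,
#' \eqn{\%T = 100\, I/I_0} first.  Transmittance above 100\% (possible in
#' noisy measurements) yields a negative absorbance and a warning rather
#' than an error; values are never clamped, so the round trip is exact.
#'
#' @param percent_t percent transmittance values in (0, 100]; or NULL.
#' @param I,I0 sample and background single-beam intensities (both > 0),
#'   used when \code{percent_t} is NULL.
#' @param wavenumbers optional matching wavenumber grid (cm^-1).
#' @return object of class \code{absorbance_spectrum} with
#'   \code{percent_transmittance} and \code{absorbance}.
#' @export
absorbance_from_transmittance <- function(percent_t = NULL, I = NULL,
                                          I0 = NULL, wavenumbers = NULL) {
  if (is.null(percent_t)) {
    if (is.null(I) || is.null(I0)) {
      stop("supply percent_t, or both I and I0")
    }
    stopifnot(length(I) == length(I0))
    if (any(I <= 0) || any(I0 <= 0)) stop("intensities must be positive")
    percent_t <- 100 * I / I0
  }
  if (any(percent_t <= 0)) stop("percent transmittance must be positive")
  if (any(percent_t > 100)) {
    warning(sum(percent_t > 100),
            " point(s) with %T > 100 (negative absorbance retained)")
  }
  A <- -log10(percent_t / 100)
  structure(list(wavenumbers = wavenumbers,
                 percent_transmittance = percent_t,
                 absorbance = A, I = I, I0 = I0),
            class = "absorbance_spectrum")
}

# ---------------------------------------------------------------------------
# Two-column TSV serialization with a '#'-prefixed metadata header

#' Write an x/value table as TSV with commented metadata header
#'
#' @param x,values numeric columns.
#' @param path output path.
#' @param meta named list written as \code{# key: value} header lines.
#' @param colnames column names for the data header line.
#' @return \code{path}, invisibly.
#' @export
write_xy_tsv <- function(x, values, path, meta = list(),
                         colnames = c("x", "value")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(paste0("# ", k, ": ", paste(meta[[k]], collapse = " ")), con)
  }
  writeLines(paste(colnames, collapse = "\t"), con)
  writeLines(paste(format(x, digits = 12, trim = TRUE),
                   format(values, digits = 12, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Read a two-column TSV written by \code{\link{write_xy_tsv}}
#'
#' @param path input path.
#' @return list with \code{data} (two-column data.frame) and \code{meta}
#'   (named character list from the header).
#' @export
read_xy_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!hdr]
  df <- read.table(text = body, header = TRUE, sep = "\t")
  list(data = df, meta = meta)
}
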