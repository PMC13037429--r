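#' Ground-truth connectivity specification for the recording generator
#'
#' @param roi_corr 9x9 symmetric positive semi-definite target correlation
#'   matrix of the latent ROI hemodynamics (unit diagonal).
#' @param hbo_amp HbO fluctuation amplitude (SD of the nodewise
#'   concentration change) in uM (default 1).
#' @param hbr_ratio HbR/HbO anticorrelation scale: \eqn{\Delta HbR =
#'   -hbr\_ratio \cdot \Delta HbO + \nu} (default 0.3).
#' @param hbr_noise_frac SD of the independent HbR noise \eqn{\nu} as a
#'   fraction of \code{hbr_ratio * hbo_amp} (default 0.2).
#' @param band latent frequency band in Hz (default c(0.01, 0.08)).
#' @return validated list of class \code{connectivity_spec}.
#' @export
connectivity_spec <- function(roi_corr = diag(9), hbo_amp = 1,
                              hbr_ratio = 0.3, hbr_noise_frac = 0.2,
                              band = c(0.01, 0.08)) {
  roi_corr <- as.matrix(roi_corr)
  if (!isTRUE(all.equal(unname(roi_corr), unname(t(roi_corr)),
                        tolerance = 1e-10, check.attributes = FALSE)))
    stop("roi_corr must be symmetric")
  if (any(abs(diag(roi_corr) - 1) > 1e-10))
    stop("roi_corr must have unit diagonal")
  off <- roi_corr[upper.tri(roi_corr)]
  if (any(abs(off) >= 1)) stop("|off-diagonal| correlations must be < 1")
  if (min(eigen(roi_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("roi_corr must be positive semi-definite")
  structure(list(roi_corr = roi_corr, hbo_amp = hbo_amp,
                 hbr_ratio = hbr_ratio, hbr_noise_frac = hbr_noise_frac,
                 band = band),
            class = "connectivity_spec")
}

#' Artifact specification for the recording generator
#'
#' @param spike_times motion-spike centers, seconds from recording start.
#' @param spike_amp spike amplitude in OD units (default 0.5).
#' @param narrowband_channels indices (into the full channel table) that
#'   receive narrowband light contamination; empty for none.
#' @param narrowband_freq contamination frequency, Hz (default 3.5; must be
#'   below the 5-Hz Nyquist).
#' @param narrowband_amp contamination amplitude in intensity units
#'   (default 0.05, i.e. 5 percent of the unit source-calibrated level).
#' @param narrowband_interval optional \code{c(start_s, end_s)} restricting
#'   the contamination in time (default: whole recording).
#' @param drift_amp slow multiplicative drift, fraction per hour
#'   (default 0).
#' @return validated list of class \code{artifact_spec}.
#' @export
artifact_spec <- function(spike_times = numeric(), spike_amp = 0.5,
                          narrowband_channels = integer(),
                          narrowband_freq = 3.5, narrowband_amp = 0.05,
                          narrowband_interval = NULL, drift_amp = 0) {
  if (narrowband_freq >= 5)
    stop("narrowband_freq must be below the 5-Hz Nyquist")
  structure(list(spike_times = spike_times, spike_amp = spike_amp,
                 narrowband_channels = as.integer(narrowband_channels),
                 narrowband_freq = narrowband_freq,
                 narrowband_amp = narrowband_amp,
                 narrowband_interval = narrowband_interval,
                 drift_amp = drift_amp),
            class = "artifact_spec")
}

# band-limited unit-variance latents with *exact* sample correlation:
# FFT band-pass of white noise, then whitening of the realized covariance,
# then mixing with a square root of the target correlation matrix.
.gen_latents <- function(n, fs, band, target_corr, rng) {
  k <- nrow(target_corr)
  X <- matrix(rng$rnorm(n * k), n, k)
  X <- .fft_bandpass(X, fs, band[1], band[2])
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / n
  e <- eigen(C, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  Xw <- X %*% W                               # identity sample covariance
  et <- eigen(target_corr, symmetric = TRUE)
  Rh <- diag(sqrt(pmax(et$values, 0))) %*% t(et$vectors)
  Xw %*% Rh                                   # sample covariance = target
}

#' Generate a synthetic two-wavelength DOT recording
#'
#' Band-limited latent hemodynamics with the target ROI correlation matrix
#' are planted as \eqn{\Delta HbO} on volumetric nodes within 15 mm of each
#' 10-20 landmark (nodes assigned to the nearest landmark), with
#' \eqn{\Delta HbR = -r \cdot \Delta HbO + \nu}. Concentrations are
#' converted to absorption changes via the extinction table,
#' forward-projected through the Jacobian to \eqn{\Delta OD}, and turned
#' into intensities \eqn{I = I_0 e^{-\Delta OD}} with multiplicative
#' measurement noise; motion spikes, narrowband contamination and drift are
#' superposed per the artifact specification.
#'
#' @param head a \code{head_model}.
#' @param jacobian a \code{dot_jacobian} for the same model.
#' @param spec a \code{\link{connectivity_spec}}.
#' @param art an \code{\link{artifact_spec}}.
#' @param duration_s recording length in seconds.
#' @param seed integer RNG seed.
#' @param fs sampling frequency, Hz (default 10).
#' @param roi_radius_mm planting sphere radius around each landmark
#'   (default 15).
#' @param I0 source-calibrated baseline intensity (default 1).
#' @param noise_cv multiplicative measurement-noise CV (default 0.005).
#' @param extinction extinction matrix (see
#'   \code{\link{extinction_defaults}}).
#' @return object of class \code{dot_recording}: \code{fs}, \code{t}
#'   (seconds), \code{intensity} (channels x samples), \code{channels}
#'   (full channel table), plus a \code{truth} list carrying the latent ROI
#'   signals, the clean \eqn{\Delta OD}, and the generator inputs.
#' @export
gen_dot_recording <- function(head, jacobian, spec, art = artifact_spec(),
                              duration_s, seed, fs = 10,
                              roi_radius_mm = 15, I0 = 1,
                              noise_cv = 0.005,
                              extinction = extinction_defaults()) {
  stopifnot(inherits(head, "head_model"),
            inherits(jacobian, "dot_jacobian"),
            inherits(spec, "connectivity_spec"),
            inherits(art, "artifact_spec"))
  n <- round(duration_s * fs)
  tt <- seq(0, by = 1 / fs, length.out = n)
  rng <- .seeded_rng(seed)
  nroi <- nrow(spec$roi_corr)
  # latents: ROI HbO (exact target correlation) + independent HbR noise
  L_hbo <- .gen_latents(n, fs, spec$band, spec$roi_corr, rng)
  L_nu <- .gen_latents(n, fs, spec$band, diag(nroi), rng)
  # node-to-ROI assignment: nearest landmark within the planting radius
  d2 <- .pairwise_dist2(head$vol, head$landmarks)
  nearest <- max.col(-d2)
  within <- d2[cbind(seq_len(nrow(d2)), nearest)] <= roi_radius_mm^2
  P <- matrix(0, nrow(head$vol), nroi)
  P[cbind(which(within), nearest[within])] <- 1
  # concentration amplitudes (uM): HbO and the independent HbR component
  amp_nu <- spec$hbr_noise_frac * spec$hbr_ratio * spec$hbo_amp
  wl <- jacobian$wavelengths
  ln10 <- log(10)
  od <- vector("list", length(wl))
  for (w in seq_along(wl)) {
    e <- extinction[as.character(wl[w]), ]
    # dmua = ln10 * (eHbO - eHbR*ratio) * hbo_amp * L_hbo
    #      + ln10 * eHbR * amp_nu * L_nu   (per node in its ROI)
    A <- jacobian$J[[w]] %*% P                       # pairs x nroi
    c_hbo <- ln10 * (e["HbO"] - e["HbR"] * spec$hbr_ratio) * spec$hbo_amp
    c_nu <- ln10 * e["HbR"] * amp_nu
    od[[w]] <- A %*% (c_hbo * t(L_hbo) + c_nu * t(L_nu))  # pairs x n
  }
  od_clean <- do.call(rbind, od)          # channels x n, wavelength-major
  ch <- .channel_table(jacobian)
  nch <- nrow(ch)
  # motion spikes: additive OD transients shared across channels with a
  # random per-channel scale in [0.5, 1.5]
  od_art <- matrix(0, nch, n)
  if (length(art$spike_times) > 0) {
    scale <- 0.5 + rng$runif(nch)
    bump <- rowSums(sapply(art$spike_times, function(ts)
      exp(-0.5 * ((tt - ts) / 0.3)^2)))
    od_art <- od_art + art$spike_amp * outer(scale, bump)
  }
  intensity <- I0 * exp(-(od_clean + od_art))
  if (art$drift_amp != 0) {
    sgn <- sign(rng$runif(nch) - 0.5)
    intensity <- intensity *
      (1 + outer(sgn * art$drift_amp, tt / 3600))
  }
  intensity <- intensity * (1 + noise_cv * matrix(rng$rnorm(nch * n), nch, n))
  if (length(art$narrowband_channels) > 0) {
    phase <- 2 * pi * rng$runif(length(art$narrowband_channels))
    gate <- if (is.null(art$narrowband_interval)) rep(1, n) else
      as.numeric(tt >= art$narrowband_interval[1] &
                 tt <= art$narrowband_interval[2])
    for (j in seq_along(art$narrowband_channels)) {
      k <- art$narrowband_channels[j]
      intensity[k, ] <- intensity[k, ] + art$narrowband_amp * gate *
        sin(2 * pi * art$narrowband_freq * tt + phase[j])
    }
  }
  structure(list(fs = fs, t = tt, intensity = intensity, channels = ch,
                 I0 = I0,
                 truth = list(latent_hbo = L_hbo, od_clean = od_clean,
                              spec = spec, art = art, seed = seed,
                              roi_nodes = P)),
            class = "dot_recording")
}

# full channel table (wavelength-major) implied by a jacobian's pair table
.channel_table <- function(jacobian) {
  do.call(rbind, lapply(jacobian$wavelengths, function(w) {
    d <- jacobian$pairs
    d$wavelength <- w
    d
  }))
}

.pairwise_dist2 <- function(a, b) {
  # rows of a vs rows of b, squared Euclidean
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

#' @export
print.dot_recording <- function(x, ...) {
  cat(sprintf("<dot_recording> %d channels x %d samples at %g Hz (%.0f s)\n",
              nrow(x$intensity), ncol(x$intensity), x$fs,
              ncol(x$intensity) / x$fs))
  invisible(x)
}
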