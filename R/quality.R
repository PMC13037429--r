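#' Channel mask constructor
#'
#' @param good logical vector, one element per channel (wavelength-major
#'   ordering of the channel table).
#' @param reason character vector of exclusion codes (\code{NA} where
#'   good): \code{range}, \code{snr}, \code{psd_low_band},
#'   \code{psd_high_band}.
#' @param channels the channel table the mask refers to.
#' @return object of class \code{channel_mask} with the per-channel fields
#'   plus \code{pair_good}: a source-detector pair is usable only if both
#'   of its wavelengths pass (required for two-wavelength unmixing).
#' @export
channel_mask <- function(good, reason = rep(NA_character_, length(good)),
                         channels) {
  stopifnot(length(good) == nrow(channels))
  npair <- length(good) / length(unique(channels$wavelength))
  pair_good <- Reduce(`&`, split(good, channels$wavelength))
  structure(list(good = good, reason = reason, channels = channels,
                 pair_good = pair_good, n_pairs = as.integer(npair)),
            class = "channel_mask")
}

#' @export
print.channel_mask <- function(x, ...) {
  cat(sprintf("<channel_mask> %d/%d channels good, %d/%d pairs usable\n",
              sum(x$good), length(x$good), sum(x$pair_good),
              length(x$pair_good)))
  invisible(x)
}

# intersection of masks; first-listed reason wins
.combine_masks <- function(a, b) {
  good <- a$good & b$good
  reason <- ifelse(!a$good, a$reason, b$reason)
  channel_mask(good, reason, a$channels)
}

#' Prune channels on intensity range and signal-to-noise ratio
#'
#' A channel is kept iff its window-mean intensity lies within
#' \code{[d_low, d_high]} and its SNR (mean / SD over the window) is at
#' least \code{snr_min}. Zero-variance channels have infinite SNR and are
#' kept if their range passes.
#'
#' @param window a \code{dot_recording} window of at least 30 s.
#' @param d_low,d_high intensity range bounds (defaults 5e-4 and 3).
#' @param snr_min minimum SNR (default 1).
#' @return a \code{\link{channel_mask}}.
#' @export
prune_channels <- function(window, d_low = 5e-4, d_high = 3, snr_min = 1) {
  stopifnot(inherits(window, "dot_recording"))
  if (ncol(window$intensity) < 30 * window$fs)
    stop("pruning window must be at least 30 s")
  m <- rowMeans(window$intensity)
  s <- apply(window$intensity, 1, stats::sd)
  snr <- ifelse(s == 0, Inf, m / s)
  range_ok <- m >= d_low & m <= d_high
  snr_ok <- snr >= snr_min
  reason <- rep(NA_character_, length(m))
  reason[!range_ok] <- "range"
  reason[range_ok & !snr_ok] <- "snr"
  channel_mask(range_ok & snr_ok, reason, window$channels)
}

#' Welch power spectral density
#'
#' One-sided Welch estimate: Hann-windowed segments with 50 percent
#' overlap, per-segment demeaning, periodograms normalized to density
#' (power per Hz) and averaged.
#'
#' @param x numeric vector.
#' @param fs sampling frequency, Hz.
#' @param seg_len segment length in samples (default \code{60 * fs}).
#' @return list with \code{freq} (Hz) and \code{psd} (power/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = round(60 * fs)) {
  m <- .welch_psd_mat(matrix(x, nrow = 1), fs, seg_len)
  list(freq = m$freq, psd = m$psd[1, ])
}

# Welch estimate for all rows of a channels x samples matrix at once
.welch_psd_mat <- function(X, fs, seg_len = round(60 * fs)) {
  n <- ncol(X)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  U <- sum(w^2)
  acc <- matrix(0, seg_len, nrow(X))
  for (s in starts) {
    seg <- t(X[, s:(s + seg_len - 1), drop = FALSE])
    seg <- sweep(seg, 2, colMeans(seg)) * w
    acc <- acc + abs(stats::mvfft(seg))^2
  }
  psd <- acc / (length(starts) * fs * U)
  half <- seq_len(floor(seg_len / 2) + 1)
  psd <- psd[half, , drop = FALSE]
  inner <- seq(2, length(half) - 1)
  psd[inner, ] <- 2 * psd[inner, ]                        # one-sided
  list(freq = (half - 1) * fs / seg_len, psd = t(psd))
}

#' Flag channels with narrowband spectral contamination
#'
#' Channels whose Welch PSD of demeaned intensity peaks above 0.09 W/Hz
#' in 0.05-2 Hz, or above 0.01 W/Hz in 3-4 Hz, are flagged; the 3-4 Hz
#' band targets narrowband ambient-light contamination. Demeaning makes
#' the screen invariant to constant offsets; the thresholds are absolute
#' spectral densities in the device's (source-calibrated, order-one)
#' intensity units.
#'
#' @param window a \code{dot_recording} window of at least 5 min.
#' @param low_band,low_thresh low screening band in Hz and its PSD
#'   threshold (defaults \code{c(0.05, 2)} and 0.09).
#' @param high_band,high_thresh high screening band and threshold
#'   (defaults \code{c(3, 4)} and 0.01).
#' @return a \code{\link{channel_mask}} with reasons
#'   \code{psd_low_band} / \code{psd_high_band}.
#' @export
psd_flags <- function(window, low_band = c(0.05, 2), low_thresh = 0.09,
                      high_band = c(3, 4), high_thresh = 0.01) {
  stopifnot(inherits(window, "dot_recording"))
  X <- window$intensity - rowMeans(window$intensity)
  p <- .welch_psd_mat(X, window$fs)
  in_lo <- p$freq >= low_band[1] & p$freq <= low_band[2]
  in_hi <- p$freq >= high_band[1] & p$freq <= high_band[2]
  max_lo <- apply(p$psd[, in_lo, drop = FALSE], 1, max)
  max_hi <- apply(p$psd[, in_hi, drop = FALSE], 1, max)
  flag_lo <- max_lo >= low_thresh
  flag_hi <- !flag_lo & max_hi >= high_thresh
  reason <- rep(NA_character_, nrow(X))
  reason[flag_lo] <- "psd_low_band"
  reason[flag_hi] <- "psd_high_band"
  channel_mask(!(flag_lo | flag_hi), reason, window$channels)
}

#' Coverage parameters
#'
#' @param pthresh minimum measurable relative intensity change, percent
#'   (default 1).
#' @param actvol activation volume over which a hemodynamic response is
#'   expected, mm^3 (default 10).
#' @param vhat median per-node volume of the volumetric model, mm^3.
#' @param dmua expected absorption change during a response, per mm
#'   (default 0.001).
#' @param reading \code{"divide"} (default) or \code{"multiply"}: how the
#'   activation-volume factor enters the threshold (the published formula
#'   is typographically ambiguous; see \code{\link{coverage_threshold}}).
#' @return validated list of class \code{coverage_params}.
#' @export
coverage_params <- function(pthresh = 1, actvol = 10, vhat = 125,
                            dmua = 0.001, reading = c("divide", "multiply")) {
  if (pthresh < 0) stop("pthresh must be >= 0")
  if (actvol <= 0 || vhat <= 0 || dmua <= 0)
    stop("actvol, vhat and dmua must be positive")
  structure(list(pthresh = pthresh, actvol = actvol, vhat = vhat,
                 dmua = dmua, reading = match.arg(reading)),
            class = "coverage_params")
}

#' Minimum sensitivity for a node to count as covered
#'
#' \deqn{C_{thresh} = \ln\!\big((100 + p_{thresh})/100\big) \,/\,
#'   \big((actvol/\hat V)\,\Delta\mu_a\big)}
#' under the default \code{"divide"} reading (natural log, consistent with
#' natural-log OD throughout the pipeline); the \code{"multiply"} reading
#' uses \eqn{\ln(\cdot) \cdot (actvol/\hat V) \cdot \Delta\mu_a}. Units:
#' \eqn{\Delta OD} per mm\eqn{^{-1}}.
#'
#' @param p a \code{\link{coverage_params}} object.
#' @return scalar threshold.
#' @export
coverage_threshold <- function(p) {
  stopifnot(inherits(p, "coverage_params"))
  base <- log((100 + p$pthresh) / 100)
  fac <- (p$actvol / p$vhat) * p$dmua
  if (p$reading == "divide") base / fac else base * fac
}

#' Aggregate sensitivity map over good channels
#'
#' Per volumetric node, the sum of absolute Jacobian entries over usable
#' source-detector pairs, at the reference wavelength (850 nm by default).
#'
#' @param jacobian a \code{dot_jacobian}.
#' @param mask a \code{\link{channel_mask}} (pair usability is taken from
#'   \code{mask$pair_good}).
#' @param wavelength reference wavelength (default: last, i.e. 850 nm) or
#'   \code{"mean"} for the mean over wavelengths.
#' @return list of class \code{sensitivity_map}: \code{sensitivity} per
#'   node, \code{n_channels} contributing.
#' @export
sensitivity_map <- function(jacobian, mask, wavelength = NULL) {
  stopifnot(inherits(jacobian, "dot_jacobian"),
            inherits(mask, "channel_mask"))
  keep <- mask$pair_good
  if (length(keep) != nrow(jacobian$pairs))
    stop("mask and jacobian dimensions disagree")
  pick <- function(J) colSums(abs(J[keep, , drop = FALSE]))
  if (identical(wavelength, "mean")) {
    s <- Reduce(`+`, lapply(jacobian$J, pick)) / length(jacobian$J)
  } else {
    w <- if (is.null(wavelength)) length(jacobian$J) else
      which(jacobian$wavelengths == wavelength)
    s <- pick(jacobian$J[[w]])
  }
  if (!any(keep)) warning("all channels bad: zero sensitivity map")
  structure(list(sensitivity = s, n_channels = sum(keep)),
            class = "sensitivity_map")
}

#' Mean sensitivity within the nine 15-mm ROI spheres
#'
#' @param map a \code{\link{sensitivity_map}}.
#' @param head the \code{head_model} the map was computed on.
#' @param radius_mm ROI sphere radius (default 15).
#' @return named numeric vector of nine per-ROI mean node sensitivities.
#' @export
roi_mean_sensitivity <- function(map, head, radius_mm = 15) {
  stopifnot(inherits(map, "sensitivity_map"), inherits(head, "head_model"))
  d2 <- .pairwise_dist2(head$vol, head$landmarks)
  vapply(seq_len(nrow(head$landmarks)), function(j) {
    idx <- which(d2[, j] <= radius_mm^2)
    if (length(idx) == 0)
      stop("empty ROI sphere at landmark ", rownames(head$landmarks)[j])
    mean(map$sensitivity[idx])
  }, numeric(1)) -> v
  names(v) <- rownames(head$landmarks)
  v
}

#' Select the best 5-min window inside a euglycemic span
#'
#' Scans candidate 5-min windows at 1-min increments across the span. For
#' each candidate, channels are pruned on range/SNR and screened on PSD,
#' the sensitivity map is recomputed from the remaining good channels, and
#' the nine ROI mean sensitivities are evaluated. Among candidates whose
#' nine ROI means all reach the coverage threshold, the one with the
#' highest total (sum of ROI means) wins, earliest start breaking ties. If
#' no candidate is feasible, the fallback ranks by (number of covered
#' ROIs, then total sensitivity) and reports \code{feasible = FALSE}.
#'
#' @param recording a \code{dot_recording}.
#' @param span \code{c(start_min, end_min)} within the recording.
#' @param jacobian,head model objects matching the recording's montage.
#' @param cov a \code{\link{coverage_params}}; its \code{vhat} defaults to
#'   the model's per-node volume if \code{NULL}.
#' @param step_min search increment in minutes (default 1).
#' @param window_min window length in minutes (default 5).
#' @return list of class \code{window_choice}: \code{start_min},
#'   \code{mask}, \code{roi_mean_sensitivity}, \code{total_sensitivity},
#'   \code{feasible}.
#' @export
select_best_window <- function(recording, span, jacobian, head,
                               cov = NULL, step_min = 1, window_min = 5) {
  stopifnot(inherits(recording, "dot_recording"))
  if (span[2] - span[1] < window_min)
    stop("span shorter than the window length")
  if (is.null(cov)) cov <- coverage_params(vhat = head$node_volume_mm3)
  cthresh <- coverage_threshold(cov)
  starts <- seq(span[1], span[2] - window_min, by = step_min)
  best <- NULL
  for (s in starts) {
    win <- extract_window(recording, s * 60, window_min * 60)
    mask <- .combine_masks(prune_channels(win), psd_flags(win))
    map <- suppressWarnings(sensitivity_map(jacobian, mask))
    rms <- roi_mean_sensitivity(map, head)
    cand <- list(start_min = s, mask = mask, roi_mean_sensitivity = rms,
                 total_sensitivity = sum(rms),
                 n_covered = sum(rms >= cthresh),
                 feasible = all(rms >= cthresh))
    if (is.null(best) || .better_window(cand, best)) best <- cand
  }
  structure(best, class = "window_choice")
}

# strict ordering: feasibility, then covered-ROI count, then total
# sensitivity; ties keep the earlier (incumbent) start
.better_window <- function(cand, best) {
  if (cand$feasible != best$feasible) return(cand$feasible)
  if (cand$n_covered != best$n_covered) return(cand$n_covered > best$n_covered)
  cand$total_sensitivity > best$total_sensitivity
}

#' @export
print.window_choice <- function(x, ...) {
  cat(sprintf(
    "<window_choice> start %g min, %d/9 ROIs covered, total %.4g%s\n",
    x$start_min, x$n_covered, x$total_sensitivity,
    if (x$feasible) "" else " (infeasible: fallback choice)"))
  invisible(x)
}
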