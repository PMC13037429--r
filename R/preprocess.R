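#' Extract a time window from a recording
#'
#' @param recording a \code{dot_recording}.
#' @param start_s window start in seconds from recording start.
#' @param duration_s window length in seconds (default 300).
#' @return a \code{dot_recording} restricted to the window.
#' @export
extract_window <- function(recording, start_s, duration_s = 300) {
  stopifnot(inherits(recording, "dot_recording"))
  idx <- which(recording$t >= start_s &
               recording$t < start_s + duration_s)
  if (length(idx) < 2) stop("window outside the recording")
  out <- recording
  out$t <- recording$t[idx]
  out$intensity <- recording$intensity[, idx, drop = FALSE]
  out$truth <- NULL
  out
}

#' Convert an intensity window to optical density
#'
#' \eqn{OD(t) = -\ln(I(t) / \bar I)} per channel, with the window mean as
#' the reference intensity; zero-mean up to the log nonlinearity and
#' invariant to per-channel intensity scaling.
#'
#' @param window a \code{dot_recording} (typically from
#'   \code{\link{extract_window}}).
#' @param good optional logical vector of channels required to be strictly
#'   positive (default: all); nonpositive samples on such channels raise
#'   an error naming the channel.
#' @return object of class \code{od_window}: \code{od} (channels x
#'   samples), \code{fs}, \code{channels}.
#' @export
intensity_to_od <- function(window, good = NULL) {
  stopifnot(inherits(window, "dot_recording"))
  I <- window$intensity
  if (is.null(good)) good <- rep(TRUE, nrow(I))
  bad <- which(good & apply(I <= 0, 1, any))
  if (length(bad) > 0)
    stop("nonpositive intensity on good channel(s): ",
         paste(bad, collapse = ", "))
  m <- rowMeans(I)
  od <- -log(I / m)
  od[!good, ] <- 0
  structure(list(od = od, fs = window$fs, channels = window$channels),
            class = "od_window")
}

#' @export
print.od_window <- function(x, ...) {
  cat(sprintf("<od_window> %d channels x %d samples at %g Hz\n",
              nrow(x$od), ncol(x$od), x$fs))
  invisible(x)
}

# ---- periodized orthogonal DWT (Daubechies-5) -------------------------
# Analysis: a[k] = sum_n g[n] x[(2k + n) mod N]; the even-shift rows of the
# quadrature-mirror pair form an orthonormal basis, so synthesis is the
# transpose. Operates on a time x channels matrix, vectorized over columns.

.dwt_level <- function(X, lo, hi) {
  N <- nrow(X); L <- length(lo)
  K <- N / 2
  A <- matrix(0, K, ncol(X)); D <- A
  base <- 2 * (seq_len(K) - 1)
  for (n in seq_len(L)) {
    Xn <- X[(base + n - 1) %% N + 1, , drop = FALSE]
    A <- A + lo[n] * Xn
    D <- D + hi[n] * Xn
  }
  list(A = A, D = D)
}

.idwt_level <- function(A, D, lo, hi) {
  K <- nrow(A); N <- 2 * K; L <- length(lo)
  X <- matrix(0, N, ncol(A))
  base <- 2 * (seq_len(K) - 1)
  for (n in seq_len(L)) {
    rows <- (base + n - 1) %% N + 1
    X[rows, ] <- X[rows, ] + lo[n] * A + hi[n] * D
  }
  X
}

.dwt_forward <- function(X, depth, lo = .db5_dec_lo, hi = .db5_dec_hi) {
  details <- vector("list", depth)
  for (j in seq_len(depth)) {
    lv <- .dwt_level(X, lo, hi)
    details[[j]] <- lv$D
    X <- lv$A
  }
  list(approx = X, details = details)
}

.dwt_inverse <- function(dec, lo = .db5_dec_lo, hi = .db5_dec_hi) {
  X <- dec$approx
  for (j in rev(seq_along(dec$details)))
    X <- .idwt_level(X, dec$details[[j]], lo, hi)
  X
}

#' Wavelet motion-artifact correction
#'
#' Per channel: periodized Daubechies-5 discrete wavelet transform;
#' detail coefficients falling outside \eqn{[Q_1 - k\,IQR,\; Q_3 +
#' k\,IQR]} at each level are set to zero (spike-like transients produce
#' exactly such outlying coefficients); inverse transform. The default
#' depth decomposes while each detail band's upper edge stays above
#' \code{f_protect}, so the low-frequency analysis band stays essentially
#' in the untouched approximation and every thresholded level retains
#' enough coefficients for stable quartile estimates. The window is
#' reflected-padded to a multiple of \eqn{2^{depth}} and truncated after
#' reconstruction.
#'
#' @param od an \code{od_window}.
#' @param iqr_k interquartile multiplier (default 1.2).
#' @param depth decomposition depth; default
#'   \code{ceiling(log2(fs / f_protect)) - 1}, reduced with a warning if
#'   the window is too short.
#' @param f_protect upper edge of the protected low-frequency band
#'   (default 0.08 Hz, the band-pass edge that follows).
#' @return corrected \code{od_window}, same shape.
#' @export
wavelet_motion_correct <- function(od, iqr_k = 1.2, depth = NULL,
                                   f_protect = 0.08) {
  stopifnot(inherits(od, "od_window"))
  n <- ncol(od$od)
  if (is.null(depth)) depth <- ceiling(log2(od$fs / f_protect)) - 1
  while (depth > 1 && n / 2^depth < length(.db5_dec_lo)) {
    depth <- depth - 1
    warning("window too short for requested depth; reduced to ", depth)
  }
  X <- t(od$od)                           # time x channels
  npad <- ceiling(n / 2^depth) * 2^depth
  if (npad > n) {
    extra <- npad - n
    X <- rbind(X, X[n:(n - extra + 1), , drop = FALSE])  # reflection
  }
  Xr <- .cpp_wavelet_correct(X, .db5_dec_lo, .db5_dec_hi, depth, iqr_k)
  out <- od
  out$od <- t(Xr[seq_len(n), , drop = FALSE])
  out
}

# pure-R reference path for the same operation (used as an independent
# cross-check of the compiled core in the test suite)
.wavelet_correct_r <- function(X, depth, iqr_k) {
  dec <- .dwt_forward(X, depth)
  for (j in seq_along(dec$details)) {
    D <- dec$details[[j]]
    for (ch in seq_len(ncol(D))) {
      q <- stats::quantile(D[, ch], c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      out <- D[, ch] < q[1] - iqr_k * iqr | D[, ch] > q[2] + iqr_k * iqr
      D[out, ch] <- 0
    }
    dec$details[[j]] <- D
  }
  .dwt_inverse(dec)
}

# direct-form IIR on the columns of a matrix: MA part by one-sided
# convolution, AR part by the recursive filter (a[1] normalized to 1)
.iir_mat <- function(b, a, X) {
  nb <- length(b)
  if (nb > 1) {
    Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
    Z <- stats::filter(Xp, b, method = "convolution", sides = 1)
    Z <- Z[nb:nrow(Xp), , drop = FALSE]
  } else Z <- b * X
  a <- a / a[1]
  if (length(a) > 1)
    Z <- stats::filter(Z, -a[-1], method = "recursive")
  matrix(as.numeric(Z), nrow(X), ncol(X))
}

# zero-phase forward-backward IIR with odd-reflection edge padding,
# vectorized over the columns of a time x channels matrix
.filtfilt_mat <- function(b, a, X, pad = NULL) {
  n <- nrow(X)
  if (is.null(pad)) pad <- min(n - 1, 500)
  top <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[pad + 1 - seq_len(pad) + 1, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[n - seq_len(pad), , drop = FALSE]
  Y <- rbind(top, X, bot)
  Y <- .iir_mat(b, a, Y)
  Y <- .iir_mat(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y <- Y[nrow(Y):1, , drop = FALSE]
  Y[pad + seq_len(n), , drop = FALSE]
}

# FFT brick-wall band-pass on a time x channels matrix (zero-phase)
.fft_bandpass <- function(X, fs, f_low, f_high) {
  n <- nrow(X)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                    # two-sided frequency magnitude
  keep <- f >= f_low & f <= f_high
  Y <- stats::mvfft(X)
  Y[!keep, ] <- 0
  Re(stats::mvfft(Y, inverse = TRUE)) / n
}

#' Zero-phase band-pass filter
#'
#' Order-3 Butterworth high-pass and low-pass sections applied
#' forward-backward (\code{signal::filtfilt}); the cascade of two order-3
#' sections is numerically stable at the extreme 0.009-Hz normalized
#' cutoff. An FFT brick-wall alternative is provided for verification.
#'
#' @param od an \code{od_window}.
#' @param f_low,f_high cut-off frequencies in Hz (defaults 0.009 and
#'   0.08).
#' @param method \code{"butter"} (default) or \code{"fft"}.
#' @param order Butterworth section order (default 3).
#' @return filtered \code{od_window}.
#' @export
bandpass_filter <- function(od, f_low = 0.009, f_high = 0.08,
                            method = c("butter", "fft"), order = 3) {
  stopifnot(inherits(od, "od_window"))
  if (f_low >= f_high) stop("f_low must be below f_high")
  if (od$fs <= 2 * f_high) stop("sampling rate too low for f_high")
  method <- match.arg(method)
  X <- t(od$od)
  if (method == "fft") {
    Xf <- .fft_bandpass(X, od$fs, f_low, f_high)
  } else {
    hp <- signal::butter(order, f_low / (od$fs / 2), type = "high")
    lp <- signal::butter(order, f_high / (od$fs / 2), type = "low")
    Xf <- .cpp_filtfilt2(X, hp$b, hp$a, lp$b, lp$a, 500L)
  }
  out <- od
  out$od <- t(Xf)
  out
}

#' Standard preprocessing chain for one 5-min window
#'
#' Fixed order: optical-density conversion, wavelet motion correction,
#' band-pass filtering.
#'
#' @param window a \code{dot_recording} window.
#' @param good optional logical channel mask (see
#'   \code{\link{intensity_to_od}}).
#' @param iqr_k,f_low,f_high stage parameters (see the stage functions).
#' @return preprocessed \code{od_window}.
#' @export
preprocess_window <- function(window, good = NULL, iqr_k = 1.2,
                              f_low = 0.009, f_high = 0.08) {
  od <- intensity_to_od(window, good)
  od <- wavelet_motion_correct(od, iqr_k = iqr_k)
  bandpass_filter(od, f_low, f_high)
}
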