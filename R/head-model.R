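#' Generate a hemispherical preterm head model and DOT montage
#'
#' Desk-scale stand-in for an atlas head mesh: a hemisphere of the given
#' scalp radius (default 44 mm, matching a 27.9-cm head circumference),
#' with a quasi-uniform cortical surface node set at a fixed depth below
#' the scalp, a regular volumetric grid filling a shell beneath the scalp,
#' the nine 10-20 landmarks (F3, FZ, F4, C3, CZ, C4, P3, PZ, P4) at fixed
#' spherical angles, and an 8-source / 8-detector montage at approximate
#' 10-5 positions giving 64 source-detector pairs per wavelength.
#'
#' @param radius_mm scalp radius in mm (default 44).
#' @param grid_mm volumetric grid spacing in mm (default 5); must be no
#'   coarser than \code{radius_mm / 4}.
#' @param cortex_depth_mm depth of the cortical surface below the scalp
#'   (default 7).
#' @param shell_mm volumetric shell: nodes with scalp depth in
#'   \code{[shell_mm[1], shell_mm[2]]} (default \code{c(3, 20)}).
#' @param n_surface number of cortical surface nodes (default 600).
#' @param wavelengths wavelengths in nm (default \code{c(780, 850)}).
#' @return list with \code{head} (class \code{head_model}: \code{surface}
#'   Nx3, \code{vol} Mx3, \code{node_volume_mm3}, \code{landmarks} 9x3,
#'   \code{radius_mm}, \code{grid_mm}, \code{cortex_depth_mm}) and
#'   \code{montage} (class \code{dot_montage}: \code{sources} 8x3,
#'   \code{detectors} 8x3, \code{channels} data.frame with one row per
#'   source-detector pair per wavelength).
#' @export
gen_head_model <- function(radius_mm = 44, grid_mm = 5,
                           cortex_depth_mm = 7, shell_mm = c(3, 20),
                           n_surface = 600, wavelengths = c(780, 850)) {
  if (grid_mm > radius_mm / 4)
    stop("grid coarser than radius/4: degenerate mesh")
  R <- radius_mm
  # Fibonacci hemisphere for the cortical surface
  i <- seq_len(n_surface) - 0.5
  z <- i / n_surface                       # uniform in z on (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(1 - z^2)
  Rc <- R - cortex_depth_mm
  surface <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z) * Rc
  # volumetric grid in a shell beneath the scalp
  g <- seq(-R, R, by = grid_mm)
  vol <- as.matrix(expand.grid(x = g, y = g, z = g[g >= 0]))
  r <- sqrt(rowSums(vol^2))
  keep <- r <= R - shell_mm[1] & r >= R - shell_mm[2]
  vol <- vol[keep, , drop = FALSE]
  dimnames(vol) <- list(NULL, c("x", "y", "z"))
  landmarks <- .landmark_unit * R
  sources <- .optode_unit$sources * R
  detectors <- .optode_unit$detectors * R
  pairs <- expand.grid(detector = seq_len(nrow(detectors)),
                       source = seq_len(nrow(sources)))
  sep <- sqrt(rowSums((sources[pairs$source, ] -
                       detectors[pairs$detector, ])^2))
  channels <- do.call(rbind, lapply(wavelengths, function(wl)
    data.frame(source = pairs$source, detector = pairs$detector,
               wavelength = wl, separation_mm = sep)))
  rownames(channels) <- NULL
  head <- structure(list(surface = surface, vol = vol,
                         node_volume_mm3 = grid_mm^3,
                         landmarks = landmarks, radius_mm = R,
                         grid_mm = grid_mm,
                         cortex_depth_mm = cortex_depth_mm),
                    class = "head_model")
  montage <- structure(list(sources = sources, detectors = detectors,
                            channels = channels, wavelengths = wavelengths),
                       class = "dot_montage")
  list(head = head, montage = montage)
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf(
    "<head_model> radius %g mm, %d surface / %d volumetric nodes (%g mm grid)\n",
    x$radius_mm, nrow(x$surface), nrow(x$vol), x$grid_mm))
  invisible(x)
}

#' @export
print.dot_montage <- function(x, ...) {
  cat(sprintf("<dot_montage> %d sources, %d detectors, %d channels\n",
              nrow(x$sources), nrow(x$detectors), nrow(x$channels)))
  invisible(x)
}

# diffusion Green's function for a CW semi-infinite medium with an
# extrapolated-boundary image source, evaluated radially from the optode's
# local surface normal. 'pos' optode scalp position; 'nodes' Mx3.
.green_semiinf <- function(pos, nodes, mua, musp, min_dist = 1) {
  D <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / D)
  z0 <- 1 / musp
  zb <- 2 * D                       # extrapolated boundary (Reff ~ 0)
  nrm <- pos / sqrt(sum(pos^2))
  p_real <- pos - z0 * nrm          # source sunk one transport length
  p_img <- pos + (z0 + 2 * zb) * nrm
  g <- function(p) {
    d <- sqrt(colSums((t(nodes) - p)^2))
    d <- pmax(d, min_dist)
    exp(-mueff * d) / (4 * pi * D * d)
  }
  pmax(g(p_real) - g(p_img), 0)
}

#' Analytic sensitivity (Jacobian) for a continuous-wave montage
#'
#' Adjoint (Rytov) sensitivity of each channel's optical density to a unit
#' absorption change at each volumetric node, for a homogeneous
#' semi-infinite medium:
#' \eqn{J(ch, node) = V \, G(s, node) G(node, d) / G(s, d)}, with G the
#' CW diffusion Green's function including an extrapolated-boundary image
#' source, and V the per-node volume. Entries are non-negative and decay
#' with depth. Node-optode distances are floored at 1 mm to regularize
#' near-coincident geometry.
#'
#' @param head a \code{head_model}.
#' @param montage a \code{dot_montage}.
#' @param mua,musp background absorption and reduced scattering, per mm;
#'   scalars or named vectors keyed by wavelength (defaults 0.01 and 1.0).
#' @return object of class \code{dot_jacobian}: list with per-wavelength
#'   matrices \code{J} (one per wavelength, pairs x nodes, units
#'   \eqn{\Delta OD} per mm\eqn{^{-1}} absorption change), the pair table
#'   \code{pairs} (source, detector, separation), \code{wavelengths},
#'   and \code{node_volume_mm3}.
#' @export
gen_jacobian <- function(head, montage, mua = 0.01, musp = 1.0) {
  stopifnot(inherits(head, "head_model"), inherits(montage, "dot_montage"))
  if (any(mua <= 0) || any(musp <= 0)) stop("mua and musp must be positive")
  wl <- montage$wavelengths
  getp <- function(x, w) {
    if (length(x) == 1) return(unname(x))
    if (!is.null(names(x)) && as.character(w) %in% names(x))
      return(unname(x[as.character(w)]))
    stop("per-wavelength optical property vector must be named by wavelength")
  }
  one_wl <- montage$channels[montage$channels$wavelength == wl[1],
                             c("source", "detector", "separation_mm")]
  V <- head$node_volume_mm3
  J <- lapply(wl, function(w) {
    ma <- getp(mua, w); ms <- getp(musp, w)
    Gs <- lapply(seq_len(nrow(montage$sources)), function(i)
      .green_semiinf(montage$sources[i, ], head$vol, ma, ms))
    Gd <- lapply(seq_len(nrow(montage$detectors)), function(i)
      .green_semiinf(montage$detectors[i, ], head$vol, ma, ms))
    m <- matrix(0, nrow(one_wl), nrow(head$vol))
    for (k in seq_len(nrow(one_wl))) {
      s <- one_wl$source[k]; d <- one_wl$detector[k]
      gsd <- .green_semiinf(montage$sources[s, ,  drop = TRUE],
                            matrix(montage$detectors[d, ], 1), ma, ms)
      m[k, ] <- V * Gs[[s]] * Gd[[d]] / max(gsd, 1e-300)
    }
    m
  })
  names(J) <- as.character(wl)
  structure(list(J = J, pairs = one_wl, wavelengths = wl,
                 node_volume_mm3 = V),
            class = "dot_jacobian")
}

#' @export
print.dot_jacobian <- function(x, ...) {
  cat(sprintf("<dot_jacobian> %d pairs x %d nodes at %s nm\n",
              nrow(x$pairs), ncol(x$J[[1]]),
              paste(x$wavelengths, collapse = "/")))
  invisible(x)
}
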