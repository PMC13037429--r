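#' Reconstruction configuration
#'
#' @param lambda Tikhonov regularization parameter (default 0.1).
#' @param extinction 2x2 extinction matrix, rows = wavelengths, columns =
#'   c(HbO, HbR) (default \code{\link{extinction_defaults}}).
#' @param surface_radius_mm volumetric-to-surface averaging radius
#'   (default 3).
#' @return validated list of class \code{recon_config}.
#' @export
recon_config <- function(lambda = 0.1, extinction = extinction_defaults(),
                         surface_radius_mm = 3) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (abs(det(extinction)) < 1e-300) stop("extinction matrix not invertible")
  structure(list(lambda = lambda, extinction = extinction,
                 surface_radius_mm = surface_radius_mm),
            class = "recon_config")
}

#' Tikhonov-regularized pseudoinverse of a Jacobian
#'
#' \deqn{J^\# = J^T (J J^T + \lambda\, s_{max} I)^{-1}}
#' with \eqn{s_{max}} the largest singular value of \eqn{J J^T} (computed
#' as the largest eigenvalue of the symmetric product). The inverse is
#' applied via a symmetric linear solve, not explicit inversion.
#'
#' @param J channels x nodes matrix.
#' @param lambda regularization parameter (default 0.1).
#' @return nodes x channels matrix \eqn{J^\#}.
#' @export
tikhonov_pseudoinverse <- function(J, lambda = 0.1) {
  J <- as.matrix(J)
  if (all(J == 0)) stop("J is zero")
  JJt <- tcrossprod(J)
  smax <- max(eigen(JJt, symmetric = TRUE, only.values = TRUE)$values)
  M <- JJt + diag(lambda * smax, nrow(JJt))
  sol <- tryCatch(solve(M, J), error = function(e)
    stop("singular system; use lambda > 0 for rank-deficient J"))
  t(sol)
}

#' Reconstruct absorption changes from optical density
#'
#' \eqn{\Delta\mu_a(t) = J^\# \Delta OD(t)} applied sample-wise; linear in
#' the input. \code{J#} must have been built from the same good-channel
#' subset as the OD rows supplied.
#'
#' @param Jsharp nodes x channels pseudoinverse.
#' @param od channels x samples OD matrix (one wavelength).
#' @return nodes x samples matrix of absorption changes (per mm).
#' @export
reconstruct_mua <- function(Jsharp, od) {
  if (ncol(Jsharp) != nrow(od))
    stop("dimension mismatch between J# and OD window")
  Jsharp %*% od
}

#' Spectral unmixing of absorption changes to hemoglobin
#'
#' Per node and sample solves the 2x2 modified Beer-Lambert system
#' \eqn{[\Delta\mu_a^{780}; \Delta\mu_a^{850}] = \ln 10 \cdot E \cdot
#' [\Delta HbO; \Delta HbR]}.
#'
#' @param dmua_780,dmua_850 nodes x samples absorption changes.
#' @param extinction 2x2 base-10 extinction matrix (mm^-1/uM).
#' @param cond_warn warn if the condition number of E exceeds this bound
#'   (default 100).
#' @return list with \code{HbO} and \code{HbR} (nodes x samples, uM).
#' @export
unmix_hemoglobin <- function(dmua_780, dmua_850,
                             extinction = extinction_defaults(),
                             cond_warn = 100) {
  E <- log(10) * extinction
  if (kappa(E) > cond_warn)
    warning("extinction matrix poorly conditioned (kappa > ", cond_warn, ")")
  Einv <- solve(E)
  list(HbO = Einv[1, 1] * dmua_780 + Einv[1, 2] * dmua_850,
       HbR = Einv[2, 1] * dmua_780 + Einv[2, 2] * dmua_850)
}

# neighbor lists: for each surface node, volumetric nodes within radius;
# empty neighborhoods fall back to the nearest volumetric node (flagged)
.surface_neighbors <- function(head, radius_mm) {
  d2 <- .pairwise_dist2(head$surface, head$vol)
  lapply(seq_len(nrow(head$surface)), function(i) {
    idx <- which(d2[i, ] <= radius_mm^2)
    if (length(idx) == 0)
      list(idx = which.min(d2[i, ]), fallback = TRUE)
    else list(idx = idx, fallback = FALSE)
  })
}

#' Map a volumetric node series onto the cortical surface
#'
#' Each surface node receives the mean of the volumetric values within a
#' 3-mm-radius sphere centered on it; a surface node with an empty sphere
#' (possible on coarse grids) receives the nearest volumetric node's value
#' and is flagged.
#'
#' @param vol_series nodes x samples matrix (or vector) of volumetric
#'   values.
#' @param head a \code{head_model}.
#' @param radius_mm averaging radius (default 3).
#' @return list with \code{values} (surface nodes x samples) and
#'   \code{fallback} (logical per surface node).
#' @export
map_to_surface <- function(vol_series, head, radius_mm = 3) {
  stopifnot(inherits(head, "head_model"))
  if (is.vector(vol_series)) vol_series <- matrix(vol_series, ncol = 1)
  nb <- .surface_neighbors(head, radius_mm)
  W <- .surface_weights(nb, nrow(vol_series))
  list(values = W %*% vol_series,
       fallback = vapply(nb, `[[`, logical(1), "fallback"))
}

# sparse-ish averaging operator as a dense matrix (surface x vol)
.surface_weights <- function(nb, nvol) {
  W <- matrix(0, length(nb), nvol)
  for (i in seq_along(nb)) W[i, nb[[i]]$idx] <- 1 / length(nb[[i]]$idx)
  W
}

#' Reconstruct hemoglobin surface series for one preprocessed window
#'
#' Full explicit chain: per-wavelength Tikhonov reconstruction of
#' \eqn{\Delta\mu_a}, per-node spectral unmixing, volumetric-to-surface
#' mapping.
#'
#' @param od a preprocessed \code{od_window} (both wavelengths).
#' @param jacobian a \code{dot_jacobian}.
#' @param head the matching \code{head_model}.
#' @param mask a \code{channel_mask}; only usable pairs enter the
#'   inversion (default: all pairs).
#' @param config a \code{\link{recon_config}}.
#' @return list with surface \code{HbO} and \code{HbR} (surface nodes x
#'   samples), the volumetric series, and the \code{fallback} flags.
#' @export
reconstruct_window <- function(od, jacobian, head, mask = NULL,
                               config = recon_config()) {
  stopifnot(inherits(od, "od_window"))
  npair <- nrow(jacobian$pairs)
  keep <- if (is.null(mask)) rep(TRUE, npair) else mask$pair_good
  wl <- jacobian$wavelengths
  mua <- lapply(seq_along(wl), function(w) {
    rows <- which(od$channels$wavelength == wl[w])[keep]
    Jm <- jacobian$J[[w]][keep, , drop = FALSE]
    Js <- tikhonov_pseudoinverse(Jm, config$lambda)
    reconstruct_mua(Js, od$od[rows, , drop = FALSE])
  })
  hb <- unmix_hemoglobin(mua[[1]], mua[[2]], config$extinction)
  sHbO <- map_to_surface(hb$HbO, head, config$surface_radius_mm)
  sHbR <- map_to_surface(hb$HbR, head, config$surface_radius_mm)
  list(HbO = sHbO$values, HbR = sHbR$values,
       vol = list(HbO = hb$HbO, HbR = hb$HbR, dmua = mua),
       fallback = sHbO$fallback)
}
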