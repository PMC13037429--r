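#' Build the nine connectivity ROIs on the cortical surface
#'
#' Surface nodes within 15 mm of each 10-20 landmark form the candidate
#' membership. Every node carries a unique label: a node inside both a
#' central (FZ, CZ, PZ) and a lateral sphere is assigned to the lateral
#' one; remaining multi-sphere nodes go to the nearest center. Nodes with
#' surface-mapped sensitivity at or above the coverage threshold count as
#' covered; an ROI is included only if at least one third of its member
#' nodes are covered.
#'
#' @param head a \code{head_model}.
#' @param sensitivity per-surface-node sensitivity (e.g. a volumetric
#'   \code{\link{sensitivity_map}} passed through
#'   \code{\link{map_to_surface}}).
#' @param cthresh coverage threshold (see
#'   \code{\link{coverage_threshold}}).
#' @param radius_mm ROI sphere radius (default 15).
#' @param min_coverage_frac inclusion fraction (default 1/3).
#' @return object of class \code{roi_set}: per-ROI lists with
#'   \code{members}, \code{covered}, \code{included}, plus \code{names}.
#' @export
build_rois <- function(head, sensitivity, cthresh, radius_mm = 15,
                       min_coverage_frac = 1 / 3) {
  stopifnot(inherits(head, "head_model"))
  lm <- head$landmarks
  if (nrow(lm) != 9) stop("expected 9 landmarks")
  central <- rownames(lm) %in% c("FZ", "CZ", "PZ")
  d2 <- .pairwise_dist2(head$surface, lm)
  inside <- d2 <= radius_mm^2
  label <- rep(NA_integer_, nrow(head$surface))
  for (i in seq_len(nrow(head$surface))) {
    hits <- which(inside[i, ])
    if (length(hits) == 0) next
    lat <- hits[!central[hits]]
    pool <- if (length(lat) > 0) lat else hits  # lateral precedence
    label[i] <- pool[which.min(d2[i, pool])]
  }
  rois <- lapply(seq_len(9), function(j) {
    members <- which(label == j)
    covered <- members[sensitivity[members] >= cthresh]
    included <- length(members) > 0 &&
      length(covered) >= min_coverage_frac * length(members)
    if (length(members) == 0)
      warning("ROI ", rownames(lm)[j], " has no member nodes; excluded")
    list(members = members, covered = covered, included = included)
  })
  names(rois) <- rownames(lm)
  structure(list(rois = rois, names = rownames(lm)), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  inc <- vapply(x$rois, `[[`, logical(1), "included")
  cat(sprintf("<roi_set> %d/9 ROIs included (%s)\n", sum(inc),
              paste(x$names[inc], collapse = ", ")))
  invisible(x)
}

#' ROI-average time courses
#'
#' Per included ROI, the mean over covered member nodes at each sample;
#' excluded ROIs yield rows of \code{NA}.
#'
#' @param surface_series surface nodes x samples matrix.
#' @param rois a \code{\link{build_rois}} result on the same model.
#' @return 9 x samples matrix, rownames = ROI names.
#' @export
roi_timecourses <- function(surface_series, rois) {
  stopifnot(inherits(rois, "roi_set"))
  out <- matrix(NA_real_, 9, ncol(surface_series),
                dimnames = list(rois$names, NULL))
  for (j in seq_len(9)) {
    r <- rois$rois[[j]]
    if (!r$included || length(r$covered) == 0) next
    out[j, ] <- colMeans(surface_series[r$covered, , drop = FALSE])
  }
  out
}

#' Fisher Z transform with clipping
#'
#' \eqn{Z = \mathrm{atanh}(R)} with \eqn{|R|} clipped to
#' \code{1 - clip} so degenerate identical signals give a finite sentinel.
#'
#' @param r correlation value(s).
#' @param clip clipping margin (default 1e-7).
#' @return Fisher Z value(s).
#' @export
fisher_z <- function(r, clip = 1e-7) {
  atanh(pmin(pmax(r, -(1 - clip)), 1 - clip))
}

#' Task-free connectivity matrix of a window
#'
#' Pairwise Pearson correlations between ROI time courses over the 5-min
#' window, with the Fisher Z transform. Pairs involving an excluded ROI
#' (or a zero-variance course, warned) are missing.
#'
#' @param roi_courses 9 x samples matrix from
#'   \code{\link{roi_timecourses}}.
#' @param chromophore,window optional tags carried on the result.
#' @return object of class \code{tffc_matrix} with 9x9 \code{R} and
#'   \code{Z} and the tags.
#' @export
tffc_matrix <- function(roi_courses, chromophore = NA, window = NA) {
  ok <- rowSums(is.na(roi_courses)) == 0
  if (sum(ok) < 2) stop("need at least 2 included ROIs")
  if (ncol(roi_courses) < 100) stop("need at least 100 samples")
  sds <- apply(roi_courses[ok, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance ROI course; its pairs recorded missing")
    ok[ok][sds == 0] <- FALSE
  }
  R <- matrix(NA_real_, 9, 9, dimnames = dimnames(roi_courses)[c(1, 1)])
  R[ok, ok] <- stats::cor(t(roi_courses[ok, , drop = FALSE]))
  diag(R)[ok] <- 1
  structure(list(R = R, Z = fisher_z(R),
                 chromophore = chromophore, window = window),
            class = "tffc_matrix")
}

#' @export
print.tffc_matrix <- function(x, ...) {
  cat(sprintf("<tffc_matrix> %s / %s: %d ROI pairs defined\n",
              x$chromophore, x$window,
              sum(!is.na(x$Z[upper.tri(x$Z)]))))
  invisible(x)
}

#' Group t-value of one ROI pair's Fisher Z scores
#'
#' \eqn{t = \bar Z / (sd(Z)/\sqrt{n})} with a two-sided p-value on
#' \eqn{n - 1} degrees of freedom; missing patients are dropped and n
#' adjusted.
#'
#' @param z numeric vector of per-patient Fisher Z values (NA allowed).
#' @return named vector \code{c(t, p, n)}; \code{t} is \code{Inf} with
#'   \code{p = 0} if the Z values are identical and nonzero (documented
#'   sentinel), and an error is raised if they are identical at zero.
#' @export
group_t <- function(z) {
  z <- z[!is.na(z)]
  n <- length(z)
  if (n < 2) stop("need at least 2 non-missing Z values")
  s <- stats::sd(z)
  if (s == 0) {
    if (mean(z) == 0) stop("degenerate: all Z equal zero")
    return(c(t = Inf * sign(mean(z)), p = 0, n = n))
  }
  t <- mean(z) / (s / sqrt(n))
  c(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), n = n)
}

#' Per-pair group statistics of a window's connectivity stack
#'
#' @param z_stack patients x pairs matrix of Fisher Z values (pairs =
#'   upper triangle, see \code{\link{stack_z}}).
#' @return data.frame with \code{pair}, \code{t}, \code{p}, \code{p_fdr},
#'   \code{n} (BH-FDR within the stack's pair family).
#' @export
group_stats <- function(z_stack) {
  res <- t(apply(z_stack, 2, function(z)
    tryCatch(group_t(z), error = function(e) c(t = NA, p = NA, n = 0))))
  out <- data.frame(pair = colnames(z_stack), t = res[, "t"],
                    p = res[, "p"], n = res[, "n"],
                    stringsAsFactors = FALSE)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Flatten tfFC matrices into a patients x pairs stack
#'
#' @param mats list of \code{tffc_matrix} objects (one per patient).
#' @return patients x 36 matrix of upper-triangle Z values, with
#'   "A-B" pair names.
#' @export
stack_z <- function(mats) {
  nm <- rownames(mats[[1]]$Z)
  ut <- which(upper.tri(mats[[1]]$Z))
  pairs <- outer(nm, nm, paste, sep = "-")[ut]
  out <- t(vapply(mats, function(m) m$Z[ut], numeric(length(ut))))
  colnames(out) <- pairs
  out
}

#' Two-sample comparison of connectivity between windows
#'
#' Per ROI pair, an unpaired two-sample t-test (pooled variance by
#' default; Welch and paired variants available) between the patients'
#' Fisher Z values in the first and last windows.
#'
#' @param z_first,z_last patients x pairs Z stacks.
#' @param variant \code{"student"} (default), \code{"welch"} or
#'   \code{"paired"}.
#' @return data.frame with \code{pair}, \code{t}, \code{p}, \code{p_fdr},
#'   \code{n1}, \code{n2}; pairs with insufficient n are flagged NA.
#' @export
window_comparison <- function(z_first, z_last,
                              variant = c("student", "welch", "paired")) {
  variant <- match.arg(variant)
  stopifnot(identical(colnames(z_first), colnames(z_last)))
  res <- lapply(seq_len(ncol(z_first)), function(j) {
    a <- z_first[, j]; b <- z_last[, j]
    if (variant == "paired") {
      ok <- !is.na(a) & !is.na(b)
      a <- a[ok]; b <- b[ok]
      if (length(a) < 2) return(c(NA, NA, length(a), length(a)))
      tt <- stats::t.test(b, a, paired = TRUE)
      return(c(tt$statistic, tt$p.value, length(a), length(a)))
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      return(c(NA, NA, length(a), length(b)))
    tt <- stats::t.test(b, a, var.equal = (variant == "student"))
    c(tt$statistic, tt$p.value, length(a), length(b))
  })
  res <- do.call(rbind, res)
  out <- data.frame(pair = colnames(z_first), t = res[, 1], p = res[, 2],
                    n1 = res[, 3], n2 = res[, 4], stringsAsFactors = FALSE)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- bh_fdr(out$p[ok])
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up FDR adjustment (delegates to
#' \code{stats::p.adjust(method = "BH")}): sort ascending,
#' \eqn{adj_{(i)} = \min_{j \ge i} p_{(j)} m / j} capped at 1, restored to
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
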