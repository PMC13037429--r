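#' Per-patient connectivity change between windows
#'
#' \eqn{\Delta Z = Z_{last} - Z_{first}} elementwise; missing wherever
#' either side is missing.
#'
#' @param z_first,z_last patients x pairs Fisher Z stacks (see
#'   \code{\link{stack_z}}) or two \code{tffc_matrix} objects of one
#'   patient.
#' @return object of the same shape as the inputs.
#' @export
delta_tffc <- function(z_first, z_last) {
  if (inherits(z_first, "tffc_matrix")) {
    stopifnot(inherits(z_last, "tffc_matrix"))
    return(z_last$Z - z_first$Z)
  }
  stopifnot(identical(dim(z_first), dim(z_last)))
  z_last - z_first
}

#' Correlate connectivity changes with glucose metrics
#'
#' Pearson correlation of each ROI pair's \eqn{\Delta Z} with each of the
#' eight glucose metrics across patients, two-sided p-values, and BH-FDR
#' across the family of all (pair, metric) cells within a chromophore.
#' Cells with fewer than \code{min_n} complete observations, or a constant
#' metric or constant \eqn{\Delta Z}, are skipped with a flag.
#'
#' @param delta_stack patients x pairs \eqn{\Delta Z} matrix.
#' @param metrics patients x metrics matrix (columns named, typically the
#'   eight of \code{\link{glucose_metrics}}).
#' @param min_n minimum complete observations per cell (default 3).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param fdr_family \code{"all"} (default: one BH family over every
#'   tested cell) or \code{"per_metric"}.
#' @return data.frame with \code{pair}, \code{metric}, \code{r}, \code{p},
#'   \code{p_fdr}, \code{n}, \code{skipped}.
#' @export
correlate_with_metrics <- function(delta_stack, metrics, min_n = 3,
                                   method = c("pearson", "spearman"),
                                   fdr_family = c("all", "per_metric")) {
  method <- match.arg(method)
  fdr_family <- match.arg(fdr_family)
  stopifnot(nrow(delta_stack) == nrow(metrics))
  cells <- expand.grid(pair = colnames(delta_stack),
                       metric = colnames(metrics),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    dz <- delta_stack[, cells$pair[i]]
    gm <- metrics[, cells$metric[i]]
    ok <- !is.na(dz) & !is.na(gm)
    n <- sum(ok)
    if (n < min_n || stats::sd(dz[ok]) == 0 || stats::sd(gm[ok]) == 0)
      return(c(r = NA, p = NA, n = n, skipped = 1))
    ct <- stats::cor.test(dz[ok], gm[ok], method = method, exact = FALSE)
    c(r = unname(ct$estimate), p = ct$p.value, n = n, skipped = 0)
  })
  res <- do.call(rbind, res)
  out <- cbind(cells, as.data.frame(res))
  out$skipped <- out$skipped == 1
  out$p_fdr <- NA_real_
  if (fdr_family == "all") {
    ok <- !out$skipped
    out$p_fdr[ok] <- bh_fdr(out$p[ok])
  } else {
    for (m in unique(out$metric)) {
      ok <- !out$skipped & out$metric == m
      out$p_fdr[ok] <- bh_fdr(out$p[ok])
    }
  }
  out
}
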