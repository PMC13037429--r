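#' Collapsed ROI projection operator
#'
#' The whole chain Tikhonov reconstruction -> spectral unmixing ->
#' surface mapping -> covered-node ROI averaging is linear and
#' time-separable, so for a fixed channel mask it collapses to one
#' 9 x channels operator per wavelength and chromophore:
#' \deqn{ROI_{HbX}(t) = E^{-1}_{X,780}\, T_{780}\, \Delta OD_{780}(t) +
#'   E^{-1}_{X,850}\, T_{850}\, \Delta OD_{850}(t)}
#' with \eqn{T_w = R\, W\, J^\#_w} (R the covered-node ROI averaging, W
#' the surface mapping). The result is algebraically identical to the
#' explicit \code{\link{reconstruct_window}} path (asserted in the test
#' suite) at a fraction of the cost.
#'
#' @param jacobian,head model objects.
#' @param rois a \code{\link{build_rois}} result.
#' @param mask optional \code{channel_mask} (default: all pairs usable).
#' @param config a \code{\link{recon_config}}.
#' @return object of class \code{roi_projection} with per-chromophore
#'   lists of per-wavelength 9 x n_good_pairs matrices, the pair subset,
#'   and the ROI inclusion flags.
#' @export
roi_projection <- function(jacobian, head, rois, mask = NULL,
                           config = recon_config()) {
  npair <- nrow(jacobian$pairs)
  keep <- if (is.null(mask)) rep(TRUE, npair) else mask$pair_good
  included <- vapply(rois$rois, `[[`, logical(1), "included")
  Rmat <- matrix(0, 9, nrow(head$surface))
  for (j in seq_len(9)) {
    r <- rois$rois[[j]]
    if (r$included && length(r$covered) > 0)
      Rmat[j, r$covered] <- 1 / length(r$covered)
  }
  W <- .surface_weights(.surface_neighbors(head, config$surface_radius_mm),
                        nrow(head$vol))
  RW <- Rmat %*% W
  Tw <- lapply(jacobian$J, function(J) {
    Js <- tikhonov_pseudoinverse(J[keep, , drop = FALSE], config$lambda)
    RW %*% Js
  })
  Einv <- solve(log(10) * config$extinction)
  structure(list(T = Tw, Einv = Einv, keep = keep, included = included,
                 roi_names = rois$names,
                 wavelengths = jacobian$wavelengths),
            class = "roi_projection")
}

#' Apply a collapsed ROI projection to a preprocessed window
#'
#' @param proj a \code{\link{roi_projection}}.
#' @param od a preprocessed \code{od_window}.
#' @return list with \code{HbO} and \code{HbR} 9 x samples ROI courses
#'   (\code{NA} rows for excluded ROIs).
#' @export
project_roi_courses <- function(proj, od) {
  wl <- proj$wavelengths
  odw <- lapply(seq_along(wl), function(w) {
    rows <- which(od$channels$wavelength == wl[w])[proj$keep]
    od$od[rows, , drop = FALSE]
  })
  mix <- function(k) {
    out <- proj$Einv[k, 1] * (proj$T[[1]] %*% odw[[1]]) +
      proj$Einv[k, 2] * (proj$T[[2]] %*% odw[[2]])
    out[!proj$included, ] <- NA_real_
    rownames(out) <- proj$roi_names
    out
  }
  list(HbO = mix(1), HbR = mix(2))
}

# resting-state-like baseline ROI correlation: Gaussian distance kernel
# plus a common physiological component; positive definite by construction
.baseline_roi_corr <- function(head, scale_mm = 40, common = 0.15,
                               local = 0.5) {
  d2 <- .pairwise_dist2(head$landmarks, head$landmarks)
  C <- common + local * exp(-d2 / scale_mm^2)
  diag(C) <- 1
  C
}

# set one pair's correlation, shrinking toward the base matrix until the
# result stays positive definite
.set_pair_corr <- function(C, i, j, r) {
  out <- C
  out[i, j] <- out[j, i] <- r
  for (k in 0:20) {
    if (min(eigen(out, symmetric = TRUE,
                  only.values = TRUE)$values) > 1e-6) return(out)
    r <- 0.8 * r + 0.2 * C[i, j]
    out[i, j] <- out[j, i] <- r
  }
  C
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Each patient receives a CGM trace (AR(1) euglycemic baseline with a
#' patient-specific number and severity of glycemic excursions, giving a
#' realistic spread of glucose variability across the cohort) and one DOT
#' recording per analysis window carrying band-limited ROI hemodynamics
#' with a known correlation structure. A cohort-level linear relation
#' between the glucose SD metric and the planted connectivity change
#' \eqn{\Delta Z} of one ROI pair is injected at a chosen population
#' correlation: \eqn{\Delta Z_i = b\,SD_i + \varepsilon_i} with the noise
#' variance set from the realized SD spread so that
#' \eqn{cor(SD, \Delta Z) = planted\_r} in population.
#'
#' @param n_patients cohort size (default 12).
#' @param planted_r population correlation between glucose SD and the
#'   planted pair's \eqn{\Delta Z} (default 0.9; 0 gives a null cohort
#'   whose \eqn{\Delta Z} noise has the same marginal SD).
#' @param planted_pair character pair of ROI names (default
#'   \code{c("F3", "P3")}).
#' @param delta_sd SD across patients of the systematic \eqn{\Delta Z}
#'   component (default 0.75, matching the magnitude of connectivity
#'   change implied by the reported cohort-level associations; well above
#'   the 5-min Fisher-Z estimation noise floor).
#' @param seed integer seed.
#' @param head,jacobian shared model objects (defaults generated at
#'   package defaults).
#' @param rec_minutes length of each per-window recording (default 5).
#' @param cgm_minutes CGM trace length (default 2880, i.e. 2 days).
#' @param spec_base baseline \code{\link{connectivity_spec}}; default
#'   uses the distance-kernel ROI correlation.
#' @param art per-window \code{\link{artifact_spec}} (default: none).
#' @return list of class \code{synthetic_cohort}: \code{patients} (each
#'   with \code{trace}, \code{recordings$first/last}, \code{truth}),
#'   shared \code{head}, \code{jacobian}, and \code{truth} (planted pair,
#'   per-patient \eqn{\Delta Z}, glucose SDs).
#' @export
simulate_cohort <- function(n_patients = 12, planted_r = 0.9,
                            planted_pair = c("F3", "P3"), delta_sd = 0.75,
                            seed = 1L, head = NULL, jacobian = NULL,
                            rec_minutes = 5, cgm_minutes = 2880,
                            spec_base = NULL, art = artifact_spec()) {
  if (is.null(head)) {
    hm <- gen_head_model()
    head <- hm$head
    if (is.null(jacobian)) jacobian <- gen_jacobian(hm$head, hm$montage)
  }
  stopifnot(!is.null(jacobian))
  rng <- .seeded_rng(seed)
  base_corr <- if (is.null(spec_base)) .baseline_roi_corr(head) else
    spec_base$roi_corr
  roi_names <- rownames(head$landmarks)
  ip <- match(planted_pair, roi_names)
  if (any(is.na(ip))) stop("unknown planted ROI pair")
  # pass 1: CGM traces with patient-specific severity
  traces <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sev <- rng$runif(1)
    n_ev <- 1 + floor(rng$runif(1) * 3)
    ev_start <- sort(200 + rng$runif(n_ev) * (cgm_minutes - 800))
    ev_start <- ev_start - (ev_start %% 5)
    klass <- ifelse(rng$runif(n_ev) < 0.7,
                    ifelse(rng$runif(n_ev) < 0.2 + 0.6 * sev, "S_hyper",
                           "m_hyper"),
                    ifelse(rng$runif(n_ev) < 0.2 + 0.6 * sev, "S_hypo",
                           "m_hypo"))
    plateau <- vapply(klass, function(k) switch(k,
      S_hyper = 185 + 40 * sev, m_hyper = 150 + 25 * sev,
      S_hypo = 44 - 10 * sev, m_hypo = 65 - 12 * sev), numeric(1))
    dur <- 25 + round(rng$runif(n_ev) * 12 * (1 + 2 * sev)) * 5
    ev <- data.frame(klass = klass, start_min = ev_start,
                     duration_min = dur, plateau_mgdl = plateau)
    ev <- ev[c(TRUE, diff(ev$start_min) > dur[-length(dur)] + 30), ,
             drop = FALSE]
    p <- cgm_sim_params(cgm_minutes, baseline_sd = 6 + 8 * sev,
                        events = ev,
                        seed = floor(rng$runif(1) * 2^30))
    traces[[i]] <- gen_cgm_trace(p)
  }
  sds <- vapply(traces, function(tr) glucose_metrics(tr)["sd"], numeric(1))
  # pass 2: planted delta-Z from the realized SD spread
  sd_c <- sds - mean(sds)
  b <- if (stats::sd(sds) > 0) delta_sd / stats::sd(sds) else 0
  if (planted_r > 0) {
    eps_sd <- delta_sd * sqrt(1 / planted_r^2 - 1)
    delta <- b * sd_c + rng$rnorm(n_patients) * eps_sd
  } else {
    delta <- rng$rnorm(n_patients) * delta_sd
  }
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    z0 <- fisher_z(base_corr[ip[1], ip[2]])
    r1 <- tanh(z0 + delta[i])
    corr_last <- .set_pair_corr(base_corr, ip[1], ip[2], r1)
    spec_first <- connectivity_spec(roi_corr = base_corr)
    spec_last <- connectivity_spec(roi_corr = corr_last)
    rec <- lapply(list(first = spec_first, last = spec_last), function(sp)
      gen_dot_recording(head, jacobian, sp, art,
                        duration_s = rec_minutes * 60,
                        seed = floor(rng$runif(1) * 2^30)))
    patients[[i]] <- list(trace = traces[[i]], recordings = rec,
                          truth = list(delta_z = delta[i],
                                       corr_first = base_corr,
                                       corr_last = corr_last))
  }
  structure(list(patients = patients, head = head, jacobian = jacobian,
                 truth = list(planted_pair = planted_pair,
                              planted_r = planted_r, delta = delta,
                              glucose_sd = unname(sds))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, planted %s-%s r=%g\n",
              length(x$patients), x$truth$planted_pair[1],
              x$truth$planted_pair[2], x$truth$planted_r))
  invisible(x)
}

#' Analyze a cohort's per-window recordings
#'
#' For every patient and window: preprocess (OD, wavelet motion
#' correction, band-pass), project to ROI courses through the collapsed
#' reconstruction operator, and compute the tfFC matrices. Then, at the
#' cohort level: per-window group t-values, the first-vs-last window
#' comparison, per-patient \eqn{\Delta Z}, and the association of
#' \eqn{\Delta Z} with the eight glucose metrics, all BH-FDR corrected.
#'
#' @param cohort a \code{\link{simulate_cohort}} result (or a list with
#'   the same structure built from real data readers).
#' @param config a \code{\link{recon_config}}.
#' @param cov a \code{\link{coverage_params}}; default uses the model's
#'   node volume.
#' @param chromophore which chromophore drives the association stage
#'   (default \code{"HbO"}).
#' @return list of class \code{cohort_results}: \code{z_first},
#'   \code{z_last} (patient x pair stacks per chromophore),
#'   \code{group_first}, \code{group_last}, \code{comparison},
#'   \code{delta}, \code{metrics}, \code{association}, \code{rois}.
#' @export
analyze_cohort <- function(cohort, config = recon_config(), cov = NULL,
                           chromophore = "HbO") {
  head <- cohort$head; jac <- cohort$jacobian
  if (is.null(cov)) cov <- coverage_params(vhat = head$node_volume_mm3,
                                           reading = "multiply")
  cthresh <- coverage_threshold(cov)
  all_good <- channel_mask(rep(TRUE, nrow(.channel_table(jac))),
                           channels = .channel_table(jac))
  smap <- sensitivity_map(jac, all_good)
  ssens <- map_to_surface(smap$sensitivity, head,
                          config$surface_radius_mm)$values[, 1]
  rois <- build_rois(head, ssens, cthresh)
  proj <- roi_projection(jac, head, rois, mask = all_good, config = config)
  mats <- lapply(cohort$patients, function(p) {
    lapply(p$recordings, function(rec) {
      od <- preprocess_window(rec)
      rc <- project_roi_courses(proj, od)
      lapply(rc, function(m) tffc_matrix(m))
    })
  })
  stacks <- function(win, chrom)
    stack_z(lapply(mats, function(m) m[[win]][[chrom]]))
  out <- list(rois = rois)
  for (ch in c("HbO", "HbR")) {
    out$z_first[[ch]] <- stacks("first", ch)
    out$z_last[[ch]] <- stacks("last", ch)
    out$group_first[[ch]] <- group_stats(out$z_first[[ch]])
    out$group_last[[ch]] <- group_stats(out$z_last[[ch]])
    out$comparison[[ch]] <- window_comparison(out$z_first[[ch]],
                                              out$z_last[[ch]])
    out$delta[[ch]] <- delta_tffc(out$z_first[[ch]], out$z_last[[ch]])
  }
  out$metrics <- .metrics_matrix(cohort$patients)
  out$association <- correlate_with_metrics(out$delta[[chromophore]],
                                            out$metrics)
  structure(out, class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  nsig <- sum(x$association$p_fdr <= 0.05, na.rm = TRUE)
  cat(sprintf(
    "<cohort_results> %d patients, %d FDR-significant association cells\n",
    nrow(x$metrics), nsig))
  invisible(x)
}

#' Full-pipeline configuration with study defaults
#'
#' Bundles every tunable at its published default: glycemic thresholds,
#' the 45-min critical gap, the 510-min span separation, channel pruning
#' bounds (dRange, SNR), PSD screening bands and thresholds, coverage
#' parameters, the 0.009-0.08 Hz band, wavelet iqr 1.2, Tikhonov lambda
#' 0.1, 15-mm ROI radius, 3-mm surface mapping, FDR q 0.05.
#'
#' @param seed integer seed recorded in provenance.
#' @param ... overrides for any listed field.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    critical_gap_min = 45, min_gap_min = 510, window_min = 5,
    search_step_min = 1,
    d_low = 5e-4, d_high = 3, snr_min = 1,
    psd_low_band = c(0.05, 2), psd_low_thresh = 0.09,
    psd_high_band = c(3, 4), psd_high_thresh = 0.01,
    pthresh = 1, actvol = 10, dmua = 0.001,
    f_low = 0.009, f_high = 0.08, iqr_k = 1.2,
    lambda = 0.1, roi_radius_mm = 15, surface_radius_mm = 3,
    fdr_q = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full analysis end to end on a cohort
#'
#' Orchestrates every stage in order: glycemic event classification,
#' cohort-level critical gap, patient inclusion rules, euglycemic span
#' delimitation, best-window selection inside each span's recording,
#' preprocessing, explicit Tikhonov reconstruction, ROI connectivity,
#' group and window-comparison statistics, and the \eqn{\Delta Z}-vs-
#' glucose association. Stage errors are logged per patient and the
#' cohort stages proceed with the remaining patients.
#'
#' @param cohort a \code{synthetic_cohort} (recordings are interpreted as
#'   covering the euglycemic spans; window selection runs inside each
#'   recording).
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{run_results}: per-patient \code{events},
#'   \code{spans}, \code{windows}, \code{masks}; inclusion table;
#'   cohort-level results as in \code{\link{analyze_cohort}};
#'   \code{exclusion_log}; and a \code{provenance} record.
#' @export
run_all <- function(cohort, config = run_config()) {
  cfg <- config
  head <- cohort$head; jac <- cohort$jacobian
  cov <- coverage_params(pthresh = cfg$pthresh, actvol = cfg$actvol,
                         vhat = head$node_volume_mm3, dmua = cfg$dmua,
                         reading = "multiply")
  rcfg <- recon_config(lambda = cfg$lambda,
                       surface_radius_mm = cfg$surface_radius_mm)
  events <- lapply(cohort$patients, function(p) classify_events(p$trace))
  all_dur <- unlist(lapply(events, function(e) e$duration_min))
  cgap <- if (length(all_dur) > 0) critical_gap(all_dur) else
    cfg$critical_gap_min
  pat_in <- lapply(seq_along(cohort$patients), function(i) {
    p <- cohort$patients[[i]]
    span_total <- diff(range(p$trace$t)) + 5
    list(trace = p$trace,
         dot_intervals = matrix(c(0, span_total), 1))
  })
  incl <- apply_inclusion_rules(pat_in, gap_min = cgap,
                                min_window = cfg$window_min,
                                min_gap = cfg$min_gap_min)
  log <- character()
  per_patient <- vector("list", length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    per_patient[i] <- list(tryCatch({
      sp <- euglycemic_spans(p$trace, events[[i]],
                             min_gap = cfg$min_gap_min,
                             min_span = cfg$window_min)
      wins <- lapply(p$recordings, function(rec) {
        rec_min <- length(rec$t) / rec$fs / 60
        select_best_window(rec, c(0, rec_min), jac, head, cov = cov,
                           step_min = cfg$search_step_min,
                           window_min = cfg$window_min)
      })
      mats <- lapply(names(p$recordings), function(w) {
        rec <- p$recordings[[w]]
        win <- extract_window(rec, wins[[w]]$start_min * 60,
                              cfg$window_min * 60)
        mask <- wins[[w]]$mask
        od <- preprocess_window(win, good = NULL, iqr_k = cfg$iqr_k,
                                f_low = cfg$f_low, f_high = cfg$f_high)
        rr <- reconstruct_window(od, jac, head, mask = mask,
                                 config = rcfg)
        smap <- suppressWarnings(sensitivity_map(jac, mask))
        ssens <- map_to_surface(smap$sensitivity, head,
                                cfg$surface_radius_mm)$values[, 1]
        rois <- build_rois(head, ssens, coverage_threshold(cov),
                           radius_mm = cfg$roi_radius_mm)
        lapply(list(HbO = rr$HbO, HbR = rr$HbR), function(s)
          tffc_matrix(roi_timecourses(s, rois), window = w))
      })
      names(mats) <- names(p$recordings)
      list(events = events[[i]], spans = sp, windows = wins, mats = mats)
    }, error = function(e) {
      log <<- c(log, sprintf("patient %d: %s", i, conditionMessage(e)))
      NULL
    }))
  }
  ok <- which(incl$included & !vapply(per_patient, is.null, logical(1)))
  if (length(ok) < 2) stop("fewer than 2 analyzable patients")
  out <- list(critical_gap = cgap, inclusion = incl,
              per_patient = per_patient, exclusion_log = log)
  for (ch in c("HbO", "HbR")) {
    zf <- stack_z(lapply(per_patient[ok],
                         function(q) q$mats$first[[ch]]))
    zl <- stack_z(lapply(per_patient[ok],
                         function(q) q$mats$last[[ch]]))
    out$z_first[[ch]] <- zf
    out$z_last[[ch]] <- zl
    out$group_first[[ch]] <- group_stats(zf)
    out$group_last[[ch]] <- group_stats(zl)
    out$comparison[[ch]] <- window_comparison(zf, zl)
    out$delta[[ch]] <- delta_tffc(zf, zl)
  }
  out$metrics <- .metrics_matrix(cohort$patients[ok])
  out$association <- correlate_with_metrics(out$delta$HbO, out$metrics)
  out$provenance <- list(
    config = unclass(cfg), seed = cfg$seed,
    config_md5 = .config_hash(cfg),
    package_version = as.character(utils::packageVersion("glucodot")),
    r_version = R.version.string,
    n_included = length(ok))
  structure(out, class = "run_results")
}

.metrics_matrix <- function(patients) {
  t(vapply(patients, function(p) glucose_metrics(p$trace),
           c(mean = 0, sd = 0, min = 0, max = 0,
             tir = 0, tor = 0, tbr = 0, tar = 0)))
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(cfg)), collapse = ""), f)
  unname(tools::md5sum(f))
}
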