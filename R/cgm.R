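#' Sensor-glucose trace constructor
#'
#' A sensor glucose concentration (SGC) trace on the CGM device's fixed
#' 5-minute sampling grid. Values are mg/dL; recording gaps are carried as
#' \code{NA} values plus an explicit missing mask.
#'
#' @param t sample times in minutes since acquisition start; must be an
#'   exact 5-minute grid.
#' @param sgc glucose values in mg/dL, \code{NA} where missing.
#' @param missing optional logical mask; defaults to \code{is.na(sgc)}.
#' @return object of class \code{sgc_trace} with fields \code{t},
#'   \code{sgc}, \code{missing}.
#' @export
sgc_trace <- function(t, sgc, missing = NULL) {
  t <- as.numeric(t); sgc <- as.numeric(sgc)
  if (length(t) != length(sgc)) stop("t and sgc lengths differ")
  if (length(t) == 0) stop("empty trace")
  if (any(diff(t) != 5)) stop("trace must be on an exact 5-min grid")
  if (is.null(missing)) missing <- is.na(sgc)
  missing <- as.logical(missing) | is.na(sgc)
  sgc[missing] <- NA_real_
  if (any(sgc[!missing] <= 0)) stop("sgc must be positive where present")
  structure(list(t = t, sgc = sgc, missing = missing), class = "sgc_trace")
}

#' @export
print.sgc_trace <- function(x, ...) {
  cat(sprintf("<sgc_trace> %d samples (%.0f min), %d missing\n",
              length(x$t), diff(range(x$t)) + 5, sum(x$missing)))
  invisible(x)
}

#' Classify one glucose value into a glycemic class
#'
#' Thresholds: euglycemia is 72 to 144 mg/dL inclusive; above-euglycemic
#' values are mild hyperglycemia up to 180 mg/dL and severe beyond; sub-
#' euglycemic values are mild hypoglycemia down to 47 mg/dL and severe
#' below. The bands between the published strict bounds (47-48 and
#' 179-180 mg/dL) are closed by a half-open completion that preserves every
#' printed strict inequality; override via \code{thresholds}.
#'
#' @param sgc numeric vector of glucose values, mg/dL (\code{NA} allowed).
#' @param thresholds list with elements \code{eu_lo}, \code{eu_hi},
#'   \code{s_hypo_hi}, \code{s_hyper_lo}.
#' @return factor with levels \code{S_hypo, m_hypo, eu, m_hyper, S_hyper,
#'   unknown} (\code{unknown} for missing samples).
#' @export
classify_sample <- function(sgc, thresholds = .glycemic_defaults) {
  th <- thresholds
  out <- rep("unknown", length(sgc))
  ok <- !is.na(sgc)
  x <- sgc[ok]
  cls <- ifelse(x < th$s_hypo_hi, "S_hypo",
         ifelse(x < th$eu_lo, "m_hypo",
         ifelse(x <= th$eu_hi, "eu",
         ifelse(x <= th$s_hyper_lo, "m_hyper", "S_hyper"))))
  out[ok] <- cls
  factor(out, levels = c("S_hypo", "m_hypo", "eu", "m_hyper", "S_hyper",
                         "unknown"))
}

#' Detect glycemic events in a trace
#'
#' An event is a maximal run of at least four consecutive samples (15 min
#' spanned, 20 min of sample coverage) in the same non-euglycemic class.
#' Runs are broken by missing samples and by class changes; by default
#' adjacent mild/severe excursions of the same direction are separate
#' events (\code{merge_severity = TRUE} pools m/S hypo and m/S hyper).
#'
#' @param trace an \code{sgc_trace}.
#' @param min_samples minimum run length in samples (default 4).
#' @param merge_severity pool mild and severe classes of the same direction
#'   before run detection (default FALSE).
#' @param thresholds passed to \code{\link{classify_sample}}.
#' @return data.frame with columns \code{klass}, \code{start_idx},
#'   \code{end_idx} (1-based, inclusive), \code{n_samples},
#'   \code{duration_min} (5 x n_samples; see Details),
#'   \code{span_min} (5 x (n_samples - 1)).
#' @details Two duration conventions coexist in the field: sample-count
#'   coverage (4 samples = 20 min) and inter-sample span (4 samples =
#'   15 min). Both are returned; \code{duration_min} (sample count) is the
#'   package default wherever one number is needed.
#' @export
classify_events <- function(trace, min_samples = 4L, merge_severity = FALSE,
                            thresholds = .glycemic_defaults) {
  stopifnot(inherits(trace, "sgc_trace"))
  cls <- as.character(classify_sample(trace$sgc, thresholds))
  key <- cls
  if (merge_severity) {
    key[key %in% c("S_hypo", "m_hypo")] <- "hypo"
    key[key %in% c("S_hyper", "m_hyper")] <- "hyper"
  }
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !(r$values %in% c("eu", "unknown")) & r$lengths >= min_samples
  out <- data.frame(
    klass = r$values[keep],
    start_idx = starts[keep],
    end_idx = ends[keep],
    stringsAsFactors = FALSE)
  out$n_samples <- out$end_idx - out$start_idx + 1L
  out$duration_min <- 5 * out$n_samples
  out$span_min <- 5 * (out$n_samples - 1L)
  out[order(out$start_idx), , drop = FALSE]
}

#' Critical gap from the pooled event-duration distribution
#'
#' First quartile of the durations of all glycemic events pooled across
#' patients; used as the maximum tolerable CGM gap for patient inclusion.
#'
#' @param event_durations numeric vector of event durations in minutes.
#' @param convention \code{"interpolate"} (default; linear interpolation
#'   between order statistics, \code{stats::quantile} type 7) or
#'   \code{"nearest_rank"} (type 1).
#' @return first quartile, minutes.
#' @export
critical_gap <- function(event_durations,
                         convention = c("interpolate", "nearest_rank")) {
  if (length(event_durations) == 0) stop("no event durations supplied")
  convention <- match.arg(convention)
  type <- if (convention == "interpolate") 7 else 1
  unname(stats::quantile(event_durations, probs = 0.25, type = type,
                         names = FALSE))
}

# missing runs of a trace as (start_idx, end_idx, duration_min)
.gap_runs <- function(trace) {
  r <- rle(trace$missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             duration_min = 5 * r$lengths[keep])
}

#' Apply the three patient-inclusion rules
#'
#' Rule 1: the SGC signal starts in euglycemia. Rule 2: every CGM gap is
#' shorter than the critical gap. Rule 3: DOT recording is available for at
#' least \code{min_window} minutes inside both the first and last
#' euglycemic spans (patients whose spans cannot be constructed fail
#' rule 3).
#'
#' @param patients list; each element a list with \code{trace} (an
#'   \code{sgc_trace}) and \code{dot_intervals} (two-column matrix of
#'   recording availability, minutes).
#' @param gap_min critical gap in minutes (default 45).
#' @param min_window minimum usable window, minutes (default 5).
#' @param min_gap minimum separation between spans passed to
#'   \code{\link{euglycemic_spans}}.
#' @return data.frame with logical columns \code{rule1}, \code{rule2},
#'   \code{rule3}, \code{included}.
#' @export
apply_inclusion_rules <- function(patients, gap_min = 45, min_window = 5,
                                  min_gap = 510) {
  res <- lapply(patients, function(p) {
    tr <- p$trace
    first_present <- which(!tr$missing)[1]
    rule1 <- !is.na(first_present) &&
      as.character(classify_sample(tr$sgc[first_present])) == "eu"
    gaps <- .gap_runs(tr)
    rule2 <- all(gaps$duration_min < gap_min)
    rule3 <- FALSE
    sp <- tryCatch(
      euglycemic_spans(tr, classify_events(tr), min_gap = min_gap,
                       min_span = min_window),
      error = function(e) NULL)
    if (!is.null(sp) && !is.null(p$dot_intervals)) {
      iv <- p$dot_intervals
      covers <- function(span) {
        any(pmin(iv[, 2], span[2]) - pmax(iv[, 1], span[1]) >= min_window)
      }
      rule3 <- covers(c(sp$first[1], sp$first[2])) &&
        covers(c(sp$last[1], sp$last[2]))
    }
    c(rule1 = rule1, rule2 = rule2, rule3 = rule3)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$included <- out$rule1 & out$rule2 & out$rule3
  out
}

#' Delimit the first and last euglycemic spans
#'
#' The first span runs from the start of the acquisition to the onset of
#' the first glycemic event; the last span runs from the first sample after
#' the last event to the end of the signal (or the last euglycemic sample,
#' if the acquisition ends out of range). If the gap between the spans is
#' below \code{min_gap}, the first span's end is anticipated and, only if
#' that would shrink it below \code{min_span}, the last span's start is
#' postponed, until the gap constraint holds.
#'
#' @param trace an \code{sgc_trace}.
#' @param events event table from \code{\link{classify_events}}.
#' @param min_gap minimum separation in minutes between the end of the
#'   first span and the start of the last (default 510).
#' @param min_span minimum usable span length, minutes (default 5).
#' @return list of class \code{euglycemic_spans}: \code{first},
#'   \code{last} (each \code{c(start_min, end_min)}), \code{adjusted}.
#' @export
euglycemic_spans <- function(trace, events, min_gap = 510, min_span = 5) {
  stopifnot(inherits(trace, "sgc_trace"))
  if (is.null(events) || nrow(events) == 0)
    stop("no glycemic event; last window undefined")
  t0 <- trace$t[1]
  first_start <- t0
  first_end <- trace$t[events$start_idx[1]]
  last_start <- trace$t[events$end_idx[nrow(events)]] + 5
  cls <- as.character(classify_sample(trace$sgc))
  eu_idx <- which(cls == "eu")
  n <- length(trace$t)
  last_end <- if (cls[n] == "eu") trace$t[n] else trace$t[max(eu_idx)]
  if (last_end < last_start)
    stop("no euglycemic samples after the last event")
  adjusted <- FALSE
  if (last_start - first_end < min_gap) {
    adjusted <- TRUE
    first_end <- last_start - min_gap
    if (first_end < first_start + min_span) {
      first_end <- first_start + min_span
      last_start <- first_end + min_gap
    }
  }
  if (first_end - first_start < min_span ||
      last_end - last_start < min_span)
    stop("euglycemic spans shorter than min_span after adjustment")
  structure(list(first = c(start_min = first_start, end_min = first_end),
                 last = c(start_min = last_start, end_min = last_end),
                 adjusted = adjusted),
            class = "euglycemic_spans")
}

#' @export
print.euglycemic_spans <- function(x, ...) {
  cat(sprintf("<euglycemic_spans> first [%g, %g] min, last [%g, %g] min%s\n",
              x$first[1], x$first[2], x$last[1], x$last[2],
              if (x$adjusted) " (adjusted)" else ""))
  invisible(x)
}

#' Eight summary metrics of a glucose trace
#'
#' Mean, SD, minimum and maximum of the SGC signal over the whole
#' acquisition, plus the percentage of time in (TIR), outside (TOR), below
#' (TBR) and above (TAR) the euglycemic range 72-144 mg/dL. Percentages
#' are over present (non-missing) samples.
#'
#' @param trace an \code{sgc_trace}.
#' @param thresholds glycemic thresholds (see
#'   \code{\link{classify_sample}}).
#' @return named numeric vector \code{mean, sd, min, max, tir, tor, tbr,
#'   tar}.
#' @export
glucose_metrics <- function(trace, thresholds = .glycemic_defaults) {
  stopifnot(inherits(trace, "sgc_trace"))
  x <- trace$sgc[!trace$missing]
  if (length(x) < 2) stop("need at least two present samples")
  tbr <- 100 * mean(x < thresholds$eu_lo)
  tar <- 100 * mean(x > thresholds$eu_hi)
  c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
    tir = 100 - tbr - tar, tor = tbr + tar, tbr = tbr, tar = tar)
}
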