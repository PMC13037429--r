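#' Parameters for the synthetic CGM generator
#'
#' @param duration_min total trace length in minutes (multiple of 5).
#' @param baseline_mean,baseline_sd euglycemic baseline level and
#'   stationary SD, mg/dL.
#' @param ar_coefficient first-order autoregressive coefficient of the
#'   baseline, in [0, 1).
#' @param events data.frame with columns \code{klass} (one of
#'   \code{S_hypo, m_hypo, m_hyper, S_hyper}), \code{start_min},
#'   \code{duration_min}, \code{plateau_mgdl}; may be empty.
#' @param gaps data.frame with columns \code{start_min},
#'   \code{duration_min}; may be empty.
#' @param seed integer RNG seed.
#' @return validated list of class \code{cgm_sim_params}.
#' @export
cgm_sim_params <- function(duration_min, baseline_mean = 105,
                           baseline_sd = 10, ar_coefficient = 0.9,
                           events = NULL, gaps = NULL, seed = 1L) {
  if (duration_min %% 5 != 0) stop("duration_min must be a multiple of 5")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  if (is.null(events))
    events <- data.frame(klass = character(), start_min = numeric(),
                         duration_min = numeric(), plateau_mgdl = numeric())
  if (is.null(gaps))
    gaps <- data.frame(start_min = numeric(), duration_min = numeric())
  if (nrow(events) > 1) {
    ev <- events[order(events$start_min), ]
    if (any(ev$start_min[-1] < (ev$start_min + ev$duration_min)[-nrow(ev)]))
      stop("overlapping events")
    events <- ev
  }
  th <- .glycemic_defaults
  band <- function(k) switch(k,
    S_hypo = c(1, th$s_hypo_hi - 1e-9),
    m_hypo = c(th$s_hypo_hi, th$eu_lo - 1e-9),
    m_hyper = c(th$eu_hi + 1e-9, th$s_hyper_lo),
    S_hyper = c(th$s_hyper_lo + 1e-9, 600),
    stop("unknown event class: ", k))
  for (i in seq_len(nrow(events))) {
    b <- band(events$klass[i])
    if (events$plateau_mgdl[i] < b[1] || events$plateau_mgdl[i] > b[2])
      stop("plateau outside nominal band for class ", events$klass[i])
  }
  if (nrow(gaps) > 1) {
    gp <- gaps[order(gaps$start_min), ]
    if (any(gp$start_min[-1] < (gp$start_min + gp$duration_min)[-nrow(gp)]))
      stop("overlapping gaps")
    gaps <- gp
  }
  structure(list(duration_min = duration_min, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, ar_coefficient = ar_coefficient,
                 events = events, gaps = gaps, seed = as.integer(seed)),
            class = "cgm_sim_params")
}

#' Generate a synthetic sensor-glucose trace
#'
#' Euglycemic AR(1) baseline clipped to 72-144 mg/dL, with injected
#' hypo-/hyperglycemic excursions held inside their nominal class band for
#' the stated duration, and recording gaps marked missing.
#'
#' @param params a \code{\link{cgm_sim_params}} object.
#' @return an \code{\link{sgc_trace}}.
#' @export
gen_cgm_trace <- function(params) {
  stopifnot(inherits(params, "cgm_sim_params"))
  p <- params
  n <- p$duration_min / 5
  t <- seq(0, by = 5, length.out = n)
  rng <- .seeded_rng(p$seed)
  innov_sd <- p$baseline_sd * sqrt(1 - p$ar_coefficient^2)
  x <- numeric(n)
  x[1] <- p$baseline_mean
  eps <- rng$rnorm(n) * innov_sd
  for (i in seq_len(n - 1))
    x[i + 1] <- p$baseline_mean + p$ar_coefficient * (x[i] - p$baseline_mean) +
      eps[i + 1]
  x <- pmin(pmax(x, .glycemic_defaults$eu_lo), .glycemic_defaults$eu_hi)
  th <- .glycemic_defaults
  for (i in seq_len(nrow(p$events))) {
    ev <- p$events[i, ]
    idx <- which(t >= ev$start_min & t < ev$start_min + ev$duration_min)
    b <- switch(ev$klass,
      S_hypo = c(1, th$s_hypo_hi - 0.5),
      m_hypo = c(th$s_hypo_hi, th$eu_lo - 0.5),
      m_hyper = c(th$eu_hi + 0.5, th$s_hyper_lo),
      S_hyper = c(th$s_hyper_lo + 0.5, 600))
    x[idx] <- pmin(pmax(ev$plateau_mgdl + rng$rnorm(length(idx)) * 1.5,
                        b[1]), b[2])
  }
  miss <- rep(FALSE, n)
  for (i in seq_len(nrow(p$gaps))) {
    gp <- p$gaps[i, ]
    miss[t >= gp$start_min & t < gp$start_min + gp$duration_min] <- TRUE
  }
  x[miss] <- NA_real_
  sgc_trace(t, x, miss)
}

# private RNG stream: isolates generator draws from the global RNG state
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = function(n, ...) draw(stats::rnorm, n, ...),
       runif = function(n, ...) draw(stats::runif, n, ...),
       sample = function(...) draw(base::sample, ...))
}
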