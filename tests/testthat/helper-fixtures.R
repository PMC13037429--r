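# shared fixtures, built once per test run

.fix <- local({
  env <- new.env()
  get_model <- function() {
    if (is.null(env$hm)) {
      env$hm <- gen_head_model()
      env$jac <- gen_jacobian(env$hm$head, env$hm$montage)
    }
    list(head = env$hm$head, montage = env$hm$montage, jac = env$jac)
  }
  get_rois <- function() {
    if (is.null(env$rois)) {
      m <- get_model()
      mask <- channel_mask(rep(TRUE, 128),
                           channels = glucodot:::.channel_table(m$jac))
      smap <- sensitivity_map(m$jac, mask)
      ssens <- map_to_surface(smap$sensitivity, m$head)$values[, 1]
      cov <- coverage_params(vhat = m$head$node_volume_mm3,
                             reading = "multiply")
      env$rois <- build_rois(m$head, ssens, coverage_threshold(cov))
      env$proj <- roi_projection(m$jac, m$head, env$rois)
    }
    list(rois = env$rois, proj = env$proj)
  }
  list(model = get_model, rois = get_rois)
})

make_trace <- function(values, missing = NULL) {
  sgc_trace(seq(0, by = 5, length.out = length(values)), values, missing)
}

# independent brute-force event scanner: walks every start index and
# extends runs sample by sample; no rle machinery
oracle_events <- function(trace, min_samples = 4L) {
  cls <- as.character(classify_sample(trace$sgc))
  n <- length(cls)
  out <- list()
  s <- 1L
  while (s <= n) {
    if (cls[s] %in% c("eu", "unknown")) { s <- s + 1L; next }
    e <- s
    while (e < n && cls[e + 1L] == cls[s]) e <- e + 1L
    if (e - s + 1L >= min_samples)
      out[[length(out) + 1L]] <- data.frame(
        klass = cls[s], start_idx = s, end_idx = e,
        stringsAsFactors = FALSE)
    s <- e + 1L
  }
  if (length(out) == 0)
    return(data.frame(klass = character(), start_idx = integer(),
                      end_idx = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

random_trace <- function(n = 288) {
  v <- sample(c(30, 60, 100, 160, 200, NA), n, replace = TRUE,
              prob = c(.08, .12, .5, .15, .1, .05))
  make_trace(v)
}

make_od <- function(x, fs = 10) {
  structure(list(od = matrix(x, nrow = 1), fs = fs,
                 channels = data.frame(wavelength = 780)),
            class = "od_window")
}

band_noise <- function(n, fs = 10, lo = 0.01, hi = 0.08) {
  glucodot:::.fft_bandpass(matrix(stats::rnorm(n)), fs, lo, hi)[, 1]
}
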