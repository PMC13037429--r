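#' Write / read a CGM trace as delimited text
#'
#' Columns: \code{minutes}, \code{sgc_mgdl} (empty where missing),
#' \code{missing_flag} (0/1). Values are written with full precision so
#' the round trip is exact.
#'
#' @param trace an \code{sgc_trace}.
#' @param path output file.
#' @return \code{write_cgm}: the path, invisibly. \code{read_cgm}: an
#'   \code{sgc_trace}.
#' @export
write_cgm <- function(trace, path) {
  stopifnot(inherits(trace, "sgc_trace"))
  d <- data.frame(minutes = .fmt(trace$t),
                  sgc_mgdl = ifelse(trace$missing, "", .fmt(trace$sgc)),
                  missing_flag = as.integer(trace$missing))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param tolerance_min maximum snap distance to the 5-min grid (default
#'   0.5); larger timestamp irregularity is an error.
#' @rdname write_cgm
#' @export
read_cgm <- function(path, tolerance_min = 0.5) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = c("", "NA"))
  need <- c("minutes", "sgc_mgdl", "missing_flag")
  if (!all(need %in% names(d)))
    stop("CGM file must have columns: ", paste(need, collapse = ", "))
  t <- d$minutes
  if (any(diff(t) <= 0))
    stop("non-monotone time at line ", which(diff(t) <= 0)[1] + 1)
  snapped <- round(t / 5) * 5
  off <- abs(t - snapped)
  if (any(off > tolerance_min))
    stop("timestamp off the 5-min grid at line ",
         which(off > tolerance_min)[1] + 1)
  if (any(diff(snapped) != 5))
    stop("wrong cadence (expected 5 min) at line ",
         which(diff(snapped) != 5)[1] + 1)
  sgc_trace(snapped, d$sgc_mgdl, d$missing_flag == 1)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write / read a DOT recording as a text container
#'
#' Plain-text stand-in for an HDF5 (SNIRF-style) recording: a one-line
#' JSON header (sampling rate, wavelengths, baseline intensity) followed
#' by the tab-separated channel table and the intensity matrix at full
#' precision. The round trip is bit-exact.
#'
#' @param recording a \code{dot_recording}.
#' @param path output file.
#' @return \code{write_recording}: the path, invisibly.
#'   \code{read_recording}: a \code{dot_recording} (without ground truth).
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "dot_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(
    format = "glucodot-recording-v1", fs = recording$fs,
    wavelengths = sort(unique(recording$channels$wavelength)),
    I0 = recording$I0,
    n_channels = nrow(recording$intensity),
    n_samples = ncol(recording$intensity)), auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  ch <- recording$channels
  writeLines(paste(ch$source, ch$detector, ch$wavelength,
                   .fmt(ch$separation_mm), sep = "\t"), con)
  utils::write.table(
    matrix(.fmt(recording$intensity), nrow(recording$intensity)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "glucodot-recording-v1"))
    stop("not a glucodot recording file")
  if (length(hdr$wavelengths) < 2)
    stop("two wavelengths required for hemoglobin unmixing")
  nch <- hdr$n_channels
  ch <- utils::read.table(text = lines[2:(1 + nch)], sep = "\t",
                          col.names = c("source", "detector", "wavelength",
                                        "separation_mm"))
  I <- as.matrix(utils::read.table(text = lines[(2 + nch):length(lines)],
                                   sep = "\t"))
  dimnames(I) <- NULL
  stopifnot(nrow(I) == nch, ncol(I) == hdr$n_samples)
  structure(list(fs = hdr$fs,
                 t = seq(0, by = 1 / hdr$fs, length.out = ncol(I)),
                 intensity = I, channels = ch, I0 = hdr$I0, truth = NULL),
            class = "dot_recording")
}

#' Write / read a head model as node/element text
#'
#' JSON header (radius, grid, depths) followed by labeled coordinate
#' blocks for landmarks, surface and volumetric nodes.
#'
#' @param head a \code{head_model}.
#' @param path output file.
#' @return \code{write_head_model}: the path, invisibly.
#'   \code{read_head_model}: a \code{head_model}.
#' @export
write_head_model <- function(head, path) {
  stopifnot(inherits(head, "head_model"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(
    format = "glucodot-head-v1", radius_mm = head$radius_mm,
    grid_mm = head$grid_mm, cortex_depth_mm = head$cortex_depth_mm,
    node_volume_mm3 = head$node_volume_mm3,
    n_surface = nrow(head$surface), n_vol = nrow(head$vol)),
    auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  wr <- function(tag, m, names = NULL) {
    lab <- if (is.null(names)) rep(tag, nrow(m)) else paste(tag, names)
    writeLines(paste(lab, .fmt(m[, 1]), .fmt(m[, 2]), .fmt(m[, 3]),
                     sep = "\t"), con)
  }
  wr("landmark", head$landmarks, rownames(head$landmarks))
  wr("surface", head$surface)
  wr("vol", head$vol)
  invisible(path)
}

#' @rdname write_head_model
#' @export
read_head_model <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "glucodot-head-v1")) stop("not a head model file")
  body <- utils::read.table(text = lines[-1], sep = "\t",
                            col.names = c("tag", "x", "y", "z"))
  pick <- function(tag) {
    m <- as.matrix(body[startsWith(body$tag, tag), c("x", "y", "z")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  }
  lmrows <- startsWith(body$tag, "landmark")
  lm <- as.matrix(body[lmrows, c("x", "y", "z")])
  rownames(lm) <- sub("^landmark ", "", body$tag[lmrows])
  colnames(lm) <- c("x", "y", "z")
  structure(list(surface = pick("surface"), vol = pick("vol"),
                 node_volume_mm3 = hdr$node_volume_mm3, landmarks = lm,
                 radius_mm = hdr$radius_mm, grid_mm = hdr$grid_mm,
                 cortex_depth_mm = hdr$cortex_depth_mm),
            class = "head_model")
}

#' Write / read a Jacobian as a dense matrix container
#'
#' JSON header, then the pair table, then one full-precision matrix block
#' per wavelength.
#'
#' @param jacobian a \code{dot_jacobian}.
#' @param path output file.
#' @return \code{write_jacobian}: the path, invisibly.
#'   \code{read_jacobian}: a \code{dot_jacobian}.
#' @export
write_jacobian <- function(jacobian, path) {
  stopifnot(inherits(jacobian, "dot_jacobian"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(
    format = "glucodot-jacobian-v1",
    wavelengths = jacobian$wavelengths,
    n_pairs = nrow(jacobian$pairs), n_nodes = ncol(jacobian$J[[1]]),
    node_volume_mm3 = jacobian$node_volume_mm3),
    auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  p <- jacobian$pairs
  writeLines(paste(p$source, p$detector, .fmt(p$separation_mm), sep = "\t"),
             con)
  for (J in jacobian$J)
    utils::write.table(matrix(.fmt(J), nrow(J)), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_jacobian
#' @export
read_jacobian <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$format, "glucodot-jacobian-v1"))
    stop("not a jacobian file")
  np <- hdr$n_pairs
  pairs <- utils::read.table(text = lines[2:(1 + np)], sep = "\t",
                             col.names = c("source", "detector",
                                           "separation_mm"))
  J <- lapply(seq_along(hdr$wavelengths), function(w) {
    block <- lines[(2 + np + (w - 1) * np):(1 + np + w * np)]
    m <- as.matrix(utils::read.table(text = block, sep = "\t"))
    dimnames(m) <- NULL
    m
  })
  names(J) <- as.character(hdr$wavelengths)
  structure(list(J = J, pairs = pairs, wavelengths = hdr$wavelengths,
                 node_volume_mm3 = hdr$node_volume_mm3),
            class = "dot_jacobian")
}
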