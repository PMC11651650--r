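#' Write a multichannel time-lapse stack to TIFF with a JSON sidecar
#'
#' Pages are written time-major in TCYX order as 16-bit grayscale; axis
#' layout, dimensions, physical pixel size and frame interval go to a JSON
#' sidecar (`<path>.json`), since baseline TIFF has no standard slot for
#' them. Intensities must lie in \[0, 1\] on the 16-bit grid (see
#' [gen_fusion_movie()]); writing and re-reading is then bit-exact.
#'
#' @param stack numeric array (time, channel, y, x), values in \[0, 1\].
#' @param path output TIFF path.
#' @param pixel_size physical pixel size, µm.
#' @param frame_interval_min frame interval, minutes.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, pixel_size,
                              frame_interval_min = NA_real_) {
  stopifnot(length(dim(stack)) == 4L, pixel_size > 0)
  d <- dim(stack)
  pages <- vector("list", d[1L] * d[2L])
  i <- 1L
  for (t in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    pages[[i]] <- matrix(stack[t, ch, , ], d[3L], d[4L])
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = "TCYX", n_time = d[1L], n_channel = d[2L],
               height = d[3L], width = d[4L],
               pixel_size_um = pixel_size,
               frame_interval_min = frame_interval_min,
               bits_per_sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a multichannel time-lapse stack
#'
#' Reads a TIFF written by [write_image_stack()] (or any grayscale
#' multi-page TIFF) and normalizes axes to (time, channel, y, x). Layout and
#' physical pixel size come from the JSON sidecar when present; a bare
#' multi-page TIFF without sidecar is treated as single-channel with one
#' page per frame. An explicit `pixel_size` argument overrides metadata with
#' a warning; without either the reader errors.
#'
#' @param path TIFF path.
#' @param pixel_size optional physical pixel size in µm, overriding
#'   metadata.
#' @return A list with `stack` (T x C x Y x X array), `pixel_size`, and
#'   `frame_interval_min` (NA when unknown).
#' @export
read_image_stack <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop(sprintf("unknown axis layout: page with %d samples per pixel",
                     dim(p)[3L]))
      p <- p[, , 1L]
    }
    p
  })
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (is.null(meta)) {
    nt <- length(pages)
    nc <- 1L
    fi <- NA_real_
    meta_px <- NULL
  } else {
    nt <- meta$n_time
    nc <- meta$n_channel
    fi <- if (is.null(meta$frame_interval_min) ||
              !is.numeric(meta$frame_interval_min)) NA_real_
          else as.numeric(meta$frame_interval_min)
    meta_px <- meta$pixel_size_um
    if (!identical(meta$axes, "TCYX"))
      stop(sprintf("unknown axis layout '%s' (expected TCYX)", meta$axes))
    if (nt * nc != length(pages))
      stop("sidecar dimensions do not match page count")
  }
  if (!is.null(pixel_size)) {
    if (!is.null(meta_px) && !isTRUE(all.equal(pixel_size, meta_px)))
      warning(sprintf(
        "pixel size flag %g um overrides metadata value %g um",
        pixel_size, as.numeric(meta_px)))
    px <- pixel_size
  } else if (!is.null(meta_px)) {
    px <- as.numeric(meta_px)
  } else {
    stop("no pixel size in metadata and none supplied")
  }
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])
  stack <- array(NA_real_, c(nt, nc, h, w))
  i <- 1L
  for (t in seq_len(nt)) for (ch in seq_len(nc)) {
    stack[t, ch, , ] <- pages[[i]]
    i <- i + 1L
  }
  list(stack = stack, pixel_size = px, frame_interval_min = fi)
}

#' Read a FRAP trace from CSV
#'
#' Expects columns `time_min`, `I_frap`, `I_whole`, `I_base`; pre-bleach
#' rows are flagged by negative time (or an optional logical `prebleach`
#' column). Pre-bleach anchors are the means over the pre-bleach rows.
#'
#' @param path CSV path.
#' @return A [frap_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_min", "I_frap", "I_whole", "I_base")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "),
         "; required schema: ", paste(req, collapse = ", "))
  if (any(diff(df$time_min) <= 0))
    stop("time_min must be strictly increasing (is the file sorted?)")
  if ("prebleach" %in% names(df) && any(df$prebleach != (df$time_min < 0)))
    stop("prebleach column inconsistent with negative-time convention")
  frap_trace(df$time_min, df$I_frap, df$I_whole, df$I_base)
}

#' Write a FRAP trace to CSV
#'
#' @param trace a [frap_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  utils::write.csv(
    data.frame(time_min = trace$time_min, I_frap = trace$I_frap,
               I_whole = trace$I_whole, I_base = trace$I_base),
    path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes results together with the run configuration, seed and package
#' version, with deterministic field ordering, so that two runs with the
#' same seed and config produce byte-identical reports.
#'
#' @param results a named list (or data frame) of results.
#' @param path output JSON path.
#' @param config named list of run parameters (thresholds, bounds, ...).
#' @param seed the run's seed.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = list(), seed = NA_integer_) {
  report <- list(
    package = "titinflow",
    version = as.character(utils::packageVersion("titinflow")),
    seed = seed,
    config = config[order(names(config))],
    results = if (is.data.frame(results)) results
              else results[order(names(results))])
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
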