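#' Mixing class labels
#'
#' The five threshold classes used to score how two differently labelled
#' titin populations mix through a syncytium, plus `background` and the
#' `both_weak` combination (both channels between the weak and strong
#' thresholds) needed so that every pixel falls in exactly one class.
#'
#' @return Character vector of class names in their integer coding order
#'   (`background` = 0).
#' @export
mixing_classes <- function() {
  c("background", "only_red", "majority_red", "mixed",
    "majority_green", "only_green", "both_weak")
}

#' Calibrate a channel against reference cells
#'
#' Maps raw intensities to percent of a bright positive reference: the mean
#' intensity over a negative (unlabelled) cell ROI is set to 0% and the mean
#' over a bright positive neighbouring cell to 100%.
#'
#' @param frame 2-D intensity matrix.
#' @param neg_roi,pos_roi logical masks over `frame` (or index vectors)
#'   selecting the negative and positive reference cells; non-empty and
#'   disjoint.
#' @param channel `"red"` or `"green"`.
#' @return An object of class `"channel_calibration"`: list with `I_neg`,
#'   `I_pos`, `channel`.
#' @export
calibrate_channel <- function(frame, neg_roi, pos_roi,
                              channel = c("red", "green")) {
  channel <- match.arg(channel)
  ni <- if (is.logical(neg_roi)) which(neg_roi) else as.integer(neg_roi)
  pi <- if (is.logical(pos_roi)) which(pos_roi) else as.integer(pos_roi)
  if (!length(ni) || !length(pi)) stop("reference ROIs must be non-empty")
  if (length(intersect(ni, pi))) stop("reference ROIs must be disjoint")
  I_neg <- mean(frame[ni])
  I_pos <- mean(frame[pi])
  if (I_pos <= I_neg)
    stop("calibration error: positive reference not brighter than negative")
  structure(list(I_neg = I_neg, I_pos = I_pos, channel = channel),
            class = "channel_calibration")
}

#' Express intensities as percent of the calibration range
#'
#' `100 * (I - I_neg) / (I_pos - I_neg)`, clipped to \[0, 150\].
#'
#' @param I intensity matrix or vector.
#' @param cal a [calibrate_channel()] result.
#' @return Relative intensity in percent, same shape as `I`.
#' @export
relative_intensity <- function(I, cal) {
  stopifnot(inherits(cal, "channel_calibration"))
  pmin(pmax(100 * (I - cal$I_neg) / (cal$I_pos - cal$I_neg), 0), 150)
}

# 3x3 median filter with edge replication; operates on a matrix
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m)
  pad <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  stackv <- vapply(1:9, function(i) {
    dr <- (i - 1L) %% 3L
    dc <- (i - 1L) %/% 3L
    as.vector(pad[dr + seq_len(nr), dc + seq_len(nc)])
  }, numeric(nr * nc))
  matrix(apply(stackv, 1L, stats::median), nr, nc)
}

#' Classify pixels into mixing classes by the 20%/50% thresholds
#'
#' Each pixel's calibrated red and green intensities are binned as no signal
#' (<= weak threshold), weak (between thresholds, inclusive) or strong
#' (> strong threshold); equality falls to the weaker bin. The bin pair maps
#' to: `only_red` (red signal, no green), `majority_red` (strong red, weak
#' green), `mixed` (both strong), `majority_green` (weak red, strong green),
#' `only_green` (green signal, no red), `background` (neither), and
#' `both_weak` (both weak).
#'
#' @param red_pct,green_pct calibrated percent-intensity matrices of equal
#'   shape (see [relative_intensity()]).
#' @param weak,strong thresholds in percent (defaults 20 and 50).
#' @param pixel_size pixel edge length in µm, attached to the result.
#' @return An integer matrix of class `"mixing_map"` coding
#'   [mixing_classes()] from 0, with attributes `classes` and `pixel_size`.
#' @export
classify_pixels <- function(red_pct, green_pct, weak = 20, strong = 50,
                            pixel_size = NA_real_) {
  if (!identical(dim(red_pct), dim(green_pct)))
    stop("red and green images must have the same shape")
  stopifnot(weak < strong)
  bin <- function(x) (x > weak) + (x > strong)  # 0 none, 1 weak, 2 strong
  r <- bin(red_pct)
  g <- bin(green_pct)
  # lookup by 3*r + g
  lut <- c(0L, 5L, 5L,   # r none : background, only_green, only_green
           1L, 6L, 4L,   # r weak : only_red, both_weak, majority_green
           1L, 2L, 3L)   # r strong: only_red, majority_red, mixed
  lab <- matrix(lut[3L * r + g + 1L], nrow(r), ncol(r))
  structure(lab, class = "mixing_map", classes = mixing_classes(),
            pixel_size = pixel_size)
}

#' @export
print.mixing_map <- function(x, ...) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 7L)
  names(tab) <- mixing_classes()
  cat(sprintf("mixing map %d x %d px (pixel %s um)\n", nrow(x), ncol(x),
              format(attr(x, "pixel_size"))))
  print(tab)
  invisible(x)
}

#' Per-class areas of a mixing map
#'
#' `area(class) = pixel count * pixel_size^2`; the cell area is the total
#' over all non-background classes.
#'
#' @param map a [classify_pixels()] result.
#' @param pixel_size µm per pixel; defaults to the map's attribute.
#' @return Named numeric vector of areas in µm², one per class, plus
#'   `cell_area`.
#' @export
measure_areas <- function(map, pixel_size = attr(map, "pixel_size")) {
  if (is.na(pixel_size)) stop("pixel_size not set")
  counts <- tabulate(as.integer(map) + 1L, nbins = 7L)
  areas <- counts * pixel_size^2
  names(areas) <- mixing_classes()
  c(areas, cell_area = sum(areas[-1L]))
}

#' Mixing time series of a two-channel fusion movie
#'
#' Classifies every frame of a (time, channel, y, x) stack with a single
#' per-movie calibration and reports per-class absolute areas and the mixed
#' area as a percentage of the cell area over time. A 3x3 median filter
#' (edge-replicated) can be applied to the percent images before
#' thresholding to suppress shot noise.
#'
#' @param stack numeric array with dimensions (time, channel, y, x);
#'   channel 1 is red, channel 2 green.
#' @param cal_red,cal_green [calibrate_channel()] results for the two
#'   channels.
#' @param pixel_size µm per pixel.
#' @param frame_times_hr frame acquisition times in hours; defaults to
#'   half-hour spacing (two frames per hour) starting at 0.
#' @param weak,strong classification thresholds in percent.
#' @param median_filter apply the 3x3 median filter before thresholding.
#' @return An object of class `"mixing_timeseries"`: a data frame with one
#'   row per frame (`frame`, `time_hr`, one `area_*` column per class in µm²,
#'   `cell_area`, `mixed_pct`), with the per-frame label maps in attribute
#'   `maps`.
#' @export
mixing_timeseries <- function(stack, cal_red, cal_green, pixel_size,
                              frame_times_hr = NULL, weak = 20, strong = 50,
                              median_filter = TRUE) {
  stopifnot(length(dim(stack)) == 4L)
  if (missing(cal_red) || missing(cal_green) ||
      !inherits(cal_red, "channel_calibration") ||
      !inherits(cal_green, "channel_calibration"))
    stop("calibration required for both channels")
  nt <- dim(stack)[1L]
  if (nt < 2L) stop("need at least 2 frames")
  if (is.null(frame_times_hr)) frame_times_hr <- (seq_len(nt) - 1L) * 0.5
  stopifnot(length(frame_times_hr) == nt)
  maps <- vector("list", nt)
  rows <- vector("list", nt)
  for (f in seq_len(nt)) {
    rp <- relative_intensity(stack[f, 1L, , ], cal_red)
    gp <- relative_intensity(stack[f, 2L, , ], cal_green)
    if (median_filter) {
      rp <- median_filter3(rp)
      gp <- median_filter3(gp)
    }
    map <- classify_pixels(rp, gp, weak = weak, strong = strong,
                           pixel_size = pixel_size)
    maps[[f]] <- map
    a <- measure_areas(map)
    rows[[f]] <- data.frame(
      frame = f, time_hr = frame_times_hr[f],
      area_only_red = a[["only_red"]],
      area_majority_red = a[["majority_red"]],
      area_mixed = a[["mixed"]],
      area_majority_green = a[["majority_green"]],
      area_only_green = a[["only_green"]],
      area_both_weak = a[["both_weak"]],
      cell_area = a[["cell_area"]])
  }
  out <- do.call(rbind, rows)
  out$mixed_pct <- ifelse(out$cell_area > 0,
                          100 * out$area_mixed / out$cell_area, 0)
  structure(out, maps = maps, pixel_size = pixel_size,
            class = c("mixing_timeseries", "data.frame"))
}

#' Exclude cells by area
#'
#' Keeps cells whose area lies within the inclusive bounds; the defaults
#' exclude very small (< 1000 µm²) and very large (> 10,000 µm²) cells whose
#' size would confound mixing-speed comparisons.
#'
#' @param areas cell areas, µm².
#' @param min_area,max_area inclusive bounds, µm².
#' @return Integer indices of the kept cells.
#' @export
filter_cells_by_area <- function(areas, min_area = 1000, max_area = 10000) {
  stopifnot(all(areas >= 0))
  which(areas >= min_area & areas <= max_area)
}

#' Initial spread rate of the mixed area
#'
#' Least-squares slope of absolute mixed area against time over the initial
#' growth window: from the first frame with nonzero mixed area to the first
#' frame reaching 90% of the final mixed area.
#'
#' @param series a [mixing_timeseries()] (or data frame with `time_hr` and
#'   `area_mixed`).
#' @param growth_fraction end of the fit window as a fraction of the final
#'   mixed area (default 0.9).
#' @return A list with `rate_um2_per_hr`, `rate_um2_per_s`, and the fit
#'   `window` (frame indices). If the mixed area never grows the rate is 0
#'   with a warning.
#' @export
spread_rate <- function(series, growth_fraction = 0.9) {
  stopifnot(all(c("time_hr", "area_mixed") %in% names(series)))
  am <- series$area_mixed
  if (all(am <= 0)) {
    warning("mixed area never grows; spread rate 0")
    return(list(rate_um2_per_hr = 0, rate_um2_per_s = 0, window = integer()))
  }
  first <- which(am > 0)[1L]
  target <- growth_fraction * am[length(am)]
  last <- which(am >= target)[1L]
  if (is.na(last) || last <= first) last <- length(am)
  idx <- first:last
  if (length(idx) < 3L) idx <- first:min(first + 2L, length(am))
  if (length(idx) < 2L) {
    warning("too few growing frames; spread rate 0")
    return(list(rate_um2_per_hr = 0, rate_um2_per_s = 0, window = idx))
  }
  slope <- unname(stats::coef(stats::lm(am[idx] ~ series$time_hr[idx]))[2L])
  list(rate_um2_per_hr = slope, rate_um2_per_s = slope / 3600,
       window = idx)
}

#' Width of the invading-channel gradient
#'
#' The axial distance over which the invading channel's relative intensity
#' falls from the strong to the weak threshold (50% to 20% by default),
#' located by linear interpolation on an optionally smoothed 1-D profile.
#' This operationalizes the visible extent of protein spread between two
#' neighbouring nuclei.
#'
#' @param x_um axial positions, µm, strictly increasing.
#' @param pct invading-channel relative intensity in percent at `x_um`.
#' @param weak,strong the two thresholds in percent.
#' @param smooth_window odd moving-average window length in samples; 1
#'   disables smoothing.
#' @return Width in µm, or `NA` (with a warning) if the profile does not
#'   cross both thresholds.
#' @examples
#' x <- seq(0, 300, by = 1)
#' gradient_width(x, 100 * exp(-x / 54.6))  # ~50 um
#' @export
gradient_width <- function(x_um, pct, weak = 20, strong = 50,
                           smooth_window = 1L) {
  stopifnot(length(x_um) == length(pct), all(diff(x_um) > 0), weak < strong)
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    if (k %% 2L == 0L) k <- k + 1L
    sm <- stats::filter(pct, rep(1 / k, k), sides = 2)
    keep <- !is.na(sm)
    pct <- as.numeric(sm[keep])
    x_um <- x_um[keep]
  }
  cross_down <- function(level, from = 1L) {
    for (i in seq(from, length(pct) - 1L)) {
      if (pct[i] >= level && pct[i + 1L] < level) {
        if (pct[i] == pct[i + 1L]) return(list(x = x_um[i], i = i))
        frac <- (pct[i] - level) / (pct[i] - pct[i + 1L])
        return(list(x = x_um[i] + frac * (x_um[i + 1L] - x_um[i]), i = i))
      }
    }
    NULL
  }
  cs <- cross_down(strong)
  if (is.null(cs)) {
    warning("profile never crosses the strong threshold; width undefined")
    return(NA_real_)
  }
  cw <- cross_down(weak, from = cs$i)
  if (is.null(cw)) {
    warning("profile never crosses the weak threshold; width undefined")
    return(NA_real_)
  }
  cw$x - cs$x
}
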