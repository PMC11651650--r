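#' FRAP trace container
#'
#' Bundles the time-stamped intensities needed to normalize a fluorescence
#' recovery after photobleaching (FRAP) experiment: the bleached region of
#' interest, the whole cell (acquisition-bleaching reference), the background,
#' and the pre-bleach anchor intensities.
#'
#' Pre-bleach samples are identified by negative time; `t = 0` is the first
#' post-bleach frame. If the pre-bleach anchors are not given they are taken
#' as the means of `I_frap` / `I_whole` over the pre-bleach rows.
#'
#' @param time_min time of each sample in minutes, strictly increasing;
#'   pre-bleach samples have negative time.
#' @param I_frap intensity of the bleached ROI at each time.
#' @param I_whole whole-cell intensity at each time.
#' @param I_base background intensity at each time (scalar recycled).
#' @param I_frap_pre,I_whole_pre pre-bleach anchor intensities; defaults are
#'   the means over pre-bleach rows.
#' @return An object of class `"frap_trace"`.
#' @seealso [normalize_trace()], [frap_fit()], [read_trace_csv()]
#' @export
frap_trace <- function(time_min, I_frap, I_whole, I_base = 0,
                       I_frap_pre = NULL, I_whole_pre = NULL) {
  time_min <- as.numeric(time_min)
  n <- length(time_min)
  I_frap <- rep_len(as.numeric(I_frap), n)
  I_whole <- rep_len(as.numeric(I_whole), n)
  I_base <- rep_len(as.numeric(I_base), n)
  if (n < 2L) stop("a FRAP trace needs at least two samples")
  if (any(diff(time_min) <= 0))
    stop("time must be strictly increasing")
  if (any(I_frap < 0) || any(I_whole < 0) || any(I_base < 0))
    stop("intensities must be non-negative")
  bad <- which(I_whole <= I_base)
  if (length(bad))
    stop(sprintf(
      "degenerate trace: whole-cell intensity <= background at t = %g min",
      time_min[bad[1L]]))
  pre <- time_min < 0
  if (is.null(I_frap_pre)) {
    if (!any(pre)) stop("no pre-bleach samples and no I_frap_pre given")
    I_frap_pre <- mean(I_frap[pre])
  }
  if (is.null(I_whole_pre)) {
    if (!any(pre)) stop("no pre-bleach samples and no I_whole_pre given")
    I_whole_pre <- mean(I_whole[pre])
  }
  if (I_frap_pre <= 0) stop("I_frap_pre must be positive")
  structure(
    list(time_min = time_min, I_frap = I_frap, I_whole = I_whole,
         I_base = I_base, I_frap_pre = I_frap_pre, I_whole_pre = I_whole_pre),
    class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  pre <- sum(x$time_min < 0)
  cat(sprintf(
    "FRAP trace: %d samples (%d pre-bleach), t = %g..%g min\n",
    length(x$time_min), pre, min(x$time_min), max(x$time_min)))
  invisible(x)
}

#' Double normalization of a FRAP trace
#'
#' Applies the standard double normalization: background-subtracted ROI
#' intensity divided by background-subtracted whole-cell intensity (correcting
#' for acquisition photobleaching), rescaled by the pre-bleach whole-cell to
#' ROI ratio so that the pre-bleach level maps to ~1,
#' \deqn{I_{norm}(t) = \frac{I_{frap}(t) - I_{base}(t)}{I_{whole}(t) -
#'   I_{base}(t)} \cdot \frac{I_{whole,pre}}{I_{frap,pre}}.}
#'
#' The result is invariant under uniform rescaling of all intensities by a
#' positive constant.
#'
#' @param trace a [frap_trace()].
#' @return A data frame with columns `time_min`, `intensity` (dimensionless)
#'   and `prebleach` (logical).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  y <- (trace$I_frap - trace$I_base) / (trace$I_whole - trace$I_base) *
    (trace$I_whole_pre / trace$I_frap_pre)
  data.frame(time_min = trace$time_min, intensity = y,
             prebleach = trace$time_min < 0)
}

#' Mobile fraction from anchor intensities
#'
#' The fraction of fluorescent protein exchanging into the bleached region by
#' the recovery plateau: `Mf = (F_end - F_post) / (F_pre - F_post)`.
#'
#' @param F_pre pre-bleach intensity.
#' @param F_post intensity immediately after bleaching; must be below `F_pre`.
#' @param F_end plateau intensity at the end of recovery.
#' @return The mobile fraction. Values above 1 (overshoot, e.g. from noise in
#'   the plateau estimate) are returned as computed with a warning.
#' @examples
#' mobile_fraction(F_pre = 1, F_post = 0.2, F_end = 0.784)  # 0.73
#' @export
mobile_fraction <- function(F_pre, F_post, F_end) {
  if (F_pre == F_post)
    stop("mobile fraction undefined: F_pre equals F_post")
  if (F_pre < F_post)
    stop("F_pre must exceed F_post")
  if (F_end < F_post)
    stop("F_end must be at least F_post")
  mf <- (F_end - F_post) / (F_pre - F_post)
  if (mf > 1)
    warning(sprintf("mobile fraction %.3f exceeds 1 (plateau above pre-bleach)", mf))
  mf
}

#' Exchange half-life from a rate constant
#'
#' Time at which half of the recoverable signal has returned for a
#' single-exponential association: `t_half = ln(2) / K`.
#'
#' @param K association rate constant, per minute; must be positive.
#' @return Half-life in minutes.
#' @export
half_life <- function(K) {
  if (any(K <= 0)) stop("K must be positive")
  log(2) / K
}
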