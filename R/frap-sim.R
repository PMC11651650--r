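#' Acquisition schedule for simulated FRAP traces
#'
#' The default time base: one pre-bleach frame, the first post-bleach frame at
#' t = 0, then every 5 min for the first 30 min, every 30 min up to 2 hr, and
#' every hour out to 14 hr of recovery (23 samples in total).
#'
#' @param prebleach_times times (min, negative) of pre-bleach frames; one by
#'   default.
#' @return Numeric vector of times in minutes, strictly increasing.
#' @export
frap_schedule <- function(prebleach_times = -5) {
  c(sort(prebleach_times), 0, seq(5, 30, by = 5),
    seq(60, 120, by = 30), seq(180, 840, by = 60))
}

#' Configuration for the FRAP trace simulator
#'
#' Defaults are the Z-disk titin conditions observed in myotubes: mobile
#' fraction 0.73, fast-phase share 37% with the fast phase recovering within
#' ~5 min and the slow phase over hours (overall half-life ~1.5 hr), 1%
#' relative Gaussian noise on the standard 23-point schedule.
#'
#' @param mobile_fraction fraction of protein that exchanges by the plateau,
#'   in \[0, 1\].
#' @param frac_fast share of the recoverable span carried by the fast rate,
#'   in \[0, 1\].
#' @param k_fast,k_slow association rates, per minute; `k_fast > k_slow`
#'   whenever both phases are present.
#' @param bleach_depth post-/pre-bleach intensity ratio in \[0, 1\].
#' @param noise_sd sd of additive Gaussian noise, relative intensity units.
#' @param acquisition_times strictly increasing times in minutes with at
#'   least one pre-bleach (negative) sample.
#' @param whole_cell_decay_rate acquisition photobleaching of the whole-cell
#'   signal, per minute.
#' @param background_level constant background intensity, relative units.
#' @param seed integer seed; the same seed reproduces the trace bit-for-bit.
#' @return An object of class `"frap_sim_config"`.
#' @export
frap_sim_config <- function(mobile_fraction = 0.73,
                            frac_fast = 0.37,
                            k_fast = log(2) / 2.5,
                            k_slow = log(2) / 90,
                            bleach_depth = 0.2,
                            noise_sd = 0.01,
                            acquisition_times = frap_schedule(),
                            whole_cell_decay_rate = 0,
                            background_level = 0.05,
                            seed = 1L) {
  cfg <- list(mobile_fraction = mobile_fraction, frac_fast = frac_fast,
              k_fast = k_fast, k_slow = k_slow, bleach_depth = bleach_depth,
              noise_sd = noise_sd, acquisition_times = acquisition_times,
              whole_cell_decay_rate = whole_cell_decay_rate,
              background_level = background_level, seed = as.integer(seed))
  validate_frap_sim_config(cfg)
  structure(cfg, class = "frap_sim_config")
}

validate_frap_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$acquisition_times))
  if (any(diff(cfg$acquisition_times) <= 0))
    stop("acquisition_times must be strictly increasing")
  if (!any(cfg$acquisition_times < 0))
    stop("acquisition_times must include at least one pre-bleach (negative) sample")
  if (cfg$mobile_fraction < 0 || cfg$mobile_fraction > 1)
    stop("mobile_fraction must be in [0, 1]")
  if (cfg$frac_fast < 0 || cfg$frac_fast > 1)
    stop("frac_fast must be in [0, 1]")
  if (!is.finite(cfg$k_fast) || !is.finite(cfg$k_slow) ||
      cfg$k_fast <= 0 || cfg$k_slow <= 0)
    stop("rates must be finite and positive")
  if (cfg$frac_fast > 0 && cfg$frac_fast < 1 && cfg$k_fast <= cfg$k_slow)
    stop("k_fast must exceed k_slow when both phases are present")
  if (cfg$bleach_depth < 0 || cfg$bleach_depth > 1)
    stop("bleach_depth must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$whole_cell_decay_rate < 0) stop("whole_cell_decay_rate must be >= 0")
  if (cfg$background_level < 0) stop("background_level must be >= 0")
  invisible(cfg)
}

# noiseless normalized recovery at post-bleach times t (minutes, t >= 0)
frap_model_curve <- function(t, y0, span, frac_fast, k_fast, k_slow) {
  y0 + span * (frac_fast * (1 - exp(-k_fast * t)) +
                 (1 - frac_fast) * (1 - exp(-k_slow * t)))
}

#' Simulate a FRAP trace with known ground truth
#'
#' Generates raw ROI / whole-cell / background intensities such that double
#' normalization ([normalize_trace()]) recovers the biphasic association
#' curve
#' \deqn{y(t) = y_0 + M_f (1 - y_0) [f (1 - e^{-k_{fast} t}) +
#'   (1 - f)(1 - e^{-k_{slow} t})]}
#' with \eqn{y_0} the bleach depth. Pre-bleach samples sit at relative
#' intensity 1. The whole-cell signal decays at the configured acquisition
#' photobleaching rate; Gaussian noise of sd `noise_sd` is added to the ROI
#' and whole-cell channels.
#'
#' @param config a [frap_sim_config()].
#' @return A list with components `trace` (a [frap_trace()]) and `truth`
#'   (the config plus the noiseless normalized recovery curve).
#' @export
gen_frap_trace <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  validate_frap_sim_config(config)
  t <- config$acquisition_times
  pre <- t < 0
  y0 <- config$bleach_depth
  span <- config$mobile_fraction * (1 - y0)
  y <- numeric(length(t))
  y[pre] <- 1
  y[!pre] <- frap_model_curve(t[!pre], y0, span, config$frac_fast,
                              config$k_fast, config$k_slow)
  b <- config$background_level
  # whole-cell signal above background; bleached ROI scales it by y(t)
  W <- exp(-config$whole_cell_decay_rate * pmax(t, 0))
  I_whole <- b + W
  I_frap <- b + y * W
  I_base <- rep(b, length(t))
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed, {
      matrix(stats::rnorm(2L * length(t), sd = config$noise_sd), ncol = 2L)
    })
    I_frap <- pmax(I_frap + noise[, 1L], 0)
    I_whole <- pmax(I_whole + noise[, 2L], I_base + 1e-6)
  }
  trace <- frap_trace(t, I_frap, I_whole, I_base,
                      I_frap_pre = b + 1, I_whole_pre = b + 1)
  truth <- list(
    config = config,
    normalized = data.frame(time_min = t,
                            intensity = ifelse(pre, 1, y)))
  list(trace = trace, truth = truth)
}

#' Simulate a fixed-cell (no-recovery) control trace
#'
#' Chemically fixed cells cannot exchange protein, so the bleached striated
#' pattern must not recover; any apparent recovery would indicate fluorophore
#' reactivation. The control forces the mobile fraction to zero and keeps
#' everything else from `config`.
#'
#' @param config a [frap_sim_config()]; its `mobile_fraction` is ignored.
#' @return A [frap_trace()].
#' @export
gen_fixed_cell_trace <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  cfg <- config
  cfg$mobile_fraction <- 0
  gen_frap_trace(cfg)$trace
}
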