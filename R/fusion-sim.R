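#' Configuration for the two-channel fusion movie simulator
#'
#' Emulates a time lapse of a red-labelled and a green-labelled myocyte that
#' fuse: before the fusion frame each label fills its own half of the fiber;
#' from the fusion frame on, each species spreads along the fiber axis by
#' 1-D diffusion with first-order decay, replenished at a fixed-concentration
#' source at its nuclear domain. Transport is 1-D along the fiber axis and
#' broadcast across the fiber width; frames are imaged at two frames per
#' hour by default.
#'
#' @param fiber_length,fiber_width fiber dimensions, µm.
#' @param pixel_size µm per pixel (isotropic). The default 0.5 µm keeps the
#'   explicit transport substeps tractable; 0.1311 µm is the microscope
#'   pixel pitch and is accepted.
#' @param frame_interval minutes between frames (30 = two frames per hour).
#' @param n_frames number of frames.
#' @param fusion_frame 1-based index of the first frame after membrane
#'   breakdown; earlier frames show disjoint labels. Must be < `n_frames`.
#' @param D_red,D_green diffusion coefficients, µm²/s.
#' @param tau protein half-life, s.
#' @param source_positions list with `red` and `green` nuclear-domain centre
#'   positions along the fiber, µm.
#' @param source_halfwidth half-width of each nuclear source region, µm.
#' @param noise_sd sd of additive Gaussian noise, relative intensity units
#'   (1 = positive calibration anchor).
#' @param seed integer seed.
#' @return An object of class `"fusion_sim_config"`.
#' @export
fusion_sim_config <- function(fiber_length = 200, fiber_width = 20,
                              pixel_size = 0.5, frame_interval = 30,
                              n_frames = 17L, fusion_frame = 2L,
                              D_red = 0.3, D_green = 0.3,
                              tau = 3.024e5,
                              source_positions = list(red = 10,
                                                      green = fiber_length - 10),
                              source_halfwidth = 5,
                              noise_sd = 0.01, seed = 1L) {
  cfg <- list(fiber_length = fiber_length, fiber_width = fiber_width,
              pixel_size = pixel_size, frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              fusion_frame = as.integer(fusion_frame),
              D_red = D_red, D_green = D_green, tau = tau,
              source_positions = source_positions,
              source_halfwidth = source_halfwidth,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_fusion_sim_config(cfg)
  structure(cfg, class = "fusion_sim_config")
}

validate_fusion_sim_config <- function(cfg) {
  if (cfg$pixel_size <= 0) stop("pixel_size must be positive")
  if (cfg$D_red < 0 || cfg$D_green < 0) stop("diffusion coefficients must be >= 0")
  if (cfg$tau <= 0) stop("tau must be positive")
  if (cfg$fusion_frame >= cfg$n_frames)
    stop("fusion_frame must be < n_frames")
  if (cfg$fusion_frame < 1L) stop("fusion_frame must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  sp <- cfg$source_positions
  if (!all(c("red", "green") %in% names(sp)))
    stop("source_positions needs 'red' and 'green'")
  if (any(unlist(sp) < 0) || any(unlist(sp) > cfg$fiber_length))
    stop("source positions must lie within the fiber")
  mid <- cfg$fiber_length / 2
  if (sp$red >= mid || sp$green <= mid)
    stop("red source must lie in the left half and green in the right half ",
         "(pre-fusion masks must be disjoint)")
  invisible(cfg)
}

quantize16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

#' Simulate a two-channel fusion movie with ground truth
#'
#' Builds a (time, channel, y, x) intensity stack on the configured grid.
#' Concentrations are in percent of the calibration anchor (100 = a bright
#' positive cell); channel intensities are concentration / 100 with Gaussian
#' noise added and quantized to the 16-bit camera grid. Ground-truth mixing
#' maps are computed from the quantized noiseless fields with
#' [classify_pixels()] under an identity calibration (0 -> 0%, 1 -> 100%).
#'
#' @param config a [fusion_sim_config()].
#' @return A list with `stack` (array T x 2 x Y x X, channel 1 red),
#'   `times_hr`, `pixel_size`, and `truth` (config, per-frame noiseless 1-D
#'   concentration profiles `conc_red` / `conc_green`, and `class_maps`).
#' @export
gen_fusion_movie <- function(config) {
  stopifnot(inherits(config, "fusion_sim_config"))
  validate_fusion_sim_config(config)
  px <- config$pixel_size
  nx <- max(3L, round(config$fiber_length / px))
  ny <- max(1L, round(config$fiber_width / px))
  x <- (seq_len(nx) - 0.5) * px
  mid <- config$fiber_length / 2
  red_mask <- x < mid
  sp <- config$source_positions
  hw <- config$source_halfwidth
  src_red <- list(from = sp$red - hw, to = sp$red + hw, c0 = 100)
  src_green <- list(from = sp$green - hw, to = sp$green + hw, c0 = 100)

  nt <- config$n_frames
  frame_s <- config$frame_interval * 60
  t_post <- (seq(config$fusion_frame, nt) - config$fusion_frame) * frame_s
  Dmax <- max(config$D_red, config$D_green)
  dt <- if (Dmax > 0) 0.8 * px^2 / (2 * Dmax) else frame_s
  dt <- frame_s / max(1, ceiling(frame_s / dt))  # whole substeps per frame

  evolve <- function(init, D, src) {
    simulate_1d(init, D = D, tau = config$tau, dx = px, dt = dt,
                t_out = t_post, source = src)$profiles
  }
  conc_red <- matrix(NA_real_, nt, nx)
  conc_green <- matrix(NA_real_, nt, nx)
  pre <- seq_len(config$fusion_frame - 1L)
  for (f in pre) {
    conc_red[f, ] <- ifelse(red_mask, 100, 0)
    conc_green[f, ] <- ifelse(red_mask, 0, 100)
  }
  conc_red[config$fusion_frame:nt, ] <-
    evolve(ifelse(red_mask, 100, 0), config$D_red, src_red)
  conc_green[config$fusion_frame:nt, ] <-
    evolve(ifelse(red_mask, 0, 100), config$D_green, src_green)

  stack <- array(NA_real_, c(nt, 2L, ny, nx))
  class_maps <- vector("list", nt)
  noise <- if (config$noise_sd > 0)
    with_seed(config$seed,
              array(stats::rnorm(nt * 2L * ny * nx, sd = config$noise_sd),
                    c(nt, 2L, ny, nx)))
  else NULL
  for (f in seq_len(nt)) {
    r2d <- matrix(rep(conc_red[f, ] / 100, each = ny), ny, nx)
    g2d <- matrix(rep(conc_green[f, ] / 100, each = ny), ny, nx)
    rq <- quantize16(r2d)
    gq <- quantize16(g2d)
    class_maps[[f]] <- classify_pixels(100 * rq, 100 * gq, pixel_size = px)
    if (!is.null(noise)) {
      rq <- quantize16(r2d + noise[f, 1L, , ])
      gq <- quantize16(g2d + noise[f, 2L, , ])
    }
    stack[f, 1L, , ] <- rq
    stack[f, 2L, , ] <- gq
  }
  list(stack = stack,
       times_hr = (seq_len(nt) - 1L) * config$frame_interval / 60,
       pixel_size = px,
       truth = list(config = config, conc_red = conc_red,
                    conc_green = conc_green, class_maps = class_maps))
}

#' Identity calibration for synthetic movies
#'
#' Synthetic stacks store intensities with 0 = negative and 1 = positive
#' anchor, so calibration is the identity mapping to percent.
#'
#' @param channel `"red"` or `"green"`.
#' @return A `"channel_calibration"` with `I_neg = 0`, `I_pos = 1`.
#' @export
identity_calibration <- function(channel = c("red", "green")) {
  channel <- match.arg(channel)
  structure(list(I_neg = 0, I_pos = 1, channel = channel),
            class = "channel_calibration")
}
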