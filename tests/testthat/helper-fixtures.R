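# small shared fixtures for unit tests

quiet_fit <- function(...) suppressWarnings(frap_fit(...))

# a coarse fusion movie that runs in well under a second
small_fusion_config <- function(...) {
  args <- list(fiber_length = 100, fiber_width = 10, pixel_size = 2,
               n_frames = 9L, fusion_frame = 2L, noise_sd = 0,
               source_positions = list(red = 10, green = 90))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fusion_sim_config, args)
}

noiseless_frap <- function(...) {
  gen_frap_trace(frap_sim_config(noise_sd = 0, ...))
}
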