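test_that("the default acquisition schedule has 23 points", {
  # pre-bleach, t = 0, every 5 min to 30 min, every 30 min to 2 hr,
  # hourly to 14 hr
  expect_length(frap_schedule(), 23L)
  expect_equal(sum(frap_schedule() < 0), 1L)
})

test_that("an immobile protein never recovers", {
  sim <- gen_frap_trace(frap_sim_config(mobile_fraction = 0, noise_sd = 0,
                                        bleach_depth = 0.2))
  y <- normalize_trace(sim$trace)
  post <- !y$prebleach
  expect_equal(y$intensity[post], rep(0.2, sum(post)), tolerance = 1e-12)
})

test_that("one half-life of a monophasic recovery restores half the span", {
  cfg <- frap_sim_config(frac_fast = 1, k_fast = log(2), noise_sd = 0,
                         acquisition_times = c(-5, 0, 1, 2, 5, 10, 30))
  truth <- gen_frap_trace(cfg)$truth$normalized
  y0 <- cfg$bleach_depth
  span <- cfg$mobile_fraction * (1 - y0)
  expect_equal(truth$intensity[truth$time_min == 1], y0 + 0.5 * span,
               tolerance = 1e-12)
})

test_that("pre-bleach samples sit at relative intensity 1", {
  for (seed in c(1, 42)) {
    tr <- gen_fixed_cell_trace(frap_sim_config(seed = seed, noise_sd = 0))
    y <- normalize_trace(tr)
    expect_equal(mean(y$intensity[y$prebleach]), 1, tolerance = 1e-12)
  }
})

test_that("the same seed reproduces traces bit-for-bit", {
  a <- gen_frap_trace(frap_sim_config(seed = 11))
  b <- gen_frap_trace(frap_sim_config(seed = 11))
  expect_identical(a, b)
  c <- gen_frap_trace(frap_sim_config(seed = 12))
  expect_false(identical(a$trace$I_frap, c$trace$I_frap))
})

test_that("fixed-cell control equals an immobile simulation", {
  cfg <- frap_sim_config(noise_sd = 0)
  fixed <- gen_fixed_cell_trace(cfg)
  immobile <- gen_frap_trace(frap_sim_config(mobile_fraction = 0,
                                             noise_sd = 0))$trace
  expect_equal(fixed$I_frap, immobile$I_frap, tolerance = 1e-12)
})

test_that("invalid simulator configs are rejected", {
  expect_error(frap_sim_config(acquisition_times = c(0, 5, 5)),
               "strictly increasing")
  expect_error(frap_sim_config(acquisition_times = c(0, 5, 10)),
               "pre-bleach")
  expect_error(frap_sim_config(frac_fast = 1.2), "frac_fast")
  expect_error(frap_sim_config(k_fast = 0.01, k_slow = 0.1), "k_fast")
  expect_error(frap_sim_config(k_fast = Inf), "finite")
})

test_that("fusion movies are deterministic and honour degenerate transport", {
  cfg <- small_fusion_config(noise_sd = 0.01, seed = 3)
  expect_identical(gen_fusion_movie(cfg), gen_fusion_movie(cfg))

  # no transport: both channels static after fusion, mixed area stays 0
  cfg0 <- small_fusion_config(D_red = 0, D_green = 0, tau = Inf)
  mv <- gen_fusion_movie(cfg0)
  expect_equal(mv$stack[1, , , ], mv$stack[dim(mv$stack)[1], , , ],
               tolerance = 1e-12)
  mixed_area <- vapply(mv$truth$class_maps,
                       function(m) measure_areas(m)[["mixed"]], numeric(1))
  expect_equal(mixed_area, rep(0, length(mixed_area)))
})

test_that("symmetric fusion movies are invariant under red/green swap", {
  mv <- gen_fusion_movie(small_fusion_config())
  for (f in c(1, 5, 9)) {
    a <- measure_areas(mv$truth$class_maps[[f]])
    expect_equal(a[["only_red"]], a[["only_green"]])
    expect_equal(a[["majority_red"]], a[["majority_green"]])
  }
})

test_that("label mass without sources decays at the configured half-life", {
  tau <- 3600
  sim <- simulate_1d(rep(100, 60), D = 0.2, tau = tau, dx = 1, dt = 2,
                     t_out = seq(0, 3 * tau, by = tau / 2))
  expected <- sim$mass[1] * exp(-log(2) * sim$times / tau)
  expect_equal(sim$mass, expected, tolerance = 0.01)
})

test_that("steady-state invasion profile follows the decay length", {
  # D = 0.3 um^2/s, tau = 3.024e5 s -> lambda ~ 361.8 um
  lam <- decay_length(0.3, 3.024e5, ln2 = 0.693)
  expect_equal(lam, 361.8, tolerance = 1e-3)
})

test_that("overlapping pre-fusion masks are rejected", {
  expect_error(
    fusion_sim_config(fiber_length = 100,
                      source_positions = list(red = 80, green = 90)),
    "disjoint")
  expect_error(fusion_sim_config(n_frames = 5, fusion_frame = 5),
               "fusion_frame")
})
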