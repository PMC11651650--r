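test_that("a noiseless monophasic curve is recovered to machine accuracy", {
  # K = 0.00236 / min -> t_half = ln2 / K ~ 294 min ~ 4.9 hr
  cfg <- frap_sim_config(frac_fast = 1, k_fast = 0.00236, noise_sd = 0)
  fit <- frap_fit(gen_frap_trace(cfg)$trace, model = "one")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["K"]), 0.00236, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.00236, tolerance = 1e-6)
  expect_equal(fit$t_half / 60, 4.9, tolerance = 0.01)
  expect_equal(fit$mobile_fraction, cfg$mobile_fraction, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["y0"]), cfg$bleach_depth, tolerance = 1e-6)
})

test_that("a noiseless biphasic curve is recovered to machine accuracy", {
  cfg <- frap_sim_config(noise_sd = 0)  # f = 0.37, rate ratio 36
  fit <- frap_fit(gen_frap_trace(cfg)$trace, model = "two")
  expect_equal(unname(coef(fit)["K_fast"]), cfg$k_fast, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["K_slow"]), cfg$k_slow, tolerance = 1e-3)
  expect_equal(fit$percent_fast, 37, tolerance = 1e-3)
  expect_equal(fit$mobile_fraction, 0.73, tolerance = 1e-6)
})

test_that("a flat curve yields a vanishing fitted span", {
  cfg <- frap_sim_config(mobile_fraction = 0, noise_sd = 0)
  fit <- quiet_fit(gen_frap_trace(cfg)$trace, model = "one")
  expect_lt(fit$Mf, 1e-3)
})

test_that("the two-phase model nests the one-phase model", {
  sim <- gen_frap_trace(frap_sim_config(frac_fast = 1, k_fast = 0.05,
                                        noise_sd = 0))
  f1 <- frap_fit(sim$trace, model = "one")
  f2 <- frap_fit(sim$trace, model = "two")
  expect_lte(f2$rss, f1$rss + 1e-9)
})

test_that("rate ordering is enforced regardless of generator input", {
  t <- seq(0, 840, by = 20)
  y <- 0.2 + 0.5 *
    (0.6 * (1 - exp(-0.005 * t)) + 0.4 * (1 - exp(-0.2 * t)))
  fit <- frap_fit(data.frame(time_min = t, intensity = y), model = "two")
  co <- coef(fit)
  expect_gt(co[["K_fast"]], co[["K_slow"]])
  expect_equal(co[["K_fast"]], 0.2, tolerance = 1e-4)
  expect_equal(co[["frac_fast"]], 0.4, tolerance = 1e-4)
})

test_that("the fitted half-life halves the recoverable span", {
  fit <- frap_fit(noiseless_frap()$trace, model = "two")
  y_half <- predict(fit, fit$t_half)
  co <- coef(fit)
  expect_equal(unname(y_half - co["y0"]), fit$Mf / 2, tolerance = 1e-8)
})

test_that("noisy recovery estimates land near the truth", {
  cfg <- frap_sim_config(noise_sd = 0.01, seed = 5)
  fit <- frap_fit(gen_frap_trace(cfg)$trace, model = "two")
  expect_lt(abs(fit$mobile_fraction - 0.73), 0.03)
})

test_that("model selection behaves on identical and nested fits", {
  sim <- gen_frap_trace(frap_sim_config(frac_fast = 1, k_fast = 0.01,
                                        noise_sd = 0.01, seed = 2))
  f1 <- frap_fit(sim$trace, model = "one")
  # identical rss -> p = 1, one-phase chosen
  f2_fake <- frap_fit(sim$trace, model = "two")
  f2_fake$rss <- f1$rss
  sel <- select_model(f1, f2_fake)
  expect_equal(sel$p_value, 1)
  expect_equal(sel$model, "one_phase")
  # pathological rss ordering -> one-phase with a warning
  f2_fake$rss <- f1$rss * 2
  expect_warning(sel2 <- select_model(f1, f2_fake), "one-phase")
  expect_equal(sel2$model, "one_phase")
})

test_that("auto selection prefers two-phase on strongly biphasic data", {
  sim <- gen_frap_trace(frap_sim_config(noise_sd = 0.01, seed = 9))
  fit <- frap_fit(sim$trace, model = "auto")
  expect_equal(fit$model, "two_phase")
  expect_lt(fit$selection$p_value, 0.05)
})

test_that("fit methods are coherent", {
  fit <- frap_fit(noiseless_frap()$trace, model = "two")
  expect_equal(fitted(fit) + residuals(fit), fit$data$intensity)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(length(coef(fit)), 5L)
  expect_output(print(fit), "two-phase")
  tab <- frap_fit_table(list(fit))
  expect_equal(tab$percent_fast, fit$percent_fast)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_points, 3L))
})

test_that("failed fits return diagnostics instead of throwing", {
  # two points are below the precondition for any fit
  expect_error(frap_fit(data.frame(time_min = 0:2, intensity = 1),
                        model = "one"), "at least 4")
  expect_error(frap_fit(data.frame(time_min = 0:4, intensity = 1),
                        model = "two"), "at least 6")
})
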