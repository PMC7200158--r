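small_cfg <- function(...) {
  tirf_sim_config(size = 64, n_spots = 5, frames = 6, seed = 2, ...)
}

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_tirf_stack(small_cfg())
  s2 <- simulate_tirf_stack(small_cfg())
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_mals_series(500, 10, c(0.5, 1, 2), 0.05, 11, seed = 4)
  m2 <- simulate_mals_series(500, 10, c(0.5, 1, 2), 0.05, 11, seed = 4)
  expect_identical(m1, m2)
  f1 <- simulate_mgv_fields(10, 10, seed = 5)
  expect_identical(f1, simulate_mgv_fields(10, 10, seed = 5))
})

test_that("noise-free signal obeys photon conservation", {
  cfg <- small_cfg(background = 0, background_gradient = 0,
                   shot_noise = FALSE, read_noise_sd = 0)
  sim <- simulate_tirf_stack(cfg)
  for (f in 1:6) {
    frame_sum <- sum(sim$stack$data[f, , ])
    alive <- sum(sim$truth$per_frame$surviving[sim$truth$per_frame$frame == f])
    expect_equal(frame_sum, 120 * alive, tolerance = 1e-6)
    expect_equal(sim$truth$signal_sum[f], frame_sum, tolerance = 1e-9)
  }
  # one 3-fluorophore spot integrates to exactly 3 g before noise
  cfg1 <- tirf_sim_config(size = 64, n_spots = 1, frames = 1,
                          copy_probs = c(0, 0, 1), background = 0,
                          background_gradient = 0, shot_noise = FALSE,
                          read_noise_sd = 0, bleach_rate = 0, seed = 3)
  sim1 <- simulate_tirf_stack(cfg1)
  expect_equal(sum(sim1$stack$data), 3 * 120, tolerance = 1e-6)
})

test_that("an empty field reproduces the background noise model", {
  cfg <- tirf_sim_config(size = 256, n_spots = 0, frames = 2,
                         background = 50, background_gradient = 0,
                         read_noise_sd = 3, seed = 6)
  sim <- simulate_tirf_stack(cfg)
  fr <- sim$stack$data[1, , ]
  expect_equal(mean(fr), 50, tolerance = 0.01 * 50)
  # variance ~ Poisson + read noise (clamping at zero is negligible here)
  expect_equal(var(as.vector(fr)), 50 + 9, tolerance = 0.05 * 59)
})

test_that("ensemble bleaching decays at the configured rate", {
  cfg <- tirf_sim_config(size = 256, n_spots = 200, frames = 25,
                         bleach_rate = 0.05, shot_noise = FALSE,
                         read_noise_sd = 0, diffusion_sd = 0, seed = 7)
  sim <- simulate_tirf_stack(cfg)
  pf <- sim$truth$per_frame
  nbar <- mean(sim$truth$spots$n)
  for (t in c(5, 15, 25)) {
    obs <- mean(pf$intensity[pf$frame == t])
    expected <- 120 * nbar * exp(-0.05 * (t - 1))
    # binomial sampling error over 200 spots
    se <- 120 * sqrt(nbar * exp(-0.05 * (t - 1)) *
                       (1 - exp(-0.05 * (t - 1))) / 200)
    expect_lt(abs(obs - expected), 4 * se + 1e-9)
  }
})

test_that("the MALS series forward model hits the worked values", {
  s <- simulate_mals_series(946.554, 10, 0.71, 0, 11)
  expect_equal(s$average_mass_kDa, 15, tolerance = 1e-4)
  s2 <- simulate_mals_series(1e12, 10, c(0.5, 1), 0, 11)
  expect_equal(s2$average_mass_kDa, c(10, 10), tolerance = 1e-6)
  expect_error(simulate_mals_series(-5, 10, 1, 0, 11), "kd")
})

test_that("MGV field groups carry the configured effect", {
  f <- simulate_mgv_fields(40, 40, baseline = 100, effect_frac = 0.15,
                           noise_sd = 5, seed = 8)
  expect_length(f$a, 40)
  expect_length(f$b, 40)
  expect_equal(mean(f$a), 115, tolerance = 0.03 * 115)
  expect_equal(mean(f$b), 100, tolerance = 0.03 * 100)
  expect_error(simulate_mgv_fields(0, 10), ">= 1")
})

test_that("configuration invariants are enforced", {
  expect_error(tirf_sim_config(copy_probs = c(0.5, 0.4)), "sum to 1")
  expect_error(tirf_sim_config(frames = 0), "frames")
  expect_error(tirf_sim_config(g = -1), "> 0")
  expect_error(tirf_sim_config(bleach_rate = -0.1), ">= 0")
})
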