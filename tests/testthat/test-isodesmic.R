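test_that("dimer-truncated solve matches hand algebra", {
  # c_tot = 1000, M_avg = 12.5: m + 2d = 1000, (10m + 20d)/(m + d) = 12.5
  # => d = 200, m = 600, K = m^2/d = 1800
  fit <- solve_isodesmic(isodesmic_system(1000, 10, 2), 12.5)
  expect_equal(fit$distribution$concentrations, c(600, 200),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$kd$kd, 1800, tolerance = 1e-8)

  # M_avg = 1.5 M1 at N = 2 forces m = d = c_tot / 3
  fit2 <- solve_isodesmic(isodesmic_system(710, 10, 2), 15)
  expect_equal(fit2$distribution$concentrations, c(710 / 3, 710 / 3),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit2$kd$kd, 710 / 3, tolerance = 1e-6)
})

test_that("trimer-truncated solve matches the closed-form root", {
  # with x = d/m, the mass constraint at N = 3, M_avg = 1.5 M1 reduces to
  # 3x^2 + x - 1 = 0
  x <- (-1 + sqrt(13)) / 6
  fit <- solve_isodesmic(isodesmic_system(710, 10, 3), 15)
  m <- fit$distribution$concentrations[1]
  d <- fit$distribution$concentrations[2]
  expect_equal(d / m, x, tolerance = 1e-6)
  expect_equal(fit$kd$kd, m / x, tolerance = 1e-6)
})

test_that("solver agrees with a brute-force (m, K) grid search", {
  for (N in 2:5) {
    fit <- solve_isodesmic(isodesmic_system(710, 10, N), 15)
    gs <- grid_search_kd(710, 10, 15, N)
    expect_lt(abs(fit$kd$kd - gs["k"]) / gs["k"], 0.01)
    expect_lt(abs(fit$distribution$concentrations[1] - gs["m"]), 1)
  }
})

test_that("solutions conserve protomers and have equal stepwise K", {
  for (N in c(2, 5, 11, 50)) for (mavg in c(11, 15, 25)) {
    if (mavg >= 10 * N) next
    fit <- solve_isodesmic(isodesmic_system(710, 10, N), mavg)
    conc <- fit$distribution$concentrations
    n <- seq_along(conc)
    expect_lt(abs(sum(n * conc) - 710) / 710, 1e-8)
    expect_equal(fit$distribution$number_average_mass, mavg,
                 tolerance = 1e-8)
    if (N > 2) {
      k_step <- conc[1] * conc[1:(N - 1)] / conc[2:N]
      expect_lt(diff(range(k_step)) / k_step[1], 1e-6)
    }
    expect_true(all(conc >= 0))
  }
})

test_that("K_D is non-decreasing in truncation order and converges", {
  tab <- convergence_table(710, 10, 15, 2:11)
  expect_true(all(diff(tab$kd_nM) >= 0))
  expect_lt(abs(tab$kd_nM[10] - infinite_limit_kd(15, 10, 710)), 1)
  # successive high orders differ by < 1 nM
  expect_lt(tab$kd_nM[10] - tab$kd_nM[9], 1)
})

test_that("infinite-limit closed form is the large-N solver limit", {
  expect_equal(infinite_limit_kd(15, 10, 710), 710 * (2 / 3)^2 / (1 / 3),
               tolerance = 1e-12)
  expect_equal(infinite_limit_kd(20, 10, 1000), 500, tolerance = 1e-12)
  big <- solve_isodesmic(isodesmic_system(710, 10, 200), 15)$kd$kd
  expect_equal(big, infinite_limit_kd(15, 10, 710), tolerance = 1e-6)
})

test_that("forward model round-trips with the solver", {
  for (N in c(2, 3, 11)) {
    fit <- solve_isodesmic(isodesmic_system(710, 10, N), 15)
    expect_equal(predict_average_mass(fit$kd$kd, 710, 10, N), 15,
                 tolerance = 1e-6)
  }
  expect_equal(predict_average_mass(1800, 1000, 10, 2), 12.5,
               tolerance = 1e-8)
  # no-association limit
  expect_equal(predict_average_mass(1e12, 710, 10, 11), 10,
               tolerance = 1e-6)
})

test_that("infeasible average masses raise informative errors", {
  sys <- isodesmic_system(710, 10, 11)
  expect_error(solve_isodesmic(sys, 10), "infeasible")
  expect_error(solve_isodesmic(sys, 9), "infeasible")
  expect_error(solve_isodesmic(sys, 110), "infeasible")
  expect_error(solve_isodesmic(isodesmic_system(710, 10, 1), 15),
               "max_order")
  expect_error(infinite_limit_kd(10, 10, 710), "exceed")
  expect_error(isodesmic_system(-1, 10, 2))
  expect_error(isodesmic_system(710, 0, 2))
})

test_that("oligomer count is the mass ratio", {
  expect_equal(oligomer_count(90, 9.9), 90 / 9.9)
  expect_true(oligomer_count(90, 9.9) > 8 && oligomer_count(90, 9.9) < 10)
  expect_equal(oligomer_count(9.9, 9.9), 1)
  expect_equal(round(oligomer_count(41, 9.9)), 4)
  expect_error(oligomer_count(-1, 9.9))
  expect_error(oligomer_count(90, 0))
})

test_that("series fitting recovers the generating K_D", {
  s <- simulate_mals_series(500, 10, c(0.2, 0.5, 1, 2, 5), 0, 11)
  fit <- fit_kd_to_series(s, 10, 11)
  expect_equal(fit$kd, 500, tolerance = 1e-4)

  # one row reduces to the direct solve
  f1 <- fit_kd_to_series(mals_series(0.71, 15), 10, 11)
  expect_equal(f1$kd, solve_isodesmic(isodesmic_system(710, 10, 11), 15)$kd$kd,
               tolerance = 1e-5)
})

test_that("noisy series fit lands in the grid-search bracket", {
  s <- simulate_mals_series(500, 10, c(0.2, 0.5, 1, 2, 5),
                            noise_sd_frac = 0.05, max_order = 11, seed = 7)
  fit <- fit_kd_to_series(s, 10, 11)
  # 1-D grid oracle over K on the same objective
  kg <- exp(seq(log(50), log(5000), length.out = 600))
  sse <- vapply(kg, function(k) {
    pred <- vapply(s$detector_conc_uM * 1e3, function(ct)
      predict_average_mass(k, ct, 10, 11), numeric(1))
    sum((pred - s$average_mass_kDa)^2)
  }, numeric(1))
  jbest <- which.min(sse)
  expect_gt(fit$kd, kg[max(1, jbest - 1)])
  expect_lt(fit$kd, kg[min(length(kg), jbest + 1)])
})

test_that("mals_series validates its rows", {
  expect_error(mals_series(numeric(0), numeric(0)), "one row")
  expect_error(mals_series(c(1, 1), c(10, 20)), "unique")
  expect_error(mals_series(c(1, -2), c(10, 20)), "positive")
  expect_error(fit_kd_to_series(mals_series(0.71, 9), 10, 11), "infeasible")
})
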