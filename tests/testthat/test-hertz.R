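test_that("hertz_force follows the sphere-on-half-space closed form", {
  expect_equal(hertz_force(0, 10, 0.5, 5), 0)
  # direct evaluation: (4/3) * (10/0.75) * sqrt(5) * 1^1.5 nN
  expect_equal(hertz_force(1, 10, 0.5, 5), (4 / 3) * (10 / 0.75) * sqrt(5),
               tolerance = 1e-12)
  expect_equal(hertz_force(1, 10, 0.5, 5), 39.75, tolerance = 1e-3)
  # delta^(3/2) power law
  expect_equal(hertz_force(4, 10, 0.5, 5) / hertz_force(1, 10, 0.5, 5), 8,
               tolerance = 1e-12)
  expect_equal(hertz_force(-1, 10, 0.5, 5), 0)
  # SI consistency: kPa/um inputs equal the SI value in N times 1e9
  FSI <- (4 / 3) * (10e3 / 0.75) * sqrt(5e-6) * (1e-6)^1.5
  expect_equal(hertz_force(1, 10, 0.5, 5), FSI * 1e9, tolerance = 1e-12)
})

test_that("indentation kinematics subtract the cantilever deflection", {
  # rigid surface: deflection equals piezo travel past contact, so delta = 0
  z <- seq(-1, 2, length.out = 100)
  d_nm <- pmax(z - 0.5, 0) * 1000
  cv <- force_curve(z = z, deflection = d_nm, k = 0.08, R = 5)
  ind <- to_indentation(cv, 0.5)
  expect_lt(max(abs(ind$delta_um[z >= 0.5])), 1e-12)
  # nanoindenter reports indentation directly
  cvn <- force_curve(z = z, force = pmax(z, 0), k = 4.14, R = 45.5,
                     instrument = "nanoindenter")
  expect_equal(to_indentation(cvn, 0)$delta_um, z)
  expect_error(force_curve(z = z, k = 0.08, R = 5), "exactly one")
  # synthetic generator round-trips its own (delta, force)
  cv2 <- gen_force_curves(10, z0 = 0.3, noise_sd = 0, seed = 3)[[1]]
  ind2 <- to_indentation(cv2, 0.3)
  expect_lt(max(abs(ind2$delta_um - cv2$meta$delta_true)), 1e-9)
  expect_lt(max(abs(ind2$force_nN - cv2$meta$force_true)), 1e-9)
})

test_that("noiseless fits recover modulus and contact point to 0.1 percent", {
  for (instr in c("afm", "nanoindenter")) {
    cv <- gen_force_curves(12, z0 = 0.3, noise_sd = 0, instrument = instr,
                           seed = 5)[[1]]
    fit <- fit_hertz(cv)
    expect_true(fit$valid)
    expect_lt(abs(fit$E_kPa - 12) / 12, 1e-3)
    expect_lt(abs(fit$z0_um - 0.3), 1e-3)
  }
})

test_that("recovered modulus is monotone in the true modulus", {
  Es <- c(1, 3, 10, 30, 100)
  Ehat <- vapply(Es, function(E) {
    fit_hertz(gen_force_curves(E, noise_sd = 0, seed = 17)[[1]])$E_kPa
  }, numeric(1))
  expect_true(all(diff(Ehat) > 0))
})

test_that("noisy recovery stays within 5 percent median error", {
  curves <- gen_force_curves(10, z0 = 0.3, noise_sd = 0.02, n = 100,
                             seed = 21)
  Ehat <- vapply(curves, function(cv) fit_hertz(cv)$E_kPa, numeric(1))
  expect_lt(stats::median(abs(Ehat - 10) / 10), 0.05)
})

test_that("a constant force baseline is absorbed by the 3-parameter fit", {
  cv <- gen_force_curves(10, z0 = 0.3, noise_sd = 0, seed = 9)[[1]]
  cvb <- cv; cvb$force_nN <- cv$force_nN + 0.8
  fb <- fit_hertz(cvb, baseline = TRUE)
  expect_lt(abs(fb$E_kPa - 10) / 10, 0.005)
  expect_equal(fb$baseline_nN, 0.8, tolerance = 0.05)
})

test_that("degenerate curves are flagged invalid rather than erroring", {
  z <- seq(0, 3, length.out = 200)
  rigid <- force_curve(z = z, deflection = pmax(z - 1, 0) * 1000, k = 0.08,
                       R = 5)
  fit <- fit_hertz(rigid)
  expect_false(fit$valid)
  expect_error(fit_hertz(force_curve(z = 1:10, force = 1:10, k = 1, R = 5)),
               "at least 50")
})

test_that("aggregation schemes pool fits as specified", {
  expect_equal(aggregate_fits(c(8, 10, 12))$mean, 10)
  expect_equal(aggregate_fits(c(8, 10, 12))$sd, 2)
  expect_equal(aggregate_fits(c(8, 10, 12))$n, 3)
  one <- aggregate_fits(5)
  expect_equal(one$mean, 5)
  # per-unit medians differ from the pooled mean under skew
  set.seed(31)
  E <- exp(rnorm(300, log(10), 0.6))
  unit <- rep(1:10, each = 30)
  pooled <- aggregate_fits(E)
  byunit <- aggregate_fits(E, "median_per_unit", unit)
  expect_lt(byunit$mean, pooled$mean)  # lognormal: median < mean
  expect_error(aggregate_fits(rep(NA_real_, 3)), "no valid fits")
})
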