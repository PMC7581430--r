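ref_dims <- epiphysis_dims(height = 2, top_d1 = 4, top_d2 = 3,
                           side_d1 = 3.5, side_d2 = 2.5)

test_that("deformation series is contact-referenced and offset-invariant", {
  # positions already zero-referenced: identity at zero threshold
  rec <- list(position_mm = seq(0, 1, length.out = 101),
              load_N = 2.5 * seq(0, 1, length.out = 101))
  expect_equal(deformation_series(rec, threshold = 0), rec$position_mm,
               tolerance = 1e-12)
  # default threshold shifts by the position at 2 percent load only
  expect_lt(max(abs(deformation_series(rec) - rec$position_mm)), 0.021)
  # uniform position offset leaves the output unchanged
  rec2 <- rec; rec2$position_mm <- rec$position_mm + 7.3
  expect_equal(deformation_series(rec2), deformation_series(rec),
               tolerance = 1e-12)
  # approach phase then ramp: contact point recovered
  recf <- list(position_mm = c(seq(-0.5, 0, length.out = 50),
                               seq(0.01, 1, length.out = 100)),
               load_N = c(rep(0, 50), 2.5 * seq(0.01, 1, length.out = 100)))
  expect_lt(max(abs(deformation_series(recf)[51:150] -
                    recf$position_mm[51:150])), 0.03)
  expect_error(deformation_series(list(position_mm = 1:10 / 10,
                                       load_N = rep(0, 10))), "contact")
})

test_that("stiffness recovers exact and bilinear slopes", {
  d <- seq(0, 2, length.out = 200)
  f <- stiffness_fit(d, 2.5 * d)
  expect_equal(f$stiffness, 2.5, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # bilinear: slope 10 to 40 percent of the load range, then slope 2
  brk <- 0.4 * 10 * 2 / (10)  # deformation at the break
  load <- ifelse(d <= brk, 10 * d, 10 * brk + 2 * (d - brk))
  fb <- stiffness_fit(d, load)
  expect_equal(fb$stiffness, 10, tolerance = 0.01)
  expect_error(stiffness_fit(d, rep(1, 200)), "degenerate")
  # invariance to sample duplication
  fd <- stiffness_fit(rep(d, each = 2), rep(2.5 * d, each = 2))
  expect_equal(fd$stiffness, 2.5, tolerance = 1e-10)
})

test_that("stress-strain conversion uses oval areas and height", {
  rec <- list(position_mm = c(0, 0.025, 0.05), load_N = c(0, 0.5, 1))
  ss <- to_stress_strain(rec, ref_dims, "vertical", threshold = 0)
  expect_equal(max(ss$stress_MPa), 1 / (pi * 2 * 1.5), tolerance = 1e-9)
  expect_equal(max(ss$stress_MPa), 0.1061033, tolerance = 1e-6)
  expect_equal(ss$strain[3] - ss$strain[1], 0.05 / 2, tolerance = 1e-9)
  # doubling both diameters quarters the stress
  dims2 <- epiphysis_dims(2, 8, 6, 7, 5)
  ss2 <- to_stress_strain(rec, dims2, "vertical", threshold = 0)
  expect_equal(ss2$stress_MPa, ss$stress_MPa / 4, tolerance = 1e-12)
  # angled loading uses the side oval
  ssa <- to_stress_strain(rec, ref_dims, "angled")
  expect_equal(max(ssa$stress_MPa), 1 / (pi * 1.75 * 1.25), tolerance = 1e-9)
  # bijectivity: un-normalising recovers the record
  expect_equal(ss$stress_MPa * pi * 2 * 1.5, rec$load_N, tolerance = 1e-12)
})

test_that("0.2 percent offset yield matches the closed-form intersection", {
  # elastic slope 10 MPa to 0.5 MPa, then slope 1: intersection of
  # 10 (eps - 0.002) with 0.5 + (eps - 0.05) is eps = 0.47/9
  eps <- seq(0, 0.2, length.out = 2001)
  sig <- ifelse(eps <= 0.05, 10 * eps, 0.5 + 1 * (eps - 0.05))
  y <- offset_yield(data.frame(strain = eps, stress_MPa = sig))
  expect_equal(y$yield_strain, 0.47 / 9, tolerance = 1e-5)
  expect_equal(y$yield_MPa, 0.5 + (0.47 / 9 - 0.05), tolerance = 1e-5)
  expect_equal(y$yield_MPa, 0.50222, tolerance = 1e-4)
  # purely linear curve never crosses the offset line
  expect_error(offset_yield(data.frame(strain = eps, stress_MPa = 10 * eps)),
               "no yield")
  # elastic-perfectly-plastic: yield at the plateau
  sigp <- pmin(10 * eps, 0.8)
  yp <- offset_yield(data.frame(strain = eps, stress_MPa = sigp))
  expect_equal(yp$yield_MPa, 0.8, tolerance = 1e-9)
})

test_that("pressure-matched load inverts the oval-area stress", {
  # the published pressure-load equivalence: 0.023 MPa on a 8.6957 mm^2 oval
  dims <- epiphysis_dims(height = 2, top_d1 = 4, top_d2 = 4 * 8.6957 /
                           (pi * 4), side_d1 = 3, side_d2 = 2)
  expect_equal(load_for_pressure(0.023, dims), 0.2, tolerance = 1e-4)
  expect_equal(load_for_pressure(0, dims), 0)
  dims2 <- epiphysis_dims(2, dims$top_d1 * 2, dims$top_d2, 3, 2)
  expect_equal(load_for_pressure(0.023, dims2),
               2 * load_for_pressure(0.023, dims), tolerance = 1e-12)
  expect_error(load_for_pressure(-1, dims), ">= 0")
  expect_equal(soc_protection_fold(), 25)
})

test_that("stiffness and yield are recovered from noisy synthetic records", {
  n <- 200
  st <- yd <- numeric(n)
  for (i in seq_len(n)) {
    rec <- gen_load_deformation(stiffness_true = 30, yield_stress_true = 0.4,
                                dims = ref_dims, noise_sd = 0.01,
                                seed = 1000 + i)
    sm <- mech_summary(rec, ref_dims, "vertical")
    st[i] <- sm$stiffness_N_mm
    yd[i] <- sm$yield_MPa
  }
  expect_lt(stats::median(abs(st - 30) / 30), 0.02)
  # analytic 0.2 percent offset yield of the bilinear generator
  A <- pi * ref_dims$top_d1 * ref_dims$top_d2 / 4
  E0 <- 30 * ref_dims$height / A
  ey <- 0.4 / E0
  eps_y <- (0.4 - 0.2 * E0 * ey + E0 * 0.002) / (0.8 * E0)
  sig_y <- 0.4 + 0.2 * E0 * (eps_y - ey)
  expect_lt(stats::median(abs(yd - sig_y) / sig_y, na.rm = TRUE), 0.03)
  # noiseless recovery is essentially exact
  # noiseless recovery: stiffness exact; yield within the small systematic
  # shift of the 2 percent contact threshold
  rec0 <- gen_load_deformation(30, 0.4, ref_dims, noise_sd = 0, seed = 7)
  sm0 <- mech_summary(rec0, ref_dims, "vertical")
  expect_equal(sm0$stiffness_N_mm, 30, tolerance = 1e-3)
  expect_equal(sm0$yield_MPa, sig_y, tolerance = 0.02)
})
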