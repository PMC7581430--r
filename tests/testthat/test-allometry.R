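test_that("stylopod diameter follows the combined power law", {
  law <- allometric_law("combined")
  expect_equal(stylopod_diameter(1, law), 1.26)
  # direct evaluation of 1.26 * 1000^0.364
  expect_equal(stylopod_diameter(1000, law), 1.26 * exp(0.364 * log(1000)),
               tolerance = 1e-12)
  expect_equal(stylopod_diameter(1000, law), 15.5716, tolerance = 1e-4)
  expect_equal(stylopod_diameter(2, law) / stylopod_diameter(1, law),
               2^0.364, tolerance = 1e-12)
  expect_error(stylopod_diameter(-1, law), "positive")
  expect_error(allometric_law("custom", a = 1.5), "0 < a")
})

test_that("pressure fold reproduces the published range", {
  expect_equal(round(pressure_fold(1000, 0.3944), 1), 4.3)
  expect_equal(pressure_fold(1000, 0.364), 1000^0.272, tolerance = 1e-12)
  expect_lt(pressure_fold(1000, 0.364), 6.6)
  expect_equal(pressure_fold(123.4, 0.5), 1)
  # all three published exponents round into [4.3, 6.6]
  folds <- round(pressure_fold(1000, c(0.366, 0.3944, 0.364)), 1)
  expect_true(all(folds >= 4.3 & folds <= 6.6))
})

test_that("pressure fold is multiplicative and consistent with diameters", {
  set.seed(42)
  r1 <- runif(20, 0.1, 50); r2 <- runif(20, 0.1, 50); a <- runif(20, 0.2, 0.5)
  expect_equal(pressure_fold(r1 * r2, a),
               pressure_fold(r1, a) * pressure_fold(r2, a),
               tolerance = 1e-12)
  law <- allometric_law("custom", k = 2.5, a = 0.41)
  d_ratio <- stylopod_diameter(r1, law) / stylopod_diameter(1, law)
  expect_equal(pressure_fold(r1, 0.41), r1 / d_ratio^2, tolerance = 1e-12)
})

test_that("compensation diameter fold back-solves the published claim", {
  expect_equal(compensation_diameter_fold(5, anchor_mass = 5), 1)
  # mass ratio 8100 with a = 0.364 gives about 3.4
  expect_equal(compensation_diameter_fold(8100, allometric_law("combined")),
               8100^0.136, tolerance = 1e-12)
  expect_equal(round(compensation_diameter_fold(8100), 1), 3.4)
  f <- compensation_diameter_fold(c(1, 10, 100, 1000))
  expect_true(all(diff(f) > 0))
})

test_that("fold table reports rounded folds over a grid", {
  tb <- pressure_fold_table(1000, c(0.3944, 0.364))
  expect_identical(tb$pressure_fold, c(4.3, 6.5))
})
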