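test_that("principal stresses match the dense eigensolver on random tensors", {
  tens <- gen_stress_tensors(200, scale = 2, seed = 11)
  pr <- principal_stresses(tens$S11, tens$S22, tens$S12, tens$S33)
  expect_lt(max(abs(pr - as.matrix(tens[c("o1", "o2", "o3")]))), 1e-10)
  expect_true(all(pr[, 1] >= pr[, 2] & pr[, 2] >= pr[, 3]))
  # frozen simple cases
  expect_equal(unname(principal_stresses(-1, -3, 0, -2)[1, ]), c(-1, -2, -3))
  expect_equal(unname(principal_stresses(0, 0, 1, 0)[1, ]), c(1, 0, -1))
})

test_that("octahedral shear matches sqrt(2 J2 / 3) and the closed forms", {
  tens <- gen_stress_tensors(10000, scale = 3, seed = 12)
  pr <- principal_stresses(tens$S11, tens$S22, tens$S12, tens$S33)
  expect_lt(max(abs(octahedral_shear(pr) - tens$o_tau)), 1e-10)
  expect_equal(octahedral_shear(5, 5, 5), 0)
  expect_equal(octahedral_shear(3, 0, 0), sqrt(2) / 3 * 3, tolerance = 1e-12)
  expect_equal(octahedral_shear(2, 0, -2), sqrt(6) / 3 * 2, tolerance = 1e-12)
})

test_that("hydrostatic stress equals the trace mean, with plotting flip", {
  tens <- gen_stress_tensors(500, scale = 1, seed = 13)
  pr <- principal_stresses(tens$S11, tens$S22, tens$S12, tens$S33)
  h <- hydrostatic_stress(pr)
  expect_lt(max(abs(h - (tens$S11 + tens$S22 + tens$S33) / 3)), 1e-12)
  expect_lt(max(abs(h - tens$o_hyd)), 1e-12)
  expect_identical(hydrostatic_stress(pr, plotting = TRUE), -h)
  expect_equal(hydrostatic_stress(2, 2, 2), 2)
  expect_equal(hydrostatic_stress(3, 0, 0), 1)
})

test_that("second PK stress reproduces imposed states", {
  fx <- gen_block_fixture(10, 10, E = 6, nu = 0.47, p = 0.01, target_h = 1)
  mesh <- fx$mesh
  # zero displacement -> zero tensors
  sol0 <- structure(list(u = matrix(0, nrow(mesh$nodes), 2),
                         small_strain = FALSE), class = "fem_solution")
  sf0 <- second_pk_stress(sol0, mesh, fx$mat)
  expect_equal(max(abs(as.matrix(sf0[c("S11", "S22", "S12", "S33")]))), 0)
  # block under uniform pressure: plane-strain uniaxial state
  sol <- solve_elasticity(mesh, fx$mat, fx$bc, fx$lc, small_strain = TRUE)
  sf <- second_pk_stress(sol, mesh, fx$mat)
  expect_equal(mean(sf$S22), -0.01, tolerance = 1e-4)
  expect_lt(max(abs(sf$S11)), 1e-4 * 0.01)
  expect_equal(mean(sf$S33), -0.47 * 0.01, tolerance = 1e-4)
  # imposed affine displacement: S = lambda tr(E) I + 2 mu E exactly
  A <- matrix(c(2e-3, 5e-4, -3e-4, -1e-3), 2, 2)
  ua <- t(A %*% t(mesh$nodes))
  sola <- structure(list(u = ua, small_strain = TRUE),
                    class = "fem_solution")
  sfa <- second_pk_stress(sola, mesh, fx$mat)
  lp <- lame_parameters(6, 0.47)
  Eps <- (A + t(A)) / 2
  expect_lt(max(abs(sfa$S11 - (lp["lambda"] * sum(diag(Eps)) +
                               2 * lp["mu"] * Eps[1, 1]))), 1e-10)
  expect_lt(max(abs(sfa$S12 - 2 * lp["mu"] * Eps[1, 2])), 1e-10)
  expect_lt(max(abs(sfa$S33 - lp["lambda"] * sum(diag(Eps)))), 1e-10)
  expect_error(second_pk_stress(sol0, epi_mesh("with_soc"), fx$mat),
               "sizes differ")
})

test_that("zone summaries respect constants, partitions and area weights", {
  m <- epi_mesh("with_soc")
  field <- data.frame(area = m$area, tau_oct = rep(3, nrow(m$tri)))
  zone <- zone_elements(m, label = "growth_plate_band")
  zs <- zone_summary(field, zone, "tau_oct")
  expect_equal(zs$peak, 3)
  expect_equal(zs$mean, 3)
  one <- zone_summary(field, zone[1], "tau_oct")
  expect_equal(one$peak, one$mean)
  # max over thirds equals the band peak
  field$tau_oct <- abs(sin(seq_len(nrow(m$tri))))
  th <- zone_thirds(m, zone)
  zp <- vapply(th, function(z) zone_summary(field, z, "tau_oct")$peak,
               numeric(1))
  expect_equal(max(zp), zone_summary(field, zone, "tau_oct")$peak)
  expect_warning(zone_summary(field, integer(0)), "empty")
})

test_that("deflection and deformed coordinates follow the displacement", {
  run <- epi_solution("with_soc", 90, 0.3)
  mesh <- run$mesh
  # zero load
  sol0 <- structure(list(u = matrix(0, nrow(mesh$nodes), 2)),
                    class = "fem_solution")
  expect_equal(deflection(sol0, mesh, run$lc), 0)
  expect_identical(deformed_coordinates(mesh, sol0), mesh$nodes)
  # rigid translation shifts every node
  solr <- structure(list(u = cbind(rep(0.3, nrow(mesh$nodes)),
                                   rep(-0.2, nrow(mesh$nodes)))),
                    class = "fem_solution")
  dc <- deformed_coordinates(mesh, solr)
  expect_equal(dc - mesh$nodes, solr$u, tolerance = 1e-12,
               ignore_attr = TRUE)
  # round trip
  expect_lt(max(abs(deformed_coordinates(mesh, run$sol) - mesh$nodes -
                    run$sol$u)), 1e-12)
  # apex deflection under the vertical sector is the apex |u|
  apex <- which(!is.na(mesh$node_theta))[
    which.min(abs(mesh$node_theta[which(!is.na(mesh$node_theta))] - 90))]
  expect_equal(run$deflection, sqrt(sum(run$sol$u[apex, ]^2)))
})
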