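test_that("Lame constants match the closed forms", {
  expect_equal(lame_parameters(1, 0), c(lambda = 0, mu = 0.5))
  lp <- lame_parameters(6, 0.47)
  expect_equal(unname(lp["lambda"]), 6 * 0.47 / (1.47 * 0.06),
               tolerance = 1e-12)
  expect_equal(unname(lp["lambda"]), 31.97279, tolerance = 1e-6)
  expect_equal(unname(lp["mu"]), 2.040816, tolerance = 1e-6)
  lp2 <- lame_parameters(500, 0.2)
  expect_equal(unname(lp2["lambda"]), 138.8889, tolerance = 1e-6)
  expect_equal(unname(lp2["mu"]), 208.3333, tolerance = 1e-6)
  expect_error(lame_parameters(6, 0.5), "incompressible")
  expect_error(lame_parameters(-1, 0.3), "E must be")
})

test_that("the stiff insert is about eighty-fold stiffer than cartilage", {
  mm <- material_map("with_soc")
  expect_gte(mm$stiff_insert$E / mm$epiphyseal_cartilage$E, 80)
  # no-SOC variant swaps the insert material for cartilage
  mm0 <- material_map("no_soc")
  expect_identical(mm0$stiff_insert, mm0$epiphyseal_cartilage)
})

test_that("sector pressure is quadratic, symmetric, zero at the borders", {
  lc <- load_case(90, 0.3)
  expect_equal(sector_pressure(90, lc), 0.3)
  expect_equal(sector_pressure(c(67.5, 112.5), lc), c(0, 0))
  expect_equal(sector_pressure(c(90 - 11.25, 90 + 11.25), lc),
               c(0.225, 0.225))
  expect_equal(sector_pressure(c(0, 180), lc), c(0, 0))  # clamps outside
  lcw <- load_case(90, 0.3, wide_support = TRUE)
  expect_equal(lcw$sector_half_width, 67.5)
  expect_equal(sector_pressure(90 + 67.5, lcw), 0)
})

test_that("uniform pressure on a block reproduces the plane-strain form", {
  fx <- gen_block_fixture(10, 10, E = 6, nu = 0.47, p = 0.01, target_h = 1)
  expect_equal(fx$analytic$u_top, -0.012985, tolerance = 1e-4)
  sol <- solve_elasticity(fx$mesh, fx$mat, fx$bc, fx$lc, small_strain = TRUE)
  top <- which(abs(fx$mesh$nodes[, 2] - 10) < 1e-9)
  expect_equal(mean(sol$u[top, 2]), fx$analytic$u_top, tolerance = 0.005)
  # zero load gives the zero field
  lc0 <- load_case(peak_pressure = 0, tag = "top", n_steps = 1,
                   profile = function(x, y, th) rep(0, length(x)))
  sol0 <- solve_elasticity(fx$mesh, fx$mat, fx$bc, lc0)
  expect_equal(max(abs(sol0$u)), 0)
})

test_that("patch test: affine boundary displacement is reproduced exactly", {
  fx <- gen_block_fixture(4, 4, target_h = 1)
  mesh <- fx$mesh
  # impose u = A x + b on every boundary node (both components)
  A <- matrix(c(1e-3, 4e-4, -2e-4, 5e-4), 2, 2)
  b <- c(2e-4, -1e-4)
  bnodes <- unique(unlist(mesh$boundary_edges[c("n1", "n2", "mid")]))
  uexact <- t(A %*% t(mesh$nodes)) + matrix(b, nrow(mesh$nodes), 2,
                                            byrow = TRUE)
  bc <- new_bc(c(2 * bnodes - 1, 2 * bnodes),
               c(uexact[bnodes, 1], uexact[bnodes, 2]))
  lc0 <- load_case(peak_pressure = 0, tag = "top", n_steps = 1,
                   profile = function(x, y, th) rep(0, length(x)))
  sol <- solve_elasticity(mesh, fx$mat, bc, lc0, small_strain = TRUE)
  expect_lt(max(abs(sol$u - uexact)), 1e-10)
})

test_that("low loads are linear: doubling pressure doubles displacement", {
  mesh <- epi_mesh("with_soc")
  mat <- material_map("with_soc")
  bc <- boundary_conditions(mesh, "epiphysis")
  lc1 <- load_case(90, 1e-3, n_steps = 1)
  lc2 <- load_case(90, 2e-3, n_steps = 1)
  s1 <- solve_elasticity(mesh, mat, bc, lc1)
  s2 <- solve_elasticity(mesh, mat, bc, lc2)
  expect_equal(sqrt(sum(s2$u^2)) / sqrt(sum(s1$u^2)), 2, tolerance = 0.005)
  # finite vs small strain agree at vanishing load
  s1l <- solve_elasticity(mesh, mat, bc, lc1, small_strain = TRUE)
  expect_equal(deflection(s1, mesh, lc1), deflection(s1l, mesh, lc1),
               tolerance = 1e-3)
})

test_that("vertical load on the symmetric mesh gives a symmetric field", {
  run <- epi_solution("with_soc", 90, 0.3)
  mesh <- run$mesh; u <- run$sol$u
  key <- epimech:::node_key(mesh$nodes[, 1], mesh$nodes[, 2])
  mirror <- match(epimech:::node_key(-mesh$nodes[, 1], mesh$nodes[, 2]), key)
  err <- sqrt(sum((u[, 1] + u[mirror, 1])^2 + (u[, 2] - u[mirror, 2])^2))
  expect_lt(err, 1e-6 * sqrt(sum(u^2)))
})

test_that("deflection changes by < 1 percent under mesh halving", {
  d1 <- epi_solution("with_soc", 90, 0.3)$deflection
  d2 <- epi_solution("with_soc", 90, 0.3, h = 0.45)$deflection
  expect_lt(abs(d1 - d2) / d2, 0.01)
})

test_that("stiff structures stiffen the joint and temper band shear", {
  # highest supra-physiological load all variants statically sustain (the
  # SVK model collapses at its compressive limit point near 1.4 MPa peak)
  peak <- 1.2
  soc <- epi_solution("with_soc", 90, peak)
  non <- epi_solution("no_soc", 90, peak)
  pro <- epi_solution("protrusions_extended", 90, peak)
  # the ossification center stiffens the whole structure...
  expect_lt(soc$deflection, non$deflection)
  expect_lt(soc$deflection, pro$deflection)
  # ...while ossified protrusions do not improve overall stiffness much
  expect_lt(abs(pro$deflection - non$deflection) / non$deflection, 0.2)
  # under vertical load the center converts band loading into hydrostatic
  # compression (the well-tolerated, confinement-protected state)
  hyd <- function(run) abs(run$band_summary$mean[
    run$band_summary$measure == "hydrostatic"])
  expect_gt(hyd(soc), hyd(non))
  # under the angled load both stiff structures lower the band's
  # area-weighted octahedral shear, and the deflection ordering persists
  soc45 <- epi_solution("with_soc", 45, peak)
  non45 <- epi_solution("no_soc", 45, peak)
  pro45 <- epi_solution("protrusions_extended", 45, peak)
  expect_lt(soc45$deflection, non45$deflection)
  expect_lt(pro45$deflection, non45$deflection)
  tau_mean <- function(run) run$band_summary$mean[
    run$band_summary$measure == "tau_oct"]
  expect_lt(tau_mean(soc45), tau_mean(non45))
  expect_lt(tau_mean(pro45), tau_mean(non45))
})

test_that("vertical loading elevates band hydrostatic stress centrally", {
  run <- epi_solution("with_soc", 90, 0.3)
  th <- zone_thirds(run$mesh, run$band)
  hyd <- vapply(th, function(z) {
    w <- run$field$area[z]
    sum(w * run$field$hydrostatic[z]) / sum(w)
  }, numeric(1))
  expect_lt(hyd[["middle"]], hyd[["left"]])   # more compressive centrally
  expect_lt(hyd[["middle"]], hyd[["right"]])
})
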