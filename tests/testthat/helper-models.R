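# Shared fixtures. Epiphysis solves are expensive, so meshes and solutions
# are computed once per test run and memoised here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# default-geometry meshes at the working resolution used by the model tests
epi_mesh <- function(variant = "with_soc", h = 0.9) {
  key <- if (variant %in% c("no_soc", "with_soc")) "soc" else variant
  cached(sprintf("mesh_%s_%g", key, h), {
    generate_mesh(build_geometry(epiphysis_params(), variant), h)
  })
}

# memoised epiphysis solution
epi_solution <- function(variant, angle, peak, wide_support = FALSE,
                         h = 0.9) {
  key <- sprintf("sol_%s_%g_%g_%s_%g", variant, angle, peak, wide_support, h)
  cached(key, {
    mesh <- epi_mesh(variant, h)
    mat <- material_map(variant)
    bc <- boundary_conditions(mesh, "epiphysis")
    lc <- load_case(angle, peak, wide_support = wide_support,
                    n_steps = max(1, ceiling(peak / 0.3)))
    sol <- solve_elasticity(mesh, mat, bc, lc)
    field <- scalar_measures(second_pk_stress(sol, mesh, mat))
    band <- zone_elements(mesh, label = "growth_plate_band")
    list(mesh = mesh, mat = mat, lc = lc, sol = sol, field = field,
         band = band, deflection = deflection(sol, mesh, lc),
         band_summary = zone_summary(field, band))
  })
}

band_peak <- function(run, measure) {
  s <- run$band_summary
  s$peak[s$measure == measure]
}
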