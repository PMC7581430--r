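test_that("parameter validation enforces the domain invariants", {
  expect_s3_class(epiphysis_params(), "epiphysis_params")
  expect_error(epiphysis_params(top_radius = -1), "positive")
  expect_error(epiphysis_params(top_radius = 30), "bottom_width")
  expect_error(epiphysis_params(soc_ry = 12), "below the stiff insert")
  expect_error(epiphysis_params(soc_rx = 16.9), "strictly inside")
})

test_that("variants share the outer geometry and conserve area", {
  p <- epiphysis_params()
  outer <- abs(epimech:::ring_area_signed(outer_boundary(p)))
  for (v in variant_ids()) {
    g <- build_geometry(p, v)
    expect_equal(polygons_area(g), outer, tolerance = 1e-9)
  }
  # with/without ossification center share polygons exactly
  g1 <- build_geometry(p, "with_soc")
  g2 <- build_geometry(p, "no_soc")
  expect_identical(lapply(g1, `[[`, "rings"), lapply(g2, `[[`, "rings"))
})

test_that("exactly five subdomain labels and an insert in every variant", {
  p <- epiphysis_params()
  expect_length(subdomain_labels(), 5)
  for (v in variant_ids()) {
    g <- build_geometry(p, v)
    labs <- vapply(g, `[[`, character(1), "label")
    expect_true("stiff_insert" %in% labs)
    expect_true(all(labs %in% subdomain_labels()))
  }
})

test_that("protrusion variants carry the requested number of fingers", {
  p <- epiphysis_params(prot_count = 4)
  g <- build_geometry(p, "protrusions_extended")
  labs <- vapply(g, `[[`, character(1), "label")
  expect_identical(sum(labs == "stiff_insert"), 4L)
  # an even count has no centerline finger, so no half polygons; fingers are
  # stadium-shaped (width 2, depth 10, rounded ends of radius 1)
  areas <- vapply(g[labs == "stiff_insert"], polygon_area, numeric(1))
  expect_equal(areas, rep(areas[1], 4), tolerance = 1e-12)
  expect_true(all(areas > 2 * 8 & areas <= 2 * 8 + pi))
  expect_error(epiphysis_params(prot_count = 7, prot_spacing = 8) |>
                 build_geometry("protrusions_extended"), "strictly inside")
})

test_that("geometry is mirror-symmetric about the centerline", {
  g <- build_geometry(epiphysis_params(), "protrusions_small")
  mirr <- vapply(g, function(p) p$mirror_of, integer(1))
  for (i in which(!is.na(mirr))) {
    src <- g[[mirr[i]]]
    expect_identical(g[[i]]$label, src$label)
    a <- do.call(rbind, g[[i]]$rings)
    b <- do.call(rbind, src$rings)
    expect_identical(sort(epimech:::node_key(-a[, 1], a[, 2])),
                     sort(epimech:::node_key(b[, 1], b[, 2])))
  }
})

test_that("zone selection filters by band and partitions into thirds", {
  m <- epi_mesh("with_soc")
  all_el <- zone_elements(m, y_range = c(-1, 100))
  expect_identical(all_el, seq_len(nrow(m$tri)))
  expect_warning(empty <- zone_elements(m, y_range = c(100, 200)), "empty")
  expect_length(empty, 0)
  band <- zone_elements(m, label = "growth_plate_band")
  expect_identical(sort(unique(m$label[band])), "growth_plate_band")
  th <- zone_thirds(m, band)
  expect_identical(sort(c(th$left, th$middle, th$right)), sort(band))
  expect_length(intersect(th$left, th$right), 0)
  expect_length(intersect(th$left, th$middle), 0)
  # thirds split the band x-extent into equal-width intervals
  expect_true(max(m$centroid[th$left, 1]) < min(m$centroid[th$right, 1]))
})
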