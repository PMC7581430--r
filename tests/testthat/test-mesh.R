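test_that("unit square mesh conserves area and refines monotonically", {
  sq <- block_polygons(1, 1)
  m <- generate_mesh(sq, 0.5)
  expect_equal(sum(m$area), 1, tolerance = 1e-9)
  expect_true(all(m$area > 0))
  m2 <- generate_mesh(sq, 0.25)
  expect_gt(nrow(m2$tri), nrow(m$tri))
  expect_equal(sum(m2$area), 1, tolerance = 1e-9)
  expect_silent(validate_mesh(m))
  expect_silent(validate_mesh(m2))
  expect_error(generate_mesh(sq, -1), "> 0")
})

test_that("epiphysis meshes satisfy the mesh invariants at h and h/2", {
  for (v in c("with_soc", "protrusions_extended")) {
    m <- epi_mesh(v)
    expect_silent(validate_mesh(m))
    expect_true(nrow(m$tri) > 1000)
  }
  m2 <- epi_mesh("with_soc", 0.45)
  expect_silent(validate_mesh(m2))
  expect_gt(nrow(m2$tri), nrow(epi_mesh("with_soc")$tri))
})

test_that("element labels match the polygon containing each centroid", {
  g <- build_geometry(epiphysis_params(), "with_soc")
  m <- epi_mesh("with_soc")
  # point-in-polygon oracle per polygon
  for (pl in g) {
    inside <- as.logical(epimech:::points_in_rings_cpp(m$centroid, pl$rings))
    expect_true(all(m$label[inside] == pl$label))
  }
})

test_that("meshes are exactly mirror-symmetric with symmetric labels", {
  m <- epi_mesh("with_soc")
  key <- epimech:::node_key(m$nodes[, 1], m$nodes[, 2])
  mkey <- epimech:::node_key(-m$nodes[, 1], m$nodes[, 2])
  expect_true(all(mkey %in% key))
  # mirrored element multisets per label, via centroid keys (rounded: the
  # centroid summation order differs by an ulp between the halves)
  ck <- function(x, y) sprintf("%.8f_%.8f", x + 0, y)
  ckey <- paste(ck(m$centroid[, 1], m$centroid[, 2]), m$label)
  mckey <- paste(ck(-m$centroid[, 1], m$centroid[, 2]), m$label)
  expect_identical(sort(ckey), sort(mckey))
})

test_that("top-arc nodes lie on the circle and carry polar angles", {
  m <- epi_mesh("with_soc")
  arcn <- which(!is.na(m$node_theta))
  expect_gt(length(arcn), 50)
  r <- sqrt(m$nodes[arcn, 1]^2 + (m$nodes[arcn, 2] - 49)^2)
  expect_true(all(abs(r - 17) < 1e-6 * 17))
  expect_true(all(m$node_theta[arcn] >= 0 & m$node_theta[arcn] <= 180))
  apex <- arcn[which.max(m$nodes[arcn, 2])]
  expect_equal(m$node_theta[apex], 90)
})
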