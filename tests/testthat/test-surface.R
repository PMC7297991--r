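test_that("label areas sum exactly to the total and scale quadratically", {
  m <- generate_test_mesh("icosphere", radius = 1, subdivisions = 3,
                          n_sectors = 5)
  tab <- mesh_area_by_label(m)
  per <- tab[tab$label != "total", ]
  expect_identical(sum(per$area_mm2), tab$area_mm2[tab$label == "total"])
  s <- 2.5
  m2 <- surface_mesh(m$vertices * s, m$triangles, m$labels)
  tab2 <- mesh_area_by_label(m2)
  expect_equal(tab2$area_mm2, tab$area_mm2 * s^2, tolerance = 1e-10)
})

test_that("sphere curvature is 1/R at every vertex and scales inversely", {
  m1 <- generate_test_mesh("icosphere", radius = 1, subdivisions = 4)
  f1 <- vertex_mean_curvature(m1)
  expect_true(all(f1$valid))
  expect_true(all(abs(abs(f1$H) - 1) < 0.02))
  m2 <- generate_test_mesh("icosphere", radius = 2, subdivisions = 4)
  f2 <- vertex_mean_curvature(m2)
  expect_equal(mean(abs(f2$H)), 0.5, tolerance = 0.02)
  expect_equal(abs(f2$H), abs(f1$H) / 2, tolerance = 0.02)
})

test_that("ellipsoid pole curvature matches the analytic value", {
  # ellipsoid (a,b,c) at the pole (a,0,0): H = a (1/b^2 + 1/c^2) / 2 = 2
  m <- generate_test_mesh("ellipsoid", axes = c(2, 1, 1), subdivisions = 4)
  f <- vertex_mean_curvature(m)
  pole <- which.max(m$vertices[, 1])
  expect_equal(max(m$vertices[pole, 1]), 2, tolerance = 1e-9)
  expect_equal(abs(f$H[pole]), 2, tolerance = 0.1)
})

test_that("areas and curvature magnitudes are invariant to rigid motion", {
  m <- generate_test_mesh("icosphere", radius = 1.3, subdivisions = 3,
                          n_sectors = 4)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  m2 <- surface_mesh(m$vertices %*% t(R) + rep(c(5, -2, 1), each = nrow(m$vertices)),
                     m$triangles, m$labels)
  a1 <- mesh_area_by_label(m); a2 <- mesh_area_by_label(m2)
  expect_equal(a2$area_mm2, a1$area_mm2, tolerance = 1e-8)
  h1 <- abs(vertex_mean_curvature(m)$H)
  h2 <- abs(vertex_mean_curvature(m2)$H)
  expect_equal(h2, h1, tolerance = 1e-8)
})

test_that("refinement shrinks the sphere curvature error monotonically", {
  errs <- vapply(3:5, function(k) {
    f <- vertex_mean_curvature(generate_test_mesh("icosphere", radius = 1,
                                                  subdivisions = k))
    max(abs(abs(f$H) - 1))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("regional curvature averaging follows the stated conventions", {
  m <- generate_test_mesh("icosphere", radius = 1, subdivisions = 4,
                          n_sectors = 4)
  f <- vertex_mean_curvature(m)
  whole <- average_abs_curvature(f, m)
  one_label <- surface_mesh(m$vertices, m$triangles, rep(7L, nrow(m$vertices)))
  expect_identical(average_abs_curvature(vertex_mean_curvature(one_label),
                                         one_label, label = 7L), whole)
  expect_equal(whole, 1, tolerance = 0.02)
  # |mean| <= mean of absolute values, strictly informative on mixed-sign fields
  bumpy <- surface_mesh(m$vertices * (1 + 0.25 * sin(3 * atan2(m$vertices[, 2],
                                                               m$vertices[, 1]))),
                        m$triangles, m$labels)
  fb <- vertex_mean_curvature(bumpy)
  expect_gte(mean(abs(fb$H[fb$valid])), abs(mean(fb$H[fb$valid])))
  expect_error(average_abs_curvature(f, m, label = 99), "label")
  aw <- average_abs_curvature(f, m, area_weighted = TRUE)
  expect_equal(aw, whole, tolerance = 0.01)
})

test_that("surface_metrics summarises area and curvature per label", {
  m <- generate_test_mesh("icosphere", radius = 2, subdivisions = 4,
                          n_sectors = 3)
  sm <- surface_metrics(m)
  expect_setequal(sm$label, c("1", "2", "3", "total"))
  expect_equal(sm$curv_abs_mean[sm$label == "total"], 0.5, tolerance = 0.02)
  expect_equal(sm$area_mm2[sm$label == "total"], 4 * pi * 4, tolerance = 0.5)
})

test_that("degenerate neighbourhoods are marked invalid, not fabricated", {
  # tetrahedron: every two/three-ring has only 3 neighbours
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  tet <- surface_mesh(v, f)
  fld <- vertex_mean_curvature(tet)
  expect_true(all(!fld$valid))
  expect_error(average_abs_curvature(fld, tet), "no valid")
})
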