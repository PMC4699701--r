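test_that("the spline reproduces curves inside its model class", {
  # straight segment: exactly representable
  s <- seq(0, 1, length.out = 50)
  seg <- cbind(100 + 300 * s, -200 + 500 * s, 50 - 100 * s)
  path <- fit_column_path(seg, span_trim = 0)
  dev <- vapply(seq_len(nrow(path$samples)), function(i) {
    p <- path$samples[i, ]
    a <- seg[1, ]; d <- seg[50, ] - a
    tt <- sum((p - a) * d) / sum(d^2)
    sqrt(sum((a + pmin(pmax(tt, 0), 1) * d - p)^2))
  }, numeric(1))
  expect_lt(max(dev), 1e-6)

  # planar parabola sampled uniformly: quadratic per axis, exactly representable
  s <- seq(-1, 1, length.out = 200)
  par3 <- cbind(400 * s, 300 * s^2, rep(0, 200))
  path2 <- fit_column_path(par3, span_trim = 0)
  # deviation from the continuous curve: residual of y = 300 (x/400)^2, z = 0
  dev2 <- abs(path2$samples[, 2] - 300 * (path2$samples[, 1] / 400)^2) +
    abs(path2$samples[, 3])
  expect_lt(max(dev2), 1e-3)
})

test_that("the fitted path tracks a noisy smooth curve below the noise scale", {
  hx <- helix_cells(n = 500, sigma = 20, seed = 7)
  path <- fit_column_path(hx$cells)
  dev <- vapply(seq(1, nrow(path$samples), by = 10), function(i) {
    min(sqrt(colSums((t(hx$base) - path$samples[i, ])^2)))
  }, numeric(1))
  expect_lt(mean(dev), 20)
})

test_that("degenerate clouds are rejected", {
  expect_error(fit_column_path(matrix(1, 5, 3)), "at least 10")
  expect_error(fit_column_path(matrix(rep(c(1, 2, 3), each = 12), 12, 3)),
               "coincident")
})

test_that("boundary intersections match the analytic sphere piercings", {
  r <- 100
  mesh <- unit_sphere_mesh(r, subdivisions = 3L)
  # straight vertical path through the centre, top cap is pial (+y)
  s <- seq(0, 1, length.out = 60)
  seg <- cbind(rep(0, 60), 60 - 120 * s, rep(0, 60))
  path <- intersect_boundary(fit_column_path(seg, span_trim = 0), mesh)
  # analytic piercings at (0, +-r, 0); chord error of the subdivided sphere
  chord_tol <- r * 0.01
  expect_lt(sqrt(sum((path$pial_point - c(0, r, 0))^2)), chord_tol)
  expect_lt(sqrt(sum((path$ventral_point - c(0, -r, 0))^2)), chord_tol)
  expect_equal(path$total_length, 2 * r, tolerance = 0.01)

  # already-on-surface end returned (essentially) unchanged
  surf_y <- max(mesh$vertices[abs(mesh$vertices[, 1]) < 1e-6 &
                                abs(mesh$vertices[, 3]) < 1e-6, 2])
  seg2 <- cbind(rep(0, 60), seq(surf_y, -60, length.out = 60), rep(0, 60))
  path2 <- intersect_boundary(fit_column_path(seg2, span_trim = 0), mesh)
  expect_lt(sqrt(sum((path2$pial_point - c(0, surf_y, 0))^2)), 1)

  # path fully outside the mesh: no intersection
  seg3 <- cbind(rep(3 * r, 60), 60 - 120 * s, rep(0, 60))
  expect_error(intersect_boundary(fit_column_path(seg3, span_trim = 0), mesh),
               "no intersection")
})

test_that("ambiguous pial assignment is reported", {
  mesh <- unit_sphere_mesh(100)
  # horizontal path: both ends exit through non-pial equatorial faces
  s <- seq(0, 1, length.out = 60)
  seg <- cbind(60 - 120 * s, rep(0, 60), rep(0, 60))
  expect_error(intersect_boundary(fit_column_path(seg, span_trim = 0), mesh),
               "neither end")
})

test_that("unit-column coordinates have the defining geometry", {
  mesh <- unit_sphere_mesh(100, subdivisions = 3L)
  s <- seq(0, 1, length.out = 60)
  seg <- cbind(rep(0, 60), 60 - 120 * s, rep(0, 60))
  path <- intersect_boundary(fit_column_path(seg, span_trim = 0), mesh)

  probe <- rbind(path$pial_point,                    # t = 0, r = 0
                 path_point(path, 0.5) + c(30, 0, 0) # t = 0.5, r = 30
  )
  uc <- unitize(probe, path)
  expect_equal(uc$t, c(0, 0.5), tolerance = 1e-2)
  expect_equal(uc$r_um, c(0, 30), tolerance = 0.1)
  expect_false(any(uc$clipped))

  # a cell beyond the pial end is clipped to t = 0
  beyond <- matrix(path$pial_point + c(0, 25, 0), 1)
  uc2 <- unitize(beyond, path)
  expect_equal(uc2$t, 0)
  expect_true(uc2$clipped)
})

test_that("generated cells recover their true unit depth on a curved column", {
  mesh <- simulate_mesh()
  sim <- simulate_columns(mesh, n_columns = 4L, sigma = 0, lambda = 20,
                          seed = 21)
  # with no radial scatter there are no outliers, so the full-span fit applies
  rec <- reconstruct_columns(sim$cells, mesh, span_trim = 0)
  err <- abs(rec$unit_columns$t - sim$truth$cells$t)
  expect_gt(length(err), 100L)
  expect_lt(max(err), 0.01)
})

test_that("unit coordinates and profiles are invariant to rigid motion", {
  mesh <- simulate_mesh()
  sim <- simulate_columns(mesh, n_columns = 4L, seed = 31)
  rec <- reconstruct_columns(sim$cells, mesh)

  set.seed(99)
  R <- random_rotation()
  shift <- c(300, -150, 800)
  rot_mesh <- nucleus_mesh(sweep(mesh$vertices %*% t(R), 2, shift, "+"),
                           mesh$faces, mesh$pial_faces)
  rot_cells <- sim$cells
  xyz <- sweep(as.matrix(sim$cells[c("x_um", "y_um", "z_um")]) %*% t(R),
               2, shift, "+")
  rot_cells$x_um <- xyz[, 1]; rot_cells$y_um <- xyz[, 2]; rot_cells$z_um <- xyz[, 3]
  rec2 <- reconstruct_columns(rot_cells, rot_mesh)

  expect_equal(rec2$unit_columns$t, rec$unit_columns$t, tolerance = 1e-6)
  expect_equal(rec2$unit_columns$r_um, rec$unit_columns$r_um, tolerance = 1e-6)
  p1 <- count_profile(rec$unit_columns)
  p2 <- count_profile(rec2$unit_columns)
  expect_equal(p2$mean, p1$mean)
})
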