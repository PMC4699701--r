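straight_path <- function(from, to, mesh = NULL, n = 50) {
  s <- seq(0, 1, length.out = n)
  seg <- cbind(from[1] + s * (to[1] - from[1]),
               from[2] + s * (to[2] - from[2]),
               from[3] + s * (to[3] - from[3]))
  p <- fit_column_path(seg, span_trim = 0)
  if (!is.null(mesh)) p <- intersect_boundary(p, mesh) else p
}

test_that("iso-percentile points are arc-length points of each path", {
  mesh <- unit_sphere_mesh(100, subdivisions = 3L)
  paths <- list(a = straight_path(c(0, 60, 0), c(0, -60, 0), mesh),
                b = straight_path(c(20, 60, 5), c(20, -60, 5), mesh))
  p0 <- iso_percentile_points(paths, 0)
  p1 <- iso_percentile_points(paths, 1)
  expect_equal(unname(as.matrix(p0[p0$animal_id == "a", 2:4]))[1, ],
               paths$a$pial_point, tolerance = 1e-9)
  expect_equal(unname(as.matrix(p1[p1$animal_id == "b", 2:4]))[1, ],
               paths$b$ventral_point, tolerance = 1e-9)
  # straight path: t = 0.5 is the chord midpoint
  mid <- iso_percentile_points(paths["a"], 0.5)
  expect_equal(unname(as.matrix(mid[, 2:4]))[1, ],
               (paths$a$pial_point + paths$a$ventral_point) / 2,
               tolerance = 1e-6)
})

test_that("best-fit plane recovers exact and symmetric planes", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  set.seed(3)
  R <- random_rotation()
  posed <- sq %*% t(R) + 5
  pl <- best_fit_plane(posed)
  res <- abs((sweep(posed, 2, pl$origin)) %*% pl$normal)
  expect_lt(max(res), 1e-9)

  # symmetric points about z = 0: normal forced to the z axis
  pts <- rbind(c(1, 0, 0.3), c(1, 0, -0.3), c(-1, 1, 0.2), c(-1, 1, -0.2),
               c(0, -1, 0.1), c(0, -1, -0.1))
  pl2 <- best_fit_plane(pts)
  expect_gt(abs(pl2$normal[3]), 1 - 1e-9)

  expect_error(best_fit_plane(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("best-fit plane normal is accurate on noisy samples", {
  set.seed(11)
  uv <- matrix(runif(400, -100, 100), 200, 2)
  pts <- cbind(uv, rnorm(200, sd = 1))  # SNR ~ 100 in-plane vs out
  R <- random_rotation()
  pl <- best_fit_plane(pts %*% t(R))
  truth <- R[, 3]
  ang <- acos(min(abs(sum(pl$normal * truth)), 1)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("similarity alignment recovers constructed transforms", {
  set.seed(21)
  A <- matrix(rnorm(24, sd = 80), 12, 2)
  ids <- as.character(1:12)
  # identity
  st0 <- align_maps(as_map(A, ids), as_map(A, ids))
  expect_equal(st0$expansion, 1, tolerance = 1e-8)
  expect_equal(st0$rotation_rad, 0, tolerance = 1e-8)
  expect_equal(c(st0$tx_um, st0$ty_um), c(0, 0), tolerance = 1e-6)
  # rotation by 90 degrees and scale 2
  Rot <- matrix(c(0, 1, -1, 0), 2, 2)
  B <- 2 * A %*% t(Rot)
  st <- align_maps(as_map(A, ids), as_map(B, ids))
  expect_equal(st$expansion, 2, tolerance = 1e-6)
  expect_equal(st$rotation_rad, pi / 2, tolerance = 1e-6)
  expect_lt(st$residual_um2, 1e-12)
  expect_error(align_maps(as_map(A[1, , drop = FALSE], "1"),
                          as_map(A[1, , drop = FALSE], "2")), "shared")
})

test_that("constrained minimization matches closed-form Procrustes on interior problems", {
  set.seed(31)
  worst <- 0
  for (i in 1:200) {
    A <- matrix(rnorm(24, sd = 50), 12, 2)
    e <- runif(1, 0.3, 3)
    th <- runif(1, -2.8, 2.8)
    B <- e * A %*% t(rot2_ref(th)) + rnorm(2, sd = 20) +
      matrix(rnorm(24, sd = 4), 12, 2)
    cf <- procrustes_similarity(A, B)
    st <- align_maps(as_map(A), as_map(B))
    worst <- max(worst, abs(st$expansion - cf$expansion),
                 abs(st$rotation_rad - cf$rotation))
  }
  expect_lt(worst, 1e-6)
})

test_that("alignment steps are invariant to rigid motion of the 3D dataset", {
  mesh <- simulate_mesh()
  sim <- simulate_columns(mesh, n_columns = 9L, seed = 51)
  rec <- reconstruct_columns(sim$cells, mesh)
  st <- align_stack(percentile_maps(rec$paths))

  set.seed(52)
  R <- random_rotation()
  shift <- c(-400, 250, 100)
  rot_mesh <- nucleus_mesh(sweep(mesh$vertices %*% t(R), 2, shift, "+"),
                           mesh$faces, mesh$pial_faces)
  cells2 <- sim$cells
  xyz <- sweep(as.matrix(sim$cells[c("x_um", "y_um", "z_um")]) %*% t(R),
               2, shift, "+")
  cells2$x_um <- xyz[, 1]; cells2$y_um <- xyz[, 2]; cells2$z_um <- xyz[, 3]
  st2 <- align_stack(percentile_maps(reconstruct_columns(cells2, rot_mesh)$paths))
  expect_equal(st2$expansion, st$expansion, tolerance = 1e-4)
  expect_equal(st2$rotation_rad, st$rotation_rad, tolerance = 1e-4)
  expect_equal(st2$residual_um2, st$residual_um2, tolerance = 1e-3)
})

test_that("stack orientation is gauge invariant", {
  mesh <- simulate_mesh()
  sim <- simulate_columns(mesh, n_columns = 9L, seed = 61)
  rec <- reconstruct_columns(sim$cells, mesh)
  stack <- percentile_maps(rec$paths, orient = FALSE)
  ref <- align_stack(orient_stack(stack, rec$paths))

  # scramble the bases: random in-plane rotations and normal flips
  set.seed(62)
  scr <- stack
  for (i in seq_len(nrow(scr$planes))) {
    phi <- runif(1, 0, 2 * pi)
    sgn <- sample(c(1, -1), 1)
    e1 <- scr$planes$e1[[i]]; e2 <- scr$planes$e2[[i]]
    scr$planes$e1[[i]] <- cos(phi) * e1 + sin(phi) * e2
    scr$planes$e2[[i]] <- sgn * (-sin(phi) * e1 + cos(phi) * e2)
    scr$planes$normal[[i]] <- sgn * scr$planes$normal[[i]]
  }
  out <- align_stack(orient_stack(scr, rec$paths))
  expect_equal(out$rotation_rad, ref$rotation_rad, tolerance = 1e-6)
  expect_equal(out$expansion, ref$expansion, tolerance = 1e-8)

  # identical planes stay identical after orientation
  same <- orient_stack(stack, rec$paths)
  same2 <- orient_stack(same, rec$paths)
  expect_equal(same2$planes$e1, same$planes$e1, tolerance = 1e-9)
})

test_that("cumulative trajectory sums rotations and multiplies expansions", {
  steps <- tibble::tibble(depth = seq(0.05, 1, by = 0.05),
                          expansion = rep(1, 20),
                          rotation_rad = rep(0.1, 20),
                          residual_um2 = 0, n_shared = 10)
  tr <- cumulative_trajectory(steps)
  expect_equal(tr$depth[1], 0)
  expect_equal(tr$cum_rotation_rad[21], 2.0)
  expect_equal(tr$cum_expansion, rep(1, 21))

  steps$expansion <- rep(1.05, 20)
  tr2 <- cumulative_trajectory(steps)
  expect_equal(tr2$cum_expansion[21], 1.05^20)
})

test_that("composing noiseless steps agrees with direct alignment", {
  set.seed(71)
  A <- matrix(rnorm(20, sd = 60), 10, 2)
  ids <- as.character(1:10)
  s1 <- list(e = 1.2, th = 0.3)
  s2 <- list(e = 0.9, th = -0.15)
  B <- s1$e * A %*% t(rot2_ref(s1$th))
  C <- s2$e * B %*% t(rot2_ref(s2$th))
  d02 <- align_maps(as_map(A, ids), as_map(C, ids))
  expect_equal(d02$expansion, s1$e * s2$e, tolerance = 1e-6)
  expect_equal(d02$rotation_rad, s1$th + s2$th, tolerance = 1e-6)
})
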