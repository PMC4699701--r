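#' Simulate an ellipsoidal nucleus boundary mesh
#'
#' Builds a closed triangulated ellipsoid by subdividing an icosahedron and
#' projecting onto the ellipsoid, and labels as pial the faces whose
#' centroid direction lies within `cap_angle` of the dorsal (+y) pole. Only
#' the intersection and containment behaviour of the boundary matters to the
#' pipeline, so an ellipsoid stands in for the real nucleus shape.
#'
#' @param radii Semi-axes in micrometres, `c(x, y, z)` =
#'   (medio-lateral, dorso-ventral, antero-posterior).
#' @param cap_angle Polar half-angle of the pial cap in radians
#'   (default 1.2, a broad dorsal cap so every column's extrapolated entry
#'   crossing lands on labelled faces).
#' @param subdivisions Icosahedron subdivision level (default 3, 1280 faces;
#'   enclosed volume is then within 1% of the analytic `4*pi*abc/3`).
#' @param center Ellipsoid centre (micrometres).
#' @return A [nucleus_mesh()].
#' @export
simulate_mesh <- function(radii = c(500, 420, 620), cap_angle = 1.2,
                          subdivisions = 3L, center = c(0, 0, 0)) {
  if (length(radii) != 3L || any(!is.finite(radii)) || any(radii <= 0)) {
    abort("radii must be three positive semi-axes")
  }
  ico <- icosphere(subdivisions)
  verts <- sweep(ico$vertices %*% diag(radii), 2, center, "+")
  ctr_dir <- face_centroids(list(vertices = ico$vertices, faces = ico$faces))
  ctr_dir <- ctr_dir / row_norms(ctr_dir)
  polar <- acos(pmin(pmax(ctr_dir[, 2], -1), 1))  # angle from +y pole
  pial <- which(polar < cap_angle)
  nucleus_mesh(verts, ico$faces, pial)
}

# unit icosphere: subdivided icosahedron with deduplicated vertices
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / row_norms(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(subdivisions)) {
    edge_mid <- new.env()
    verts <- v
    mid_index <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        m <- unitize_vec((verts[i, ] + verts[j, ]) / 2)
        v <<- rbind(v, m)
        idx <- nrow(v)
        edge_mid[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- mid_index(a, b); bc <- mid_index(b, c_); ca <- mid_index(c_, a)
      nf[(4 * t - 3):(4 * t), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Simulate a group of projection columns with known ground truth
#'
#' Generates `n_columns` curved column trajectories from the pial cap to the
#' ventral surface of the mesh, laterally arranged on a grid around a common
#' bowed spine. The lateral offset of each column is rotated along depth by
#' the prescribed cumulative rotation field `theta_field(t)` and scaled by
#' the expansion field `expansion_field(t)`. Cells are placed per 5% depth
#' bin with Poisson(`lambda`) counts and Rayleigh(`sigma`) radial scatter in
#' the local normal plane. V1 injection sites are an affine image of the
#' column grid offsets, with a fraction `scramble` of the column-injection
#' pairings randomly re-paired (the controllable disorder dial for
#' topography).
#'
#' @param mesh A [nucleus_mesh()] (typically [simulate_mesh()]).
#' @param n_columns Number of columns (default 16, an adult-group cohort).
#' @param lambda Expected cells per 5% depth bin: a single rate or a vector
#'   of 20 per-bin rates (default a near-uniform profile declining toward
#'   the deep core, about 105 cells per column).
#' @param sigma Rayleigh scale of radial scatter in micrometres: scalar or
#'   function of depth `t` (default 40).
#' @param theta_field Cumulative rotation field, a function of `t` in
#'   radians with `theta_field(0) = 0` (default `0.8 * t`).
#' @param expansion_field Cumulative expansion field, a function of `t` with
#'   `expansion_field(0) = 1` (default `1 + 0.4 * t`).
#' @param curvature_um Lateral bow amplitude of the common spine
#'   (default 80).
#' @param grid_spacing_um Column grid spacing at the pial end (default 120).
#' @param scramble Fraction of injection-column pairings to scramble,
#'   in `[0, 1]` (default 0).
#' @param group Group label stamped on the cells (default `"WT"`).
#' @param seed Integer seed; all draws derive from it.
#' @return A list with `cells` (tibble as [read_cells()]), `injections`
#'   (tibble as [read_injections()]), `mesh`, and `truth` (list: per-cell
#'   `cells` tibble with true `t` and `r_um`, per-column dense `paths`,
#'   `theta_field`, `expansion_field`, `pairing` tibble, and the arguments).
#' @export
simulate_columns <- function(mesh,
                             n_columns = 16L,
                             lambda = c(rep(6, 10), seq(6, 3, length.out = 10)),
                             sigma = 40,
                             theta_field = function(t) 0.8 * t,
                             expansion_field = function(t) 1 + 0.4 * t,
                             curvature_um = 80,
                             grid_spacing_um = 120,
                             scramble = 0,
                             group = "WT",
                             seed = 1L) {
  stopifnot(inherits(mesh, "nucleus_mesh"))
  if (scramble < 0 || scramble > 1) abort("scramble must be in [0, 1]")
  lambda <- rep_len(as.numeric(lambda), 20L)
  if (any(lambda < 0)) abort("lambda rates must be non-negative")
  sigma_fun <- if (is.function(sigma)) sigma else function(t) rep_len(sigma, length(t))
  if (any(sigma_fun(seq(0, 1, 0.1)) < 0)) abort("sigma must be non-negative")

  ctr <- colMeans(mesh$vertices)
  half <- apply(abs(sweep(mesh$vertices, 2, ctr)), 2, max)  # semi-axes

  spine <- function(s) {
    cbind(ctr[1] + curvature_um * sin(pi * s),
          ctr[2] + half[2] * (0.95 - 1.9 * s),
          ctr[3] + 0.3 * curvature_um * sin(pi * s / 2))
  }
  frame_at <- function(s) {
    h <- 1e-4
    tan_ <- (spine(s + h) - spine(s - h)) / (2 * h)
    t(apply(tan_, 1, function(tv) unitize_vec(tv)))
  }
  # in-plane frame: Gram-Schmidt of global x and z against the tangent
  basis_at <- function(s) {
    tn <- frame_at(s)
    lapply(seq_len(nrow(tn)), function(i) {
      tv <- tn[i, ]
      b1 <- unitize_vec(c(1, 0, 0) - sum(c(1, 0, 0) * tv) * tv)
      b2 <- unitize_vec(crossprod_3(tv, b1))
      cbind(b1, b2)
    })
  }

  # column offsets at the pial end: a jittered grid. Perfectly regular
  # spacing is rank-degenerate for neighbourhood metrics (all four nearest
  # neighbours tie), which no real injection array exhibits.
  set.seed(derive_seed(seed, 0L))
  n_side <- ceiling(sqrt(n_columns))
  gx <- (seq_len(n_side) - (n_side + 1) / 2) * grid_spacing_um
  grid <- as.matrix(expand.grid(gx, gx))[seq_len(n_columns), , drop = FALSE]
  grid <- grid + matrix(runif(2 * n_columns, -0.35, 0.35) * grid_spacing_um,
                        n_columns, 2L)

  inside <- function(P) {
    d <- sweep(P, 2, ctr)
    rowSums(sweep(d, 2, half, "/")^2) - 1
  }
  clamp01 <- function(s) pmin(pmax(s, 0), 1)

  path_fun_factory <- function(off, s0 = NULL, s1 = NULL) {
    # fields take the chord-normalized depth once the crossings are known
    function(s) {
      tt <- if (is.null(s0)) clamp01(s) else clamp01((s - s0) / (s1 - s0))
      base <- spine(s)
      bases <- basis_at(s)
      th <- theta_field(tt)
      ex <- expansion_field(tt)
      o <- cbind(ex * (cos(th) * off[1] - sin(th) * off[2]),
                 ex * (sin(th) * off[1] + cos(th) * off[2]))
      base + t(vapply(seq_along(s), function(i) {
        bases[[i]] %*% o[i, ]
      }, numeric(3)))
    }
  }

  find_crossings <- function(pf) {
    sg <- seq(-0.35, 1.35, length.out = 500)
    g <- inside(pf(sg))
    sgn <- sign(g)
    flips <- which(diff(sgn) != 0)
    if (length(flips) < 2L) abort("column does not cross the boundary twice")
    root <- function(i) {
      stats::uniroot(function(s) inside(pf(s)), c(sg[i], sg[i + 1]),
                     tol = 1e-8)$root
    }
    c(root(flips[1]), root(flips[length(flips)]))
  }

  set.seed(derive_seed(seed, 1L))
  animal_ids <- sprintf("sim%02d", seq_len(n_columns))
  cells_list <- list()
  truth_cells <- list()
  paths <- list()
  for (j in seq_len(n_columns)) {
    off <- grid[j, ]
    cross0 <- find_crossings(path_fun_factory(off))
    pf <- path_fun_factory(off, cross0[1], cross0[2])
    cross <- find_crossings(pf)
    s_grid <- seq(cross[1], cross[2], length.out = 600)
    P <- pf(s_grid)
    arc <- c(0, cumsum(row_norms(diff(P))))
    t_grid <- arc / arc[length(arc)]
    paths[[j]] <- list(animal_id = animal_ids[j], samples = P, t = t_grid,
                       entry_offset = off)

    counts <- rpois(20L, lambda)
    if (sum(counts) == 0L) next
    t_cells <- unlist(lapply(seq_len(20L), function(b) {
      runif(counts[b], (b - 1) * 0.05, b * 0.05)
    }))
    n_c <- length(t_cells)
    s_cells <- approx(t_grid, s_grid, xout = t_cells, ties = "ordered")$y
    base <- pf(s_cells)
    tanv <- frame_at(s_cells)
    r <- sigma_fun(t_cells) * sqrt(-2 * log(runif(n_c)))
    phi <- runif(n_c, 0, 2 * pi)
    pos <- base
    for (i in seq_len(n_c)) {
      tv <- tanv[i, ]
      b1 <- unitize_vec(c(1, 0, 0) - sum(c(1, 0, 0) * tv) * tv)
      b2 <- unitize_vec(crossprod_3(tv, b1))
      pos[i, ] <- base[i, ] + r[i] * (cos(phi[i]) * b1 + sin(phi[i]) * b2)
    }
    cells_list[[j]] <- tibble(
      animal_id = animal_ids[j], group = group, tracer = "red",
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    truth_cells[[j]] <- tibble(animal_id = animal_ids[j], t = t_cells, r_um = r)
  }
  cells <- bind_rows(cells_list)
  if (nrow(cells) == 0L) abort("rates produced zero cells in every column")

  # injections: affine image of the entry offsets, partially re-paired
  inj_ap <- 1.0 + 0.004 * grid[, 1]
  inj_ml <- 2.5 + 0.004 * grid[, 2]
  pairing <- seq_len(n_columns)
  n_scr <- ceiling(scramble * n_columns)
  if (n_scr >= 2L) {
    subset_idx <- sample(n_columns, n_scr)
    pairing[subset_idx] <- subset_idx[deranged(length(subset_idx))]
  }
  injections <- tibble(
    animal_id = animal_ids,
    ap_mm = inj_ap[pairing], ml_mm = inj_ml[pairing],
    volume_nl = rep(30, n_columns))

  list(
    cells = cells,
    injections = injections,
    mesh = mesh,
    truth = list(
      cells = bind_rows(truth_cells),
      paths = setNames(paths, animal_ids),
      theta_field = theta_field,
      expansion_field = expansion_field,
      sigma = sigma_fun, lambda = lambda,
      pairing = tibble(animal_id = animal_ids, source_column = animal_ids[pairing]),
      scramble = scramble, seed = seed)
  )
}

# random permutation of 1..n without fixed points (n >= 2)
deranged <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_mesh()] plus [simulate_columns()].
#'
#' @param seed Integer seed.
#' @param ... Passed to [simulate_columns()].
#' @param mesh_args List of arguments for [simulate_mesh()].
#' @return As [simulate_columns()].
#' @export
simulate_dataset <- function(seed = 1L, ..., mesh_args = list()) {
  mesh <- do.call(simulate_mesh, mesh_args)
  simulate_columns(mesh, seed = seed, ...)
}

#' Simulate a profile matrix of known latent rank
#'
#' Rows are random loadings on `rank` smooth depth basis profiles plus
#' Gaussian noise, then standardized row-wise — the ground-truth bench for
#' [pls_latent_scan()].
#'
#' @param n_profiles Number of rows (default 16).
#' @param rank True latent rank `k >= 1` (default 4).
#' @param noise_sd Noise standard deviation relative to unit-scale signal
#'   (default 0.05).
#' @param n_levels Depth levels (default 21).
#' @param seed Integer seed.
#' @return List with `matrix` (a standardized `profile_matrix`), `raw` (the
#'   unstandardized signal-plus-noise matrix) and `rank`.
#' @export
simulate_profile_matrix <- function(n_profiles = 16L, rank = 4L,
                                    noise_sd = 0.05, n_levels = 21L,
                                    seed = 1L) {
  if (rank < 1L) abort("rank must be at least 1")
  if (rank >= min(n_profiles, n_levels)) {
    abort("rank must be smaller than both matrix dimensions")
  }
  set.seed(derive_seed(seed, 2L))
  t <- seq(0, 1, length.out = n_levels)
  basis <- t(vapply(seq_len(rank), function(i) {
    cos(pi * i * t + runif(1, 0, 2 * pi))
  }, numeric(n_levels)))
  loadings <- matrix(rnorm(n_profiles * rank), n_profiles, rank)
  raw <- loadings %*% basis + noise_sd * matrix(rnorm(n_profiles * n_levels),
                                                n_profiles, n_levels)
  mat <- t(apply(raw, 1, standardize_profile))
  colnames(mat) <- format(t, trim = TRUE)
  ri <- tibble(metric = sprintf("profile%02d", seq_len(n_profiles)),
               group = "sim")
  rownames(mat) <- ri$metric
  list(matrix = structure(mat, row_info = ri,
                          class = c("profile_matrix", "matrix", "array")),
       raw = raw, rank = rank)
}
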