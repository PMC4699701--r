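#' Iso-percentile 3D points along a set of column paths
#'
#' Returns, for each column that spans depth `t`, the arc-length point at
#' fraction `t` along its unitized path (pial to ventral).
#'
#' @param paths Named list of `column_path` objects (names or `animal_id`
#'   identify columns) processed by [intersect_boundary()].
#' @param t A single depth in `[0, 1]`.
#' @return Tibble with columns `animal_id`, `x_um`, `y_um`, `z_um`.
#' @export
iso_percentile_points <- function(paths, t) {
  stopifnot(length(t) == 1L, t >= 0, t <= 1)
  rows <- purrr::imap(paths, function(p, nm) {
    span <- p$span %||% c(0, 1)
    if (t < span[1] - 1e-12 || t > span[2] + 1e-12) return(NULL)
    pt <- path_point(p, t)
    tibble(animal_id = if (!is.null(p$animal_id) && !is.na(p$animal_id))
      p$animal_id else as.character(nm),
      x_um = pt[1], y_um = pt[2], z_um = pt[3])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) abort(paste0("empty map: no columns span depth ", t))
  out
}

#' Total least-squares plane through 3D points
#'
#' The plane through the centroid whose normal is the smallest-variance
#' principal direction; the in-plane basis is the two leading principal
#' directions.
#'
#' @param points Numeric matrix n x 3 (n >= 3, not collinear) or a tibble
#'   with `x_um, y_um, z_um`.
#' @return List with `origin` (centroid), `basis` (3 x 2 orthonormal),
#'   `normal` (unit vector).
#' @export
best_fit_plane <- function(points) {
  X <- cells_matrix(points)
  if (nrow(X) < 3L) abort("need at least 3 points for a plane")
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0, nv = 3)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-12) {
    abort("degenerate plane fit: points are collinear")
  }
  list(origin = ctr, basis = sv$v[, 1:2, drop = FALSE], normal = sv$v[, 3])
}

#' Build the per-depth 2D map stack of a column group
#'
#' At each depth level a best-fit plane is fitted to the iso-percentile
#' points and the points are orthogonally projected into the plane's
#' 2D coordinates. The stack is then gauge-fixed by [orient_stack()] so that
#' plane normals co-orient with the mean pial-to-ventral direction and each
#' basis is rotated in-plane to minimize spurious rotation relative to its
#' shallower neighbour.
#'
#' @param paths Named list of unitized `column_path` objects.
#' @param depths Depth levels (default 0 to 1 in steps of 0.05, 21 levels).
#' @param orient Apply [orient_stack()] (default TRUE).
#' @return An object of class `map_stack`: list with `points` (tibble:
#'   `depth, animal_id, u_um, v_um`) and `planes` (tibble: `depth, origin,
#'   e1, e2, normal` as list-columns).
#' @export
percentile_maps <- function(paths, depths = seq(0, 1, by = 0.05), orient = TRUE) {
  planes <- purrr::map(depths, function(t) {
    pts <- iso_percentile_points(paths, t)
    pl <- best_fit_plane(pts)
    list(depth = t, plane = pl, pts = pts)
  })
  stack <- structure(list(
    points = bind_rows(purrr::map(planes, function(z) {
      project_to_plane(z$pts, z$plane, z$depth)
    })),
    planes = tibble(
      depth = depths,
      origin = purrr::map(planes, ~ .x$plane$origin),
      e1 = purrr::map(planes, ~ .x$plane$basis[, 1]),
      e2 = purrr::map(planes, ~ .x$plane$basis[, 2]),
      normal = purrr::map(planes, ~ .x$plane$normal)
    ),
    points3d = purrr::map(planes, "pts")
  ), class = "map_stack")
  if (orient) orient_stack(stack, paths) else stack
}

project_to_plane <- function(pts, plane, depth) {
  X <- sweep(as.matrix(pts[c("x_um", "y_um", "z_um")]), 2, plane$origin)
  uv <- X %*% plane$basis
  tibble(depth = depth, animal_id = pts$animal_id,
         u_um = uv[, 1], v_um = uv[, 2])
}

#' @export
print.map_stack <- function(x, ...) {
  cat("<map_stack> ", nrow(x$planes), " depth levels, ",
      dplyr::n_distinct(x$points$animal_id), " columns\n", sep = "")
  invisible(x)
}

#' Gauge-fix the bases of a map stack
#'
#' Principal-axis bases are defined only up to sign flips and in-plane
#' rotation, which would contaminate between-depth rotation estimates.
#' Normals are co-oriented with the mean pial-to-ventral direction of the
#' columns (keeping the basis right-handed), then each basis is rotated
#' in-plane to the orientation closest to its shallower neighbour's basis.
#' Relative geometry of the mapped points is unchanged.
#'
#' @param stack A `map_stack`.
#' @param paths The column paths the stack was built from (used for the mean
#'   pial-to-ventral direction); optional if the stack was built by
#'   [percentile_maps()] from at least 2 depths.
#' @return The re-gauged `map_stack`.
#' @export
orient_stack <- function(stack, paths = NULL) {
  pl <- stack$planes
  n_lev <- nrow(pl)
  if (!is.null(paths)) {
    dirs <- purrr::map(paths, ~ .x$ventral_point - .x$pial_point)
    down <- unitize_vec(Reduce(`+`, dirs) / length(dirs))
  } else {
    if (n_lev < 2L) abort("cannot infer the depth direction from one plane")
    down <- unitize_vec(pl$origin[[n_lev]] - pl$origin[[1]])
  }
  prev_basis <- NULL
  for (i in seq_len(n_lev)) {
    e1 <- pl$e1[[i]]; nrm <- pl$normal[[i]]
    if (sum(nrm * down) < 0) nrm <- -nrm
    # right-handed in-plane frame: guarantees pure rotations between depths
    e2 <- crossprod_3(nrm, e1)
    if (!is.null(prev_basis)) {
      p1 <- prev_basis[, 1]; p2 <- prev_basis[, 2]
      a <- sum(p1 * e1) + sum(p2 * e2)
      b <- sum(p1 * e2) - sum(p2 * e1)
      phi <- atan2(b, a)
      e1n <- cos(phi) * e1 + sin(phi) * e2
      e2n <- -sin(phi) * e1 + cos(phi) * e2
      e1 <- e1n; e2 <- e2n
    }
    pl$e1[[i]] <- e1; pl$e2[[i]] <- e2; pl$normal[[i]] <- nrm
    prev_basis <- cbind(e1, e2)
  }
  stack$planes <- pl
  stack$points <- bind_rows(purrr::map(seq_len(n_lev), function(i) {
    project_to_plane(stack$points3d[[i]],
                     list(origin = pl$origin[[i]],
                          basis = cbind(pl$e1[[i]], pl$e2[[i]])),
                     pl$depth[i])
  }))
  stack
}

#' Constrained similarity alignment of two 2D maps
#'
#' Finds expansion `E`, rotation `theta` (counter-clockwise positive) and
#' translation minimizing the mean squared distance between
#' `E * R(theta) * a_i + translation` and `b_i` over columns shared by the
#' two maps. The optimum is found by bounded non-linear minimization
#' (`E` in `[0.1, 10]`, `theta` in `(-pi, pi]`) initialized at the
#' closed-form 2D similarity Procrustes solution; on interior problems the
#' two agree to solver tolerance.
#'
#' @param map_a,map_b Tibbles with `animal_id`, `u_um`, `v_um` (depth columns
#'   are ignored); at least 2 shared columns.
#' @param bounds_e Expansion bounds (default `c(0.1, 10)`).
#' @return An object of class `alignment_step`: one-row tibble with columns
#'   `expansion`, `rotation_rad`, `tx_um`, `ty_um`, `residual_um2` (mean
#'   squared), `n_shared`.
#' @export
align_maps <- function(map_a, map_b, bounds_e = c(0.1, 10)) {
  shared <- intersect(map_a$animal_id, map_b$animal_id)
  if (length(shared) < 2L) abort("need at least 2 shared columns to align maps")
  A <- as.matrix(map_a[match(shared, map_a$animal_id), c("u_um", "v_um")])
  B <- as.matrix(map_b[match(shared, map_b$animal_id), c("u_um", "v_um")])
  if (max(row_norms(sweep(A, 2, colMeans(A)))) < 1e-12) {
    abort("degenerate map: all points of one map coincident")
  }
  init <- procrustes_similarity(A, B)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(par) {
    M <- Ac %*% t(par[1] * rot2(par[2]))
    mean(rowSums((M - Bc)^2))
  }
  par0 <- c(min(max(init$expansion, bounds_e[1]), bounds_e[2]), init$rotation)
  opt <- optim(par0, obj, method = "L-BFGS-B",
               lower = c(bounds_e[1], -pi), upper = c(bounds_e[2], pi),
               control = list(factr = 1e3))
  e_hat <- opt$par[1]
  th_hat <- wrap_angle(opt$par[2])
  tr <- unname(colMeans(B) - e_hat * (rot2(th_hat) %*% colMeans(A))[, 1])
  structure(tibble(
    expansion = e_hat, rotation_rad = th_hat,
    tx_um = tr[1], ty_um = tr[2],
    residual_um2 = opt$value, n_shared = length(shared)
  ), class = c("alignment_step", "tbl_df", "tbl", "data.frame"))
}

#' Closed-form 2D similarity Procrustes solution
#'
#' Least-squares rotation + uniform scale + translation mapping `A` onto
#' `B` (no reflection). Serves as the analytic reference for [align_maps()].
#'
#' @param A,B Numeric n x 2 matrices of matched points.
#' @return List with `expansion`, `rotation`, `translation`, `residual_um2`.
#' @export
procrustes_similarity <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == 2L, ncol(B) == 2L)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  dot <- sum(Ac * Bc)
  crs <- sum(Ac[, 1] * Bc[, 2] - Ac[, 2] * Bc[, 1])
  theta <- atan2(crs, dot)
  denom <- sum(Ac^2)
  if (denom == 0) abort("degenerate map: all points of one map coincident")
  e <- sqrt(dot^2 + crs^2) / denom
  tr <- colMeans(B) - e * (rot2(theta) %*% colMeans(A))[, 1]
  resid <- mean(rowSums((Ac %*% t(e * rot2(theta)) - Bc)^2))
  list(expansion = e, rotation = theta, translation = tr, residual_um2 = resid)
}

#' Align all neighbouring depth maps of a stack
#'
#' Each depth level is aligned to its shallower neighbour (the step transform
#' maps the shallower map onto the deeper one); columns absent at either
#' depth are dropped pairwise.
#'
#' @param stack A `map_stack`.
#' @inheritParams align_maps
#' @return Tibble of [align_maps()] rows with a leading `depth` column (the
#'   deeper level of each pair).
#' @export
align_stack <- function(stack, bounds_e = c(0.1, 10)) {
  depths <- sort(unique(stack$points$depth))
  steps <- purrr::map(seq_along(depths)[-1], function(i) {
    a <- dplyr::filter(stack$points, .data$depth == depths[i - 1])
    b <- dplyr::filter(stack$points, .data$depth == depths[i])
    st <- align_maps(a, b, bounds_e = bounds_e)
    mutate(st, depth = depths[i], .before = 1)
  })
  bind_rows(steps)
}

#' Cumulative rotation and expansion along the column
#'
#' Anchored at the pial plane: cumulative rotation is the running sum of the
#' step rotations (0 at depth 0) and cumulative expansion the running product
#' of step expansions (1 at depth 0).
#'
#' @param steps Output of [align_stack()] (ordered by depth).
#' @return Tibble with `depth`, `cum_rotation_rad`, `cum_expansion`.
#' @export
cumulative_trajectory <- function(steps) {
  steps <- arrange(steps, .data$depth)
  depth0 <- if (nrow(steps) >= 2L) steps$depth[1] - diff(steps$depth)[1] else 0
  tibble(
    depth = c(depth0, steps$depth),
    cum_rotation_rad = c(0, cumsum(steps$rotation_rad)),
    cum_expansion = c(1, cumprod(steps$expansion))
  )
}
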