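#' Fit a projection-column trajectory through a 3D cell cloud
#'
#' The column path is modelled per axis as a piecewise-quadratic polynomial
#' (a degree-2 B-spline) with `n_breaks` uniformly spaced interior breaks,
#' fitted by least squares. The ordering parameter is obtained by projecting
#' the cells onto the first principal axis of the cloud and ranking; it is
#' then refined once by re-projecting every cell onto the fitted path and
#' refitting (one fixed iteration).
#'
#' @param cells Tibble with columns `x_um, y_um, z_um` (or a numeric n x 3
#'   matrix); at least 10 cells, not all coincident.
#' @param n_breaks Number of uniformly spaced interior breaks (default 5).
#' @param n_dense Number of dense samples used to represent the path.
#' @param span_trim Quantile of projected cell positions anchoring the
#'   refined parameter span (default 0.05; 0 reproduces the full-range
#'   parameterization).
#' @return An object of class `column_path` with the spline coefficients, the
#'   interior breaks, and a dense arc-length-parameterized polyline. Boundary
#'   intersections are added by [intersect_boundary()].
#' @export
fit_column_path <- function(cells, n_breaks = 5L, n_dense = 1001L,
                            span_trim = 0.05) {
  X <- cells_matrix(cells)
  n <- nrow(X)
  if (n < 10L) abort("need at least 10 cells to fit a column path")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9) abort("degenerate cell cloud: all cells coincident")
  # rank-based ordering along the first principal axis
  proj <- Xc %*% sv$v[, 1]
  u <- (rank(proj, ties.method = "first") - 1) / (n - 1)
  fit <- fit_quadratic_spline(u, X, n_breaks)
  # one refinement pass: re-parameterize by nearest point on the fitted path.
  # The refined span is anchored at the span_trim/1-span_trim quantiles of
  # the projected positions, so a single extreme cell cannot set the end of
  # the domain and destabilize the (extrapolated) end pieces; the boundary
  # extension of intersect_boundary() recovers the trimmed ends.
  dense <- eval_spline(fit, seq(0, 1, length.out = n_dense))
  # parameter (not arc-length) of the nearest path point: keeps curves that
  # are exactly representable in the spline family fixed points of the
  # refinement
  u2 <- nearest_on_polyline(X, dense)$param
  qq <- unname(quantile(u2, c(span_trim, 1 - span_trim)))
  if (qq[2] - qq[1] < 1e-9) abort("degenerate configuration: path collapsed")
  u2 <- pmin(pmax((u2 - qq[1]) / (qq[2] - qq[1]), 0), 1)
  fit <- fit_quadratic_spline(u2, X, n_breaks)
  dense <- eval_spline(fit, seq(0, 1, length.out = n_dense))
  structure(list(
    coef = fit$coef, knots = fit$knots, degree = 2L,
    animal_id = attr(cells, "animal_id") %||%
      (if (is.data.frame(cells) && "animal_id" %in% names(cells))
        as.character(cells$animal_id[1]) else NA_character_),
    n_cells = n,
    samples = dense,
    pial_point = NULL, ventral_point = NULL,
    polyline = NULL, arclen = NULL, total_length = NULL,
    span = c(0, 1)
  ), class = "column_path")
}

#' @export
print.column_path <- function(x, ...) {
  cat("<column_path> animal ", x$animal_id, ", ", x$n_cells, " cells",
      if (!is.null(x$total_length))
        paste0(", length ", format(x$total_length, digits = 5), " um"),
      "\n", sep = "")
  invisible(x)
}

# least-squares degree-2 B-spline fit of each coordinate against u in [0,1]
fit_quadratic_spline <- function(u, X, n_breaks) {
  knots <- seq_len(n_breaks) / (n_breaks + 1)
  B <- splines::bs(u, knots = knots, degree = 2L, intercept = TRUE,
                   Boundary.knots = c(0, 1))
  qr_B <- qr(B)
  if (qr_B$rank < ncol(B)) {
    abort("rank-deficient spline design: cells do not support the break scheme")
  }
  coef <- qr.coef(qr_B, X)
  list(coef = coef, knots = knots)
}

eval_spline <- function(fit, u) {
  B <- splines::bs(pmin(pmax(u, 0), 1), knots = fit$knots, degree = 2L,
                   intercept = TRUE, Boundary.knots = c(0, 1))
  unname(B %*% fit$coef)
}

# Nearest point on a densely sampled polyline for each query point: nearest
# vertex, then continuous refinement by projection onto the two adjacent
# segments. `s` is the normalized arc length of the refined foot point,
# `param` the continuous fractional-index parameter in [0, 1], `d` the
# Euclidean distance.
nearest_on_polyline <- function(points, poly) {
  n_poly <- nrow(poly)
  seglen <- row_norms(diff(poly))
  cum <- c(0, cumsum(seglen))
  total <- cum[n_poly]
  idx <- integer(nrow(points))
  d <- numeric(nrow(points))
  # chunked distance computation keeps memory bounded
  step <- max(1L, floor(2e6 / n_poly))
  for (start in seq(1L, nrow(points), by = step)) {
    rows <- start:min(start + step - 1L, nrow(points))
    dd <- outer(rowSums(points[rows, , drop = FALSE]^2), rowSums(poly^2), "+") -
      2 * points[rows, , drop = FALSE] %*% t(poly)
    j <- max.col(-dd, ties.method = "first")
    idx[rows] <- j
    d[rows] <- sqrt(pmax(dd[cbind(seq_along(rows), j)], 0))
  }
  best_d <- d
  best_arc <- cum[idx]
  best_ci <- idx - 1                      # continuous 0-based index
  for (side in c(-1L, 0L)) {
    a_i <- idx + side                     # segment a_i -> a_i + 1
    valid <- a_i >= 1L & a_i <= n_poly - 1L
    a_c <- pmin(pmax(a_i, 1L), n_poly - 1L)
    A <- poly[a_c, , drop = FALSE]
    AB <- poly[a_c + 1L, , drop = FALSE] - A
    tt <- rowSums((points - A) * AB) / pmax(rowSums(AB^2), 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    P <- A + AB * tt
    dd <- sqrt(rowSums((points - P)^2))
    upd <- valid & dd <= best_d
    best_d[upd] <- dd[upd]
    best_arc[upd] <- cum[a_c[upd]] + seglen[a_c[upd]] * tt[upd]
    best_ci[upd] <- (a_c[upd] - 1L) + tt[upd]
  }
  list(index = idx,
       s = if (total > 0) best_arc / total else best_arc,
       param = best_ci / (n_poly - 1),
       d = best_d, arclen = best_arc, total = total)
}

#' Intersect an extrapolated column path with the nucleus boundary
#'
#' Each end of the fitted path is extended along its terminal tangent until
#' it first crosses the mesh; the end whose crossing lands on a pial-labelled
#' face becomes the pial end (unit depth 0) and the other the ventral end
#' (unit depth 1). The returned path carries the boundary points, a dense
#' pial-to-ventral polyline and the total arc length.
#'
#' @param path A [fit_column_path()] result.
#' @param mesh A [nucleus_mesh()].
#' @param max_extension Maximum extension at each end, as a multiple of the
#'   fitted path's own length (default 5).
#' @return The `column_path` with `pial_point`, `ventral_point`, `polyline`,
#'   `arclen` and `total_length` filled in.
#' @export
intersect_boundary <- function(path, mesh, max_extension = 5) {
  stopifnot(inherits(path, "column_path"), inherits(mesh, "nucleus_mesh"))
  dense <- path$samples
  inner_len <- sum(row_norms(diff(dense)))
  if (inner_len <= 0) abort("degenerate path: zero length")
  # terminal tangents from the dense samples, pointing outward at each end
  # Each end may have overshot the boundary (quadratic end pieces swing on
  # noisy clouds); the ray is therefore cast from the last dense sample that
  # is still inside the mesh, along the outward local tangent.
  n_d <- nrow(dense)
  end_hit <- function(ord) {
    probe <- head(ord, 100L)
    ins <- points_in_mesh(dense[probe, , drop = FALSE], mesh)
    if (!any(ins)) return(NULL)
    k <- which(ins)[1]
    i_in <- probe[k]
    nb <- ord[which(ord == i_in) + 1L]
    dir <- unitize_vec(dense[i_in, ] - dense[nb, ])
    hits <- ray_mesh_all(mesh, dense[i_in, ], dir)
    if (is.null(hits)) return(NULL)
    ahead <- which(hits$t >= -1e-9 & hits$t <= max_extension * inner_len)
    if (!length(ahead)) return(NULL)
    list(point = dense[i_in, ] + hits$t[ahead[1]] * dir,
         face = hits$face[ahead[1]], i_in = i_in)
  }
  hit0 <- end_hit(seq_len(n_d))
  hit1 <- end_hit(rev(seq_len(n_d)))
  if (is.null(hit0) || is.null(hit1)) {
    abort("no intersection: extrapolated column does not reach the mesh boundary")
  }
  p0 <- hit0$point
  p1 <- hit1$point
  dense <- dense[hit0$i_in:hit1$i_in, , drop = FALSE]
  if (nrow(dense) < 2L) abort("degenerate path: fully outside the mesh")
  pial0 <- hit0$face %in% mesh$pial_faces
  pial1 <- hit1$face %in% mesh$pial_faces
  if (pial0 && pial1) abort("ambiguous column: both ends cross pial-labelled faces")
  if (!pial0 && !pial1) abort("ambiguous column: neither end crosses a pial-labelled face")
  if (pial0) {
    poly <- rbind(p0, dense, p1)
    path$pial_point <- p0
    path$ventral_point <- p1
  } else {
    poly <- rbind(p1, dense[rev(seq_len(nrow(dense))), ], p0)
    path$pial_point <- p1
    path$ventral_point <- p0
  }
  # drop duplicated points if an end already lay on the surface
  keep <- c(TRUE, row_norms(diff(poly)) > 1e-9)
  poly <- poly[keep, , drop = FALSE]
  dimnames(poly) <- NULL
  path$polyline <- poly
  path$arclen <- c(0, cumsum(row_norms(diff(poly))))
  path$total_length <- path$arclen[length(path$arclen)]
  path
}

#' Point on a unitized column path at a given depth
#'
#' Linear interpolation of the dense polyline at arc-length fraction `t`
#' (0 = pial, 1 = ventral).
#'
#' @param path A `column_path` processed by [intersect_boundary()].
#' @param t Depth fractions in `[0, 1]`.
#' @return Numeric matrix, `length(t)` x 3.
#' @export
path_point <- function(path, t) {
  if (is.null(path$polyline)) abort("path has no boundary intersections yet")
  s <- pmin(pmax(t, 0), 1) * path$total_length
  out <- vapply(1:3, function(j) {
    approx(path$arclen, path$polyline[, j], xout = s, ties = "ordered")$y
  }, numeric(length(t)))
  matrix(out, ncol = 3L)
}

#' Express cells in unit-column coordinates
#'
#' Each cell is assigned the normalized arc-length `t` of its nearest point
#' on the column polyline (0 = pial, 1 = ventral) and the Euclidean distance
#' `r_um` to that point. Cells whose nearest point is an endpoint and that
#' lie beyond it along the terminal tangent are clipped to t = 0 or 1 and
#' flagged.
#'
#' @param cells Tibble with `x_um, y_um, z_um` (and optionally `animal_id`).
#' @param path A `column_path` processed by [intersect_boundary()].
#' @return A tibble with columns `animal_id`, `t`, `r_um`, `clipped`.
#' @export
unitize <- function(cells, path) {
  if (is.null(path$polyline)) abort("path has no boundary intersections yet")
  X <- cells_matrix(cells)
  np <- nearest_on_polyline(X, path$polyline)
  t <- np$arclen / path$total_length
  n_poly <- nrow(path$polyline)
  tan0 <- unitize_vec(path$polyline[1, ] - path$polyline[2, ])
  tan1 <- unitize_vec(path$polyline[n_poly, ] - path$polyline[n_poly - 1, ])
  beyond0 <- np$index == 1L &
    (sweep(X, 2, path$polyline[1, ]) %*% tan0)[, 1] > 0
  beyond1 <- np$index == n_poly &
    (sweep(X, 2, path$polyline[n_poly, ]) %*% tan1)[, 1] > 0
  tibble(
    animal_id = if (is.data.frame(cells) && "animal_id" %in% names(cells))
      as.character(cells$animal_id) else path$animal_id,
    t = unname(pmin(pmax(t, 0), 1)),
    r_um = unname(np$d),
    clipped = beyond0 | beyond1
  )
}

# accepts a tibble with x_um/y_um/z_um or a bare numeric matrix
cells_matrix <- function(cells) {
  if (is.matrix(cells)) {
    stopifnot(ncol(cells) == 3L)
    X <- cells
  } else {
    need <- c("x_um", "y_um", "z_um")
    if (!all(need %in% names(cells))) {
      abort("cells must have columns x_um, y_um, z_um")
    }
    X <- as.matrix(cells[need])
  }
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) abort("non-finite cell coordinates")
  unname(X)
}
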