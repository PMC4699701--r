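# Ray/mesh geometry used by boundary intersection and containment checks.

# Moller-Trumbore ray-triangle intersection, vectorized over all faces.
# Returns all line crossings as a list(t, face) sorted by t, or NULL.
ray_mesh_all <- function(mesh, origin, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  d <- matrix(dir, nrow(f), 3L, byrow = TRUE)
  # h = dir x e2
  h <- cbind(d[, 2] * e2[, 3] - d[, 3] * e2[, 2],
             d[, 3] * e2[, 1] - d[, 1] * e2[, 3],
             d[, 1] * e2[, 2] - d[, 2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- matrix(origin, nrow(f), 3L, byrow = TRUE) - a
  u <- rowSums(s * h) / det
  # q = s x e1
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- rowSums(d * q) / det
  tt <- rowSums(e2 * q) / det
  eps <- 1e-9
  hit <- ok & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps
  if (!any(hit)) return(NULL)
  idx <- which(hit)
  ord <- order(tt[idx])
  list(t = unname(tt[idx][ord]), face = unname(idx[ord]))
}

# Boundary crossing for one path end: origin is the path endpoint and dir its
# outward terminal tangent. If the endpoint is still inside the mesh, the
# first crossing ahead is taken; if the fitted end already overshot the
# boundary, the exit crossing just behind it is taken instead.
end_boundary_hit <- function(mesh, origin, dir, max_forward, max_back) {
  hits <- ray_mesh_all(mesh, origin, dir)
  if (is.null(hits)) return(NULL)
  ahead <- which(hits$t >= -1e-9 & hits$t <= max_forward)
  if (length(ahead)) {
    i <- ahead[1]
    return(list(t = hits$t[i], face = hits$face[i]))
  }
  behind <- which(hits$t < 0 & hits$t >= -max_back)
  if (length(behind)) {
    i <- behind[length(behind)]
    return(list(t = hits$t[i], face = hits$face[i]))
  }
  NULL
}

# Outward unit normals of all faces.
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / row_norms(n)
}

# Face centroids.
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Test whether points lie inside a mesh
#'
#' Ray-parity containment, optionally after inflating the mesh about its
#' centroid by `tolerance` micrometres so that cells marginally outside the
#' boundary (e.g. scatter at the surface) still validate.
#'
#' @param points Numeric matrix, n x 3 (micrometres).
#' @param mesh A [nucleus_mesh()].
#' @param tolerance Radial inflation in micrometres (default 0).
#' @return Logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh, tolerance = 0) {
  points <- matrix(as.numeric(points), ncol = 3L)
  m <- mesh
  if (tolerance > 0) {
    ctr <- colMeans(mesh$vertices)
    vc <- sweep(mesh$vertices, 2, ctr)
    r <- pmax(row_norms(vc), 1e-12)
    m <- mesh
    m$vertices <- sweep(vc * (1 + tolerance / r), 2, ctr, "+")
  }
  # irrational direction avoids edge-grazing ties on structured meshes
  dir <- unitize_vec(c(0.5641895835, 0.7236067977, 0.3969026042))
  vapply(seq_len(nrow(points)), function(i) {
    crossings <- count_ray_crossings(m, points[i, ], dir)
    crossings %% 2L == 1L
  }, logical(1))
}

count_ray_crossings <- function(mesh, origin, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  d <- matrix(dir, nrow(f), 3L, byrow = TRUE)
  h <- cbind(d[, 2] * e2[, 3] - d[, 3] * e2[, 2],
             d[, 3] * e2[, 1] - d[, 1] * e2[, 3],
             d[, 1] * e2[, 2] - d[, 2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- matrix(origin, nrow(f), 3L, byrow = TRUE) - a
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- rowSums(d * q) / det
  tt <- rowSums(e2 * q) / det
  sum(ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 0)
}
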