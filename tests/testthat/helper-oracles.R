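# Shared fixtures and independent oracles, built in code at test time.

# Brute-force topographic product: literal triple loop over points, ranks
# and neighbour prefixes. Kept deliberately naive and independent of the
# package's vectorized implementation.
bf_topographic_product <- function(A, B) {
  N <- nrow(A)
  Da <- as.matrix(stats::dist(A))
  Db <- as.matrix(stats::dist(B))
  total <- 0
  for (j in seq_len(N)) {
    na <- setdiff(order(Da[j, ]), j)   # stable order: ties by lowest index
    nb <- setdiff(order(Db[j, ]), j)
    for (k in seq_len(N - 1)) {
      s <- 0
      for (l in seq_len(k)) {
        s <- s + log(Db[j, na[l]] / Db[j, nb[l]]) +
          log(Da[j, na[l]] / Da[j, nb[l]])
      }
      total <- total + s / (2 * k)
    }
  }
  total / (N * (N - 1))
}

# All permutations of 1..n (independent of the package's enumerator).
bf_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in bf_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# 2D rotation matrix, counter-clockwise (test-local copy).
rot2_ref <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Cells scattered around a gentle 3D helix-like curve, with ground truth.
helix_cells <- function(n = 300, sigma = 5, seed = 1,
                        radius = 120, pitch = 900, turns = 0.6) {
  set.seed(seed)
  s <- sort(runif(n))
  base <- cbind(radius * cos(2 * pi * turns * s),
                pitch * (s - 0.5),
                radius * sin(2 * pi * turns * s))
  noise <- matrix(rnorm(3 * n, sd = sigma), n, 3)
  list(cells = tibble::tibble(animal_id = "hx", x_um = base[, 1] + noise[, 1],
                              y_um = base[, 2] + noise[, 2],
                              z_um = base[, 3] + noise[, 3]),
       base = base, s = s)
}

# Small shared meshes (icosphere-based; built once per test run).
unit_sphere_mesh <- function(r = 100, subdivisions = 2L) {
  simulate_mesh(radii = rep(r, 3), cap_angle = pi / 4,
                subdivisions = subdivisions)
}

# Deterministic jittered 2D configuration (non-degenerate neighbour ranks).
jittered_grid <- function(n = 16, spacing = 100, seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  g <- as.matrix(expand.grid(seq_len(side), seq_len(side)))[seq_len(n), ] * spacing
  unname(g + matrix(runif(2 * n, -0.3, 0.3) * spacing, n, 2))
}

# Tibble wrapper for a 2D configuration matrix.
as_map <- function(m, ids = as.character(seq_len(nrow(m))), depth = 0) {
  tibble::tibble(depth = depth, animal_id = ids, u_um = m[, 1], v_um = m[, 2])
}
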