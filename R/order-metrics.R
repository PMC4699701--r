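#' Raw topographic product between two matched point configurations
#'
#' The topographic product of Bauer and Pawelzik quantifies how well
#' neighbourhood ranks are preserved between two spaces holding the same
#' labelled points. For point `j` and neighbour rank `k`, with `n_a(j,k)` the
#' k-th nearest neighbour of `j` in space `a` (ties broken by lowest index)
#' and `d_a`, `d_b` the within-space distances,
#' \deqn{Q_1 = d_b(j, n_a(j,k)) / d_b(j, n_b(j,k)), \quad
#'       Q_2 = d_a(j, n_a(j,k)) / d_a(j, n_b(j,k)),}
#' \deqn{P = \frac{1}{N(N-1)} \sum_j \sum_{k=1}^{N-1}
#'       \log\Big[\big(\prod_{l \le k} Q_1(j,l)\,Q_2(j,l)\big)^{1/2k}\Big].}
#' `P = 0` when the two spaces have identical neighbourhood structure; the
#' sign flips when the spaces are exchanged, so order is usually summarized
#' by `|P|` (see [normalized_pt()]).
#'
#' @param space_a,space_b Numeric matrices (N x d, d may differ between
#'   spaces) or tibbles with `u_um`/`v_um` or `x_um`/`y_um`/`z_um` columns;
#'   rows matched by position, N >= 3.
#' @param jitter If TRUE, coincident points within a space are separated by
#'   a deterministic jitter of `1e-6 *` configuration diameter before
#'   distances are taken; if FALSE (default) coincident points are an error.
#' @return The raw product `P` (a scalar).
#' @export
topographic_product <- function(space_a, space_b, jitter = FALSE) {
  A <- config_matrix(space_a)
  B <- config_matrix(space_b)
  if (nrow(A) != nrow(B)) abort("matched configurations must have equal point counts")
  if (nrow(A) < 3L) abort("need at least 3 matched points")
  Da <- config_dist(A, jitter)
  Db <- config_dist(B, jitter)
  tp_core(Da, Db)
}

# distance matrix with coincident-point policy
config_dist <- function(X, jitter) {
  D <- as.matrix(stats::dist(X))
  if (any(D[upper.tri(D)] == 0)) {
    if (!jitter) {
      abort(paste0("coincident points within one space give zero distances; ",
                   "set jitter = TRUE to separate them deterministically"))
    }
    diam <- max(D)
    if (diam == 0) abort("all points of one space coincident; cannot jitter")
    n <- nrow(X)
    # deterministic low-discrepancy offsets, scaled to 1e-6 * diameter
    ang <- 2 * pi * (seq_len(n) * 0.6180339887498949) %% (2 * pi)
    off <- 1e-6 * diam * seq_len(n) / n
    Xj <- X
    Xj[, 1] <- Xj[, 1] + off * cos(ang)
    Xj[, 2] <- Xj[, 2] + off * sin(ang)
    D <- as.matrix(stats::dist(Xj))
  }
  D
}

# core double sum over points and neighbour ranks, vectorized
tp_core <- function(Da, Db) {
  N <- nrow(Da)
  diag(Da) <- Inf
  diag(Db) <- Inf
  orda <- t(apply(Da, 1, order))[, seq_len(N - 1), drop = FALSE]
  ordb <- t(apply(Db, 1, order))[, seq_len(N - 1), drop = FALSE]
  j <- rep(seq_len(N), N - 1)
  ia <- cbind(j, as.vector(orda))
  ib <- cbind(j, as.vector(ordb))
  L <- (log(Db[ia]) - log(Db[ib])) + (log(Da[ia]) - log(Da[ib]))
  L <- matrix(L, N, N - 1)
  C <- if (N == 2L) L else t(apply(L, 1, cumsum))
  k <- matrix(rep(seq_len(N - 1), each = N), N)
  sum(C / (2 * k)) / (N * (N - 1))
}

#' Permutation-normalized topographic product
#'
#' The raw product has no absolute scale, so it is normalized by the mean
#' `|P|` of random relabellings of one space: `P_t = |P_obs| / mean_perm |P|`.
#' 0 means perfect order and values near 1 complete disorder (values above 1
#' are possible and are not clipped). The Monte-Carlo p-value is
#' `(1 + #{permutations with |P_perm| <= |P_obs|}) / (1 + n_perm)`, the
#' probability of a relabelling at least as ordered as the observed map.
#'
#' @inheritParams topographic_product
#' @param n_perm Number of permutations (>= 99), or `"exhaustive"` to
#'   enumerate all `N!` relabellings (N <= 7).
#' @param seed Integer seed for the permutation draws.
#' @return A one-row tibble (class `order_result`): `raw_p`, `norm_pt`,
#'   `p_value`, `n_points`, `n_perm`, `seed`, `low_n`.
#' @export
normalized_pt <- function(space_a, space_b, n_perm = 999, seed = 1L,
                          jitter = FALSE) {
  A <- config_matrix(space_a)
  B <- config_matrix(space_b)
  if (nrow(A) != nrow(B)) abort("matched configurations must have equal point counts")
  N <- nrow(A)
  if (N < 3L) abort("need at least 3 matched points")
  Da <- config_dist(A, jitter)
  Db <- config_dist(B, jitter)
  p_obs <- tp_core(Da, Db)

  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive) {
    if (N > 7L) abort("exhaustive enumeration limited to N <= 7")
    perms <- all_permutations(N)
  } else {
    if (!is.numeric(n_perm) || n_perm < 99) abort("n_perm must be >= 99")
    n_perm <- as.integer(n_perm)
    perms <- with_seed_local(seed, replicate(n_perm, sample.int(N), simplify = FALSE))
  }
  p_perm <- vapply(perms, function(p) tp_core(Da, Db[p, p]), numeric(1))
  denom <- mean(abs(p_perm))
  if (denom == 0) abort("degenerate permutation null: all permuted |P| are zero")
  tibble_result <- tibble(
    raw_p = p_obs,
    norm_pt = abs(p_obs) / denom,
    p_value = (1 + sum(abs(p_perm) <= abs(p_obs))) / (1 + length(perms)),
    n_points = N,
    n_perm = length(perms),
    seed = as.integer(seed),
    low_n = N <= 3L
  )
  structure(tibble_result, class = c("order_result", class(tibble_result)))
}

#' Monte-Carlo p-value for map order
#'
#' Convenience wrapper returning only the permutation p-value of
#' [normalized_pt()].
#'
#' @inheritParams normalized_pt
#' @return A single p-value in `(0, 1]`.
#' @export
order_pvalue <- function(space_a, space_b, n_perm = 999, seed = 1L,
                         jitter = FALSE) {
  normalized_pt(space_a, space_b, n_perm = n_perm, seed = seed,
                jitter = jitter)$p_value
}

# evaluate code under a given seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Topological order between neighbouring depth maps
#'
#' For each consecutive pair of depth levels, [normalized_pt()] between the
#' two 2D maps, matched by `animal_id` (columns absent at either depth are
#' dropped pairwise).
#'
#' @param stack A `map_stack` from [percentile_maps()].
#' @inheritParams normalized_pt
#' @return Tibble of order results with leading `comparison = "topology"`
#'   and `depth` (the deeper level) columns.
#' @export
topology_profile <- function(stack, n_perm = 999, seed = 1L, jitter = FALSE) {
  depths <- sort(unique(stack$points$depth))
  out <- purrr::map(seq_along(depths)[-1], function(i) {
    a <- dplyr::filter(stack$points, .data$depth == depths[i - 1])
    b <- dplyr::filter(stack$points, .data$depth == depths[i])
    shared <- intersect(a$animal_id, b$animal_id)
    if (length(shared) < 3L) {
      abort(paste0("fewer than 3 shared columns between depths ",
                   depths[i - 1], " and ", depths[i]))
    }
    res <- normalized_pt(
      as.matrix(a[match(shared, a$animal_id), c("u_um", "v_um")]),
      as.matrix(b[match(shared, b$animal_id), c("u_um", "v_um")]),
      n_perm = n_perm, seed = derive_seed(seed, i), jitter = jitter)
    mutate(res, comparison = "topology", depth = depths[i], .before = 1)
  })
  bind_rows(out)
}

#' Order between the pial and ventral end maps
#'
#' [normalized_pt()] between the shallowest and deepest maps of the stack,
#' the end-to-end summary of preserved topological order.
#'
#' @inheritParams topology_profile
#' @return One order-result row with `comparison = "end_to_end"`.
#' @export
end_to_end_order <- function(stack, n_perm = 999, seed = 1L, jitter = FALSE) {
  depths <- range(stack$points$depth)
  a <- dplyr::filter(stack$points, .data$depth == depths[1])
  b <- dplyr::filter(stack$points, .data$depth == depths[2])
  shared <- intersect(a$animal_id, b$animal_id)
  if (length(shared) < 3L) abort("fewer than 3 columns shared by the end maps")
  res <- normalized_pt(
    as.matrix(a[match(shared, a$animal_id), c("u_um", "v_um")]),
    as.matrix(b[match(shared, b$animal_id), c("u_um", "v_um")]),
    n_perm = n_perm, seed = derive_seed(seed, 0L), jitter = jitter)
  mutate(res, comparison = "end_to_end", depth = depths[2], .before = 1)
}

#' Topographical order between V1 injection sites and each depth map
#'
#' [normalized_pt()] between the 2D configuration of V1 injection sites and
#' the map at every depth level, matched by `animal_id`.
#'
#' @param injections Tibble with `animal_id`, `ap_mm`, `ml_mm`; every mapped
#'   column must have an injection record.
#' @inheritParams topology_profile
#' @return Tibble of order results with `comparison = "topography"` and
#'   `depth` columns (one row per depth level).
#' @export
topography_profile <- function(injections, stack, n_perm = 999, seed = 1L,
                               jitter = FALSE) {
  depths <- sort(unique(stack$points$depth))
  out <- purrr::map(seq_along(depths), function(i) {
    b <- dplyr::filter(stack$points, .data$depth == depths[i])
    missing <- setdiff(b$animal_id, injections$animal_id)
    if (length(missing)) {
      abort(paste0("no injection record for mapped column(s): ",
                   paste(missing, collapse = ", ")))
    }
    inj <- injections[match(b$animal_id, injections$animal_id), ]
    res <- normalized_pt(
      as.matrix(inj[c("ap_mm", "ml_mm")]),
      as.matrix(b[c("u_um", "v_um")]),
      n_perm = n_perm, seed = derive_seed(seed, 100L + i), jitter = jitter)
    mutate(res, comparison = "topography", depth = depths[i], .before = 1)
  })
  bind_rows(out)
}

# accepts matrix or tibble configurations
config_matrix <- function(x) {
  if (is.matrix(x)) {
    X <- x
  } else if (is.data.frame(x)) {
    if (all(c("u_um", "v_um") %in% names(x))) {
      X <- as.matrix(x[c("u_um", "v_um")])
    } else if (all(c("ap_mm", "ml_mm") %in% names(x))) {
      X <- as.matrix(x[c("ap_mm", "ml_mm")])
    } else if (all(c("x_um", "y_um", "z_um") %in% names(x))) {
      X <- as.matrix(x[c("x_um", "y_um", "z_um")])
    } else {
      abort("cannot interpret configuration columns")
    }
  } else {
    abort("configuration must be a matrix or data frame")
  }
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) abort("non-finite coordinates in configuration")
  unname(X)
}
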