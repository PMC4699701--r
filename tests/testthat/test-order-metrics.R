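test_that("the raw product vanishes for identical neighbourhood structure", {
  set.seed(1)
  A <- matrix(rnorm(20), 10, 2)
  expect_identical(topographic_product(A, A), 0)
  # uniform scaling preserves ranks and ratios
  expect_identical(topographic_product(A, 3 * A), 0)
  # rotation + translation of one space preserve it too
  B <- A %*% t(rot2_ref(1.1)) + 40
  expect_equal(topographic_product(A, B), 0, tolerance = 1e-12)
})

test_that("the raw product matches the brute-force double sum", {
  # five collinear points with two labels swapped: small enough to hand-check
  A <- cbind(1:5, 0)
  B <- A[c(1, 3, 2, 4, 5), ]
  expect_equal(topographic_product(A, B), bf_topographic_product(A, B),
               tolerance = 1e-12)
  # random configurations for all sizes up to 7, mixed dimensions
  set.seed(42)
  for (N in 3:7) {
    for (rep in 1:10) {
      A <- matrix(rnorm(2 * N), N, 2)
      B <- matrix(rnorm(3 * N), N, 3)
      expect_equal(topographic_product(A, B), bf_topographic_product(A, B),
                   tolerance = 1e-12)
    }
  }
})

test_that("|P| is symmetric under exchanging the two spaces", {
  set.seed(7)
  for (rep in 1:20) {
    A <- matrix(rnorm(16), 8, 2)
    B <- matrix(rnorm(16), 8, 2)
    expect_equal(abs(topographic_product(A, B)),
                 abs(topographic_product(B, A)), tolerance = 1e-12)
  }
})

test_that("coincident points are rejected unless jitter is requested", {
  A <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0))
  B <- matrix(rnorm(8), 4, 2)
  expect_error(topographic_product(A, B), "coincident")
  expect_true(is.finite(topographic_product(A, B, jitter = TRUE)))
})

test_that("normalized P_t is 0 for identical maps and ~1 for random relabellings", {
  set.seed(3)
  A <- matrix(rnorm(24, sd = 50), 12, 2)
  res <- normalized_pt(A, A, n_perm = 99, seed = 7)
  expect_identical(res$norm_pt, 0)
  res2 <- normalized_pt(A, A, n_perm = 99, seed = 8)
  expect_identical(res2$norm_pt, 0)

  vals <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    B <- A[sample(12), ]
    normalized_pt(A, B, n_perm = 99, seed = i)$norm_pt
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 0.15)
})

test_that("normalized P_t is invariant to similarity transforms of either space", {
  set.seed(5)
  A <- matrix(rnorm(20, sd = 30), 10, 2)
  B <- A[sample(10), ] + matrix(rnorm(20, sd = 10), 10, 2)
  base <- normalized_pt(A, B, n_perm = 199, seed = 3)
  tA <- 2.5 * A %*% t(rot2_ref(0.7)) + 100
  tB <- 0.3 * B %*% t(rot2_ref(-2.1)) - 40
  expect_equal(normalized_pt(tA, B, n_perm = 199, seed = 3)$norm_pt,
               base$norm_pt, tolerance = 1e-10)
  expect_equal(normalized_pt(A, tB, n_perm = 199, seed = 3)$norm_pt,
               base$norm_pt, tolerance = 1e-10)
})

test_that("exhaustive enumeration reproduces a hand-rolled normalization", {
  set.seed(9)
  A <- matrix(rnorm(12, sd = 10), 6, 2)
  B <- A
  B[c(2, 5), ] <- B[c(5, 2), ]   # one swapped pair
  # a whisper of noise so B is not an exact relabelling: exact relabellings
  # tie |P| across whole permutation classes and make the p-value depend on
  # floating-point tie-breaking
  B <- B + matrix(rnorm(12, sd = 1e-3), 6, 2)
  res <- normalized_pt(A, B, n_perm = "exhaustive")
  p_obs <- bf_topographic_product(A, B)
  perms <- bf_permutations(6L)
  expect_length(perms, 720L)
  p_perm <- vapply(perms, function(p) bf_topographic_product(A, B[p, ]),
                   numeric(1))
  expect_equal(res$raw_p, p_obs, tolerance = 1e-8)
  expect_equal(res$norm_pt, abs(p_obs) / mean(abs(p_perm)), tolerance = 1e-8)
  expect_equal(res$p_value,
               (1 + sum(abs(p_perm) <= abs(p_obs))) / (1 + 720), tolerance = 1e-12)
})

test_that("Monte-Carlo normalization converges to the exhaustive value", {
  set.seed(13)
  A <- matrix(rnorm(12, sd = 10), 6, 2)
  B <- A[c(2, 1, 3, 4, 6, 5), ] + matrix(rnorm(12, sd = 1e-2), 6, 2)
  exact <- normalized_pt(A, B, n_perm = "exhaustive")
  mc <- normalized_pt(A, B, n_perm = 4999, seed = 17)
  expect_lt(abs(mc$norm_pt - exact$norm_pt) / exact$norm_pt, 0.05)
  expect_lt(abs(mc$p_value - exact$p_value), 0.02)
})

test_that("p-values behave at the boundaries", {
  set.seed(19)
  A <- matrix(rnorm(20, sd = 30), 10, 2)
  # perfectly ordered map: no permutation can tie |P| = 0
  res <- normalized_pt(A, 1.7 * A + 5, n_perm = 99, seed = 23)
  expect_equal(res$p_value, 0.01)
  # observed equal to the worst enumerable arrangement has p = 1
  A5 <- cbind(c(0, 1, 2, 3, 10), 0)
  perms <- bf_permutations(5L)
  pv <- vapply(perms, function(p) abs(bf_topographic_product(A5, A5[p, ])),
               numeric(1))
  worst <- perms[[which.max(pv)]]
  res2 <- normalized_pt(A5, A5[worst, ], n_perm = "exhaustive")
  expect_equal(res2$p_value, 1)
})

test_that("profile wrappers drop unmatched columns and flag low n", {
  mesh <- simulate_mesh()
  sim <- simulate_columns(mesh, n_columns = 9L, sigma = 5, seed = 71)
  rec <- reconstruct_columns(sim$cells, mesh)
  stack <- percentile_maps(rec$paths)

  topo <- topology_profile(stack, n_perm = 99, seed = 3)
  expect_equal(nrow(topo), 20L)
  expect_true(all(topo$comparison == "topology"))
  expect_true(all(topo$norm_pt >= 0))

  ee <- end_to_end_order(stack, n_perm = 99, seed = 4)
  expect_equal(ee$n_points, 9L)
  expect_false(ee$low_n)

  tg <- topography_profile(sim$injections, stack, n_perm = 99, seed = 5)
  expect_equal(nrow(tg), 21L)
  expect_error(
    topography_profile(dplyr::slice(sim$injections, -1), stack,
                       n_perm = 99, seed = 5),
    "no injection record.*sim01")

  # translated copies of one map at all depths are perfectly ordered
  pts <- jittered_grid(9, seed = 2)
  fake <- stack
  fake$points <- dplyr::bind_rows(lapply(seq(0, 1, 0.05), function(d) {
    as_map(pts + d * 100, ids = sprintf("sim%02d", 1:9), depth = d)
  }))
  topo2 <- topology_profile(fake, n_perm = 99, seed = 6)
  expect_true(all(topo2$norm_pt == 0))
})

test_that("results are deterministic in the seed", {
  set.seed(29)
  A <- matrix(rnorm(24), 12, 2)
  B <- matrix(rnorm(24), 12, 2)
  r1 <- normalized_pt(A, B, n_perm = 199, seed = 31)
  r2 <- normalized_pt(A, B, n_perm = 199, seed = 31)
  expect_identical(r1, r2)
  expect_identical(order_pvalue(A, B, n_perm = 199, seed = 31), r1$p_value)
})
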