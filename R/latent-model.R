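#' Shape-preserving standardization of a depth profile
#'
#' Subtracts the mean and divides by the population (1/n) standard
#' deviation, so that only the shape of the profile — not its scale or
#' offset — enters downstream latent-variable analysis.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Numeric vector with mean 0 and population variance 1.
#' @export
standardize_profile <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort("need at least 2 values to standardize")
  if (!all(is.finite(values))) abort("profile contains non-finite values")
  s <- sqrt(mean((values - mean(values))^2))
  if (s == 0) abort("constant profile cannot be standardized")
  (values - mean(values)) / s
}

#' Assemble the metric-by-depth profile matrix
#'
#' Stacks, per group, the four depth profiles (cell counts, radial spread,
#' topological order, topographical order) into one matrix sharing a common
#' depth axis of 21 levels (0 to 1 in steps of 0.05). Count and spread
#' profiles, defined on 20 bins, are resampled to the 21 levels by linear
#' interpolation of their bin centres (constant extension at the ends);
#' topology, defined on the 20 between-level comparisons, is interpolated the
#' same way. Every row is then standardized by [standardize_profile()].
#'
#' @param counts,spreads Named lists (by group) of [count_profile()] /
#'   [spread_profile()] tibbles.
#' @param topology Named list of [topology_profile()] tibbles.
#' @param topography Named list of [topography_profile()] tibbles.
#' @return An object of class `profile_matrix`: a numeric matrix (rows =
#'   metric x group, columns = 21 depth levels) with attribute `row_info`, a
#'   tibble of `metric` and `group` per row.
#' @export
assemble_profiles <- function(counts, spreads, topology, topography) {
  groups <- names(counts)
  if (is.null(groups)) abort("profile lists must be named by group")
  for (nm in c("spreads", "topology", "topography")) {
    lst <- get(nm)
    gap <- setdiff(groups, names(lst))
    if (length(gap)) {
      abort(paste0("missing ", nm, " profile for group(s): ",
                   paste(gap, collapse = ", ")))
    }
  }
  levels <- seq(0, 1, by = 0.05)
  rows <- list()
  info <- list()
  for (g in groups) {
    cnt <- counts[[g]]
    spr <- spreads[[g]]
    top <- topology[[g]]
    tpg <- topography[[g]]
    row_set <- list(
      count = approx((cnt$bin_lo + cnt$bin_hi) / 2, cnt$mean, xout = levels, rule = 2)$y,
      spread = approx((spr$bin_lo + spr$bin_hi) / 2, spr$mean, xout = levels, rule = 2)$y,
      topology = approx(top$depth, top$norm_pt, xout = levels, rule = 2)$y,
      topography = approx(tpg$depth, tpg$norm_pt, xout = levels, rule = 2)$y
    )
    for (m in names(row_set)) {
      rows[[length(rows) + 1L]] <- standardize_profile(row_set[[m]])
      info[[length(info) + 1L]] <- tibble(metric = m, group = g)
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- format(levels, trim = TRUE)
  ri <- bind_rows(info)
  rownames(mat) <- paste(ri$metric, ri$group, sep = "_")
  structure(mat, row_info = ri, class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x), " profiles x ", ncol(x), " depth levels\n",
      sep = "")
  print(attr(x, "row_info"))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.profile_matrix <- function(x, ...) {
  ri <- attr(x, "row_info")
  m <- x
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  out <- as_tibble(as.data.frame(m))
  dplyr::bind_cols(ri, out)
}

# NIPALS PLS2 on column-centered X/Y; X = Y gives a principal-component-like
# autoassociative decomposition. Returns weights/loadings for `ncomp`
# components plus per-component explained Y variance.
pls_nipals <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500L) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  x_mean <- attr(Xc, "scaled:center")
  y_mean <- attr(Yc, "scaled:center")
  ss_y <- sum(Yc^2)
  n <- nrow(Xc)
  W <- matrix(0, ncol(X), ncomp)
  P <- matrix(0, ncol(X), ncomp)
  Q <- matrix(0, ncol(Y), ncomp)
  TT <- matrix(0, n, ncomp)
  expl <- numeric(ncomp)
  Xd <- Xc
  Yd <- Yc
  ss_x0 <- sum(Xc^2)
  ncomp_eff <- 0L
  for (a in seq_len(ncomp)) {
    # stop once the deflated matrices carry no variance (exact low rank)
    if (sum(Xd^2) < 1e-12 * max(ss_x0, 1) ||
        sum(Yd^2) < 1e-12 * max(ss_y, 1)) break
    u <- Yd[, which.max(colSums(Yd^2))]
    w <- crossprod(Xd, u)
    w <- w / sqrt(sum(w^2))
    repeat_count <- 0L
    repeat {
      t_sc <- Xd %*% w
      q <- crossprod(Yd, t_sc) / sum(t_sc^2)
      u_new <- Yd %*% q / sum(q^2)
      w_new <- crossprod(Xd, u_new)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sum((w_new - w)^2)
      w <- w_new
      u <- u_new
      repeat_count <- repeat_count + 1L
      if (delta < tol || repeat_count >= max_iter) break
    }
    t_sc <- Xd %*% w
    p <- crossprod(Xd, t_sc) / sum(t_sc^2)
    q <- crossprod(Yd, t_sc) / sum(t_sc^2)
    Xd <- Xd - t_sc %*% t(p)
    Yd <- Yd - t_sc %*% t(q)
    W[, a] <- w
    P[, a] <- p
    Q[, a] <- q
    TT[, a] <- t_sc
    expl[a] <- 100 * (sum(t_sc^2) * sum(q^2)) / ss_y
    ncomp_eff <- a
  }
  list(W = W, P = P, Q = Q, scores = TT, x_mean = x_mean, y_mean = y_mean,
       pct_var_y = expl, ncomp_eff = ncomp_eff)
}

# prediction coefficient matrix for the first `a` components
pls_coef <- function(fit, a) {
  a <- min(a, fit$ncomp_eff)
  if (a == 0L) return(matrix(0, nrow(fit$W), nrow(fit$Q)))
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  Q <- fit$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

pls_predict <- function(fit, a, Xnew) {
  B <- pls_coef(fit, a)
  sweep(sweep(Xnew, 2, fit$x_mean) %*% B, 2, fit$y_mean, "+")
}

#' Cross-validated PLS scan of the number of latent depth factors
#'
#' Fits an autoassociative partial-least-squares decomposition of the
#' profile matrix (by default the matrix predicts itself, `X = Y`; rows are
#' observations, depth levels variables) for 1 to `max_latents` components,
#' reporting the cumulative percentage of variance explained and the
#' cross-validated mean squared reconstruction error of held-out rows under
#' leave-one-out (default) or k-fold partitions.
#'
#' @param profiles A `profile_matrix` (or plain numeric matrix).
#' @param max_latents Largest latent count scanned; must be smaller than
#'   both dimensions of the matrix.
#' @param folds `"loo"` for leave-one-out or an integer k >= 2 for k-fold.
#' @param seed Seed controlling the k-fold assignment (leave-one-out is
#'   deterministic).
#' @param orientation `"rows_obs"` (default; rows = observations) or
#'   `"cols_obs"` to transpose the matrix first.
#' @return An object of class `latent_scan`: tibble with `n_latents`,
#'   `pct_var_explained` (cumulative), `cv_mse`, plus attributes
#'   `fold_scheme` and `seed`.
#' @export
pls_latent_scan <- function(profiles, max_latents = NULL, folds = "loo",
                            seed = 1L, orientation = c("rows_obs", "cols_obs")) {
  orientation <- match.arg(orientation)
  M <- unclass(profiles)
  attr(M, "row_info") <- NULL
  if (orientation == "cols_obs") M <- t(M)
  n <- nrow(M)
  p <- ncol(M)
  if (is.null(max_latents)) max_latents <- min(n, p) - 1L
  if (max_latents >= min(n, p)) {
    abort("max_latents must be smaller than both matrix dimensions")
  }
  if (max_latents < 1L) abort("max_latents must be at least 1")

  fit <- pls_nipals(M, M, max_latents)
  pct <- cumsum(fit$pct_var_y)

  if (identical(folds, "loo")) {
    fold_id <- seq_len(n)
    scheme <- "leave-one-out"
  } else {
    k <- as.integer(folds)
    if (is.na(k) || k < 2L) abort("folds must be \"loo\" or an integer >= 2")
    if (k > n) abort("more folds than rows")
    fold_id <- with_seed_local(derive_seed(seed, 7L),
                               sample(rep_len(seq_len(k), n)))
    scheme <- paste0(k, "-fold")
  }
  # Held-out rows are scored from one interleaved half of the depth levels
  # and reconstructed on the other half (Wold-style column-split CV).
  # Scoring a held-out row on all levels and reconstructing the same levels
  # would make the error non-increasing in the latent count by construction,
  # so no minimum could mark the rank.
  half_a <- seq(1L, p, by = 2L)
  half_b <- seq(2L, p, by = 2L)
  n_folds <- length(unique(fold_id))
  sq_err <- matrix(0, n_folds, max_latents)
  n_held <- numeric(n_folds)
  for (f in sort(unique(fold_id))) {
    hold <- which(fold_id == f)
    train <- M[-hold, , drop = FALSE]
    a_cap <- min(max_latents, nrow(train) - 1L, p)
    fit_f <- pls_nipals(train, train, a_cap)
    H <- sweep(M[hold, , drop = FALSE], 2, fit_f$x_mean)
    for (a in seq_len(max_latents)) {
      a_use <- min(a, a_cap, fit_f$ncomp_eff)
      P_a <- fit_f$P[, seq_len(a_use), drop = FALSE]
      err <- 0
      for (sp in list(list(obs = half_a, prd = half_b),
                      list(obs = half_b, prd = half_a))) {
        sc <- t(qr.coef(qr(P_a[sp$obs, , drop = FALSE]),
                        t(H[, sp$obs, drop = FALSE])))
        sc[is.na(sc)] <- 0
        err <- err + sum((sc %*% t(P_a[sp$prd, , drop = FALSE]) -
                            H[, sp$prd, drop = FALSE])^2)
      }
      sq_err[f, a] <- err
    }
    n_held[f] <- length(hold) * p
  }
  cv_mse <- colSums(sq_err) / sum(n_held)

  out <- tibble(n_latents = seq_len(max_latents),
                pct_var_explained = pct,
                cv_mse = cv_mse)
  structure(out, fold_scheme = scheme, seed = as.integer(seed),
            orientation = orientation,
            class = c("latent_scan", class(out)))
}

#' @rdname pls_latent_scan
#' @param x A `latent_scan`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.latent_scan <- function(x, ...) {
  as_tibble(unclass(x)[c("n_latents", "pct_var_explained", "cv_mse")])
}

#' @rdname pls_latent_scan
#' @exportS3Method generics::glance
glance.latent_scan <- function(x, ...) {
  tibble(
    max_latents = max(x$n_latents),
    best_cv_latents = x$n_latents[which.min(x$cv_mse)],
    min_cv_mse = min(x$cv_mse),
    pct_var_at_best = x$pct_var_explained[which.min(x$cv_mse)],
    fold_scheme = attr(x, "fold_scheme")
  )
}
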