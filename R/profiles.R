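#' Cell-count depth profile across columns
#'
#' The unit column is divided into 20 half-open bins of width 0.05 (the last
#' bin closed, so t = 1 falls in bin 20). For each column the non-clipped
#' cells are counted per bin; the profile is the across-column mean with its
#' standard error.
#'
#' @param unit_columns Tibble from [unitize()] (may pool several columns;
#'   columns are identified by `animal_id`).
#' @param group Optional group label attached to the output.
#' @return A tibble with columns `bin`, `bin_lo`, `bin_hi`, `mean`, `sem`,
#'   `n_columns`, `kind = "count"`, `group`.
#' @export
count_profile <- function(unit_columns, group = NA_character_) {
  uc <- dplyr::filter(unit_columns, !.data$clipped)
  if (nrow(uc) == 0L) abort("no in-range cells to profile")
  uc$bin <- depth_bin(uc$t)
  grid <- tidyr::expand_grid(animal_id = unique(unit_columns$animal_id),
                             bin = 1:20)
  per_col <- uc %>%
    dplyr::count(.data$animal_id, .data$bin) %>%
    dplyr::right_join(grid, by = c("animal_id", "bin")) %>%
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  per_col %>%
    group_by(.data$bin) %>%
    summarise(mean = mean(.data$n), sem = sem(.data$n),
              n_columns = dplyr::n(), .groups = "drop") %>%
    mutate(bin_lo = (.data$bin - 1) * 0.05, bin_hi = .data$bin * 0.05,
           kind = "count", group = group) %>%
    select("bin", "bin_lo", "bin_hi", "mean", "sem", "n_columns", "kind", "group")
}

#' Radial-spread depth profile
#'
#' Per-bin mean perpendicular distance of cells from the column trajectory,
#' pooled across columns, scaled by `volume_scale` to correct for nucleus
#' size differences between groups (`volume_scale = (V_ref / V_group)^(1/3)`,
#' the linear scale factor that maps the group nucleus onto the reference
#' volume).
#'
#' @inheritParams count_profile
#' @param volume_scale Positive linear scale factor (default 1).
#' @return A tibble like [count_profile()] with `kind = "spread"`; `mean` and
#'   `sem` are micrometres.
#' @export
spread_profile <- function(unit_columns, volume_scale = 1, group = NA_character_) {
  if (!is.finite(volume_scale) || volume_scale <= 0) {
    abort("volume_scale must be a positive number")
  }
  uc <- dplyr::filter(unit_columns, !.data$clipped)
  if (nrow(uc) == 0L) abort("no in-range cells to profile")
  uc$bin <- depth_bin(uc$t)
  uc %>%
    group_by(.data$bin) %>%
    summarise(mean = mean(.data$r_um) * volume_scale,
              sem = sem(.data$r_um) * volume_scale,
              n_columns = dplyr::n_distinct(.data$animal_id),
              .groups = "drop") %>%
    mutate(bin_lo = (.data$bin - 1) * 0.05, bin_hi = .data$bin * 0.05,
           kind = "spread", group = group) %>%
    select("bin", "bin_lo", "bin_hi", "mean", "sem", "n_columns", "kind", "group")
}

# bin index 1..20 for t in [0,1]; t = 1 assigned to the last bin
depth_bin <- function(t) {
  pmin(floor(t / 0.05), 19) + 1L
}

#' Maximum-likelihood Rayleigh fit to radial distances
#'
#' The Rayleigh scale is the closed-form MLE
#' \eqn{\hat\sigma = \sqrt{\sum r_i^2 / (2n)}}; equivalently
#' \eqn{\hat\sigma^2} is half the mean squared radius.
#'
#' @param radii Non-negative distances (micrometres); at least 2, not all 0.
#' @return An object of class `rayleigh_fit` with elements `sigma`, `n`,
#'   `loglik`.
#' @export
fit_rayleigh <- function(radii) {
  radii <- as.numeric(radii)
  if (length(radii) < 2L) abort("need at least 2 radii")
  if (any(!is.finite(radii)) || any(radii < 0)) abort("radii must be finite and non-negative")
  if (all(radii == 0)) abort("degenerate fit: all radii are zero")
  n <- length(radii)
  sigma <- sqrt(sum(radii^2) / (2 * n))
  pos <- radii[radii > 0]
  loglik <- sum(log(pos)) - 2 * n * log(sigma) - sum(radii^2) / (2 * sigma^2)
  if (any(radii == 0)) loglik <- -Inf  # density vanishes at r = 0
  structure(list(sigma = sigma, n = n, loglik = loglik), class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat("<rayleigh_fit> sigma = ", format(x$sigma, digits = 6), " um, n = ",
      x$n, ", logLik = ", format(x$loglik, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_rayleigh
#' @param x A `rayleigh_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rayleigh_fit <- function(x, ...) {
  tibble(term = "sigma", estimate = x$sigma,
         # asymptotic sd of the MLE: sigma / sqrt(4n)
         std.error = x$sigma / sqrt(4 * x$n))
}

#' @rdname fit_rayleigh
#' @exportS3Method generics::glance
glance.rayleigh_fit <- function(x, ...) {
  tibble(sigma = x$sigma, nobs = x$n, logLik = x$loglik,
         AIC = 2 - 2 * x$loglik)
}
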