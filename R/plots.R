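#' Plot a depth profile
#'
#' Mean with SEM ribbon against depth-bin centre, one panel per profile
#' kind when the tibble holds several.
#'
#' @param profile Output of [count_profile()] / [spread_profile()] (rows may
#'   be concatenated).
#' @return A ggplot.
#' @export
plot_depth_profile <- function(profile) {
  dat <- mutate(profile, mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot2::ggplot(dat, ggplot2::aes(.data$mid, .data$mean,
                                    colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "unit-column depth (0 = pial, 1 = ventral)",
                  y = "mean ± SEM") +
    ggplot2::theme_minimal()
}

#' Plot the 2D maps of a stack
#'
#' @param stack A `map_stack`.
#' @param depths Subset of depth levels to show (default all).
#' @return A ggplot, one facet per depth.
#' @export
plot_map_stack <- function(stack, depths = NULL) {
  pts <- stack$points
  if (!is.null(depths)) pts <- dplyr::filter(pts, .data$depth %in% depths)
  ggplot2::ggplot(pts, ggplot2::aes(.data$u_um, .data$v_um,
                                    colour = .data$animal_id)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~depth) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "u (µm)", y = "v (µm)") +
    ggplot2::theme_minimal()
}

#' Plot cumulative rotation and expansion against depth
#'
#' @param trajectory Output of [cumulative_trajectory()].
#' @return A ggplot with two panels.
#' @export
plot_trajectory <- function(trajectory) {
  long <- tidyr::pivot_longer(trajectory, c("cum_rotation_rad", "cum_expansion"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$depth, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "unit-column depth") +
    ggplot2::theme_minimal()
}

#' Plot normalized topographic-product profiles
#'
#' Normalized order metric against depth with significance marks
#' (`p < 0.05`).
#'
#' @param order_tbl Rows from [topology_profile()] /
#'   [topography_profile()] / [end_to_end_order()].
#' @return A ggplot.
#' @export
plot_order_profile <- function(order_tbl) {
  ggplot2::ggplot(order_tbl, ggplot2::aes(.data$depth, .data$norm_pt,
                                          colour = .data$comparison)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$p_value < 0.05), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 8, `FALSE` = 16),
                                name = "p < 0.05") +
    ggplot2::labs(x = "unit-column depth",
                  y = "normalized topographic product") +
    ggplot2::theme_minimal()
}

#' @rdname pls_latent_scan
#' @param object A `latent_scan`.
#' @exportS3Method ggplot2::autoplot
autoplot.latent_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("pct_var_explained", "cv_mse"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$n_latents, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "number of latents") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
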