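# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a two-group comparison
#'
#' @param x A `coro_test` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble: method, statistic, p_value, n_1, n_2, summary_1,
#'   summary_2, degenerate.
#' @export
tidy.coro_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_1 = x$n_a, n_2 = x$n_b,
         summary_1 = x$summary_a$summary, summary_2 = x$summary_b$summary,
         degenerate = x$degenerate)
}

#' @rdname tidy.coro_test
#' @export
glance.coro_test <- function(x, ...) {
  tibble(method = x$method, p_value = x$p_value,
         n = x$n_a + x$n_b)
}

#' Tidy a contrast-matrix result
#'
#' @param x A `coro_contrasts` tibble from [run_contrast_matrix()].
#' @param ... Unused.
#' @return A plain tibble of the per-contrast results.
#' @export
tidy.coro_contrasts <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "coro_contrasts")
  as_tibble(out)
}

#' @rdname tidy.coro_contrasts
#' @export
glance.coro_contrasts <- function(x, ...) {
  tibble(n_contrasts = nrow(x),
         n_families = dplyr::n_distinct(x$family),
         n_significant = sum(x$significant, na.rm = TRUE))
}

#' Tidy / summarise a study
#'
#' @param x A `coro_study` from [run_study()].
#' @param ... Unused.
#' @return `tidy()`: the per-contrast results tibble. `glance()`: one-row
#'   study summary.
#' @export
tidy.coro_study <- function(x, ...) tidy(x$results)

#' @rdname tidy.coro_study
#' @export
glance.coro_study <- function(x, ...) {
  bind_cols(tibble(n_cases = dplyr::n_distinct(x$table$case),
                   n_segments = dplyr::n_distinct(x$table$segment)),
            glance(x$results))
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Correlation heatmap of a contrast matrix
#'
#' Tile map of the Spearman correlation coefficients per segment, with
#' asterisks marking Holm-adjusted significance (* < 0.05, ** < 0.01,
#' *** < 0.001).
#'
#' @param object A `coro_contrasts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 geom_tile geom_text scale_fill_gradient2 theme_minimal
#'   element_text theme
#' @export
autoplot.coro_contrasts <- function(object, ...) {
  dd <- filter(as_tibble(object), .data$type == "correlation") |>
    mutate(stars = significance_stars(.data$p_adjusted))
  if (!nrow(dd)) abort("no correlation contrasts to plot.")
  ggplot(dd, aes(.data$contrast, .data$segment, fill = .data$estimate)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f%s", .data$estimate, .data$stars)),
              size = 3) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1), name = "Spearman ρ") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.coro_contrasts
#' @export
autoplot.coro_study <- function(object, ...) autoplot(object$results, ...)

#' Cross-sectional map of cycle-averaged LNH
#'
#' Plots the cycle-averaged local normalized helicity of the cells nearest
#' to an axial position, coloured by handedness (red right-handed, blue
#' left-handed).
#'
#' @param lnh_avg Tibble from [lnh_cycle_average()].
#' @param z_slice Axial position (m); defaults to the mid-plane.
#' @param tol Slab half-thickness (m); defaults to the median axial spacing.
#' @return A ggplot object.
#' @importFrom ggplot2 geom_point scale_colour_gradient2 coord_equal
#' @export
plot_lnh_slice <- function(lnh_avg, z_slice = NULL, tol = NULL) {
  z_slice <- z_slice %||% stats::median(lnh_avg$z)
  tol <- tol %||% (diff(range(lnh_avg$z)) /
                     max(dplyr::n_distinct(lnh_avg$z), 2L))
  dd <- filter(lnh_avg, abs(.data$z - z_slice) <= tol)
  ggplot(dd, aes(.data$x, .data$y, colour = .data$lnh_mean)) +
    geom_point(size = 2) +
    scale_colour_gradient2(low = "#2166ac", mid = "grey90", high = "#b2182b",
                           limits = c(-1, 1), name = "LNH") +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)")
}
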