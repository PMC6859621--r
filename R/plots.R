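# ggplot2 visualisations for the main result types.

mat_to_df <- function(img) {
  tibble(
    x = rep(seq_len(ncol(img)), each = nrow(img)),
    y = rep(seq_len(nrow(img)), ncol(img)),
    intensity = as.vector(img)
  )
}

circle_df <- function(center, radius, n = 180) {
  th <- seq(0, 2 * pi, length.out = n)
  tibble(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

#' Plot a fundus pair with the measurement annuli
#'
#' Renders the 532 nm channel with the ONH outline, the oximetry annulus
#' (1-2 ONH radii) and the tortuosity annulus (1.5-5 radii).
#'
#' @param object A `fundus_pair`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fundus_pair <- function(object, ...) {
  df <- mat_to_df(object$image_532)
  rings <- list_rbind(list(
    mutate(circle_df(object$onh_center, object$onh_radius), ring = "ONH"),
    mutate(circle_df(object$onh_center, 2 * object$onh_radius),
           ring = "oximetry"),
    mutate(circle_df(object$onh_center, 1.5 * object$onh_radius),
           ring = "tortuosity inner"),
    mutate(circle_df(object$onh_center, 5 * object$onh_radius),
           ring = "tortuosity outer")
  ))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(group = .data$ring,
                                    color = .data$ring),
                       linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(color = NULL, title = "532 nm fundus image") +
    ggplot2::theme_void()
}

#' Pseudo-color SO2 overlay
#'
#' Shows per-segment SO2 values at their segment centroids over the 532 nm
#' image, mimicking a color-coded oximetry map.
#'
#' @param pair A `fundus_pair`.
#' @param oximetry Result of [measure_oximetry()].
#' @return A ggplot.
#' @export
plot_so2_overlay <- function(pair, oximetry) {
  df <- mat_to_df(pair$image_532)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_point(data = oximetry,
                        ggplot2::aes(color = .data$so2), size = 2.5) +
    ggplot2::scale_color_viridis_c(option = "plasma", limits = c(0, 100)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(color = expression(SO[2] ~ "(%)")) +
    ggplot2::theme_void()
}

#' Scatter of oxygen content against a tortuosity metric
#'
#' One point per cohort row (subject x eye x vessel type), colored by
#' vessel type, with a linear trend per the pooled data.
#'
#' @param table Cohort table from [aggregate_cohort()].
#' @param metric `"vii"` or `"vti"`.
#' @return A ggplot.
#' @export
plot_o2_tortuosity <- function(table, metric = c("vii", "vti")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(table,
                  ggplot2::aes(.data[[metric]], .data$o2_content)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$vessel_type),
                        alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "grey30", linewidth = 0.6) +
    ggplot2::scale_color_manual(values = c(artery = "#c23b22",
                                           vein = "#1f6fb2")) +
    ggplot2::labs(x = toupper(metric),
                  y = expression(O[2] ~ "content (mL" * O[2] * "/dL)"),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a mixed-model result
#'
#' @param object An `lmm_result`.
#' @param ... Unused.
#' @return A ggplot showing fixed-effect estimates with 95% intervals.
#' @export
autoplot.lmm_result <- function(object, ...) {
  td <- tidy(object) |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = sprintf("Effect on %s", object$response), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
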