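#' Forest plot of per-variant and combined causal estimates
#'
#' @param data An `mr_set` / data frame of instruments, or a table already
#'   produced by [forest_data()].
#' @param conf_level Interval level when `data` is an instrument set.
#' @return A ggplot object.
#' @export
plot_forest <- function(data, conf_level = 0.95) {
  tab <- if (all(c("label", "conf.low", "conf.high") %in% names(data))) {
    tibble::as_tibble(data)
  } else {
    forest_data(data, conf_level = conf_level)
  }
  tab$label <- factor(tab$label, levels = rev(tab$label))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta, y = .data$label,
                                    colour = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_colour_manual(
      values = c(single = "black", combined = "red"), guide = "none") +
    ggplot2::labs(x = "causal effect estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of instrument effects with fitted MR regression lines
#'
#' @param data An `mr_set` / data frame of instruments.
#' @return A ggplot object: one point (with +/- 1 SE error bars in both
#'   directions) per instrument after orientation, with the IVW
#'   (through-origin) and MR-Egger lines.
#' @export
plot_scatter <- function(data) {
  pts <- scatter_data(data)
  lines <- attr(pts, "lines")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$beta_exposure,
                                    y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome),
      width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - .data$se_exposure,
      xmax = .data$beta_exposure + .data$se_exposure),
      height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
    ggplot2::labs(x = "effect on exposure (ln scale)",
                  y = "effect on outcome", colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot a power curve
#'
#' @param data A table from [power_curve()] (columns `effect`, `power`).
#' @param target_power Optional horizontal reference line.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(data, target_power = 0.8) {
  p <- ggplot2::ggplot(tibble::as_tibble(data),
                       ggplot2::aes(x = .data$effect, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "causal effect (odds ratio or beta per 1 SD)",
                  y = "power") +
    ggplot2::theme_minimal()
  if (!is.null(target_power)) {
    p <- p + ggplot2::geom_hline(yintercept = target_power,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' @export
autoplot.mr_set <- function(object, type = c("scatter", "forest"), ...) {
  type <- match.arg(type)
  if (type == "scatter") plot_scatter(object) else plot_forest(object)
}
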