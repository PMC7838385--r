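# ggplot2 displays for the main result types

#' @rdname fmen_plots
#' @title Plots for fmenr result objects
#' @description `autoplot` methods and `plot_*` helpers: threshold-scan
#'   diagnostics, spacing distributions against the Poisson and Wigner
#'   forms, the Zi-Pi role plane, the log-log degree distribution and the
#'   module-environment correlation heatmap.
#' @param object,x an fmenr result object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fmen_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("p_poisson", "p_wigner"),
                            names_to = "fit", values_to = "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$st, y = .data$p, colour = .data$fit)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "selected_st"), linetype = 2) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 3) +
    ggplot2::labs(x = "similarity threshold (st)", y = "goodness-of-fit p",
                  colour = NULL,
                  title = "RMT threshold scan",
                  subtitle = "dashed line: selected threshold") +
    ggplot2::theme_minimal()
}

#' @rdname fmen_plots
#' @export
autoplot.fmen_nnsd <- function(object, ...) {
  s <- seq(0.01, max(3, max(object$spacings)), length.out = 200)
  curves <- dplyr::bind_rows(
    tibble::tibble(s = s, d = exp(-s), law = "Poisson"),
    tibble::tibble(s = s, d = (pi * s / 2) * exp(-pi * s^2 / 4), law = "Wigner-Dyson")
  )
  ggplot2::ggplot(tibble::tibble(spacing = object$spacings),
                  ggplot2::aes(x = .data$spacing)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$s, y = .data$d, colour = .data$law)) +
    ggplot2::labs(x = "unfolded spacing s", y = "density", colour = NULL,
                  title = paste0("NNSD at st = ", object$st,
                                 " (verdict: ", object$verdict, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname fmen_plots
#' @param roles tibble from [node_roles()].
#' @export
plot_zipi <- function(roles) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$pi, y = .data$zi,
                                      colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 2.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.62, linetype = 2) +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module connectivity (Zi)",
                  title = "Node roles") +
    ggplot2::theme_minimal()
}

#' @rdname fmen_plots
#' @param network an `fmen_network`.
#' @export
plot_degree_distribution <- function(network) {
  deg <- igraph::degree(network$graph)
  tab <- table(deg[deg > 0])
  df <- tibble::tibble(degree = as.numeric(names(tab)),
                       frequency = as.numeric(tab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(title = "Degree distribution (log-log)",
                  x = "degree k", y = "frequency") +
    ggplot2::theme_minimal()
}

#' @rdname fmen_plots
#' @param env_cor tibble from [env_correlation()].
#' @export
plot_module_env <- function(env_cor) {
  df <- dplyr::mutate(env_cor,
                      label = ifelse(.data$p_value < 0.05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable,
                                   y = factor(.data$module),
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "module",
                  title = "Module eigengene vs environment (Spearman rho)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
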