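#' Convergence plot of an optimization campaign
#'
#' Individual evaluations with the running best-so-far yield overlaid.
#'
#' @param log An experiment log.
#' @return A ggplot object.
#' @export
plot_convergence <- function(log) {
  trace <- best_so_far_trace(log)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$evaluation)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$yield_gL),
                        colour = "grey50", size = 1.5) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_gL), colour = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::labs(x = "Evaluation", y = "mRNA yield (g/L)",
                  title = "Best-so-far convergence") +
    ggplot2::theme_minimal()
}

#' Parameter-importance bar chart from Shapley attributions
#'
#' @param attributions Output of [shap_explain()] (or an
#'   [importance_summary()] table).
#' @return A ggplot object.
#' @export
plot_importance <- function(attributions) {
  s <- if ("mean_abs_phi" %in% names(attributions)) {
    attributions
  } else {
    importance_summary(attributions)
  }
  s$parameter <- factor(s$parameter, levels = rev(s$parameter))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean_abs_phi,
                                  y = .data$parameter)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "mean |phi| (g/L)", y = NULL,
                  title = "Parameter importance (Shapley effects)") +
    ggplot2::theme_minimal()
}

#' Parallel-coordinates view of all evaluated conditions
#'
#' Each line is one reaction, coloured by its measured yield; every parameter
#' axis is scaled to its domain.
#'
#' @param log An experiment log.
#' @param space The [param_space()].
#' @return A ggplot object.
#' @export
plot_parallel_coordinates <- function(log, space = ivt_space()) {
  d <- parallel_coordinates_data(log, space)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$position,
                                  group = .data$evaluation,
                                  colour = .data$yield_gL)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "yield (g/L)") +
    ggplot2::labs(x = NULL, y = "scaled value",
                  title = "Evaluated reaction conditions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Kinetic profile plot: mRNA accumulation and dsRNA ratio
#'
#' @param profile Output of [ivt_kinetic_profile()].
#' @return A ggplot object (mRNA curve; dsRNA ratio as a dashed overlay on a
#'   secondary axis).
#' @export
plot_kinetics <- function(profile) {
  scale <- max(profile$mrna_gL) / max(max(profile$dsrna_ratio), 1e-9)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mrna_gL), colour = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dsrna_ratio * scale),
                       colour = "#b2182b", linetype = "dashed") +
    ggplot2::scale_y_continuous(
      name = "mRNA (g/L)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "dsRNA/RNAtotal")
    ) +
    ggplot2::labs(x = "time (min)", title = "Simulated IVT kinetics") +
    ggplot2::theme_minimal()
}
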