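#' Plot a degradation time course
#'
#' One line per oligosaccharide species, concentration (mM) against time
#' (minutes) — the standard way HPLC degradation data are displayed.
#'
#' @param object A `time_course`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot time_course
#' @export
autoplot.time_course <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(object)),
                              dplyr::all_of(tc_species(object)),
                              names_to = "species", values_to = "conc_mM")
  long$species <- factor(
    paste0("GlcNAc", sub("^glcnac([0-9]+)_mM$", "\\1", long$species)),
    levels = paste0("GlcNAc", sort(unique(as.integer(
      sub("^glcnac([0-9]+)_mM$", "\\1", tc_species(object))))))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$conc_mM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (min)", y = "concentration (mM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cost trajectory of a subsite fit
#'
#' Cost F (mM^2) per accepted Powell iteration, on a log scale; monotone
#' descent is a quick sanity check on the optimizer.
#'
#' @param object A `subsite_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot subsite_fit
#' @export
autoplot.subsite_fit <- function(object, ...) {
  traj <- object$trajectory
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$iteration, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Powell iteration", y = expression(F ~ (mM^2))) +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten fit over its data
#'
#' @param fit An `mm_fit`.
#' @param n_curve Points on the fitted curve.
#'
#' @return A ggplot object.
#' @export
plot_michaelis_menten <- function(fit, n_curve = 200) {
  d <- fit$data
  S <- seq(0, max(d$substrate_uM), length.out = n_curve)
  curve <- tibble(substrate_uM = S,
                  rate = michaelis_menten_rate(S, fit$Km_uM, fit$kcat_s,
                                               fit$enzyme_total_uM))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate_uM, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "substrate (uM)", y = "initial rate") +
    ggplot2::theme_minimal()
}
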