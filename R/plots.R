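# ggplot2 autoplot methods for the package's result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Rhombogram plot
#'
#' Effective g of each doublet component against E/D.
#'
#' @param object an [rhombogram()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mm_rhombogram <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("geff_x", "geff_y", "geff_z"),
                              names_to = "component", values_to = "geff")
  ggplot(long, aes(x = .data$E_over_D, y = .data$geff,
                   colour = .data$component)) +
    geom_line() +
    facet_wrap(~doublet, labeller = ggplot2::label_both) +
    labs(x = "E/D", y = expression(g[eff]),
         title = "S = 5/2 effective-g rhombogram") +
    theme_minimal()
}

#' Rhombicity-scan plot
#'
#' Objective value against E/D with the estimate marked.
#'
#' @param object an [estimate_rhombicity()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mm_rhombicity <- function(object, ...) {
  ggplot(object$scan, aes(x = .data$E_over_D, y = .data$objective)) +
    geom_line() +
    geom_vline(xintercept = object$E_over_D, linetype = "dashed") +
    labs(x = "E/D", y = "summed |g mismatch|",
         title = sprintf("Rhombicity scan: E/D = %.3f", object$E_over_D)) +
    theme_minimal()
}

#' Loop-hit histogram plot
#'
#' Number of closure hits per gap length.
#'
#' @param object a [search_fragments()] hit table.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mm_loop_hits <- function(object, ...) {
  ggplot(hit_histogram(object), aes(x = factor(.data$gap_length),
                                    y = .data$n_hits)) +
    geom_col() +
    labs(x = "gap length (residues)", y = "hits within cutoff",
         title = "Loop-closure fragment search") +
    theme_minimal()
}

#' Fit plot (titration or Randles-Sevcik)
#'
#' Data points with the fitted model curve.
#'
#' @param object an `mm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  if (object$model == "binding_isotherm_1to1") {
    p <- ggplot(object$data, aes(x = .data$L, y = .data$A)) +
      geom_point() +
      labs(x = "total ligand (M)", y = "absorbance",
           title = sprintf("1:1 binding isotherm (Kd = %.3g M%s)",
                           object$params["kd"],
                           if (length(object$flags)) ", upper limit" else ""))
    if (!is.null(object$fitted)) {
      p <- p + geom_line(data = object$fitted,
                         aes(x = .data$ligand_total_M, y = .data$absorbance),
                         colour = "red", linetype = "dashed")
    }
    return(p + theme_minimal())
  }
  d <- object$data
  d$sqrt_v <- sqrt(d$scan_rate)
  d$abs_ip <- abs(d$i_p)
  ggplot(d, aes(x = .data$sqrt_v, y = .data$abs_ip)) +
    geom_point() +
    ggplot2::geom_abline(slope = object$params["slope"], intercept = 0,
                         linetype = "dashed", colour = "red") +
    labs(x = expression(sqrt(nu) ~ (V^{1/2} ~ s^{-1/2})), y = "|i_p| (A)",
         title = sprintf("Randles-Sevcik: D = %.3g cm²/s",
                         object$params["D"])) +
    theme_minimal()
}

#' Voltammogram plot
#'
#' @param data tibble with potential_V and current_A.
#' @param analysis optional [analyze_voltammogram()] result to mark peaks.
#' @return a ggplot.
#' @export
plot_voltammogram <- function(data, analysis = NULL) {
  p <- ggplot(data, aes(x = .data$potential_V, y = .data$current_A)) +
    geom_line() +
    labs(x = "potential (V)", y = "current (A)") +
    theme_minimal()
  if (!is.null(analysis) && is.finite(analysis$E_half)) {
    p <- p + geom_vline(xintercept = analysis$E_half, linetype = "dotted")
  }
  p
}
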