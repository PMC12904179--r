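#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_line
#'   geom_ribbon geom_hline labs scale_y_log10 facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Forest plot of a hazard-ratio set
#'
#' @param object An `hr_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hr_set
#' @export
autoplot.hr_set <- function(object, ...) {
  d <- tidy(object) |>
    mutate(level = factor(.data$level, levels = unique(.data$level)))
  ggplot(d, aes(x = .data$level, y = .data$hr)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.15) +
    scale_y_log10() +
    labs(x = NULL, y = "Hazard ratio (95% CI)",
         title = paste0(toupper(object$index), " — ", object$exposure))
}

#' Dose-response curve from a restricted cubic spline fit
#'
#' @param object A `spline_dr`.
#' @param ... Unused.
#' @return A ggplot (log-HR scale, referenced to the stated score value).
#' @method autoplot spline_dr
#' @export
autoplot.spline_dr <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$score, y = exp(.data$log_hr))) +
    geom_ribbon(aes(ymin = exp(.data$lo), ymax = exp(.data$hi)),
                fill = "grey80") +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    scale_y_log10() +
    labs(x = paste0(toupper(object$index), " score"),
         y = "Hazard ratio (95% CI)",
         subtitle = paste0("Nonlinearity p = ",
                           signif(object$p_nonlinear, 2),
                           "; reference score ", signif(object$ref_value, 4)))
}

#' Years-of-life-gained plot across exposure groups
#'
#' @param object An `le_estimates` tibble.
#' @param start_age Which start age to plot.
#' @param ... Unused.
#' @return A ggplot faceted by sex.
#' @method autoplot le_estimates
#' @export
autoplot.le_estimates <- function(object, start_age = min(object$start_age), ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$start_age == !!start_age)
  p <- ggplot(d, aes(x = .data$group, y = .data$gain)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point(size = 2) +
    facet_wrap(~sex) +
    labs(x = NULL, y = paste0("Years of life gained at age ", start_age))
  if (all(c("gain_lo", "gain_hi") %in% names(d))) {
    p <- p + geom_errorbar(aes(ymin = .data$gain_lo, ymax = .data$gain_hi),
                           width = 0.15)
  }
  p
}
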