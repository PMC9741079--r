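# Basic plots of the analysis results: per-panel dimension-vs-temperature
# scatters with trend lines, and amplitude bars with class means +/- sd.

#' Scatter of one dimension against optimum growth temperature
#'
#' One (enzyme, subunit) panel: points per species, resolved structures
#' distinguished from predicted ones, with the OLS trend line dotted.
#'
#' @param dataset a [measurement_dataset()].
#' @param enzyme,subunit panel selectors.
#' @param dimension `"length"`, `"surface"` or `"volume"`.
#' @return a ggplot object.
#' @export
plot_dimension_scatter <- function(dataset, enzyme, subunit,
                                   dimension = c("length", "surface", "volume")) {
  dimension <- match.arg(dimension)
  sel <- dataset$enzyme == enzyme & dataset$subunit == subunit
  df <- as.data.frame(dataset)[sel, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for that (enzyme, subunit)", call. = FALSE)
  unit <- c(length = "Å", surface = "Å²",
            volume = "Å³")[[dimension]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_opt, y = .data[[dimension]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", colour = "grey30") +
    ggplot2::labs(x = "Optimum growth temperature (°C)",
                  y = paste0("Tunnel ", dimension, " (", unit, ")"),
                  title = paste(enzyme, subunit)) +
    ggplot2::theme_classic()
}

#' Amplitude bars with class means across temperature classes
#'
#' Mirrors the class-summary view of the analysis: grey bars span the range
#' (minimum to maximum) of one dimension in each temperature class; red
#' squares mark the class mean with +/- one sd error bars.
#'
#' @param dataset a [measurement_dataset()].
#' @param enzyme,subunit panel selectors.
#' @param dimension `"length"`, `"surface"` or `"volume"`.
#' @return a ggplot object.
#' @export
plot_amplitudes <- function(dataset, enzyme, subunit,
                            dimension = c("length", "surface", "volume")) {
  dimension <- match.arg(dimension)
  sel <- dataset$enzyme == enzyme & dataset$subunit == subunit
  df <- as.data.frame(dataset)[sel, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for that (enzyme, subunit)", call. = FALSE)
  agg <- do.call(rbind, lapply(split(df[[dimension]], df$t_class), function(v)
    data.frame(lo = min(v), hi = max(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_)))
  agg$t_class <- factor(rownames(agg), levels = T_CLASSES)
  unit <- c(length = "Å", surface = "Å²",
            volume = "Å³")[[dimension]]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$t_class)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = as.numeric(.data$t_class) - 0.35,
                                    xmax = as.numeric(.data$t_class) + 0.35,
                                    ymin = .data$lo, ymax = .data$hi),
                       fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), colour = "red",
                        shape = 15, size = 3) +
    ggplot2::labs(x = "Optimum growth temperature class (°C)",
                  y = paste0("Tunnel ", dimension, " (", unit, ")"),
                  title = paste(enzyme, subunit)) +
    ggplot2::theme_classic()
}
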