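# Statistical analysis of tunnel dimensions versus optimum growth
# temperature: temperature classes, within-class amplitude (range) summaries,
# variance-ratio F tests with Bonferroni correction, and linear trend fits.

#' Assign optimum growth temperatures to temperature classes
#'
#' Three classes: `"<50"` (t_opt < 50), `"50-80"` (50 <= t_opt <= 80) and
#' `">80"` (t_opt > 80) degrees C. The boundary temperatures 50 and 80 fall
#' in the middle class, so the three classes partition the temperature axis
#' with no gaps or overlaps. Vectorized.
#'
#' @param t_opt numeric optimum growth temperature(s), degrees C, finite, > 0.
#' @return character vector of class labels.
#' @export
assign_class <- function(t_opt) {
  if (!is.numeric(t_opt) || any(!is.finite(t_opt)) || any(t_opt <= 0))
    stop("t_opt must be numeric, finite and > 0", call. = FALSE)
  ifelse(t_opt < 50, "<50", ifelse(t_opt <= 80, "50-80", ">80"))
}

#' Summarize one temperature class
#'
#' The amplitude is the range, maximum minus minimum, of the values — the
#' variability statistic used throughout. The mean is arithmetic and the
#' standard deviation uses the sample (n - 1) denominator; with a single
#' value the sd is `NA` (flagged) and the amplitude is 0.
#'
#' @param values numeric measurements (same dimension and units), length >= 1.
#' @return a list with `n`, `mean`, `sd`, `amplitude`.
#' @export
class_summary <- function(values) {
  if (length(values) == 0)
    stop("cannot summarize an empty class", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be numeric and finite", call. = FALSE)
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) >= 2) sd(values) else NA_real_,
       amplitude = max(values) - min(values))
}

#' Amplitude fold ratio between the coolest and hottest classes
#'
#' For each (enzyme, subunit) panel, the ratio of the `"<50"` class amplitude
#' to the `">80"` class amplitude of one dimension. Requires n >= 2 in both
#' classes; a zero amplitude in the `">80"` class makes the ratio undefined
#' (`NA` with a note), never infinite.
#'
#' @param dataset a [measurement_dataset()].
#' @param dimension `"length"`, `"surface"` or `"volume"`.
#' @return a `data.frame` with one row per (enzyme, subunit): class sizes,
#'   the two amplitudes, `ratio` and a `note` for undefined cases.
#' @export
amplitude_fold_ratio <- function(dataset, dimension = c("length", "surface", "volume")) {
  dimension <- match.arg(dimension)
  stopifnot(inherits(dataset, "measurement_dataset"))
  panels <- unique(dataset[, c("enzyme", "subunit")])
  panels <- panels[order(panels$enzyme, panels$subunit), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(panels)), function(i) {
    sel <- dataset$enzyme == panels$enzyme[i] & dataset$subunit == panels$subunit[i]
    lo <- dataset[[dimension]][sel & dataset$t_class == "<50"]
    hi <- dataset[[dimension]][sel & dataset$t_class == ">80"]
    row <- data.frame(enzyme = panels$enzyme[i], subunit = panels$subunit[i],
                      dimension = dimension,
                      n_low = length(lo), n_high = length(hi),
                      amplitude_low = NA_real_, amplitude_high = NA_real_,
                      ratio = NA_real_, note = "")
    if (length(lo) < 2 || length(hi) < 2) {
      row$note <- "needs n >= 2 in both <50 and >80 classes"
      return(row)
    }
    row$amplitude_low <- max(lo) - min(lo)
    row$amplitude_high <- max(hi) - min(hi)
    if (row$amplitude_high == 0) {
      row$note <- "undefined: zero amplitude in >80 class"
    } else {
      row$ratio <- row$amplitude_low / row$amplitude_high
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Variance-ratio (F) test between two samples
#'
#' Compares the variability of two samples with the F statistic
#' `s_larger^2 / s_smaller^2` (the larger variance in the numerator, so
#' `F >= 1`), degrees of freedom n - 1 each, and a two-sided p-value
#' `2 * min(P(F <= f), P(F >= f))` capped at 1. Swapping the samples leaves
#' the result unchanged by construction.
#'
#' @param values_a,values_b numeric samples with n >= 2 each.
#' @return a list with `f_stat`, `df_num`, `df_den`, `p_value`,
#'   `larger` (`"a"` or `"b"`, which sample had the larger variance), and
#'   `testable` (`FALSE` when both variances are zero, p undefined).
#' @export
variance_ratio_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("both samples need n >= 2 for a variance-ratio test", call. = FALSE)
  va <- var(values_a)
  vb <- var(values_b)
  if (va == 0 && vb == 0)
    return(list(f_stat = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
                p_value = NA_real_, larger = NA_character_, testable = FALSE))
  if (va >= vb) {
    f <- va / vb
    df1 <- length(values_a) - 1L
    df2 <- length(values_b) - 1L
    larger <- "a"
  } else {
    f <- vb / va
    df1 <- length(values_b) - 1L
    df2 <- length(values_a) - 1L
    larger <- "b"
  }
  p <- min(1, 2 * min(pf(f, df1, df2), 1 - pf(f, df1, df2)))
  list(f_stat = f, df_num = df1, df_den = df2, p_value = p,
       larger = larger, testable = TRUE)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, preserving order. The family size `m` may exceed
#' the number of p-values supplied (e.g. when some comparisons in the family
#' were not testable).
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m family size, at least `length(p_values)`.
#' @return adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("family size m must be >= the number of p-values", call. = FALSE)
  pmin(1, m * p_values)
}

#' Fit a linear trend of one dimension on optimum growth temperature
#'
#' Ordinary least squares of the dimension on `t_opt`; no weighting.
#'
#' @param dataset a [measurement_dataset()] (or any data.frame with `t_opt`
#'   and the dimension column) with at least 3 rows and at least 2 distinct
#'   `t_opt` values.
#' @param dimension `"length"`, `"surface"` or `"volume"`.
#' @return a list with `slope` (units per degree C), `intercept`,
#'   `r_squared`. A constant response gives slope 0 and `r_squared` 0.
#' @export
fit_trend <- function(dataset, dimension = c("length", "surface", "volume")) {
  dimension <- match.arg(dimension)
  y <- dataset[[dimension]]
  t <- dataset$t_opt
  if (length(y) < 3)
    stop("trend fit needs at least 3 points", call. = FALSE)
  if (length(unique(t)) < 2)
    stop("trend fit needs at least 2 distinct t_opt values", call. = FALSE)
  if (var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0))
  fit <- lm(y ~ t)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Full variability analysis across temperature classes
#'
#' For every (enzyme, subunit, dimension) panel in the dataset: per-class
#' summaries (n, mean, sd, amplitude), variance-ratio comparisons of the
#' `"50-80"` and `">80"` classes against the reference `"<50"` class with
#' Bonferroni correction (family size `m`, default 2 — the two against-
#' reference comparisons in each panel), the `"<50"`/`">80"` amplitude fold
#' ratio, and a linear trend on `t_opt`. Comparisons involving a class with
#' n < 2 are flagged not testable and the run continues. Results are
#' deterministic and independent of the row order of the dataset.
#'
#' @param dataset a non-empty [measurement_dataset()].
#' @param alpha significance level for the adjusted p-values (default 0.05).
#' @param m Bonferroni family size per panel (default 2).
#' @param dimensions dimensions to analyse.
#' @return an object of class `tunnel_analysis`: a list of data.frames
#'   `summaries`, `comparisons`, `ratios`, `trends`.
#' @export
analyze <- function(dataset, alpha = 0.05, m = 2,
                    dimensions = c("length", "surface", "volume")) {
  stopifnot(inherits(dataset, "measurement_dataset"))
  if (nrow(dataset) == 0)
    stop("cannot analyse an empty dataset", call. = FALSE)
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  panels <- unique(dataset[, c("enzyme", "subunit")])
  panels <- panels[order(panels$enzyme, panels$subunit), , drop = FALSE]

  summaries <- list()
  comparisons <- list()
  ratios <- list()
  trends <- list()
  for (i in seq_len(nrow(panels))) {
    enz <- panels$enzyme[i]
    sub <- panels$subunit[i]
    sel <- dataset$enzyme == enz & dataset$subunit == sub
    for (dim in dimensions) {
      by_class <- lapply(setNames(T_CLASSES, T_CLASSES), function(cl)
        sort(dataset[[dim]][sel & dataset$t_class == cl]))
      for (cl in T_CLASSES) {
        v <- by_class[[cl]]
        s <- if (length(v)) class_summary(v) else
          list(n = 0L, mean = NA_real_, sd = NA_real_, amplitude = NA_real_)
        summaries[[length(summaries) + 1L]] <-
          data.frame(enzyme = enz, subunit = sub, dimension = dim,
                     t_class = cl, n = s$n, mean = s$mean, sd = s$sd,
                     amplitude = s$amplitude)
      }
      ref <- by_class[["<50"]]
      for (cl in c("50-80", ">80")) {
        v <- by_class[[cl]]
        row <- data.frame(enzyme = enz, subunit = sub, dimension = dim,
                          class_a = "<50", class_b = cl,
                          f_stat = NA_real_, df_num = NA_integer_,
                          df_den = NA_integer_, p_raw = NA_real_,
                          p_adjusted = NA_real_, significant = NA,
                          testable = FALSE)
        if (length(ref) >= 2 && length(v) >= 2) {
          vt <- variance_ratio_test(ref, v)
          if (isTRUE(vt$testable)) {
            row$f_stat <- vt$f_stat
            row$df_num <- vt$df_num
            row$df_den <- vt$df_den
            row$p_raw <- vt$p_value
            row$p_adjusted <- bonferroni_adjust(vt$p_value, m)
            row$significant <- row$p_adjusted < alpha
            row$testable <- TRUE
          }
        }
        comparisons[[length(comparisons) + 1L]] <- row
      }
      panel_data <- dataset[sel, , drop = FALSE]
      ratios[[length(ratios) + 1L]] <- amplitude_fold_ratio(
        measurement_dataset(panel_data), dim)
      tr <- if (nrow(panel_data) >= 3 && length(unique(panel_data$t_opt)) >= 2)
        fit_trend(panel_data, dim) else list(slope = NA_real_,
                                             intercept = NA_real_,
                                             r_squared = NA_real_)
      trends[[length(trends) + 1L]] <-
        data.frame(enzyme = enz, subunit = sub, dimension = dim,
                   slope = tr$slope, intercept = tr$intercept,
                   r_squared = tr$r_squared)
    }
  }
  bind <- function(x) {
    df <- do.call(rbind, x)
    rownames(df) <- NULL
    df
  }
  structure(list(summaries = bind(summaries), comparisons = bind(comparisons),
                 ratios = bind(ratios), trends = bind(trends),
                 alpha = alpha, m = m),
            class = "tunnel_analysis")
}

#' @export
print.tunnel_analysis <- function(x, ...) {
  n_panels <- nrow(unique(x$comparisons[, c("enzyme", "subunit", "dimension")]))
  cat("tunnel_analysis:", n_panels, "panels,",
      nrow(x$comparisons), "class comparisons (alpha =", x$alpha,
      ", Bonferroni m =", x$m, ")\n")
  sig <- x$comparisons$significant
  cat("  significant vs <50 class:", sum(sig, na.rm = TRUE), "of",
      sum(x$comparisons$testable), "testable\n")
  invisible(x)
}

#' Write analysis results to TSV files
#'
#' Writes the comparisons table to `path` (one row per panel and class
#' comparison) and, when `dir` is used, the summaries, ratios and trends
#' alongside it.
#'
#' @param analysis a `tunnel_analysis`.
#' @param path output TSV for the comparisons table.
#' @param all if `TRUE`, also write `summaries.tsv`, `ratios.tsv`,
#'   `trends.tsv` next to `path`.
#' @export
write_analysis <- function(analysis, path, all = FALSE) {
  stopifnot(inherits(analysis, "tunnel_analysis"))
  write.table(analysis$comparisons, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (all) {
    base <- dirname(path)
    write.table(analysis$summaries, file.path(base, "summaries.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(analysis$ratios, file.path(base, "ratios.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(analysis$trends, file.path(base, "trends.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
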