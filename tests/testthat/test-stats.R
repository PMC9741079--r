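test_that("temperature classes follow the <50 / 50-80 / >80 convention", {
  expect_equal(assign_class(37), "<50")
  expect_equal(assign_class(110), ">80")
  # boundary temperatures belong to the middle class
  expect_equal(assign_class(c(50, 80)), c("50-80", "50-80"))
  expect_error(assign_class(-3), "> 0")
  expect_error(assign_class(NaN))
})

test_that("assign_class partitions the temperature axis with no gaps", {
  t <- seq(0.5, 129.5, by = 0.25)
  cl <- assign_class(t)
  expect_true(all(cl %in% c("<50", "50-80", ">80")))
  expect_equal(cl == "<50", t < 50)
  expect_equal(cl == "50-80", t >= 50 & t <= 80)
  expect_equal(cl == ">80", t > 80)
})

test_that("class summaries report n, mean, sample sd and amplitude", {
  s <- class_summary(c(2, 5, 9))
  expect_equal(s$n, 3)
  expect_equal(s$amplitude, 7)
  expect_equal(s$mean, 16 / 3)
  expect_equal(s$sd, sqrt(37 / 3), tolerance = 1e-12)  # = 3.511885

  one <- class_summary(5)
  expect_equal(one$amplitude, 0)
  expect_true(is.na(one$sd))

  expect_equal(class_summary(c(9, 2, 5)), s)  # order invariance
  expect_error(class_summary(numeric(0)), "empty")
})

test_that("class summaries: amplitude/sd translation and scale behaviour", {
  set.seed(5)
  v <- rnorm(25, 50, 8)
  s0 <- class_summary(v)
  shifted <- class_summary(v + 13.7)
  expect_equal(shifted$amplitude, s0$amplitude)
  expect_equal(shifted$sd, s0$sd)
  scaled <- class_summary(v * 3)
  expect_equal(scaled$amplitude, 3 * s0$amplitude)
  expect_equal(scaled$sd, 3 * s0$sd)
})

test_that("variance-ratio test matches the F distribution and is symmetric", {
  x <- c(1, 2, 3, 4)
  expect_equal(variance_ratio_test(x, x)$f_stat, 1)
  expect_equal(variance_ratio_test(x, x)$p_value, 1)

  # n = 11 each, variance ratio 4: p frozen from numeric integration of the
  # F(10, 10) density over the upper tail, doubled
  a <- c(-4, -3, -2, -1, 0, 1, 2, 3, 4, 5, 6) / 1  # var 11
  b <- a / 2                                       # var 11/4
  res <- variance_ratio_test(a, b)
  expect_equal(res$f_stat, 4)
  expect_equal(res$df_num, 10)
  expect_equal(res$df_den, 10)
  oracle_p <- 2 * integrate(function(x) df(x, 10, 10), 4, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(res$p_value, oracle_p, tolerance = 1e-8)
  expect_equal(res$p_value, 0.03916288, tolerance = 1e-6)

  swapped <- variance_ratio_test(b, a)
  expect_equal(swapped$f_stat, res$f_stat)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$larger, "b")

  # independent route: stats::var.test two-sided p
  set.seed(42)
  u <- rnorm(12, 0, 3)
  v <- rnorm(9, 0, 1)
  expect_equal(variance_ratio_test(u, v)$p_value,
               stats::var.test(u, v)$p.value, tolerance = 1e-12)

  flat <- variance_ratio_test(c(1, 2, 3), c(2, 2))
  expect_true(flat$testable)  # one zero variance: infinite F, p = 0
  expect_equal(flat$p_value, 0)
  both_flat <- variance_ratio_test(c(1, 1, 1), c(2, 2, 2))
  expect_false(both_flat$testable)
  expect_error(variance_ratio_test(1, c(1, 2)), "n >= 2")
})

test_that("Bonferroni adjustment multiplies, caps and preserves order", {
  expect_equal(bonferroni_adjust(0.01, m = 2), 0.02)
  expect_equal(bonferroni_adjust(0.6, m = 3), 1)
  p <- sort(runif(10))
  adj <- bonferroni_adjust(p, m = 12)
  expect_false(is.unsorted(adj))
  expect_true(all(adj <= 1))
  expect_error(bonferroni_adjust(1.2, m = 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "family size")
})

test_that("trend fits recover exact lines and degenerate inputs", {
  df <- data.frame(t_opt = c(20, 40, 60, 90), length = 2 * c(20, 40, 60, 90) + 1,
                   surface = 5, volume = 1)
  tr <- suppressWarnings(fit_trend(df, "length"))  # lm flags the perfect fit
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 1)
  expect_equal(tr$r_squared, 1)

  flat <- fit_trend(df, "surface")
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(fit_trend(df[1:2, ], "length"), "3 points")
  same_t <- data.frame(t_opt = c(30, 30, 30), length = 1:3,
                       surface = 1, volume = 1)
  expect_error(fit_trend(same_t, "length"), "distinct t_opt")
})

test_that("trend slope estimates fall within 3 standard errors of truth", {
  hits <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    t <- runif(40, 18, 110)
    beta <- 0.8
    y <- 30 + beta * t + rnorm(40, sd = 10)
    fit <- lm(y ~ t)
    abs(coef(fit)[2] - beta) <= 3 * summary(fit)$coefficients[2, 2]
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("analyze produces full panel bookkeeping on a synthetic dataset", {
  ds <- generate_dimension_dataset(dimension_gen_spec(n_per_class = 10, seed = 4))
  res <- analyze(ds)
  panels <- unique(res$comparisons[, c("enzyme", "subunit", "dimension")])
  expect_equal(nrow(panels), 18)  # 2 enzymes x 3 subunits x 3 dimensions
  expect_equal(nrow(res$comparisons), 36)  # two comparisons per panel
  expect_true(all(res$comparisons$testable))
  expect_equal(nrow(res$summaries), 54)
  expect_true(all(res$summaries$n == 10))
  # adjusted p-values are the Bonferroni (m = 2) transform of raw ones
  expect_equal(res$comparisons$p_adjusted,
               pmin(1, 2 * res$comparisons$p_raw))
})

test_that("analyze flags untestable comparisons but still summarizes", {
  ds <- measurement_dataset(data.frame(
    species = c("a", "b", "c"), enzyme = "Mmr", subunit = "alpha",
    t_opt = c(25, 30, 45), length = c(80, 90, 100),
    surface = c(1500, 1600, 1700), volume = c(2500, 2600, 2700)))
  res <- analyze(ds)
  expect_true(all(!res$comparisons$testable))
  expect_true(all(is.na(res$comparisons$p_raw)))
  s <- res$summaries
  expect_equal(s$n[s$t_class == "<50" & s$dimension == "length"], 3)
  expect_equal(s$n[s$t_class == ">80" & s$dimension == "length"], 0)
})

test_that("analyze is invariant to dataset row order", {
  ds <- generate_dimension_dataset(dimension_gen_spec(n_per_class = 8, seed = 12))
  res1 <- analyze(ds)
  set.seed(1)
  shuffled <- measurement_dataset(
    as.data.frame(ds)[sample(nrow(ds)), c("species", "enzyme", "subunit",
                                          "t_opt", "length", "surface",
                                          "volume")])
  res2 <- analyze(shuffled)
  expect_equal(res1$comparisons, res2$comparisons)
  expect_equal(res1$summaries, res2$summaries)
  expect_equal(res1$trends, res2$trends)
})

test_that("amplitude fold ratios follow their definition", {
  mk <- function(lo, hi) {
    n <- length(lo) + length(hi)
    measurement_dataset(data.frame(
      species = paste0("s", seq_len(n)), enzyme = "Mmr", subunit = "alpha",
      t_opt = c(rep(30, length(lo)), rep(95, length(hi))),
      length = c(lo, hi), surface = 1, volume = 1))
  }
  r <- amplitude_fold_ratio(mk(c(0.001, 7.001), c(3, 4)), "length")
  expect_equal(r$ratio, 7, tolerance = 1e-9)
  same <- amplitude_fold_ratio(mk(c(1, 5), c(2, 6)), "length")
  expect_equal(same$ratio, 1)
  degen <- amplitude_fold_ratio(mk(c(1, 5), c(2, 2)), "length")
  expect_true(is.na(degen$ratio))
  expect_match(degen$note, "undefined")
  toofew <- amplitude_fold_ratio(mk(c(1, 5), 2), "length")
  expect_true(is.na(toofew$ratio))
  expect_match(toofew$note, "n >= 2")
})
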