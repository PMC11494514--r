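test_that("cumulative connectivity distribution counts tail fractions", {
  A <- matrix(0L, 3, 3)
  A[1, 1] <- 1L; A[2, 2] <- 1L; A[3, 1:2] <- 1L   # plant degrees 1,1,2
  d <- cumulative_distribution(bmat(A), "plants")
  expect_equal(d$k, c(1, 2))
  expect_equal(d$p, c(1, 1 / 3))
  # all degrees equal: a single point at P = 1
  d2 <- cumulative_distribution(bmat(diag(3)), "plants")
  expect_equal(d2$k, 1)
  expect_equal(d2$p, 1)
  expect_error(cumulative_distribution(bmat(matrix(1, 1, 1)), "plants"),
               "2 species")
})

test_that("adding a link shifts the cumulative distribution up pointwise", {
  set.seed(2)
  A <- rand_binary(6, 6)
  B <- A; B[which(A == 0)[1]] <- 1
  da <- cumulative_distribution(bmat(A), "plants")
  db <- cumulative_distribution(bmat(B), "plants")
  shared <- intersect(da$k, db$k)
  expect_true(all(db$p[match(shared, db$k)] >=
                    da$p[match(shared, da$k)]))
})

test_that("model selection recovers the generating family", {
  k <- 1:12
  # exact power law P = k^-1
  dp <- structure(list(side = "pollinators", k = as.numeric(k), p = 1 / k),
                  class = "degree_distribution")
  fp <- fit_connectivity_models(dp)
  expect_equal(fp$model[fp$selected], "power_law")
  expect_equal(fp$b[fp$model == "power_law"], 1, tolerance = 1e-6)
  # truncated fit on power-law data: huge cutoff, AIC within 2
  expect_gt(fp$k_x[fp$model == "truncated_power_law"], 1e3)
  expect_lt(fp$aic[fp$model == "truncated_power_law"] -
              fp$aic[fp$model == "power_law"], 2 + 1e-9)
  # exact exponential decay
  de <- structure(list(side = "pollinators", k = as.numeric(k),
                       p = exp(-(k - 1) / 3)),
                  class = "degree_distribution")
  fe <- fit_connectivity_models(de)
  expect_equal(fe$model[fe$selected], "exponential")
  expect_equal(fe$gamma[fe$model == "exponential"], 3 * log(10),
               tolerance = 1e-6)
  # exact truncated power law
  dt <- structure(list(side = "pollinators", k = as.numeric(k),
                       p = k^-0.7 * exp(-k / 4) / exp(-1 / 4)),
                  class = "degree_distribution")
  ft <- fit_connectivity_models(dt)
  expect_equal(ft$model[ft$selected], "truncated_power_law")
  expect_equal(ft$b[ft$model == "truncated_power_law"], 0.7,
               tolerance = 1e-6)
  expect_equal(ft$k_x[ft$model == "truncated_power_law"], 4 * log(10),
               tolerance = 1e-6)
})

test_that("the truncated model is skipped below 4 distinct degrees", {
  d <- structure(list(side = "plants", k = c(1, 2, 3), p = c(1, .5, .2)),
                 class = "degree_distribution")
  f <- fit_connectivity_models(d)
  expect_false("truncated_power_law" %in% f$model)
  expect_equal(attr(f, "skipped"), "truncated_power_law")
})

test_that("f-s regression reproduces closed-form OLS", {
  set.seed(14)
  f <- exp(rnorm(30)); s <- exp(0.6 * log(f) + rnorm(30, 0, 0.2))
  r <- fs_regression(f, s)
  x <- log10(f); y <- log10(s)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r$slope, slope, tolerance = 1e-10)
  expect_equal(r$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
})

test_that("f-s regression degenerate and limit cases", {
  f <- c(1, 2, 4, 8, 16)
  # exact fits make summary.lm grumble about perfect residuals; the point
  # here is the limiting values themselves
  r1 <- suppressWarnings(fs_regression(f, f))      # s = f exactly
  expect_equal(r1$slope, 1)
  expect_equal(r1$r_squared, 1)
  r0 <- suppressWarnings(fs_regression(f, rep(3, 5)))  # constant s
  expect_equal(r0$slope, 0)
  expect_equal(r0$r_squared, 0)
  set.seed(6)
  f2 <- exp(rnorm(200))
  s2 <- f2^0.5 * exp(rnorm(200, 0, 1e-4))   # vanishing multiplicative noise
  expect_equal(fs_regression(f2, s2)$slope, 0.5, tolerance = 1e-3)
  expect_warning(
    r <- fs_regression(c(0, f), c(1, 2.2, 3.7, 8.4, 15.1, 33)),
    "excluding")
  expect_equal(r$n_excluded, 1L)
  expect_error(fs_regression(c(1, 2), c(1, 2)), "3 usable")
})

test_that("slope comparison: identical groups give F = 0", {
  set.seed(10)
  g <- list(f = exp(rnorm(20)), s = exp(rnorm(20)))
  cmp <- compare_slopes(list(a = g, b = g, c = g))
  expect_equal(cmp$F, 0, tolerance = 1e-10)
  expect_equal(cmp$df1, 2L)
})

test_that("two-group slope F equals the squared slope-difference t", {
  set.seed(15)
  mk <- function(b) {
    f <- exp(rnorm(40))
    list(f = f, s = exp(b * log(f) + rnorm(40, 0, 0.3)))
  }
  g1 <- mk(0.5); g2 <- mk(1.0)
  cmp <- compare_slopes(list(a = g1, b = g2))
  dat <- data.frame(
    y = log10(c(g1$s, g2$s)), x = log10(c(g1$f, g2$f)),
    g = rep(c("a", "b"), each = 40))
  fit <- lm(y ~ x * g, data = dat)
  tstat <- summary(fit)$coefficients["x:gb", "t value"]
  expect_equal(cmp$F, tstat^2, tolerance = 1e-10)
})

test_that("slope heterogeneity is detected and df bookkeeping is exact", {
  set.seed(16)
  mk <- function(b, n) {
    f <- exp(rnorm(n))
    list(f = f, s = exp(b * log(f) + rnorm(n, 0, 0.1)))
  }
  cmp <- compare_slopes(list(a = mk(0.5, 100), b = mk(1.5, 100)))
  expect_lt(cmp$p_value, 0.001)
  # 3 groups over 109 points: F has (2, 103) degrees of freedom
  cmp3 <- compare_slopes(list(a = mk(1, 36), b = mk(1, 36), c = mk(1, 37)))
  expect_equal(cmp3$df1, 2L)
  expect_equal(cmp3$df2, 103L)
  expect_error(compare_slopes(list(a = mk(1, 10))), "2 groups")
})
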