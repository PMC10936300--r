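test_that("loss, RMSE and N-RMSE follow their defining arithmetic", {
  s <- eval_series(c(100, 50), c(90, 60), peak_moment = 100)
  expect_equal(regression_loss(s), 100)
  expect_equal(rmse(s), 10)
  expect_equal(n_rmse(s), 0.10)
  perfect <- eval_series(1:10, 1:10)
  expect_equal(regression_loss(perfect), 0)
  expect_error(eval_series(1:3, 1:4), "same length")
  expect_error(n_rmse(eval_series(c(0, 0), c(1, 2), peak_moment = 0)),
               "positive")
  # homogeneity: scaling both series by c scales rmse by |c|, not n_rmse
  set.seed(11)
  y <- rnorm(50, 50, 10); yh <- y + rnorm(50)
  s1 <- eval_series(y, yh)
  s2 <- eval_series(-3 * y, -3 * yh, peak_moment = 3 * s1$peak_moment)
  expect_equal(rmse(s2), 3 * rmse(s1))
  expect_equal(n_rmse(s2), n_rmse(s1))
})

test_that("r_squared matches independent references and transform rules", {
  s <- eval_series(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(r_squared(s), stats::cor(s$y, s$yhat)^2, tolerance = 1e-14)
  aff <- eval_series(1:20, 2 * (1:20) + 3)
  expect_equal(r_squared(aff), 1)
  expect_error(r_squared(eval_series(rep(2, 5), 1:5)), "constant")
  # invariance under positive affine transforms of either series
  set.seed(12)
  y <- rnorm(40); yh <- 0.8 * y + rnorm(40, 0, 0.3)
  base <- r_squared(eval_series(y, yh))
  expect_equal(r_squared(eval_series(2 * y + 7, yh)), base, tolerance = 1e-12)
  expect_equal(r_squared(eval_series(y, 0.1 * yh - 4)), base, tolerance = 1e-12)
  # residual form agrees with its own definition
  s2 <- eval_series(y, yh)
  expect_equal(r_squared(s2, form = "residual"),
               1 - sum((y - yh)^2) / sum((y - mean(y))^2))
})

test_that("five metrics equal a second implementation on 1000 seeded series", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 20, 8)
    yh <- y + rnorm(n, 0, 2)
    s <- eval_series(y, yh, peak_moment = max(abs(y)))
    # reference route: crossprod / cor / lm, distinct from the package forms
    res <- y - yh
    ref <- c(loss = as.numeric(crossprod(res)) / n,
             rmse = sqrt(as.numeric(crossprod(res)) / n),
             n_rmse = sqrt(as.numeric(crossprod(res)) / n) / max(abs(y)),
             r2 = stats::cor(y, yh)^2)
    got <- c(loss = regression_loss(s), rmse = rmse(s), n_rmse = n_rmse(s),
             r2 = r_squared(s))
    worst <- max(worst, abs(got - ref) / pmax(abs(ref), 1e-12))
    if (i <= 25) {
      fit <- linear_fit(s)
      ref_fit <- summary(stats::lm(yh ~ y))
      expect_equal(fit$slope, ref_fit$coefficients["y", "Estimate"])
      expect_equal(fit$slope_se, ref_fit$coefficients["y", "Std. Error"])
    }
    expect_equal(regression_loss(s), rmse(s)^2, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-10)
})

test_that("linear agreement fit detects the identity relation", {
  s <- eval_series(1:50, 1:50)
  # lm flags the zero-residual fit as "essentially perfect"; that is the point
  fit <- suppressWarnings(linear_fit(s))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_error(linear_fit(eval_series(1:2, 3:4)), "N >= 3")
  expect_error(linear_fit(eval_series(rep(1, 5), rnorm(5))), "constant")
  # consistency: with additive noise, slope ~ 1 and intercept ~ 0 within 2 SE
  set.seed(13)
  y <- runif(400, 0, 120)
  s2 <- eval_series(y, y + rnorm(400, 0, 5))
  fit2 <- linear_fit(s2)
  expect_lt(abs(fit2$slope - 1), 2 * fit2$slope_se)
  expect_lt(abs(fit2$intercept), 2 * fit2$intercept_se)
})

test_that("group comparison gates branches on Shapiro-Wilk normality", {
  # identical columns: nothing is significant
  m0 <- matrix(rep(rnorm(8), 3), 8, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  r0 <- compare_groups(m0)
  expect_true(all(r0$pairwise$p > 0.05))
  expect_true(all(r0$pairwise$flag == ""))

  # clear paired shift, n = 8 gaussian: parametric branch, p below .05,
  # and the p-value equals the hand-computed paired t-test
  set.seed(14)
  base <- rnorm(8, 10, 1)
  m2 <- cbind(A = base, B = base + 5 + rnorm(8, 0, 0.5))
  r2 <- compare_groups(m2)
  expect_equal(r2$branch, "parametric")
  expect_lt(r2$omnibus$p, 0.05)
  d <- m2[, 1] - m2[, 2]
  tstat <- mean(d) / (stats::sd(d) / sqrt(8))
  p_ref <- 2 * stats::pt(-abs(tstat), df = 7)
  expect_equal(r2$omnibus$p, p_ref, tolerance = 1e-12)

  # heavy-tailed column fails SW -> nonparametric branch (SW itself is the
  # reference for the gate)
  set.seed(15)
  heavy <- rcauchy(12)^3
  m3 <- cbind(A = rnorm(12), B = heavy)
  expect_lt(stats::shapiro.test(heavy)$p.value, 0.05)
  r3 <- compare_groups(m3)
  expect_equal(r3$branch, "nonparametric")

  # branch selection is a pure function of the SW p-values
  for (seed in 16:20) {
    set.seed(seed)
    mm <- cbind(A = rnorm(10), B = rexp(10)^2, C = rnorm(10, 2))
    rr <- compare_groups(mm)
    expected <- all(apply(mm, 2, function(cl) stats::shapiro.test(cl)$p.value) > 0.05)
    expect_equal(rr$branch == "parametric", expected)
  }
  expect_error(compare_groups(matrix(1:6, 2, 3)), "3 subjects")
  expect_error(compare_groups(matrix(1:6, 6, 1)), "2 conditions")
})

test_that("three-condition designs produce omnibus and Tukey-flagged pairs", {
  set.seed(17)
  n <- 10
  base <- rnorm(n, 10, 1)
  m <- cbind(R1 = base + rnorm(n, 0, 0.4),
             R2 = base - 2 + rnorm(n, 0, 0.4),
             R3 = base - 2 + rnorm(n, 0, 0.4))
  r <- compare_groups(m)
  expect_equal(nrow(r$pairwise), 3)
  expect_lt(r$omnibus$p, 0.05)
  big <- r$pairwise[r$pairwise$a == "R1" & r$pairwise$b == "R2", ]
  expect_lt(big$p, 0.05)
  expect_true(big$flag %in% c("*", "**", "***"))
  # Tukey-adjusted p-values are consistent with the estimates
  expect_equal(order(abs(r$pairwise$estimate)), order(-r$pairwise$p))
  # nonparametric route on ranks for skewed data
  set.seed(18)
  mnp <- cbind(R1 = rexp(12)^2, R2 = rexp(12)^2 + 4, R3 = rexp(12)^2)
  rnp <- compare_groups(mnp)
  expect_equal(rnp$branch, "nonparametric")
  expect_equal(rnp$omnibus$test, "Friedman")
  expect_equal(nrow(rnp$pairwise), 3)
})
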