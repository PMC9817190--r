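# closed-form simple-regression solution via explicit normal equations
ols_oracle <- function(xx, yy) {
  n <- length(xx)
  sxx <- sum(xx^2) - sum(xx)^2 / n
  sxy <- sum(xx * yy) - sum(xx) * sum(yy) / n
  slope <- sxy / sxx
  intercept <- mean(yy) - slope * mean(xx)
  yhat <- intercept + slope * xx
  r2 <- 1 - sum((yy - yhat)^2) / sum((yy - mean(yy))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

test_that("noiseless exponential data are recovered exactly", {
  x <- 1:8
  lx <- 1000 * exp(-0.5 * x)
  fit <- fit_survivorship(lx, x)
  expect_equal(fit$b, 0.5, tolerance = 1e-12)
  expect_equal(fit$N0, 1000, tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(fit$N0, fit$b))
  expect_equal(predict(fit, 3), 1000 * exp(-1.5), tolerance = 1e-9)
})

test_that("noiseless power data are recovered exactly by the power model", {
  x <- 1:8
  lx <- 1000 * x^(-1.3)
  fit <- fit_survivorship(lx, x, model = "power")
  expect_equal(fit$b, 1.3, tolerance = 1e-12)
  expect_equal(fit$N0, 1000, tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
})

test_that("log-scale fits agree with a normal-equations oracle on noisy data", {
  set.seed(51)
  for (rep in 1:10) {
    x <- 1:10
    lx <- 800 * exp(-0.3 * x + rnorm(10, 0, 0.2))
    fe <- fit_survivorship(lx, x)
    oe <- ols_oracle(x, log(lx))
    expect_equal(fe$b, -oe$slope, tolerance = 1e-10)
    expect_equal(fe$N0, exp(oe$intercept), tolerance = 1e-8)
    expect_equal(fe$r.squared, oe$r2, tolerance = 1e-10)
    expect_equal(fe$f.statistic, 8 * oe$r2 / (1 - oe$r2), tolerance = 1e-8)
    fp <- fit_survivorship(lx, x, model = "power")
    op <- ols_oracle(log(x), log(lx))
    expect_equal(fp$b, -op$slope, tolerance = 1e-10)
  }
})

test_that("fit preconditions are enforced", {
  expect_error(fit_survivorship(c(10, 5)), "at least 3")
  expect_error(fit_survivorship(c(10, 5, 0)), "positive")
  expect_error(fit_survivorship(c(10, 5, 2), x = c(0, 1, 2), model = "power"),
               ">= 1")
})

test_that("Deevey classification picks the generating curve shape", {
  x <- 1:8
  lt <- static_life_table(focal_age_counts())
  cls <- classify_deevey(lx = lt)
  expect_equal(cls$best_model, "exponential")
  expect_equal(cls$deevey_type, "II")

  pure_power <- classify_deevey(lx = 1000 * x^(-1))
  expect_equal(pure_power$deevey_type, "III")

  # tie (flat series fits both perfectly) resolves to exponential
  flat <- classify_deevey(lx = rep(500, 8))
  expect_equal(flat$best_model, "exponential")

  expect_error(
    classify_deevey(fit_survivorship(1000 * exp(-0.4 * x)),
                    fit_survivorship(1000 * (1:6)^(-1), model = "power")),
    "same data")
})

test_that("classification recovers the generating model in simulation", {
  # moderate replicate count keeps the suite quick; the acceptance test
  # exercises the full parameter-recovery criterion
  correct_exp <- correct_pow <- 0
  n_rep <- 40
  for (i in 1:n_rep) {
    a_exp <- generate_from_survivorship(2e4, 0.5, "exponential", seed = 1000 + i)
    if (classify_deevey(lx = as.numeric(a_exp))$best_model == "exponential")
      correct_exp <- correct_exp + 1
    a_pow <- generate_from_survivorship(2e4, 1.6, "power", seed = 2000 + i)
    if (classify_deevey(lx = as.numeric(a_pow))$best_model == "power")
      correct_pow <- correct_pow + 1
  }
  expect_gte(correct_exp / n_rep, 0.9)
  expect_gte(correct_pow / n_rep, 0.9)
})

test_that("survival functions match hand products and the telescoping identity", {
  lt <- static_life_table(focal_age_counts())
  sf <- survival_functions(lt)
  # hand product: S(4) = 0.9412 * 1 * 0.875 * 0.5 = l_5 / l_1
  expect_equal(sf$S_cum[4], prod(lt$S[1:4]), tolerance = 1e-12)
  expect_equal(sf$S_cum[4], lt$l[5] / lt$l[1], tolerance = 1e-12)
  expect_equal(sf$lambda[4], 2 * (1 - sf$S_cum[4]) / (1 + sf$S_cum[4]),
               tolerance = 1e-12)
  expect_equal(round(sf$S_cum[4], 4), 0.4118)
  expect_equal(round(sf$lambda[4], 4), 0.8333)
  # identity S(i) = l_{i+1}/l_1 across all classes, and F + S = 1
  expect_equal(sf$S_cum, lt$l[-1] / lt$l[1], tolerance = 1e-12)
  expect_equal(sf$F + sf$S_cum, rep(1, nrow(sf)), tolerance = 1e-12)
  # mortality density telescopes back to cumulative mortality
  expect_equal(cumsum(sf$f) * attr(sf, "h"), sf$F, tolerance = 1e-12)
})

test_that("an immortal cohort yields flat unit survival and zero hazard", {
  sf <- survival_functions(rep(1, 5))
  expect_equal(sf$S_cum, rep(1, 5))
  expect_equal(sf$F, rep(0, 5))
  expect_equal(sf$f, rep(0, 5))
  expect_equal(sf$lambda, rep(0, 5))
})

test_that("per-class mode and interval scaling behave as documented", {
  lt <- static_life_table(focal_age_counts())
  pc <- survival_functions(lt, mode = "per_class")
  expect_equal(pc$F, 1 - pc$S_x, tolerance = 1e-12)
  expect_equal(pc$lambda, 2 * (1 - pc$S_x) / (1 + pc$S_x), tolerance = 1e-12)
  # doubling the class interval halves density and hazard
  h2 <- survival_functions(lt, h = 2)
  h1 <- survival_functions(lt, h = 1)
  expect_equal(h2$f, h1$f / 2, tolerance = 1e-12)
  expect_equal(h2$lambda, h1$lambda / 2, tolerance = 1e-12)
  expect_error(survival_functions(lt, h = 0), "> 0")
})

test_that("monotone tables keep f and lambda non-negative and S non-increasing", {
  set.seed(61)
  for (rep in 1:10) {
    A <- sort(rpois(8, 400) + 1, decreasing = TRUE)
    sf <- survival_functions(static_life_table(A))
    expect_true(all(diff(sf$S_cum) <= 1e-12))
    expect_true(all(sf$f >= -1e-12))
    expect_true(all(sf$lambda >= -1e-12))
  }
})
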