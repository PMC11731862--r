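test_that("fit_ols matches textbook closed forms", {
  # constant outcome: intercept 3, zero residual SE
  df <- data.frame(y = rep(3, 6), x = rnorm(6))
  f <- fit_ols(df, "y", "x")
  expect_equal(unname(f$coefficients["(Intercept)"]), 3, tolerance = 1e-12)
  expect_equal(unname(f$standard_errors), c(0, 0), tolerance = 1e-10)
  # hand-solved normal equations: x=(0,1,2), y=(1,3,5) -> y = 1 + 2x
  df2 <- data.frame(y = c(1, 3, 5), x = c(0, 1, 2))
  f2 <- fit_ols(df2, "y", "x")
  expect_equal(unname(f2$coefficients), c(1, 2), tolerance = 1e-12)
  # intercept-only model estimates the sample mean
  df3 <- data.frame(y = c(2, 4, 9, 1))
  f3 <- fit_ols(df3, "y", character(0))
  expect_equal(unname(f3$coefficients), mean(df3$y), tolerance = 1e-12)
  # classical SEs agree with stats::lm
  set.seed(4)
  df4 <- data.frame(y = rnorm(50), x = rnorm(50), g = factor(sample(letters[1:3], 50, TRUE)))
  f4 <- fit_ols(df4, "y", c("x", "g"))
  lm4 <- stats::lm(y ~ x + g, df4)
  expect_equal(unname(f4$coefficients), unname(stats::coef(lm4)),
               tolerance = 1e-10)
  expect_equal(unname(f4$standard_errors),
               unname(sqrt(diag(stats::vcov(lm4)))), tolerance = 1e-10)
  expect_equal(f4$aic, stats::AIC(lm4), tolerance = 1e-8)
  expect_equal(f4$bic, stats::BIC(lm4), tolerance = 1e-8)
})

test_that("fit_logistic matches the 2x2 closed form", {
  # balanced outcome, intercept-only -> logit(0.5) = 0
  df0 <- data.frame(y = rep(c(0, 1), 10))
  f0 <- fit_logistic(df0, "y", character(0))
  expect_equal(unname(f0$coefficients), 0, tolerance = 1e-8)
  # saturated 2x2 with counts (a,b,c,d) = (10,20,30,40):
  # slope = ln(ad/bc), intercept = ln(c/d)
  df <- data.frame(
    x = c(rep(1, 30), rep(0, 70)),
    y = c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40)))
  f <- fit_logistic(df, "y", "x")
  expect_equal(unname(f$coefficients["x"]), log(10 * 40 / (20 * 30)),
               tolerance = 1e-7)
  expect_equal(unname(f$coefficients["(Intercept)"]), log(30 / 40),
               tolerance = 1e-7)
  # constant predictor -> singular design
  dfc <- data.frame(y = rep(c(0, 1), 10), x = 1)
  expect_error(fit_logistic(dfc, "y", "x"), "collinear")
  # single-class outcome -> separation error
  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)),
                            "y", "x"), "separation")
})

test_that("fit_negbin recovers the score identity and flags boundaries", {
  # intercept-only NB: exp(intercept) = sample mean (score equation at MLE)
  set.seed(21)
  y <- rnbinom(500, size = 1, mu = 3)
  df <- data.frame(y = y)
  f <- fit_negbin(df, "y", character(0))
  expect_equal(exp(unname(f$coefficients["(Intercept)"])), mean(y),
               tolerance = 1e-6)
  expect_true(is.finite(f$lnalpha))
  # equidispersed (Poisson) data: dispersion collapses to the boundary
  set.seed(22)
  dfp <- data.frame(y = rpois(2000, 4))
  fp <- fit_negbin(dfp, "y", character(0))
  expect_true(fp$boundary || fp$lnalpha < -5)
})

test_that("select_count_family picks by AIC and BIC", {
  set.seed(31)
  n <- 2000
  x <- rnorm(n)
  # strongly overdispersed: negbin wins on both criteria
  y_nb <- rnbinom(n, size = 0.4, mu = exp(1 + 0.3 * x))
  sel <- select_count_family(data.frame(y = y_nb, x = x), "y", "x")
  expect_equal(sel$recommendation, "negbin")
  expect_lt(sel$criteria$aic[2], sel$criteria$aic[1])
  expect_lt(sel$criteria$bic[2], sel$criteria$bic[1])
  # Poisson data at large n: BIC's heavier penalty prefers Poisson
  y_p <- rpois(n, exp(1 + 0.3 * x))
  selp <- select_count_family(data.frame(y = y_p, x = x), "y", "x")
  expect_equal(selp$by_bic, "poisson")
  # BIC >= AIC whenever ln(n) >= 2
  expect_true(all(selp$criteria$bic >= selp$criteria$aic))
  expect_true(all(sel$criteria$bic >= sel$criteria$aic))
})

test_that("pool_rubin reproduces the combining rules by hand", {
  mk <- function(est) fake_reg(c(b = est), se = sqrt(0.5), n = 100)
  pooled <- pool_rubin(list(mk(1), mk(2), mk(3)))
  expect_equal(unname(pooled$q_bar), 2)
  expect_equal(unname(pooled$W), 0.5)
  expect_equal(unname(pooled$B_var), 1)
  expect_equal(unname(pooled$T_var), 11 / 6, tolerance = 1e-12)
  # identical results across m: B = 0, T = W, finite df
  same <- pool_rubin(list(mk(2), mk(2), mk(2)))
  expect_equal(unname(same$B_var), 0)
  expect_equal(unname(same$T_var), unname(same$W))
  expect_true(is.finite(same$df) && same$df > 0)
  # name mismatch
  other <- fake_reg(c(z = 1), se = 1)
  expect_error(pool_rubin(list(mk(1), other)), "alignment error")
})

test_that("pooled total variance dominates within-imputation variance", {
  set.seed(41)
  for (rep in 1:20) {
    m <- sample(2:6, 1)
    k <- sample(1:4, 1)
    nms <- paste0("b", seq_len(k))
    fits <- lapply(seq_len(m), function(i) {
      fake_reg(stats::setNames(rnorm(k), nms),
               se = sqrt(stats::runif(k, 0.1, 2)), n = 50)
    })
    pooled <- pool_rubin(fits)
    expect_true(all(pooled$T_var >= pooled$W - 1e-12))
    expect_true(all(pooled$B_var >= 0))
    expect_true(all(pooled$df > 0))
  }
})

test_that("each family recovers its own generative coefficients (coverage)", {
  # 95% CI coverage within [90%, 99%] over replicates of each family
  set.seed(51)
  n <- 5000
  reps <- 200
  cover <- matrix(NA, reps, 3,
                  dimnames = list(NULL, c("ols", "logistic", "negbin")))
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    dfo <- data.frame(y = 1 + 0.5 * x + rnorm(n, 0, 2), x = x)
    fo <- fit_ols(dfo, "y", "x")
    ci <- fo$coefficients["x"] + c(-1, 1) * 1.96 * fo$standard_errors["x"]
    cover[r, "ols"] <- ci[1] <= 0.5 && 0.5 <= ci[2]
    dfl <- data.frame(y = rbinom(n, 1, plogis(-0.5 + 0.8 * x)), x = x)
    fl <- fit_logistic(dfl, "y", "x")
    ci <- fl$coefficients["x"] + c(-1, 1) * 1.96 * fl$standard_errors["x"]
    cover[r, "logistic"] <- ci[1] <= 0.8 && 0.8 <= ci[2]
    dfn <- data.frame(y = rnbinom(n, size = 1 / 2, mu = exp(0.8 + 0.4 * x)),
                      x = x)
    fn <- fit_negbin(dfn, "y", "x")
    ci <- fn$coefficients["x"] + c(-1, 1) * 1.96 * fn$standard_errors["x"]
    cover[r, "negbin"] <- ci[1] <= 0.4 && 0.4 <= ci[2]
  }
  rate <- colMeans(cover)
  expect_true(all(rate >= 0.90 & rate <= 0.99),
              label = paste(rate, collapse = " "))
})
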