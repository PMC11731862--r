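test_that("fit_conditional matches closed forms and flags degeneracies", {
  # exact line: slope 2, zero residual variance
  x <- c(1, 2, 3, 4, 5)
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fit_conditional(2 * x, X, "bayes_linear")
  expect_equal(unname(f$beta), c(0, 2), tolerance = 1e-10)
  expect_equal(f$sigma2, 0, tolerance = 1e-16)
  # hand-solved normal equations on 3 points (plus 2 for the n >= p+2 guard)
  x3 <- c(0, 1, 2, 3, 4)
  f3 <- fit_conditional(x3, cbind("(Intercept)" = 1, x = x3), "bayes_linear")
  expect_equal(unname(f3$beta), c(0, 1), tolerance = 1e-12)
  # logistic with a single observed class is a separation error
  expect_error(
    fit_conditional(rep(1, 10), cbind("(Intercept)" = rep(1, 10), x = rnorm(10)),
                    "logistic"),
    "separation")
  # collinear design names the offending column
  Xs <- cbind("(Intercept)" = 1, a = x, b = 2 * x)
  expect_error(fit_conditional(2 * x, Xs, "bayes_linear"), "collinear.*b")
  # too few rows
  expect_error(fit_conditional(1:3, cbind("(Intercept)" = 1, x = 1:3),
                               "bayes_linear"), "too few")
})

test_that("draw_parameters has the advertised sampling distribution", {
  set.seed(42)
  n <- 60
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n, 0, 1.5)
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fit_conditional(y, X, "bayes_linear")
  # degenerate posterior: zero residual variance collapses to the estimate
  f0 <- fit_conditional(2 * x, X, "bayes_linear")
  set.seed(1)
  d0 <- draw_parameters(f0)
  expect_identical(unname(d0$beta_star), unname(f0$beta))
  # fixed rng state reproduces the draw
  set.seed(7); d1 <- draw_parameters(f)
  set.seed(7); d2 <- draw_parameters(f)
  expect_identical(d1$beta_star, d2$beta_star)
  expect_identical(d1$sigma2_star, d2$sigma2_star)
  # MC check: empirical covariance of beta* ~ sigma2hat (X'X)^-1 within 15%.
  # (t-inflation from the sigma2 draw at df = 58 is ~3.5%, inside the band.)
  set.seed(123)
  draws <- t(replicate(2000, draw_parameters(f)$beta_star))
  target <- f$sigma2 * f$cov_unscaled
  emp <- stats::cov(draws)
  expect_true(all(abs(emp - target) <= 0.15 * max(abs(target))))
  expect_lt(max(abs(colMeans(draws) - f$beta)), 0.1)
})

test_that("impute_from_conditional respects each family's support", {
  set.seed(5)
  n <- 50
  x <- rnorm(n)
  y <- round(rnorm(n, 10 + x), 2)
  X <- cbind("(Intercept)" = 1, x = x)
  # zero rows to impute -> empty output
  f <- fit_conditional(y, X, "bayes_linear")
  set.seed(1); phi <- draw_parameters(f)
  expect_length(impute_from_conditional(phi, X[0, , drop = FALSE]), 0)
  # pmm draws live in the observed support
  fp <- fit_conditional(y, X, "pmm")
  set.seed(2); phip <- draw_parameters(fp)
  Xmis <- cbind("(Intercept)" = 1, x = rnorm(200))
  vals <- impute_from_conditional(phip, Xmis, pmm_k = 5)
  expect_true(all(vals %in% y))
  expect_error(impute_from_conditional(phip, Xmis, pmm_k = 51), "donor-pool")
  # logistic imputation frequency matches the linear predictor
  phi_b <- structure(list(family = "logistic",
                          beta_star = c("(Intercept)" = qlogis(0.3), x = 0),
                          design_names = c("(Intercept)", "x")),
                     class = "la_phi")
  Xb <- cbind("(Intercept)" = rep(1, 1e4), x = rnorm(1e4))
  set.seed(3)
  vb <- impute_from_conditional(phi_b, Xb)
  expect_lt(abs(mean(vb) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("the multinomial conditional fits and imputes sanely", {
  set.seed(11)
  n <- 600
  x <- rnorm(n)
  # data from a known baseline-category logit
  eta2 <- 0.5 + 1 * x
  eta3 <- -0.5 - 1 * x
  den <- 1 + exp(eta2) + exp(eta3)
  u <- runif(n)
  p1 <- 1 / den; p2 <- exp(eta2) / den
  y <- ifelse(u < p1, "p", ifelse(u < p1 + p2, "q", "r"))
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fit_conditional(factor(y, levels = c("p", "q", "r")), X, "multinomial")
  expect_equal(unname(f$beta[c("q:(Intercept)", "q:x")]), c(0.5, 1),
               tolerance = 0.35)
  expect_equal(unname(f$beta[c("r:(Intercept)", "r:x")]), c(-0.5, -1),
               tolerance = 0.35)
  set.seed(12); phi <- draw_parameters(f)
  vals <- impute_from_conditional(phi, X)
  expect_true(all(vals %in% c("p", "q", "r")))
  # imputed class frequencies track the observed ones
  expect_lt(max(abs(prop.table(table(factor(vals, levels = c("p", "q", "r")))) -
                    prop.table(table(factor(y, levels = c("p", "q", "r")))))),
            0.06)
})

test_that("run_mice is the identity on complete data", {
  tab <- toy_table(20)
  out <- run_mice(tab, m = 3, maxit = 2, seed = 1)
  expect_length(out$datasets, 3)
  for (d in out$datasets) expect_identical(d, tab$data)
})

test_that("run_mice preserves observed cells, completes, and varies across m", {
  set.seed(200)
  n <- 200
  df <- data.frame(z = rnorm(n, 10, 2),
                   w = rnorm(n, 0, 1))
  df$z[sample(n, 80)] <- NA
  schema <- variable_schema(schema_variable("z", "continuous"),
                            schema_variable("w", "continuous"))
  tab <- harmonized_table(df, schema)
  out <- run_mice(tab, m = 4, maxit = 3, seed = 9)
  obs <- which(!is.na(df$z))
  for (d in out$datasets) {
    expect_false(anyNA(d))                       # completeness
    expect_identical(d$z[obs], df$z[obs])        # observed-cell preservation
    expect_identical(d$w, df$w)
  }
  # between-imputation variability: some imputed cell differs
  mis <- which(is.na(df$z))
  expect_true(any(out$datasets[[1]]$z[mis] != out$datasets[[2]]$z[mis]))
  # seed contract
  out2 <- run_mice(tab, m = 4, maxit = 3, seed = 9)
  expect_identical(out$datasets, out2$datasets)
  out3 <- run_mice(tab, m = 4, maxit = 3, seed = 10)
  expect_false(identical(out$datasets, out3$datasets))
  # diagnostics cover every (imputation, iteration)
  expect_equal(nrow(out$diagnostics), 4 * 3)
})

test_that("MCAR imputation reproduces the generating distribution", {
  # 50% MCAR from N(10, 4): imputed-value mean within 3 MC SEs of 10
  set.seed(77)
  n <- 400
  df <- data.frame(z = rnorm(n, 10, 2), w = rnorm(n))
  mis <- sample(n, n / 2)
  df$z[mis] <- NA
  tab <- harmonized_table(df, variable_schema(
    schema_variable("z", "continuous"), schema_variable("w", "continuous")))
  out <- run_mice(tab, m = 20, maxit = 2, seed = 5)
  imp <- unlist(lapply(out$datasets, function(d) d$z[mis]))
  se <- 2 / sqrt(length(mis))                    # between-m dependence ignored;
  expect_lt(abs(mean(imp) - 10), 3 * se * 2)     # doubled to stay honest
  expect_lt(abs(stats::sd(imp) - 2), 0.4)
})

test_that("with one incomplete variable, T does not change the distribution", {
  # p = 1: each sweep refits on the same observed rows, so T = 1 and T = 10
  # draws are equal in distribution; compare means over replicates
  set.seed(55)
  n <- 120
  df <- data.frame(z = rnorm(n, 4, 1), w = rnorm(n))
  mis <- sample(n, 40)
  df$z[mis] <- NA
  tab <- harmonized_table(df, variable_schema(
    schema_variable("z", "continuous"), schema_variable("w", "continuous")))
  means_for <- function(T, seeds) {
    vapply(seeds, function(s) {
      out <- run_mice(tab, m = 1, maxit = T, seed = s)
      mean(out$datasets[[1]]$z[mis])
    }, numeric(1))
  }
  m1 <- means_for(1, 1:60)
  m10 <- means_for(10, 61:120)
  pooled_se <- sqrt(stats::var(m1) / 60 + stats::var(m10) / 60)
  expect_lt(abs(mean(m1) - mean(m10)), 4 * pooled_se)
})

test_that("run_mice validates its inputs", {
  df <- data.frame(z = c(1, NA, 3), w = 1:3)
  tab <- harmonized_table(df, variable_schema(
    schema_variable("z", "continuous"), schema_variable("w", "continuous")))
  expect_error(run_mice(tab, specs = list(), m = 2, maxit = 1, seed = 1),
               "without a conditional spec")
  expect_error(conditional_spec("z", "bayes_linear", c("z", "w")),
               "cannot predict itself")
  # errors are annotated with variable and iteration
  expect_error(run_mice(tab, m = 2, maxit = 1, seed = 1),
               "imputation failed for variable 'z'")
})
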