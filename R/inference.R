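# Validation regressions (OLS / logistic / NB2) over the package's
# reference-coded design, plus Rubin's-rules pooling across imputations.

as_analysis_frame <- function(table) {
  if (inherits(table, "la_table")) table$data else as.data.frame(table)
}

new_reg <- function(family, beta, se, vcov, n, loglik, aic, bic,
                    lnalpha = NA_real_, se_lnalpha = NA_real_,
                    boundary = FALSE) {
  structure(list(family = family, coefficients = beta,
                 standard_errors = stats::setNames(se, names(beta)),
                 vcov = vcov, n = n, loglik = loglik, aic = aic, bic = bic,
                 lnalpha = lnalpha, se_lnalpha = se_lnalpha,
                 boundary = boundary),
            class = "la_reg")
}

#' @export
print.la_reg <- function(x, ...) {
  z <- x$coefficients / x$standard_errors
  p <- 2 * stats::pnorm(-abs(z))
  df <- data.frame(estimate = round(x$coefficients, 4),
                   se = round(x$standard_errors, 4),
                   stars = significance_stars(p))
  cat("<", x$family, " fit> n=", x$n, ", aic=", round(x$aic, 1), "\n", sep = "")
  print(df)
  invisible(x)
}

#' Ordinary least squares with classical standard errors
#'
#' @param table a `la_table` or data frame.
#' @param outcome continuous outcome variable.
#' @param predictors character vector of predictor variables (categoricals
#'   enter as reference-coded dummies).
#' @return a `la_reg`.
#' @export
fit_ols <- function(table, outcome, predictors) {
  df <- as_analysis_frame(table)
  y <- as.numeric(df[[outcome]])
  X <- build_design(df, predictors)
  check_design(X, n_min = ncol(X) + 1)
  q <- qr(X)
  beta <- stats::setNames(qr.coef(q, y), colnames(X))
  res <- y - as.numeric(X %*% beta)
  n <- length(y); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  cov_unscaled <- chol2inv(qr.R(q))
  V <- s2 * cov_unscaled
  dimnames(V) <- list(colnames(X), colnames(X))
  s2_mle <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi * s2_mle) + 1)
  k <- p + 1  # + residual variance
  new_reg("ols", beta, sqrt(pmax(diag(V), 0)), V, n, ll,
          aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k)
}

#' Logistic regression (IRLS maximum likelihood)
#'
#' @inheritParams fit_ols
#' @param outcome binary outcome (0/1 or 2-level factor); both classes must
#'   be present.
#' @export
fit_logistic <- function(table, outcome, predictors) {
  df <- as_analysis_frame(table)
  y <- binarize(df[[outcome]])
  if (length(unique(y)) < 2) {
    stop("separation error: outcome has a single class", call. = FALSE)
  }
  X <- build_design(df, predictors)
  check_design(X, n_min = ncol(X) + 1)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- stats::setNames(fit$coefficients, colnames(X))
  if (!fit$converged || any(abs(beta) > 25)) {
    stop("separation error: logistic fit diverged", call. = FALSE)
  }
  V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  dimnames(V) <- list(colnames(X), colnames(X))
  n <- length(y); p <- ncol(X)
  ll <- -fit$deviance / 2
  new_reg("logistic", beta, sqrt(diag(V)), V, n, ll,
          aic = -2 * ll + 2 * p, bic = -2 * ll + log(n) * p)
}

#' Negative-binomial (NB2) regression
#'
#' Variance `mu + alpha mu^2`; the dispersion is reported as
#' `lnalpha = log(alpha)` with a delta-method SE. Effectively equidispersed
#' fits (alpha ~ 0) are flagged `boundary` with `lnalpha = -Inf`.
#'
#' @inheritParams fit_ols
#' @param outcome non-negative integer count outcome.
#' @export
fit_negbin <- function(table, outcome, predictors) {
  df <- as_analysis_frame(table)
  y <- as.numeric(df[[outcome]])
  if (any(is.na(y)) || any(y < 0 | y != round(y))) {
    stop("count outcome must be non-negative integers", call. = FALSE)
  }
  X <- build_design(df, predictors)
  check_design(X, n_min = ncol(X) + 2)
  nb <- fit_negbin_matrix(y, X)
  V <- nb$vcov
  lnalpha <- if (nb$boundary) -Inf else nb$lnalpha
  new_reg("negbin", nb$beta, sqrt(diag(V)), V, length(y), nb$loglik,
          aic = nb$aic, bic = nb$bic, lnalpha = lnalpha,
          se_lnalpha = nb$se_lnalpha, boundary = nb$boundary)
}

#' Poisson regression (for count-family comparison)
#' @inheritParams fit_negbin
#' @export
fit_poisson <- function(table, outcome, predictors) {
  df <- as_analysis_frame(table)
  y <- as.numeric(df[[outcome]])
  X <- build_design(df, predictors)
  check_design(X, n_min = ncol(X) + 1)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  if (!fit$converged) stop("convergence error in Poisson fit", call. = FALSE)
  beta <- stats::setNames(fit$coefficients, colnames(X))
  V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  dimnames(V) <- list(colnames(X), colnames(X))
  n <- length(y); p <- ncol(X)
  ll <- sum(stats::dpois(y, exp(as.numeric(X %*% beta)), log = TRUE))
  new_reg("poisson", beta, sqrt(diag(V)), V, n, ll,
          aic = -2 * ll + 2 * p, bic = -2 * ll + log(n) * p)
}

#' Choose between Poisson and negative binomial for a count outcome
#'
#' Fits both and recommends the family with the lower AIC and lower BIC;
#' when the two criteria disagree the recommendation is `"disagreement"`.
#'
#' @inheritParams fit_negbin
#' @return list with `recommendation`, `criteria` (AIC/BIC table) and the two
#'   fits.
#' @export
select_count_family <- function(table, outcome, predictors) {
  pois <- fit_poisson(table, outcome, predictors)
  nb <- fit_negbin(table, outcome, predictors)
  criteria <- data.frame(family = c("poisson", "negbin"),
                         aic = c(pois$aic, nb$aic),
                         bic = c(pois$bic, nb$bic),
                         loglik = c(pois$loglik, nb$loglik))
  by_aic <- criteria$family[which.min(criteria$aic)]
  by_bic <- criteria$family[which.min(criteria$bic)]
  rec <- if (identical(by_aic, by_bic)) by_aic else "disagreement"
  list(recommendation = rec, by_aic = by_aic, by_bic = by_bic,
       criteria = criteria, poisson = pois, negbin = nb)
}

#' Pool regression results across imputations by Rubin's rules
#'
#' Pooled estimate `q_bar` = mean; within-variance `W` = mean squared SE;
#' between-variance `B` = sample variance of estimates; total variance
#' `T = W + (1 + 1/m) B`. Inference uses the t reference with Barnard-Rubin
#' small-sample degrees of freedom. When every fit carries a finite
#' `lnalpha`, the dispersion is pooled as an additional `lnalpha` row.
#'
#' @param results list of `la_reg` with identical coefficient names (m >= 2).
#' @return a `la_pool` with fields `q_bar`, `W`, `B_var`, `T_var`, `se`,
#'   `df`, `p`, `stars`, `m`, `n`.
#' @export
pool_rubin <- function(results) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1), "la_reg")))
  m <- length(results)
  nms <- names(results[[1]]$coefficients)
  for (r in results[-1]) {
    if (!identical(names(r$coefficients), nms)) {
      stop("alignment error: coefficient names differ across imputations",
           call. = FALSE)
    }
  }
  Q <- do.call(rbind, lapply(results, `[[`, "coefficients"))
  U <- do.call(rbind, lapply(results, function(r) r$standard_errors^2))
  colnames(Q) <- colnames(U) <- nms
  if (all(vapply(results, function(r) is.finite(r$lnalpha), logical(1)))) {
    Q <- cbind(Q, lnalpha = vapply(results, `[[`, numeric(1), "lnalpha"))
    U <- cbind(U, lnalpha = vapply(results, `[[`, numeric(1), "se_lnalpha")^2)
    nms <- c(nms, "lnalpha")
  }
  q_bar <- colMeans(Q)
  W <- colMeans(U)
  B <- apply(Q, 2, stats::var)
  T_var <- W + (1 + 1 / m) * B
  n <- mean(vapply(results, `[[`, numeric(1), "n"))
  k <- length(results[[1]]$coefficients)
  nu_com <- max(n - k, 1)
  lambda <- (1 + 1 / m) * B / T_var        # fraction of missing information
  lambda[T_var == 0] <- 0
  nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
  nu_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  df <- ifelse(is.infinite(nu_old), nu_obs,
               nu_old * nu_obs / (nu_old + nu_obs))
  se <- sqrt(T_var)
  tstat <- ifelse(se > 0, q_bar / se, Inf * sign(q_bar))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(q_bar = q_bar, W = W, B_var = B, T_var = T_var, se = se,
                 df = df, p = p, stars = significance_stars(p),
                 m = m, n = n, family = results[[1]]$family),
            class = "la_pool")
}

#' @export
print.la_pool <- function(x, ...) {
  df <- data.frame(estimate = round(x$q_bar, 4), se = round(x$se, 4),
                   df = round(x$df, 1), p = signif(x$p, 3), stars = x$stars)
  cat("<pooled ", x$family, " fit> m=", x$m, ", n=", x$n, "\n", sep = "")
  print(df)
  invisible(x)
}

#' Fit and pool a regression over a fused result's datasets
#'
#' @param fused a `la_fused` (or `la_mids`).
#' @param outcome,predictors model specification.
#' @param family `"ols"`, `"logistic"` or `"negbin"`.
#' @return a `la_pool`; attribute `"fits"` holds the per-imputation `la_reg`s.
#' @export
analyze_fused <- function(fused, outcome, predictors,
                          family = c("ols", "logistic", "negbin")) {
  family <- match.arg(family)
  fitter <- switch(family, ols = fit_ols, logistic = fit_logistic,
                   negbin = fit_negbin)
  fits <- lapply(fused$datasets, fitter, outcome = outcome,
                 predictors = predictors)
  out <- pool_rubin(fits)
  attr(out, "fits") <- fits
  out
}

#' Serialize a regression or pooled result to a data frame
#'
#' One row per coefficient: estimate, SE, df, p, stars.
#' @param x a `la_reg` or `la_pool`.
#' @export
result_frame <- function(x) {
  if (inherits(x, "la_pool")) {
    data.frame(term = names(x$q_bar), estimate = unname(x$q_bar),
               se = unname(x$se), df = unname(x$df), p = unname(x$p),
               stars = unname(x$stars), stringsAsFactors = FALSE)
  } else if (inherits(x, "la_reg")) {
    est <- x$coefficients; se <- x$standard_errors
    if (is.finite(x$lnalpha)) {
      est <- c(est, lnalpha = x$lnalpha)
      se <- c(se, lnalpha = x$se_lnalpha)
    }
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(term = names(est), estimate = unname(est), se = unname(se),
               df = NA_real_, p = unname(p),
               stars = significance_stars(p), stringsAsFactors = FALSE)
  } else stop("unsupported result type", call. = FALSE)
}
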