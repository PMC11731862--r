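# Chained-equations multiple imputation by fully conditional specification:
# each incomplete variable X_j gets a univariate conditional model g_j given
# the other (currently completed) variables; each Gibbs sweep refits g_j on
# the observed rows, draws the model parameters phi_j from their approximate
# posterior (proper imputation), and redraws the missing cells. After T
# sweeps one completed dataset is emitted; the cycle repeats m times.

#' Specify the conditional imputation model for one variable
#'
#' @param variable the incomplete variable the model imputes.
#' @param family one of `"bayes_linear"`, `"logistic"`, `"multinomial"`,
#'   `"pmm"`, `"negbin_draw"`.
#' @param predictors other variables entering the prediction equation.
#' @param pmm_k donor-pool size for predictive mean matching.
#' @return a `la_spec`.
#' @export
conditional_spec <- function(variable, family, predictors, pmm_k = 5L) {
  family <- match.arg(family, c("bayes_linear", "logistic", "multinomial",
                                "pmm", "negbin_draw"))
  if (variable %in% predictors) {
    stop("variable '", variable, "' cannot predict itself", call. = FALSE)
  }
  stopifnot(pmm_k >= 1)
  structure(list(variable = variable, family = family,
                 predictors = predictors, pmm_k = as.integer(pmm_k)),
            class = "la_spec")
}

# default conditional family for a schema family
default_conditional_family <- function(schema_family) {
  switch(schema_family,
         continuous = "bayes_linear",
         binary = "logistic",
         categorical = "multinomial",
         count = "negbin_draw",
         stop("no conditional family for schema family ", schema_family))
}

check_design <- function(X, n_min) {
  if (nrow(X) < n_min) {
    stop("too few observed rows (", nrow(X), ") for ", ncol(X),
         " predictors", call. = FALSE)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(q)
}

# baseline-category multinomial logit MLE (BFGS, analytic gradient,
# covariance from the numerical Hessian at the optimum)
fit_multinomial_logit <- function(y, X, maxit = 200) {
  f <- droplevels(factor(y))
  levs <- levels(f)
  K <- length(levs)
  if (K < 2) stop("separation error: outcome has a single observed class",
                  call. = FALSE)
  p <- ncol(X)
  Y <- outer(as.integer(f), seq_len(K), `==`) * 1   # n x K indicator
  nll <- function(theta) {
    Th <- matrix(theta, p, K - 1)
    eta <- cbind(0, X %*% Th)
    eta <- eta - apply(eta, 1, max)
    -sum(rowSums(Y * eta) - log(rowSums(exp(eta))))
  }
  grad <- function(theta) {
    Th <- matrix(theta, p, K - 1)
    eta <- cbind(0, X %*% Th)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta); P <- P / rowSums(P)
    G <- t(X) %*% (P[, -1, drop = FALSE] - Y[, -1, drop = FALSE])
    as.numeric(G)
  }
  o <- stats::optim(rep(0, p * (K - 1)), nll, grad, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-12))
  if (o$convergence != 0) {
    stop("convergence error: multinomial fit did not converge", call. = FALSE)
  }
  if (max(abs(o$par)) > 25) {
    stop("separation error: multinomial coefficients diverged", call. = FALSE)
  }
  H <- stats::optimHess(o$par, nll, grad)
  V <- tryCatch(solve(H), error = function(e) {
    stop("numerical error: multinomial information matrix is singular",
         call. = FALSE)
  })
  nms <- as.vector(outer(colnames(X), levs[-1], function(a, b) paste0(b, ":", a)))
  list(beta = stats::setNames(o$par, nms), vcov = V, levels = levs,
       loglik = -o$value)
}

#' Fit a univariate conditional model on the observed rows
#'
#' `bayes_linear` uses least squares (coefficients, residual variance and the
#' unscaled covariance `(X'X)^-1`); the likelihood families return the MLE
#' with inverse-Hessian covariance.
#'
#' @param y_observed outcome values on rows where the variable is observed.
#' @param X_observed design matrix (including intercept) on those rows.
#' @param family conditional family, see [conditional_spec()].
#' @return a `la_fit_conditional` carrying the estimates and everything
#'   [draw_parameters()] needs.
#' @export
fit_conditional <- function(y_observed, X_observed, family) {
  family <- match.arg(family, c("bayes_linear", "logistic", "multinomial",
                                "pmm", "negbin_draw"))
  X <- as.matrix(X_observed)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_design(X, n_min = ncol(X) + 2)
  out <- switch(family,
    bayes_linear = ,
    pmm = {
      y <- as.numeric(y_observed)
      q <- qr(X)
      beta <- stats::setNames(qr.coef(q, y), colnames(X))
      res <- y - as.numeric(X %*% beta)
      df <- length(y) - ncol(X)
      sigma2 <- if (df > 0) sum(res^2) / df else 0
      R <- qr.R(q)
      cov_unscaled <- chol2inv(R)
      dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
      list(beta = beta, sigma2 = sigma2, df = df, cov_unscaled = cov_unscaled,
           y_obs = y, pred_obs = as.numeric(X %*% beta))
    },
    logistic = {
      y <- binarize(y_observed)
      if (length(unique(y)) < 2) {
        stop("separation error: outcome has a single observed class",
             call. = FALSE)
      }
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial())
      )
      beta <- stats::setNames(fit$coefficients, colnames(X))
      if (!fit$converged || any(abs(beta) > 25)) {
        stop("separation error: logistic fit diverged", call. = FALSE)
      }
      w <- fit$weights
      V <- chol2inv(chol(crossprod(X * sqrt(w))))
      dimnames(V) <- list(colnames(X), colnames(X))
      list(beta = beta, vcov = V)
    },
    multinomial = fit_multinomial_logit(y_observed, X),
    negbin_draw = {
      y <- as.numeric(y_observed)
      if (any(y < 0 | y != round(y))) {
        stop("negbin outcome must be non-negative integers", call. = FALSE)
      }
      nb <- fit_negbin_matrix(y, X)
      list(beta = nb$beta, vcov = nb$vcov, lnalpha = nb$lnalpha,
           se_lnalpha = nb$se_lnalpha)
    })
  structure(c(out, list(family = family, n = nrow(X), p = ncol(X),
                        design_names = colnames(X))),
            class = "la_fit_conditional")
}

# 0/1 coercion for binary outcomes (factor second level / logical / numeric)
binarize <- function(y) {
  if (is.factor(y)) return(as.integer(y) - 1L)
  if (is.logical(y)) return(as.integer(y))
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (!all(u %in% c(0, 1))) {
    stop("binary outcome must be coded 0/1 (or be a 2-level factor)",
         call. = FALSE)
  }
  as.integer(y)
}

# MASS::glm.nb over a design matrix, mapping names back to the design
fit_negbin_matrix <- function(y, X) {
  keep <- colnames(X) != "(Intercept)"
  dfr <- as.data.frame(X[, keep, drop = FALSE])
  safe <- paste0("V", seq_len(sum(keep)), recycle0 = TRUE)
  names(dfr) <- safe
  dfr$.y <- y
  fml <- if (sum(keep) == 0) .y ~ 1 else .y ~ .
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = dfr,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) {
      stop("convergence error in negative-binomial fit: ",
           conditionMessage(e), call. = FALSE)
    })
  beta <- fit$coefficients
  map <- c("(Intercept)", colnames(X)[keep])
  names(beta) <- map[match(names(beta), c("(Intercept)", safe))]
  beta <- beta[colnames(X)]
  V <- stats::vcov(fit)
  dimnames(V) <- list(map[match(rownames(V), c("(Intercept)", safe))],
                      map[match(colnames(V), c("(Intercept)", safe))])
  V <- V[colnames(X), colnames(X), drop = FALSE]
  theta <- fit$theta
  se_theta <- fit$SE.theta
  lnalpha <- -log(theta)
  # boundary: the fitted extra-dispersion factor alpha*mu is negligible, so
  # the variance is within 5% of Poisson and lnalpha is effectively -Inf
  boundary <- theta > 1e4 ||
    mean(stats::fitted(fit)) / theta < 0.05
  list(beta = beta, vcov = V, lnalpha = lnalpha,
       se_lnalpha = if (boundary) NA_real_ else se_theta / theta,
       theta = theta, boundary = boundary,
       loglik = as.numeric(stats::logLik(fit)),
       aic = stats::AIC(fit), bic = stats::BIC(fit), fit = fit)
}

#' Draw imputation-model parameters from their approximate posterior
#'
#' `bayes_linear`/`pmm`: exact normal-inverse-chi-square draw —
#' `sigma2* = RSS / chisq(df)`, `beta* ~ N(betahat, sigma2* (X'X)^-1)`.
#' Likelihood families: large-sample draw `beta* ~ N(betahat, Vhat)`;
#' `negbin_draw` additionally draws `lnalpha*` from its normal approximation.
#' A zero residual variance collapses the posterior to the estimate.
#'
#' Consumes the current R random stream; seed it through [run_mice()].
#'
#' @param fitted a `la_fit_conditional`.
#' @return a `la_phi` parameter draw.
#' @export
draw_parameters <- function(fitted) {
  stopifnot(inherits(fitted, "la_fit_conditional"))
  fam <- fitted$family
  phi <- if (fam %in% c("bayes_linear", "pmm")) {
    if (fitted$sigma2 <= 0) {
      list(beta_star = fitted$beta, sigma2_star = 0)
    } else {
      s2 <- fitted$sigma2 * fitted$df / stats::rchisq(1, fitted$df)
      R <- tryCatch(chol(fitted$cov_unscaled), error = function(e) {
        stop("numerical error: (X'X)^-1 not positive definite", call. = FALSE)
      })
      b <- fitted$beta + sqrt(s2) * as.numeric(t(R) %*% stats::rnorm(fitted$p))
      list(beta_star = stats::setNames(b, names(fitted$beta)), sigma2_star = s2)
    }
  } else {
    R <- tryCatch(chol(fitted$vcov), error = function(e) {
      stop("numerical error: parameter covariance not positive definite",
           call. = FALSE)
    })
    b <- fitted$beta + as.numeric(t(R) %*% stats::rnorm(length(fitted$beta)))
    out <- list(beta_star = stats::setNames(b, names(fitted$beta)))
    if (fam == "negbin_draw") {
      out$lnalpha_star <- if (is.na(fitted$se_lnalpha)) fitted$lnalpha else
        stats::rnorm(1, fitted$lnalpha, fitted$se_lnalpha)
    }
    out
  }
  structure(c(phi, list(family = fam,
                        levels = fitted$levels,
                        y_obs = fitted$y_obs,
                        pred_obs = fitted$pred_obs,
                        design_names = fitted$design_names)),
            class = "la_phi")
}

#' Impute missing values from a drawn conditional
#'
#' @param phi a [draw_parameters()] draw.
#' @param X_missing design matrix of the rows to impute (same columns as the
#'   fit's design).
#' @param pmm_k donor-pool size (pmm only).
#' @return imputed values: numeric, 0/1, factor level labels, or counts.
#' @export
impute_from_conditional <- function(phi, X_missing, pmm_k = 5L) {
  stopifnot(inherits(phi, "la_phi"))
  X <- as.matrix(X_missing)
  if (nrow(X) == 0) {
    return(switch(phi$family, multinomial = character(0), numeric(0)))
  }
  stopifnot(identical(colnames(X), phi$design_names))
  switch(phi$family,
    bayes_linear = {
      mu <- as.numeric(X %*% phi$beta_star)
      stats::rnorm(nrow(X), mu, sqrt(phi$sigma2_star))
    },
    logistic = {
      p <- stats::plogis(as.numeric(X %*% phi$beta_star))
      stats::rbinom(nrow(X), 1, p)
    },
    multinomial = {
      K <- length(phi$levels)
      Th <- matrix(phi$beta_star, ncol = K - 1)
      eta <- cbind(0, X %*% Th)
      eta <- eta - apply(eta, 1, max)
      P <- exp(eta); P <- P / rowSums(P)
      idx <- vapply(seq_len(nrow(X)),
                    function(i) sample.int(K, 1, prob = P[i, ]), integer(1))
      phi$levels[idx]
    },
    pmm = {
      if (length(phi$y_obs) < pmm_k) {
        stop("donor-pool error: ", length(phi$y_obs),
             " observed rows for pmm_k = ", pmm_k, call. = FALSE)
      }
      pred_mis <- as.numeric(X %*% phi$beta_star)
      vapply(pred_mis, function(pm) {
        d <- abs(phi$pred_obs - pm)
        donors <- order(d)[seq_len(pmm_k)]
        phi$y_obs[donors[sample.int(pmm_k, 1)]]
      }, numeric(1))
    },
    negbin_draw = {
      mu <- exp(as.numeric(X %*% phi$beta_star))
      stats::rnbinom(nrow(X), size = 1 / exp(phi$lnalpha_star), mu = mu)
    })
}

# map engine-level imputed values back onto a schema column
imputed_to_column <- function(values, var) {
  if (var$family %in% c("binary", "categorical")) {
    if (is.numeric(values)) values <- var$categories[values + 1L]
    factor(values, levels = var$categories)
  } else if (var$family == "count") {
    as.integer(values)
  } else as.numeric(values)
}

#' Run chained-equations multiple imputation
#'
#' Visits the incomplete variables in spec order each iteration, refitting
#' each conditional on the currently completed data, drawing its parameters
#' and redrawing the missing cells; after `maxit` iterations one completed
#' dataset is emitted, and the cycle repeats for `m` datasets. Missing cells
#' are initialized by resampling the observed values of their column.
#'
#' @param table a `la_table`.
#' @param specs list of [conditional_spec()]; default: one spec per incomplete
#'   variable, family by schema type, predictors = all other non-id variables.
#' @param m number of imputed datasets (`>= 1`).
#' @param maxit number of chained iterations T (`>= 1`).
#' @param seed integer seed; identical inputs and seed give an identical set.
#' @return a `la_mids`: `datasets` (m completed data frames), `m`, `maxit`,
#'   `seed`, `specs`, and `diagnostics` (per-variable mean/sd chain traces of
#'   the imputed values by imputation and iteration).
#' @export
run_mice <- function(table, specs = NULL, m = 10L, maxit = 10L, seed = NULL) {
  stopifnot(inherits(table, "la_table"), m >= 1, maxit >= 1)
  data <- table$data
  schema <- table$schema
  incomplete <- names(data)[vapply(data, anyNA, logical(1))]
  if (is.null(specs)) {
    specs <- lapply(incomplete, function(v) {
      preds <- setdiff(names(schema), v)
      preds <- preds[vapply(schema[preds], function(s)
        !s$role %in% c("id", "cluster"), logical(1))]
      conditional_spec(v, default_conditional_family(schema[[v]]$family), preds)
    })
  }
  spec_vars <- vapply(specs, `[[`, character(1), "variable")
  uncovered <- setdiff(incomplete, spec_vars)
  if (length(uncovered)) {
    stop("incomplete variable(s) without a conditional spec: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  specs <- specs[spec_vars %in% incomplete]
  miss_idx <- lapply(data, function(x) which(is.na(x)))
  diag_rows <- list()
  datasets <- with_seed(seed, lapply(seq_len(m), function(imp) {
    completed <- data
    # t = 0 initialization: draws from the observed marginal of each column
    for (sp in specs) {
      v <- sp$variable
      idx <- miss_idx[[v]]
      obs <- completed[[v]][-idx]
      if (!length(obs)) stop("variable '", v, "' has no observed values",
                             call. = FALSE)
      completed[[v]][idx] <- sample(obs, length(idx), replace = TRUE)
    }
    for (t in seq_len(maxit)) {
      for (sp in specs) {
        v <- sp$variable
        idx <- miss_idx[[v]]
        step <- function() {
          X <- build_design(completed, sp$predictors)
          y_obs <- data[[v]][-idx]
          X_obs <- X[-idx, , drop = FALSE]
          # drop predictors constant on the observed rows (e.g. a dummy for a
          # category with no donor support); they are inestimable and the
          # imputation proceeds at the reference behaviour
          const <- apply(X_obs, 2, function(col) all(col == col[1]))
          const["(Intercept)"] <- FALSE
          if (any(const)) X <- X[, !const, drop = FALSE]
          fit <- fit_conditional(y_obs, X[-idx, , drop = FALSE], sp$family)
          phi <- draw_parameters(fit)
          vals <- impute_from_conditional(phi, X[idx, , drop = FALSE],
                                          pmm_k = sp$pmm_k)
          imputed_to_column(vals, schema[[v]])
        }
        vals <- tryCatch(step(), error = function(e) {
          stop("imputation failed for variable '", v, "' (iteration ", t,
               ", imputation ", imp, "): ", conditionMessage(e),
               call. = FALSE)
        })
        completed[[v]][idx] <- vals
        num <- if (is.factor(vals)) as.numeric(vals) - 1 else as.numeric(vals)
        diag_rows[[length(diag_rows) + 1L]] <<- data.frame(
          imputation = imp, iteration = t, variable = v,
          mean = mean(num), sd = stats::sd(num))
      }
    }
    completed
  }))
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(imputation = integer(), iteration = integer(),
               variable = character(), mean = numeric(), sd = numeric())
  structure(list(datasets = datasets, m = as.integer(m),
                 maxit = as.integer(maxit), seed = seed, specs = specs,
                 schema = schema, diagnostics = diagnostics),
            class = "la_mids")
}

#' @export
print.la_mids <- function(x, ...) {
  cat("<imputed set> m=", x$m, ", T=", x$maxit, ", variables: ",
      paste(vapply(x$specs, `[[`, character(1), "variable"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write an imputed set as CSVs plus a JSON manifest
#'
#' @param mids a `la_mids`.
#' @param dir output directory (created if needed).
#' @export
write_imputed_set <- function(mids, dir) {
  stopifnot(inherits(mids, "la_mids"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(mids$m)) {
    utils::write.csv(mids$datasets[[i]],
                     file.path(dir, sprintf("imputation_%03d.csv", i)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(m = mids$m, maxit = mids$maxit, seed = mids$seed,
                   specs = lapply(mids$specs, unclass),
                   diagnostics = mids$diagnostics)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
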