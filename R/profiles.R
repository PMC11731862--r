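# Latent-normal calibration for the age marginal: profiles state the
# *observed* (post-truncation) mean/sd, so the latent N(mu, sigma^2) is
# moment-matched so that its left truncation at `lower` reproduces them.
calibrate_truncnorm <- function(target_mean, target_sd, lower) {
  stopifnot(target_sd > 0, target_mean > lower)
  obj <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    a <- (lower - mu) / s
    lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
    m <- mu + s * lam
    v <- s^2 * (1 + a * lam - lam^2)
    (m - target_mean)^2 + (sqrt(v) - target_sd)^2
  }
  o <- stats::optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 10000))
  if (o$value > 1e-6) {
    stop("truncated-normal calibration failed for mean=", target_mean,
         " sd=", target_sd, " lower=", lower, call. = FALSE)
  }
  list(mu = o$par[1], sigma = exp(o$par[2]), lower = lower)
}

# Negative-binomial moment match for count marginals (mean, sd). Equidispersed
# or underdispersed marginals fall back to Poisson (size = Inf).
negbin_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  v <- sd^2
  if (v <= mean) return(list(mu = mean, size = Inf))
  list(mu = mean, size = mean^2 / (v - mean))
}

#' Load or construct a population profile
#'
#' A profile states the marginal distribution of every comparison-vector
#' variable — category probabilities for categorical variables, observed
#' (mean, sd) for the age and dependant-count marginals — plus a default
#' sample size and a repeat-user clustering rate. The packaged `"csew"`
#' (survey-like, n 1,232) and `"rcew"` (service-like, n 6,102) profiles carry
#' the published descriptive statistics verbatim as config.
#'
#' @param x `"csew"`, `"rcew"`, a path to a profile JSON, or a list with the
#'   same structure.
#' @return a `la_profile` with fields `name`, `n_default`, `cluster_rate`,
#'   `marginals`, `schema`, `dependence`.
#' @export
population_profile <- function(x) {
  if (is.character(x) && length(x) == 1) {
    path <- if (x %in% c("csew", "rcew")) {
      extdata_path(paste0("profile_", x, ".json"))
    } else x
    x <- read_json_config(path)
  }
  stopifnot(is.list(x), !is.null(x$marginals))
  pct <- isTRUE(x$marginals_are_percent)
  marg <- list()
  vars <- list()
  for (nm in names(x$marginals)) {
    m <- x$marginals[[nm]]
    if (!is.null(m$mean)) {
      stopifnot(m$sd > 0)
      if (!is.null(m$min)) {
        marg[[nm]] <- list(kind = "continuous", mean = m$mean, sd = m$sd,
                           min = m$min)
        vars[[nm]] <- schema_variable(nm, "continuous")
      } else {
        marg[[nm]] <- list(kind = "count", mean = m$mean, sd = m$sd)
        vars[[nm]] <- schema_variable(nm, "count")
      }
    } else {
      p <- unlist(m)
      if (pct) p <- p / 100
      if (abs(sum(p) - 1) > 0.005) {
        stop("category probabilities for '", nm, "' sum to ", sum(p),
             call. = FALSE)
      }
      p <- p / sum(p)
      marg[[nm]] <- list(kind = "categorical", p = p)
      fam <- if (length(p) == 2) "binary" else "categorical"
      vars[[nm]] <- schema_variable(nm, fam, categories = names(p))
    }
  }
  cr <- if (is.null(x$cluster_rate)) 0 else x$cluster_rate
  stopifnot(cr >= 0, cr < 1)
  structure(list(name = if (is.null(x$name)) "profile" else x$name,
                 n_default = if (is.null(x$n_default)) NA_integer_ else as.integer(x$n_default),
                 cluster_rate = cr,
                 marginals = marg,
                 schema = variable_schema(vars),
                 dependence = x$dependence),
            class = "la_profile")
}

#' @export
print.la_profile <- function(x, ...) {
  cat("<population profile '", x$name, "'> n_default=", x$n_default,
      ", ", length(x$marginals), " variables\n", sep = "")
  invisible(x)
}

#' Load or construct a generative outcome model
#'
#' The outcome follows a linear predictor over the comparison-vector design
#' columns, `eta = X beta + D gamma`, with family-specific noise:
#' gaussian (`y = eta + e`, `e ~ N(0, sigma2)`), bernoulli
#' (`y ~ Bin(1, expit(eta))`) or `count_negbin`
#' (`y ~ NB(mean exp(eta), var mu + alpha mu^2)`).
#'
#' @param x `"age"`, `"gender"`, `"frequency"` (the packaged models, whose
#'   coefficients are the published donor-survey regression columns), a path
#'   to a model JSON, or a list.
#' @return a `la_outcome`.
#' @export
outcome_model <- function(x) {
  if (is.character(x) && length(x) == 1) {
    path <- if (x %in% c("age", "gender", "frequency")) {
      extdata_path(paste0("outcome_", x, ".json"))
    } else x
    x <- read_json_config(path)
  }
  family <- match.arg(x$family, c("gaussian", "bernoulli", "count_negbin"))
  beta <- unlist(x$beta)
  gamma <- if (length(x$gamma)) unlist(x$gamma) else numeric(0)
  dispersion <- x$dispersion
  if (is.null(dispersion) && !is.null(x$lnalpha)) dispersion <- exp(x$lnalpha)
  if (family == "gaussian" && (is.null(x$sigma2) || x$sigma2 <= 0)) {
    stop("gaussian outcome model needs sigma2 > 0", call. = FALSE)
  }
  if (family == "count_negbin" && (is.null(dispersion) || dispersion <= 0)) {
    stop("count_negbin outcome model needs dispersion > 0", call. = FALSE)
  }
  structure(list(outcome = x$outcome, family = family, beta = beta,
                 gamma = gamma,
                 sigma2 = if (is.null(x$sigma2)) NA_real_ else x$sigma2,
                 dispersion = if (is.null(dispersion)) NA_real_ else dispersion),
            class = "la_outcome")
}

#' Draw covariate records from a population profile
#'
#' Categorical variables are multinomial draws from the profile marginals; age
#' is a left-truncated normal whose latent parameters are moment-matched so
#' the truncated distribution has the stated mean/sd, rounded to whole years;
#' counts are moment-matched negative-binomial draws. By default variables are
#' drawn independently; `profile$dependence` optionally lists
#' `{child, parent, table}` entries giving child category probabilities
#' conditional on the parent's category.
#'
#' @param profile a [population_profile()].
#' @param n number of records (`>= 0`); default `profile$n_default`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a `la_table`; a `cluster` id column is appended when
#'   `cluster_rate > 0`.
#' @export
generate_covariates <- function(profile, n = profile$n_default, seed = NULL) {
  stopifnot(inherits(profile, "la_profile"), n >= 0)
  n <- as.integer(n)
  with_seed(seed, {
    cols <- list()
    for (nm in names(profile$marginals)) {
      m <- profile$marginals[[nm]]
      cols[[nm]] <- switch(m$kind,
        categorical = {
          cats <- names(m$p)
          if (n == 0) character(0) else sample(cats, n, replace = TRUE, prob = m$p)
        },
        continuous = {
          cal <- calibrate_truncnorm(m$mean, m$sd, m$min)
          if (n == 0) numeric(0) else {
            lo <- stats::pnorm(cal$lower, cal$mu, cal$sigma)
            x <- stats::qnorm(stats::runif(n, lo, 1), cal$mu, cal$sigma)
            pmax(round(x), m$min)
          }
        },
        count = {
          nb <- negbin_moments(m$mean, m$sd)
          if (n == 0) integer(0) else if (is.infinite(nb$size)) {
            stats::rpois(n, nb$mu)
          } else {
            stats::rnbinom(n, size = nb$size, mu = nb$mu)
          }
        })
    }
    # conditional-dependence hook: resample child given parent category
    for (dep in profile$dependence) {
      child <- dep$child; parent <- dep$parent
      stopifnot(child %in% names(cols), parent %in% names(cols))
      pv <- as.character(cols[[parent]])
      cv <- character(n)
      for (pc in unique(pv)) {
        pr <- unlist(dep$table[[pc]])
        if (is.null(pr)) stop("dependence table for '", child,
                              "' lacks parent category '", pc, "'", call. = FALSE)
        idx <- which(pv == pc)
        cv[idx] <- sample(names(pr), length(idx), replace = TRUE,
                          prob = pr / sum(pr))
      }
      cols[[child]] <- cv
    }
    schema <- profile$schema
    if (profile$cluster_rate > 0 && n > 0) {
      cl <- integer(n); nxt <- 1L
      for (i in seq_len(n)) {
        if (i > 1 && stats::runif(1) < profile$cluster_rate) {
          cl[i] <- cl[sample.int(i - 1L, 1L)]
        } else {
          cl[i] <- nxt; nxt <- nxt + 1L
        }
      }
      cols[["cluster"]] <- cl
      schema <- variable_schema(c(unclass(schema), list(
        cluster = schema_variable("cluster", "count", role = "cluster"))))
    }
    df <- if (n == 0) {
      as.data.frame(cols, stringsAsFactors = FALSE)
    } else as.data.frame(cols, stringsAsFactors = FALSE)
    harmonized_table(df, schema)
  })
}

#' Generate an outcome column from a generative model
#'
#' @param covariates a `la_table` of covariate records.
#' @param model a [outcome_model()].
#' @param seed integer seed.
#' @return vector of length `n_rows(covariates)`: numeric (gaussian), 0/1
#'   integer (bernoulli) or non-negative integer (count_negbin).
#' @export
generate_outcome <- function(covariates, model, seed = NULL) {
  stopifnot(inherits(covariates, "la_table"), inherits(model, "la_outcome"))
  data <- covariates$data
  vars <- setdiff(names(covariates$schema), model$outcome)
  X <- build_design(data, vars)
  missing_cols <- setdiff(names(model$beta), colnames(X))
  if (length(missing_cols)) {
    stop("outcome model coefficients without design columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  eta <- as.numeric(X[, names(model$beta), drop = FALSE] %*% model$beta)
  if (length(model$gamma)) {
    dmiss <- setdiff(names(model$gamma), names(data))
    if (length(dmiss)) {
      stop("cluster-level covariates not present: ",
           paste(dmiss, collapse = ", "), call. = FALSE)
    }
    D <- as.matrix(as.data.frame(lapply(data[names(model$gamma)], as.numeric)))
    eta <- eta + as.numeric(D %*% model$gamma)
  }
  n <- length(eta)
  with_seed(seed, switch(model$family,
    gaussian = eta + stats::rnorm(n, 0, sqrt(model$sigma2)),
    bernoulli = stats::rbinom(n, 1, stats::plogis(eta)),
    count_negbin = stats::rnbinom(n, size = 1 / model$dispersion, mu = exp(eta))
  ))
}

#' Describe a two-population fusion scenario
#'
#' The look-alike assumption is encoded by a single shared [outcome_model()]
#' governing the target in both populations, while the covariate marginals
#' differ between the profiles.
#'
#' @param profile_A,profile_B recipient / donor [population_profile()]s.
#' @param outcome shared [outcome_model()].
#' @param n_A,n_B record counts; default the profiles' `n_default`.
#' @param seed integer seed fully determining the realization.
#' @return a `la_scenario`.
#' @export
fusion_scenario <- function(profile_A, profile_B, outcome,
                            n_A = profile_A$n_default,
                            n_B = profile_B$n_default, seed = 1L) {
  stopifnot(inherits(profile_A, "la_profile"), inherits(profile_B, "la_profile"),
            inherits(outcome, "la_outcome"), n_A >= 0, n_B >= 0)
  structure(list(profile_A = profile_A, profile_B = profile_B,
                 outcome = outcome, n_A = as.integer(n_A),
                 n_B = as.integer(n_B), seed = as.integer(seed)),
            class = "la_scenario")
}

# attach/replace the outcome column on a covariate table
attach_outcome <- function(tab, model, values) {
  schema <- tab$schema
  nm <- model$outcome
  if (nm %in% names(schema)) {
    var <- schema[[nm]]
    if (var$family %in% c("binary", "categorical") && model$family == "bernoulli") {
      values <- var$categories[values + 1L]   # 0 -> reference, 1 -> second level
    }
  } else {
    fam <- switch(model$family, gaussian = "continuous",
                  count_negbin = "count", bernoulli = "binary")
    var <- if (fam == "binary") {
      values <- c("no", "yes")[values + 1L]
      schema_variable(nm, "binary", c("no", "yes"), role = "target")
    } else schema_variable(nm, fam, role = "target")
    schema <- variable_schema(c(unclass(schema), stats::setNames(list(var), nm)))
  }
  df <- tab$data
  df[[nm]] <- values
  harmonized_table(df, schema, source_label = tab$source_label)
}

#' Realize a fusion scenario
#'
#' Draws covariates and the shared outcome for both populations, then masks
#' the outcome completely in the recipient table A (the mass-missingness the
#' method targets) while B keeps it observed.
#'
#' @param scenario a [fusion_scenario()].
#' @return list with `A` (outcome column fully masked), `B` (fully observed)
#'   and `truth` (the masked values, the generative model and the seed),
#'   usable for recovery tests.
#' @export
make_fusion_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "la_scenario"))
  seed <- scenario$seed
  A_cov <- generate_covariates(scenario$profile_A, scenario$n_A,
                               child_seed(seed, 1))
  B_cov <- generate_covariates(scenario$profile_B, scenario$n_B,
                               child_seed(seed, 2))
  y_A <- generate_outcome(A_cov, scenario$outcome, child_seed(seed, 3))
  y_B <- generate_outcome(B_cov, scenario$outcome, child_seed(seed, 4))
  A <- attach_outcome(A_cov, scenario$outcome, y_A)
  B <- attach_outcome(B_cov, scenario$outcome, y_B)
  truth_values <- A$data[[scenario$outcome$outcome]]
  A <- mask_variable(A, scenario$outcome$outcome)
  A$source_label <- rep("A", n_rows(A))
  B$source_label <- rep("B", n_rows(B))
  list(A = A, B = B,
       truth = list(outcome = scenario$outcome$outcome,
                    values = truth_values,
                    model = scenario$outcome, seed = seed))
}
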