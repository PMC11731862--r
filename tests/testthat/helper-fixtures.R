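# Shared fixtures: everything is built in code at test time.

toy_schema <- function() {
  variable_schema(
    schema_variable("x", "binary", c("a", "b")),
    schema_variable("g", "categorical", c("p", "q", "r")),
    schema_variable("z", "continuous"),
    schema_variable("k", "count")
  )
}

toy_table <- function(n = 8) {
  set.seed(99)
  harmonized_table(
    data.frame(x = sample(c("a", "b"), n, TRUE),
               g = sample(c("p", "q", "r"), n, TRUE),
               z = rnorm(n), k = rpois(n, 2)),
    toy_schema())
}

# a small three-variable profile for cheap generator tests
mini_profile <- function(name = "mini", n_default = 200) {
  population_profile(list(
    name = name, n_default = n_default,
    marginals = list(
      x = list(a = 0.3, b = 0.7),
      age = list(mean = 40, sd = 10, min = 16),
      k = list(mean = 1.5, sd = 2)
    )))
}

# gaussian outcome over the mini profile's design
mini_outcome <- function(sigma2 = 4) {
  outcome_model(list(outcome = "y", family = "gaussian",
                     beta = list("(Intercept)" = 10, "x=b" = 2, age = 0.1),
                     sigma2 = sigma2))
}

# two identical populations sharing one outcome: the exchangeability oracle
mini_scenario <- function(n_A = 300, n_B = 300, seed = 5, sigma2 = 4) {
  fusion_scenario(mini_profile("A"), mini_profile("B"), mini_outcome(sigma2),
                  n_A = n_A, n_B = n_B, seed = seed)
}

perp_rule <- function() {
  recode_rule("perpetrator",
              mapping = c("former partner" = "domestic",
                          "partner" = "domestic",
                          "colleague" = "acquaintance",
                          "friend" = "acquaintance",
                          "stranger" = "stranger_unknown",
                          "unknown" = "stranger_unknown"),
              priority_order = c("domestic", "acquaintance",
                                 "stranger_unknown"))
}

# construct a bare regression result for reporting tests
fake_reg <- function(est, se, family = "ols", n = 100) {
  nms <- names(est)
  structure(list(family = family, coefficients = est,
                 standard_errors = stats::setNames(se, nms),
                 vcov = diag(se^2, length(se)), n = n,
                 loglik = NA_real_, aic = NA_real_, bic = NA_real_,
                 lnalpha = NA_real_, se_lnalpha = NA_real_,
                 boundary = FALSE),
            class = "la_reg")
}
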