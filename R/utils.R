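#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All package randomness funnels through here so that
# (inputs, seed) fully determine every output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and an index, kept below 2^31.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + index * 9973) %% 2147483629)
}

#' Build a reference-coded design matrix
#'
#' Categorical variables enter as dummies named `"<variable>=<level>"` for
#' every non-reference level (the reference is the first factor level);
#' continuous and count variables enter as themselves. Column naming is stable
#' across the generator, the imputation engine and the validation regressions,
#' so coefficient vectors can be specified by name in configuration files.
#'
#' @param data data frame holding the variables.
#' @param vars character vector of variable names to include, in order.
#' @param intercept logical; prepend an `(Intercept)` column of ones.
#' @return numeric matrix with one row per row of `data`.
#' @export
build_design <- function(data, vars, intercept = TRUE) {
  stopifnot(is.data.frame(data))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("design variables not found in data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, n)
  for (v in vars) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x)) {
      f <- if (is.factor(x)) x else factor(x)
      levs <- levels(f)
      for (lev in levs[-1]) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(f == lev)
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}

# Significance markers matching the reporting convention
# *** p<0.001, ** p<0.01, * p<0.05.
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

read_json_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

write_json_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

# locate a packaged config file under inst/extdata
extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "lookalike")
  if (!nzchar(p)) stop("packaged file not found: ", file, call. = FALSE)
  p
}
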