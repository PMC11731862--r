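# Sentinel returned when every raw code on a record is an exclusion code
# (e.g. childhood abuse in the service records).
EXCLUDED <- ".excluded"

#' Declare a recode rule
#'
#' Maps raw source codes (many-to-one) onto the harmonized categories of one
#' schema variable. When a record carries several raw codes mapping to
#' different categories, the category earliest in `priority_order` wins —
#' e.g. a perpetrator recorded as both former partner and stranger is coded
#' domestic, prioritising the closer relationship. Codes in `drop_codes` mark
#' the whole record for exclusion (only if no retained code is present).
#'
#' @param target_variable harmonized variable the rule feeds.
#' @param mapping named character vector: raw code -> harmonized category.
#' @param priority_order permutation of the target's categories used to break
#'   multi-code ties; default: category order of the schema variable.
#' @param drop_codes raw codes whose records are excluded.
#' @param source_variable raw column name; defaults to `target_variable`.
#' @param sep regular expression splitting multi-code cells; default `";"`.
#' @return a `la_rule`.
#' @export
recode_rule <- function(target_variable, mapping, priority_order = NULL,
                        drop_codes = character(), source_variable = target_variable,
                        sep = ";") {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  structure(list(target = target_variable, source = source_variable,
                 mapping = mapping, priority = priority_order,
                 drop = as.character(drop_codes), sep = sep),
            class = "la_rule")
}

validate_rule <- function(rule, schema) {
  var <- schema_var(schema, rule$target)
  if (!var$family %in% c("binary", "categorical")) return(invisible(rule))
  bad <- setdiff(unique(unname(rule$mapping)), var$categories)
  if (length(bad)) {
    stop("rule for '", rule$target, "' maps onto non-schema categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(rule$priority) &&
      !setequal(rule$priority, var$categories)) {
    stop("priority_order for '", rule$target,
         "' must be a permutation of its categories", call. = FALSE)
  }
  invisible(rule)
}

#' Recode one record's raw codes into a harmonized category
#'
#' @param raw_codes non-empty character vector of raw codes for one record.
#' @param rule a [recode_rule()].
#' @return the harmonized category, or the `".excluded"` sentinel when every
#'   code is a drop code.
#' @export
recode_categorical <- function(raw_codes, rule) {
  raw_codes <- as.character(raw_codes)
  raw_codes <- raw_codes[!is.na(raw_codes) & nzchar(trimws(raw_codes))]
  if (!length(raw_codes)) stop("raw_codes must be non-empty", call. = FALSE)
  raw_codes <- trimws(raw_codes)
  unknown <- setdiff(raw_codes, c(names(rule$mapping), rule$drop))
  if (length(unknown)) {
    stop("unknown raw code(s) for variable '", rule$target, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  kept <- setdiff(raw_codes, rule$drop)
  if (!length(kept)) return(EXCLUDED)
  cats <- unique(unname(rule$mapping[kept]))
  if (length(cats) == 1L || is.null(rule$priority)) return(cats[[1]])
  rule$priority[min(match(cats, rule$priority))]
}

#' Harmonize a raw dataset against a schema
#'
#' Applies every recode rule, excludes records whose codes are all drop codes
#' (e.g. presenting for childhood abuse), and applies the adult eligibility
#' filter (age of 16 and over, inclusive). Cells that are missing in the raw
#' data stay missing. Variables without a rule are carried through and coerced
#' to their schema type.
#'
#' @param raw_table data frame of raw source data.
#' @param rules list of [recode_rule()]s.
#' @param schema a [variable_schema()].
#' @param age_var name of the numeric age column (set `NULL` to skip the
#'   eligibility filter).
#' @param age_min minimum eligible age, inclusive.
#' @return a `la_table`; attribute `"exclusions"` reports rows dropped per
#'   rule and by the age filter.
#' @export
harmonize_dataset <- function(raw_table, rules, schema, age_var = "age",
                              age_min = 16) {
  stopifnot(is.data.frame(raw_table))
  for (r in rules) validate_rule(r, schema)
  srcs <- vapply(rules, `[[`, character(1), "source")
  missing_src <- setdiff(srcs, names(raw_table))
  if (length(missing_src)) {
    stop("raw table lacks source column(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  df <- raw_table
  exclusions <- integer(0)
  drop_row <- rep(FALSE, nrow(df))
  for (r in rules) {
    raw <- as.character(df[[r$source]])
    rec <- rep(NA_character_, length(raw))
    todo <- which(!is.na(raw) & nzchar(trimws(raw)))
    if (length(todo)) {
      rec[todo] <- vapply(strsplit(raw[todo], r$sep), recode_categorical,
                          character(1), rule = r)
    }
    hit <- !is.na(rec) & rec == EXCLUDED
    exclusions[r$target] <- sum(hit & !drop_row)
    drop_row <- drop_row | hit
    rec[hit] <- NA_character_
    df[[r$target]] <- rec
  }
  if (!is.null(age_var) && age_var %in% names(schema)) {
    if (!age_var %in% names(df)) {
      stop("raw table lacks age column '", age_var, "'", call. = FALSE)
    }
    age_raw <- df[[age_var]]
    age <- suppressWarnings(as.numeric(as.character(age_raw)))
    bad <- !is.na(age_raw) & nzchar(trimws(as.character(age_raw))) & is.na(age)
    if (any(bad)) {
      stop("non-numeric age value(s): ",
           paste(utils::head(unique(as.character(age_raw)[bad]), 5),
                 collapse = ", "), call. = FALSE)
    }
    underage <- !is.na(age) & age < age_min
    exclusions[["age_filter"]] <- sum(underage & !drop_row)
    drop_row <- drop_row | underage
    df[[age_var]] <- age
  }
  out <- harmonized_table(df[!drop_row, , drop = FALSE], schema)
  attr(out, "exclusions") <- exclusions
  out
}

#' Keep rows complete on a set of variables
#'
#' @param table a `la_table`.
#' @param vars variables that must be observed; default: the schema's
#'   comparison vector.
#' @return the filtered `la_table`, row order preserved; attribute
#'   `"dropped_per_variable"` counts, per listed variable, the rows missing it.
#' @export
select_complete_cases <- function(table,
                                  vars = comparison_vars(table$schema)) {
  stopifnot(inherits(table, "la_table"))
  bad <- setdiff(vars, names(table$schema))
  if (length(bad)) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!length(vars) || nrow(table$data) == 0) {
    attr(table, "dropped_per_variable") <- stats::setNames(integer(length(vars)), vars)
    return(table)
  }
  miss <- vapply(vars, function(v) is.na(table$data[[v]]), logical(nrow(table$data)))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = nrow(table$data))
  keep <- rowSums(miss) == 0
  out <- table
  out$data <- table$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  if (!is.null(table$source_label)) out$source_label <- table$source_label[keep]
  attr(out, "dropped_per_variable") <- stats::setNames(colSums(miss), vars)
  out
}

#' The packaged comparison-vector schema
#'
#' Ten harmonized variables shared by the survey-like and service-like data:
#' type of sexual violence, victim-perpetrator relationship, physical health
#' impact, gender, relationship status, ethnicity, employment status, housing
#' tenure, age and number of dependants.
#'
#' @return a `la_schema`.
#' @export
default_schema <- function() {
  variable_schema(
    schema_variable("sv_type", "binary", c("other_sv", "rape")),
    schema_variable("perpetrator", "categorical",
                    c("domestic", "acquaintance", "stranger_unknown")),
    schema_variable("injury", "binary", c("no_injury", "injury")),
    schema_variable("gender", "binary", c("female", "male")),
    schema_variable("relationship_status", "categorical",
                    c("married_cohabiting", "single_widowed",
                      "separated_divorced")),
    schema_variable("ethnicity", "binary", c("white", "non_white")),
    schema_variable("employment", "categorical",
                    c("employed", "unemployed", "outside_labour_force",
                      "student")),
    schema_variable("tenure", "categorical", c("homeowner", "renter", "other")),
    schema_variable("age", "continuous"),
    schema_variable("dependants", "count")
  )
}

rule_from_config <- function(cfg) {
  recode_rule(cfg$target_variable,
              mapping = unlist(cfg$mapping),
              priority_order = if (length(cfg$priority_order)) unlist(cfg$priority_order) else NULL,
              drop_codes = if (length(cfg$drop_codes)) unlist(cfg$drop_codes) else character(),
              source_variable = if (is.null(cfg$source_variable)) cfg$target_variable else cfg$source_variable)
}

#' Load harmonization rules from a JSON config
#'
#' The config has a top-level `rules` array; each entry holds
#' `target_variable`, `mapping`, and optionally `priority_order`,
#' `drop_codes`, `source_variable`.
#'
#' @param path JSON file; default: the packaged rule set, which hard-codes
#'   only the published recodes (violence type, perpetrator priority
#'   domestic > acquaintance > stranger/unknown, gender, 3-level relationship
#'   status, White/non-White ethnicity, 4-level employment, 3-level tenure).
#'   Source-system code inventories beyond those are user-supplied edits.
#' @return list of `la_rule`.
#' @export
load_rules <- function(path = extdata_path("harmonization_default.json")) {
  cfg <- read_json_config(path)
  lapply(cfg$rules, rule_from_config)
}
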