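#' Declare one harmonized variable
#'
#' @param name variable identifier (unique within a schema).
#' @param family one of `"binary"`, `"categorical"`, `"continuous"`, `"count"`.
#' @param categories ordered category labels; the first (or `reference`) is the
#'   reference level. Required for binary/categorical, must be empty otherwise.
#' @param reference reference level; defaults to the first category.
#' @param role one of `"comparison_vector"`, `"target"`, `"id"`, `"cluster"`.
#' @return a `la_variable` list.
#' @export
schema_variable <- function(name, family,
                            categories = character(),
                            reference = NULL,
                            role = "comparison_vector") {
  family <- match.arg(family, c("binary", "categorical", "continuous", "count"))
  role <- match.arg(role, c("comparison_vector", "target", "id", "cluster"))
  categories <- as.character(categories)
  if (family == "binary" && length(categories) != 2) {
    stop("binary variable '", name, "' must have exactly 2 categories",
         call. = FALSE)
  }
  if (family == "categorical" && length(categories) < 2) {
    stop("categorical variable '", name, "' must have at least 2 categories",
         call. = FALSE)
  }
  if (family %in% c("continuous", "count") && length(categories)) {
    stop(family, " variable '", name, "' must not declare categories",
         call. = FALSE)
  }
  if (is.null(reference)) reference <- if (length(categories)) categories[[1]] else NA_character_
  if (length(categories) && !reference %in% categories) {
    stop("reference level '", reference, "' is not a category of '", name, "'",
         call. = FALSE)
  }
  # store categories with the reference first: factor level order == dummy coding
  if (length(categories)) {
    categories <- c(reference, setdiff(categories, reference))
  }
  structure(list(name = name, family = family, categories = categories,
                 reference = reference, role = role),
            class = "la_variable")
}

#' Assemble a variable schema
#'
#' @param ... `la_variable` objects (or a single list of them).
#' @return a `la_schema`: named list of variables, order preserved.
#' @export
variable_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1 && !inherits(vars[[1]], "la_variable")) vars <- vars[[1]]
  stopifnot(all(vapply(vars, inherits, logical(1), "la_variable")))
  nms <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate variable names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(vars) <- nms
  structure(vars, class = "la_schema")
}

schema_names <- function(schema) names(schema)

#' Comparison-vector variable names of a schema
#' @param schema a `la_schema`.
#' @export
comparison_vars <- function(schema) {
  names(schema)[vapply(schema, function(v) v$role == "comparison_vector", logical(1))]
}

schema_var <- function(schema, name) {
  if (!name %in% names(schema)) {
    stop("variable '", name, "' is not in the schema", call. = FALSE)
  }
  schema[[name]]
}

# coerce one column to its schema type; unknown categories -> error
coerce_column <- function(x, var) {
  if (var$family %in% c("binary", "categorical")) {
    x <- as.character(x)
    bad <- stats::na.omit(setdiff(unique(x), var$categories))
    if (length(bad)) {
      stop("values outside schema categories for '", var$name, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    factor(x, levels = var$categories)
  } else if (var$family == "count") {
    xi <- suppressWarnings(as.numeric(x))
    if (any(!is.na(xi) & (xi < 0 | xi != round(xi)))) {
      stop("count variable '", var$name, "' has non-integer or negative values",
           call. = FALSE)
    }
    as.integer(xi)
  } else {
    suppressWarnings(as.numeric(x))
  }
}

#' Construct a harmonized table
#'
#' A rectangular dataset whose columns conform to a [variable_schema()];
#' missing cells are `NA`, and the observed/missing mask is exposed via
#' [missing_mask()]. `source_label` records, per row, which source dataset the
#' row came from (set by the fusion step).
#'
#' @param data data frame whose columns cover the schema variables.
#' @param schema a `la_schema`.
#' @param source_label optional character vector, one entry per row.
#' @return a `la_table`.
#' @export
harmonized_table <- function(data, schema, source_label = NULL) {
  stopifnot(is.data.frame(data), inherits(schema, "la_schema"))
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("data lacks schema columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data[names(schema)]
  for (nm in names(schema)) out[[nm]] <- coerce_column(out[[nm]], schema[[nm]])
  rownames(out) <- NULL
  if (!is.null(source_label)) {
    stopifnot(length(source_label) == nrow(out))
    source_label <- as.character(source_label)
  }
  structure(list(data = out, schema = schema, source_label = source_label),
            class = "la_table")
}

#' Observed-cell mask of a harmonized table
#'
#' @param table a `la_table`.
#' @return logical matrix, `TRUE` where the cell is observed.
#' @export
missing_mask <- function(table) {
  stopifnot(inherits(table, "la_table"))
  m <- !vapply(table$data, is.na, logical(nrow(table$data)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(table$data))
  dimnames(m) <- list(NULL, names(table$data))
  m
}

#' @export
print.la_table <- function(x, ...) {
  cat("<harmonized table> ", nrow(x$data), " rows x ", ncol(x$data),
      " variables\n", sep = "")
  obs <- missing_mask(x)
  miss <- colSums(!obs)
  if (any(miss > 0)) {
    cat("  missing cells: ",
        paste(sprintf("%s=%d", names(miss)[miss > 0], miss[miss > 0]),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$source_label)) {
    cat("  sources: ", paste(names(table(x$source_label)),
                             table(x$source_label), sep = ":", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of rows of a harmonized table
#' @param table a `la_table`.
#' @export
n_rows <- function(table) nrow(table$data)

#' Write a harmonized table as CSV plus a JSON sidecar
#'
#' The sidecar carries the schema, the per-cell observed mask and the source
#' labels, so the table round-trips through plain text.
#'
#' @param table a `la_table`.
#' @param csv_path path for the data CSV.
#' @param sidecar_path path for the JSON sidecar (default: csv path + `.json`).
#' @export
write_harmonized <- function(table, csv_path,
                             sidecar_path = paste0(csv_path, ".json")) {
  utils::write.csv(table$data, csv_path, row.names = FALSE, na = "")
  sc <- list(
    schema = lapply(unclass(table$schema), unclass),
    mask = lapply(as.data.frame(missing_mask(table)), as.logical),
    source_label = table$source_label
  )
  write_json_config(sc, sidecar_path)
  invisible(csv_path)
}

#' Read a harmonized table written by [write_harmonized()]
#' @param csv_path path to the CSV.
#' @param sidecar_path path to the JSON sidecar.
#' @export
read_harmonized <- function(csv_path, sidecar_path = paste0(csv_path, ".json")) {
  sc <- read_json_config(sidecar_path)
  schema <- variable_schema(lapply(sc$schema, function(v) {
    schema_variable(v$name, v$family,
                    categories = unlist(v$categories),
                    reference = if (is.null(v$reference) || is.na(v$reference)) NULL else v$reference,
                    role = v$role)
  }))
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  harmonized_table(df, schema,
                   source_label = if (is.null(sc$source_label)) NULL else unlist(sc$source_label))
}
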