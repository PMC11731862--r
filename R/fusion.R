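#' Specify a fusion (mass-imputation) run
#'
#' Dataset A (recipient) lacks the target variables entirely; dataset B
#' (donor) observes them. The two are stacked on the harmonized comparison
#' vector and the targets are mass-imputed into A's rows.
#'
#' @param targets variables observed in the donor, fully missing in the
#'   recipient.
#' @param comparison_vector covariates defining look-alike similarity; must be
#'   complete in both datasets (after complete-case selection) and disjoint
#'   from `targets`.
#' @param m,maxit,seed imputation count, chained iterations T, seed.
#' @param families optional named character vector overriding the default
#'   conditional family per target (e.g. `c(frequency = "pmm")`).
#' @param direction_swapped flag recorded in provenance for the robustness
#'   exercise where donor and recipient roles are exchanged.
#' @return a `la_fusion_spec`.
#' @export
fusion_spec <- function(targets, comparison_vector, m = 10L, maxit = 10L,
                        seed = NULL, families = NULL,
                        direction_swapped = FALSE) {
  overlap <- intersect(targets, comparison_vector)
  if (length(overlap)) {
    stop("targets cannot be part of the comparison vector: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(targets = targets, comparison_vector = comparison_vector,
                 m = as.integer(m), maxit = as.integer(maxit), seed = seed,
                 families = families,
                 direction_swapped = isTRUE(direction_swapped)),
            class = "la_fusion_spec")
}

same_variable <- function(a, b) {
  identical(a$family, b$family) && identical(a$categories, b$categories)
}

#' Stack recipient and donor into one table
#'
#' @param A recipient `la_table` (targets become fully masked).
#' @param B donor `la_table` (targets must be observed).
#' @param spec a [fusion_spec()].
#' @return `la_table` with `n_A + n_B` rows and `source_label` `"A"`/`"B"`.
#' @export
stack_datasets <- function(A, B, spec) {
  stopifnot(inherits(A, "la_table"), inherits(B, "la_table"),
            inherits(spec, "la_fusion_spec"))
  if (n_rows(B) == 0) stop("donor dataset B is empty", call. = FALSE)
  vars <- c(spec$comparison_vector, spec$targets)
  discordant <- character(0)
  for (v in vars) {
    inA <- v %in% names(A$schema); inB <- v %in% names(B$schema)
    if (!inA || !inB || !same_variable(A$schema[[v]], B$schema[[v]])) {
      discordant <- c(discordant, v)
    }
  }
  if (length(discordant)) {
    stop("schema mismatch between A and B for: ",
         paste(discordant, collapse = ", "), call. = FALSE)
  }
  schema <- variable_schema(lapply(vars, function(v) A$schema[[v]]))
  dfA <- A$data[vars]
  dfB <- B$data[vars]
  for (tv in spec$targets) {
    dfA[[tv]] <- dfA[[tv]][rep(NA_integer_, nrow(dfA))]  # mask all A targets
  }
  stacked <- rbind(dfA, dfB)
  out <- harmonized_table(stacked, schema,
                          source_label = c(rep("A", nrow(dfA)),
                                           rep("B", nrow(dfB))))
  cv_miss <- vapply(spec$comparison_vector,
                    function(v) anyNA(out$data[[v]]), logical(1))
  if (any(cv_miss)) {
    stop("comparison-vector variable(s) incomplete after stacking: ",
         paste(spec$comparison_vector[cv_miss], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Mask a variable completely
#'
#' Sets every cell of `name` to missing, retaining the pre-mask values in a
#' `"truth"` attribute for validation. Masking an already fully masked column
#' is the identity (the original truth sidecar is kept).
#'
#' @param table a `la_table`.
#' @param name variable to mask.
#' @return the masked `la_table`; `attr(, "truth")` is a named list of
#'   pre-mask columns.
#' @export
mask_variable <- function(table, name) {
  stopifnot(inherits(table, "la_table"))
  if (!name %in% names(table$schema)) {
    stop("unknown variable '", name, "'", call. = FALSE)
  }
  if (all(is.na(table$data[[name]]))) return(table)
  truth <- attr(table, "truth")
  if (is.null(truth)) truth <- list()
  truth[[name]] <- table$data[[name]]
  table$data[[name]] <- table$data[[name]][rep(NA_integer_, nrow(table$data))]
  attr(table, "truth") <- truth
  table
}

#' Fuse a donor's variables into a recipient by mass imputation
#'
#' Stacks A and B, runs chained-equations imputation with each target
#' predicted from the comparison vector (main effects only), and restricts
#' each completed dataset to the recipient rows: the fused synthetic dataset.
#' A warning is raised when a comparison-vector category occurring in A has
#' zero donor support in B (the imputation extrapolates there).
#'
#' @param A recipient `la_table`; targets fully missing.
#' @param B donor `la_table`; targets fully observed.
#' @param spec a [fusion_spec()].
#' @return a `la_fused`: `datasets` (m synthetic recipient tables), `n`
#'   (recipient rows), `spec`, `stacked` (the stacked input), `mids`.
#' @export
fuse <- function(A, B, spec) {
  stopifnot(inherits(spec, "la_fusion_spec"))
  for (tv in spec$targets) {
    if (!all(is.na(A$data[[tv]]))) {
      stop("target '", tv, "' must be fully missing in the recipient",
           call. = FALSE)
    }
    if (anyNA(B$data[[tv]])) {
      stop("target '", tv, "' must be fully observed in the donor",
           call. = FALSE)
    }
  }
  # extrapolation check: categories with recipient rows but no donor rows
  unsupported <- character(0)
  for (v in spec$comparison_vector) {
    if (A$schema[[v]]$family %in% c("binary", "categorical")) {
      inA <- unique(as.character(A$data[[v]]))
      inB <- unique(as.character(B$data[[v]]))
      gone <- setdiff(stats::na.omit(inA), inB)
      if (length(gone)) {
        unsupported <- c(unsupported, paste0(v, "=", gone))
      }
    }
  }
  if (length(unsupported)) {
    warning("comparison-vector categories without donor support: ",
            paste(unsupported, collapse = ", "), call. = FALSE)
  }
  stacked <- stack_datasets(A, B, spec)
  specs <- lapply(spec$targets, function(tv) {
    fam <- if (!is.null(spec$families) && tv %in% names(spec$families)) {
      spec$families[[tv]]
    } else {
      default_conditional_family(stacked$schema[[tv]]$family)
    }
    preds <- c(spec$comparison_vector, setdiff(spec$targets, tv))
    conditional_spec(tv, fam, preds)
  })
  mids <- run_mice(stacked, specs, m = spec$m, maxit = spec$maxit,
                   seed = spec$seed)
  recipient <- stacked$source_label == "A"
  datasets <- lapply(mids$datasets, function(d) {
    out <- d[recipient, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  structure(list(datasets = datasets, n = sum(recipient), spec = spec,
                 schema = stacked$schema, mids = mids),
            class = "la_fused")
}

#' @export
print.la_fused <- function(x, ...) {
  cat("<fused result> m=", length(x$datasets), " synthetic datasets of ",
      x$n, " recipient rows; targets: ",
      paste(x$spec$targets, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a fused result as CSVs plus a manifest
#' @param fused a `la_fused`.
#' @param dir output directory.
#' @export
write_fused <- function(fused, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fused$datasets)) {
    utils::write.csv(fused$datasets[[i]],
                     file.path(dir, sprintf("fused_%03d.csv", i)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(n = fused$n, m = fused$spec$m, maxit = fused$spec$maxit,
                   seed = fused$spec$seed, targets = fused$spec$targets,
                   comparison_vector = fused$spec$comparison_vector,
                   direction_swapped = fused$spec$direction_swapped)
  write_json_config(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
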