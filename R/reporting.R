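# Three-column comparison reporting: recipient-original, donor, and fused
# synthetic estimates side by side, mirroring the validation-table layout
# (coefficient with SE in brackets beneath, significance stars in the cell).

#' Build a three-column comparison table
#'
#' @param res_A recipient-original result (`la_reg` or `la_pool`), or `NULL`
#'   when the target never exists in the recipient (the real-application
#'   case, reported as a two-column table).
#' @param res_B donor result.
#' @param pooled_syn pooled result on the fused synthetic datasets.
#' @return a `la_comparison` (data frame of estimate/SE/stars per column plus
#'   a per-column n footer).
#' @export
build_comparison <- function(res_A, res_B, pooled_syn) {
  fr <- list(A_original = if (is.null(res_A)) NULL else result_frame(res_A),
             B_donor = result_frame(res_B),
             synthetic = result_frame(pooled_syn))
  fr <- Filter(Negate(is.null), fr)
  terms <- fr[[1]]$term
  for (f in fr[-1]) {
    if (!identical(f$term, terms)) {
      stop("alignment error: predictor sets differ between columns",
           call. = FALSE)
    }
  }
  tab <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (col in names(fr)) {
    tab[[paste0(col, "_estimate")]] <- fr[[col]]$estimate
    tab[[paste0(col, "_se")]] <- fr[[col]]$se
    tab[[paste0(col, "_stars")]] <- fr[[col]]$stars
  }
  res <- list(A_original = res_A, B_donor = res_B, synthetic = pooled_syn)
  res <- Filter(Negate(is.null), res)
  structure(list(table = tab,
                 columns = names(fr),
                 n = vapply(res, `[[`, numeric(1), "n")),
            class = "la_comparison")
}

#' Render a comparison table as aligned text
#'
#' Estimates carry their stars; standard errors are printed in brackets on
#' the following line; the footer gives per-column n.
#'
#' @param x a `la_comparison`.
#' @param digits decimal places.
#' @export
format.la_comparison <- function(x, digits = 3, ...) {
  tab <- x$table
  cols <- x$columns
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  lines <- character(0)
  w_term <- max(nchar(tab$term), nchar("term"))
  cells_est <- lapply(cols, function(cl)
    paste0(fmt(tab[[paste0(cl, "_estimate")]]), tab[[paste0(cl, "_stars")]]))
  cells_se <- lapply(cols, function(cl)
    paste0("(", fmt(tab[[paste0(cl, "_se")]]), ")"))
  w_col <- mapply(function(e, s) max(nchar(c(e, s))), cells_est, cells_se)
  w_col <- pmax(w_col, nchar(cols))
  pad <- function(s, w) {
    w <- rep_len(w, length(s))
    vapply(seq_along(s), function(i) formatC(s[i], width = w[i]), character(1))
  }
  lines <- c(lines, paste(c(pad("term", w_term), pad(cols, w_col)),
                          collapse = "  "))
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines,
               paste(c(pad(tab$term[i], w_term),
                       pad(vapply(seq_along(cols), function(j) cells_est[[j]][i],
                                  character(1)), w_col)), collapse = "  "),
               paste(c(pad("", w_term),
                       pad(vapply(seq_along(cols), function(j) cells_se[[j]][i],
                                  character(1)), w_col)), collapse = "  "))
  }
  lines <- c(lines,
             paste(c(pad("N", w_term), pad(format(x$n), w_col)), collapse = "  "),
             "*** p<0.001, ** p<0.01, * p<0.05; standard errors (SE) in brackets")
  paste(lines, collapse = "\n")
}

#' @export
print.la_comparison <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a comparison table to CSV (lossless)
#'
#' Estimates and SEs are written at full double precision, so
#' [read_comparison()] reproduces the stored values exactly.
#'
#' @param x a `la_comparison`.
#' @param path CSV path.
#' @export
write_comparison <- function(x, path) {
  tab <- x$table
  for (nm in names(tab)) {
    if (is.numeric(tab[[nm]])) {
      tab[[nm]] <- formatC(tab[[nm]], format = "g", digits = 17)
    }
  }
  footer <- tab[1, , drop = FALSE]
  footer[1, ] <- ""
  footer$term <- "__n__"
  for (cl in x$columns) {
    footer[[paste0(cl, "_estimate")]] <- as.character(x$n[[cl]])
  }
  utils::write.csv(rbind(tab, footer), path, row.names = FALSE)
  invisible(path)
}

#' Read a comparison table written by [write_comparison()]
#' @param path CSV path.
#' @export
read_comparison <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cols <- sub("_estimate$", "", grep("_estimate$", names(raw), value = TRUE))
  is_footer <- raw$term == "__n__"
  n <- as.numeric(raw[is_footer, paste0(cols, "_estimate")])
  names(n) <- cols
  tab <- raw[!is_footer, , drop = FALSE]
  for (nm in names(tab)) {
    if (grepl("_(estimate|se)$", nm)) tab[[nm]] <- as.numeric(tab[[nm]])
    if (grepl("_stars$", nm)) tab[[nm]][is.na(tab[[nm]])] <- ""
  }
  rownames(tab) <- NULL
  structure(list(table = tab, columns = cols, n = n),
            class = "la_comparison")
}

#' Concordance between the donor analysis and the fused synthetic analysis
#'
#' Operationalizes the method's validity claim — the fused synthetic dataset
#' should mimic the donor's associations in sign and magnitude — as
#' fractions: sign agreement, significance-star agreement, the mean absolute
#' relative coefficient difference, and the list of coefficients whose
#' significance category flips.
#'
#' @param res_B donor result (`la_reg` or `la_pool`).
#' @param pooled_syn pooled synthetic result.
#' @param truth optional generative [outcome_model()]; adds bias and RMSE of
#'   the pooled estimates against the true coefficients.
#' @param eps guard for the relative-difference denominator.
#' @return a `la_concordance` list.
#' @export
concordance <- function(res_B, pooled_syn, truth = NULL, eps = 1e-8) {
  fB <- result_frame(res_B)
  fS <- result_frame(pooled_syn)
  if (!identical(fB$term, fS$term)) {
    stop("alignment error: predictor sets differ", call. = FALSE)
  }
  b <- fB$estimate; s <- fS$estimate
  sign_agreement <- mean(sign(b) == sign(s))
  significance_agreement <- mean(fB$stars == fS$stars)
  mard <- mean(abs(s - b) / pmax(abs(b), eps))
  flips <- fB$term[fB$stars != fS$stars]
  out <- list(sign_agreement = sign_agreement,
              significance_agreement = significance_agreement,
              mean_abs_relative_diff = mard, flips = flips)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "la_outcome"))
    common <- intersect(names(truth$beta), fS$term)
    est <- stats::setNames(fS$estimate, fS$term)[common]
    err <- est - truth$beta[common]
    out$bias <- mean(err)
    out$rmse <- sqrt(mean(err^2))
    out$true_coefficients <- truth$beta[common]
  }
  structure(out, class = "la_concordance")
}

#' @export
print.la_concordance <- function(x, ...) {
  cat("<concordance> sign agreement ", round(x$sign_agreement, 3),
      ", significance agreement ", round(x$significance_agreement, 3),
      ", mean |rel diff| ", round(x$mean_abs_relative_diff, 3), "\n", sep = "")
  if (length(x$flips)) {
    cat("  significance flips: ", paste(x$flips, collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$rmse)) {
    cat("  vs truth: bias ", round(x$bias, 4), ", rmse ", round(x$rmse, 4),
        "\n", sep = "")
  }
  invisible(x)
}
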