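#' Mean +/- 2 SD outlier screen over expression and clinical-score variables
#'
#' For every screened variable the interval `[mean - 2*SD, mean + 2*SD]`
#' (sample SD, n-1 denominator) is computed once on the pre-exclusion data;
#' a sample falling outside the interval is an outlier for that variable.
#' Exclusion combines the per-variable flags:
#' * `rule = "and"` (default): outlier on the expression variable AND on at
#'   least one item variable;
#' * `rule = "or"`: outlier on the expression variable OR any item variable.
#'
#' Screening is single-pass: intervals are never recomputed after removal.
#' A zero-SD variable screens nobody.
#'
#' @param values data.frame of per-sample variables; rownames or a `sample`
#'   column identify samples.
#' @param expression_var name of the expression (delta-Ct) column.
#' @param item_vars names of the score columns (e.g. the four ADOS items).
#' @param rule `"and"` or `"or"` (see above).
#' @param k interval half-width in SD units (default 2).
#' @return list of class `outlier_screen`: `intervals` (variable, mean, sd,
#'   lo, hi), `flags` (logical sample x variable matrix), `excluded`
#'   (sample ids), `audit` (per excluded sample, which variables triggered).
#' @export
screen_outliers <- function(values, expression_var, item_vars,
                            rule = c("and", "or"), k = 2) {
  rule <- match.arg(rule)
  ids <- if ("sample" %in% names(values)) as.character(values$sample)
         else rownames(values)
  vars <- c(expression_var, item_vars)
  miss <- setdiff(vars, names(values))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  flags <- sapply(vars, function(v) {
    x <- values[[v]]
    if (all(is.na(x))) stop("all values missing for variable: ", v)
    if (sum(!is.na(x)) < 3) stop("need >= 3 non-missing values for: ", v)
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (s == 0) return(rep(FALSE, length(x)))
    !is.na(x) & (x < m - k * s | x > m + k * s)
  })
  rownames(flags) <- ids
  intervals <- data.frame(
    variable = vars,
    mean = vapply(vars, function(v) mean(values[[v]], na.rm = TRUE), 1),
    sd = vapply(vars, function(v) stats::sd(values[[v]], na.rm = TRUE), 1),
    stringsAsFactors = FALSE)
  intervals$lo <- intervals$mean - k * intervals$sd
  intervals$hi <- intervals$mean + k * intervals$sd
  rownames(intervals) <- NULL
  expr_hit <- flags[, expression_var]
  item_hit <- if (length(item_vars))
    rowSums(flags[, item_vars, drop = FALSE]) > 0 else rep(FALSE, length(ids))
  excluded_mask <- if (rule == "and") expr_hit & item_hit else expr_hit | item_hit
  excluded <- ids[excluded_mask]
  audit <- lapply(stats::setNames(excluded, excluded), function(s)
    vars[flags[s, ]])
  structure(list(intervals = intervals, flags = flags, excluded = excluded,
                 audit = audit, rule = rule, k = k),
            class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf("outlier_screen (rule '%s', mean +/- %g SD): %d of %d excluded\n",
              x$rule, x$k, length(x$excluded), nrow(x$flags)))
  if (length(x$excluded)) cat(" ", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
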