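#' Multiple-testing adjustment (single shared implementation)
#'
#' Thin wrapper over [stats::p.adjust()] so that every consumer in the
#' package (clinical correlation, enrichment) adjusts p-values through one
#' code path. `family_size` fixes the family denominator even when some
#' tests are not testable (NT) or not emitted.
#'
#' @param p numeric vector of raw p-values (NA allowed).
#' @param method `"holm"`, `"BH"` or `"bonferroni"`.
#' @param family_size family size m; default `length(p)`.
#' @return adjusted p-values, clipped to 1.
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH", "bonferroni"),
                           family_size = length(p)) {
  method <- match.arg(method)
  stopifnot(family_size >= sum(!is.na(p)))
  stats::p.adjust(p, method = method, n = family_size)
}

#' Default correlation scopes: general plus class-specific families
#'
#' Builds the 16-test family used for marker-vs-score correlation: all
#' patients and controls against IQ, YGTSS and the four ADOS items; ASD+NC
#' against the ADOS items; TS+NC against YGTSS; TS+ASD+NC against YGTSS and
#' the ADOS items. Class-specific scopes pair one patient class with the
#' controls because several scales are only meaningful for that class.
#'
#' @param cohort a `cohort_table`.
#' @return list of scopes (label, sample ids, variable names).
#' @export
default_correlation_scopes <- function(cohort) {
  sid <- function(gs) cohort$sample[cohort$group %in% gs]
  ados <- c("ADOS_A", "ADOS_B", "ADOS_C", "ADOS_D")
  list(
    list(label = "all patients and NCs",
         samples = cohort$sample, vars = c("IQ", "YGTSS", ados)),
    list(label = "ASD patients and NCs",
         samples = sid(c("ASD", "NC")), vars = ados),
    list(label = "TS patients and NCs",
         samples = sid(c("TS", "NC")), vars = "YGTSS"),
    list(label = "TS+ASD patients and NCs",
         samples = sid(c("TS+ASD", "NC")), vars = c("YGTSS", ados)))
}

#' Normality-gated correlation of marker delta-Ct with clinical scores
#'
#' For every (scope, score) pair, Pearson correlation is used when both
#' variables pass the normality check within the scope, Spearman (average
#' ranks for ties) otherwise. Raw two-sided p-values are corrected three
#' ways across the fixed family of `family_size` tests: a Bonferroni verdict
#' at `alpha / family_size`, Holm-adjusted p, and Benjamini-Hochberg
#' adjusted p. A zero-variance variable yields a not-testable (NT) record
#' that still consumes a family slot.
#'
#' @param dct named numeric vector: marker delta-Ct per sample.
#' @param cohort a `cohort_table` with the score columns.
#' @param scopes list of scopes as from [default_correlation_scopes()].
#' @param family_size family size m (default: number of records).
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame of class `correlation_table`: scope, variable, method,
#'   n, r, CI bounds, raw p, `bonferroni_alpha`, `bonferroni_significant`,
#'   `p_holm`, `p_bh`.
#' @export
correlate <- function(dct, cohort, scopes = default_correlation_scopes(cohort),
                      family_size = NULL, alpha = 0.05) {
  rows <- list()
  for (sc in scopes) {
    ids <- intersect(sc$samples, names(dct))
    for (v in sc$vars) {
      x <- dct[ids]
      y <- cohort[[v]][match(ids, cohort$sample)]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      rec <- list(scope = sc$label, variable = v, method = "NT", n = n,
                  r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                  p = NA_real_)
      if (n >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
        gate <- normality_check(list(x = x, y = y), alpha = alpha)
        if (gate$verdict == "normal") {
          ht <- stats::cor.test(x, y, method = "pearson")
          rec$method <- "Pearson"
          rec$r <- unname(ht$estimate)
          if (!is.null(ht$conf.int)) {  # needs n >= 4
            rec$ci_lo <- ht$conf.int[1]; rec$ci_hi <- ht$conf.int[2]
          }
          rec$p <- ht$p.value
        } else {
          ht <- suppressWarnings(
            stats::cor.test(x, y, method = "spearman", exact = FALSE))
          rec$method <- "Spearman"
          rec$r <- unname(ht$estimate)
          # Fisher-transform approximate CI
          z <- atanh(min(max(rec$r, -1 + 1e-12), 1 - 1e-12))
          se <- 1 / sqrt(n - 3)
          rec$ci_lo <- tanh(z - stats::qnorm(1 - alpha / 2) * se)
          rec$ci_hi <- tanh(z + stats::qnorm(1 - alpha / 2) * se)
          rec$p <- ht$p.value
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- if (is.null(family_size)) nrow(out) else family_size
  if (m < nrow(out)) stop("family_size smaller than the number of records")
  out$bonferroni_alpha <- alpha / m
  out$bonferroni_significant <- !is.na(out$p) & out$p <= alpha / m
  out$p_holm <- adjust_pvalues(out$p, "holm", family_size = m)
  out$p_bh <- adjust_pvalues(out$p, "BH", family_size = m)
  attr(out, "family_size") <- m
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Ordinary least-squares line for a significant correlation
#'
#' Follow-up regression of a clinical score on the marker delta-Ct,
#' intended to be run only for correlations that pass the configured
#' significance gates.
#'
#' @param x delta-Ct vector (predictor).
#' @param y score vector (response).
#' @return list of class `linear_fit`: `slope`, `intercept`, `p`
#'   (two-sided, nonzero slope), `fit` (the `lm` object).
#' @export
fit_line <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0) stop("constant predictor; slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(list(slope = cf["x", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 p = cf["x", "Pr(>|t|)"], fit = fit),
            class = "linear_fit")
}
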