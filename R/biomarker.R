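#' ROC curve with maximum-Youden cutoff for a single marker
#'
#' Evaluates every distinct marker value (plus infinite sentinels) as a
#' decision threshold. With `direction = "<="` (the default, matching a
#' marker whose positive class sits at lower delta-Ct) a sample is called
#' positive when `value <= cutoff`; with `">="` when `value >= cutoff`.
#' AUC is computed by the trapezoid rule and equals the two-sample rank
#' (Mann-Whitney) statistic. The optimal cutoff maximizes the Youden index
#' `J = sensitivity + specificity - 1`; ties break toward higher
#' specificity, then lower threshold. An optional bootstrap 95% CI for the
#' AUC is available via `n_boot`.
#'
#' @param values numeric marker values (e.g. delta-Ct), named or not.
#' @param labels logical or two-level vector; `positive` names the positive
#'   class (default `TRUE` for logical labels).
#' @param direction `"<="` or `">="`: side of the cutoff called positive.
#' @param positive positive-class label.
#' @param n_boot bootstrap replicates for the AUC CI (0 = skip).
#' @param seed seed for the bootstrap.
#' @return list of class `roc_curve`: `points` (threshold, sensitivity,
#'   specificity, fpr, tpr, youden), `auc`, `auc_rank`, `ci` (if bootstrapped),
#'   `cutoff`, `sensitivity`, `specificity`, `youden`, `direction`.
#' @export
roc_curve <- function(values, labels, direction = c("<=", ">="),
                      positive = TRUE, n_boot = 0L, seed = 1L) {
  direction <- match.arg(direction)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  pos <- labels == positive
  if (!any(pos) || !any(!pos)) stop("both classes must be non-empty")

  thr <- c(-Inf, sort(unique(values)), Inf)
  called_pos <- if (direction == "<=")
    outer(values, thr, `<=`) else outer(values, thr, `>=`)
  sens <- colSums(called_pos[pos, , drop = FALSE]) / sum(pos)
  spec <- colSums(!called_pos[!pos, , drop = FALSE]) / sum(!pos)
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec,
                    fpr = 1 - spec, tpr = sens, youden = sens + spec - 1)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL

  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  auc_rank <- .auc_rank(values, pos, direction)

  jmax <- max(pts$youden)
  cand <- pts[abs(pts$youden - jmax) < 1e-12, ]
  cand <- cand[order(-cand$specificity, cand$threshold), ]
  best <- cand[1, ]

  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    idx_p <- which(pos); idx_n <- which(!pos)
    boots <- replicate(n_boot, {
      i <- c(sample(idx_p, replace = TRUE), sample(idx_n, replace = TRUE))
      .auc_rank(values[i], pos[i], direction)
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }

  structure(list(points = pts, auc = auc, auc_rank = auc_rank, ci = ci,
                 cutoff = best$threshold, sensitivity = best$sensitivity,
                 specificity = best$specificity, youden = best$youden,
                 direction = direction, n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_curve")
}

# Mann-Whitney formulation: P(pos scores on the positive side of neg) + ties/2
.auc_rank <- function(values, pos, direction) {
  vp <- values[pos]; vn <- values[!pos]
  cmp <- if (direction == "<=") outer(vp, vn, `<`) else outer(vp, vn, `>`)
  ties <- outer(vp, vn, `==`)
  (sum(cmp) + 0.5 * sum(ties)) / (length(vp) * length(vn))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.3f (%d pos / %d neg); max Youden J = %.3f at cutoff %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$n_pos, x$n_neg, x$youden, x$cutoff,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Univariate logistic model for a single marker
#'
#' Maximum-likelihood logistic regression of class on the marker value. On
#' complete separation the ML estimate diverges; with
#' `fallback = "ridge"` (default) a lightly L2-penalized fit is used instead
#' and flagged in the result.
#'
#' @param values numeric marker values.
#' @param labels class labels; `positive` marks the positive class.
#' @param positive positive-class label.
#' @param fallback `"ridge"` or `"error"` on complete separation.
#' @param lambda ridge penalty for the fallback.
#' @return list of class `logistic_model`: `intercept`, `slope`, `prob`
#'   (fitted probabilities), `separated`, plus a `predict` closure.
#' @export
fit_logistic <- function(values, labels, positive = TRUE,
                         fallback = c("ridge", "error"), lambda = 1e-2) {
  fallback <- match.arg(fallback)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  y <- as.integer(labels[ok] == positive)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  fit <- suppressWarnings(stats::glm(y ~ values, family = stats::binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || all(p > 1 - 1e-8 | p < 1e-8)
  coefs <- stats::coef(fit)
  if (separated) {
    if (fallback == "error") stop("complete separation; no fallback enabled")
    message("complete separation: using ridge-penalized logistic fit")
    nll <- function(b) {
      eta <- b[1] + b[2] * values
      sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * b[2]^2
    }
    coefs <- stats::optim(c(0, 0), nll, method = "BFGS")$par
    names(coefs) <- c("(Intercept)", "values")
  }
  predict_fn <- function(newvalues)
    stats::plogis(coefs[1] + coefs[2] * newvalues)
  structure(list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
                 prob = predict_fn(values), separated = separated,
                 predict = predict_fn),
            class = "logistic_model")
}

# one stratified train/test split; returns indices of the training set
.stratified_train <- function(y, train_fraction) {
  idx <- unlist(lapply(unique(y), function(cl) {
    who <- which(y == cl)
    n_tr <- min(max(round(train_fraction * length(who)), 1L), length(who) - 1L)
    sample(who, n_tr)
  }))
  sort(idx)
}

#' Repeated random sub-sampling cross-validation of the logistic marker model
#'
#' Each repeat draws a stratified split (default 2/3 train, 1/3 test), fits
#' the univariate logistic model on the training samples and scores the test
#' samples. Reported: per-repeat test AUC, the average ROC curve (vertical
#' averaging of TPR on a 101-point FPR grid), the average AUC, per-sample
#' predicted probabilities averaged over the repeats in which the sample was
#' tested, sensitivity/specificity of the averaged probabilities at the 0.5
#' rule, and the misclassified sample ids.
#'
#' @param values named numeric marker values.
#' @param labels class labels aligned with `values`.
#' @param positive positive-class label.
#' @param repeats number of random splits (default 100).
#' @param train_fraction training share (default 2/3).
#' @param seed integer seed.
#' @return list of class `cv_report`: `auc` (mean test AUC), `auc_per_repeat`,
#'   `roc_grid` (fpr, mean tpr), `probabilities` (per-sample averages),
#'   `sensitivity`, `specificity`, `misclassified`, `repeats`.
#' @export
cross_validate <- function(values, labels, positive = TRUE, repeats = 100L,
                           train_fraction = 2 / 3, seed = 1L) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (is.null(names(values))) names(values) <- seq_along(values)
  y <- labels == positive
  stopifnot(sum(y) >= 2, sum(!y) >= 2, repeats >= 1)
  set.seed(seed)
  grid <- seq(0, 1, length.out = 101L)
  tpr_sum <- numeric(101L)
  aucs <- numeric(repeats)
  p_sum <- p_cnt <- stats::setNames(numeric(length(values)), names(values))
  for (r in seq_len(repeats)) {
    tr <- .stratified_train(y, train_fraction)
    te <- setdiff(seq_along(values), tr)
    mod <- fit_logistic(values[tr], y[tr], positive = TRUE)
    p_te <- mod$predict(values[te])
    roc <- roc_curve(p_te, y[te], direction = ">=")
    aucs[r] <- roc$auc
    tpr_sum <- tpr_sum + .tpr_at(roc$points, grid)
    p_sum[te] <- p_sum[te] + p_te
    p_cnt[te] <- p_cnt[te] + 1
  }
  probs <- ifelse(p_cnt > 0, p_sum / p_cnt, NA_real_)
  pred_pos <- !is.na(probs) & probs > 0.5
  sens <- sum(pred_pos & y) / sum(y)
  spec <- sum(!pred_pos & !y) / sum(!y)
  structure(list(auc = mean(aucs), auc_per_repeat = aucs,
                 roc_grid = data.frame(fpr = grid, tpr = tpr_sum / repeats),
                 probabilities = probs,
                 sensitivity = sens, specificity = spec,
                 misclassified = names(values)[pred_pos != y],
                 repeats = repeats, train_fraction = train_fraction),
            class = "cv_report")
}

# step-function TPR of an ROC at given FPR values (vertical averaging)
.tpr_at <- function(points, fpr) {
  vapply(fpr, function(f) max(points$tpr[points$fpr <= f + 1e-12]), numeric(1))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d repeats (train %.0f%%): average AUC %.3f, sensitivity %.2f%%, specificity %.2f%%\n",
              x$repeats, 100 * x$train_fraction, x$auc,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Permutation test on the cross-validated AUC of the marker model
#'
#' Builds the null distribution by re-assigning class labels at random and
#' re-evaluating the model with a short repeated sub-sampling CV
#' (`inner_repeats`, default 3) per permutation; the observed AUC comes from
#' the identical CV procedure on the true labels. The p-value uses the
#' add-one rule `(b + 1) / (n_perm + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_perm number of label permutations (default 100).
#' @param inner_repeats CV repeats per permutation (default 3).
#' @return list of class `permutation_report`: `observed_auc`, `null_auc`,
#'   `p`, `n_perm`, `inner_repeats`.
#' @export
permutation_test <- function(values, labels, positive = TRUE, n_perm = 100L,
                             inner_repeats = 3L, train_fraction = 2 / 3,
                             seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  y <- labels == positive
  observed <- cross_validate(values, y, positive = TRUE,
                             repeats = inner_repeats,
                             train_fraction = train_fraction, seed = seed)$auc
  null_auc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 10000L + b)
    yb <- sample(y)
    null_auc[b] <- cross_validate(values, yb, positive = TRUE,
                                  repeats = inner_repeats,
                                  train_fraction = train_fraction,
                                  seed = seed + 20000L + b)$auc
  }
  p <- (sum(null_auc >= observed) + 1) / (n_perm + 1)
  structure(list(observed_auc = observed, null_auc = null_auc, p = p,
                 n_perm = n_perm, inner_repeats = inner_repeats),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation_report: observed AUC %.3f vs %d permutations (inner CV x%d): p = %.4g\n",
              x$observed_auc, x$n_perm, x$inner_repeats, x$p))
  invisible(x)
}
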