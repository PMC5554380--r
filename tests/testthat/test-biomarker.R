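test_that("perfect separation gives AUC = 1 and Youden J = 1", {
  v <- c(1, 1.5, 2, 5, 5.5, 6)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)  # positives at low delta-Ct
  roc <- roc_curve(v, lab)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_true(roc$cutoff >= 2 && roc$cutoff < 5)
})

test_that("AUC equals the exhaustive pair-counting oracle, ties at 1/2", {
  v <- c(1, 2, 3, 4, 3, 4, 5, 6)
  lab <- rep(c(TRUE, FALSE), each = 4)
  roc <- roc_curve(v, lab)
  expect_equal(roc$auc, auc_pair_oracle(v, lab))
  expect_equal(roc$auc_rank, auc_pair_oracle(v, lab))
})

test_that("trapezoid AUC equals the rank-statistic AUC on random data", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(8:40, 1)
    v <- round(rnorm(n, 3, 1), sample(c(1, 2, 8), 1))  # force some ties
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    dirn <- sample(c("<=", ">="), 1)
    roc <- roc_curve(v, lab, direction = dirn)
    expect_equal(roc$auc, roc$auc_rank, tolerance = 1e-12)
    expect_equal(roc$auc, auc_pair_oracle(v, lab, dirn), tolerance = 1e-12)
  }
})

test_that("curve anchors at (0,0) and (1,1); Youden argmax matches exhaustive search", {
  set.seed(91)
  v <- rnorm(30, 3, 1); lab <- runif(30) < 0.4
  roc <- roc_curve(v, lab)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  # exhaustive threshold search oracle
  js <- vapply(roc$points$threshold, function(t) {
    called <- v <= t
    sum(called & lab) / sum(lab) + sum(!called & !lab) / sum(!lab) - 1
  }, numeric(1))
  expect_equal(roc$youden, max(js), tolerance = 1e-12)
  expect_equal(roc$points$youden, js, tolerance = 1e-12)
})

test_that("flipping the decision direction mirrors AUC and swaps sens/spec", {
  set.seed(92)
  v <- rnorm(40, 3, 1); lab <- runif(40) < 0.5
  a <- roc_curve(v, lab, direction = "<=")
  b <- roc_curve(v, lab, direction = ">=")
  expect_equal(a$auc, 1 - b$auc, tolerance = 1e-12)
})

test_that("our ROC AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  v <- rnorm(60, 3, 1); lab <- runif(60) < 0.45
  ours <- roc_curve(v, lab, direction = "<=")
  theirs <- suppressMessages(pROC::roc(response = lab, predictor = v,
                                       direction = ">"))  # pos class lower
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("logistic model: symmetry, monotonicity and recovery of known coefficients", {
  # overlapping classes, symmetric about 4: x with label L mirrors 8-x with !L
  v <- c(1, 2, 3, 5, 6, 7)
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  mod <- fit_logistic(v, lab)
  expect_equal(unname(mod$predict(4)), 0.5, tolerance = 1e-6)
  expect_true(mod$slope < 0)  # lower delta-Ct -> higher positive probability
  expect_true(all(diff(mod$predict(seq(0, 8, 0.5))) < 0))

  set.seed(94)
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    x <- rnorm(500)
    y <- runif(500) < plogis(-2 * x)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    ci <- suppressMessages(confint.default(fit))["x", ]
    ci[1] <= -2 && -2 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("complete separation triggers the ridge fallback (or an error on request)", {
  v <- c(1, 2, 3, 10, 11, 12)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_message(mod <- fit_logistic(v, lab, fallback = "ridge"),
                 "complete separation")
  expect_true(mod$separated)
  expect_true(is.finite(mod$slope))
  expect_error(suppressMessages(fit_logistic(v, lab, fallback = "error")),
               "separation")
})

test_that("cross-validation on separated classes returns AUC 1 and is seed-deterministic", {
  v <- setNames(c(1, 1.2, 1.4, 1.6, 5, 5.2, 5.4, 5.6), paste0("s", 1:8))
  lab <- rep(c(TRUE, FALSE), each = 4)
  cv <- cross_validate(v, lab, repeats = 20, seed = 7)
  expect_equal(cv$auc, 1)
  cv2 <- cross_validate(v, lab, repeats = 20, seed = 7)
  expect_identical(cv$auc_per_repeat, cv2$auc_per_repeat)
  expect_identical(cv$probabilities, cv2$probabilities)
  expect_length(cv$misclassified, 0)
})

test_that("average CV AUC tracks the binormal closed form at n = 30 + 25", {
  delta <- 1; sigma <- 1
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    v <- c(rnorm(30, 2 - delta, sigma), rnorm(25, 2, sigma))
    names(v) <- paste0("s", seq_along(v))
    lab <- rep(c(TRUE, FALSE), c(30, 25))
    cross_validate(v, lab, repeats = 100, seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - pnorm(delta / sqrt(2))), 0.05)
})

test_that("resubstitution AUC is optimistic relative to CV AUC on average", {
  diffs <- vapply(1:15, function(s) {
    set.seed(s)
    v <- c(rnorm(20, 1.6, 1), rnorm(20, 2.4, 1))
    names(v) <- paste0("s", seq_along(v))
    lab <- rep(c(TRUE, FALSE), each = 20)
    roc_curve(v, lab)$auc - cross_validate(v, lab, repeats = 50, seed = s)$auc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("permutation test validates inputs and finds strong signal", {
  v <- setNames(c(rnorm(12, 0, 1), rnorm(12, 3, 1)), paste0("s", 1:24))
  lab <- rep(c(TRUE, FALSE), each = 12)
  expect_error(permutation_test(v, lab, n_perm = 0), "n_perm")
  sig <- vapply(1:10, function(s)
    permutation_test(v, lab, n_perm = 50, seed = s)$p <= 0.05, logical(1))
  expect_gte(mean(sig), 0.95)
})
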