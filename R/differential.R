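#' SAM-style two-class unpaired permutation test on a delta-Ct matrix
#'
#' Per-miRNA relative difference `d = (mean(g1) - mean(g2)) / (s + s0)` with
#' the pooled standard error `s` and a fudge factor `s0` chosen on the
#' percentile grid of `s` to minimize the coefficient of variation of `d`
#' across the spread of `s` (the original SAM recipe). The false discovery
#' rate is calibrated by permuting the group labels: with
#' `choose(n, n1) <= n_perm` all distinct label assignments are enumerated,
#' otherwise `n_perm` random assignments are drawn. Per-miRNA q-values use
#' the symmetric cutoff at `|d|`, scaled by the pi0 estimate from the
#' interquartile band of the permuted statistics, then monotonized.
#'
#' @param dct `delta_ct_matrix` or plain numeric matrix (miRNAs x samples).
#' @param g1,g2 sample ids of the two groups (each >= 2).
#' @param fdr_cutoff FDR level for the call set (default 0.15).
#' @param n_perm minimum number of permutations (default 100).
#' @param seed integer seed for the permutation draw.
#' @param s0 optional fudge-factor override; default: percentile-grid search.
#' @return list of class `sam_result`: `table` (miRNA, d, s, q), `s0`,
#'   `s0_percentile`, `n_perm_used`, `exhaustive`, `called` (ids at
#'   `q <= fdr_cutoff`), `dropped` (ids with no data in a group), `pi0`.
#' @export
sam_two_class <- function(dct, g1, g2, fdr_cutoff = 0.15, n_perm = 100L,
                          seed = 1L, s0 = NULL) {
  x <- if (inherits(dct, "delta_ct_matrix")) dct$dct else as.matrix(dct)
  stopifnot(length(g1) >= 2, length(g2) >= 2,
            all(c(g1, g2) %in% colnames(x)))
  x <- x[, c(g1, g2), drop = FALSE]
  labels <- c(rep(TRUE, length(g1)), rep(FALSE, length(g2)))

  ok1 <- rowSums(!is.na(x[, labels, drop = FALSE])) > 0
  ok2 <- rowSums(!is.na(x[, !labels, drop = FALSE])) > 0
  dropped <- rownames(x)[!(ok1 & ok2)]
  if (length(dropped))
    message(sprintf("dropping %d miRNA(s) with no data in one group", length(dropped)))
  x <- x[ok1 & ok2, , drop = FALSE]
  if (!nrow(x)) stop("no testable miRNAs")

  ds <- .sam_d(x, labels, s0 = 0)
  s <- ds$s
  if (is.null(s0)) {
    grid <- stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
    cvs <- vapply(grid, function(s0c) .sam_cv(ds$r, s, s0c), numeric(1))
    pick <- which.min(cvs)
    if (!is.finite(cvs[pick])) {  # too few rows to profile the CV: fall back
      s0 <- stats::median(s)
      s0_pct <- 0.5
    } else {
      s0 <- grid[pick]
      s0_pct <- (pick - 1) * 0.05
    }
  } else s0_pct <- NA_real_
  d <- ds$r / (s + s0)

  n <- length(labels)
  n1 <- sum(labels)
  all_assign <- utils::combn(n, n1)
  exhaustive <- ncol(all_assign) <= n_perm
  if (exhaustive) {
    perms <- all_assign
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n, n1))
  }
  B <- ncol(perms)
  dperm <- matrix(NA_real_, nrow(x), B)
  for (b in seq_len(B)) {
    lab <- rep(FALSE, n)
    lab[perms[, b]] <- TRUE
    db <- .sam_d(x, lab, s0 = s0)
    dperm[, b] <- db$d
  }

  abs_d <- abs(d)
  abs_perm <- abs(as.vector(dperm))
  # expected count of permuted |d*| >= |d_i|, averaged over permutations
  exp_count <- (length(abs_perm) - findInterval(abs_d - 1e-12, sort(abs_perm))) / B
  obs_count <- vapply(abs_d, function(t) sum(abs_d >= t - 1e-12), numeric(1))
  qb <- stats::quantile(as.vector(dperm), c(0.25, 0.75), na.rm = TRUE)
  pi0 <- min(1, sum(d >= qb[1] & d <= qb[2]) / (0.5 * length(d)))
  q <- pmin(1, pi0 * exp_count / obs_count)
  ord <- order(abs_d, decreasing = TRUE)
  q[ord] <- rev(cummin(rev(q[ord])))

  tab <- data.frame(miRNA = rownames(x), d = d, s = s, q = q,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$d)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, s0 = s0, s0_percentile = s0_pct,
                 n_perm_used = B, exhaustive = exhaustive,
                 called = tab$miRNA[tab$q <= fdr_cutoff],
                 dropped = dropped, pi0 = unname(pi0),
                 fdr_cutoff = fdr_cutoff),
            class = "sam_result")
}

# relative difference r, pooled SE s, and d for one labelling
.sam_d <- function(x, labels, s0 = 0) {
  x1 <- x[, labels, drop = FALSE]
  x2 <- x[, !labels, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / pmax(n1 + n2 - 2, 1))
  r <- m1 - m2
  list(r = r, s = s, d = r / (s + s0))
}

# coefficient of variation of the MAD of d across s-quantile windows
.sam_cv <- function(r, s, s0) {
  d <- r / (s + s0)
  nw <- min(100L, max(2L, floor(length(s) / 4)))
  br <- stats::quantile(s, seq(0, 1, length.out = nw + 1), names = FALSE)
  grp <- cut(s, unique(br), include.lowest = TRUE)
  mads <- tapply(d, grp, stats::mad)
  mads <- mads[!is.na(mads) & mads > 0]
  if (length(mads) < 2) return(Inf)
  stats::sd(mads) / abs(mean(mads))
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d miRNAs tested, %d permutations%s, s0 = %.4g\n",
              nrow(x$table), x$n_perm_used,
              if (x$exhaustive) " (exhaustive)" else "", x$s0))
  cat(sprintf("  %d called at q <= %.2f\n", length(x$called), x$fdr_cutoff))
  invisible(x)
}

#' Ordinary one-way ANOVA with Tukey multiple comparisons on one miRNA
#'
#' Tests differential expression of a single miRNA's delta-Ct across the
#' cohort groups, then identifies which group pairs differ via Tukey's
#' honestly-significant-difference test (multiplicity-adjusted p from the
#' studentized-range distribution, deterministic). Pairwise fold changes use
#' the 2^-ddCt convention.
#'
#' @param dct `delta_ct_matrix`, or named numeric vector of delta-Ct.
#' @param cohort a `cohort_table` (sample, group).
#' @param mirna id, required when `dct` is a matrix object.
#' @param alpha significance level for the reported verdicts (default 0.05).
#' @return list of class `anova_tukey_result`: `F`, `p`, `pairs` (data.frame
#'   with diff, adjusted p, fc), `groups` (n, mean, sd), `alpha`.
#' @export
anova_tukey <- function(dct, cohort, mirna = NULL, alpha = 0.05) {
  v <- if (inherits(dct, "delta_ct_matrix")) {
    stopifnot(!is.null(mirna))
    dct$dct[mirna, ]
  } else dct
  idx <- match(cohort$sample, names(v))
  stopifnot(!anyNA(idx))
  df <- data.frame(y = as.numeric(v[idx]), g = droplevels(cohort$group))
  df <- df[!is.na(df$y), ]
  tabn <- table(df$g)
  if (length(tabn) < 2 || any(tabn < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (all(tapply(df$y, df$g, stats::sd) == 0))
    stop("zero within-group variance everywhere; F undefined")
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  # diff is mean(level_i) - mean(level_j) for pair "i-j"; FC = 2^-ddCt
  pairs$fc <- 2^(-pairs$diff)
  rownames(pairs) <- NULL
  gs <- data.frame(group = names(tabn), n = as.integer(tabn),
                   mean = as.numeric(tapply(df$y, df$g, mean)),
                   sd = as.numeric(tapply(df$y, df$g, stats::sd)),
                   stringsAsFactors = FALSE)
  structure(list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                 pairs = pairs, groups = gs, alpha = alpha),
            class = "anova_tukey_result")
}

#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines the skewness and kurtosis z-transforms (D'Agostino 1970;
#' Anscombe & Glynn 1983) into `K2 = Z1^2 + Z2^2`, chi-squared with 2 df
#' under normality. Requires n >= 8 for a stable kurtosis transform.
#'
#' @param x numeric vector.
#' @return list: `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson K2 requires n >= 8")
  if (stats::sd(x) == 0) stop("constant vector; K2 undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Per-group normality check (D'Agostino-Pearson K2 + Shapiro-Wilk)
#'
#' Runs both tests in every group and returns a combined verdict:
#' non-normal if either test rejects at `alpha` in any group. K2 is omitted
#' (with a note) for groups below n = 8; a constant group makes Shapiro-Wilk
#' undefined and forces a non-normal verdict by convention.
#'
#' @param values named list of numeric vectors, one per group.
#' @param alpha significance level (default 0.05).
#' @return list of class `normality_report`: `table` (group, n, K2, K2 p,
#'   W, W p), `verdict` ("normal"/"non-normal"), `notes`.
#' @export
normality_check <- function(values, alpha = 0.05) {
  stopifnot(is.list(values), length(values) >= 1)
  notes <- character()
  rows <- lapply(names(values), function(g) {
    x <- values[[g]][!is.na(values[[g]])]
    n <- length(x)
    k2 <- k2p <- NA_real_
    w <- wp <- NA_real_
    degenerate <- FALSE
    if (n >= 3 && stats::sd(x) > 0) {
      sw <- stats::shapiro.test(x)
      w <- unname(sw$statistic); wp <- sw$p.value
    } else {
      notes <<- c(notes, sprintf("group '%s': Shapiro-Wilk undefined (n=%d%s)",
                                 g, n, if (n >= 3) ", constant" else ""))
      degenerate <- TRUE
    }
    if (n >= 8 && stats::sd(x) > 0) {
      dk <- dagostino_k2(x)
      k2 <- dk$statistic; k2p <- dk$p.value
    } else if (n < 8) {
      notes <<- c(notes, sprintf("group '%s': K2 omitted (n=%d < 8)", g, n))
    }
    data.frame(group = g, n = n, K2 = k2, K2_p = k2p, W = w, W_p = wp,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  reject <- any(tab$K2_p <= alpha, na.rm = TRUE) ||
    any(tab$W_p <= alpha, na.rm = TRUE) || any(tab$degenerate)
  structure(list(table = tab,
                 verdict = if (reject) "non-normal" else "normal",
                 alpha = alpha, notes = notes),
            class = "normality_report")
}
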