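#' Flagged-well-aware reference profile of a Ct matrix
#'
#' For the samples of one comparison, computes the per-sample median and mean
#' Ct over the "complete" miRNAs only: any miRNA with at least one flagged
#' well among those samples is excluded from both statistics in every sample.
#' The profile reflects the loaded mass of template cDNA on each card and is
#' the yardstick against which candidate endogenous controls are ranked.
#'
#' @param ct a [ct_matrix()].
#' @param samples sample ids (or indices) of the comparison; default all.
#' @return list of class `reference_profile`: `median`, `mean` (named per
#'   sample), `excluded` (miRNA ids dropped by the flag rule), `samples`.
#' @export
build_reference_profile <- function(ct, samples = colnames(ct$ct)) {
  stopifnot(inherits(ct, "ct_matrix"))
  vals <- ct_values(ct)[, samples, drop = FALSE]
  if (ncol(vals) < 2) stop("need at least 2 samples for a reference profile")
  excluded <- rownames(vals)[apply(is.na(vals), 1, any)]
  keep <- vals[!rownames(vals) %in% excluded, , drop = FALSE]
  if (nrow(keep) < 2) stop("no unflagged complete rows")
  structure(list(
    median = apply(keep, 2, stats::median),
    mean = colMeans(keep),
    excluded = excluded,
    samples = colnames(vals)), class = "reference_profile")
}

#' Rank candidate endogenous controls by correlation with the reference
#'
#' Each non-excluded miRNA's Ct vector is Pearson-correlated with the
#' per-sample median and mean reference profiles; miRNAs are ranked by
#' descending correlation (default: the average of the two correlations —
#' both component rankings are reported). Selection follows the two-stage
#' stability-then-abundance rule: take the `m` most correlated miRNAs, then
#' keep the `k` most abundant (lowest mean Ct) among them, so the selected
#' controls are both stable and well expressed. Ties in r break toward lower
#' mean Ct, then lexicographic id. Zero-variance rows have undefined
#' correlation and are dropped from the ranking with a message.
#'
#' @param ct a [ct_matrix()].
#' @param profile matching [build_reference_profile()].
#' @param k number of controls to select (default 3).
#' @param m stability pool size for the abundance stage (default 10).
#' @param rank_by `"average"`, `"median"` or `"mean"`: which correlation
#'   drives the ranking.
#' @return list of class `control_ranking`: `table` (data.frame with
#'   r_median, r_mean, r, mean_ct, rank, selected), `selected` (ids).
#' @export
rank_endogenous_controls <- function(ct, profile, k = 3L, m = 10L,
                                     rank_by = c("average", "median", "mean")) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(profile, "reference_profile"),
            k >= 1L, m >= k)
  rank_by <- match.arg(rank_by)
  vals <- ct_values(ct)[, profile$samples, drop = FALSE]
  vals <- vals[!rownames(vals) %in% profile$excluded, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  zv <- sds == 0 | is.na(sds)
  if (any(zv))
    message(sprintf("dropping %d zero-variance miRNA(s) from control ranking", sum(zv)))
  vals <- vals[!zv, , drop = FALSE]
  if (!nrow(vals)) stop("no rankable miRNAs")
  r_med <- apply(vals, 1, stats::cor, y = profile$median)
  r_mean <- apply(vals, 1, stats::cor, y = profile$mean)
  r <- switch(rank_by, average = (r_med + r_mean) / 2, median = r_med, mean = r_mean)
  mean_ct <- rowMeans(vals)
  ord <- order(-r, mean_ct, rownames(vals))
  tab <- data.frame(miRNA = rownames(vals), r_median = r_med, r_mean = r_mean,
                    r = r, mean_ct = mean_ct, stringsAsFactors = FALSE)[ord, ]
  tab$rank <- seq_len(nrow(tab))
  pool <- tab$miRNA[seq_len(min(m, nrow(tab)))]
  sel_n <- min(k, nrow(tab))
  selected <- pool[order(tab$mean_ct[match(pool, tab$miRNA)])][seq_len(sel_n)]
  tab$selected <- tab$miRNA %in% selected
  rownames(tab) <- NULL
  structure(list(table = tab, selected = selected, k = k, m = m,
                 rank_by = rank_by), class = "control_ranking")
}

#' Normalize a Ct matrix to selected endogenous controls (delta-Ct)
#'
#' `dCt(miRNA, sample) = Ct(miRNA, sample) - mean(Ct(controls, sample))`.
#' Lower delta-Ct means higher relative expression. A cell is defined only
#' where the target well and every control well are unflagged; a flagged
#' control well invalidates that sample's reference (error, or the sample is
#' dropped when `on_flagged_control = "drop_sample"`).
#'
#' @param ct a [ct_matrix()].
#' @param controls character vector of control miRNA ids (non-empty).
#' @param samples sample subset; default all.
#' @param on_flagged_control `"error"` (default) or `"drop_sample"`.
#' @return list of class `delta_ct_matrix`: `dct` (matrix, NA where
#'   undefined), `controls`, `reference` (per-sample reference Ct).
#' @export
compute_delta_ct <- function(ct, controls, samples = colnames(ct$ct),
                             on_flagged_control = c("error", "drop_sample")) {
  stopifnot(inherits(ct, "ct_matrix"), length(controls) >= 1)
  on_flagged_control <- match.arg(on_flagged_control)
  missing_ctrl <- setdiff(controls, rownames(ct$ct))
  if (length(missing_ctrl))
    stop("control(s) not in matrix: ", paste(missing_ctrl, collapse = ", "))
  vals <- ct_values(ct)[, samples, drop = FALSE]
  cvals <- vals[controls, , drop = FALSE]
  bad <- colnames(cvals)[apply(is.na(cvals), 2, any)]
  if (length(bad)) {
    if (on_flagged_control == "error")
      stop("flagged control well in sample(s): ", paste(bad, collapse = ", "))
    vals <- vals[, setdiff(colnames(vals), bad), drop = FALSE]
    cvals <- cvals[, colnames(vals), drop = FALSE]
  }
  reference <- colMeans(cvals)
  dct <- sweep(vals, 2, reference)
  structure(list(dct = dct, controls = controls, reference = reference),
            class = "delta_ct_matrix")
}

#' @export
print.delta_ct_matrix <- function(x, ...) {
  cat(sprintf("delta_ct_matrix: %d miRNAs x %d samples, controls: %s\n",
              nrow(x$dct), ncol(x$dct), paste(x$controls, collapse = ", ")))
  invisible(x)
}

#' Fold change between two sample groups by the 2^-ddCt method
#'
#' `ddCt = mean dCt(group1) - mean dCt(group2)` over non-missing cells, and
#' `FC = 2^-ddCt`, so FC > 1 means higher expression in group1.
#'
#' @param dct a `delta_ct_matrix` or a plain named numeric vector of
#'   delta-Ct values for one miRNA.
#' @param g1,g2 sample id vectors for the two groups.
#' @param mirna miRNA id (required when `dct` is a matrix object).
#' @return list: `mean_g1`, `mean_g2`, `ddct`, `fc`, `n_g1`, `n_g2`.
#' @export
fold_change <- function(dct, g1, g2, mirna = NULL) {
  v <- if (inherits(dct, "delta_ct_matrix")) {
    stopifnot(!is.null(mirna), mirna %in% rownames(dct$dct))
    dct$dct[mirna, ]
  } else dct
  x1 <- v[g1]; x1 <- x1[!is.na(x1)]
  x2 <- v[g2]; x2 <- x2[!is.na(x2)]
  if (!length(x1) || !length(x2))
    stop("a group is empty after removing missing delta-Ct values")
  ddct <- mean(x1) - mean(x2)
  list(mean_g1 = mean(x1), mean_g2 = mean(x2), ddct = ddct,
       fc = 2^(-ddct), n_g1 = length(x1), n_g2 = length(x2))
}

#' One-call customized normalization for a two-group comparison
#'
#' Convenience wrapper chaining [build_reference_profile()],
#' [rank_endogenous_controls()] and [compute_delta_ct()] on the union of the
#' two groups' samples, mirroring the per-comparison workflow: the reference
#' profile, exclusion set and control ranking are recomputed for each
#' comparison.
#'
#' @inheritParams rank_endogenous_controls
#' @param samples samples of the comparison.
#' @param on_flagged_control see [compute_delta_ct()].
#' @return list: `profile`, `ranking`, `dct` (a `delta_ct_matrix`).
#' @export
normalize_comparison <- function(ct, samples, k = 3L, m = 10L,
                                 rank_by = "average",
                                 on_flagged_control = "drop_sample") {
  profile <- build_reference_profile(ct, samples)
  ranking <- rank_endogenous_controls(ct, profile, k = k, m = m,
                                      rank_by = rank_by)
  dct <- compute_delta_ct(ct, ranking$selected, samples,
                          on_flagged_control = on_flagged_control)
  list(profile = profile, ranking = ranking, dct = dct)
}
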