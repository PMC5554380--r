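#' Simulation configuration for synthetic serum-miRNA cohorts
#'
#' Bundles every tunable of the two generators, [simulate_profiling()] and
#' [simulate_validation_cohort()]. Defaults reproduce the study-design
#' conditions the pipeline targets: a 754-miRNA two-panel TLDA profiling set
#' over 4 ASD / 5 TS / 4 TS+ASD / 3 NC sera, and a 30/24/25/25 four-group
#' validation cohort whose marker miRNA sits at a lower delta-Ct (higher
#' expression) in ASD, with tic severity (YGTSS) linearly tied to the marker
#' delta-Ct.
#'
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @param profiling_groups named integer vector of per-group sample counts
#'   for the profiling arm.
#' @param n_mirna_panel miRNAs per TLDA panel (two panels; 2 x 377 = 754).
#' @param baseline_ct_range baseline mean Ct per miRNA is drawn uniformly
#'   from this range (cycles).
#' @param noise_sd_range per-miRNA biological/technical SD drawn uniformly
#'   from this range (cycles).
#' @param loading_sd SD of the per-sample loading offset (cycles), the
#'   template-mass shift every well on a card shares.
#' @param n_controls number of designated stable endogenous-control miRNAs.
#' @param control_sd residual SD of the stable controls (cycles; near zero).
#' @param marker_effect cycles added to the marker miRNA's Ct in the
#'   affected groups of the profiling arm (negative = upregulated).
#' @param marker_groups groups receiving `marker_effect`.
#' @param flag_prob per-well probability of a flagged (undetermined) well.
#' @param flag_high_ct_bias if `TRUE`, flag probability scales with baseline
#'   Ct (low-abundance wells fail more often), emulating real undetermined
#'   wells; default is missing-at-random.
#' @param validation_groups named integer vector of validation-cohort sizes.
#' @param marker_mu named numeric: group means of the marker's delta-Ct in
#'   the validation cohort. Defaults place ASD lowest, at separations that
#'   emulate the discrimination levels the method is meant to detect.
#' @param marker_sd within-group SD of the marker delta-Ct.
#' @param ygtss_slope,ygtss_intercept,ygtss_sd linear model
#'   YGTSS = slope * delta-Ct + intercept + N(0, sd); scores are rounded to
#'   integers and clamped to 0..100 after generation.
#' @param iq_mean,iq_sd,ados_mean,ados_sd group-conditional score models
#'   (lists of named numeric vectors); NC ADOS items are fixed at 0.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       profiling_groups = c(ASD = 4L, TS = 5L, `TS+ASD` = 4L, NC = 3L),
                       n_mirna_panel = 377L,
                       baseline_ct_range = c(22, 35),
                       noise_sd_range = c(0.5, 1.5),
                       loading_sd = 0.5,
                       n_controls = 3L,
                       control_sd = 0.01,
                       marker_effect = -3,
                       marker_groups = "ASD",
                       flag_prob = 0.05,
                       flag_high_ct_bias = FALSE,
                       validation_groups = c(ASD = 30L, TS = 24L, `TS+ASD` = 25L, NC = 25L),
                       marker_mu = c(ASD = 2.0, TS = 2.75, `TS+ASD` = 3.0, NC = 2.7),
                       marker_sd = 0.9,
                       ygtss_slope = 4.537,
                       ygtss_intercept = -3.269,
                       ygtss_sd = 5,
                       iq_mean = c(ASD = 59.4, TS = 93.7, `TS+ASD` = 94.6, NC = 80.9),
                       iq_sd = c(ASD = 20.6, TS = 19.1, `TS+ASD` = 8.9, NC = 24.5),
                       ados_mean = list(
                         ADOS_A = c(ASD = 7.3, TS = 0, `TS+ASD` = 6.4, NC = 0),
                         ADOS_B = c(ASD = 7.6, TS = 0, `TS+ASD` = 8.5, NC = 0),
                         ADOS_C = c(ASD = 3.0, TS = 0, `TS+ASD` = 3.1, NC = 0),
                         ADOS_D = c(ASD = 3.5, TS = 2.4, `TS+ASD` = 3.7, NC = 0)),
                       ados_sd = list(
                         ADOS_A = c(ASD = 2.3, TS = 0, `TS+ASD` = 3.2, NC = 0),
                         ADOS_B = c(ASD = 2.1, TS = 0, `TS+ASD` = 3.9, NC = 0),
                         ADOS_C = c(ASD = 2.5, TS = 0, `TS+ASD` = 4.3, NC = 0),
                         ADOS_D = c(ASD = 1.6, TS = 1.6, `TS+ASD` = 1.9, NC = 0))) {
  cfg <- as.list(environment())
  stopifnot(cfg$flag_prob >= 0, cfg$flag_prob <= 1,
            cfg$loading_sd >= 0, cfg$marker_sd >= 0, cfg$ygtss_sd >= 0,
            cfg$control_sd >= 0,
            all(cfg$profiling_groups >= 2L),
            all(cfg$validation_groups >= 2L),
            cfg$n_controls >= 0L, cfg$n_mirna_panel > cfg$n_controls)
  class(cfg) <- "sim_config"
  cfg
}

.sample_ids <- function(groups) {
  unlist(lapply(names(groups), function(g) {
    sprintf("%s_%02d", gsub("\\+", "", g), seq_len(groups[[g]]))
  }), use.names = FALSE)
}

#' Simulate a TLDA-style profiling Ct matrix
#'
#' One panel per call. Each well is
#' `Ct = baseline(miRNA) + loading(sample) + effect(marker rows, affected
#' groups) + noise`, with wells flagged independently (optionally biased
#' toward high-Ct rows). Designated stable-control rows carry near-zero
#' biological variance, so they track the per-sample loading offset and
#' should be recovered by [rank_endogenous_controls()].
#'
#' @param config a [sim_config()].
#' @param panel panel label, `"A"` or `"B"` (panels differ only by seed
#'   stream).
#' @return a [ct_matrix()] with attribute `truth`: a list carrying the
#'   group assignment, true loading offsets, designated stable controls and
#'   true differentially expressed (marker) miRNAs.
#' @export
simulate_profiling <- function(config = sim_config(), panel = "A") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L * (match(panel, c("A", "B"), nomatch = 3L) - 1L))
  groups <- config$profiling_groups
  samples <- .sample_ids(groups)
  group_of <- rep(names(groups), groups)
  m <- config$n_mirna_panel
  mirnas <- sprintf("miR-%s-%03d", panel, seq_len(m))
  controls <- if (config$n_controls > 0L)
    sprintf("miR-%s-ctrl%d", panel, seq_len(config$n_controls)) else character()
  mirnas[seq_along(controls)] <- controls

  baseline <- stats::runif(m, config$baseline_ct_range[1], config$baseline_ct_range[2])
  noise_sd <- stats::runif(m, config$noise_sd_range[1], config$noise_sd_range[2])
  # controls: abundant and stable
  baseline[seq_along(controls)] <- stats::runif(length(controls), 22, 26)
  noise_sd[seq_along(controls)] <- config$control_sd
  loading <- stats::rnorm(length(samples), 0, config$loading_sd)

  marker <- if (m > length(controls)) mirnas[length(controls) + 1L] else character()
  eff <- matrix(0, m, length(samples))
  if (length(marker) && config$marker_effect != 0)
    eff[match(marker, mirnas), group_of %in% config$marker_groups] <- config$marker_effect

  ct <- outer(baseline, loading, `+`) + eff +
    matrix(stats::rnorm(m * length(samples), 0, 1), m) * noise_sd
  dimnames(ct) <- list(mirnas, samples)

  p <- config$flag_prob
  pmat <- if (config$flag_high_ct_bias && p > 0) {
    # scale so the matrix-wide mean flag rate stays ~ flag_prob
    w <- (baseline - min(baseline)) / max(diff(range(baseline)), 1e-9)
    matrix(pmin(1, 2 * p * w), m, length(samples))
  } else matrix(p, m, length(samples))
  flag <- matrix(stats::runif(m * length(samples)) < pmat, m,
                 dimnames = dimnames(ct))

  out <- ct_matrix(ct, flag, panel = panel)
  attr(out, "truth") <- list(
    group = stats::setNames(group_of, samples),
    loading = stats::setNames(loading, samples),
    stable_controls = controls,
    de_mirnas = if (config$marker_effect != 0) marker else character(),
    marker_effect = config$marker_effect,
    n_flagged = sum(flag))
  out
}

#' Simulate a validation cohort: marker delta-Ct plus clinical scores
#'
#' Marker delta-Ct for a sample in group g is drawn from
#' `Normal(marker_mu[g], marker_sd)`. YGTSS is generated from the configured
#' linear model on the latent delta-Ct plus Gaussian noise; ADOS items and IQ
#' are group-conditional Gaussians (NC ADOS fixed at 0). Scores are rounded
#' to integers (the scales are integer-valued) and clamped to their ranges
#' after generation, so the latent linear model is exact before rounding.
#'
#' @param config a [sim_config()].
#' @return list with `dct` (named numeric vector of marker delta-Ct per
#'   sample), `cohort` (a `cohort_table`), and `truth` (the generating
#'   parameters plus the unrounded YGTSS).
#' @export
simulate_validation_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 7L)
  groups <- config$validation_groups
  stopifnot(all(names(groups) %in% names(config$marker_mu)))
  samples <- .sample_ids(groups)
  group_of <- rep(names(groups), groups)
  n <- length(samples)

  dct <- stats::rnorm(n, config$marker_mu[group_of], config$marker_sd)
  names(dct) <- samples

  ygtss_latent <- config$ygtss_slope * dct + config$ygtss_intercept +
    stats::rnorm(n, 0, config$ygtss_sd)
  ygtss <- pmin(100, pmax(0, round(ygtss_latent)))

  iq <- round(stats::rnorm(n, config$iq_mean[group_of], config$iq_sd[group_of]))
  iq <- pmax(1, iq)

  ados <- sapply(names(config$ados_mean), function(item) {
    mu <- config$ados_mean[[item]][group_of]
    sd <- config$ados_sd[[item]][group_of]
    pmax(0, round(stats::rnorm(n, mu, sd)))
  })
  rownames(ados) <- samples

  cohort <- as_cohort_table(data.frame(
    sample = samples, group = group_of, IQ = iq, YGTSS = ygtss,
    ados, check.names = FALSE, stringsAsFactors = FALSE))

  list(dct = dct, cohort = cohort,
       truth = list(mu = config$marker_mu[names(groups)], sd = config$marker_sd,
                    slope = config$ygtss_slope, intercept = config$ygtss_intercept,
                    ygtss_sd = config$ygtss_sd, ygtss_latent = ygtss_latent,
                    group = stats::setNames(group_of, samples)))
}
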