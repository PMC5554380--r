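mk_ct <- function(ct, flag = NULL) {
  dimnames(ct) <- list(paste0("m", seq_len(nrow(ct))),
                       paste0("s", seq_len(ncol(ct))))
  ct_matrix(ct, flag)
}

test_that("reference profile: per-sample median/mean over complete rows only", {
  x <- mk_ct(cbind(c(20, 30, 40), c(21, 31, 41)))
  pr <- build_reference_profile(x)
  expect_equal(unname(pr$median), c(30, 31))
  expect_equal(unname(pr$mean), c(30, 31))
  expect_length(pr$excluded, 0)

  # one flagged well in row 2 drops row 2 from BOTH samples' statistics
  flag <- matrix(FALSE, 3, 2); flag[2, 1] <- TRUE
  xf <- mk_ct(cbind(c(20, 30, 40), c(21, 31, 41)), flag)
  prf <- build_reference_profile(xf)
  expect_equal(prf$excluded, "m2")
  expect_equal(unname(prf$median), c(30, 31))  # median of {20,40}, {21,41}
  expect_equal(unname(prf$mean), c(30, 31))
})

test_that("reference profile errors when every row is flagged somewhere", {
  flag <- diag(2) == 1
  x <- mk_ct(cbind(c(20, 30), c(21, 31)), flag)
  expect_error(build_reference_profile(x), "no unflagged complete rows")
})

test_that("a row tracking the profile plus a constant ranks first (affine invariance)", {
  set.seed(7)
  base <- matrix(rnorm(20, 28, 2), 5, 4)
  x <- mk_ct(base)
  pr <- build_reference_profile(x)
  # row 1 becomes the median profile + 3 cycles; rank against that profile
  base[1, ] <- pr$median + 3
  x2 <- mk_ct(base)
  rk <- rank_endogenous_controls(x2, pr, k = 1, rank_by = "median")
  expect_equal(rk$table$miRNA[1], "m1")
  expect_equal(rk$table$r_median[1], 1, tolerance = 1e-12)
})

test_that("control ranking equals the all-pairs correlation oracle on small matrices", {
  for (s in 1:10) {
    set.seed(s)
    nr <- sample(3:6, 1); ns <- sample(3:6, 1)
    x <- mk_ct(matrix(rnorm(nr * ns, 27, 3), nr, ns))
    pr <- build_reference_profile(x)
    rk <- rank_endogenous_controls(x, pr, k = 2, m = nr)
    vals <- ct_values(x)
    r_oracle <- (apply(vals, 1, cor, y = pr$median) +
                   apply(vals, 1, cor, y = pr$mean)) / 2
    ord_oracle <- order(-r_oracle, rowMeans(vals), rownames(vals))
    expect_equal(rk$table$miRNA, rownames(vals)[ord_oracle])
    expect_equal(rk$table$r, unname(r_oracle[ord_oracle]), tolerance = 1e-12)
  }
})

test_that("zero-variance rows are dropped from the ranking with a note", {
  x <- mk_ct(rbind(c(25, 25, 25), matrix(rnorm(9, 28, 2), 3, 3)))
  pr <- build_reference_profile(x)
  expect_message(rk <- rank_endogenous_controls(x, pr, k = 1),
                 "zero-variance")
  expect_false("m1" %in% rk$table$miRNA)
})

test_that("two-stage selection keeps the k most abundant of the m most stable", {
  set.seed(41)
  base <- matrix(rnorm(40, 30, 0.2), 10, 4)
  offs <- rnorm(4, 0, 2)
  base <- sweep(base, 2, offs, `+`)             # all rows track loading
  base <- base + seq(0, 9)                      # abundance gradient by row
  x <- mk_ct(base)
  pr <- build_reference_profile(x)
  rk <- rank_endogenous_controls(x, pr, k = 3, m = 10)
  # all 10 rows are in the stability pool; the 3 most abundant must win
  expect_setequal(rk$selected, c("m1", "m2", "m3"))
})

test_that("delta-Ct arithmetic and self-normalization identities hold", {
  x <- mk_ct(rbind(c(20, 20), c(22, 22), c(25, 26)))
  d <- compute_delta_ct(x, controls = c("m1", "m2"))
  expect_equal(unname(d$dct["m3", ]), c(25 - 21, 26 - 21))
  d_self <- compute_delta_ct(x, controls = "m3")
  expect_equal(unname(d_self$dct["m3", ]), c(0, 0))
})

test_that("delta-Ct round-trips: adding the reference back reproduces Ct", {
  prof <- simulate_profiling(sim_config(seed = 12L, n_mirna_panel = 50L), "A")
  pr <- build_reference_profile(prof)
  rk <- suppressMessages(rank_endogenous_controls(prof, pr))
  d <- compute_delta_ct(prof, rk$selected, on_flagged_control = "drop_sample")
  rebuilt <- sweep(d$dct, 2, d$reference, `+`)
  orig <- ct_values(prof)[rownames(rebuilt), colnames(rebuilt)]
  expect_equal(rebuilt, orig, tolerance = 1e-12)
})

test_that("flagged control wells error unless the drop-sample fallback is on", {
  flag <- matrix(FALSE, 2, 2); flag[1, 2] <- TRUE
  x <- mk_ct(rbind(c(20, 20), c(25, 26)), flag)
  expect_error(compute_delta_ct(x, "m1"), "flagged control well.*s2")
  d <- compute_delta_ct(x, "m1", on_flagged_control = "drop_sample")
  expect_equal(colnames(d$dct), "s1")
})

test_that("fold change follows 2^-ddCt and is antisymmetric", {
  v <- c(a1 = 3, a2 = 3, b1 = 4, b2 = 4)
  expect_equal(fold_change(v, c("a1", "a2"), c("b1", "b2"))$fc, 2)
  expect_equal(fold_change(v, c("b1", "b2"), c("a1", "a2"))$fc, 0.5)
  v2 <- c(a1 = 5, b1 = 5)
  expect_equal(fold_change(v2, "a1", "b1")$fc, 1)
  v3 <- c(a1 = 1, b1 = 3)
  expect_equal(fold_change(v3, "a1", "b1")$ddct, -2)
  expect_equal(fold_change(v3, "a1", "b1")$fc, 4)
  set.seed(5)
  vr <- setNames(rnorm(8, 4, 1), paste0("s", 1:8))
  f12 <- fold_change(vr, paste0("s", 1:4), paste0("s", 5:8))$fc
  f21 <- fold_change(vr, paste0("s", 5:8), paste0("s", 1:4))$fc
  expect_equal(f12 * f21, 1, tolerance = 1e-12)
})

test_that("adding a flag shrinks the rankable set without touching other rows", {
  set.seed(31)
  base <- matrix(rnorm(24, 28, 2), 6, 4)
  x <- mk_ct(base)
  pr <- build_reference_profile(x)
  flag <- matrix(FALSE, 6, 4); flag[4, 2] <- TRUE
  xf <- mk_ct(base, flag)
  prf <- build_reference_profile(xf)
  expect_true(all(pr$excluded %in% prf$excluded))
  expect_equal(prf$excluded, "m4")
  rk <- rank_endogenous_controls(x, pr, k = 1)
  rkf <- rank_endogenous_controls(xf, prf, k = 1)
  expect_true(all(rkf$table$miRNA %in% setdiff(rk$table$miRNA, "m4")))
})

test_that("normalizing by true loading offsets and by selected controls agree", {
  cfg <- sim_config(seed = 17L, n_mirna_panel = 120L, control_sd = 0.05,
                    flag_prob = 0)
  prof <- simulate_profiling(cfg, "A")
  tr <- attr(prof, "truth")
  g1 <- names(tr$group)[tr$group == "ASD"]
  g2 <- names(tr$group)[tr$group == "NC"]
  # m = 3: normalize to the top three stable rows themselves
  nc <- suppressMessages(normalize_comparison(prof, c(g1, g2), k = 3, m = 3))
  # oracle normalization: subtract the true per-sample loading offset
  vals <- ct_values(prof)[, colnames(nc$dct$dct)]
  oracle <- sweep(vals, 2, tr$loading[colnames(vals)])
  common <- intersect(rownames(nc$dct$dct), rownames(oracle))
  g1u <- intersect(g1, colnames(oracle)); g2u <- intersect(g2, colnames(oracle))
  diff_est <- rowMeans(nc$dct$dct[common, g1u], na.rm = TRUE) -
    rowMeans(nc$dct$dct[common, g2u], na.rm = TRUE)
  diff_true <- rowMeans(oracle[common, g1u], na.rm = TRUE) -
    rowMeans(oracle[common, g2u], na.rm = TRUE)
  ok <- is.finite(diff_est) & is.finite(diff_true)
  expect_lt(max(abs(diff_est[ok] - diff_true[ok])), 0.2)
})
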