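# small fixtures built in code, shared across test files

# write a Ct matrix text file and return its path
write_ct_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy cohort: one sample per group unless sizes given
toy_cohort <- function(sizes = c(ASD = 1L, TS = 1L, `TS+ASD` = 1L, NC = 1L)) {
  ids <- unlist(lapply(names(sizes), function(g)
    sprintf("%s_%d", gsub("\\+", "", g), seq_len(sizes[[g]]))))
  as_cohort_table(data.frame(
    sample = ids, group = rep(names(sizes), sizes),
    IQ = 100, YGTSS = 10, ADOS_A = 1, ADOS_B = 1, ADOS_C = 1, ADOS_D = 1,
    check.names = FALSE, stringsAsFactors = FALSE))
}

# brute-force step-down Holm adjustment over a family of size m
holm_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(ord)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# brute-force step-up Benjamini-Hochberg adjustment over a family of size m
bh_oracle <- function(p, m = length(p)) {
  ord <- order(p, decreasing = TRUE)
  ranks <- rank(p, ties.method = "first")
  adj <- numeric(length(p))
  running <- Inf
  for (i in ord) {
    running <- min(running, m * p[i] / ranks[i])
    adj[i] <- min(1, running)
  }
  adj
}

# exhaustive-pair AUC oracle: fraction of (pos, neg) pairs concordant with
# the decision direction, ties counted 1/2
auc_pair_oracle <- function(values, pos, direction = "<=") {
  vp <- values[pos]; vn <- values[!pos]
  tot <- 0
  for (a in vp) for (b in vn) {
    tot <- tot + if (a == b) 0.5 else if (direction == "<=") (a < b) else (a > b)
  }
  tot / (length(vp) * length(vn))
}
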