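# Independent oracles used by the tests. These deliberately re-derive each
# statistic from first principles (loops over risk sets, grid searches,
# exhaustive enumeration) and never call the package's survival wrappers or
# the survival package.

# Hand product-limit estimator with Greenwood variance, censored-after-event
# convention at tied times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  gsum <- 0
  out <- data.frame(time = ts, at_risk = NA_real_, events = NA_real_,
                    survival = NA_real_, greenwood_var = NA_real_)
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    gsum <- gsum + d / (n * (n - d))
    out$at_risk[i] <- n
    out$events[i] <- d
    out$survival[i] <- s
    # variance degenerates to 0 once the curve reaches 0
    out$greenwood_var[i] <- if (s == 0) 0 else s^2 * gsum
  }
  out
}

# Two-group log-rank statistic: sum of observed-minus-expected for group 1
# over distinct event times with hypergeometric variance.
logrank_oracle_2g <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- oe^2 / v
  list(oe = oe, var = v, chi2 = chi2,
       p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Negative log partial likelihood for a single covariate, Breslow form (the
# test data has no tied event times, so all tie conventions coincide).
cox_nll_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# Grid-search maximizer of the partial likelihood.
cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  nll <- vapply(grid, cox_nll_oracle, numeric(1), time = time, event = event,
                x = x)
  grid[which.min(nll)]
}

# Exact two-sided rank-sum p-value by enumeration of all assignments of the
# pooled ranks to the first sample (feasible for n, m <= 8).
wilcoxon_exact_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Per-base arm coverage oracle on a small arm: classify every base.
arm_call_oracle <- function(seg_start, seg_end, seg_log2, arm_start, arm_end,
                            event_log2 = 0.3, coverage = 0.5) {
  bases <- seq(arm_start, arm_end - 1)
  up <- rep(FALSE, length(bases)); dn <- rep(FALSE, length(bases))
  for (i in seq_along(seg_start)) {
    inseg <- bases >= seg_start[i] & bases < seg_end[i]
    if (seg_log2[i] > event_log2) up <- up | inseg
    if (seg_log2[i] < -event_log2) dn <- dn | inseg
  }
  gain_frac <- mean(up); loss_frac <- mean(dn)
  call <- "neutral"
  if (gain_frac >= coverage || loss_frac >= coverage) {
    call <- if (gain_frac >= loss_frac) "gain" else "loss"
  }
  list(call = call, gain_frac = gain_frac, loss_frac = loss_frac)
}

# Brute-force re-evaluation of the ordered decision tree, written against
# the rule text rather than the classifier implementation.
classify_oracle <- function(profile, config = classifier_config()) {
  muts <- profile$mutations
  qual_genes <- muts$gene
  if (config$require_pathogenic_for_tier1) {
    qual_genes <- muts$gene[!is.na(muts$score) &
                              muts$score >= config$pathogenicity_threshold]
  }
  if (length(intersect(qual_genes, config$tier1_mutation_genes)) > 0) {
    return("RAS_PI3K_AKT")
  }
  del <- names(profile$cnv)[profile$cnv == "deleted"]
  amp <- names(profile$cnv)[profile$cnv == "amplified"]
  if (length(intersect(del, config$tier2_deletion_genes)) > 0 ||
      length(intersect(amp, config$tier2_amplification_genes)) > 0) {
    return("CELL_CYCLE")
  }
  "UNCLASSIFIED"
}

# Small helper: write a mutation file from a data.frame of raw MAF columns.
write_raw_maf <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal in-memory profile constructor for classifier tests.
make_profile <- function(sample_id = "S1", genes = character(),
                         classes = rep("nonsynonymous_SNV", length(genes)),
                         scores = rep(NA_real_, length(genes)),
                         cnv = character()) {
  structure(list(
    sample_id = sample_id,
    mutations = data.frame(sample_id = rep(sample_id, length(genes)),
                           gene = genes, variant_class = classes,
                           score = scores, stringsAsFactors = FALSE),
    cnv = cnv, tmb = length(genes) / 38
  ), class = "npc_profile")
}
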