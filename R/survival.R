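#' Kaplan-Meier product-limit estimate with Greenwood variance
#'
#' Computes the product-limit estimate of the survival function over the
#' distinct event times, with the Greenwood variance accumulated at each
#' event time. Subjects censored at an event time are removed from risk
#' sets after that time (censored-after-event convention). The estimation
#' itself is delegated to [survival::survfit()].
#'
#' @param time_months Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return An object of class `npc_km`: `event_times`, `survival`,
#'   `greenwood_var`, `at_risk`, `n_events`, plus the cohort size `n` and the
#'   maximum follow-up `max_time`.
#' @export
km_estimate <- function(time_months, event) {
  if (length(time_months) == 0) stop("km_estimate: no records", call. = FALSE)
  if (length(time_months) != length(event)) {
    stop("km_estimate: time and event lengths differ", call. = FALSE)
  }
  if (any(is.na(time_months)) || any(time_months < 0)) {
    stop("km_estimate: times must be non-negative and non-missing", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("km_estimate: event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, conf.type = "none")
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  # survfit's std.err is on the cumulative-hazard scale; Greenwood variance
  # of S(t) is S(t)^2 * sum d/(n(n-d)).
  gvar <- (surv * fit$std.err[keep])^2
  gvar[is.nan(gvar)] <- 0
  structure(list(
    event_times = fit$time[keep],
    survival = surv,
    greenwood_var = gvar,
    at_risk = fit$n.risk[keep],
    n_events = fit$n.event[keep],
    n = length(time_months),
    max_time = max(time_months)
  ), class = "npc_km")
}

#' @export
print.npc_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d distinct event time(s)\n",
              x$n, length(x$event_times)))
  if (length(x$event_times) > 0) {
    print(utils::head(data.frame(time = x$event_times, at_risk = x$at_risk,
                                 events = x$n_events,
                                 survival = round(x$survival, 4)), 10))
  }
  invisible(x)
}

#' Survival rate at a fixed horizon with confidence interval
#'
#' Evaluates the Kaplan-Meier step function at a horizon (right-continuous:
#' a horizon between two event times takes the value of the earlier step)
#' and attaches a 95% confidence interval. The default interval uses the
#' complementary log-log transform of the Greenwood variance, which respects
#' the `[0,1]` range and yields the asymmetric intervals typical of survival
#' rates; a plain (untransformed) Greenwood interval is available by flag.
#'
#' @param curve An `npc_km` object.
#' @param horizon_months Non-negative horizon (e.g. 60 for 5-year rates).
#' @param conf_type `"loglog"` (default) or `"plain"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A list: `rate`, `ci` (length-2 vector), `extrapolated` (`TRUE`
#'   when the horizon exceeds the last follow-up time).
#' @export
survival_rate_at <- function(curve, horizon_months, conf_type = c("loglog", "plain"),
                             conf_level = 0.95) {
  stopifnot(inherits(curve, "npc_km"))
  conf_type <- match.arg(conf_type)
  if (horizon_months < 0) stop("survival_rate_at: horizon must be >= 0", call. = FALSE)
  extrapolated <- horizon_months > curve$max_time
  if (extrapolated) {
    warning("horizon beyond last follow-up; returning rate at last step",
            call. = FALSE)
  }
  idx <- which(curve$event_times <= horizon_months)
  if (length(idx) == 0) {
    return(list(rate = 1, ci = c(1, 1), extrapolated = extrapolated))
  }
  i <- max(idx)
  s <- curve$survival[i]
  v <- curve$greenwood_var[i]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (s <= 0) {
    ci <- c(0, 0)
  } else if (v == 0) {
    ci <- c(s, s)
  } else if (conf_type == "loglog") {
    if (s >= 1) {
      ci <- c(s, s)
    } else {
      se_cll <- sqrt(v) / (s * abs(log(s)))
      ci <- c(s^exp(z * se_cll), s^exp(-z * se_cll))
    }
  } else {
    ci <- pmin(1, pmax(0, s + c(-1, 1) * z * sqrt(v)))
  }
  list(rate = s, ci = ci, extrapolated = extrapolated)
}

#' k-group log-rank test
#'
#' Observed-minus-expected test with hypergeometric variance summed over the
#' distinct event times, referred to a chi-square distribution with k-1
#' degrees of freedom. Delegates to [survival::survdiff()].
#'
#' @param time_months Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels (k >= 2 nonempty groups).
#' @return An object of class `npc_logrank`: `chi2`, `df`, `p_value`, and
#'   the per-group observed/expected table.
#' @export
logrank_test <- function(time_months, event, group) {
  group <- as.factor(as.character(group))
  k <- nlevels(group)
  if (k < 2) stop("logrank_test: need at least 2 groups", call. = FALSE)
  if (any(table(group) == 0)) stop("logrank_test: empty group", call. = FALSE)
  if (sum(event) == 0) {
    stop("logrank_test: no events; statistic undefined", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  df <- k - 1L
  chi2 <- unname(sd$chisq)
  structure(list(
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    observed = sd$obs, expected = sd$exp, groups = levels(group)
  ), class = "npc_logrank")
}

#' @export
print.npc_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by maximum partial likelihood via [survival::coxph()],
#' with Efron handling of tied event times by default (follow-up recorded in
#' months guarantees ties); Breslow is available for cross-checks. Reports
#' Wald confidence intervals and p-values per coefficient.
#'
#' @param data Data.frame containing the time, event and covariate columns.
#' @param time_col,event_col Column names of follow-up time and event
#'   indicator.
#' @param covariates Character vector of covariate column names (numeric, or
#'   factors/characters which are dummy-coded; set the reference level by
#'   making the column a factor).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the Wald intervals, default 0.95.
#' @return An object of class `npc_cox`: `table` (one row per coefficient:
#'   term, coef, hr, ci_low, ci_high, se, p_value), `loglik`, `n`,
#'   `n_events`, `ties`.
#' @export
cox_fit <- function(data, time_col = "time", event_col = "event",
                    covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  miss <- setdiff(c(time_col, event_col, covariates), names(data))
  if (length(miss) > 0) {
    stop("cox_fit: column(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[, c(time_col, event_col, covariates), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  if (sum(data[[event_col]]) < 1) stop("cox_fit: no events", call. = FALSE)
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      stop("cox_fit: covariate constant across all records: ", cv, call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(survival::coxph(fml, data = data, ties = ties))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- which(is.na(cf) | abs(cf) > 15 | se > 100)
  if (length(bad) > 0) {
    stop("cox_fit: likelihood did not converge (possible monotone likelihood / ",
         "perfect separation) for: ", paste(names(cf)[bad], collapse = ", "),
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
    ci_low = exp(unname(cf) - z * se), ci_high = exp(unname(cf) + z * se),
    se = unname(se),
    p_value = 2 * stats::pnorm(-abs(unname(cf) / se)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 n = nrow(data), n_events = sum(data[[event_col]]),
                 ties = ties), class = "npc_cox")
}

#' @export
print.npc_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- x$table
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$ci_low, tab$ci_high)
  print(tab[, c("term", "coef", "hr", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with the normal approximation and tie-corrected
#' variance (no continuity correction), as used for comparing continuous
#' clinical variables and mutation burden between cohorts.
#'
#' @param x,y Numeric samples, both nonempty.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("rank_sum_test: both samples must be nonempty", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1) return(1)
  stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction on an r x c count table;
#' degrees of freedom (r-1)(c-1).
#'
#' @param table_counts Matrix of non-negative counts, at least 2 x 2.
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
chi_square_test <- function(table_counts) {
  tab <- as.matrix(table_counts)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("chi_square_test: table must be at least 2x2", call. = FALSE)
  }
  if (any(tab < 0)) stop("chi_square_test: negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi_square_test: zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values, monotone in the sorted order, capped at 1;
#' the input order is preserved in the output.
#'
#' @param p_values Numeric vector of p-values in `[0,1]`.
#' @return Adjusted q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("bh_adjust: p-values must be in [0,1] and non-missing", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
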