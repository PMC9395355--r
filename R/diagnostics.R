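#' Contingency table for one test-versus-reference comparison
#'
#' Either construct directly from counts, or cross-tabulate two aligned
#' per-subject call vectors with [build_table()].
#'
#' @param tp,fp,fn,tn nonnegative integer counts (`tp` = test suspicious
#'   and reference suspicious).
#' @param test_name,reference_name labels of the compared tiers.
#' @param n_excluded subjects dropped before tabulation (not
#'   interpretable or absent in either vector).
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn, test_name = "test",
                              reference_name = "reference",
                              n_excluded = 0L) {
  counts <- c(tp, fp, fn, tn)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be nonnegative integers")
  assert_that(sum(counts) >= 1, "table must contain at least one subject")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 total = as.integer(sum(counts)),
                 test_name = test_name, reference_name = reference_name,
                 n_excluded = as.integer(n_excluded)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s vs %s (n=%d, excluded=%d)\n",
              x$test_name, x$reference_name, x$total, x$n_excluded))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("suspicious", "non_suspicious"),
                              reference = c("suspicious",
                                            "non_suspicious")))
  print(m)
  invisible(x)
}

#' Build a contingency table from aligned call vectors
#'
#' Subjects whose call is `not_interpretable`, `absent` or `NA` in either
#' vector are excluded from the table and counted in `n_excluded`,
#' mirroring the exclusion of non-interpretable remote reads in field
#' analyses.
#'
#' @param test_calls,reference_calls character vectors of equal length
#'   with values among `suspicious`, `non_suspicious`,
#'   `not_interpretable`, `absent`.
#' @param test_name,reference_name tier labels.
#' @return a [contingency_table()].
#' @export
build_table <- function(test_calls, reference_calls, test_name = "test",
                        reference_name = "reference") {
  assert_that(length(test_calls) == length(reference_calls),
              "call vectors must have equal length")
  drop_vals <- c("not_interpretable", "absent")
  keep <- !(test_calls %in% drop_vals) & !(reference_calls %in% drop_vals) &
    !is.na(test_calls) & !is.na(reference_calls)
  assert_that(any(keep), "no subjects left after exclusions")
  t_pos <- test_calls[keep] == "suspicious"
  r_pos <- reference_calls[keep] == "suspicious"
  contingency_table(sum(t_pos & r_pos), sum(t_pos & !r_pos),
                    sum(!t_pos & r_pos), sum(!t_pos & !r_pos),
                    test_name, reference_name,
                    n_excluded = sum(!keep))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Closed-form beta-quantile implementation of the exact interval:
#' `lower = qbeta(a/2, x, n - x + 1)`, `upper = qbeta(1 - a/2, x + 1,
#' n - x)`, with the conventional endpoints 0 at `x = 0` and 1 at
#' `x = n`. The interval always contains `x / n`.
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `>= 1`.
#' @param conf_level confidence level (default 0.95).
#' @return named vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  assert_that(n >= 1 && x >= 0 && x <= n, "need 0 <= x <= n, n >= 1")
  a <- 1 - conf_level
  lower <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# One proportion with its exact CI; NA triple when the denominator is 0
# (the metric is undefined, never reported as 0).
prop_ci <- function(num, den, conf_level) {
  if (den == 0) {
    return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  ci <- clopper_pearson(num, den, conf_level)
  c(estimate = num / den, lower = ci[["lower"]], upper = ci[["upper"]])
}

#' Diagnostic accuracy metrics for a contingency table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/total` and prevalence
#' `(tp+fn)/total`, each with an exact Clopper-Pearson confidence
#' interval, plus Cohen's kappa (see [cohen_kappa()]) and precision /
#' recall / F1 (see [f1_score()]). A metric with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' Display rounding (`format()` / `print()`) is to the nearest integer
#' percent, half away from zero, and kappa to two decimals — recorded in
#' the report's `rounding_convention`.
#'
#' @param table a [contingency_table()].
#' @param conf_level confidence level for all intervals.
#' @return an object of class `metrics_report`: a list with one
#'   `c(estimate, lower, upper)` entry per metric, `kappa`, `f1`,
#'   `table` and `rounding_convention`.
#' @export
metrics_report <- function(table, conf_level = 0.95) {
  assert_that(inherits(table, "contingency_table"),
              "table must be a contingency_table")
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- table$total
  rep <- list(
    sensitivity = prop_ci(tp, tp + fn, conf_level),
    specificity = prop_ci(tn, tn + fp, conf_level),
    ppv = prop_ci(tp, tp + fp, conf_level),
    npv = prop_ci(tn, tn + fn, conf_level),
    accuracy = prop_ci(tp + tn, n, conf_level),
    prevalence = prop_ci(tp + fn, n, conf_level),
    kappa = if (n >= 2) cohen_kappa(table, conf_level) else {
      c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    },
    f1 = f1_score(table),
    table = table,
    rounding_convention = paste("nearest integer percent, half away",
                                "from zero; kappa to 2 dp"))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s vs %s (n=%d)\n", x$table$test_name,
              x$table$reference_name, x$table$total))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
              "prevalence")) {
    e <- x[[m]]
    if (is.na(e[["estimate"]])) {
      cat(sprintf("  %-11s undefined\n", m))
    } else {
      cat(sprintf("  %-11s %3d%% (CI %.2f-%.2f)\n", m,
                  percent_round(e[["estimate"]]), 100 * e[["lower"]],
                  100 * e[["upper"]]))
    }
  }
  cat(sprintf("  %-11s %.2f (CI %.2f-%.2f)\n", "kappa",
              x$kappa[["estimate"]], x$kappa[["lower"]],
              x$kappa[["upper"]]))
  cat(sprintf("  %-11s %.3f (precision %.3f, recall %.3f)\n", "f1",
              x$f1[["f1"]], x$f1[["precision"]], x$f1[["recall"]]))
  invisible(x)
}

#' Cohen's kappa for a 2x2 contingency table
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = (tp + tn)/N` and chance agreement `pe` from the marginal
#' products. The computation goes through the general weighted-kappa
#' formula; for a binary table linear-weighted, quadratic-weighted and
#' unweighted kappa coincide, and the implementation asserts this
#' identity. The confidence interval uses the standard asymptotic
#' (Fleiss-Cohen-Everitt) variance, truncated to `[-1, 1]`.
#'
#' @param table a [contingency_table()] with `total >= 2`.
#' @param conf_level confidence level.
#' @return named vector `c(estimate, lower, upper)`; all `NA` when the
#'   marginals are degenerate (`pe = 1`).
#' @export
cohen_kappa <- function(table, conf_level = 0.95) {
  assert_that(inherits(table, "contingency_table"),
              "table must be a contingency_table")
  n <- table$total
  assert_that(n >= 2, "kappa needs at least 2 subjects")
  p <- matrix(c(table$tp, table$fn, table$fp, table$tn), 2, 2) / n
  rs <- rowSums(p) # test marginals
  cs <- colSums(p) # reference marginals
  po <- sum(diag(p))
  pe <- sum(rs * cs)
  if (abs(1 - pe) < 1e-12) {
    return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  kap <- (po - pe) / (1 - pe)
  # weighted kappa with weights w_ij; identical to unweighted for 2x2
  wkappa <- function(w) {
    1 - sum(w * p) / sum(w * outer(rs, cs))
  }
  w_lin <- abs(outer(0:1, 0:1, "-"))
  stopifnot(abs(wkappa(w_lin) - kap) < 1e-12,
            abs(wkappa(w_lin^2) - kap) < 1e-12)
  # Fleiss-Cohen-Everitt asymptotic variance
  a_term <- sum(diag(p) * ((1 - pe) - (rs + cs) * (1 - po))^2)
  b_term <- (1 - po)^2 * (p[1, 2] * (cs[2] + rs[1])^2 +
                            p[2, 1] * (cs[1] + rs[2])^2)
  c_term <- (po * pe - 2 * pe + po)^2
  se <- sqrt((a_term + b_term - c_term) / (n * (1 - pe)^4))
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(estimate = kap, lower = max(-1, kap - z * se),
    upper = min(1, kap + z * se))
}

#' Precision, recall and F1 score
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`. A zero
#' denominator leaves precision or recall undefined (`NA`); F1 is defined
#' as 0 whenever `precision + recall` is 0 or either factor is
#' undefined.
#'
#' @param table a [contingency_table()].
#' @return named vector `c(precision, recall, f1)`.
#' @export
f1_score <- function(table) {
  assert_that(inherits(table, "contingency_table"),
              "table must be a contingency_table")
  precision <- if (table$tp + table$fp == 0) NA_real_ else {
    table$tp / (table$tp + table$fp)
  }
  recall <- if (table$tp + table$fn == 0) NA_real_ else {
    table$tp / (table$tp + table$fn)
  }
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Exact non-inferiority sample size for a sensitivity estimate
#'
#' Smallest `n` such that the exact one-sided binomial test of
#' `H0: p <= p0 - delta` at level `alpha` has power at least `power`
#' when the true sensitivity is `p0`. The critical value for each `n` is
#' the smallest count `c` with `P(X >= c | p0 - delta) <= alpha`; power
#' is `P(X >= c | p0)`. Exact enumeration — no normal approximation. The
#' power curve in `n` is sawtoothed, so the returned `n` is the first
#' crossing, with the achieved power and critical value attached as
#' attributes.
#'
#' @param p0 assumed true sensitivity, in `(0, 1)`.
#' @param delta non-inferiority margin, `0 < delta < p0`.
#' @param power target power in `(0, 1)` (default 0.80).
#' @param alpha one-sided significance level (default 0.05).
#' @param n_max search bound (default 10000).
#' @return integer `n` with attributes `critical_value` and
#'   `achieved_power`.
#' @export
sample_size_noninferiority <- function(p0, delta, power = 0.80,
                                       alpha = 0.05, n_max = 10000) {
  assert_that(p0 > 0 && p0 < 1, "p0 must lie in (0,1)")
  assert_that(delta > 0 && delta < p0,
              "infeasible margin: need 0 < delta < p0")
  assert_that(power > 0 && power < 1, "power must lie in (0,1)")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0,1)")
  p_null <- p0 - delta
  for (n in seq_len(n_max)) {
    crit <- qbinom(1 - alpha, n, p_null) + 1
    if (crit > n) next # rejection impossible at this n
    pow <- 1 - pbinom(crit - 1, n, p0)
    if (pow >= power) {
      return(structure(as.integer(n), critical_value = as.integer(crit),
                       achieved_power = pow))
    }
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}

#' Uncertainty-threshold sweep
#'
#' For each threshold `tau`: the referral fraction is the proportion of
#' cases with uncertainty strictly above `tau`, and the retained
#' accuracy is the agreement between predicted and reference labels on
#' the complement (the auto-decided cases). A threshold that refers
#' every case has undefined (`NA`) retained accuracy.
#'
#' @param predictions a [classify_batch()] frame, or any data.frame with
#'   columns `label` and `uncertainty`.
#' @param labels reference labels (`suspicious` / `non_suspicious`),
#'   aligned with `predictions`.
#' @param taus thresholds to evaluate (default `seq(0, 0.5, 0.01)`).
#' @return a `data.frame` of class `uncertainty_sweep` with columns
#'   `tau`, `referral_fraction`, `retained_accuracy`, `n_retained`,
#'   sorted by `tau`.
#' @export
uncertainty_sweep <- function(predictions, labels,
                              taus = seq(0, 0.5, 0.01)) {
  assert_that(all(c("label", "uncertainty") %in% names(predictions)),
              "predictions must have label and uncertainty columns")
  assert_that(nrow(predictions) == length(labels),
              "labels must align with predictions")
  u <- predictions$uncertainty
  correct <- predictions$label == labels
  taus <- sort(taus)
  out <- do.call(rbind, lapply(taus, function(tau) {
    refer <- u > tau
    n_ret <- sum(!refer)
    data.frame(tau = tau, referral_fraction = mean(refer),
               retained_accuracy = if (n_ret == 0) NA_real_ else {
                 mean(correct[!refer])
               },
               n_retained = n_ret)
  }))
  structure(out, class = c("uncertainty_sweep", "data.frame"))
}

#' Calibrate the referral threshold on held-out predictions
#'
#' Reproduces the threshold-selection procedure of the field study: sweep
#' candidate uncertainty thresholds on a held-out (validation) set and
#' choose the one that maximizes retained accuracy subject to a referral
#' budget. Ties resolve to the largest threshold (fewest referrals). The
#' resulting `tau` is then applied unchanged to new data.
#'
#' @param predictions held-out predictions (see [uncertainty_sweep()]).
#' @param labels reference labels aligned with `predictions`.
#' @param taus candidate thresholds.
#' @param max_referral largest acceptable referral fraction (default
#'   0.25).
#' @return the selected threshold, with the full sweep attached as
#'   attribute `sweep`.
#' @export
calibrate_tau <- function(predictions, labels, taus = seq(0, 0.5, 0.01),
                          max_referral = 0.25) {
  # the largest observed uncertainty is always a feasible threshold
  # (strict exceedance refers nobody there), so the sweep always has a
  # candidate within any budget
  taus <- unique(c(taus, max(predictions$uncertainty)))
  sw <- uncertainty_sweep(predictions, labels, taus)
  ok <- !is.na(sw$retained_accuracy) & sw$referral_fraction <= max_referral
  assert_that(any(ok), "no threshold satisfies the referral budget")
  cand <- sw[ok, ]
  best <- cand[cand$retained_accuracy == max(cand$retained_accuracy), ]
  structure(max(best$tau), sweep = sw)
}

#' Export a metrics report (or list of reports) as a tidy data.frame
#'
#' Raw proportions, exact CIs and the display-rounded strings side by
#' side — the table-style report written by the workflow layer.
#'
#' @param reports a `metrics_report` or list of them.
#' @return a `data.frame` with one row per (comparison, metric).
#' @export
report_frame <- function(reports) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    rows <- lapply(c("sensitivity", "specificity", "ppv", "npv",
                     "accuracy", "prevalence"), function(m) {
      e <- r[[m]]
      data.frame(test = r$table$test_name,
                 reference = r$table$reference_name, metric = m,
                 estimate = e[["estimate"]], lower = e[["lower"]],
                 upper = e[["upper"]],
                 display = if (is.na(e[["estimate"]])) "undefined" else {
                   sprintf("%d%%", percent_round(e[["estimate"]]))
                 },
                 stringsAsFactors = FALSE)
    })
    k <- r$kappa
    rows <- c(rows, list(data.frame(
      test = r$table$test_name, reference = r$table$reference_name,
      metric = "kappa", estimate = k[["estimate"]], lower = k[["lower"]],
      upper = k[["upper"]],
      display = sprintf("%.2f", k[["estimate"]]),
      stringsAsFactors = FALSE)))
    do.call(rbind, rows)
  }))
}
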