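# Diagnostic-accuracy layer: contingency construction, metrics with
# exact intervals, agreement, F1, sample size, threshold sweep.

test_that("build_table cross-tabulates and excludes uninterpretable calls", {
  test <- c("suspicious", "suspicious", "non_suspicious", "non_suspicious",
            "suspicious", "not_interpretable", "suspicious")
  ref <- c("suspicious", "non_suspicious", "suspicious", "non_suspicious",
           "suspicious", "suspicious", "absent")
  tab <- build_table(test, ref, "a", "b")
  expect_s3_class(tab, "contingency_table")
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(2, 1, 1, 1))
  expect_equal(tab$n_excluded, 2)
  expect_equal(tab$total, 5)

  # identical vectors give a diagonal table
  same <- c("suspicious", "non_suspicious", "suspicious")
  tab2 <- build_table(same, same)
  expect_equal(tab2$fp + tab2$fn, 0)

  expect_error(build_table("suspicious", c("suspicious", "suspicious")),
               "equal length")
  expect_error(build_table("not_interpretable", "suspicious"),
               "no subjects")
})

test_that("metrics match per-subject brute-force counting on random cohorts", {
  set.seed(404)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    test <- sample(c("suspicious", "non_suspicious", "not_interpretable"),
                   n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    ref <- sample(c("suspicious", "non_suspicious"), n, replace = TRUE)
    keep <- test != "not_interpretable"
    if (!any(keep)) next
    tab <- build_table(test, ref)
    tp <- sum(test == "suspicious" & ref == "suspicious")
    fp <- sum(test == "suspicious" & ref == "non_suspicious")
    fn <- sum(test == "non_suspicious" & ref == "suspicious")
    tn <- sum(test == "non_suspicious" & ref == "non_suspicious")
    expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(tp, fp, fn, tn))
    rep <- metrics_report(tab)
    if (tp + fn > 0) {
      expect_equal(rep$sensitivity[["estimate"]], tp / (tp + fn))
    } else {
      expect_true(is.na(rep$sensitivity[["estimate"]]))
    }
    if (tn + fp > 0) {
      expect_equal(rep$specificity[["estimate"]], tn / (tn + fp))
    }
    expect_equal(rep$accuracy[["estimate"]], (tp + tn) / sum(keep))
  }
})

test_that("clopper_pearson agrees with binom.test and contains the estimate", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:300, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    bt <- binom.test(x, n)$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-12)
    expect_true(ci[["lower"]] <= x / n + 1e-12)
    expect_true(ci[["upper"]] >= x / n - 1e-12)
  }
})

test_that("exact interval coverage reaches the nominal level", {
  # 10,000 replicates at n = 100, p = 0.8
  set.seed(2024)
  n <- 100; p <- 0.8
  x <- rbinom(10000, n, p)
  lower <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  coverage <- mean(lower <= p & p <= upper)
  expect_gte(coverage, 0.95 - 0.01)
})

test_that("undefined metrics are NA, not zero", {
  tab <- contingency_table(tp = 0, fp = 3, fn = 0, tn = 7)
  rep <- metrics_report(tab)
  expect_true(is.na(rep$sensitivity[["estimate"]])) # tp + fn = 0
  expect_false(is.na(rep$specificity[["estimate"]]))
})

test_that("cohen_kappa has its fixed points and symmetries", {
  # perfect agreement
  expect_equal(cohen_kappa(contingency_table(10, 0, 0, 15))[["estimate"]], 1)
  # label swap invariance: swapping positive/negative maps
  # (tp,fp,fn,tn) -> (tn,fn,fp,tp)
  set.seed(7)
  for (i in 1:50) {
    cnt <- rmultinom(1, sample(20:500, 1), runif(4, 0.05, 1))
    if (any(rowSums(matrix(cnt, 2)) == 0)) next
    k1 <- cohen_kappa(contingency_table(cnt[1], cnt[2], cnt[3], cnt[4]))
    k2 <- cohen_kappa(contingency_table(cnt[4], cnt[3], cnt[2], cnt[1]))
    expect_equal(k1[["estimate"]], k2[["estimate"]], tolerance = 1e-12)
    expect_true(abs(k1[["estimate"]]) <= 1)
    expect_true(k1[["lower"]] <= k1[["estimate"]] &&
                  k1[["estimate"]] <= k1[["upper"]])
  }
  # degenerate marginals
  expect_true(is.na(cohen_kappa(contingency_table(5, 0, 0, 0))[["estimate"]]))
})

test_that("f1_score follows the harmonic-mean definition and conventions", {
  # precision = recall = r implies f1 = r
  for (r in c(0.2, 0.5, 0.9)) {
    tp <- 90; fp <- round(tp / r) - tp; fn <- round(tp / r) - tp
    f <- f1_score(contingency_table(tp, fp, fn, 10))
    expect_equal(f[["precision"]], f[["recall"]])
    expect_equal(f[["f1"]], f[["precision"]], tolerance = 1e-10)
  }
  # direct arithmetic on a known column
  f <- f1_score(contingency_table(507, 113, 8, 124))
  expect_equal(f[["precision"]], 507 / 620)
  expect_equal(f[["recall"]], 507 / 515)
  expect_equal(f[["f1"]],
               2 * (507 / 620) * (507 / 515) / (507 / 620 + 507 / 515))
  # degenerate: no predicted or true positives
  f0 <- f1_score(contingency_table(0, 0, 5, 3))
  expect_equal(f0[["f1"]], 0)
  expect_true(is.na(f0[["precision"]]))
})

test_that("sample size matches exhaustive binomial power enumeration", {
  # independent oracle: scan every n and every critical value directly
  oracle <- function(p0, delta, power, alpha, n_max = 500) {
    p_null <- p0 - delta
    for (n in 1:n_max) {
      crit <- NA
      for (k in 0:n) {
        if (1 - pbinom(k - 1, n, p_null) <= alpha) { crit <- k; break }
      }
      if (is.na(crit)) next
      if (1 - pbinom(crit - 1, n, p0) >= power) return(n)
    }
    NA
  }
  n_hat <- sample_size_noninferiority(0.865, 0.10, 0.80, 0.05)
  expect_identical(as.integer(n_hat), oracle(0.865, 0.10, 0.80, 0.05))
  expect_equal(as.integer(n_hat), 100L)
  expect_gte(attr(n_hat, "achieved_power"), 0.80)

  # a second parameter set
  expect_identical(as.integer(sample_size_noninferiority(0.9, 0.15, 0.8,
                                                         0.05)),
                   oracle(0.9, 0.15, 0.8, 0.05))

  # boundary: as the power target vanishes, n approaches the smallest n
  # where rejection is possible at all (p_null^n <= alpha)
  n_min <- as.integer(sample_size_noninferiority(0.865, 0.10, 1e-9, 0.05))
  expect_identical(n_min, oracle(0.865, 0.10, 1e-9, 0.05))
  expect_identical(n_min, 12L)

  # monotone: required n non-increasing in the margin delta
  ns <- vapply(c(0.06, 0.08, 0.10, 0.12, 0.15), function(d) {
    as.integer(sample_size_noninferiority(0.865, d, 0.80, 0.05))
  }, integer(1))
  expect_true(all(diff(ns) <= 0))

  expect_error(sample_size_noninferiority(0.865, 0.9), "infeasible")
})

test_that("uncertainty_sweep thresholds refer strict exceedances", {
  preds <- data.frame(
    label = c("suspicious", "suspicious", "non_suspicious",
              "non_suspicious", "suspicious"),
    uncertainty = c(0.05, 0.20, 0.10, 0.30, 0.20))
  labels <- c("suspicious", "non_suspicious", "non_suspicious",
              "suspicious", "suspicious")
  sw <- uncertainty_sweep(preds, labels, taus = c(0.1, 0.2, 0.3, 0.4))
  # at tau = max(u), only strict exceedances count: none
  expect_equal(sw$referral_fraction[sw$tau == 0.3], 0)
  expect_equal(sw$referral_fraction[sw$tau == 0.4], 0)
  # counting oracle at tau = 0.1: refer the three with u > 0.1
  expect_equal(sw$referral_fraction[sw$tau == 0.1], 3 / 5)
  expect_equal(sw$retained_accuracy[sw$tau == 0.1], 1)
  # monotone non-increasing referral in tau
  expect_true(all(diff(sw$referral_fraction) <= 0))
  # all referred -> undefined retained accuracy
  sw0 <- uncertainty_sweep(preds, labels, taus = c(0.01))
  expect_true(is.na(sw0$retained_accuracy))
})

test_that("calibrate_tau maximizes retained accuracy within the budget", {
  set.seed(5)
  n <- 400
  correct <- runif(n) < 0.85
  # errors carry systematically higher uncertainty
  u <- ifelse(correct, runif(n, 0, 0.1), runif(n, 0.05, 0.3))
  labels <- rep("suspicious", n)
  pred_label <- ifelse(correct, "suspicious", "non_suspicious")
  preds <- data.frame(label = pred_label, uncertainty = u)
  tau <- calibrate_tau(preds, labels, taus = seq(0, 0.4, 0.02),
                       max_referral = 0.5)
  sw <- attr(tau, "sweep")
  ok <- !is.na(sw$retained_accuracy) & sw$referral_fraction <= 0.5
  expect_equal(max(sw$retained_accuracy[ok]),
               sw$retained_accuracy[sw$tau == as.numeric(tau)])
  # retained accuracy at the chosen threshold beats the full set
  expect_gt(sw$retained_accuracy[sw$tau == as.numeric(tau)],
            mean(correct))
})
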