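#' Rater error profile for one screening tier
#'
#' Each tier (frontline health worker, onsite specialist, remote
#' specialist) calls subjects suspicious or non-suspicious with the given
#' sensitivity and specificity relative to true status. Only the remote
#' tier, which reads uploaded images, can additionally declare a case
#' `not_interpretable` (poor image quality); those cases are excluded from
#' analysis sets.
#'
#' @param tier one of `"fhw"`, `"onsite_specialist"`, `"remote_specialist"`.
#' @param sensitivity,specificity probabilities in `[0, 1]`.
#' @param not_interpretable_rate probability in `[0, 1]`; must be 0 for
#'   non-remote tiers.
#' @return an object of class `rater_profile`.
#' @export
rater_profile <- function(tier = c("fhw", "onsite_specialist",
                                   "remote_specialist"),
                          sensitivity, specificity,
                          not_interpretable_rate = 0) {
  tier <- match.arg(tier)
  for (p in c(sensitivity, specificity, not_interpretable_rate)) {
    assert_that(is.numeric(p) && p >= 0 && p <= 1,
                "rater probabilities must lie in [0,1]")
  }
  if (tier != "remote_specialist") {
    assert_that(not_interpretable_rate == 0,
                "not_interpretable_rate must be 0 for non-remote tiers")
  }
  structure(list(tier = tier, sensitivity = sensitivity,
                 specificity = specificity,
                 not_interpretable_rate = not_interpretable_rate),
            class = "rater_profile")
}

#' Screening cohort configuration
#'
#' Defaults mirror the structure of the field screening study the package
#' models: 5025 recruited subjects, 42% true prevalence of suspicious
#' disease (OPMD or OSCC), a frontline-health-worker tier with 60%
#' sensitivity and 78% specificity, specialist tiers in the mid-90s, a 6%
#' not-interpretable rate for remote image reads, onsite specialist review
#' of 37.5% of remote-suspicious referrals (16% of the cohort overall),
#' and 20% biopsy compliance among onsite-suspicious referrals.
#'
#' @param n_subjects number of recruited subjects (`>= 1`).
#' @param prevalence proportion of truly suspicious subjects in `[0, 1]`.
#' @param rater_profiles named list with elements `fhw`, `onsite`,
#'   `remote`, each a [rater_profile()].
#' @param biopsy_compliance probability that an onsite-suspicious subject
#'   undergoes biopsy.
#' @param onsite_fraction fraction of remote-suspicious subjects who are
#'   additionally examined by the onsite specialist.
#' @param image_size pixels per image side for any images generated from
#'   this cohort.
#' @param noise_sd,blur_sigma phenotype rendering parameters (see
#'   [phenotype_spec()]).
#' @param seed mandatory integer seed; fixes all randomness.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5025,
                          prevalence = 0.42,
                          rater_profiles = list(
                            fhw = rater_profile("fhw", 0.60, 0.78),
                            onsite = rater_profile("onsite_specialist",
                                                   0.94, 0.90),
                            remote = rater_profile("remote_specialist",
                                                   0.95, 0.90,
                                                   not_interpretable_rate = 0.06)),
                          biopsy_compliance = 0.20,
                          onsite_fraction = 0.375,
                          image_size = 64,
                          noise_sd = 0.02,
                          blur_sigma = 0.8,
                          seed) {
  assert_that(!missing(seed) && is.numeric(seed),
              "seed is mandatory in cohort_config")
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  assert_that(prevalence >= 0 && prevalence <= 1,
              "prevalence must lie in [0,1]")
  assert_that(length(rater_profiles) >= 1,
              "at least one rater profile is required")
  assert_that(all(c("fhw", "onsite", "remote") %in% names(rater_profiles)),
              "rater_profiles must contain fhw, onsite and remote entries")
  for (rp in rater_profiles) {
    assert_that(inherits(rp, "rater_profile"),
                "rater_profiles entries must be rater_profile objects")
  }
  assert_that(biopsy_compliance >= 0 && biopsy_compliance <= 1,
              "biopsy_compliance must lie in [0,1]")
  assert_that(onsite_fraction >= 0 && onsite_fraction <= 1,
              "onsite_fraction must lie in [0,1]")
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 rater_profiles = rater_profiles,
                 biopsy_compliance = biopsy_compliance,
                 onsite_fraction = onsite_fraction,
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw one tier's suspicious / non-suspicious calls given true status.
draw_calls <- function(truth, profile) {
  n <- length(truth)
  p_call <- ifelse(truth, profile$sensitivity, 1 - profile$specificity)
  ifelse(runif(n) < p_call, "suspicious", "non_suspicious")
}

#' Simulate a multi-tier screening cohort
#'
#' True status is Bernoulli(prevalence). Rater calls are drawn
#' independently across tiers given true status (Bernoulli(sensitivity)
#' for suspicious subjects, Bernoulli(specificity) for non-suspicious).
#' The remote tier's not-interpretable flag is drawn before its call.
#' Onsite review is restricted to a fraction of remote-suspicious
#' subjects, and biopsy to onsite-suspicious subjects with probability
#' `biopsy_compliance` — reproducing the verification bias of real
#' screening cascades, where histology is obtained almost exclusively
#' from test-positive subjects.
#'
#' Histology for biopsied subjects follows the class label: `oscc` maps
#' to an OSCC histology, `opmd` to dysplasia, and truly non-suspicious
#' subjects to non-dysplasia.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with one row per subject and columns
#'   `subject_id`, `true_status`, `class_label`, `fhw_call`,
#'   `onsite_call`, `remote_call`, `biopsied`, `histology`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "config must be a cohort_config")
  rp <- config$rater_profiles
  withr::with_seed(config$seed, {
    n <- config$n_subjects
    truth <- runif(n) < config$prevalence
    class_label <- character(n)
    class_label[truth] <- ifelse(runif(sum(truth)) < 0.7, "opmd", "oscc")
    class_label[!truth] <- ifelse(runif(sum(!truth)) < 0.6, "normal", "benign")

    fhw_call <- draw_calls(truth, rp$fhw)
    # not-interpretable drawn before the remote call
    ni <- runif(n) < rp$remote$not_interpretable_rate
    remote_call <- draw_calls(truth, rp$remote)
    remote_call[ni] <- "not_interpretable"

    onsite_seen <- remote_call == "suspicious" &
      runif(n) < config$onsite_fraction
    onsite_call <- rep("absent", n)
    onsite_call[onsite_seen] <- draw_calls(truth[onsite_seen], rp$onsite)

    biopsied <- onsite_call == "suspicious" &
      runif(n) < config$biopsy_compliance
    histology <- rep("absent", n)
    histology[biopsied] <- ifelse(
      truth[biopsied],
      ifelse(class_label[biopsied] == "oscc", "oscc", "dysplasia"),
      "non_dysplasia")

    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      true_status = ifelse(truth, "suspicious", "non_suspicious"),
      class_label = class_label,
      fhw_call = fhw_call,
      onsite_call = onsite_call,
      remote_call = remote_call,
      biopsied = biopsied,
      histology = histology,
      stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort table as CSV
#'
#' The schema is the fixed header
#' `subject_id,true_status,class_label,fhw_call,onsite_call,remote_call,biopsied,histology`.
#'
#' @param cohort a cohort `data.frame` from [generate_cohort()].
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "true_status", "class_label", "fhw_call",
            "onsite_call", "remote_call", "biopsied", "histology")
  assert_that(all(cols %in% names(cohort)), "cohort is missing schema columns")
  write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$biopsied <- as.logical(df$biopsied)
  df
}

#' Write / read a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  assert_that(inherits(config, "cohort_config"),
              "config must be a cohort_config")
  lst <- unclass(config)
  lst$rater_profiles <- lapply(lst$rater_profiles, unclass)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lst <- yaml::read_yaml(path)
  assert_that(!is.null(lst$seed), "seed is mandatory in a cohort config")
  profiles <- lapply(lst$rater_profiles, function(p) {
    rater_profile(p$tier, p$sensitivity, p$specificity,
                  p$not_interpretable_rate %||% 0)
  })
  cohort_config(n_subjects = lst$n_subjects, prevalence = lst$prevalence,
                rater_profiles = profiles,
                biopsy_compliance = lst$biopsy_compliance,
                onsite_fraction = lst$onsite_fraction,
                image_size = lst$image_size,
                noise_sd = lst$noise_sd, blur_sigma = lst$blur_sigma,
                seed = lst$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
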