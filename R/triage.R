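#' Run the full simulated screening cascade
#'
#' Wires every stage into the three-level triage the field study
#' deployed: frontline health workers capture dual-mode images (with a
#' sharpness quality gate and one recapture attempt for failed pairs),
#' a phone-tier CNN classifies in real time, a cloud-tier Bayesian CNN
#' adds Monte-Carlo-dropout uncertainty, and cases whose uncertainty
#' exceeds `tau` are referred to the simulated remote specialist, whose
#' call overrides the model's for those cases only. Rater tiers (FHW,
#' onsite, remote) and biopsy verification come from the cohort
#' simulator. Subjects whose remote read is not interpretable are
#' excluded from all comparisons.
#'
#' The report contains a consort-style stage table, one contingency
#' table + metrics report per tier pair (analogous to the field study's
#' comparison table), the uncertainty sweep of the cloud tier, and a
#' config hash; everything is reproducible from `(configs, tau, seed)`.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param model_cfg a [model_config()]; ignored when `model` is given.
#' @param model optional pre-trained `oralscreen_model`; when `NULL` and
#'   `include_cnn = TRUE`, a model is trained on a freshly generated
#'   training set of `n_train` pairs (disjoint seed stream).
#' @param tau uncertainty referral threshold (default 0.15).
#' @param taus thresholds for the uncertainty sweep.
#' @param n_train,n_val training and validation pairs for the internally
#'   trained model.
#' @param quality_threshold sharpness threshold for the capture gate.
#' @param include_cnn simulate the CNN tiers; `FALSE` gives a fast
#'   rater-tiers-only report (no images, no training).
#' @param mc_passes stochastic passes for the cloud tier (model config
#'   default if `NULL`).
#' @param oracle_referral if `TRUE`, referred cases receive the true
#'   status instead of the simulated remote specialist's call — an
#'   upper-bound experiment.
#' @param phenotype_fun function `(class_label, image_size, seed,
#'   noise_sd, blur_sigma) -> phenotype_spec` used to render each
#'   subject's images (default [default_phenotype()]); lets experiments
#'   swap in e.g. fully separable phenotypes.
#' @param verbose print stage progress.
#' @return an object of class `study_report`: list with `consort`,
#'   `comparisons` (named list of [metrics_report()]), `tables` (the
#'   matching [contingency_table()]s), `sweep`, `predictions`,
#'   `config_hash`, `seed`.
#' @export
run_screening <- function(cohort_cfg, model_cfg = model_config(),
                          model = NULL, tau = 0.15,
                          taus = seq(0, 0.5, 0.01),
                          n_train = 600, n_val = 200,
                          quality_threshold = 0.005,
                          include_cnn = TRUE, mc_passes = NULL,
                          oracle_referral = FALSE,
                          phenotype_fun = default_phenotype,
                          verbose = FALSE) {
  assert_that(inherits(cohort_cfg, "cohort_config"),
              "cohort_cfg must be a cohort_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("screening stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating cohort (n=%d)", cohort_cfg$n_subjects)
  cohort <- stage("cohort", generate_cohort(cohort_cfg))
  analyzed <- cohort$remote_call != "not_interpretable"

  predictions <- NULL
  if (include_cnn) {
    if (is.null(model)) {
      say("training classifier (%d train pairs)", n_train)
      model <- stage("train", {
        ds <- generate_dataset(
          n_train_val = n_train + n_val, n_test = 1,
          train_frac = n_train / (n_train + n_val),
          prevalence = cohort_cfg$prevalence,
          image_size = cohort_cfg$image_size,
          noise_sd = cohort_cfg$noise_sd,
          blur_sigma = cohort_cfg$blur_sigma,
          seed = derive_seed(cohort_cfg$seed, 301L))
        train(ds, model_cfg)
      })
    }
    say("imaging and classifying %d analyzed subjects", sum(analyzed))
    idx <- which(analyzed)
    fused <- stage("imaging", lapply(idx, function(i) {
      s <- derive_seed(cohort_cfg$seed, 1000L + i)
      render <- function(blur) {
        spec <- phenotype_fun(cohort$class_label[i],
                              cohort_cfg$image_size, seed = s,
                              noise_sd = cohort_cfg$noise_sd,
                              blur_sigma = blur)
        generate_image_pair(spec, seed = derive_seed(s, 7L),
                            image_size = cohort_cfg$image_size,
                            subject_id = cohort$subject_id[i])
      }
      pair <- render(cohort_cfg$blur_sigma)
      q <- quality_gate(pair, quality_threshold)
      recaptured <- FALSE
      if (!q$passed) { # one recapture at best focus
        pair <- render(0)
        recaptured <- TRUE
      }
      f <- fuse_channels(pair)
      attr(f, "recaptured") <- recaptured
      f
    }))
    n_recaptured <- sum(vapply(fused, function(f) {
      isTRUE(attr(f, "recaptured"))
    }, logical(1)))

    # phone tier: deterministic single pass
    phone_p <- stage("phone_tier", {
      x <- array(unlist(lapply(fused, `[[`, "channels"),
                        use.names = FALSE),
                 c(model$input_shape, length(fused)))
      forward_chunked(model$layers, x, dropout_active = FALSE)
    })
    phone_call <- ifelse(phone_p >= 0.5, "suspicious", "non_suspicious")

    # cloud tier: Monte-Carlo dropout
    say("cloud tier Monte-Carlo passes")
    cloud <- stage("cloud_tier",
                   classify_batch(model, fused, tau = tau, T = mc_passes,
                                  seed = derive_seed(cohort_cfg$seed,
                                                     302L)))
    referred <- cloud$triage == "refer"
    final_call <- cloud$label
    override <- if (oracle_referral) {
      cohort$true_status[idx]
    } else {
      cohort$remote_call[idx]
    }
    final_call[referred] <- override[referred]

    predictions <- data.frame(
      subject_id = cohort$subject_id[idx],
      phone_call = phone_call,
      p_suspicious = cloud$p_suspicious,
      uncertainty = cloud$uncertainty,
      cloud_call = cloud$label,
      triage = cloud$triage,
      final_call = final_call,
      recaptured = FALSE,
      stringsAsFactors = FALSE)
    predictions$recaptured[seq_along(fused)] <- vapply(fused, function(f) {
      isTRUE(attr(f, "recaptured"))
    }, logical(1))
  }

  # tier-pair comparisons on the analyzed population
  say("building comparisons")
  an <- cohort[analyzed, ]
  histology_call <- ifelse(
    an$histology == "absent", "absent",
    ifelse(an$histology %in% c("oscc", "dysplasia"), "suspicious",
           "non_suspicious"))
  cmp_defs <- list(
    onsite_vs_histology = list(an$onsite_call, histology_call,
                               "onsite_specialist", "histology"),
    remote_vs_onsite = list(an$remote_call, an$onsite_call,
                            "remote_specialist", "onsite_specialist"),
    fhw_vs_remote = list(an$fhw_call, an$remote_call, "fhw",
                         "remote_specialist"),
    fhw_vs_onsite = list(an$fhw_call, an$onsite_call, "fhw",
                         "onsite_specialist"))
  if (include_cnn) {
    cmp_defs$phone_vs_remote <- list(predictions$phone_call,
                                     an$remote_call, "phone_cnn",
                                     "remote_specialist")
    cmp_defs$cloud_vs_remote <- list(predictions$cloud_call,
                                     an$remote_call, "cloud_bdl",
                                     "remote_specialist")
    cmp_defs$final_vs_remote <- list(predictions$final_call,
                                     an$remote_call,
                                     "cloud_bdl_with_referral",
                                     "remote_specialist")
  }
  # comparisons with no eligible subjects (e.g. nobody biopsied in a
  # small cohort) are omitted from the report, not fatal
  tables <- lapply(names(cmp_defs), function(nm) {
    d <- cmp_defs[[nm]]
    tryCatch(
      stage(paste0("compare_", nm),
            build_table(d[[1]], d[[2]], d[[3]], d[[4]])),
      error = function(e) {
        if (grepl("no subjects left", conditionMessage(e))) NULL else
          stop(e)
      })
  })
  names(tables) <- names(cmp_defs)
  tables <- Filter(Negate(is.null), tables)
  comparisons <- lapply(tables, metrics_report)

  sweep <- NULL
  if (include_cnn) {
    eligible <- an$remote_call != "not_interpretable"
    sweep <- uncertainty_sweep(
      data.frame(label = predictions$cloud_call,
                 uncertainty = predictions$uncertainty),
      an$remote_call, taus)
  }

  consort <- data.frame(
    stage = c("recruited", "not_interpretable", "analyzed",
              "fhw_suspicious", "remote_suspicious", "onsite_seen",
              "onsite_suspicious", "biopsied"),
    parent = c(NA, "recruited", "recruited", "analyzed", "analyzed",
               "remote_suspicious", "onsite_seen", "onsite_suspicious"),
    count = c(nrow(cohort), sum(!analyzed), sum(analyzed),
              sum(an$fhw_call == "suspicious"),
              sum(an$remote_call == "suspicious"),
              sum(an$onsite_call != "absent"),
              sum(an$onsite_call == "suspicious"),
              sum(an$biopsied)),
    stringsAsFactors = FALSE)
  if (include_cnn) {
    consort <- rbind(consort, data.frame(
      stage = c("recaptured", "referred_by_uncertainty"),
      parent = c("analyzed", "analyzed"),
      count = c(n_recaptured, sum(predictions$triage == "refer"))))
  }

  structure(list(consort = consort, comparisons = comparisons,
                 tables = tables, sweep = sweep,
                 predictions = predictions, cohort = cohort,
                 tau = tau,
                 config_hash = rlang::hash(list(cohort_cfg, model_cfg,
                                                tau, taus)),
                 seed = cohort_cfg$seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d, tau %.2f, %d comparisons\n",
              x$seed, x$tau, length(x$comparisons)))
  print(consort_counts(x))
  invisible(x)
}

#' Consort-style stage table with percentages of the parent stage
#'
#' @param report a [run_screening()] report.
#' @return a `data.frame` with columns `stage`, `parent`, `count`,
#'   `pct_of_parent` (1 dp).
#' @export
consort_counts <- function(report) {
  assert_that(inherits(report, "study_report"),
              "report must be a study_report")
  con <- report$consort
  parent_count <- con$count[match(con$parent, con$stage)]
  con$pct_of_parent <- ifelse(is.na(parent_count), NA_real_,
                              round(100 * con$count / parent_count, 1))
  con
}

#' Write a study report as stable JSON plus CSV tables
#'
#' Emits `report.json` (consort, metric estimates and CIs, sweep, config
#' hash), `table1.csv` (the tidy tier-comparison metric table) and
#' `consort.csv`.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  assert_that(inherits(report, "study_report"),
              "report must be a study_report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frame <- report_frame(report$comparisons)
  write.csv(frame, file.path(dir, "table1.csv"), row.names = FALSE)
  write.csv(consort_counts(report), file.path(dir, "consort.csv"),
            row.names = FALSE)
  json <- list(seed = report$seed, tau = report$tau,
               config_hash = report$config_hash,
               consort = consort_counts(report),
               metrics = frame,
               sweep = report$sweep)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file.path(dir, c("report.json", "table1.csv", "consort.csv")))
}
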