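#' Generate a labeled image dataset with train / validation / test splits
#'
#' Samples subject class labels at the configured prevalence, renders one
#' WLI/AFI pair per subject, and splits subjects into training,
#' cross-validation and a standalone test set. The split is seeded,
#' disjoint by subject, and stratified by the four-way class label with
#' exact allocation (per-class counts within one of the ideal
#' proportions). The standalone test set is generated from its own seed
#' stream and is never seen during training.
#'
#' Default sizes mirror the field study's probe-image dataset: 5329
#' training/cross-validation pairs and 1416 standalone test pairs.
#' Desk-scale analyses pass much smaller sizes.
#'
#' @param n_train_val subjects in the combined training +
#'   cross-validation pool.
#' @param n_test subjects in the standalone test set.
#' @param train_frac fraction of the pool assigned to training
#'   (default 0.75; the remainder is cross-validation).
#' @param prevalence proportion of suspicious (opmd or oscc) subjects.
#' @param image_size image side in pixels.
#' @param noise_sd,blur_sigma rendering parameters (see
#'   [phenotype_spec()]).
#' @param seed integer seed fixing labels, geometry, pixels and split.
#' @return a list of class `screening_dataset` with elements `train`,
#'   `validation`, `test`; each is a list of records holding `pair` (a
#'   [dual_mode_image()]), `class_label`, `label` (`TRUE` for
#'   suspicious) and `subject_id`.
#' @export
generate_dataset <- function(n_train_val = 5329, n_test = 1416,
                             train_frac = 0.75, prevalence = 0.42,
                             image_size = 64, noise_sd = 0.02,
                             blur_sigma = 0.8, seed = 1) {
  assert_that(n_train_val >= 2 && n_test >= 1,
              "each split must contain at least one subject")
  assert_that(train_frac > 0 && train_frac < 1,
              "train_frac must lie in (0,1)")
  make_pool <- function(n, seed, prefix) {
    withr::with_seed(seed, {
      truth <- runif(n) < prevalence
      cls <- character(n)
      cls[truth] <- ifelse(runif(sum(truth)) < 0.7, "opmd", "oscc")
      cls[!truth] <- ifelse(runif(sum(!truth)) < 0.6, "normal", "benign")
      data.frame(subject_id = sprintf("%s%05d", prefix, seq_len(n)),
                 class_label = cls, label = truth,
                 stringsAsFactors = FALSE)
    })
  }
  pool <- make_pool(n_train_val, derive_seed(seed, 1L), "T")
  test_pool <- make_pool(n_test, derive_seed(seed, 2L), "X")

  # exact stratified allocation: per class, round(train_frac * n_k) to train
  split <- withr::with_seed(derive_seed(seed, 3L), {
    assign <- rep("validation", nrow(pool))
    for (cl in unique(pool$class_label)) {
      idx <- which(pool$class_label == cl)
      idx <- sample(idx)
      n_tr <- round(train_frac * length(idx))
      assign[idx[seq_len(n_tr)]] <- "train"
    }
    assign
  })

  render <- function(df, seed0) {
    lapply(seq_len(nrow(df)), function(i) {
      s <- derive_seed(seed0, i)
      spec <- default_phenotype(df$class_label[i], image_size, seed = s,
                                noise_sd = noise_sd, blur_sigma = blur_sigma)
      list(pair = generate_image_pair(spec, seed = derive_seed(s, 7L),
                                      image_size = image_size,
                                      subject_id = df$subject_id[i]),
           class_label = df$class_label[i], label = df$label[i],
           subject_id = df$subject_id[i])
    })
  }
  out <- list(train = render(pool[split == "train", ], derive_seed(seed, 4L)),
              validation = render(pool[split == "validation", ],
                                  derive_seed(seed, 5L)),
              test = render(test_pool, derive_seed(seed, 6L)))
  structure(out, class = "screening_dataset",
            prevalence = prevalence, seed = seed)
}

#' @export
print.screening_dataset <- function(x, ...) {
  cat(sprintf("<screening_dataset> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}
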