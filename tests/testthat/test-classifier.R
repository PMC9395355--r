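# Focal loss, augmentation and Monte-Carlo prediction mechanics
# (training behaviour is covered in test-training.R).

test_that("focal loss reduces to cross-entropy and has its fixed points", {
  p_grid <- seq(0.01, 1, 0.01)
  expect_equal(focal_loss(p_grid, alpha = 1, gamma = 0), -log(p_grid))
  expect_equal(focal_loss(1, alpha = 1, gamma = 2), 0)
  expect_equal(focal_loss(1, alpha = 1, gamma = 0), 0)
  # hand evaluation: p = 0.9, gamma = 2, alpha = 0.25
  expect_equal(focal_loss(0.9, alpha = 0.25, gamma = 2),
               0.25 * 0.1^2 * (-log(0.9)))
  # nonnegative and strictly decreasing in p
  l <- focal_loss(p_grid, alpha = 0.25, gamma = 2)
  expect_true(all(l >= 0))
  expect_true(all(diff(l) < 0))
  # domain errors
  expect_error(focal_loss(-0.1), "\\[0, 1\\]")
  expect_error(focal_loss(1.1), "\\[0, 1\\]")
})

test_that("focal gradient matches numerical differentiation", {
  ns <- asNamespace("oralscreen")
  set.seed(1)
  z <- matrix(rnorm(2 * 6), 2, 6)
  y <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  for (prm in list(c(1, 0), c(0.25, 2), c(0.5, 1))) {
    probs <- ns$softmax_cols(z)
    g <- ns$focal_loss_grad(probs, y, prm[1], prm[2])
    for (j in sample(length(z), 6)) {
      eps <- 1e-6
      zp <- z; zp[j] <- zp[j] + eps
      zm <- z; zm[j] <- zm[j] - eps
      lp <- ns$mean_focal_loss(ns$softmax_cols(zp), y, prm[1], prm[2])
      lm <- ns$mean_focal_loss(ns$softmax_cols(zm), y, prm[1], prm[2])
      expect_equal(g[j], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("augmentation operations are label-preserving involutions", {
  spec <- fixture_loss_spec(noise_sd = 0.02)
  fused <- fuse_channels(generate_image_pair(spec, seed = 3))
  # forced identity is a no-op
  expect_identical(augment(fused, op = "identity")$channels,
                   fused$channels)
  # double flips return the original
  expect_identical(
    augment(augment(fused, op = "hflip"), op = "hflip")$channels,
    fused$channels)
  expect_identical(
    augment(augment(fused, op = "vflip"), op = "vflip")$channels,
    fused$channels)
  expect_identical(
    augment(augment(fused, op = "rot180"), op = "rot180")$channels,
    fused$channels)
  # rot90 four times is the identity
  r <- fused
  for (i in 1:4) r <- augment(r, op = "rot90")
  expect_identical(r$channels, fused$channels)
  # a fixed seed reproduces the same draw; some seed maps to a no-op
  expect_identical(augment(fused, seed = 5)$channels,
                   augment(fused, seed = 5)$channels)
  ident_found <- any(vapply(1:40, function(s) {
    identical(augment(fused, seed = s)$channels, fused$channels)
  }, logical(1)))
  expect_true(ident_found)
})

test_that("jitter keeps channels inside [0,1] over many seeds", {
  spec <- fixture_loss_spec(noise_sd = 0.05)
  fused <- fuse_channels(generate_image_pair(spec, seed = 3))
  for (s in 1:100) {
    out <- augment(fused, seed = s, op = "jitter")$channels
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("mc_prediction aggregates passes per the hand oracle", {
  # constructed passes {0.4, 0.8}: mean 0.6, population SD 0.2, so the
  # case is labelled suspicious and referred at tau = 0.15
  p <- mc_prediction(c(0.4, 0.8), tau = 0.15)
  expect_equal(p$p_suspicious, 0.6)
  expect_equal(p$uncertainty, 0.2)
  expect_identical(p$label, "suspicious")
  expect_identical(p$triage, "refer")
  # the same passes are not referred at a looser threshold
  expect_identical(mc_prediction(c(0.4, 0.8), tau = 0.25)$triage, "auto")
  # tie at 0.5 resolves to suspicious (screening favours sensitivity)
  expect_identical(mc_prediction(0.5, tau = 0.1)$label, "suspicious")
  # degenerate passes: zero uncertainty, auto for any positive tau
  expect_identical(mc_prediction(rep(0.7, 5), tau = 1e-9)$triage, "auto")
})

test_that("disabled dropout collapses Monte-Carlo prediction to one pass", {
  cfg <- model_config(dropout_rate = 0, epochs = 1, seed = 2)
  model <- init_model(cfg, c(16, 16, 3))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pred <- predict_mc(model, x, tau = 0.15, seed = 1)
  expect_equal(pred$uncertainty, 0)
  expect_identical(pred$triage, "auto")
  expect_length(pred$passes, 1)
  expect_equal(pred$p_suspicious, predict_proba(model, x))
})

test_that("Monte-Carlo prediction needs at least two passes", {
  cfg <- model_config(dropout_rate = 0.5, epochs = 1, seed = 2)
  model <- init_model(cfg, c(16, 16, 3))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_error(predict_mc(model, x, T = 1), ">= 2")
  expect_error(model_config(dropout_rate = 0.5, mc_passes = 1),
               "mc_passes")
})

test_that("classify_batch preserves order, isolates failures, handles empty", {
  cfg <- model_config(epochs = 1, seed = 4)
  model <- init_model(cfg, c(16, 16, 3))
  expect_equal(nrow(classify_batch(model, list())), 0)
  good <- lapply(1:3, function(i) {
    spec <- default_phenotype("opmd", 16, seed = i)
    fuse_channels(generate_image_pair(spec, seed = i, image_size = 16,
                                      subject_id = sprintf("S%02d", i)))
  })
  bad <- array(0.5, c(8, 8, 3)) # wrong shape
  out <- classify_batch(model, c(good[1:2], list(bad), good[3]), seed = 1)
  expect_equal(nrow(out), 4)
  expect_identical(out$subject_id[1:2], c("S01", "S02"))
  expect_true(is.na(out$p_suspicious[3]) && !is.na(out$error[3]))
  expect_false(anyNA(out$p_suspicious[c(1, 2, 4)]))
  # batch result equals item-by-item results under the same seed
  solo <- predict_mc(model, good[[1]], tau = 0.15, seed = 1)
  batch1 <- classify_batch(model, good[1], tau = 0.15, seed = 1)
  expect_equal(batch1$p_suspicious, solo$p_suspicious)
  expect_equal(batch1$uncertainty, solo$uncertainty)
})

test_that("referral fraction is monotone non-increasing in tau", {
  set.seed(6)
  u <- runif(200, 0, 0.3)
  taus <- seq(0, 0.35, 0.01)
  frac <- vapply(taus, function(t) mean(u > t), numeric(1))
  expect_true(all(diff(frac) <= 0))
  # referral fraction at tau = 0 equals the fraction with u > 0
  expect_equal(frac[1], mean(u > 0))
})

test_that("model checkpoints round-trip through the JSON manifest", {
  dir <- withr::local_tempdir()
  cfg <- model_config(epochs = 1, seed = 12, head_widths = c(8, 4))
  model <- init_model(cfg, c(16, 16, 3))
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_model(dir)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(predict_proba(back, x), predict_proba(model, x))
})
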