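# Shared fixtures built in code at test time.

# A deterministic lesion shape fitting comfortably in a 64x64 frame.
fixture_shape <- function(cx = 32, cy = 30, a = 12, b = 8, theta = 0.4) {
  list(cx = cx, cy = cy, a = a, b = b, theta = theta)
}

# Noise-free phenotype with fluorescence loss at the default depth.
fixture_loss_spec <- function(noise_sd = 0, blur_sigma = 0) {
  phenotype_spec("opmd", fixture_shape(),
                 afi_fluorescence_mode = "loss",
                 noise_sd = noise_sd, blur_sigma = blur_sigma)
}

# Logical mask matching a shape (mirrors the generator's geometry).
fixture_mask <- function(shape, n = 64) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  ct <- cos(shape$theta); st <- sin(shape$theta)
  u <- ((xx - shape$cx) * ct + (yy - shape$cy) * st) / shape$a
  v <- (-(xx - shape$cx) * st + (yy - shape$cy) * ct) / shape$b
  u * u + v * v <= 1
}

# Small cohort config for fast tests.
fixture_cohort_config <- function(n = 500, seed = 42, ...) {
  cohort_config(n_subjects = n, seed = seed, ...)
}

# The six reference contingency tables as contingency_table objects.
fixture_study_tables <- function() {
  counts <- study_contingency_tables()
  tabs <- lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], contingency_table(tp, fp, fn, tn, test, reference))
  })
  names(tabs) <- counts$comparison
  tabs
}
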