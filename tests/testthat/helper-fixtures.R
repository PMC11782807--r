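# Shared fixtures: tiny profiles keep unit tests fast; the full 256x256
# geometry is exercised where a contract depends on it.

tiny_config <- function(views = c("SAX", "4CH"), n_phases = 3L,
                        feature_dim = 5L, ...) {
  cinefuse_config(views = views, n_phases = n_phases, image_size = 32L,
                  pool_grid = 4L, feature_dim = feature_dim, ...)
}

tiny_model <- function(seed = 1L, ...) cinefuse_model(tiny_config(...), seed = seed)

full_model <- function(seed = 1L, ...) cinefuse_model(cinefuse_config(...), seed = seed)

# A raw cine series with reproducible content.
raw_series <- function(h = 64, w = 64, n = 20, spacing = 1.5,
                       view = "SAX", seed = 1) {
  withr::with_seed(seed, {
    cine_series(array(runif(h * w * n, 0, 200), c(h, w, n)), spacing, view)
  })
}

# A labelled phantom exam at default geometry.
phantom_exam <- function(mPAP = 45, seed = 3, masks = TRUE,
                         config = phantom_config()) {
  generate_exam(config, c(mPAP = mPAP, PAWP = 12, PVR = 7), seed = seed,
                masks = masks)
}

# Modest phantom set encoded once and shared across training tests.
train_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(phantom_config(), n_train = 36, n_val = 10,
                             n_test = 10, seed = 101)
      cache <<- encode_dataset(ds, cinefuse_config())
    }
    cache
  }
})

# Brute-force AFFB oracle: explicit loops, no shared code with the package.
affb_oracle <- function(components, w_a, b_a) {
  n <- nrow(components); d <- ncol(components)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    s <- b_a
    for (j in seq_len(d)) s <- s + components[i, j] * w_a[j]
    raw[i] <- s
  }
  ex <- numeric(n)
  for (i in seq_len(n)) ex[i] <- exp(raw[i] - max(raw))
  alpha <- ex / sum(ex)
  fused <- numeric(d)
  for (j in seq_len(d)) {
    for (i in seq_len(n)) fused[j] <- fused[j] + alpha[i] * components[i, j]
  }
  list(fused = fused, alpha = alpha)
}
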