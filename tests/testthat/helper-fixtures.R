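# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

# A small default-parameter field (4 x 9 x 3 = 108 plots) with clips and the
# full feature matrix.
small_field <- function() {
  if (is.null(.fixtures$small)) {
    field <- generate_field(field_config(
      n_families = 4L, n_progeny_per_family = 9L, n_replications = 3L,
      rng_seed = 101L))
    plots <- clip_plots(field$orthoimage, field$layout)
    .fixtures$small <- list(field = field, plots = plots,
                            features = extract_feature_matrix(plots))
  }
  .fixtures$small
}

# A noise-free field with yield exactly proportional to plant pixel area.
linear_field <- function() {
  if (is.null(.fixtures$linear)) {
    field <- generate_field(field_config(
      n_families = 6L, n_progeny_per_family = 10L, n_replications = 3L,
      dmy_noise_sd = 0, dmy_exponent = 1, rng_seed = 202L))
    plots <- clip_plots(field$orthoimage, field$layout)
    .fixtures$linear <- list(field = field, plots = plots,
                             features = extract_feature_matrix(plots))
  }
  .fixtures$linear
}

# Uniform-colour image.
flat_image <- function(rgb, h = 16L, w = 16L, id = "flat") {
  px <- array(0L, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  plot_image(px, id)
}

# Random 8-bit image from a fixed seed.
random_image <- function(seed, h = 16L, w = 16L, id = "rand") {
  set.seed(seed)
  plot_image(array(sample(0:255, h * w * 3L, replace = TRUE), c(h, w, 3L)), id)
}

# Separable two-class image set for the CNN harness: large centred green
# plant versus bare soil.
separable_plots <- function(n = 100L, seed = 9L) {
  set.seed(seed)
  big <- rep(c(TRUE, FALSE), length.out = n)
  plots <- lapply(seq_len(n), function(i) {
    px <- array(as.integer(round(runif(32L * 32L * 3L, 90, 140))),
                c(32L, 32L, 3L))
    if (big[i]) {
      r <- 8 + sample(0:4, 1)
      for (y in 1:32) for (x in 1:32)
        if ((x - 16)^2 + (y - 16)^2 < r^2) px[y, x, ] <- c(40L, 180L, 60L)
    }
    plot_image(px, sprintf("p%03d", i))
  })
  list(plots = plots, labels = ifelse(big, "Select", "Discard"),
       ids = vapply(plots, function(p) p$plot_id, ""))
}
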