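#' Configuration of the synthetic field generator
#'
#' The generator emulates a progeny-assessment trial of individually spaced
#' plants photographed from above: a regular grid with one plant per plot,
#' rendered as a cluster of overlapping green elliptical blobs (tillers) on
#' Gaussian-textured soil with a low-frequency brightness gradient. Dry
#' matter yield follows an allometric function of the plant's true pixel
#' area, and the breeder's score is a noisy rank-based discretisation of
#' yield, so the predictive power of the score is continuously tunable.
#'
#' The default layout matches a trial of 44 families x 32 half-sib progeny
#' x 3 replications = 4,224 plots. Plots are laid out with one replication
#' block below the other: grid rows = families x replications, grid columns
#' = progeny.
#'
#' @param n_families,n_progeny_per_family,n_replications positive integers;
#'   the plot count is their product.
#' @param plot_size_px side length of each square plot in pixels.
#' @param plant_radius_px_range length-2 numeric, pixels: range of the
#'   plant's overall radius, drawn uniformly per plant.
#' @param tiller_blob_count_range length-2 integer: range of the number of
#'   elliptical blobs per plant, drawn uniformly.
#' @param dmy_coefficient grams per unit (pixel area)^`dmy_exponent`.
#' @param dmy_exponent allometric exponent linking projected area to yield.
#' @param dmy_noise_sd relative standard deviation of the multiplicative
#'   Gaussian yield noise.
#' @param score_noise_sd standard deviation, on the 0-5 scale, of the noise
#'   added before discretising the yield rank into a breeder's score. The
#'   default is calibrated (see [calibrate_score_noise()]) so that the
#'   benchmark score model reaches a held-out R-squared near 0.54.
#' @param soil_rgb_mean length-3 numeric, 0-255: mean soil colour.
#' @param soil_texture_sd per-pixel Gaussian jitter of the soil colour.
#' @param rng_seed integer seed; seeded runs are bit-identical.
#' @return An object of class `field_config`.
#' @export
field_config <- function(n_families = 44L, n_progeny_per_family = 32L,
                         n_replications = 3L, plot_size_px = 48L,
                         plant_radius_px_range = c(5, 16),
                         tiller_blob_count_range = c(3L, 40L),
                         dmy_coefficient = 0.025, dmy_exponent = 1.3,
                         dmy_noise_sd = 0.1, score_noise_sd = 1.03,
                         soil_rgb_mean = c(125, 92, 66), soil_texture_sd = 6,
                         rng_seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    n_progeny_per_family = as.integer(n_progeny_per_family),
    n_replications = as.integer(n_replications),
    plot_size_px = as.integer(plot_size_px),
    plant_radius_px_range = as.numeric(plant_radius_px_range),
    tiller_blob_count_range = as.integer(tiller_blob_count_range),
    dmy_coefficient = dmy_coefficient, dmy_exponent = dmy_exponent,
    dmy_noise_sd = dmy_noise_sd, score_noise_sd = score_noise_sd,
    soil_rgb_mean = as.numeric(soil_rgb_mean),
    soil_texture_sd = soil_texture_sd, rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (n_families < 1L || n_progeny_per_family < 1L || n_replications < 1L ||
        plot_size_px < 1L)
      stop("dimensions must be positive")
    if (length(plant_radius_px_range) != 2L ||
        any(plant_radius_px_range <= 0) ||
        diff(plant_radius_px_range) < 0)
      stop("plant_radius_px_range must be a positive, ordered pair")
    if (length(tiller_blob_count_range) != 2L ||
        any(tiller_blob_count_range < 1L) ||
        diff(tiller_blob_count_range) < 0)
      stop("tiller_blob_count_range must be a positive, ordered pair")
    if (dmy_exponent <= 0) stop("dmy_exponent must be positive")
    if (dmy_noise_sd < 0 || score_noise_sd < 0 || soil_texture_sd < 0)
      stop("noise standard deviations must be non-negative")
    if (plot_size_px < 2 * max(plant_radius_px_range))
      stop("plot size ", plot_size_px,
           " px is too small for the largest plant radius ",
           max(plant_radius_px_range), " px")
  })
  structure(cfg, class = "field_config")
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf(
    "<field_config: %d families x %d progeny x %d reps = %d plots of %d px, seed %d>\n",
    x$n_families, x$n_progeny_per_family, x$n_replications,
    x$n_families * x$n_progeny_per_family * x$n_replications,
    x$plot_size_px, x$rng_seed))
  invisible(x)
}

# Render one plant plot. Returns the plot's pixel array (double, 0-255) and
# the true plant pixel area. Blobs falling partly outside the plot are
# clipped; area counts visible plant pixels only.
render_plot <- function(ps, cfg, brightness) {
  soil <- cfg$soil_rgb_mean * brightness
  px <- array(0, c(ps, ps, 3))
  for (ch in 1:3)
    px[, , ch] <- soil[ch] + rnorm(ps * ps, 0, cfg$soil_texture_sd)

  radius <- runif(1, cfg$plant_radius_px_range[1], cfg$plant_radius_px_range[2])
  k <- sample(cfg$tiller_blob_count_range[1]:cfg$tiller_blob_count_range[2], 1L)
  centre <- (ps + 1) / 2
  mask <- matrix(FALSE, ps, ps)
  for (b in seq_len(k)) {
    cx <- centre + rnorm(1, 0, 0.35 * radius)
    cy <- centre + rnorm(1, 0, 0.35 * radius)
    a <- max(1, runif(1, 0.15, 0.45) * radius)
    bb <- max(1, runif(1, 0.15, 0.45) * radius)
    th <- runif(1, 0, pi)
    # blob colour: "plant green" HSV window with hue jitter
    hue <- runif(1, 95, 145) / 360
    sat <- runif(1, 0.45, 0.85)
    val <- runif(1, 0.17, 0.80)  # a small share of tillers falls below the
                                 # strict counter's value floor (dry/shaded
                                 # matter), so that counter slightly
                                 # under-estimates plant cover
    rgb01 <- grDevices::col2rgb(grDevices::hsv(hue, sat, val))[, 1]

    r_ext <- max(a, bb)
    rows <- max(1L, floor(cy - r_ext)):min(ps, ceiling(cy + r_ext))
    cols <- max(1L, floor(cx - r_ext)):min(ps, ceiling(cx + r_ext))
    if (!length(rows) || !length(cols)) next
    dy <- rows - cy
    dx <- cols - cx
    # rotated ellipse equation on the bounding-box subgrid
    u <- outer(dy, dx, function(y, x) (x * cos(th) + y * sin(th)) / a)
    v <- outer(dy, dx, function(y, x) (-x * sin(th) + y * cos(th)) / bb)
    inside <- u * u + v * v <= 1
    if (!any(inside)) next
    mask[rows, cols] <- mask[rows, cols] | inside
    for (ch in 1:3) {
      sl <- px[rows, cols, ch]
      sl[inside] <- rgb01[ch]
      px[rows, cols, ch] <- sl
    }
  }
  px[px < 0] <- 0
  px[px > 255] <- 255
  list(pixels = round(px), area = sum(mask))
}

#' Generate a synthetic field trial with known ground truth
#'
#' Renders an 8-bit RGB orthoimage of the configured plot grid, one plant
#' per plot, and returns it with the per-plot ground truth: true plant pixel
#' area, dry matter yield `dmy_g = dmy_coefficient * area^dmy_exponent *
#' (1 + eps)` with `eps ~ Normal(0, dmy_noise_sd)` (truncated so yield is
#' non-negative), and a breeder's score derived from the yield ranks via
#' [derive_breeder_score()]. The marginal yield distribution is
#' right-skewed under the default configuration, matching the shape typical
#' of single-plant biomass trials.
#'
#' @param config a [field_config()].
#' @return An object of class `synthetic_field`: a list with elements
#'   `orthoimage` (H x W x 3 integer array), `truth` (data frame with
#'   columns `plot_id`, `row`, `col`, `true_area_px`, `dmy_g`,
#'   `breeder_score`), `layout` (a [field_layout()]) and `config`.
#' @examples
#' field <- generate_field(field_config(n_families = 2, n_progeny_per_family = 3,
#'                                      n_replications = 1))
#' nrow(field$truth)  # 6 plots
#' @export
generate_field <- function(config = field_config()) {
  stopifnot(inherits(config, "field_config"))
  ps <- config$plot_size_px
  n_rows <- config$n_families * config$n_replications
  n_cols <- config$n_progeny_per_family
  H <- n_rows * ps; W <- n_cols * ps

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)

  ortho <- array(0L, c(H, W, 3L))
  n_plots <- n_rows * n_cols
  area <- integer(n_plots)
  row_idx <- integer(n_plots); col_idx <- integer(n_plots)
  k <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      k <- k + 1L
      # low-frequency soil brightness gradient across the field
      brightness <- 1 + 0.10 * ((cc + 0.5) / n_cols - 0.5) +
        0.05 * sin(2 * pi * (r + 0.5) / n_rows)
      rp <- render_plot(ps, config, brightness)
      ortho[r * ps + (1:ps), cc * ps + (1:ps), ] <- rp$pixels
      area[k] <- rp$area
      row_idx[k] <- r; col_idx[k] <- cc
    }
  }
  eps <- rnorm(n_plots, 0, config$dmy_noise_sd)
  dmy <- config$dmy_coefficient * area^config$dmy_exponent * pmax(0, 1 + eps)
  score <- derive_breeder_score(dmy, config$score_noise_sd,
                                rng_seed = config$rng_seed + 1L)
  truth <- data.frame(
    plot_id = plot_id_for(row_idx, col_idx), row = row_idx, col = col_idx,
    true_area_px = area, dmy_g = dmy, breeder_score = score,
    stringsAsFactors = FALSE)
  layout <- field_layout(origin_px = c(0L, 0L), n_rows = n_rows,
                         n_cols = n_cols, plot_stride_px = c(ps, ps),
                         plot_size_px = c(ps, ps))
  structure(list(orthoimage = ortho, truth = truth, layout = layout,
                 config = config),
            class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field: %d plots, raster %d x %d px, seed %d>\n",
              nrow(x$truth), dim(x$orthoimage)[1], dim(x$orthoimage)[2],
              x$config$rng_seed))
  invisible(x)
}

#' Derive an ordinal breeder's score from yield values
#'
#' The breeder's visual 0-5 score is modelled as a noisy assessment of
#' relative biomass: `score = clamp(round(5 * F(dmy) + eta), 0, 5)` where
#' `F` is the empirical CDF of the yields (scaled so the minimum maps to 0
#' and the maximum to 5) and `eta ~ Normal(0, score_noise_sd)`. With zero
#' noise the score is a monotone function of yield; as the noise grows the
#' score loses all predictive power.
#'
#' @param dmy_values numeric vector of at least 6 yields (grams).
#' @param score_noise_sd non-negative noise SD on the 0-5 scale.
#' @param rng_seed integer seed.
#' @return Integer vector of scores in 0-5, one per yield.
#' @export
derive_breeder_score <- function(dmy_values, score_noise_sd = 1.03,
                                 rng_seed = 1L) {
  n <- length(dmy_values)
  if (n == 0L) stop("empty yield vector")
  if (n < 6L) stop("need at least 6 yield values to span the 0-5 scale")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rng_seed)
  f_hat <- (rank(dmy_values, ties.method = "average") - 1) / (n - 1)
  eta <- rnorm(n, 0, score_noise_sd)
  as.integer(pmin(5, pmax(0, round(5 * f_hat + eta))))
}

# Sample skewness (method-of-moments). Internal.
skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

#' Calibrate the score noise to a target benchmark accuracy
#'
#' Tunes `score_noise_sd` by bisection until the benchmark linear model
#' (breeder's score as categorical predictor of yield, [fit_benchmark()])
#' reaches a held-out R-squared inside `band`. The benchmark R-squared is a
#' decreasing function of the score noise: with zero noise it approaches the
#' variance explained by a six-level discretisation of the yield rank, and
#' it tends to zero as the noise grows.
#'
#' @param dmy_values yields to calibrate against (e.g. from a generated
#'   field's truth table).
#' @param band length-2 numeric: acceptable held-out R-squared interval.
#' @param test_frac fraction of plots held out for evaluating R-squared.
#' @param n_rep score draws averaged per candidate noise value.
#' @param max_iter bisection iteration cap.
#' @param rng_seed integer seed.
#' @return List with elements `score_noise_sd`, `r2` (mean held-out
#'   R-squared at the returned value) and `iterations`.
#' @export
calibrate_score_noise <- function(dmy_values, band = c(0.49, 0.59),
                                  test_frac = 0.10, n_rep = 3L,
                                  max_iter = 25L, rng_seed = 1L) {
  n <- length(dmy_values)
  if (n < 60L) stop("need at least 60 yields for a stable calibration")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rng_seed)
  test_idx <- sample.int(n, max(6L, round(test_frac * n)))
  train_idx <- setdiff(seq_len(n), test_idx)

  heldout_r2 <- function(sd) {
    r2s <- vapply(seq_len(n_rep), function(rep) {
      sc <- derive_breeder_score(dmy_values, sd,
                                 rng_seed = rng_seed + 1000L * rep)
      rec <- data.frame(plot_id = as.character(seq_len(n)),
                        dmy_g = dmy_values, breeder_score = sc,
                        stringsAsFactors = FALSE)
      bm <- fit_benchmark(rec[train_idx, ])
      pred <- predict(bm, rec$breeder_score[test_idx])
      r2(dmy_values[test_idx], pred)
    }, 0)
    mean(r2s)
  }

  lo <- 0; hi <- 3
  # widen the bracket if even maximal noise leaves too much signal
  while (heldout_r2(hi) > band[2] && hi < 50) hi <- hi * 2
  it <- 0L; mid <- (lo + hi) / 2; r2_mid <- heldout_r2(mid)
  while (it < max_iter && (r2_mid < band[1] || r2_mid > band[2])) {
    if (r2_mid > band[2]) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    r2_mid <- heldout_r2(mid)
    it <- it + 1L
  }
  list(score_noise_sd = mid, r2 = r2_mid, iterations = it)
}

#' Write a ground-truth table to CSV
#'
#' Convenience wrapper fixing the column order
#' `plot_id,row,col,true_area_px,dmy_g,breeder_score`.
#'
#' @param field a [generate_field()] result.
#' @param path output CSV path.
#' @export
write_truth_table <- function(field, path) {
  utils::write.csv(field$truth[, c("plot_id", "row", "col", "true_area_px",
                                   "dmy_g", "breeder_score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
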