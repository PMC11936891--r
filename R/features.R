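#' HSV colour histogram of a plot image
#'
#' Joint 3-D histogram in HSV space with 8 bins per channel (8^3 = 512
#' cells), flattened hue-major, then saturation, then value, and
#' L1-normalised so the entries sum to 1. Hue, saturation and value are
#' taken on the `[0, 1]` scale; the bin index of a value x is
#' `min(floor(8 x), 7)`.
#'
#' @param img a [plot_image()].
#' @param bins bins per channel (default 8).
#' @return Numeric vector of length `bins^3` summing to 1.
#' @export
colour_histogram <- function(img, bins = 8L) {
  hsv <- hsv_matrix(img)
  idx <- pmin(floor(hsv * bins), bins - 1L)
  flat <- idx[1, ] * bins^2 + idx[2, ] * bins + idx[3, ]  # hue-major
  counts <- tabulate(flat + 1L, nbins = bins^3)
  counts / sum(counts)
}

#' Hu invariant moments of a plot image
#'
#' The seven Hu moments of the luminance image, invariant to translation,
#' scale and rotation of the depicted content. Each moment h is reported as
#' `sign(h) * log10(|h| + 1e-30)` for numeric stability across their many
#' orders of magnitude. A constant image carries no shape information and is
#' treated as the degenerate case: all seven entries are 0 by convention.
#'
#' @param img a [plot_image()].
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(img) {
  g <- grayscale(img)
  if (max(g) - min(g) < .Machine$double.eps * 255) return(rep(0, 7))
  h <- nrow(g); w <- ncol(g)
  x <- matrix(rep(0:(w - 1L), each = h), h, w)   # column coordinate
  y <- matrix(rep(0:(h - 1L), w), h, w)          # row coordinate
  m00 <- sum(g)
  xb <- sum(x * g) / m00
  yb <- sum(y * g) / m00
  xc <- x - xb; yc <- y - yb
  mu <- function(p, q) sum(xc^p * yc^q * g)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  hu <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
  sign(hu) * log10(abs(hu) + 1e-30)
}

# Grey-level co-occurrence matrix for one offset (drow, dcol): symmetric,
# normalised to sum 1. `levels` is an integer matrix of 0-based grey levels.
glcm_offset <- function(levels, drow, dcol, n_levels) {
  h <- nrow(levels); w <- ncol(levels)
  r1 <- max(1L, 1L - drow):min(h, h - drow)
  c1 <- max(1L, 1L - dcol):min(w, w - dcol)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + drow, c1 + dcol, drop = FALSE]
  counts <- tabulate(a * n_levels + b + 1L, nbins = n_levels^2)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- P + t(P)  # symmetric: count each pair in both orders
  P / sum(P)
}

# The 13 classic Haralick statistics of one normalised symmetric GLCM.
# Natural logarithms; 0 log 0 = 0; correlation and the first information
# measure are defined as 0 when their denominators vanish (constant image).
haralick_from_glcm <- function(P) {
  G <- nrow(P)
  i <- matrix(rep(seq_len(G), G), G, G)      # row (first) level, 1-based
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(G) * px); mu_y <- sum(seq_len(G) * py)
  sd_x <- sqrt(sum((seq_len(G) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(G) - mu_y)^2 * py))
  plog <- function(p) ifelse(p > 0, log(p), 0)

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sd_x * sd_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y) else 0
  variance <- sum((i - mu_x)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))

  # p_{x+y}(k), k = 2..2G and p_{x-y}(k), k = 0..G-1
  sums <- as.vector(i + j); diffs <- as.vector(abs(i - j))
  p_sum <- vapply(2:(2 * G), function(k) sum(P[sums == k]), 0)
  p_diff <- vapply(0:(G - 1), function(k) sum(P[diffs == k]), 0)
  ks <- 2:(2 * G); kd <- 0:(G - 1)
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  sum_entropy <- -sum(p_sum * plog(p_sum))
  entropy <- -sum(P * plog(P))
  mu_d <- sum(kd * p_diff)
  diff_var <- sum((kd - mu_d)^2 * p_diff)
  diff_entropy <- -sum(p_diff * plog(p_diff))

  hx <- -sum(px * plog(px)); hy <- -sum(py * plog(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_entropy, entropy = entropy,
    diff_variance = diff_var, diff_entropy = diff_entropy,
    imc1 = imc1, imc2 = imc2)
}

#' Haralick texture features of a plot image
#'
#' The 13 classic grey-level co-occurrence statistics. The luminance image
#' is quantised to `n_levels` grey levels (default 32); for each of the four
#' standard distance-1 offsets (horizontal, vertical and the two diagonals)
#' a symmetric, normalised co-occurrence matrix is built, the 13 statistics
#' are computed, and the per-offset values are averaged.
#'
#' @param img a [plot_image()].
#' @param n_levels grey levels for quantisation.
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(img, n_levels = 32L) {
  d <- dim(img$pixels)
  if (d[1] < 2L || d[2] < 2L) stop("image must be at least 2 x 2")
  g <- matrix(grayscale(img), d[1], d[2])
  levels <- matrix(pmin(floor(g * n_levels / 256), n_levels - 1L),
                   nrow(g), ncol(g))
  storage.mode(levels) <- "integer"
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  feats <- vapply(offs, function(o)
    haralick_from_glcm(glcm_offset(levels, o[1], o[2], n_levels)),
    numeric(13))
  rowMeans(feats)
}

#' Count green pixels by predefined shade matching (strict)
#'
#' Counts pixels whose HSV values fall inside a fixed "plant green" box:
#' hue within `hue_range` degrees, saturation at least `min_s` and value at
#' least `min_v`. The conservative thresholds make this a slight
#' under-estimate of the true number of plant pixels: dark or desaturated
#' plant material is missed.
#'
#' @param img a [plot_image()].
#' @param hue_range length-2 numeric, degrees in `[0, 360)`.
#' @param min_s,min_v saturation/value floors on the `[0, 1]` scale.
#' @return Integer pixel count.
#' @export
green_count_strict <- function(img, hue_range = c(70, 170),
                               min_s = 0.25, min_v = 0.20) {
  hsv <- hsv_matrix(img)
  hue <- hsv[1, ] * 360
  sum(hue >= hue_range[1] & hue <= hue_range[2] &
        hsv[2, ] >= min_s & hsv[3, ] >= min_v)
}

#' Count green pixels by band ratio (broad)
#'
#' Counts pixels whose green band exceeds both the red and the blue band by
#' the factor `margin` (default 1.05), on the raw 8-bit intensities. This
#' broader rule captures essentially all plant pixels and some ambiguous
#' soil pixels, so it over-estimates plant cover relative to
#' [green_count_strict()].
#'
#' @param img a [plot_image()].
#' @param margin multiplicative margin of green over red and blue.
#' @return Integer pixel count.
#' @export
green_count_broad <- function(img, margin = 1.05) {
  m <- channel_matrix(img)
  sum(m[2, ] > margin * m[1, ] & m[2, ] > margin * m[3, ])
}

#' Visible-band vegetation index statistics
#'
#' Computes four per-pixel vegetation indices from the red, green and blue
#' intensities (cast to double before any arithmetic):
#' \deqn{RGBVI = (G^2 - R B) / (G^2 + R B)}
#' \deqn{GLI = (2G - R - B) / (2G + R + B)}
#' \deqn{VARI = (G - R) / (G + R - B)}
#' \deqn{NGRDI = (G - R) / (G + R)}
#' Pixels whose denominator magnitude is below `1e-9` are excluded from
#' aggregation (VARI's denominator in particular can vanish on real soil).
#' Returns the mean and population standard deviation of each index over
#' the included pixels, ordered (RGBVI, GLI, VARI, NGRDI) x (mean, sd). If
#' every pixel is excluded for an index, its statistics are 0 and a warning
#' is issued.
#'
#' @param img a [plot_image()].
#' @return Named numeric vector of length 8.
#' @export
vegetation_indices <- function(img) {
  m <- channel_matrix(img)
  R <- m[1, ]; G <- m[2, ]; B <- m[3, ]
  defs <- list(
    rgbvi = list(num = G * G - R * B, den = G * G + R * B),
    gli   = list(num = 2 * G - R - B, den = 2 * G + R + B),
    vari  = list(num = G - R,         den = G + R - B),
    ngrdi = list(num = G - R,         den = G + R))
  out <- numeric(0)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    keep <- abs(d$den) >= 1e-9
    if (!any(keep)) {
      warning("all pixels excluded for index ", nm, "; statistics set to 0")
      stats <- c(0, 0)
    } else {
      v <- d$num[keep] / d$den[keep]
      stats <- c(mean(v), sqrt(mean((v - mean(v))^2)))
    }
    out <- c(out, setNames(stats, paste0("vi_", nm, c("_mean", "_sd"))))
  }
  out
}

#' Names of the 542 features in schema order
#'
#' @return Character vector of length 542.
#' @export
feature_names <- function() {
  c(sprintf("hist_%03d", 0:511),
    sprintf("hu_%d", 1:7),
    paste0("har_", c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "diff_variance", "diff_entropy", "imc1", "imc2")),
    c("green_strict", "green_broad"),
    c("vi_rgbvi_mean", "vi_rgbvi_sd", "vi_gli_mean", "vi_gli_sd",
      "vi_vari_mean", "vi_vari_sd", "vi_ngrdi_mean", "vi_ngrdi_sd"))
}

#' Extract the full 542-entry feature vector of a plot image
#'
#' Concatenates, in fixed schema order: the 512-bin HSV colour histogram
#' (`hist_000` ... `hist_511`, 0-based flattened position), the 7
#' log-scaled Hu moments, the 13 Haralick texture statistics, the strict
#' and broad green-pixel counts, and the 8 vegetation-index statistics.
#' Extraction is pure and deterministic.
#'
#' @param img a [plot_image()].
#' @return Named numeric vector of length 542 with attribute
#'   `schema_version`.
#' @export
extract_features <- function(img) {
  v <- c(colour_histogram(img), hu_moments(img), haralick_features(img),
         green_count_strict(img), green_count_broad(img),
         vegetation_indices(img))
  names(v) <- feature_names()
  attr(v, "schema_version") <- feature_schema_version()
  v
}

feature_schema_version <- function() "rgbpheno-features-1"

#' Extract a feature matrix for a list of plot images
#'
#' @param plots list of [plot_image()]s.
#' @return Numeric matrix, one row per plot (rownames = plot ids), 542
#'   named columns, with attribute `schema_version`.
#' @export
extract_feature_matrix <- function(plots) {
  X <- t(vapply(plots, function(p) as.numeric(extract_features(p)),
                numeric(542L)))
  rownames(X) <- vapply(plots, function(p) p$plot_id, "")
  colnames(X) <- feature_names()
  attr(X, "schema_version") <- feature_schema_version()
  X
}

#' Write or read a feature matrix as CSV with a JSON schema sidecar
#'
#' The CSV has a `plot_id` column followed by the 542 named feature
#' columns; `<path>.schema.json` records the column names and schema
#' version so models can refuse mismatched inputs.
#'
#' @param X matrix from [extract_feature_matrix()].
#' @param path CSV output path.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(plot_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(schema_version = feature_schema_version(), columns = colnames(X)),
    paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$plot_id
  schema_path <- paste0(path, ".schema.json")
  if (file.exists(schema_path)) {
    sc <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    if (!identical(unname(sc$columns), colnames(X)))
      stop("feature matrix columns do not match schema sidecar")
    attr(X, "schema_version") <- sc$schema_version
  } else attr(X, "schema_version") <- feature_schema_version()
  X
}
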