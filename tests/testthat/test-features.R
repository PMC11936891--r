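test_that("colour histogram is an L1-normalised HSV point mass for flat images", {
  img <- flat_image(c(0, 255, 0))
  h <- colour_histogram(img)
  expect_length(h, 512L)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(sum(h == 0), 511L)
  expect_equal(max(h), 1)
  # pure green: hue 1/3 -> bin 2, s = v = 1 -> bin 7; hue-major flattening
  expect_equal(which(h == 1) - 1L, 2L * 64L + 7L * 8L + 7L)
})

test_that("two colours in a 3:1 pixel ratio land 0.75/0.25 in distinct bins", {
  px <- array(0L, c(8L, 8L, 3L))
  px[, , 1] <- 255L                      # red everywhere
  px[1:2, , ] <- 0L; px[1:2, , 3] <- 255L  # top quarter blue
  h <- colour_histogram(plot_image(px, "two"))
  expect_equal(sort(h[h > 0]), c(0.25, 0.75))
})

test_that("histogram normalisation holds on random images", {
  for (s in 1:20)
    expect_equal(sum(colour_histogram(random_image(s))), 1, tolerance = 1e-9)
})

test_that("Hu moments are invariant to translation and 90-degree rotation", {
  set.seed(8)
  obj <- matrix(runif(8 * 8, 50, 255), 8, 8)
  embed <- function(dr, dc) {
    px <- array(0L, c(32L, 32L, 3L))
    for (ch in 1:3) px[dr + 1:8, dc + 1:8, ch] <- as.integer(round(obj))
    plot_image(px, "emb")
  }
  h1 <- hu_moments(embed(3L, 4L))
  h2 <- hu_moments(embed(8L, 11L))  # translated by (5, 7)
  expect_equal(h1, h2, tolerance = 1e-6)

  img <- embed(3L, 4L)
  rot <- plot_image(aperm(img$pixels, c(2, 1, 3))[, dim(img$pixels)[1]:1, ,
                                                  drop = FALSE], "rot")
  expect_equal(hu_moments(img), hu_moments(rot), tolerance = 1e-4)
})

test_that("constant images take the degenerate all-zero Hu value", {
  expect_equal(hu_moments(flat_image(c(120, 120, 120))), rep(0, 7))
  expect_equal(hu_moments(flat_image(c(0, 0, 0))), rep(0, 7))
})

test_that("first Hu moment matches a brute-force pixel-sum oracle", {
  img <- random_image(15, h = 12L, w = 10L)
  g <- rgbpheno:::grayscale(img)
  # independent loop-based moment computation
  m <- function(p, q) {
    acc <- 0
    for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
      acc <- acc + (j - 1)^p * (i - 1)^q * g[i, j]
    acc
  }
  xb <- m(1, 0) / m(0, 0); yb <- m(0, 1) / m(0, 0)
  mu <- function(p, q) {
    acc <- 0
    for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
      acc <- acc + (j - 1 - xb)^p * (i - 1 - yb)^q * g[i, j]
    acc
  }
  eta <- function(p, q) mu(p, q) / m(0, 0)^(1 + (p + q) / 2)
  hu1 <- eta(2, 0) + eta(0, 2)
  expect_equal(hu_moments(img)[1], sign(hu1) * log10(abs(hu1) + 1e-30),
               tolerance = 1e-12)
})

test_that("GLCMs are symmetric, normalised, and flat images have zero contrast", {
  img <- random_image(3)
  lv <- matrix(pmin(floor(rgbpheno:::grayscale(img) * 32 / 256), 31L), 16, 16)
  storage.mode(lv) <- "integer"
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    P <- rgbpheno:::glcm_offset(lv, o[1], o[2], 32L)
    expect_equal(P, t(P))
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
  feats <- haralick_features(flat_image(c(80, 80, 80)))
  expect_equal(unname(feats["contrast"]), 0)
  one_row <- structure(list(plot_id = "row", source = "synthetic",
                            pixels = array(0L, c(1L, 8L, 3L))),
                       class = "plot_image")
  expect_error(haralick_features(one_row), "2 x 2")
})

test_that("checkerboard Haralick features match a hand-enumerated GLCM oracle", {
  # 4x4 two-level checkerboard: dark (level 0) and bright (level 25)
  px <- array(0L, c(4L, 4L, 3L))
  bright <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  for (ch in 1:3) { sl <- px[, , ch]; sl[bright] <- 200L; px[, , ch] <- sl }
  img <- structure(list(plot_id = "cb", pixels = px, source = "synthetic"),
                   class = "plot_image")
  lv <- matrix(pmin(floor(rgbpheno:::grayscale(img) * 32 / 256), 31L), 4, 4)
  storage.mode(lv) <- "integer"

  # oracle: enumerate all neighbour pairs for one offset by explicit loops
  oracle_glcm <- function(drow, dcol) {
    counts <- matrix(0, 32, 32)
    for (i in 1:4) for (j in 1:4) {
      i2 <- i + drow; j2 <- j + dcol
      if (i2 >= 1 && i2 <= 4 && j2 >= 1 && j2 <= 4) {
        a <- lv[i, j] + 1L; b <- lv[i2, j2] + 1L
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
    counts / sum(counts)
  }
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)))
    expect_equal(rgbpheno:::glcm_offset(lv, o[1], o[2], 32L),
                 oracle_glcm(o[1], o[2]), tolerance = 1e-12)

  # horizontal/vertical neighbours always differ; diagonal neighbours never:
  # the hand-derived per-offset contrasts are d^2 = (25-0)^2, and 0
  f_h <- rgbpheno:::haralick_from_glcm(oracle_glcm(0L, 1L))
  expect_equal(unname(f_h["contrast"]), 625)
  expect_equal(unname(f_h["asm"]), 0.5)  # two cells of probability 1/2
  expect_equal(unname(f_h["entropy"]), log(2))
  f_d <- rgbpheno:::haralick_from_glcm(oracle_glcm(1L, 1L))
  expect_equal(unname(f_d["contrast"]), 0)
  # the exported value averages the four offsets
  got <- haralick_features(img)
  expect_equal(unname(got["contrast"]), mean(c(625, 625, 0, 0)))
})

test_that("strict green counter applies its HSV box", {
  expect_equal(green_count_strict(flat_image(c(0, 255, 0))), 256L)
  expect_equal(green_count_strict(flat_image(c(77, 77, 77))), 0L)  # achromatic
  # half plant-green, half soil-brown fixture
  px <- array(0L, c(16L, 16L, 3L))
  for (ch in 1:3) {
    px[1:8, , ch] <- c(60L, 160L, 60L)[ch]    # green half
    px[9:16, , ch] <- c(125L, 92L, 66L)[ch]   # soil half
  }
  expect_equal(green_count_strict(plot_image(px, "hh")), 128L)
})

test_that("broad green counter applies its band-ratio rule", {
  px <- array(0L, c(8L, 8L, 3L))
  px[, , 1] <- 100L; px[, , 2] <- 120L; px[, , 3] <- 90L
  expect_equal(green_count_broad(plot_image(px, "r")), 64L)  # 120 > 105, 94.5
  expect_equal(green_count_broad(flat_image(c(50, 50, 50))), 0L)
})

test_that("broad counter dominates strict counter on generator fixtures", {
  fx <- small_field()
  X <- fx$features
  expect_gte(nrow(X), 100L)
  expect_true(all(X[, "green_broad"] >= X[, "green_strict"]))
  # and the strict counter under-estimates true plant cover on average
  expect_lt(mean(X[, "green_strict"]), mean(fx$field$truth$true_area_px))
})

test_that("vegetation indices match their closed forms and a per-pixel oracle", {
  grey <- vegetation_indices(flat_image(c(90, 90, 90)))
  expect_equal(unname(grey), rep(0, 8))
  green <- vegetation_indices(flat_image(c(0, 255, 0)))
  expect_equal(unname(green[c(1, 3, 5, 7)]), rep(1, 4))  # all four means
  expect_equal(unname(green[c(2, 4, 6, 8)]), rep(0, 4))  # zero spread

  img <- random_image(21)
  got <- vegetation_indices(img)
  # brute-force per-pixel loop oracle
  acc <- list(rgbvi = c(), gli = c(), vari = c(), ngrdi = c())
  for (i in 1:16) for (j in 1:16) {
    R <- as.double(img$pixels[i, j, 1]); G <- as.double(img$pixels[i, j, 2])
    B <- as.double(img$pixels[i, j, 3])
    vals <- list(rgbvi = c(G * G - R * B, G * G + R * B),
                 gli = c(2 * G - R - B, 2 * G + R + B),
                 vari = c(G - R, G + R - B),
                 ngrdi = c(G - R, G + R))
    for (nm in names(vals))
      if (abs(vals[[nm]][2]) >= 1e-9)
        acc[[nm]] <- c(acc[[nm]], vals[[nm]][1] / vals[[nm]][2])
  }
  for (nm in names(acc)) {
    expect_equal(unname(got[paste0("vi_", nm, "_mean")]), mean(acc[[nm]]),
                 tolerance = 1e-12)
    expect_equal(unname(got[paste0("vi_", nm, "_sd")]),
                 sqrt(mean((acc[[nm]] - mean(acc[[nm]]))^2)),
                 tolerance = 1e-12)
  }
})

test_that("an index with every pixel excluded reports zeros with a warning", {
  w <- capture_warnings(v <- vegetation_indices(flat_image(c(0, 0, 0))))
  expect_length(w, 4L)  # all four denominators vanish on pure black
  expect_match(w, "excluded", all = TRUE)
  expect_equal(unname(v), rep(0, 8))
})

test_that("the assembled feature vector follows the 542-entry schema", {
  img <- random_image(30)
  v <- extract_features(img)
  expect_length(v, 542L)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_identical(v, extract_features(img))  # purity
  # named entries address the component outputs (0-based histogram index)
  expect_equal(unname(v["hist_004"]), colour_histogram(img)[5])
  expect_equal(unname(v["green_strict"]),
               as.numeric(green_count_strict(img)))
  expect_equal(unname(v["vi_vari_mean"]),
               unname(vegetation_indices(img)["vi_vari_mean"]))
})

test_that("feature matrices round-trip with their schema sidecar", {
  fx <- small_field()
  X <- fx$features[1:5, ]
  attr(X, "schema_version") <- rgbpheno:::feature_schema_version()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(X, path)
  back <- read_feature_matrix(path)
  expect_equal(colnames(back), colnames(X))
  expect_equal(unname(back), unname(X), tolerance = 1e-9)
})

test_that("strict green count tracks yield on noise-free linear fields", {
  fx <- linear_field()
  expect_gte(nrow(fx$features), 150L)
  rho <- cor(fx$features[, "green_strict"], fx$field$truth$dmy_g)
  expect_gt(rho, 0.95)
})
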