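#' Construct a per-plant plot image
#'
#' A `plot_image` is one per-plant clip of an RGB orthoimage: an H x W x 3
#' array of 8-bit channel intensities (0-255, RGB order, top-left origin,
#' row-major), together with a plot identifier and a provenance string.
#'
#' @param pixels numeric or integer array with `dim = c(H, W, 3)`, values in
#'   0-255. H and W must both be at least 8.
#' @param plot_id character scalar identifying the plot.
#' @param source provenance: a file path or `"synthetic"`.
#' @return An object of class `plot_image`.
#' @export
plot_image <- function(pixels, plot_id, source = "synthetic") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    stop("plot image must be at least 8 x 8 pixels, got ", d[1], " x ", d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(
    list(plot_id = as.character(plot_id), pixels = pixels,
         source = as.character(source)),
    class = "plot_image"
  )
}

#' @export
print.plot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plot_image %s: %d x %d px, source: %s>\n",
              x$plot_id, d[1], d[2], x$source))
  invisible(x)
}

#' @export
dim.plot_image <- function(x) dim(x$pixels)

# Flatten an image to a 3 x n matrix of channels (doubles), pixels in
# column-major order of the underlying array. Internal.
channel_matrix <- function(img) {
  px <- img$pixels
  n <- prod(dim(px)[1:2])
  rbind(R = as.double(px[, , 1]), G = as.double(px[, , 2]),
        B = as.double(px[, , 3]))
}

# HSV values of every pixel: 3 x n matrix with rows h, s, v, all in [0, 1]
# (h is degrees / 360). Internal.
hsv_matrix <- function(img) {
  m <- channel_matrix(img)
  grDevices::rgb2hsv(m, maxColorValue = 255)
}

# Standard luminance grayscale (Rec. 601 weights), H x W matrix of doubles
# in [0, 255]. Internal.
grayscale <- function(img) {
  px <- img$pixels
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}
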