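#' Describe the plot grid of an orthoimage
#'
#' A field layout places a regular grid of per-plant plots on an orthoimage.
#' All pixel coordinates are 0-based; a plot occupies the half-open interval
#' `[origin, origin + size)` in each axis. An optional `offsets` table shifts
#' individual plots from their grid position, a deterministic substitute for
#' manually re-centring clips around each plant.
#'
#' @param origin_px integer pair `(row, col)`: top-left corner of plot (0, 0).
#' @param n_rows,n_cols positive integers: grid dimensions.
#' @param plot_stride_px integer pair: pixel spacing between plot origins
#'   (row, col). Must be at least `plot_size_px` componentwise so plots
#'   cannot overlap.
#' @param plot_size_px integer pair `(height, width)` of every plot.
#' @param offsets optional data frame with columns `row`, `col`, `drow`,
#'   `dcol` giving per-plot pixel shifts.
#' @return An object of class `field_layout`.
#' @export
field_layout <- function(origin_px = c(0L, 0L), n_rows, n_cols,
                         plot_stride_px, plot_size_px, offsets = NULL) {
  origin_px <- as.integer(origin_px)
  plot_stride_px <- as.integer(rep_len(plot_stride_px, 2L))
  plot_size_px <- as.integer(rep_len(plot_size_px, 2L))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(length(origin_px) == 2L, n_rows >= 1L, n_cols >= 1L)
  if (any(plot_size_px < 1L)) stop("plot size must be positive")
  if (any(plot_stride_px < plot_size_px))
    stop("plot stride must be >= plot size in both axes")
  if (!is.null(offsets)) {
    need <- c("row", "col", "drow", "dcol")
    if (!all(need %in% names(offsets)))
      stop("offsets must have columns row, col, drow, dcol")
  }
  structure(list(origin_px = origin_px, n_rows = n_rows, n_cols = n_cols,
                 plot_stride_px = plot_stride_px, plot_size_px = plot_size_px,
                 offsets = offsets),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("<field_layout: %d x %d plots of %d x %d px, stride (%d, %d), origin (%d, %d)>\n",
              x$n_rows, x$n_cols, x$plot_size_px[1], x$plot_size_px[2],
              x$plot_stride_px[1], x$plot_stride_px[2],
              x$origin_px[1], x$origin_px[2]))
  invisible(x)
}

plot_id_for <- function(row, col) sprintf("r%d_c%d", row, col)

# Top-left (row, col) of one plot, 0-based, including any per-plot offset.
plot_origin <- function(layout, row, col) {
  o <- layout$origin_px + c(row, col) * layout$plot_stride_px
  off <- layout$offsets
  if (!is.null(off)) {
    i <- which(off$row == row & off$col == col)
    if (length(i) == 1L) o <- o + c(off$drow[i], off$dcol[i])
  }
  as.integer(o)
}

#' Clip an orthoimage into per-plant plot images
#'
#' Cuts the layout's regular grid out of the raster. Plot ids are assigned
#' row-major as `r{row}_c{col}` with 0-based row and column indices. Clipping
#' is a pure function of the raster and layout: repeated calls return
#' identical results.
#'
#' @param orthoimage H x W x 3 array of 8-bit RGB intensities.
#' @param layout a [field_layout()].
#' @param source provenance string recorded on each clip.
#' @return List of [plot_image()] objects, row-major order.
#' @export
clip_plots <- function(orthoimage, layout, source = "synthetic") {
  stopifnot(inherits(layout, "field_layout"))
  if (length(dim(orthoimage)) != 3L || dim(orthoimage)[3] != 3L)
    stop("orthoimage must be an H x W x 3 array")
  rd <- dim(orthoimage)
  sz <- layout$plot_size_px
  plots <- vector("list", layout$n_rows * layout$n_cols)
  k <- 0L
  for (r in seq_len(layout$n_rows) - 1L) {
    for (cc in seq_len(layout$n_cols) - 1L) {
      o <- plot_origin(layout, r, cc)
      if (o[1] < 0L || o[2] < 0L ||
          o[1] + sz[1] > rd[1] || o[2] + sz[2] > rd[2])
        stop(sprintf(
          "plot (row %d, col %d) at origin (%d, %d) exceeds raster bounds %d x %d",
          r, cc, o[1], o[2], rd[1], rd[2]))
      k <- k + 1L
      plots[[k]] <- plot_image(
        orthoimage[(o[1] + 1L):(o[1] + sz[1]), (o[2] + 1L):(o[2] + sz[2]), ,
                   drop = FALSE],
        plot_id = plot_id_for(r, cc), source = source)
    }
  }
  plots
}

#' Read or write an orthoimage raster
#'
#' PNG and (Geo)TIFF are supported, chosen by file extension. Pixels are
#' returned as an H x W x 3 integer array of 8-bit intensities; alpha
#' channels are dropped. No coordinate reference system is read or written.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_orthoimage`: H x W x 3 integer array.
#' @export
read_orthoimage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  a <- array(as.integer(round(x * 255)), dim(x))
  a
}

#' @rdname read_orthoimage
#' @param orthoimage H x W x 3 array, 0-255.
#' @export
write_orthoimage <- function(orthoimage, path) {
  ext <- tolower(tools::file_ext(path))
  x <- orthoimage / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported raster format: .", ext))
  invisible(path)
}

#' Write plot clips as PNG files
#'
#' Each clip is written to `dir/{plot_id}.png`.
#'
#' @param plots list of [plot_image()]s.
#' @param dir output directory, created if absent.
#' @return Invisibly, the written paths.
#' @export
write_clips <- function(plots, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(plots, function(p) {
    path <- file.path(dir, paste0(p$plot_id, ".png"))
    png::writePNG(p$pixels / 255, path)
    path
  }, "")
  invisible(paths)
}

#' Read plot clips from a directory of PNG files
#'
#' @param dir directory containing `{plot_id}.png` files.
#' @return List of [plot_image()]s, sorted by file name.
#' @export
read_clips <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    plot_image(read_orthoimage(f),
               plot_id = tools::file_path_sans_ext(basename(f)), source = f)
  })
}

#' Read and write plot phenotype tables
#'
#' The on-disk format is a CSV with at least the columns `plot_id`, `dmy_g`
#' (dry matter yield in grams, non-negative) and `breeder_score` (integer
#' 0-5). Any further columns (e.g. `row`, `col`, `true_area_px`,
#' `score_class`, `top_label`) are carried through unchanged, so the
#' generator's ground-truth table is read with the same function. A zero
#' yield is accepted: a harvest can be empty.
#'
#' @param path CSV file path.
#' @return `read_plot_table`: a data frame of validated phenotype records.
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plot_table(df)
}

#' @rdname read_plot_table
#' @param records data frame with the required columns.
#' @export
write_plot_table <- function(records, path) {
  validate_plot_table(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_plot_table <- function(df) {
  need <- c("plot_id", "dmy_g", "breeder_score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("plot table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df$plot_id <- as.character(df$plot_id)
  df$dmy_g <- as.numeric(df$dmy_g)
  df$breeder_score <- as.integer(df$breeder_score)
  bad <- which(is.na(df$dmy_g) | df$dmy_g < 0)
  if (length(bad))
    stop("negative or missing dmy_g in row(s): ", paste(head(bad, 5), collapse = ", "))
  bad <- which(is.na(df$breeder_score) | df$breeder_score < 0L | df$breeder_score > 5L)
  if (length(bad))
    stop("breeder_score outside 0-5 in row(s): ", paste(head(bad, 5), collapse = ", "))
  df
}

#' Read or write a field layout file
#'
#' Layouts are stored as YAML (or JSON, which YAML subsumes) with keys
#' matching the arguments of [field_layout()].
#'
#' @param path YAML file path.
#' @return `read_layout`: a [field_layout()].
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  off <- if (!is.null(y$offsets)) as.data.frame(do.call(rbind, lapply(y$offsets, as.data.frame)))
  field_layout(origin_px = unlist(y$origin_px), n_rows = y$n_rows,
               n_cols = y$n_cols, plot_stride_px = unlist(y$plot_stride_px),
               plot_size_px = unlist(y$plot_size_px), offsets = off)
}

#' @rdname read_layout
#' @param layout a [field_layout()].
#' @export
write_layout <- function(layout, path) {
  y <- list(origin_px = layout$origin_px, n_rows = layout$n_rows,
            n_cols = layout$n_cols, plot_stride_px = layout$plot_stride_px,
            plot_size_px = layout$plot_size_px)
  if (!is.null(layout$offsets))
    y$offsets <- lapply(seq_len(nrow(layout$offsets)),
                        function(i) as.list(layout$offsets[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
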