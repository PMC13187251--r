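#' Construct a slide image
#'
#' In-memory representation of one section image: an RGB raster with a
#' physical pixel spacing and a resolution ladder. Level 0 is the
#' canonical frame; all transforms are stored in level-0 pixel units.
#' Coordinates are 0-based pixel centers, x = column, y = row.
#'
#' @param pixels numeric array `H x W x 3`, values in `[0, 1]`.
#' @param spacing physical pixel spacing at level 0, micrometres/pixel.
#' @param id slide identifier string.
#' @param z_index integer position in the stack.
#' @param levels optional list of additional pyramid level rasters
#'   (level 0 is `pixels`); each must be a strictly smaller raster.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, spacing, id = "slide", z_index = NA_integer_,
                        levels = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop(errorCondition("spacing must be a positive real (um/pixel)",
                        class = c("histostack_config_error", "error")))
  }
  rasters <- c(list(pixels), levels)
  ladder <- data.frame(
    downsample = vapply(rasters, function(r) dim(pixels)[2] / dim(r)[2], 0),
    width = vapply(rasters, function(r) dim(r)[2], 0L),
    height = vapply(rasters, function(r) dim(r)[1], 0L))
  if (any(ladder$width < 1) || any(ladder$height < 1) ||
      any(diff(ladder$downsample) <= 0) || ladder$downsample[1] != 1) {
    stop(errorCondition("pyramid level ladder must start at downsample 1 and be strictly increasing",
                        class = c("histostack_config_error", "error")))
  }
  structure(list(rasters = rasters, ladder = ladder, spacing = spacing,
                 id = as.character(id), z_index = z_index),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> '%s' %dx%d px @ %g um/px, %d level(s)\n",
              x$id, x$ladder$width[1], x$ladder$height[1], x$spacing,
              nrow(x$ladder)))
  invisible(x)
}

#' Pixel raster of a slide at a pyramid level
#'
#' @param slide a [slide_image()].
#' @param level 1-based level index (1 = level 0 / full resolution).
#' @return Numeric `H x W x 3` array.
#' @export
slide_pixels <- function(slide, level = 1L) {
  stopifnot(inherits(slide, "slide_image"), level >= 1, level <= nrow(slide$ladder))
  slide$rasters[[level]]
}

#' Construct an ordered slide stack
#'
#' @param slides list of [slide_image()] objects in stack order; `z_index`
#'   is (re)assigned from list order (gap-free, strictly increasing).
#' @param slice_interval physical distance between adjacent sections,
#'   micrometres (> 0).
#' @return An object of class `slide_stack` with `k = length(slides)`.
#' @export
slide_stack <- function(slides, slice_interval) {
  if (length(slides) < 2) {
    stop(errorCondition("a stack needs at least 2 slides",
                        class = c("histostack_config_error", "error")))
  }
  stopifnot(all(vapply(slides, inherits, TRUE, "slide_image")),
            is.numeric(slice_interval), slice_interval > 0)
  for (i in seq_along(slides)) slides[[i]]$z_index <- i - 1L
  structure(list(slides = slides, slice_interval = slice_interval,
                 k = length(slides)),
            class = "slide_stack")
}

#' @export
print.slide_stack <- function(x, ...) {
  cat(sprintf("<slide_stack> k=%d slides, interval %g um\n", x$k,
              x$slice_interval))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a section image from disk
#'
#' Reads a plain PNG/TIFF or a multi-page pyramidal TIFF written by
#' [write_slide()]. The physical spacing comes from the JSON sidecar when
#' present, else from the `spacing` argument.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param spacing level-0 spacing in micrometres/pixel; required for plain
#'   images without a sidecar.
#' @param id slide identifier (default: file name without extension).
#' @return A [slide_image()].
#' @export
read_slide <- function(path, spacing = NULL, id = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("file not found: ", path),
                        class = c("histostack_io_error", "error")))
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  pages <- tryCatch({
    if (ext == "png") list(png::readPNG(path))
    else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path, all = TRUE)
    else stop("unsupported raster format: ", ext)
  }, error = function(e) {
    stop(errorCondition(paste0("unreadable image '", path, "': ",
                               conditionMessage(e)),
                        class = c("histostack_io_error", "error")))
  })
  pages <- lapply(pages, ensure_rgb)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else NULL
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing)) {
    stop(errorCondition(
      paste0("no spacing declared for plain image '", path,
             "' and no sidecar present"),
      class = c("histostack_config_error", "error")))
  }
  areas <- vapply(pages, function(p) prod(dim(p)[1:2]), 0)
  pages <- pages[order(areas, decreasing = TRUE)]
  slide_image(pages[[1]], spacing = spacing, id = id,
              levels = if (length(pages) > 1) pages[-1] else NULL)
}

ensure_rgb <- function(p) {
  if (length(dim(p)) == 3 && dim(p)[3] >= 3) p[, , 1:3, drop = FALSE]
  else p  # grayscale kept 2-D; load_stack rejects it with a named error
}

#' Write a section image as a pyramidal TIFF
#'
#' Writes a multi-page TIFF (page n = pyramid level n, factor-2 ladder)
#' with lossless deflate compression by default, plus a JSON sidecar with
#' the spacing and level ladder. Input may be a full raster or a tile
#' stream; tiles are flushed into the output canvas as they arrive, and
#' the maximum number of simultaneously live (unflushed) tiles is tracked
#' and reported. Rasters are quantized to 8 bits (`round(x * 255) / 255`)
#' so that a read-back is bit-exact.
#'
#' @param image `H x W x 3` array, or a list of tiles
#'   `list(tile =, x0 =, y0 =)` (0-based origins) covering the output
#'   exactly once, or a generator `function()` yielding such tiles then
#'   `NULL`.
#' @param path output file path (`.tif`).
#' @param spacing level-0 spacing, micrometres/pixel.
#' @param out_shape `c(width, height)`; required for tile input.
#' @param n_levels number of pyramid levels (default: halve until the
#'   short side would drop below 64, at least 1).
#' @param compression TIFF codec; `"deflate"` (lossless, default) or
#'   `"JPEG"`.
#' @param tiled kept for interface compatibility; the container is always
#'   written page-per-level (the streaming layer, not the codec layout,
#'   bounds memory).
#' @return `path`, invisibly, with attribute `max_live_tiles`.
#' @export
write_slide <- function(image, path, spacing, out_shape = NULL,
                        n_levels = NULL, compression = "deflate", tiled = TRUE) {
  if (is.array(image) && length(dim(image)) == 3) {
    canvas <- image
    max_live <- 1L
  } else {
    stopifnot(!is.null(out_shape))
    W <- out_shape[1]; H <- out_shape[2]
    canvas <- array(0, c(H, W, 3))
    covered <- matrix(FALSE, H, W)
    max_live <- 0L
    nxt <- if (is.function(image)) image else local({
      i <- 0L; tiles <- image
      function() { i <<- i + 1L; if (i > length(tiles)) NULL else tiles[[i]] }
    })
    repeat {
      tl <- nxt()
      if (is.null(tl)) break
      max_live <- max(max_live, 1L)  # each tile is flushed before the next is drawn
      th <- dim(tl$tile)[1]; tw <- dim(tl$tile)[2]
      ry <- tl$y0 + seq_len(th); rx <- tl$x0 + seq_len(tw)
      if (any(ry > H) || any(rx > W) || any(covered[ry, rx])) {
        stop(errorCondition("tile stream overlaps or exceeds the output extent",
                            class = c("histostack_io_error", "error")))
      }
      covered[ry, rx] <- TRUE
      tlt <- tl$tile
      if (length(dim(tlt)) == 2) tlt <- array(tlt, c(dim(tlt), 3))
      canvas[ry, rx, ] <- tlt
    }
    if (!all(covered)) {
      stop(errorCondition("tile stream did not cover the full output extent",
                          class = c("histostack_io_error", "error")))
    }
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  canvas <- round(canvas * 255) / 255
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  if (is.null(n_levels)) {
    n_levels <- max(1L, 1L + floor(log2(min(W, H) / 64)))
  }
  pages <- vector("list", n_levels)
  pages[[1]] <- canvas
  for (l in seq_len(n_levels - 1L)) {
    r <- resample_image(pages[[l]], 0.5)
    pages[[l + 1L]] <- round(pmin(pmax(r, 0), 1) * 255) / 255
  }
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = compression)
    TRUE
  }, error = function(e) {
    stop(errorCondition(paste0("cannot write '", path, "': ",
                               conditionMessage(e)),
                        class = c("histostack_io_error", "error")))
  })
  ladder <- data.frame(
    downsample = vapply(pages, function(p) W / dim(p)[2], 0),
    width = vapply(pages, function(p) dim(p)[2], 0L),
    height = vapply(pages, function(p) dim(p)[1], 0L))
  jsonlite::write_json(list(spacing = spacing, levels = ladder),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(structure(path, max_live_tiles = max_live))
}

#' Load an ordered stack of section images
#'
#' @param paths ordered character vector of >= 2 image paths (stack order
#'   = list order).
#' @param slice_interval physical distance between adjacent sections,
#'   micrometres.
#' @param spacing spacing(s) in micrometres/pixel for plain images
#'   (recycled); ignored where sidecars exist.
#' @return A [slide_stack()].
#' @export
load_stack <- function(paths, slice_interval, spacing = NULL) {
  if (length(paths) < 2) {
    stop(errorCondition("a stack needs at least 2 slides",
                        class = c("histostack_config_error", "error")))
  }
  spacing <- if (is.null(spacing)) vector("list", length(paths))
             else as.list(rep_len(spacing, length(paths)))
  slides <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    ext <- tolower(sub(".*\\.", "", paths[i]))
    pg <- tryCatch({
      if (ext == "png") list(png::readPNG(paths[i]))
      else tiff::readTIFF(paths[i], all = TRUE)
    }, error = function(e) {
      stop(errorCondition(paste0("unreadable image '", paths[i], "': ",
                                 conditionMessage(e)),
                          class = c("histostack_io_error", "error")))
    })
    if (length(dim(pg[[1]])) != 3 || dim(pg[[1]])[3] < 3) {
      stop(errorCondition(
        paste0("slide '", basename(paths[i]),
               "' is not RGB; all slides must share the RGB color model"),
        class = c("histostack_config_error", "error")))
    }
    slides[[i]] <- read_slide(paths[i], spacing = spacing[[i]])
  }
  slide_stack(slides, slice_interval)
}

#' Read a landmark table
#'
#' Landmark CSVs have columns `slide_id, x, y` with coordinates in level-0
#' pixels.
#'
#' @param path CSV file.
#' @return `data.frame` with columns `slide_id`, `x`, `y`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop(errorCondition("landmark CSV must have columns slide_id, x, y",
                        class = c("histostack_config_error", "error")))
  }
  df[need]
}

#' Write a landmark table
#'
#' @param landmarks `data.frame` with columns `slide_id`, `x`, `y`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks[c("slide_id", "x", "y")], path, row.names = FALSE)
  invisible(path)
}
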