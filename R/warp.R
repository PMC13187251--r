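#' Composite transform: rigid pose plus optional deformable refinement
#'
#' Bundles the rigid slide-to-reference pose with an optional
#' thin-plate-spline refinement for application by [warp_image()] /
#' [warp_tiled()]. Backward (pull) semantics: for an output pixel `p` the
#' sampled source location is `R^{-1}(p) + field(p)`.
#'
#' @param rigid a [rigid_transform()].
#' @param field optional `deformation_field` (backward displacements in
#'   the output frame).
#' @return An object of class `composite_transform`.
#' @export
composite_transform <- function(rigid, field = NULL) {
  stopifnot(is_rigid_transform(rigid),
            is.null(field) || inherits(field, "deformation_field"))
  structure(list(rigid = rigid, field = field), class = "composite_transform")
}

as_composite <- function(t) {
  if (inherits(t, "composite_transform")) t
  else if (is_rigid_transform(t)) composite_transform(t)
  else stop("expected a rigid_transform or composite_transform")
}

#' Backward coordinate map for a tile of the output frame
#'
#' For every output pixel of the requested tile, computes the source
#' coordinate to sample. Each pixel depends only on its own absolute
#' output coordinates, so the map restricted to a tile equals the global
#' map on that tile — tiles can be processed independently without
#' boundary artifacts, and tiled warps are bit-identical to monolithic
#' ones.
#'
#' @param t a [rigid_transform()] or [composite_transform()].
#' @param out_shape `c(width, height)` of the full output frame.
#' @param tile `c(x0, y0, w, h)` (0-based) region to compute; default the
#'   full frame.
#' @return A list with matrices `sx`, `sy` (h x w, source coordinates,
#'   0-based pixel centers) and the tile origin.
#' @export
build_backward_map <- function(t, out_shape, tile = c(0, 0, out_shape)) {
  t <- as_composite(t)
  stopifnot(length(out_shape) == 2, length(tile) == 4,
            tile[1] >= 0, tile[2] >= 0, tile[3] >= 1, tile[4] >= 1,
            tile[1] + tile[3] <= out_shape[1], tile[2] + tile[4] <= out_shape[2])
  w <- tile[3]; h <- tile[4]
  xs <- tile[1] + seq_len(w) - 1   # absolute output x (0-based)
  ys <- tile[2] + seq_len(h) - 1
  px <- matrix(rep(xs, each = h), h, w)
  py <- matrix(rep(ys, times = w), h, w)
  Minv <- solve(rigid_matrix(t$rigid))
  sx <- Minv[1, 1] * px + Minv[1, 2] * py + Minv[1, 3]
  sy <- Minv[2, 1] * px + Minv[2, 2] * py + Minv[2, 3]
  if (!is.null(t$field)) {
    d <- eval_deformation(t$field, cbind(as.vector(px), as.vector(py)))
    sx <- sx + matrix(d[, 1], h, w)
    sy <- sy + matrix(d[, 2], h, w)
  }
  list(sx = sx, sy = sy, x0 = tile[1], y0 = tile[2])
}

# Sample an image (H x W or H x W x C numeric array, values arbitrary) at
# real-valued 0-based coordinates. Out-of-source samples get `fill`
# (recycled per channel). Bilinear uses a fixed evaluation order so
# results are bit-stable across tilings.
sample_image <- function(img, sx, sy, interpolation = c("bilinear", "nearest"),
                         fill = 1) {
  interpolation <- match.arg(interpolation)
  dm <- dim(img)
  H <- dm[1]; W <- dm[2]
  nc <- if (length(dm) == 3) dm[3] else 1L
  fill <- rep_len(fill, nc)
  outside <- sx < 0 | sx > W - 1 | sy < 0 | sy > H - 1 | !is.finite(sx) | !is.finite(sy)
  out <- array(0, c(nrow(sx), ncol(sx), nc))
  if (interpolation == "nearest") {
    xi <- pmin(pmax(floor(sx + 0.5), 0), W - 1)
    yi <- pmin(pmax(floor(sy + 0.5), 0), H - 1)
    idx <- as.vector(yi) + 1 + as.vector(xi) * H  # linear index into H x W plane
    for (c in seq_len(nc)) {
      plane <- if (nc == 1L && length(dm) == 2) img else img[, , c]
      v <- plane[idx]
      v[as.vector(outside)] <- fill[c]
      out[, , c] <- v
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    x0c <- pmin(pmax(x0, 0), W - 1); x1c <- pmin(x0c + 1, W - 1)
    y0c <- pmin(pmax(y0, 0), H - 1); y1c <- pmin(y0c + 1, H - 1)
    i00 <- as.vector(y0c) + 1 + as.vector(x0c) * H
    i10 <- as.vector(y0c) + 1 + as.vector(x1c) * H
    i01 <- as.vector(y1c) + 1 + as.vector(x0c) * H
    i11 <- as.vector(y1c) + 1 + as.vector(x1c) * H
    wfx <- as.vector(fx); wfy <- as.vector(fy)
    for (c in seq_len(nc)) {
      plane <- if (nc == 1L && length(dm) == 2) img else img[, , c]
      v <- (plane[i00] * (1 - wfx) + plane[i10] * wfx) * (1 - wfy) +
           (plane[i01] * (1 - wfx) + plane[i11] * wfx) * wfy
      v[as.vector(outside)] <- fill[c]
      out[, , c] <- v
    }
  }
  if (nc == 1L && length(dm) == 2) out[, , 1] else out
}

#' Warp an image monolithically
#'
#' Applies a rigid (or rigid-plus-deformable) transform with backward
#' mapping. The transform maps source coordinates to output coordinates;
#' sampling uses its inverse.
#'
#' @param img numeric array `H x W` or `H x W x C` (values in `[0, 1]` by
#'   convention, not enforced).
#' @param t a [rigid_transform()] or [composite_transform()].
#' @param out_shape `c(width, height)` of the output; defaults to input.
#' @param interpolation `"bilinear"` (images) or `"nearest"` (masks).
#' @param fill background value(s) for samples outside the source.
#' @return Warped array with `out_shape` extent.
#' @export
warp_image <- function(img, t, out_shape = c(dim(img)[2], dim(img)[1]),
                       interpolation = c("bilinear", "nearest"), fill = 1) {
  interpolation <- match.arg(interpolation)
  bm <- build_backward_map(t, out_shape)
  sample_image(img, bm$sx, bm$sy, interpolation, fill)
}

#' Warp an image tile-by-tile, streaming output tiles
#'
#' Divides the output frame into `tile_size` tiles (row-major), computes
#' each tile's backward map independently, and either streams the tiles
#' into `sink(tile, x0, y0)` or assembles them. Because every output pixel
#' is computed from its absolute coordinates, the concatenated result is
#' pixel-identical to [warp_image()]; peak live pixels are
#' O(`tile_size`^2) in the streaming layer.
#'
#' @inheritParams warp_image
#' @param tile_size tile side in pixels (>= 16).
#' @param sink optional `function(tile, x0, y0)` consuming tiles (0-based
#'   origin); when `NULL` the tiles are assembled and returned.
#' @return The assembled image (invisibly when `sink` is given, with the
#'   number of tiles streamed in attribute `tiles`).
#' @export
warp_tiled <- function(img, t, tile_size = 512,
                       out_shape = c(dim(img)[2], dim(img)[1]),
                       interpolation = c("bilinear", "nearest"), fill = 1,
                       sink = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(tile_size >= 16)
  W <- out_shape[1]; H <- out_shape[2]
  assemble <- is.null(sink)
  out <- if (assemble) {
    if (length(dim(img)) == 3) array(0, c(H, W, dim(img)[3])) else matrix(0, H, W)
  } else NULL
  ntiles <- 0L
  for (y0 in seq(0, H - 1, by = tile_size)) {
    th <- min(tile_size, H - y0)
    for (x0 in seq(0, W - 1, by = tile_size)) {
      tw <- min(tile_size, W - x0)
      bm <- build_backward_map(t, out_shape, tile = c(x0, y0, tw, th))
      tl <- sample_image(img, bm$sx, bm$sy, interpolation, fill)
      ntiles <- ntiles + 1L
      if (assemble) {
        if (length(dim(img)) == 3) out[y0 + seq_len(th), x0 + seq_len(tw), ] <- tl
        else out[y0 + seq_len(th), x0 + seq_len(tw)] <- tl
      } else sink(tl, x0, y0)
    }
  }
  if (assemble) { attr(out, "tiles") <- ntiles; out }
  else invisible(structure(list(tiles = ntiles), class = "warp_stream_summary"))
}

#' Resample an image by a scale factor
#'
#' Integer downscaling uses exact block averaging (anti-aliased); any
#' other factor uses bilinear sampling with pixel-center alignment.
#'
#' @param img numeric array `H x W` or `H x W x C`.
#' @param factor output/input size ratio (e.g. 0.5 halves the image) or
#'   `NULL` when `out_shape` is given.
#' @param out_shape optional `c(width, height)` of the output.
#' @return Resampled array.
#' @export
resample_image <- function(img, factor = NULL, out_shape = NULL) {
  dm <- dim(img); H <- dm[1]; W <- dm[2]
  if (is.null(out_shape)) {
    stopifnot(is.numeric(factor), factor > 0)
    out_shape <- c(max(1L, round(W * factor)), max(1L, round(H * factor)))
  }
  Wo <- out_shape[1]; Ho <- out_shape[2]
  if (Wo == W && Ho == H) return(img)
  inv <- c(W / Wo, H / Ho)
  if (Wo <= W && Ho <= H && W %% Wo == 0 && H %% Ho == 0 && inv[1] == inv[2]) {
    b <- W %/% Wo
    nc <- if (length(dm) == 3) dm[3] else 1L
    out <- array(0, c(Ho, Wo, nc))
    for (c in seq_len(nc)) {
      plane <- if (length(dm) == 2) img else img[, , c]
      a <- array(plane, c(b, Ho, b, Wo))
      out[, , c] <- apply(a, c(2, 4), sum) / (b * b)
    }
    return(if (length(dm) == 2) out[, , 1] else out)
  }
  xs <- ((seq_len(Wo) - 0.5) * inv[1]) - 0.5
  ys <- ((seq_len(Ho) - 0.5) * inv[2]) - 0.5
  sx <- matrix(rep(xs, each = Ho), Ho, Wo)
  sy <- matrix(rep(ys, times = Wo), Ho, Wo)
  sx <- pmin(pmax(sx, 0), W - 1)
  sy <- pmin(pmax(sy, 0), H - 1)
  sample_image(img, sx, sy, "bilinear", fill = 0)
}

#' Interpolate a registered binary stack into a contiguous 3-D volume
#'
#' Inserts `steps_between` frames between each adjacent pair of registered
#' tissue masks by linear through-plane cross-fading and binarizing at
#' 0.5, producing the contiguous volume used for 3-D rendering.
#'
#' @param masks list of registered binary masks (equal `H x W`), or an
#'   `H x W x k` array.
#' @param steps_between non-negative integer count of interpolated frames
#'   per adjacent pair.
#' @param threshold binarization threshold of the cross-fade (default 0.5).
#' @return `H x W x n` binary array, `n = k + (k - 1) * steps_between`.
#' @export
interpolate_volume <- function(masks, steps_between = 0, threshold = 0.5) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  }
  stopifnot(length(masks) >= 1, steps_between >= 0)
  dm <- dim(masks[[1]])
  k <- length(masks)
  n <- k + (k - 1L) * as.integer(steps_between)
  vol <- array(0, c(dm[1], dm[2], n))
  z <- 1L
  for (i in seq_len(k)) {
    vol[, , z] <- (masks[[i]] >= threshold) * 1
    z <- z + 1L
    if (i < k && steps_between > 0) {
      for (s in seq_len(steps_between)) {
        f <- s / (steps_between + 1)
        vol[, , z] <- (((1 - f) * masks[[i]] + f * masks[[i + 1]]) >= threshold) * 1
        z <- z + 1L
      }
    }
  }
  vol
}
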