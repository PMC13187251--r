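#' Otsu threshold of an 8-bit histogram
#'
#' Returns the intensity `t` in `0:254` that maximizes the between-class
#' variance when pixels with value `<= t` form one class and `> t` the
#' other (cumulative-moment formulation; ties resolved to the smallest
#' `t`).
#'
#' @param counts integer vector of length 256 (histogram of values 0:255).
#' @return Integer threshold in `0:254`.
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  p <- counts / n
  omega <- cumsum(p)                 # P(class 0) for t = 0..255
  mu <- cumsum(p * (0:255))          # first moment up to t
  mu_t <- mu[256]
  t_all <- 0:254
  w0 <- omega[t_all + 1]
  sigma_b <- (mu_t * w0 - mu[t_all + 1])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_all[which.max(sigma_b)]
}

#' Tissue foreground mask by Otsu thresholding
#'
#' Computes the Otsu threshold on the 8-bit luminance histogram; tissue is
#' the dark class (histology on a bright glass background). Morphological
#' cleanup (closing then opening with a disc, removal of components below
#' a fraction of the foreground area) erases background noise and minor
#' artefacts. A constant-intensity image yields an all-background mask
#' with the `degenerate` flag set.
#'
#' @param image numeric `H x W x 3` RGB array in `[0, 1]` (or `H x W`
#'   grayscale).
#' @param cleanup apply morphological cleanup (default `TRUE`).
#' @param brush_radius disc radius in pixels for closing/opening.
#' @param min_component_frac discard connected components smaller than
#'   this fraction of the total foreground area.
#' @return An object of class `tissue_mask`: logical `mask`, `coverage`
#'   in `[0, 1]`, 8-bit `threshold`, and `degenerate` flag.
#' @export
compute_tissue_mask <- function(image, cleanup = TRUE, brush_radius = 2,
                                min_component_frac = 0.001) {
  stopifnot(length(image) > 0)
  lum <- if (length(dim(image)) == 3)
    0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  else image
  g <- pmin(pmax(floor(lum * 255), 0), 255)
  if (diff(range(g)) < 1) {
    mask <- matrix(FALSE, nrow(g), ncol(g))
    return(structure(list(mask = mask, coverage = 0, threshold = NA_integer_,
                          degenerate = TRUE), class = "tissue_mask"))
  }
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  thr <- otsu_threshold(counts)
  mask <- g <= thr  # tissue = dark class
  if (cleanup && any(mask)) {
    brush <- EBImage::makeBrush(2L * brush_radius + 1L, shape = "disc")
    m <- EBImage::opening(EBImage::closing(mask * 1, brush), brush)
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_frac * sum(sizes))
    mask <- matrix(lab %in% keep & lab > 0, nrow(g), ncol(g))
  }
  structure(list(mask = mask, coverage = mean(mask), threshold = thr,
                 degenerate = FALSE), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d, coverage %.3f, threshold %s%s\n",
              ncol(x$mask), nrow(x$mask), x$coverage,
              ifelse(is.na(x$threshold), "NA", x$threshold),
              ifelse(x$degenerate, " (degenerate)", "")))
  invisible(x)
}

as_mask_matrix <- function(m) {
  if (inherits(m, "tissue_mask")) m$mask else m
}

# --- Reinhard-style color statistics in the decorrelated l-alpha-beta
# space. RGB -> LMS -> log10 -> lab per the classical transfer algorithm.
.rgb2lms <- matrix(c(0.3811, 0.1967, 0.0241,
                     0.5783, 0.7244, 0.1288,
                     0.0402, 0.0782, 0.8444), 3, 3)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -1, 1, -2, 0), 3, 3, byrow = TRUE)

rgb_to_lab <- function(px) {            # px: n x 3 in [0,1]
  lms <- pmax(px %*% t(.rgb2lms), 1e-6)
  log10(lms) %*% t(.lms2lab)
}

lab_to_rgb <- function(lab) {
  lms <- 10^(lab %*% t(solve(.lms2lab)))
  rgb <- lms %*% t(solve(.rgb2lms))
  pmin(pmax(rgb, 0), 1)
}

#' Stain normalization to a stack-median color space
#'
#' Reinhard-style transfer in the decorrelated l-alpha-beta space:
#' per-slide channel means and standard deviations are computed over
#' tissue foreground pixels only, the element-wise median of the
#' per-slide statistics defines the common color space, and each slide's
#' foreground is affinely mapped onto it. Background pixels are left
#' untouched. Slides with degenerate statistics (zero variance or empty
#' mask) pass through unmodified and are flagged.
#'
#' @param images list of `H x W x 3` RGB arrays in `[0, 1]`, or a
#'   [slide_stack()] (level-0 rasters are used).
#' @param masks list of [compute_tissue_mask()] results or logical masks,
#'   one per slide.
#' @return list with `images` (normalized rasters, or the normalized
#'   [slide_stack()] if one was given), `stats` (per-slide 2 x 3
#'   mean/sd matrices), `median_stats`, and `degenerate` flags.
#' @export
normalize_stains <- function(images, masks) {
  was_stack <- inherits(images, "slide_stack")
  rasters <- if (was_stack) lapply(images$slides, slide_pixels) else images
  k <- length(rasters)
  stopifnot(k >= 2, length(masks) == k)
  masks <- lapply(masks, as_mask_matrix)
  stats <- vector("list", k); degenerate <- logical(k)
  for (i in seq_len(k)) {
    fg <- which(masks[[i]])
    if (length(fg) < 2) { degenerate[i] <- TRUE; next }
    px <- cbind(rasters[[i]][, , 1][fg], rasters[[i]][, , 2][fg],
                rasters[[i]][, , 3][fg])
    lab <- rgb_to_lab(px)
    mu <- colMeans(lab); sd <- apply(lab, 2, stats::sd)
    if (any(sd < 1e-8)) { degenerate[i] <- TRUE; next }
    stats[[i]] <- rbind(mean = mu, sd = sd)
  }
  ok <- which(!degenerate)
  if (length(ok) < 2) {
    warning("fewer than 2 non-degenerate slides; stains left unmodified")
    return(list(images = images, stats = stats, median_stats = NULL,
                degenerate = degenerate))
  }
  med <- apply(simplify2array(stats[ok]), c(1, 2), stats::median)
  out <- rasters
  for (i in ok) {
    fg <- which(masks[[i]])
    px <- cbind(rasters[[i]][, , 1][fg], rasters[[i]][, , 2][fg],
                rasters[[i]][, , 3][fg])
    lab <- rgb_to_lab(px)
    lab <- sweep(lab, 2, stats[[i]]["mean", ]) %*%
      diag(med["sd", ] / stats[[i]]["sd", ])
    lab <- sweep(lab, 2, med["mean", ], "+")
    px2 <- lab_to_rgb(lab)
    for (c in 1:3) { plane <- out[[i]][, , c]; plane[fg] <- px2[, c]
                     out[[i]][, , c] <- plane }
  }
  if (was_stack) {
    for (i in seq_len(k)) images$slides[[i]]$rasters[[1]] <- out[[i]]
    out <- images
  }
  list(images = out, stats = stats, median_stats = med,
       degenerate = degenerate)
}

#' Select the common processing spacing for a stack
#'
#' One spacing is chosen for the whole stack: the candidate (the largest
#' slide's pyramid ladder extended by integer multiples of its level-0
#' spacing) that brings the largest slide's longer side closest to
#' `target_pixels`. Ties resolve to the coarser spacing. Deterministic.
#'
#' @param stack a [slide_stack()].
#' @param target_pixels target side length in pixels (default 2000).
#' @param max_multiple largest integer resampling factor considered.
#' @return Spacing in micrometres/pixel.
#' @export
select_common_spacing <- function(stack, target_pixels = 2000,
                                  max_multiple = 64L) {
  stopifnot(inherits(stack, "slide_stack"))
  long_um <- vapply(stack$slides, function(s)
    max(s$ladder$width[1], s$ladder$height[1]) * s$spacing, 0)
  big <- stack$slides[[which.max(long_um)]]
  cand <- sort(unique(c(big$spacing * big$ladder$downsample,
                        big$spacing * seq_len(max_multiple))))
  side_px <- max(long_um) / cand
  err <- abs(side_px - target_pixels)
  best <- which(err == min(err))
  cand[max(best)]  # tie -> coarser
}

#' Preprocess a stack for alignment
#'
#' Runs the full harmonization chain: resample every slide to the common
#' spacing, compute tissue masks, normalize stains to the stack-median
#' color space, replace background with a constant color, and pad all
#' slides to identical square `D x D` dimensions (`D` = largest resampled
#' longer side), recording pad offsets so transforms compose back to the
#' original frames. RGB is preserved throughout.
#'
#' @param stack a [slide_stack()].
#' @param target_pixels target processing side length (default 2000).
#' @param background background RGB replacement color (default white, the
#'   glass-slide appearance).
#' @param normalize apply stain normalization (default `TRUE`).
#' @return An object of class `processed_stack`: `images` (list of
#'   `D x D x 3`), `masks` (list of `tissue_mask`, padded), `common_spacing`,
#'   `pad_offsets` (k x 2, x/y of original content within the padded frame),
#'   `scale_factors` (original -> processed), `color_stats`, `ids`, `k`,
#'   `slice_interval`, `level0_spacings`.
#' @export
build_processed_stack <- function(stack, target_pixels = 2000,
                                  background = c(1, 1, 1), normalize = TRUE) {
  stopifnot(inherits(stack, "slide_stack"))
  sp <- select_common_spacing(stack, target_pixels)
  k <- stack$k
  imgs <- vector("list", k); factors <- numeric(k)
  for (i in seq_len(k)) {
    s <- stack$slides[[i]]
    factors[i] <- s$spacing / sp
    imgs[[i]] <- resample_image(slide_pixels(s), factors[i])
  }
  masks <- lapply(imgs, compute_tissue_mask)
  cs <- NULL
  if (normalize) {
    ns <- normalize_stains(imgs, masks)
    imgs <- ns$images
    cs <- ns[c("stats", "median_stats", "degenerate")]
  }
  # background replacement
  for (i in seq_len(k)) {
    bg <- which(!masks[[i]]$mask)
    for (c in 1:3) { plane <- imgs[[i]][, , c]; plane[bg] <- background[c]
                     imgs[[i]][, , c] <- plane }
  }
  D <- max(vapply(imgs, function(m) max(dim(m)[1:2]), 0))
  pad <- matrix(0, k, 2, dimnames = list(NULL, c("dx", "dy")))
  for (i in seq_len(k)) {
    h <- dim(imgs[[i]])[1]; w <- dim(imgs[[i]])[2]
    dx <- floor((D - w) / 2); dy <- floor((D - h) / 2)
    pad[i, ] <- c(dx, dy)
    canvas <- array(rep(background, each = D * D), c(D, D, 3))
    canvas[dy + seq_len(h), dx + seq_len(w), ] <- imgs[[i]]
    imgs[[i]] <- canvas
    mk <- matrix(FALSE, D, D)
    mk[dy + seq_len(h), dx + seq_len(w)] <- masks[[i]]$mask
    masks[[i]]$mask <- mk
    masks[[i]]$coverage <- mean(mk)
  }
  structure(list(images = imgs, masks = masks, common_spacing = sp,
                 pad_offsets = pad, scale_factors = factors,
                 color_stats = cs,
                 ids = vapply(stack$slides, function(s) s$id, ""),
                 k = k, slice_interval = stack$slice_interval,
                 level0_spacings = vapply(stack$slides, function(s) s$spacing, 0),
                 dim = D),
            class = "processed_stack")
}

#' @export
print.processed_stack <- function(x, ...) {
  cat(sprintf("<processed_stack> k=%d, %dx%d px @ %g um/px\n", x$k, x$dim,
              x$dim, x$common_spacing))
  invisible(x)
}

#' Map original-frame coordinates into the processed frame
#'
#' Accounts for the pixel-center resampling convention and the pad offset
#' of slide `i`: `p_proc = f * p_orig + (f - 1) / 2 + pad`.
#'
#' @param pstack a `processed_stack`.
#' @param i slide index (1-based).
#' @param pts n x 2 matrix of level-0 (x, y) coordinates.
#' @return n x 2 matrix of processed-frame coordinates.
#' @export
to_processed_coords <- function(pstack, i, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  f <- pstack$scale_factors[i]
  sweep(pts * f + (f - 1) / 2, 2, pstack$pad_offsets[i, ], "+")
}
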