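#' Feature backends
#'
#' A feature backend provides the two capabilities the registration
#' pipeline consumes: `global_descriptor` (a patch-grid feature map of a
#' whole image, used for 180-degree flip resolution) and `dense_match`
#' (candidate point correspondences between two images, used for rigid
#' refinement). Backends are pluggable:
#'
#' * `"classical"` — deterministic, weight-free descriptors: each grid
#'   cell is summarized by its mean RGB absorbance, luminance standard
#'   deviation and an 8-bin gradient-orientation histogram (d = 12,
#'   stain-intensity weighted); dense matching is
#'   mutual-nearest-neighbor between (comparison-time normalized) cell
#'   descriptors.
#' * `"oracle"` — a test backend constructed from a phantom
#'   [ground truth record][perturb_stack()]: it emits planted true
#'   correspondences (optionally with noise and a configurable outlier
#'   fraction) mapped through the current slide poses. Its global
#'   descriptor is the classical one.
#' * `"pretrained"` — the contract slot for externally supplied
#'   transformer / CNN feature extractors and dense matchers. No weights
#'   ship with this package; requesting it raises an informative error.
#'   A user-built backend is any list with the same fields.
#'
#' @param id backend identifier: `"classical"`, `"oracle"` or
#'   `"pretrained"`.
#' @param ground_truth ground-truth record (oracle backend only).
#' @param n_matches number of correspondences the oracle emits per pair.
#' @param outlier_fraction fraction of oracle matches replaced by planted
#'   outliers (guaranteed at least `outlier_min_offset` pixels off the
#'   true correspondence).
#' @param noise_sd isotropic Gaussian noise (pixels) added to oracle
#'   inlier correspondences.
#' @param outlier_min_offset minimum displacement of planted outliers.
#' @return A list of class `feature_backend` with fields `id`,
#'   `capabilities`, `deterministic`, `global` and `match`.
#' @export
feature_backend <- function(id = c("classical", "oracle", "pretrained"),
                            ground_truth = NULL, n_matches = 100,
                            outlier_fraction = 0, noise_sd = 0,
                            outlier_min_offset = 10) {
  id <- match.arg(id)
  if (id == "classical") {
    structure(list(id = "classical",
                   capabilities = c("global_descriptor", "dense_match"),
                   deterministic = TRUE,
                   global = classical_grid_descriptor,
                   match = classical_dense_match),
              class = "feature_backend")
  } else if (id == "oracle") {
    if (is.null(ground_truth)) {
      stop(errorCondition("oracle backend needs a ground_truth record",
                          class = c("histostack_config_error", "error")))
    }
    structure(list(id = "oracle",
                   capabilities = c("global_descriptor", "dense_match"),
                   deterministic = TRUE,
                   ground_truth = ground_truth, n_matches = n_matches,
                   outlier_fraction = outlier_fraction, noise_sd = noise_sd,
                   outlier_min_offset = outlier_min_offset,
                   global = classical_grid_descriptor,
                   match = oracle_dense_match),
              class = "feature_backend")
  } else {
    stop(errorCondition(
      paste("the 'pretrained' backend is a plug-in contract; supply your own",
            "feature_backend list with `global` and `match` functions"),
      class = c("histostack_capability_error", "error")))
  }
}

#' @export
print.feature_backend <- function(x, ...) {
  cat(sprintf("<feature_backend> '%s' [%s]\n", x$id,
              paste(x$capabilities, collapse = ", ")))
  invisible(x)
}

#' A slide view: an image plus its registration bookkeeping
#'
#' Dense matching operates on the currently posed (warped) images; the
#' oracle backend additionally needs to know which slide it is looking at
#' and how original-frame coordinates map into the view. `map_orig` is
#' the composed map original slide frame -> current view frame.
#'
#' @param image `H x W x 3` raster as currently posed.
#' @param slide_index 1-based index in the stack.
#' @param map_orig `function(pts)` mapping n x 2 original level-slice
#'   coordinates into the view frame (identity by default).
#' @param mask optional logical tissue mask in the view frame.
#' @return A list of class `slide_view`.
#' @export
slide_view <- function(image, slide_index = NA_integer_, map_orig = identity,
                       mask = NULL) {
  structure(list(image = image, slide_index = slide_index,
                 map_orig = map_orig, mask = mask), class = "slide_view")
}

as_slide_view <- function(x) {
  if (inherits(x, "slide_view")) x else slide_view(x)
}

#' Extract a patch-grid feature map
#'
#' The image is resampled (aspect-preserving, padded with background) to
#' `side x side` and divided into a `g x g` grid of `patch x patch` cells,
#' `g = floor(side / patch)`; the backend's global descriptor summarizes
#' each cell into a d-dimensional embedding. With the contract defaults
#' (`side = 1036`, `patch = 14`) the grid is 74 x 74.
#'
#' @param image `H x W x 3` raster (or a [slide_view()]).
#' @param backend a [feature_backend()] with the `global_descriptor`
#'   capability.
#' @param side input side length fed to the descriptor (default 1036).
#' @param patch pixels per grid cell side (default 14).
#' @param background pad color.
#' @return An object of class `feature_map`: `grid` (`g x g x d` array),
#'   `patch_size`, `source_resolution`, `backend_id`.
#' @export
extract_global_features <- function(image, backend, side = 1036, patch = 14,
                                    background = 1) {
  if (inherits(image, "slide_view")) image <- image$image
  if (!"global_descriptor" %in% backend$capabilities) {
    stop(errorCondition("backend lacks the global_descriptor capability",
                        class = c("histostack_capability_error", "error")))
  }
  stopifnot(side >= patch, patch >= 2)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H != side || W != side) {
    f <- side / max(H, W)
    rs <- resample_image(image, out_shape = c(max(1L, round(W * f)),
                                              max(1L, round(H * f))))
    canvas <- array(background, c(side, side, 3))
    canvas[seq_len(dim(rs)[1]), seq_len(dim(rs)[2]), ] <- rs
    image <- canvas
  }
  g <- side %/% patch
  grid <- backend$global(image, g = g, patch = patch)
  structure(list(grid = grid, patch_size = patch, source_resolution = side,
                 backend_id = backend$id), class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<feature_map> %dx%dx%d (%s), patch %d px\n", d[1], d[2], d[3],
              x$backend_id, x$patch_size))
  invisible(x)
}

# mean (or sd) over patch x patch blocks of a (g*patch) x (g*patch)
# matrix, as a pair of block-pooling matrix products (BLAS-fast); the
# pooling matrix is cached per (g, patch)
.block_pool_cache <- new.env(parent = emptyenv())
block_pool <- function(g, patch) {
  key <- paste(g, patch, sep = "_")
  P <- .block_pool_cache[[key]]
  if (is.null(P)) {
    P <- matrix(0, g * patch, g)
    P[cbind(seq_len(g * patch), rep(seq_len(g), each = patch))] <- 1 / patch
    .block_pool_cache[[key]] <- P
  }
  P
}

block_stat <- function(m, g, patch, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  m <- m[seq_len(g * patch), seq_len(g * patch)]
  P <- block_pool(g, patch)
  mu <- crossprod(P, m %*% P)
  if (stat == "mean") mu
  else sqrt(pmax(crossprod(P, m^2 %*% P) - mu^2, 0))
}

# Classical per-cell descriptor: mean RGB absorbance (1 - mean, 3) +
# luminance sd (1) + 8-bin signed gradient-orientation histogram (8)
# -> d=12. Descriptors are deliberately NOT L2-normalized per cell: the
# flattened-map cosine used for flip resolution must weight cells by
# their stain intensity (normalization erases exactly the
# nodule-vs-stroma contrast that breaks the 180-degree symmetry, and
# radial luminance gradients are themselves 180-degree invariant).
# Dense matching normalizes at comparison time instead.
classical_grid_descriptor <- function(image, g, patch) {
  side <- g * patch
  img <- image[seq_len(side), seq_len(side), , drop = FALSE]
  lum <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  d <- 12L
  out <- array(0, c(g, g, d))
  for (c in 1:3) out[, , c] <- 1 - t(block_stat(img[, , c], g, patch))
  out[, , 4] <- t(block_stat(lum, g, patch, "sd"))
  # central-difference gradients (zero at borders)
  gx <- matrix(0, side, side); gy <- matrix(0, side, side)
  gx[, 2:(side - 1)] <- (lum[, 3:side] - lum[, 1:(side - 2)]) / 2
  gy[2:(side - 1), ] <- (lum[3:side, ] - lum[1:(side - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                       # (-pi, pi], signed: flips by 180
  bin <- pmin(floor((ang + pi) / (2 * pi / 8)), 7)
  a <- array(0, c(side, side))
  for (b in 0:7) {
    a[] <- mag * (bin == b)
    out[, , 5 + b] <- t(block_stat(a, g, patch))
  }
  # blank (background) cells get the zero vector so image comparisons are
  # driven by tissue layout, not by the constant white background
  lum_mean <- t(block_stat(lum, g, patch))
  lum_sd <- t(block_stat(lum, g, patch, "sd"))
  blank <- as.vector(lum_mean > 0.97 & lum_sd < 0.01)
  flat <- matrix(out, g * g, d)
  flat[blank, ] <- 0
  array(flat, c(g, g, d))
}

#' Cosine similarity between two feature maps
#'
#' Default aggregation flattens both `g x g x d` grids and takes the
#' cosine of the resulting vectors — token-order-sensitive, hence
#' rotation-sensitive, which the 180-degree flip test requires.
#' `"mean_token"` averages per-token cosines instead.
#'
#' @param a,b [extract_global_features()] results with identical `g` and
#'   `d`.
#' @param aggregation `"flatten"` (default) or `"mean_token"`.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b, aggregation = c("flatten", "mean_token")) {
  aggregation <- match.arg(aggregation)
  if (!identical(dim(a$grid), dim(b$grid))) {
    stop(errorCondition("feature map shapes differ",
                        class = c("histostack_config_error", "error")))
  }
  if (aggregation == "flatten") {
    va <- as.vector(a$grid); vb <- as.vector(b$grid)
    s <- sum(va * vb) / max(sqrt(sum(va^2)) * sqrt(sum(vb^2)), 1e-12)
  } else {
    d <- dim(a$grid)
    ma <- matrix(a$grid, d[1] * d[2], d[3])
    mb <- matrix(b$grid, d[1] * d[2], d[3])
    num <- rowSums(ma * mb)
    den <- sqrt(rowSums(ma^2)) * sqrt(rowSums(mb^2))
    s <- mean(num / pmax(den, 1e-12))
  }
  min(max(s, -1), 1)
}

#' Set of candidate correspondences between two slides
#'
#' @param points_a,points_b m x 2 matrices of matched (x, y) coordinates
#'   in the two view frames.
#' @param confidence m confidences in `[0, 1]`.
#' @param inlier m logical flags (all `FALSE` until RANSAC sets them).
#' @return An object of class `match_set`.
#' @export
match_set <- function(points_a, points_b,
                      confidence = rep(1, nrow(points_a)),
                      inlier = rep(FALSE, nrow(points_a))) {
  points_a <- matrix(as.numeric(points_a), ncol = 2)
  points_b <- matrix(as.numeric(points_b), ncol = 2)
  stopifnot(nrow(points_a) == nrow(points_b),
            length(confidence) == nrow(points_a),
            all(confidence >= 0 & confidence <= 1))
  structure(list(points_a = points_a, points_b = points_b,
                 confidence = as.numeric(confidence),
                 inlier = as.logical(inlier), m = nrow(points_a)),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> m=%d, %d inlier(s)\n", x$m, sum(x$inlier)))
  invisible(x)
}

#' Dense matching between two slides
#'
#' Delegates to the backend's matcher. The classical backend computes
#' mutual-nearest-neighbor matches between grid-cell descriptors of
#' tissue cells; the oracle backend emits planted ground-truth
#' correspondences. When fewer than 3 candidates are found an
#' insufficient-matches condition is signalled (as a classed warning) and
#' the short set returned — the caller decides the fallback.
#'
#' @param a,b [slide_view()] objects (plain rasters are promoted).
#' @param backend a [feature_backend()] with the `dense_match` capability.
#' @param seed integer seed for any backend randomness.
#' @param ... backend-specific options (classical: `patch`,
#'   `min_confidence`).
#' @return A [match_set()] with all `inlier` flags `FALSE`.
#' @export
dense_match <- function(a, b, backend, seed = NULL, ...) {
  if (!"dense_match" %in% backend$capabilities) {
    stop(errorCondition("backend lacks the dense_match capability",
                        class = c("histostack_capability_error", "error")))
  }
  ms <- backend$match(as_slide_view(a), as_slide_view(b), backend = backend,
                      seed = seed, ...)
  if (ms$m < 3) {
    warning(warningCondition(
      sprintf("only %d dense matches found (need >= 3)", ms$m),
      class = "histostack_insufficient_matches"))
  }
  ms
}

classical_dense_match <- function(a, b, backend, seed = NULL, patch = 14,
                                  min_confidence = 0.5, refine = TRUE,
                                  search = 5, ...) {
  da <- cell_descriptors(a$image, patch)
  db <- cell_descriptors(b$image, patch)
  if (nrow(da$desc) < 3 || nrow(db$desc) < 3) {
    return(match_set(matrix(0, 0, 2), matrix(0, 0, 2), numeric(0)))
  }
  na <- da$desc / pmax(sqrt(rowSums(da$desc^2)), 1e-12)
  nb <- db$desc / pmax(sqrt(rowSums(db$desc^2)), 1e-12)
  sim <- na %*% t(nb)               # cosine similarity between cells
  best_ab <- max.col(sim, ties.method = "first")
  best_ba <- max.col(t(sim), ties.method = "first")
  ia <- which(best_ba[best_ab] == seq_len(nrow(sim)))   # mutual NN
  ib <- best_ab[ia]
  conf <- pmin(pmax(sim[cbind(ia, ib)], 0), 1)
  keep <- conf >= min_confidence
  pa <- da$centers[ia[keep], , drop = FALSE]
  pb <- db$centers[ib[keep], , drop = FALSE]
  if (refine && nrow(pa) > 0) {
    pb <- refine_matches_ssd(a$image, b$image, pa, pb, patch = patch,
                             search = search)
  }
  match_set(pa, pb, conf[keep])
}

# Pixel-level refinement of coarse cell matches: for each matched pair,
# slide the b-side block within +-search pixels minimizing the luminance
# SSD against the a-side block, with 1-D parabolic sub-pixel
# interpolation per axis. This is the fine level of the match pyramid —
# the grid descriptors locate corresponding anatomy at cell precision,
# the local block search recovers the sub-cell displacement.
refine_matches_ssd <- function(img_a, img_b, pa, pb, patch = 14, search = 5) {
  lum_a <- 0.2126 * img_a[, , 1] + 0.7152 * img_a[, , 2] + 0.0722 * img_a[, , 3]
  lum_b <- 0.2126 * img_b[, , 1] + 0.7152 * img_b[, , 2] + 0.0722 * img_b[, , 3]
  H <- nrow(lum_a); W <- ncol(lum_a)
  h <- patch %/% 2
  offs <- expand.grid(dx = -search:search, dy = -search:search)
  n_off <- nrow(offs)
  mid <- which(offs$dx == 0 & offs$dy == 0)
  out <- pb
  for (i in seq_len(nrow(pa))) {
    ax <- round(pa[i, 1]); ay <- round(pa[i, 2])
    bx <- round(pb[i, 1]); by <- round(pb[i, 2])
    if (ax - h < 0 || ay - h < 0 || ax + h > W - 1 || ay + h > H - 1) next
    if (bx - h - search < 0 || by - h - search < 0 ||
        bx + h + search > W - 1 || by + h + search > H - 1) next
    A <- lum_a[ay - h + seq_len(patch), ax - h + seq_len(patch)]
    reg <- lum_b[by - h - search + seq_len(patch + 2 * search),
                 bx - h - search + seq_len(patch + 2 * search)]
    ssd <- vapply(seq_len(n_off), function(o) {
      sub <- reg[offs$dy[o] + search + seq_len(patch),
                 offs$dx[o] + search + seq_len(patch)]
      sum((A - sub)^2)
    }, 0)
    o <- which.min(ssd)
    dx <- offs$dx[o]; dy <- offs$dy[o]
    # sub-pixel parabola along each axis where neighbors exist
    sub_off <- function(sm, s0, sp) {
      den <- sm - 2 * s0 + sp
      if (den <= 1e-12) 0 else max(min(0.5 * (sm - sp) / den, 1), -1)
    }
    fx <- 0; fy <- 0
    ox <- which(offs$dx == dx - 1 & offs$dy == dy)
    px_ <- which(offs$dx == dx + 1 & offs$dy == dy)
    if (length(ox) && length(px_)) fx <- sub_off(ssd[ox], ssd[o], ssd[px_])
    oy <- which(offs$dx == dx & offs$dy == dy - 1)
    py_ <- which(offs$dx == dx & offs$dy == dy + 1)
    if (length(oy) && length(py_)) fy <- sub_off(ssd[oy], ssd[o], ssd[py_])
    out[i, ] <- c(bx + dx + fx, by + dy + fy)
  }
  out
}

# Descriptors + centers of tissue-bearing cells of one image at its
# native resolution (cropped to a multiple of `patch`).
cell_descriptors <- function(image, patch) {
  H <- dim(image)[1]; W <- dim(image)[2]
  g <- min(H, W) %/% patch
  grid <- classical_grid_descriptor(image, g, patch)
  lum_mean <- t(block_stat(
    0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3],
    g, patch))
  lum_sd <- t(block_stat(
    0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3],
    g, patch, "sd"))
  tissue <- as.vector(lum_mean < 0.97 & lum_sd > 1e-4)  # drop blank cells
  cx <- (seq_len(g) - 1) * patch + (patch - 1) / 2
  # grid is [x_cell, y_cell, d]; matrix() flattens with x fastest, so the
  # center table must enumerate x fastest too
  flat <- matrix(grid, g * g, dim(grid)[3])
  centers <- cbind(x = rep(cx, times = g), y = rep(cx, each = g))
  list(desc = flat[tissue, , drop = FALSE],
       centers = centers[tissue, , drop = FALSE])
}

oracle_dense_match <- function(a, b, backend, seed = NULL, ...) {
  gt <- backend$ground_truth
  ia <- a$slide_index; ib <- b$slide_index
  if (is.na(ia) || is.na(ib)) {
    stop(errorCondition("oracle backend needs slide_view objects with slide_index",
                        class = c("histostack_config_error", "error")))
  }
  with_seed(seed, {
    n <- backend$n_matches
    # sample true 3-D-consistent points in the shared unperturbed frame
    r <- gt$sample_radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x0 <- cbind(gt$sample_center[1] + r * cos(th),
                gt$sample_center[2] + r * sin(th))
    pa <- a$map_orig(apply_rigid(gt$transforms[[ia]], x0))
    pb <- b$map_orig(apply_rigid(gt$transforms[[ib]], x0))
    if (backend$noise_sd > 0) {
      pa <- pa + matrix(stats::rnorm(2 * n, 0, backend$noise_sd), n, 2)
      pb <- pb + matrix(stats::rnorm(2 * n, 0, backend$noise_sd), n, 2)
    }
    n_out <- round(backend$outlier_fraction * n)
    inl_true <- rep(TRUE, n)
    if (n_out > 0) {
      W <- dim(b$image)[2]; H <- dim(b$image)[1]
      out_idx <- seq_len(n_out)  # deterministic positions, random offsets
      for (j in out_idx) {
        repeat {
          cand <- c(stats::runif(1, 0, W - 1), stats::runif(1, 0, H - 1))
          if (sqrt(sum((cand - pb[j, ])^2)) >= backend$outlier_min_offset) break
        }
        pb[j, ] <- cand
      }
      inl_true[out_idx] <- FALSE
    }
    ms <- match_set(pa, pb, confidence = rep(1, n))
    attr(ms, "planted_inlier") <- inl_true
    ms
  })
}

#' PCA visualization of feature maps as RGB images
#'
#' Fits one PCA on the concatenated tokens of all maps, projects each
#' map's tokens onto the first three components, fixes each component's
#' sign so its score distribution has non-negative skewness, and min-max
#' scales each component to `[0, 1]` over the concatenated scores (so the
#' maps share one color scale). Components with (near-)zero variance map
#' to the constant 0.5.
#'
#' @param maps list of [extract_global_features()] results sharing `g`
#'   and `d >= 3`.
#' @return List of `g x g x 3` arrays in `[0, 1]`, one per map.
#' @export
pca_rgb <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- lapply(maps, function(m) dim(m$grid))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop(errorCondition("feature maps must share g and d",
                        class = c("histostack_config_error", "error")))
  }
  d <- dims[[1]][3]
  if (d < 3) {
    stop(errorCondition("need descriptor dimension d >= 3",
                        class = c("histostack_config_error", "error")))
  }
  g2 <- dims[[1]][1] * dims[[1]][2]
  tokens <- do.call(rbind, lapply(maps, function(m) matrix(m$grid, g2, d)))
  ctr <- colMeans(tokens)
  sv <- svd(sweep(tokens, 2, ctr), nu = 0, nv = 3)
  scores <- sweep(tokens, 2, ctr) %*% sv$v
  for (c in 1:3) {
    s <- scores[, c]
    sk <- mean((s - mean(s))^3)
    if (sk < 0) scores[, c] <- -s
  }
  lo <- apply(scores, 2, min); hi <- apply(scores, 2, max)
  rng <- hi - lo
  out <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    sc <- scores[(i - 1) * g2 + seq_len(g2), , drop = FALSE]
    rgb <- matrix(0.5, g2, 3)
    for (c in 1:3) {
      if (rng[c] > 1e-9) rgb[, c] <- (sc[, c] - lo[c]) / rng[c]
    }
    out[[i]] <- array(rgb, c(dims[[1]][1], dims[[1]][2], 3))
  }
  out
}
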