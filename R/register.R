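#' Enclosing-ellipse pose of a tissue mask
#'
#' Center = foreground centroid; orientation and axes from the second
#' central moments of the mask (for a solid ellipse the moment-equivalent
#' semi-axes are `2 * sqrt(eigenvalue)`). The orientation is only defined
#' modulo 180 degrees; masks whose axis ratio is below
#' `degenerate_ratio` are flagged as rotationally ambiguous.
#'
#' @param mask a [compute_tissue_mask()] result or logical matrix.
#' @param degenerate_ratio major/minor ratio below which the angle is
#'   flagged unreliable (default 1.05).
#' @return An object of class `ellipse_pose`: `center` (x, y), `angle`
#'   in `[0, 180)`, `axes` (major, minor semi-axes), `degenerate`.
#' @export
fit_enclosing_ellipse <- function(mask, degenerate_ratio = 1.05) {
  m <- as_mask_matrix(mask)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop(errorCondition("empty mask: cannot fit an ellipse",
                        class = c("histostack_empty_mask", "error")))
  }
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  ang <- ang %% 180
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  axes <- c(major = 2 * sqrt(max(l1, 0)), minor = 2 * sqrt(max(l2, 1e-12)))
  structure(list(center = c(cx, cy), angle = ang, axes = axes,
                 degenerate = axes[1] / axes[2] < degenerate_ratio),
            class = "ellipse_pose")
}

#' @export
print.ellipse_pose <- function(x, ...) {
  cat(sprintf("<ellipse_pose> center (%.1f, %.1f), angle %.2f deg, axes %.1f/%.1f%s\n",
              x$center[1], x$center[2], x$angle, x$axes[1], x$axes[2],
              ifelse(x$degenerate, " (degenerate)", "")))
  invisible(x)
}

#' Per-slide alignment state of a stack
#'
#' Holds the reference index, the per-slide composed rigid transforms
#' (slide processed frame -> reference frame), flip bookkeeping, optional
#' deformable refinements and per-pair diagnostics. The reference slide's
#' transform is the identity.
#'
#' @param reference_index 1-based reference slide index.
#' @param transforms list of k [rigid_transform()] objects.
#' @param flips logical k-vector of applied 180-degree corrections.
#' @param frame_center rotation center of the common frame (x, y).
#' @return An object of class `stack_alignment`.
#' @export
stack_alignment <- function(reference_index, transforms,
                            flips = rep(FALSE, length(transforms)),
                            frame_center = c(0, 0)) {
  structure(list(reference_index = reference_index, transforms = transforms,
                 flips = flips, frame_center = frame_center,
                 content_center = frame_center,
                 deformable = vector("list", length(transforms)),
                 degenerate = rep(FALSE, length(transforms)),
                 pair_diagnostics = list()),
            class = "stack_alignment")
}

#' @export
print.stack_alignment <- function(x, ...) {
  cat(sprintf("<stack_alignment> k=%d, reference %d, %d flip(s)\n",
              length(x$transforms), x$reference_index, sum(x$flips)))
  invisible(x)
}

# Middle-reference convention: lower middle for even k (0-based
# floor((k-1)/2), returned 1-based).
reference_index <- function(k) as.integer(floor((k - 1) / 2)) + 1L

# Outward visit order from the reference: r+1..k then r-1..1.
outward_order <- function(k, r) {
  c(if (r < k) (r + 1L):k, if (r > 1) (r - 1L):1L)
}

#' Initialize stack alignment from enclosing ellipses
#'
#' Selects the middle slide as the reference and maps every slide's
#' ellipse center and orientation onto the reference's (orientation
#' matched modulo 180 degrees — the flip ambiguity is resolved later by
#' [resolve_flips()]). Slides with a degenerate (near-circular) ellipse
#' fall back to centroid-only alignment and are flagged.
#'
#' @param pstack a [build_processed_stack()] result.
#' @param reference override of the reference slide index (1-based);
#'   default: the middle slide, `floor((k - 1) / 2)` in 0-based terms.
#' @return A [stack_alignment()] with initialization poses.
#' @export
initialize_stack <- function(pstack, reference = NULL) {
  stopifnot(inherits(pstack, "processed_stack"))
  k <- pstack$k
  r <- if (is.null(reference)) reference_index(k) else as.integer(reference)
  stopifnot(r >= 1, r <= k)
  poses <- lapply(pstack$masks, fit_enclosing_ellipse)
  ref <- poses[[r]]
  transforms <- vector("list", k)
  degenerate <- logical(k)
  for (i in seq_len(k)) {
    p <- poses[[i]]
    dtheta <- if (p$degenerate || ref$degenerate) 0
              else wrap_angle_180(ref$angle - p$angle)
    degenerate[i] <- p$degenerate
    tr <- ref$center - p$center
    transforms[[i]] <- rigid_transform(dtheta, tr[1], tr[2], center = p$center)
  }
  transforms[[r]] <- rigid_transform(0, 0, 0, center = ref$center)
  al <- stack_alignment(r, transforms,
                        frame_center = c((pstack$dim - 1) / 2,
                                         (pstack$dim - 1) / 2))
  al$degenerate <- degenerate
  al$ellipses <- poses
  # all slides' content centers coincide with the reference's after
  # initialization; 180-degree flips must rotate about this point
  al$content_center <- ref$center
  al
}

warp_slide <- function(pstack, align, i, interpolation = "bilinear") {
  warp_image(pstack$images[[i]], align$transforms[[i]],
             interpolation = interpolation, fill = 1)
}

warp_mask <- function(pstack, align, i) {
  warp_image(pstack$masks[[i]]$mask * 1, align$transforms[[i]],
             interpolation = "nearest", fill = 0)
}

#' Resolve 180-degree flip ambiguities
#'
#' Ellipse initialization leaves each slide's orientation ambiguous up to
#' 180 degrees. Iterating over adjacent pairs outward from the reference,
#' each non-reference slide is compared in its current pose and in the
#' pose rotated by 180 degrees about the frame center; whichever yields
#' the higher cosine similarity of global features with the (already
#' resolved) neighbor toward the reference is kept. Ties (similarity gain
#' below `tie_eps`) keep the unflipped pose; the reference is never
#' flipped.
#'
#' @param pstack a `processed_stack`.
#' @param align a [stack_alignment()] (initialization done).
#' @param backend a [feature_backend()] with `global_descriptor`.
#' @param side,patch feature-grid geometry; `side = NULL` uses the
#'   (downsampled) processed frame size rounded down to a multiple of
#'   `patch`.
#' @param tie_eps similarity gain below which no flip is applied.
#' @param downsample integer factor at which the posed comparisons are
#'   rendered (default 2); the flip decision only needs coarse anatomy.
#' @return The updated `stack_alignment` with `flips` recorded.
#' @export
resolve_flips <- function(pstack, align, backend, side = NULL, patch = 14,
                          tie_eps = 1e-6, downsample = 2) {
  k <- pstack$k; r <- align$reference_index
  ds <- as.integer(downsample)
  stopifnot(ds >= 1)
  # keep at least an 8x8 token grid: too-coarse grids cannot discriminate
  # the 180-degree pose on small frames
  while (ds > 1 && (pstack$dim %/% ds) %/% patch < 8) ds <- ds - 1L
  imgs <- if (ds > 1) lapply(pstack$images, resample_image, factor = 1 / ds)
          else pstack$images
  if (is.null(side)) side <- ((pstack$dim %/% ds) %/% patch) * patch
  feats <- function(t) {
    w <- warp_image(imgs[[feats_i]], scale_rigid(t, 1 / ds),
                    interpolation = "bilinear", fill = 1)
    extract_global_features(w, backend, side = side, patch = patch)
  }
  cache <- vector("list", k)
  feats_i <- r
  cache[[r]] <- feats(align$transforms[[r]])
  flip <- rigid_transform(180, 0, 0, center = align$content_center)
  for (i in outward_order(k, r)) {
    j <- if (i > r) i - 1L else i + 1L
    t_flip <- compose_rigid(flip, align$transforms[[i]],
                            center = align$frame_center)
    feats_i <- i
    f_cur <- feats(align$transforms[[i]])
    f_flip <- feats(t_flip)
    s_cur <- cosine_similarity(f_cur, cache[[j]])
    s_flip <- cosine_similarity(f_flip, cache[[j]])
    if (s_flip - s_cur > tie_eps) {
      align$transforms[[i]] <- t_flip
      align$flips[i] <- TRUE
      cache[[i]] <- f_flip
    } else {
      cache[[i]] <- f_cur
    }
  }
  align
}

#' RANSAC rigid transform estimation from matches
#'
#' Random-sample-consensus over minimal 2-point samples: each sample
#' yields a closed-form rigid candidate (rotation from the angle between
#' the paired difference vectors, translation from centroids); matches
#' with residual below `threshold` form the consensus. The best consensus
#' is refined by closed-form least squares over its inliers (rotation via
#' the cross-covariance SVD with the reflection branch rejected,
#' translation from centroids), and inlier flags are recomputed under the
#' refined transform. Deterministic given `seed`.
#'
#' @param matches a [match_set()] with `m >= 3`.
#' @param seed integer RNG seed.
#' @param threshold inlier residual threshold in pixels (default 3).
#' @param iterations number of sampling iterations (default 1000).
#' @param max_rotation optional cap (degrees) on the candidate rotation
#'   magnitude; candidates beyond it are discarded. Used by the pairwise
#'   refinement stage, where the global initialization has already fixed
#'   the pose and large rotations can only be spurious consensus.
#' @return List with `transform` (a [rigid_transform()] mapping
#'   `points_a` onto `points_b`, center at the origin), `matches` (inlier
#'   flags set), `n_inliers`, and `rmse` over inliers.
#' @export
estimate_rigid <- function(matches, seed = NULL, threshold = 3,
                           iterations = 1000, max_rotation = NULL) {
  stopifnot(inherits(matches, "match_set"))
  m <- matches$m
  if (m < 3) {
    stop(errorCondition(sprintf("need >= 3 matches, got %d", m),
                        class = c("histostack_insufficient_matches", "error")))
  }
  za <- complex(real = matches$points_a[, 1], imaginary = matches$points_a[, 2])
  zb <- complex(real = matches$points_b[, 1], imaginary = matches$points_b[, 2])
  best <- with_seed(seed, {
    i1 <- sample.int(m, iterations, replace = TRUE)
    i2 <- sample.int(m - 1L, iterations, replace = TRUE)
    i2 <- i2 + (i2 >= i1)                       # distinct second index
    va <- za[i2] - za[i1]; vb <- zb[i2] - zb[i1]
    ok <- Mod(va) > 1e-9
    rot <- vb / va
    rot[ok] <- rot[ok] / Mod(rot[ok])           # unit rotation per candidate
    rot[!ok] <- 1
    ca <- (za[i1] + za[i2]) / 2; cb <- (zb[i1] + zb[i2]) / 2
    tt <- cb - rot * ca
    # residual matrix: iterations x m
    res <- Mod(outer(rot, za) + matrix(tt, iterations, m) - matrix(zb, iterations, m, byrow = TRUE))
    counts <- rowSums(res < threshold)
    counts[!ok] <- 0L
    if (!is.null(max_rotation)) {
      counts[abs(wrap_angle(Arg(rot) * 180 / pi)) > max_rotation] <- 0L
    }
    b <- which.max(counts)
    list(count = counts[b], inliers = res[b, ] < threshold)
  })
  if (best$count < 3) {
    stop(errorCondition("no rigid consensus of at least 3 matches",
                        class = c("histostack_no_consensus", "error")))
  }
  fit <- procrustes_rigid(matches$points_a[best$inliers, , drop = FALSE],
                          matches$points_b[best$inliers, , drop = FALSE])
  resid <- Mod(exp(1i * fit$theta * pi / 180) * za + complex(real = fit$t[1], imaginary = fit$t[2]) - zb)
  inlier <- resid < threshold
  if (sum(inlier) >= 3) {
    fit <- procrustes_rigid(matches$points_a[inlier, , drop = FALSE],
                            matches$points_b[inlier, , drop = FALSE])
    resid <- Mod(exp(1i * fit$theta * pi / 180) * za + complex(real = fit$t[1], imaginary = fit$t[2]) - zb)
    inlier <- resid < threshold
  }
  matches$inlier <- inlier
  list(transform = rigid_transform(fit$theta, fit$t[1], fit$t[2],
                                   center = c(0, 0)),
       matches = matches, n_inliers = sum(inlier),
       rmse = sqrt(mean(resid[inlier]^2)))
}

# Closed-form least-squares rigid fit (2-D orthogonal Procrustes with the
# reflection branch rejected): rotation from the SVD of the
# cross-covariance of centered point sets, translation from centroids.
procrustes_rigid <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t <- cb - as.numeric(R %*% ca)
  list(theta = theta, t = t, R = R)
}

#' Iterative outward pairwise alignment of the whole stack
#'
#' Starting from the reference, each slide is refined against its
#' already-aligned neighbor toward the reference: the two slides are
#' warped into the common frame under their current poses, dense matches
#' are computed by the backend, a rigid refinement is estimated by RANSAC
#' and composed onto the slide's pose (refinement after initialization,
#' both about the shared frame). Pairs that fail (insufficient matches or
#' no consensus) keep the initialization pose and are recorded in the
#' diagnostics.
#'
#' @param pstack a `processed_stack`.
#' @param align a [stack_alignment()] with flips resolved.
#' @param backend a [feature_backend()] with `dense_match`.
#' @param seed integer seed, expanded deterministically per pair.
#' @param threshold,iterations RANSAC parameters.
#' @param max_rotation cap in degrees on each pairwise rotation
#'   refinement (default 30); see [estimate_rigid()].
#' @param refine pixel-level refinement of dense matches during
#'   alignment; off by default — the coarse grid matches carry the
#'   robust global signal, while local refinement can lock onto
#'   decorrelated fine structure at sparse slice intervals.
#' @param ... passed to [dense_match()].
#' @return The updated `stack_alignment` with refined transforms and
#'   per-pair diagnostics (match count, inlier count, residuals, failure
#'   flags).
#' @export
align_stack <- function(pstack, align, backend, seed = 1, threshold = 3,
                        iterations = 1000, refine = FALSE,
                        max_rotation = 30, ...) {
  k <- pstack$k; r <- align$reference_index
  diag_list <- list()
  view_cache <- vector("list", k)  # views of already-final poses
  for (i in outward_order(k, r)) {
    j <- if (i > r) i - 1L else i + 1L
    view_i <- posed_view(pstack, align, i)
    if (is.null(view_cache[[j]])) view_cache[[j]] <- posed_view(pstack, align, j)
    view_j <- view_cache[[j]]
    pair_seed <- stage_seed(seed, "match", i)
    rec <- list(pair = c(i, j), m = 0L, n_inliers = 0L, rmse = NA_real_,
                failed = FALSE, reason = NA_character_)
    est <- tryCatch({
      ms <- withCallingHandlers(
        dense_match(view_i, view_j, backend, seed = pair_seed,
                    refine = refine, ...),
        histostack_insufficient_matches = function(w) invokeRestart("muffleWarning"))
      rec$m <- ms$m
      estimate_rigid(ms, seed = pair_seed, threshold = threshold,
                     iterations = iterations, max_rotation = max_rotation)
    }, histostack_insufficient_matches = function(e) {
      rec$reason <<- "insufficient_matches"; NULL
    }, histostack_no_consensus = function(e) {
      rec$reason <<- "no_consensus"; NULL
    })
    if (is.null(est)) {
      rec$failed <- TRUE
    } else {
      step_t <- rigid_from_matrix(rigid_matrix(est$transform),
                                  center = align$frame_center, tol = 1e-6)
      align$transforms[[i]] <- compose_rigid(step_t, align$transforms[[i]],
                                             center = align$frame_center)
      rec$n_inliers <- est$n_inliers
      rec$rmse <- est$rmse
    }
    view_cache[[i]] <- if (rec$failed) view_i else posed_view(pstack, align, i)
    diag_list[[length(diag_list) + 1L]] <- rec
  }
  align$pair_diagnostics <- diag_list
  align
}

posed_view <- function(pstack, align, i) {
  f <- pstack$scale_factors[i]
  off <- pstack$pad_offsets[i, ]
  t_i <- align$transforms[[i]]
  slide_view(warp_slide(pstack, align, i), slide_index = i,
             map_orig = function(pts) {
               if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
               p <- sweep(pts * f + (f - 1) / 2, 2, off, "+")
               apply_rigid(t_i, p)
             })
}

#' Optional thin-plate-spline refinement of an aligned pair
#'
#' Fits a TPS deformation field from the inlier correspondences of an
#' already rigidly aligned pair (backward displacements
#' `f(b) = a - b` evaluated in the common frame), then resamples it onto
#' a Cartesian control grid so it can be rescaled to any resolution
#' level. Off by default in the pipeline; intended for densely sampled
#' stacks. With fewer than 4 non-collinear inliers an identity field is
#' returned.
#'
#' @param matches a [match_set()] with inlier flags set (both point sets
#'   in the common aligned frame).
#' @param out_shape `c(width, height)` of the common frame.
#' @param grid_spacing control-grid spacing in pixels.
#' @param regularization TPS smoothing weight (0 = interpolating).
#' @return A `deformation_field` on a Cartesian grid.
#' @export
refine_deformable <- function(matches, out_shape, grid_spacing = 32,
                              regularization = 0) {
  a <- matches$points_a[matches$inlier, , drop = FALSE]
  b <- matches$points_b[matches$inlier, , drop = FALSE]
  identity_field <- function() {
    xs <- seq(0, out_shape[1] - 1 + grid_spacing - 1e-9, by = grid_spacing)
    ys <- seq(0, out_shape[2] - 1 + grid_spacing - 1e-9, by = grid_spacing)
    nodes <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    fit_deformation(nodes, matrix(0, nrow(nodes), 2), grid_spacing = grid_spacing)
  }
  if (nrow(a) < 4 || qr(cbind(1, b))$rank < 3) return(identity_field())
  f <- fit_deformation(b, a - b, regularization = regularization)
  grid_deformation(f, out_shape, grid_spacing)
}
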