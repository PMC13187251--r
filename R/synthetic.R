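#' Specification of a synthetic organ phantom
#'
#' Describes a 3-D organ-like volume used to exercise the whole pipeline
#' with known ground truth. The phantom emulates the premise of sparse
#' whole-mount sampling: coarse anatomy (large smooth blobs, the organ
#' outline) persists between adjacent sparse sections, while fine
#' structures (small blobs) appear and disappear. Voxels are anisotropic:
#' `voxel_size` um in-plane and `section_spacing` um between sections, so
#' the default 256 x 256 x 96 grid spans roughly a 10 mm cross-section
#' over 38 mm of depth and a 4000 um slice interval yields ~10 slides.
#'
#' The structure-size invariants are enforced: coarse structures must be
#' thicker than the slice interval (diameter taken as 4 sigma), fine
#' structures thinner.
#'
#' @param volume_shape `c(nx, ny, nz)` voxels.
#' @param voxel_size in-plane spacing, um/voxel.
#' @param section_spacing through-plane spacing, um/section.
#' @param slice_interval default slicing interval for [slice_volume()],
#'   um (multiple of `section_spacing`).
#' @param n_coarse,n_fine numbers of random coarse / fine blobs.
#' @param coarse_sigma_z,fine_sigma_z through-plane Gaussian sigma of the
#'   blobs, in sections.
#' @param coarse_sigma_xy,fine_sigma_xy in-plane sigma range, voxels.
#' @param organ list with in-plane semi-axis fractions `ax`, `by` of the
#'   half-extent, superellipse exponent `p`, egg-shape asymmetry factor
#'   `egg` (fractional widening of the minor axis toward one end of the
#'   major axis — guarantees the outline has no 180-degree self-symmetry),
#'   per-section rotation drift `rot_drift` (deg/section) and center
#'   drift `center_drift` (voxels/section).
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(256, 256, 96), voxel_size = 40,
                         section_spacing = 400, slice_interval = 4000,
                         n_coarse = 4, n_fine = 30,
                         coarse_sigma_z = 8, fine_sigma_z = 0.8,
                         coarse_sigma_xy = c(12, 22), fine_sigma_xy = c(2, 4),
                         organ = list(ax = 0.62, by = 0.45, p = 2.5,
                                      egg = 0.22, rot_drift = 0.1,
                                      center_drift = 0.08),
                         seed = 1L) {
  spec <- list(volume_shape = as.integer(volume_shape),
               voxel_size = voxel_size, section_spacing = section_spacing,
               slice_interval = slice_interval,
               n_coarse = n_coarse, n_fine = n_fine,
               coarse_sigma_z = coarse_sigma_z, fine_sigma_z = fine_sigma_z,
               coarse_sigma_xy = coarse_sigma_xy, fine_sigma_xy = fine_sigma_xy,
               organ = organ, seed = as.integer(seed))
  coarse_diam <- 4 * coarse_sigma_z * section_spacing
  fine_diam <- 4 * fine_sigma_z * section_spacing
  if (coarse_diam <= slice_interval) {
    stop(errorCondition(
      sprintf("coarse structure diameter (%g um) must exceed the slice interval (%g um)",
              coarse_diam, slice_interval),
      class = c("histostack_config_error", "error")))
  }
  if (fine_diam >= slice_interval) {
    stop(errorCondition(
      sprintf("fine structure diameter (%g um) must be below the slice interval (%g um)",
              fine_diam, slice_interval),
      class = c("histostack_config_error", "error")))
  }
  structure(spec, class = "phantom_spec")
}

# separable Gaussian blob block within a +-3.5 sigma bounding box; the
# caller adds it in place (returning the full volume from a helper would
# copy ~50 MB per blob)
blob_block <- function(d, cx, cy, cz, sx, sy, sz, amp) {
  rx <- max(1L, ceiling(cx - 3.5 * sx)):min(d[2], floor(cx + 3.5 * sx))
  ry <- max(1L, ceiling(cy - 3.5 * sy)):min(d[1], floor(cy + 3.5 * sy))
  rz <- max(1L, ceiling(cz - 3.5 * sz)):min(d[3], floor(cz + 3.5 * sz))
  if (!length(rx) || !length(ry) || !length(rz)) return(NULL)
  gx <- exp(-0.5 * ((rx - cx) / sx)^2)
  gy <- exp(-0.5 * ((ry - cy) / sy)^2)
  gz <- exp(-0.5 * ((rz - cz) / sz)^2)
  list(rx = rx, ry = ry, rz = rz, blk = (gy %o% gx) %o% gz * amp)
}

#' Generate a synthetic organ phantom
#'
#' Builds the component fields of a 3-D organ-like volume: a smoothly
#' tapering, slowly rotating and drifting superellipse organ outline
#' (asymmetry is guaranteed by a planted off-center nodule that follows
#' the organ through all sections, so 180-degree flips are detectable),
#' coarse blobs persisting across adjacent sparse sections, fine blobs
#' decorrelating between them, and >= 2 vertical fiducial rods traversing
#' every section (the synthetic analog of laser-induced landmark holes).
#' RGB sections in an H&E-like palette are composed on demand by
#' [phantom_section()]; the full RGB volume is never materialized.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom` with the component fields, per-z
#'   organ pose tables and fiducial coordinates.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$volume_shape[1]; ny <- spec$volume_shape[2]
  nz <- spec$volume_shape[3]
  cx0 <- (nx - 1) / 2; cy0 <- (ny - 1) / 2; zc <- (nz + 1) / 2
  A <- spec$organ$ax * nx / 2; B <- spec$organ$by * ny / 2
  z <- seq_len(nz)
  scale_z <- sqrt(pmax(1 - ((z - zc) / (0.62 * nz))^2, 0.12))
  ang_z <- spec$organ$rot_drift * (z - zc)
  cx_z <- cx0 + spec$organ$center_drift * (z - zc)
  cy_z <- cy0 + 0.5 * spec$organ$center_drift * (z - zc)
  with_seed(spec$seed, {
    coarse <- array(0, c(ny, nx, nz))
    fine <- array(0, c(ny, nx, nz))
    dm <- dim(coarse)
    # planted off-center nodule: a coarse rod following the organ pose
    # through every section -> breaks 180-degree symmetry at all z
    for (zz in z) {
      th <- ang_z[zz] * pi / 180
      ox <- 0.45 * A * scale_z[zz]; oy <- 0.18 * B * scale_z[zz]
      b <- blob_block(dm,
                      cx_z[zz] + ox * cos(th) - oy * sin(th),
                      cy_z[zz] + ox * sin(th) + oy * cos(th),
                      zz, 0.28 * A * scale_z[zz], 0.26 * B * scale_z[zz],
                      0.8, 1.2)
      if (!is.null(b)) coarse[b$ry, b$rx, b$rz] <- coarse[b$ry, b$rx, b$rz] + b$blk
    }
    for (i in seq_len(spec$n_coarse)) {
      b <- blob_block(dm,
                      cx0 + stats::runif(1, -0.35, 0.35) * A,
                      cy0 + stats::runif(1, -0.35, 0.35) * B,
                      stats::runif(1, 0.15, 0.85) * nz,
                      stats::runif(1, spec$coarse_sigma_xy[1], spec$coarse_sigma_xy[2]),
                      stats::runif(1, spec$coarse_sigma_xy[1], spec$coarse_sigma_xy[2]),
                      spec$coarse_sigma_z, stats::runif(1, 0.5, 1))
      if (!is.null(b)) coarse[b$ry, b$rx, b$rz] <- coarse[b$ry, b$rx, b$rz] + b$blk
    }
    for (i in seq_len(spec$n_fine)) {
      b <- blob_block(dm,
                      cx0 + stats::runif(1, -0.6, 0.6) * A,
                      cy0 + stats::runif(1, -0.6, 0.6) * B,
                      stats::runif(1, 1, nz),
                      stats::runif(1, spec$fine_sigma_xy[1], spec$fine_sigma_xy[2]),
                      stats::runif(1, spec$fine_sigma_xy[1], spec$fine_sigma_xy[2]),
                      spec$fine_sigma_z, stats::runif(1, 0.5, 1))
      if (!is.null(b)) fine[b$ry, b$rx, b$rz] <- fine[b$ry, b$rx, b$rz] + b$blk
    }
    # fiducial rods: vertical, inside the organ core at every z
    rods <- data.frame(
      rod = 1:3,
      x = cx0 + c(-0.35, 0.3, 0) * A * min(scale_z),
      y = cy0 + c(0.15, -0.2, 0.3) * B * min(scale_z))
    structure(list(spec = spec, coarse = coarse, fine = fine,
                   organ = list(A = A, B = B, p = spec$organ$p,
                                egg = spec$organ$egg,
                                scale_z = scale_z, ang_z = ang_z,
                                cx_z = cx_z, cy_z = cy_z),
                   fiducials = rods, nx = nx, ny = ny, nz = nz),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%dx%d voxels, %d fiducial rod(s), seed %d\n",
              x$nx, x$ny, x$nz, nrow(x$fiducials), x$spec$seed))
  invisible(x)
}

#' Organ mask of one phantom section
#'
#' @param phantom a [generate_phantom()] result.
#' @param z 1-based section index.
#' @return Logical `ny x nx` matrix.
#' @export
phantom_mask <- function(phantom, z) {
  og <- phantom$organ
  nx <- phantom$nx; ny <- phantom$ny
  xs <- (seq_len(nx) - 1) - og$cx_z[z]
  ys <- (seq_len(ny) - 1) - og$cy_z[z]
  th <- og$ang_z[z] * pi / 180
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  s <- og$scale_z[z]
  # egg-shaped outline: the minor axis widens toward one end of the major
  # axis, so the section has no 180-degree self-symmetry even in outline
  b_eff <- og$B * s * (1 + og$egg * pmin(pmax(U / (og$A * s), -1), 1))
  (abs(U / (og$A * s))^og$p + abs(V / b_eff)^og$p) <= 1
}

#' Compose the RGB raster of one phantom section
#'
#' White background; organ tissue in an H&E-like pink, coarse structures
#' blended toward purple, fine structures toward dark purple; fiducial
#' rods as near-black discs.
#'
#' @param phantom a [generate_phantom()] result.
#' @param z 1-based section index.
#' @return Numeric `ny x nx x 3` array in `[0, 1]`.
#' @export
phantom_section <- function(phantom, z) {
  stopifnot(z >= 1, z <= phantom$nz)
  ny <- phantom$ny; nx <- phantom$nx
  m <- phantom_mask(phantom, z)
  cf <- pmin(phantom$coarse[, , z], 1)
  ff <- pmin(phantom$fine[, , z], 1) * 0.85
  pink <- c(0.91, 0.72, 0.84); purple <- c(0.58, 0.39, 0.66)
  dark <- c(0.33, 0.22, 0.45)
  img <- array(1, c(ny, nx, 3))
  for (c in 1:3) {
    tissue <- pink[c] * (1 - cf) + purple[c] * cf
    tissue <- tissue * (1 - ff) + dark[c] * ff
    plane <- img[, , c]
    plane[m] <- tissue[m]
    img[, , c] <- plane
  }
  # fiducial rods traverse all sections
  X <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny) - 1, times = nx), ny, nx)
  rod_col <- c(0.08, 0.08, 0.10)
  for (r in seq_len(nrow(phantom$fiducials))) {
    d <- (X - phantom$fiducials$x[r])^2 + (Y - phantom$fiducials$y[r])^2 <= 2.5^2
    for (c in 1:3) { plane <- img[, , c]; plane[d] <- rod_col[c]
                     img[, , c] <- plane }
  }
  img
}

#' Ground-truth record of a (possibly perturbed) phantom stack
#'
#' Stores the exact planted per-slide rigid perturbations (identity for a
#' freshly sliced stack), flip flags, the transformed fiducial landmark
#' coordinates, and the sampling region the oracle backend draws true
#' correspondences from. Applying `transforms[[i]]` to the unperturbed
#' section reproduces the perturbed slide exactly.
#'
#' @name ground_truth_record
NULL

new_ground_truth <- function(k, ids, dim_xy, landmarks, sample_center,
                             sample_radius, spacing, section_z) {
  ctr <- c((dim_xy[1] - 1) / 2, (dim_xy[2] - 1) / 2)
  structure(list(theta = numeric(k),
                 translations = matrix(0, k, 2),
                 flips = logical(k),
                 transforms = replicate(k, rigid_transform(0, 0, 0, ctr),
                                        simplify = FALSE),
                 landmarks = landmarks, sample_center = sample_center,
                 sample_radius = sample_radius, spacing = spacing,
                 section_z = section_z, ids = ids, image_dim = dim_xy),
            class = "ground_truth_record")
}

#' @export
print.ground_truth_record <- function(x, ...) {
  cat(sprintf("<ground_truth_record> k=%d, max |rot| %.1f deg, %d flip(s)\n",
              length(x$theta), max(abs(x$theta)), sum(x$flips)))
  invisible(x)
}

#' Slice a phantom into a slide stack with ground truth
#'
#' Takes axial sections at `interval` (a multiple of the phantom's
#' section spacing), then keeps one out of every `take_every_n` of them —
#' the subsampling protocol used to emulate increasingly sparse sampling.
#' Landmarks are subsampled consistently with the slides.
#'
#' @param phantom a [generate_phantom()] result.
#' @param interval slicing interval in um; default from the spec.
#' @param take_every_n keep every n-th slice (default 1).
#' @param max_slides optional cap on the number of slides; the kept
#'   slides are a contiguous window centered on the middle of the stack
#'   (used by experiments that vary the inter-slide distance at constant
#'   stack size).
#' @return List with `stack` (a [slide_stack()]) and `ground_truth` (an
#'   unperturbed ground-truth record).
#' @export
slice_volume <- function(phantom, interval = phantom$spec$slice_interval,
                         take_every_n = 1L, max_slides = NULL) {
  sp <- phantom$spec
  step <- interval / sp$section_spacing
  if (abs(step - round(step)) > 1e-9 || step < 1) {
    stop(errorCondition("interval must be a positive multiple of the section spacing",
                        class = c("histostack_config_error", "error")))
  }
  z_idx <- seq(1L, phantom$nz, by = as.integer(round(step)))
  z_idx <- z_idx[seq(1L, length(z_idx), by = as.integer(take_every_n))]
  if (!is.null(max_slides) && length(z_idx) > max_slides) {
    lo <- (length(z_idx) - max_slides) %/% 2 + 1L
    z_idx <- z_idx[lo:(lo + max_slides - 1L)]
  }
  if (length(z_idx) < 2) {
    stop(errorCondition("subsampling leaves fewer than 2 slides",
                        class = c("histostack_config_error", "error")))
  }
  ids <- sprintf("z%03d", z_idx)
  slides <- lapply(seq_along(z_idx), function(i)
    slide_image(phantom_section(phantom, z_idx[i]), spacing = sp$voxel_size,
                id = ids[i]))
  stack <- slide_stack(slides, slice_interval = interval * take_every_n)
  lm <- do.call(rbind, lapply(ids, function(id)
    data.frame(slide_id = id, x = phantom$fiducials$x,
               y = phantom$fiducials$y, rod = phantom$fiducials$rod)))
  og <- phantom$organ
  smin <- min(og$scale_z[z_idx])
  gt <- new_ground_truth(
    k = length(z_idx), ids = ids, dim_xy = c(phantom$nx, phantom$ny),
    landmarks = lm,
    sample_center = c(mean(og$cx_z[z_idx]), mean(og$cy_z[z_idx])),
    sample_radius = 0.55 * min(og$A, og$B) * smin,
    spacing = sp$voxel_size, section_z = z_idx)
  list(stack = stack, ground_truth = gt)
}

#' Apply random rigid perturbations and stain jitter to a stack
#'
#' Each slide receives an independent random rotation (uniform in
#' `rotation_range`), translation (uniform in `[-max_translation,
#' max_translation]` per axis), optionally a planted 180-degree flip, and
#' channel-wise affine color jitter. Horizontal mirror flips are never
#' generated (the workflow's precondition is that mirrored slides have
#' been corrected upstream). The ground-truth record receives the exact
#' planted transforms and the transformed landmark coordinates.
#'
#' @param stack a [slide_stack()].
#' @param ground_truth the stack's [ground_truth_record].
#' @param seed integer seed (deterministic perturbations).
#' @param rotation_range degrees, default `c(0, 360)`.
#' @param max_translation pixels, per axis.
#' @param flip_probability probability of planting an extra 180-degree
#'   flip on a slide (default 0).
#' @param planted_flips optional logical k-vector overriding random flips.
#' @param stain_jitter standard deviation of the channel-wise color jitter
#'   (0 disables).
#' @return List with perturbed `stack` and updated `ground_truth`.
#' @export
perturb_stack <- function(stack, ground_truth, seed = 1,
                          rotation_range = c(0, 360), max_translation = 10,
                          flip_probability = 0, planted_flips = NULL,
                          stain_jitter = 0.02) {
  stopifnot(inherits(stack, "slide_stack"),
            inherits(ground_truth, "ground_truth_record"))
  k <- stack$k
  gt <- ground_truth
  with_seed(seed, {
    for (i in seq_len(k)) {
      px <- slide_pixels(stack$slides[[i]])
      ctr <- c((dim(px)[2] - 1) / 2, (dim(px)[1] - 1) / 2)
      th <- stats::runif(1, rotation_range[1], rotation_range[2])
      fl <- if (!is.null(planted_flips)) planted_flips[i]
            else stats::runif(1) < flip_probability
      tr <- stats::runif(2, -max_translation, max_translation)
      P <- rigid_transform(th + 180 * fl, tr[1], tr[2], center = ctr)
      warped <- warp_image(px, P, interpolation = "bilinear", fill = 1)
      if (stain_jitter > 0) {
        sc <- 1 + stats::rnorm(3, 0, stain_jitter)
        off <- stats::rnorm(3, 0, stain_jitter / 2)
        for (c in 1:3) warped[, , c] <- pmin(pmax(warped[, , c] * sc[c] + off[c], 0), 1)
      }
      stack$slides[[i]]$rasters[[1]] <- warped
      gt$transforms[[i]] <- compose_rigid(P, gt$transforms[[i]], center = ctr)
      gt$theta[i] <- gt$transforms[[i]]$theta
      gt$translations[i, ] <- c(gt$transforms[[i]]$tx, gt$transforms[[i]]$ty)
      gt$flips[i] <- xor(gt$flips[i], fl)
      sel <- gt$landmarks$slide_id == gt$ids[i]
      gt$landmarks[sel, c("x", "y")] <-
        apply_rigid(P, as.matrix(gt$landmarks[sel, c("x", "y")]))
    }
    list(stack = stack, ground_truth = gt)
  })
}
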