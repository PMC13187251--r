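# Shared fixtures: all synthetic, built in code at test time.

# A small phantom for unit tests: 5 slides, runs in well under a second.
tiny_spec <- function(seed = 1L) {
  # stronger egg asymmetry than the default: at 128 px the asymmetric
  # outline must remain several cells wide for flip tests to be decidable
  phantom_spec(volume_shape = c(128, 128, 48), voxel_size = 40,
               section_spacing = 400, slice_interval = 4000,
               n_coarse = 3, n_fine = 15,
               organ = list(ax = 0.62, by = 0.45, p = 2.5, egg = 0.35,
                            rot_drift = 0.1, center_drift = 0.08),
               seed = seed)
}

tiny_stack <- function(seed = 1L, perturb = TRUE, perturb_seed = seed + 100L,
                       rotation_range = c(0, 360), max_translation = 6,
                       ...) {
  sl <- slice_volume(generate_phantom(tiny_spec(seed)))
  if (!perturb) return(sl)
  perturb_stack(sl$stack, sl$ground_truth, seed = perturb_seed,
                rotation_range = rotation_range,
                max_translation = max_translation, ...)
}

tiny_config <- function(...) {
  pipeline_config(target_pixels = 128, seed = 7, ...)
}

# Planted rigid correspondences: n inlier points under (theta, t), plus
# n_out outliers displaced by at least `min_offset`.
planted_matches <- function(n = 100, theta = 30, t = c(5, -7), noise_sd = 0,
                            n_out = 0, min_offset = 10, extent = 200,
                            seed = 1) {
  set.seed(seed)
  a <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- t(R %*% t(a)) + matrix(t, n, 2, byrow = TRUE)
  if (noise_sd > 0) b <- b + matrix(rnorm(2 * n, 0, noise_sd), n, 2)
  inlier <- rep(TRUE, n)
  if (n_out > 0) {
    idx <- seq_len(n_out)
    for (j in idx) {
      repeat {
        cand <- runif(2, 0, extent)
        if (sqrt(sum((cand - b[j, ])^2)) >= min_offset) break
      }
      b[j, ] <- cand
    }
    inlier[idx] <- FALSE
  }
  list(matches = match_set(a, b), planted_inlier = inlier,
       theta = theta, t = t)
}

# Exhaustive between-class-variance maximizer: the independent oracle
# for the histogram threshold (explicit per-threshold class statistics,
# no cumulative-moment shortcuts).
brute_force_otsu <- function(counts) {
  vals <- 0:255
  best_t <- 0L; best_v <- -Inf
  for (t in 0:254) {
    n0 <- sum(counts[vals <= t]); n1 <- sum(counts[vals > t])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(vals[vals <= t] * counts[vals <= t]) / n0
    mu1 <- sum(vals[vals > t] * counts[vals > t]) / n1
    w0 <- n0 / sum(counts); w1 <- n1 / sum(counts)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Independent closed-form rigid least squares via the complex-number
# formulation (rotation from the argument of the centered
# cross-covariance) -- used as the oracle against estimate_rigid().
oracle_rigid_fit <- function(A, B) {
  za <- complex(real = A[, 1], imaginary = A[, 2])
  zb <- complex(real = B[, 1], imaginary = B[, 2])
  ca <- mean(za); cb <- mean(zb)
  rot <- sum(Conj(za - ca) * (zb - cb))
  rot <- rot / Mod(rot)
  list(theta = Arg(rot) * 180 / pi,
       t = c(Re(cb - rot * ca), Im(cb - rot * ca)))
}

# A filled-disk RGB image (dark disk on white), for mask tests.
disk_image <- function(side = 128, cx = (side - 1) / 2, cy = (side - 1) / 2,
                       radius = 40, value = 0.3) {
  X <- matrix(rep(seq_len(side) - 1, each = side), side, side)
  Y <- matrix(rep(seq_len(side) - 1, times = side), side, side)
  m <- (X - cx)^2 + (Y - cy)^2 <= radius^2
  img <- array(1, c(side, side, 3))
  for (c in 1:3) { p <- img[, , c]; p[m] <- value; img[, , c] <- p }
  list(image = img, mask = m)
}

# Solid (super)ellipse mask with optional rotation, for moment tests.
ellipse_mask <- function(side = 512, a = 200, b = 100, angle = 0,
                         cx = (side - 1) / 2, cy = (side - 1) / 2) {
  X <- matrix(rep(seq_len(side) - 1, each = side), side, side) - cx
  Y <- matrix(rep(seq_len(side) - 1, times = side), side, side) - cy
  th <- angle * pi / 180
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  (U / a)^2 + (V / b)^2 <= 1
}
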