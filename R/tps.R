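#' Thin-plate-spline deformation field (backward-map semantics)
#'
#' A smooth 2-D displacement field defined by control points and their
#' displacements, interpolated with the thin-plate radial basis
#' `U(r) = r^2 log(r)` plus an affine part, minimizing bending energy.
#' The field is evaluated in the *output* frame and returns the
#' displacement to add to the rigidly back-projected source coordinate;
#' invertibility is not guaranteed and never needed.
#'
#' The affine side conditions (`sum w = 0`, `sum w * p = 0`) are enforced
#' through the standard bordered system, which makes the interpolant
#' exactly equivariant under similarity transforms of the plane — the
#' property [scale_deformable()] relies on to move a field between
#' resolution levels without re-fitting to matches.
#'
#' @param points n x 2 matrix of control-point locations (x, y), pixels.
#' @param displacements n x 2 matrix of displacement vectors at the
#'   control points, pixels.
#' @param regularization non-negative smoothing weight added to the kernel
#'   diagonal; 0 gives exact interpolation.
#' @param grid_spacing optional spacing (pixels) when the control points
#'   lie on a Cartesian grid; bookkeeping only.
#' @return An object of class `deformation_field`.
#' @export
fit_deformation <- function(points, displacements, regularization = 0,
                            grid_spacing = NA_real_) {
  points <- as.matrix(points); displacements <- as.matrix(displacements)
  stopifnot(ncol(points) == 2, ncol(displacements) == 2,
            nrow(points) == nrow(displacements),
            is.numeric(regularization), regularization >= 0)
  n <- nrow(points)
  if (n < 3 || qr(cbind(1, points))$rank < 3) {
    stop(errorCondition("need at least 3 non-collinear control points",
                        class = c("histostack_degenerate_tps", "error")))
  }
  K <- tps_kernel(points, points) + diag(regularization, n)
  P <- cbind(1, points)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(displacements, matrix(0, 3, 2))
  sol <- solve(A, rhs)
  structure(list(points = points, displacements = displacements,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:3, , drop = FALSE],
                 regularization = regularization,
                 grid_spacing = grid_spacing),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %d control points, lambda=%g, grid=%s px\n",
              nrow(x$points), x$regularization,
              ifelse(is.na(x$grid_spacing), "irregular", format(x$grid_spacing))))
  invisible(x)
}

# U(r) = r^2 log r, with U(0) = 0; pairwise between row sets a (m x 2)
# and b (n x 2).
tps_kernel <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  k <- matrix(0, nrow(a), nrow(b))
  pos <- d2 > 0
  k[pos] <- 0.5 * d2[pos] * log(d2[pos])  # r^2 log r = d2 * log(sqrt(d2))
  k
}

#' Evaluate a deformation field at points
#'
#' @param field a [fit_deformation()] result.
#' @param pts m x 2 matrix of (x, y) locations.
#' @return m x 2 matrix of displacement vectors.
#' @export
eval_deformation <- function(field, pts) {
  stopifnot(inherits(field, "deformation_field"))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  U <- tps_kernel(as.matrix(pts), field$points)
  U %*% field$weights + cbind(1, as.matrix(pts)) %*% field$affine
}

#' Resample a deformation field onto a Cartesian control grid
#'
#' Evaluates the field at grid nodes covering `c(0, 0)`..`(w-1, h-1)` and
#' refits an interpolating spline through the nodes, so the stored control
#' points are regular and the field can be rescaled to any resolution
#' level.
#'
#' @param field a `deformation_field`.
#' @param out_shape `c(width, height)` of the frame to cover, pixels.
#' @param grid_spacing node spacing in pixels.
#' @return A `deformation_field` with gridded control points.
#' @export
grid_deformation <- function(field, out_shape, grid_spacing) {
  stopifnot(grid_spacing > 0, length(out_shape) == 2)
  xs <- seq(0, out_shape[1] - 1 + grid_spacing - 1e-9, by = grid_spacing)
  ys <- seq(0, out_shape[2] - 1 + grid_spacing - 1e-9, by = grid_spacing)
  nodes <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  disp <- eval_deformation(field, nodes)
  fit_deformation(nodes, disp, regularization = 0, grid_spacing = grid_spacing)
}

#' Scale a deformation field between resolution levels
#'
#' Control-point locations, displacements and grid spacing are multiplied
#' by `factor`; spline weights are recomputed from the scaled control
#' points only — no re-fitting to image matches. With the bordered-system
#' side conditions the scaled field satisfies
#' `eval(scale(f, s), s * p) == s * eval(f, p)` to numerical precision.
#' The smoothing weight scales as `factor^2`, which preserves the
#' smoothing-spline minimizer under coordinate scaling (bending energy is
#' scale-invariant in 2-D while squared residuals pick up `factor^2`).
#'
#' @param field a `deformation_field`.
#' @param factor positive resampling factor.
#' @return The rescaled `deformation_field`.
#' @export
scale_deformable <- function(field, factor) {
  stopifnot(inherits(field, "deformation_field"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop(errorCondition("scale factor must be a positive real",
                        class = c("histostack_bad_factor", "error")))
  }
  fit_deformation(field$points * factor, field$displacements * factor,
                  regularization = field$regularization * factor^2,
                  grid_spacing = field$grid_spacing * factor)
}
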