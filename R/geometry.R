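#' Rigid 2-D transform (rotation + translation about a center)
#'
#' A scale- and shear-free planar transform used for all stack alignment.
#' Acting on a point `p` (0-based pixel-center coordinates, x = column,
#' y = row): `p' = R(theta) (p - center) + center + t`, where `R` rotates
#' counter-clockwise in the (x, y) basis (with y pointing down the image
#' this appears clockwise on screen).
#'
#' Parameters are stored in level-0 physical pixel units unless a function
#' explicitly works in the processed frame; [scale_rigid()] converts
#' between resolution levels.
#'
#' @param theta rotation in degrees, normalized to (-180, 180].
#' @param tx,ty translation in pixels.
#' @param center rotation center `c(x, y)` in pixels.
#' @return An object of class `rigid_transform`.
#' @seealso [compose_rigid()], [invert_rigid()], [apply_rigid()], [scale_rigid()]
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(tx), is.numeric(ty), length(center) == 2L,
            all(is.finite(c(tx, ty, center))))
  out <- list(theta = unname(wrap_angle(theta)), tx = unname(as.numeric(tx)),
              ty = unname(as.numeric(ty)), center = unname(as.numeric(center)))
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> theta=%.4f deg, t=(%.3f, %.3f), center=(%.2f, %.2f)\n",
              x$theta, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Wrap an angle in degrees to (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return Angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Wrap an angle difference modulo 180 to (-90, 90]
#'
#' Used when matching ellipse orientations, which are only defined mod 180.
#' @param a numeric vector of angles in degrees.
#' @return Angles wrapped to (-90, 90].
#' @export
wrap_angle_180 <- function(a) {
  w <- (a + 90) %% 180 - 90
  w[w == -90] <- 90
  w
}

#' Homogeneous 3x3 matrix of a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return A 3x3 numeric matrix acting on column vectors `c(x, y, 1)`.
#' @export
rigid_matrix <- function(t) {
  stopifnot(is_rigid_transform(t))
  th <- t$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- as.numeric(t$center + c(t$tx, t$ty) - R %*% t$center)
  rbind(cbind(R, b), c(0, 0, 1))
}

#' Recover a rigid transform from a homogeneous matrix
#'
#' The linear part must be a pure rotation (determinant 1, singular values
#' 1 within `tol`); otherwise an error of class `histostack_not_rigid` is
#' raised. The returned parameterization uses the supplied `center`.
#'
#' @param M 3x3 homogeneous matrix.
#' @param center rotation center to parameterize about.
#' @param tol tolerance on the singular values of the linear part.
#' @return A [rigid_transform()].
#' @export
rigid_from_matrix <- function(M, center = c(0, 0), tol = 1e-9) {
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  A <- M[1:2, 1:2]
  sv <- svd(A)$d
  if (det(A) < 0 || any(abs(sv - 1) > tol)) {
    stop(errorCondition(
      sprintf("linear part is not a pure rotation (singular values %.3g, %.3g)",
              sv[1], sv[2]),
      class = c("histostack_not_rigid", "error")))
  }
  theta <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  # t = A c + b - c
  b <- M[1:2, 3]
  tr <- as.numeric(A %*% center + b - center)
  rigid_transform(theta, tr[1], tr[2], center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#' The result is parameterized about `center` (default: `second$center`).
#'
#' @param second,first [rigid_transform()] objects.
#' @param center rotation center of the composed transform.
#' @return A [rigid_transform()].
#' @export
compose_rigid <- function(second, first, center = second$center) {
  rigid_from_matrix(rigid_matrix(second) %*% rigid_matrix(first), center = center,
                    tol = 1e-6)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @param center rotation center of the inverse (default: same as `t`).
#' @return The inverse [rigid_transform()].
#' @export
invert_rigid <- function(t, center = t$center) {
  rigid_from_matrix(solve(rigid_matrix(t)), center = center, tol = 1e-6)
}

#' Apply a rigid transform to points
#'
#' @param t a [rigid_transform()].
#' @param pts n x 2 matrix of (x, y) coordinates (a length-2 vector is
#'   treated as one point).
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_rigid <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  stopifnot(ncol(pts) == 2)
  M <- rigid_matrix(t)
  out <- cbind(pts, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}

#' Scale a rigid transform between resolution levels
#'
#' Rotation is resolution-independent; translation and center scale
#' linearly with the resampling factor, so a transform estimated at a
#' coarse processing resolution can be applied at any pyramid level.
#'
#' @param t a [rigid_transform()].
#' @param factor positive real; ratio of target resolution to the
#'   resolution `t` is expressed in (e.g. 4 when going from a level with
#'   4x the pixel pitch down to level 0).
#' @return The rescaled [rigid_transform()].
#' @export
scale_rigid <- function(t, factor) {
  stopifnot(is_rigid_transform(t))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop(errorCondition("scale factor must be a positive real",
                        class = c("histostack_bad_factor", "error")))
  }
  rigid_transform(t$theta, t$tx * factor, t$ty * factor, t$center * factor)
}

# Run code with a private RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards. Keeps all package randomness
# reproducible without clobbering the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic expansion of one user seed into per-stage sub-seeds.
stage_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  offsets <- c(preprocess = 11L, flips = 23L, align = 37L, match = 53L,
               perturb = 71L, synth = 89L, metrics = 97L)
  off <- offsets[[stage]]
  (as.integer(seed) * 127L + off * 1009L + as.integer(index) * 101L) %% 2147483587L
}
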