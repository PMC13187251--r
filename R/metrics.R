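#' Orientation accuracy of a reconstruction
#'
#' Compares predicted and ground-truth per-slide rotations relative to
#' the reference slide, on the circle (wrap-aware). A case counts as an
#' accurate reconstruction when every slide's absolute deviation from the
#' ground-truth rotation, measured with respect to the reference frame,
#' is at most `threshold` degrees (default 15).
#'
#' @param pred numeric k-vector of predicted absolute rotations (degrees).
#' @param truth numeric k-vector of ground-truth absolute rotations; pass
#'   the restoring angles so that `pred - truth` is constant across
#'   slides for a perfect reconstruction.
#' @param reference_index 1-based reference slide (default: middle slide).
#' @param threshold maximum allowed absolute deviation in degrees.
#' @return An object of class `orientation_report`: signed per-slide
#'   `deviation` in `(-180, 180]` (reference exactly 0), per-slide `pass`
#'   flags, `case_accurate`, `threshold`, `reference_index`.
#' @export
orientation_accuracy <- function(pred, truth,
                                 reference_index = NULL, threshold = 15) {
  if (length(pred) != length(truth)) {
    stop(errorCondition("pred and truth must have equal length",
                        class = c("histostack_config_error", "error")))
  }
  stopifnot(all(is.finite(pred)), all(is.finite(truth)))
  k <- length(pred)
  r <- if (is.null(reference_index)) reference_index(k) else reference_index
  dev <- wrap_angle((pred - truth) - (pred[r] - truth[r]))
  dev[r] <- 0
  pass <- abs(dev) <= threshold
  structure(list(deviation = dev, pass = pass,
                 case_accurate = all(pass), threshold = threshold,
                 reference_index = r),
            class = "orientation_report")
}

#' @export
print.orientation_report <- function(x, ...) {
  cat(sprintf("<orientation_report> case %s (threshold %g deg), max |dev| %.2f\n",
              ifelse(x$case_accurate, "ACCURATE", "failed"), x$threshold,
              max(abs(x$deviation))))
  invisible(x)
}

#' Pairwise overlap of a registered stack
#'
#' For each of the k-1 adjacent pairs, the intersection area of the two
#' registered tissue masks divided by the smaller mask's area (natural
#' tissue size differences between adjacent sections are not penalized);
#' `O` is the mean over pairs. An empty mask makes its pairs' overlap 0
#' with a flag.
#'
#' @param masks list of k registered binary masks (equal dimensions), or
#'   an `H x W x k` array.
#' @return An object of class `overlap_report`: `per_pair` (k-1 values in
#'   `[0, 1]`), `O` (their mean), `empty_pairs` flags.
#' @export
overlap <- function(masks) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  }
  masks <- lapply(masks, function(m) as_mask_matrix(m) > 0.5)
  k <- length(masks)
  stopifnot(k >= 2)
  per <- numeric(k - 1); empty <- logical(k - 1)
  for (n in seq_len(k - 1)) {
    a <- sum(masks[[n]]); b <- sum(masks[[n + 1]])
    if (a == 0 || b == 0) { per[n] <- 0; empty[n] <- TRUE; next }
    per[n] <- sum(masks[[n]] & masks[[n + 1]]) / min(a, b)
  }
  structure(list(per_pair = per, O = mean(per), empty_pairs = empty),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> O = %.4f over %d pair(s)\n", x$O,
              length(x$per_pair)))
  invisible(x)
}

#' Target registration error of a registered stack
#'
#' For each adjacent pair, the median Euclidean distance over its matched
#' coordinate pairs; the TRE is the mean of the per-pair medians. Values
#' are reported in pixels and, when a spacing is supplied, in mm
#' (`pixels * spacing / 1000`).
#'
#' @param pairs list of k-1 [match_set()] objects (or lists/data frames
#'   with `points_a`, `points_b`), each with `m >= 1` correspondences.
#' @param spacing micrometres/pixel of the frame the coordinates live in,
#'   or `NULL` for pixel-only reporting.
#' @return An object of class `tre_report`: `per_pair_px` medians,
#'   `TRE_px`, `TRE_mm` (or `NA`), `spacing`, `skipped` flags (all
#'   `FALSE` here; see [estimated_tre()]).
#' @export
tre <- function(pairs, spacing = NULL) {
  stopifnot(length(pairs) >= 1)
  med <- vapply(pairs, function(p) {
    pa <- p$points_a; pb <- p$points_b
    if (is.null(pa) || nrow(pa) == 0) {
      stop(errorCondition("a pair has no correspondences",
                          class = c("histostack_config_error", "error")))
    }
    stats::median(sqrt(rowSums((pa - pb)^2)))
  }, 0)
  structure(list(per_pair_px = med, TRE_px = mean(med),
                 TRE_mm = if (is.null(spacing)) NA_real_
                          else mean(med) * spacing / 1000,
                 spacing = if (is.null(spacing)) NA_real_ else spacing,
                 skipped = rep(FALSE, length(med))),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> TRE = %.3f px%s over %d pair(s)\n", x$TRE_px,
              ifelse(is.na(x$TRE_mm), "", sprintf(" (%.4f mm)", x$TRE_mm)),
              length(x$per_pair_px)))
  invisible(x)
}

#' Feature-estimated TRE of a registered stack
#'
#' Estimates the registration error without landmarks: for each adjacent
#' pair of the registered stack, dense matches are computed between the
#' slides as they stand (no transform is modified or applied), RANSAC
#' selects the inlier correspondences, and the TRE formula is evaluated
#' over the inlier pairs' coordinate distances. Works on stacks
#' registered by this package or externally. Pairs with insufficient
#' matches or no consensus are skipped, flagged, and excluded from the
#' mean.
#'
#' @param pstack a `processed_stack`.
#' @param align a [stack_alignment()] describing the registered poses
#'   (read-only).
#' @param backend a [feature_backend()].
#' @param seed integer seed.
#' @param threshold,iterations RANSAC parameters.
#' @param refine pixel-level refinement of matches (default `TRUE`):
#'   the error estimate needs continuous displacements, not cell-grid
#'   quantized ones.
#' @param ... passed to [dense_match()].
#' @return A `tre_report` (spacing = processing spacing) with `skipped`
#'   flags for failed pairs; `TRE_px` is `NA` if every pair failed.
#' @export
estimated_tre <- function(pstack, align, backend, seed = 1, threshold = 3,
                          iterations = 1000, refine = TRUE, ...) {
  k <- pstack$k
  med <- rep(NA_real_, k - 1); skipped <- logical(k - 1)
  views <- lapply(seq_len(k), function(i) posed_view(pstack, align, i))
  for (n in seq_len(k - 1)) {
    res <- tryCatch({
      ms <- withCallingHandlers(
        dense_match(views[[n]], views[[n + 1]], backend,
                    seed = stage_seed(seed, "metrics", n), refine = refine, ...),
        histostack_insufficient_matches = function(w) invokeRestart("muffleWarning"))
      est <- estimate_rigid(ms, seed = stage_seed(seed, "metrics", n),
                            threshold = threshold, iterations = iterations)
      inl <- est$matches$inlier
      stats::median(sqrt(rowSums((est$matches$points_a[inl, , drop = FALSE] -
                                  est$matches$points_b[inl, , drop = FALSE])^2)))
    }, histostack_insufficient_matches = function(e) NA_real_,
       histostack_no_consensus = function(e) NA_real_)
    med[n] <- res
    skipped[n] <- is.na(res)
  }
  ok <- !skipped
  structure(list(per_pair_px = med,
                 TRE_px = if (any(ok)) mean(med[ok]) else NA_real_,
                 TRE_mm = if (any(ok)) mean(med[ok]) * pstack$common_spacing / 1000
                          else NA_real_,
                 spacing = pstack$common_spacing, skipped = skipped),
            class = "tre_report")
}
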