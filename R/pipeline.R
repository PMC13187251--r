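default_config <- function() {
  list(feature_backend = "classical",
       target_pixels = 2000,
       feature_patch = 14,
       feature_side = NULL,
       min_confidence = 0.5,
       normalize_stains = TRUE,
       background = c(1, 1, 1),
       ransac = list(threshold = 3, iterations = 1000, max_rotation = 30),
       deformable = list(enabled = FALSE, grid_spacing = 32,
                         regularization = 0),
       tile_size = 512,
       output_levels = 3,
       accuracy_threshold = 15,
       seed = 1)
}

#' Pipeline configuration
#'
#' One configuration governs a whole run; every default is materialized
#' into the returned object (and echoed into the run manifest) and
#' unknown keys are rejected. The single `seed` is expanded
#' deterministically into per-stage seeds.
#'
#' @param ... overrides of the defaults: `feature_backend`
#'   (`"classical"`, `"oracle"`, `"pretrained"`), `target_pixels` (2000),
#'   `feature_patch` (14), `feature_side` (`NULL` = processed frame
#'   size), `min_confidence` (0.5), `normalize_stains` (`TRUE`),
#'   `background` (white), `ransac` (list: `threshold` 3 px,
#'   `iterations` 1000, `max_rotation` 30 deg), `deformable` (list: `enabled` FALSE,
#'   `grid_spacing` 32 px, `regularization` 0), `tile_size` (512),
#'   `output_levels` (3), `accuracy_threshold` (15 deg), `seed` (1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- default_config()
  for (key in names(user)) {
    if (!key %in% names(cfg)) {
      stop(errorCondition(paste0("unknown configuration key: ", key),
                          class = c("histostack_config_error", "error")))
    }
    if (is.list(cfg[[key]]) && !is.null(names(cfg[[key]]))) {
      sub <- user[[key]]
      bad <- setdiff(names(sub), names(cfg[[key]]))
      if (length(bad)) {
        stop(errorCondition(
          paste0("unknown configuration key: ", key, "$", bad[1]),
          class = c("histostack_config_error", "error")))
      }
      cfg[[key]][names(sub)] <- sub
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @param ... overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  pipeline_config(cfg)
}

resolve_backend <- function(config, backend = NULL, ground_truth = NULL) {
  if (!is.null(backend)) return(backend)
  if (config$feature_backend == "oracle") {
    feature_backend("oracle", ground_truth = ground_truth)
  } else {
    feature_backend(config$feature_backend)
  }
}

#' Reconstruct a stack of section images in three dimensions
#'
#' Runs the full pipeline in order: preprocessing (masking, stain
#' normalization, common-resolution resampling, square padding), ellipse
#' initialization to the middle-reference frame, 180-degree flip
#' resolution by global-feature cosine similarity, iterative outward
#' pairwise rigid refinement (RANSAC over dense matches), optional
#' thin-plate-spline refinement, and metric reports (orientation vs
#' ground truth when supplied, pairwise overlap, feature-estimated TRE).
#' Per-pair registration diagnostics and stage timings are collected in
#' the run manifest; the result is reproducible given the configuration
#' and seed.
#'
#' @param stack a [slide_stack()] (or list with `stack` and
#'   `ground_truth` as returned by [slice_volume()]/[perturb_stack()]).
#' @param config a [pipeline_config()].
#' @param backend optional [feature_backend()] overriding
#'   `config$feature_backend`.
#' @param ground_truth optional [ground_truth_record] enabling the oracle
#'   backend and the orientation report.
#' @param output_dir optional directory: writes `alignment.json`,
#'   `manifest.json` and registered slides as pyramidal TIFFs (tile
#'   streamed).
#' @return An object of class `reconstruction`: `alignment`, `pstack`,
#'   `reports` (orientation / overlap / estimated_tre), `manifest`,
#'   `config`.
#' @export
reconstruct <- function(stack, config = pipeline_config(), backend = NULL,
                        ground_truth = NULL, output_dir = NULL) {
  if (is.list(stack) && !inherits(stack, "slide_stack") &&
      !is.null(stack$stack)) {
    if (is.null(ground_truth)) ground_truth <- stack$ground_truth
    stack <- stack$stack
  }
  stopifnot(inherits(stack, "slide_stack"))
  backend <- resolve_backend(config, backend, ground_truth)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pstack <- build_processed_stack(stack, target_pixels = config$target_pixels,
                                  background = config$background,
                                  normalize = config$normalize_stains)
  timings["preprocess"] <- tic() - t0; t0 <- tic()
  align <- initialize_stack(pstack)
  timings["initialize"] <- tic() - t0; t0 <- tic()
  align <- resolve_flips(pstack, align, backend, side = config$feature_side,
                         patch = config$feature_patch)
  timings["resolve_flips"] <- tic() - t0; t0 <- tic()
  align <- align_stack(pstack, align, backend,
                       seed = config$seed,
                       threshold = config$ransac$threshold,
                       iterations = config$ransac$iterations,
                       max_rotation = config$ransac$max_rotation,
                       min_confidence = config$min_confidence,
                       patch = config$feature_patch)
  timings["align"] <- tic() - t0; t0 <- tic()
  if (isTRUE(config$deformable$enabled)) {
    r <- align$reference_index
    for (i in outward_order(pstack$k, r)) {
      j <- if (i > r) i - 1L else i + 1L
      fld <- tryCatch({
        ms <- withCallingHandlers(
          dense_match(posed_view(pstack, align, i),
                      posed_view(pstack, align, j), backend,
                      seed = stage_seed(config$seed, "match", i),
                      min_confidence = config$min_confidence,
                      patch = config$feature_patch),
          histostack_insufficient_matches = function(w)
            invokeRestart("muffleWarning"))
        est <- estimate_rigid(ms, seed = stage_seed(config$seed, "match", i),
                              threshold = config$ransac$threshold,
                              iterations = config$ransac$iterations)
        refine_deformable(est$matches, out_shape = c(pstack$dim, pstack$dim),
                          grid_spacing = config$deformable$grid_spacing,
                          regularization = config$deformable$regularization)
      }, error = function(e) NULL)
      align$deformable[i] <- list(fld)
    }
    timings["deformable"] <- tic() - t0; t0 <- tic()
  }
  reports <- list()
  reg_masks <- lapply(seq_len(pstack$k), function(i) warp_mask(pstack, align, i))
  reports$overlap <- overlap(reg_masks)
  reports$estimated_tre <- estimated_tre(
    pstack, align, backend, seed = config$seed,
    threshold = config$ransac$threshold,
    iterations = config$ransac$iterations,
    min_confidence = config$min_confidence, patch = config$feature_patch)
  if (!is.null(ground_truth)) {
    pred <- vapply(align$transforms, function(t) t$theta, 0)
    reports$orientation <- orientation_accuracy(
      pred, -ground_truth$theta, reference_index = align$reference_index,
      threshold = config$accuracy_threshold)
    reports$fiducial_tre <- fiducial_tre(pstack, align, ground_truth)
  }
  timings["metrics"] <- tic() - t0
  manifest <- list(
    package_version = as.character(utils::packageVersion("histostack")),
    config = unclass(config), backend = backend$id,
    k = pstack$k, processed_dim = pstack$dim,
    common_spacing = pstack$common_spacing,
    reference_index = align$reference_index,
    timings = as.list(round(timings, 3)),
    pair_diagnostics = align$pair_diagnostics)
  rec <- structure(list(alignment = align, pstack = pstack, reports = reports,
                        manifest = manifest, config = config),
                   class = "reconstruction")
  if (!is.null(output_dir)) write_reconstruction(rec, output_dir)
  rec
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> k=%d, overlap O=%.3f, est. TRE %.2f px\n",
              x$pstack$k, x$reports$overlap$O,
              x$reports$estimated_tre$TRE_px))
  if (!is.null(x$reports$orientation))
    cat(sprintf("  orientation: %s (max |dev| %.2f deg)\n",
                ifelse(x$reports$orientation$case_accurate, "ACCURATE", "failed"),
                max(abs(x$reports$orientation$deviation))))
  invisible(x)
}

#' Landmark (fiducial) TRE of a registered phantom stack
#'
#' Maps each slide's ground-truth landmark coordinates through its
#' processed-frame pose and evaluates the TRE formula over adjacent
#' pairs, matching landmarks by rod identity.
#'
#' @param pstack a `processed_stack`.
#' @param align a [stack_alignment()].
#' @param ground_truth a [ground_truth_record] with a `landmarks` table.
#' @return A `tre_report` in processed-frame pixels / mm.
#' @export
fiducial_tre <- function(pstack, align, ground_truth) {
  k <- pstack$k
  posed <- lapply(seq_len(k), function(i) {
    sel <- ground_truth$landmarks$slide_id == ground_truth$ids[i]
    lm <- ground_truth$landmarks[sel, ]
    lm <- lm[order(lm$rod), ]
    p <- to_processed_coords(pstack, i, as.matrix(lm[, c("x", "y")]))
    apply_rigid(align$transforms[[i]], p)
  })
  pairs <- lapply(seq_len(k - 1), function(n)
    match_set(posed[[n]], posed[[n + 1]]))
  tre(pairs, spacing = pstack$common_spacing)
}

#' Evaluate a registered stack (read-only)
#'
#' Produces the metric reports for an already registered stack — either a
#' [reconstruct()] result or a `processed_stack` with an alignment
#' (identity poses when `align` is `NULL`, for stacks registered
#' externally and loaded as-is). No transform is modified.
#'
#' @param pstack a `processed_stack` or a `reconstruction`.
#' @param align a [stack_alignment()]; `NULL` means the images are
#'   already in a common frame (identity poses).
#' @param ground_truth optional [ground_truth_record]: enables the
#'   orientation report and fiducial TRE.
#' @param backend a [feature_backend()] for the estimated TRE (default
#'   classical).
#' @param config a [pipeline_config()].
#' @return List of reports: `orientation` (if truth given), `overlap`,
#'   `estimated_tre`, `fiducial_tre` (if truth given).
#' @export
evaluate_stack <- function(pstack, align = NULL, ground_truth = NULL,
                           backend = NULL, config = pipeline_config()) {
  if (inherits(pstack, "reconstruction")) {
    if (is.null(align)) align <- pstack$alignment
    pstack <- pstack$pstack
  }
  if (is.null(align)) {
    ctr <- c((pstack$dim - 1) / 2, (pstack$dim - 1) / 2)
    align <- stack_alignment(reference_index(pstack$k),
                             replicate(pstack$k,
                                       rigid_transform(0, 0, 0, ctr),
                                       simplify = FALSE),
                             frame_center = ctr)
  }
  backend <- resolve_backend(config, backend, ground_truth)
  reports <- list()
  reg_masks <- lapply(seq_len(pstack$k), function(i) warp_mask(pstack, align, i))
  reports$overlap <- overlap(reg_masks)
  reports$estimated_tre <- estimated_tre(
    pstack, align, backend, seed = config$seed,
    threshold = config$ransac$threshold,
    iterations = config$ransac$iterations,
    min_confidence = config$min_confidence, patch = config$feature_patch)
  if (!is.null(ground_truth)) {
    pred <- vapply(align$transforms, function(t) t$theta, 0)
    reports$orientation <- orientation_accuracy(
      pred, -ground_truth$theta, reference_index = align$reference_index,
      threshold = config$accuracy_threshold)
    reports$fiducial_tre <- fiducial_tre(pstack, align, ground_truth)
  }
  reports
}

#' Express a slide's pose at its original level-0 resolution
#'
#' Conjugates the processed-frame pose with the slide's
#' original-to-processed affine (isotropic scale + pad offset), yielding
#' the rigid transform to apply to the original full-resolution raster.
#'
#' @param align a [stack_alignment()].
#' @param pstack the `processed_stack` the alignment was computed on.
#' @param i slide index.
#' @return A [rigid_transform()] in level-0 pixel units.
#' @export
alignment_at_level0 <- function(align, pstack, i) {
  f <- pstack$scale_factors[i]
  off <- pstack$pad_offsets[i, ] + (f - 1) / 2
  S <- rbind(c(f, 0, off[1]), c(0, f, off[2]), c(0, 0, 1))  # orig -> processed
  M <- solve(S) %*% rigid_matrix(align$transforms[[i]]) %*% S
  rigid_from_matrix(M, center = align$frame_center / f, tol = 1e-6)
}

#' Serialize an alignment to JSON
#'
#' Per-slide records `{id, theta, tx, ty, center, flip, level0_spacing,
#' scale_factor}` in stable order with fixed precision, so identical runs
#' produce byte-identical files.
#'
#' @param align a [stack_alignment()].
#' @param pstack the matching `processed_stack`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_alignment <- function(align, pstack, path) {
  slides <- lapply(seq_len(pstack$k), function(i) {
    t <- align$transforms[[i]]
    list(id = pstack$ids[i], theta = round(t$theta, 9),
         tx = round(t$tx, 6), ty = round(t$ty, 6),
         center = round(t$center, 6), flip = align$flips[i],
         level0_spacing = pstack$level0_spacings[i],
         scale_factor = round(pstack$scale_factors[i], 9))
  })
  jsonlite::write_json(
    list(reference_index = align$reference_index,
         common_spacing = pstack$common_spacing,
         frame_center = round(align$frame_center, 6), slides = slides),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_reconstruction <- function(rec, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  save_alignment(rec$alignment, rec$pstack,
                 file.path(output_dir, "alignment.json"))
  jsonlite::write_json(rec$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  D <- rec$pstack$dim
  ts <- rec$config$tile_size
  for (i in seq_len(rec$pstack$k)) {
    t_i <- composite_transform(rec$alignment$transforms[[i]],
                               rec$alignment$deformable[[i]])
    # stream warped tiles straight into the slide writer
    gen <- local({
      xs <- seq(0, D - 1, by = ts); ys <- seq(0, D - 1, by = ts)
      pos <- expand.grid(x0 = xs, y0 = ys)
      idx <- 0L
      function() {
        idx <<- idx + 1L
        if (idx > nrow(pos)) return(NULL)
        x0 <- pos$x0[idx]; y0 <- pos$y0[idx]
        tw <- min(ts, D - x0); th <- min(ts, D - y0)
        bm <- build_backward_map(t_i, c(D, D), tile = c(x0, y0, tw, th))
        list(tile = sample_image(rec$pstack$images[[i]], bm$sx, bm$sy,
                                 "bilinear", fill = 1),
             x0 = x0, y0 = y0)
      }
    })
    write_slide(gen, file.path(output_dir,
                               sprintf("registered_%02d_%s.tif", i,
                                       rec$pstack$ids[i])),
                spacing = rec$pstack$common_spacing, out_shape = c(D, D),
                n_levels = rec$config$output_levels)
  }
  invisible(output_dir)
}

#' Slice-distance experiment on synthetic phantoms
#'
#' Reconstructs the same phantoms at increasingly sparse subsampling
#' (one out of every n slices of a densely sliced stack) and records the
#' feature-estimated TRE of each reconstruction, emulating the protocol
#' of thinning a serially sectioned specimen. The stack size is held
#' constant (`max_slides`, centered window) so the estimate's variance
#' does not change with n; only the inter-slide distance does.
#'
#' @param take_every_n integer vector of subsampling factors.
#' @param seeds integer vector of phantom seeds.
#' @param spec_fn `function(seed)` returning the [phantom_spec()] to use.
#' @param interval base slicing interval passed to [slice_volume()];
#'   default: the phantom's section spacing (densest possible).
#' @param max_slides slides per reconstruction (default 6).
#' @param config a [pipeline_config()].
#' @param rotation_range,max_translation perturbation parameters.
#' @return `data.frame` with columns `seed`, `take_every_n`, `k`,
#'   `tre_px`.
#' @export
experiment_slice_distance <- function(take_every_n = 1:5, seeds = 1:5,
                                      spec_fn = function(seed)
                                        phantom_spec(seed = seed),
                                      interval = NULL, max_slides = 6,
                                      config = pipeline_config(),
                                      rotation_range = c(0, 360),
                                      max_translation = 6) {
  rows <- list()
  for (s in seeds) {
    ph <- generate_phantom(spec_fn(s))
    base <- if (is.null(interval)) ph$spec$section_spacing else interval
    for (n in take_every_n) {
      sl <- slice_volume(ph, interval = base, take_every_n = n,
                         max_slides = max_slides)
      pert <- perturb_stack(sl$stack, sl$ground_truth,
                            seed = stage_seed(s, "perturb", n),
                            rotation_range = rotation_range,
                            max_translation = max_translation)
      rec <- reconstruct(pert$stack, config = config,
                         ground_truth = pert$ground_truth)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, take_every_n = n, k = pert$stack$k,
        tre_px = rec$reports$estimated_tre$TRE_px)
    }
  }
  do.call(rbind, rows)
}
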