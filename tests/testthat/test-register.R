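test_that("ellipse poses recover analytic centers, angles and degeneracy", {
  m <- ellipse_mask(side = 512, a = 200, b = 100)
  e <- fit_enclosing_ellipse(m)
  expect_equal(e$center, c(255.5, 255.5), tolerance = 0.5)
  expect_lt(min(e$angle, 180 - e$angle), 0.5)
  expect_false(e$degenerate)
  expect_equal(unname(e$axes[1] / e$axes[2]), 2, tolerance = 0.05)

  e40 <- fit_enclosing_ellipse(ellipse_mask(side = 512, a = 200, b = 100,
                                            angle = 40))
  expect_equal(e40$angle, 40, tolerance = 0.5)

  circ <- fit_enclosing_ellipse(ellipse_mask(side = 256, a = 80, b = 80))
  expect_true(circ$degenerate)

  expect_error(fit_enclosing_ellipse(matrix(FALSE, 10, 10)),
               class = "histostack_empty_mask")
})

test_that("the middle slide is the reference (lower middle for even k)", {
  # 0-based floor((k-1)/2): k=5 -> 2, k=4 -> 1 (1-based 3 and 2)
  expect_equal(histostack:::reference_index(5), 3L)
  expect_equal(histostack:::reference_index(4), 2L)
  expect_equal(histostack:::reference_index(2), 1L)
  expect_equal(histostack:::outward_order(5, 3), c(4L, 5L, 2L, 1L))
})

test_that("initialization aligns ellipse poses to the reference mod 180", {
  # one image planted at known rotations
  base <- disk_image(side = 160, radius = 55)$image
  base[60:80, 95:115, ] <- 0.15        # asymmetric blotch fixes orientation
  base[70:110, 40:60, ] <- 0.55
  angles <- c(0, 30, 60, 90, 120)
  slides <- lapply(angles, function(a) {
    w <- warp_image(base, rigid_transform(a, 0, 0, c(79.5, 79.5)), fill = 1)
    slide_image(w, spacing = 40)
  })
  st <- slide_stack(slides, slice_interval = 4000)
  ps <- build_processed_stack(st, target_pixels = 160, normalize = FALSE)
  al <- initialize_stack(ps)
  expect_equal(al$reference_index, 3)
  expect_equal(al$transforms[[3]]$theta, 0)
  # orientation differences of warped masks <= 1 degree mod 180
  angs <- vapply(seq_len(5), function(i)
    fit_enclosing_ellipse(histostack:::warp_mask(ps, al, i) > 0.5)$angle, 0)
  spread <- wrap_angle_180(angs - angs[3])
  expect_lt(max(abs(spread)), 1)

  # an already-aligned stack initializes near the identity
  st2 <- slide_stack(rep(list(slide_image(base, spacing = 40)), 3),
                     slice_interval = 4000)
  ps2 <- build_processed_stack(st2, target_pixels = 160, normalize = FALSE)
  al2 <- initialize_stack(ps2)
  for (t in al2$transforms) {
    expect_lt(abs(wrap_angle_180(t$theta)), 0.5)
    expect_lt(sqrt(t$tx^2 + t$ty^2), 0.5)
  }
})

test_that("rigid estimation matches the closed-form oracle on clean data", {
  pm <- planted_matches(n = 50, theta = 30, t = c(5, -7), seed = 50)
  est <- estimate_rigid(pm$matches, seed = 1)
  expect_equal(est$transform$theta, 30, tolerance = 1e-6)
  expect_equal(c(est$transform$tx, est$transform$ty), c(5, -7),
               tolerance = 1e-6)
  orc <- oracle_rigid_fit(pm$matches$points_a, pm$matches$points_b)
  expect_equal(est$transform$theta, orc$theta, tolerance = 1e-9)
  expect_equal(c(est$transform$tx, est$transform$ty), orc$t,
               tolerance = 1e-9)
  expect_true(all(est$matches$inlier))

  idm <- match_set(pm$matches$points_a, pm$matches$points_a)
  est_id <- estimate_rigid(idm, seed = 1)
  expect_equal(est_id$transform$theta, 0, tolerance = 1e-9)
  expect_equal(c(est_id$transform$tx, est_id$transform$ty), c(0, 0),
               tolerance = 1e-9)
})

test_that("RANSAC recovers the planted inlier set among outliers", {
  pm <- planted_matches(n = 100, theta = 24, t = c(8, -3), noise_sd = 0.5,
                        n_out = 20, min_offset = 10, seed = 7)
  est <- estimate_rigid(pm$matches, seed = 7, threshold = 3,
                        iterations = 1000)
  expect_identical(est$matches$inlier, pm$planted_inlier)
  expect_lt(abs(est$transform$theta - 24), 0.2)

  # exhaustive 2-sample search oracle on a small subcase
  pm2 <- planted_matches(n = 20, theta = -40, t = c(2, 6), noise_sd = 0.3,
                         n_out = 4, min_offset = 12, seed = 8)
  A <- pm2$matches$points_a; B <- pm2$matches$points_b
  best <- 0; best_in <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    va <- A[j, ] - A[i, ]; vb <- B[j, ] - B[i, ]
    if (sqrt(sum(va^2)) < 1e-9) next
    th <- atan2(vb[2], vb[1]) - atan2(va[2], va[1])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tt <- (B[i, ] + B[j, ]) / 2 - as.numeric(R %*% (A[i, ] + A[j, ]) / 2)
    res <- sqrt(rowSums((t(R %*% t(A)) +
                           matrix(tt, 20, 2, byrow = TRUE) - B)^2))
    if (sum(res < 3) > best) { best <- sum(res < 3); best_in <- res < 3 }
  }
  est2 <- estimate_rigid(pm2$matches, seed = 3, threshold = 3,
                         iterations = 1000)
  expect_identical(est2$matches$inlier, best_in)
  expect_identical(est2$matches$inlier, pm2$planted_inlier)
})

test_that("estimation signals insufficient matches and missing consensus", {
  small <- match_set(cbind(1:2, 1:2), cbind(1:2, 1:2))
  expect_error(estimate_rigid(small, seed = 1),
               class = "histostack_insufficient_matches")
  set.seed(51)
  garbage <- match_set(cbind(runif(10, 0, 100), runif(10, 0, 100)),
                       cbind(runif(10, 0, 100), runif(10, 0, 100)))
  expect_error(estimate_rigid(garbage, seed = 2, threshold = 1e-6),
               class = "histostack_no_consensus")
})

test_that("every estimated transform is exactly rigid", {
  for (seed in 1:10) {
    pm <- planted_matches(n = 40, theta = runif(1, -180, 180),
                          t = runif(2, -20, 20), noise_sd = 1,
                          n_out = 5, seed = seed)
    est <- estimate_rigid(pm$matches, seed = seed)
    sv <- svd(rigid_matrix(est$transform)[1:2, 1:2])$d
    expect_lt(max(abs(sv - 1)), 1e-9)
  }
})

test_that("flip resolution detects exactly the planted flip on default phantoms", {
  found <- logical(3)
  for (s in 1:3) {
    sl <- slice_volume(generate_phantom(phantom_spec(seed = s)))
    pf <- rep(FALSE, sl$stack$k); pf[3] <- TRUE
    pert <- perturb_stack(sl$stack, sl$ground_truth, seed = 200 + s,
                          rotation_range = c(0, 0), max_translation = 2,
                          planted_flips = pf, stain_jitter = 0)
    ps <- build_processed_stack(pert$stack, target_pixels = 256)
    al <- resolve_flips(ps, initialize_stack(ps), feature_backend("classical"))
    found[s] <- identical(al$flips, pf)
  }
  expect_true(all(found))
})

test_that("point-symmetric stacks tie-break to no flip, deterministically", {
  d <- disk_image(side = 128, radius = 45, value = 0.35)
  img <- d$image
  img[55:74, 55:74, ] <- 0.6   # centered square keeps point symmetry
  st <- slide_stack(rep(list(slide_image(img, spacing = 40)), 4),
                    slice_interval = 4000)
  ps <- build_processed_stack(st, target_pixels = 128, normalize = FALSE)
  al1 <- resolve_flips(ps, initialize_stack(ps), feature_backend("classical"))
  al2 <- resolve_flips(ps, initialize_stack(ps), feature_backend("classical"))
  expect_false(any(al1$flips))
  expect_identical(al1$flips, al2$flips)
})

test_that("a two-slide stack aligns with a single pairwise refinement", {
  sl <- slice_volume(generate_phantom(tiny_spec(9)), max_slides = 2)
  pert <- perturb_stack(sl$stack, sl$ground_truth, seed = 9,
                        rotation_range = c(0, 360), max_translation = 5)
  rec <- reconstruct(pert$stack, config = tiny_config(),
                     backend = feature_backend("oracle",
                                               ground_truth = pert$ground_truth),
                     ground_truth = pert$ground_truth)
  expect_equal(rec$alignment$reference_index, 1)
  expect_equal(length(rec$manifest$pair_diagnostics), 1)
  expect_lt(max(abs(rec$reports$orientation$deviation)), 1)
})

test_that("alignment is idempotent on an already reconstructed stack", {
  sl <- slice_volume(generate_phantom(phantom_spec(seed = 11)))
  pert <- perturb_stack(sl$stack, sl$ground_truth, seed = 111,
                        rotation_range = c(0, 360), max_translation = 6)
  gt <- pert$ground_truth
  be <- feature_backend("oracle", ground_truth = gt)
  cfg <- pipeline_config(target_pixels = 256, seed = 7)
  rec <- reconstruct(pert$stack, config = cfg, backend = be,
                     ground_truth = gt)
  # build a new stack from the registered images; its ground truth is the
  # residual of the recovered poses
  ps <- rec$pstack
  st2 <- slide_stack(lapply(seq_len(ps$k), function(i)
    slide_image(histostack:::warp_slide(ps, rec$alignment, i),
                spacing = ps$common_spacing, id = ps$ids[i])),
    slice_interval = pert$stack$slice_interval)
  gt2 <- gt
  for (i in seq_len(ps$k)) {
    gt2$transforms[[i]] <- compose_rigid(rec$alignment$transforms[[i]],
                                         gt$transforms[[i]],
                                         center = rec$alignment$frame_center)
    gt2$theta[i] <- gt2$transforms[[i]]$theta
  }
  rec2 <- reconstruct(st2, config = cfg,
                      backend = feature_backend("oracle", ground_truth = gt2),
                      ground_truth = gt2)
  for (t in rec2$alignment$transforms) {
    expect_lt(abs(wrap_angle(t$theta)), 1)
    expect_lt(sqrt(t$tx^2 + t$ty^2), 2)
  }
})

test_that("relative geometry is invariant to the choice of reference", {
  pert <- tiny_stack(seed = 12)
  gt <- pert$ground_truth
  be <- feature_backend("oracle", ground_truth = gt)
  ps <- build_processed_stack(pert$stack, target_pixels = 128)
  run <- function(r) {
    al <- initialize_stack(ps, reference = r)
    al <- resolve_flips(ps, al, be)
    align_stack(ps, al, be, seed = 4)
  }
  a <- run(3); b <- run(2)
  rel <- function(al, i, j)
    compose_rigid(invert_rigid(al$transforms[[j]]), al$transforms[[i]],
                  center = al$frame_center)
  for (i in c(1, 4, 5)) {
    ra <- rel(a, i, 2); rb <- rel(b, i, 2)
    expect_lt(abs(wrap_angle(ra$theta - rb$theta)), 1)
    expect_lt(sqrt((ra$tx - rb$tx)^2 + (ra$ty - rb$ty)^2), 2)
  }
})

test_that("deformable refinement reproduces affine residuals and refuses degenerate input", {
  set.seed(52)
  b <- cbind(runif(12, 10, 110), runif(12, 10, 110))
  # an affine residual lies in the TPS affine part: gridding is exact
  A <- matrix(c(0.015, -0.008, 0.01, 0.02), 2, 2)
  a <- b + t(A %*% t(b)) + matrix(c(1, -2), 12, 2, byrow = TRUE)
  ms <- match_set(a, b, inlier = rep(TRUE, 12))
  fld <- refine_deformable(ms, out_shape = c(128, 128), grid_spacing = 16)
  expect_equal(fld$grid_spacing, 16)
  expect_equal(eval_deformation(fld, b), a - b, tolerance = 1e-6)

  # generic residuals are represented exactly at the stored control grid
  set.seed(53)
  a2 <- b + cbind(rnorm(12, 0, 2), rnorm(12, 0, 2))
  raw <- fit_deformation(b, a2 - b)
  fld2 <- refine_deformable(match_set(a2, b, inlier = rep(TRUE, 12)),
                            out_shape = c(128, 128), grid_spacing = 16)
  expect_equal(fld2$displacements, eval_deformation(raw, fld2$points),
               tolerance = 1e-6)

  few <- match_set(a[1:3, ], b[1:3, ], inlier = rep(TRUE, 3))
  fld0 <- refine_deformable(few, out_shape = c(128, 128), grid_spacing = 16)
  q <- cbind(runif(20, 0, 127), runif(20, 0, 127))
  expect_lt(max(abs(eval_deformation(fld0, q))), 1e-9)
})
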