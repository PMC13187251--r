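test_that("the histogram threshold equals the exhaustive between-class-variance maximizer", {
  set.seed(30)
  for (i in 1:25) {
    counts <- rpois(256, lambda = runif(1, 0.5, 50))
    if (sum(counts) == 0) counts[1] <- 1
    expect_identical(otsu_threshold(counts), brute_force_otsu(counts))
  }
  # bimodal two-Gaussian histogram, the textbook case
  x <- c(round(rnorm(5000, 60, 10)), round(rnorm(5000, 180, 15)))
  counts <- tabulate(pmin(pmax(x, 0), 255) + 1L, 256)
  expect_identical(otsu_threshold(counts), brute_force_otsu(counts))
})

test_that("a dark disk on a white field is masked to the disk", {
  d <- disk_image(side = 128, radius = 50)
  tm <- compute_tissue_mask(d$image)
  expect_false(tm$degenerate)
  # agreement up to a 1-px boundary band after morphological cleanup
  expect_true(all(tm$mask[(1:128 - 64.5)^2 %o% rep(1, 128) +
                            rep(1, 128) %o% (1:128 - 64.5)^2 <= 48^2]))
  iou <- sum(tm$mask & d$mask) / sum(tm$mask | d$mask)
  expect_gt(iou, 0.95)
  expect_equal(tm$coverage, mean(tm$mask))
})

test_that("constant images yield an all-background degenerate mask", {
  img <- array(0.5, c(32, 32, 3))
  tm <- compute_tissue_mask(img)
  expect_true(tm$degenerate)
  expect_equal(tm$coverage, 0)
  expect_false(any(tm$mask))
})

test_that("stain normalization is a fixed point on identical slides", {
  set.seed(35)
  d <- disk_image(side = 64, radius = 20, value = 0.4)
  img <- d$image + array(rnorm(64 * 64 * 3, 0, 0.04), c(64, 64, 3)) *
    array(rep(d$mask, 3), c(64, 64, 3))
  img <- pmin(pmax(img, 0.02), 0.98)
  imgs <- list(img, img, img)
  masks <- lapply(imgs, compute_tissue_mask)
  ns <- normalize_stains(imgs, masks)
  for (i in 1:3) expect_equal(ns$images[[i]], imgs[[i]], tolerance = 1e-7)
})

test_that("normalization pulls foreground means to the stack median", {
  set.seed(31)
  base <- matrix(runif(40 * 40, -0.02, 0.02), 40, 40)
  mk <- matrix(TRUE, 40, 40)
  mkimg <- function(level) {
    ch <- pmin(pmax(level / 255 + base, 0), 1)
    array(rep(ch, 3), c(40, 40, 3))
  }
  imgs <- lapply(c(10, 20, 90), mkimg)
  ns <- normalize_stains(imgs, list(mk, mk, mk))
  for (i in 1:3) {
    expect_lt(abs(mean(ns$images[[i]]) * 255 - 20), 0.5)
  }
})

test_that("normalization is invariant to slide order and symmetric for two slides", {
  set.seed(32)
  mk <- matrix(TRUE, 32, 32)
  imgs <- lapply(c(0.3, 0.5, 0.7), function(v)
    array(pmin(pmax(v + rnorm(32 * 32 * 3, 0, 0.05), 0.02), 0.98),
          c(32, 32, 3)))
  a <- normalize_stains(imgs, list(mk, mk, mk))
  b <- normalize_stains(imgs[c(3, 1, 2)], list(mk, mk, mk))
  expect_equal(a$images[[1]], b$images[[2]], tolerance = 1e-12)
  expect_equal(a$median_stats, b$median_stats, tolerance = 1e-12)

  two <- normalize_stains(imgs[1:2], list(mk, mk))
  expect_equal(two$median_stats,
               (two$stats[[1]] + two$stats[[2]]) / 2, tolerance = 1e-12)
  # both slides move toward the common space by comparable amounts
  # (exactly symmetric in the decorrelated space, approximately in RGB)
  d1 <- mean(abs(two$images[[1]] - imgs[[1]]))
  d2 <- mean(abs(two$images[[2]] - imgs[[2]]))
  expect_gt(d1, 0); expect_gt(d2, 0)
  expect_lt(abs(d1 - d2) / max(d1, d2), 0.5)
})

test_that("degenerate slides pass through with a flag", {
  mk <- matrix(TRUE, 16, 16)
  flat <- array(0.5, c(16, 16, 3))
  set.seed(33)
  ok <- array(runif(16 * 16 * 3, 0.2, 0.8), c(16, 16, 3))
  ns <- normalize_stains(list(flat, ok, ok * 0.9), list(mk, mk, mk))
  expect_true(ns$degenerate[1])
  expect_identical(ns$images[[1]], flat)
})

test_that("common spacing selection follows the ladder arithmetic and tie-break", {
  mkslide <- function(w, h, spacing, levels = NULL) {
    slide_image(array(1, c(h, w, 3)) * 0.5, spacing = spacing,
                levels = levels)
  }
  # 40 mm long side, candidates {10, 20, 40}: sides {4000, 2000, 1000}
  s <- mkslide(4000, 3000, 10,
               levels = list(array(0.5, c(1500, 2000, 3)),
                             array(0.5, c(750, 1000, 3))))
  st <- slide_stack(list(s, s), slice_interval = 4000)
  expect_equal(select_common_spacing(st, target_pixels = 2000), 20)
  # already exactly 2000 px on the long side -> native spacing
  st2 <- slide_stack(list(mkslide(2000, 1500, 20), mkslide(1800, 1200, 20)),
                     slice_interval = 4000)
  expect_equal(select_common_spacing(st2, target_pixels = 2000), 20)
  # tie between 1500 px (at 20 um) and 2500 px (at 12 um) -> coarser wins
  st3 <- slide_stack(list(mkslide(2500, 1000, 12,
                                  levels = list(array(0.5, c(600, 1500, 3)))),
                          mkslide(100, 100, 12)),
                     slice_interval = 4000)
  expect_equal(select_common_spacing(st3, target_pixels = 2000), 20)
})

test_that("processed stacks are square, pad-bookkept, and idempotent", {
  sl <- tiny_stack(seed = 5, perturb = FALSE)
  ps <- build_processed_stack(sl$stack, target_pixels = 128)
  D <- ps$dim
  for (i in seq_len(ps$k)) {
    expect_equal(dim(ps$images[[i]]), c(D, D, 3))
    expect_equal(dim(ps$masks[[i]]$mask), c(D, D))
  }
  # pad offsets map content centroids back to the original frame exactly
  i <- 1
  m0 <- compute_tissue_mask(slide_pixels(sl$stack$slides[[i]]))
  idx0 <- which(m0$mask, arr.ind = TRUE)
  c0 <- c(mean(idx0[, 2]) - 1, mean(idx0[, 1]) - 1)
  idx1 <- which(ps$masks[[i]]$mask, arr.ind = TRUE)
  c1 <- c(mean(idx1[, 2]) - 1, mean(idx1[, 1]) - 1)
  expect_equal(as.numeric(to_processed_coords(ps, i, c0)), c1,
               tolerance = 1.0)
  # padding never clips foreground when the factor is 1
  if (all(ps$scale_factors == 1)) {
    expect_equal(sum(ps$masks[[i]]$mask), sum(m0$mask))
  }
})

test_that("preprocessing its own output is idempotent up to resampling tolerance", {
  # crisp foreground so the data-driven threshold is stable across passes
  set.seed(34)
  mk <- function(v) {
    d <- disk_image(side = 96, radius = 30, value = v)
    img <- d$image
    noise <- array(rnorm(96 * 96 * 3, 0, 0.03), c(96, 96, 3))
    img[d$mask] <- pmin(pmax(img[rep(d$mask, 1)] , 0.05), 0.95)
    img <- pmin(pmax(img + noise * array(rep(d$mask, 3), dim(img)), 0), 1)
    slide_image(img, spacing = 40)
  }
  st <- slide_stack(list(mk(0.3), mk(0.4), mk(0.5)), slice_interval = 4000)
  ps <- build_processed_stack(st, target_pixels = 96)
  st2 <- slide_stack(lapply(1:3, function(j)
    slide_image(ps$images[[j]], spacing = ps$common_spacing)),
    slice_interval = 4000)
  ps2 <- build_processed_stack(st2, target_pixels = ps$dim)
  expect_equal(ps2$dim, ps$dim)
  for (j in 1:3) {
    expect_lt(mean(abs(ps2$images[[j]] - ps$images[[j]])) * 255, 1)
  }
})
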