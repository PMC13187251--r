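test_that("the token grid obeys g = floor(side / patch)", {
  be <- feature_backend("classical")
  img <- disk_image(side = 200, radius = 70)$image
  fm <- extract_global_features(img, be, side = 1036, patch = 14)
  expect_equal(dim(fm$grid)[1:2], c(74, 74))
  fm2 <- extract_global_features(img, be, side = 518, patch = 14)
  expect_equal(dim(fm2$grid)[1:2], c(37, 37))
  expect_equal(fm$patch_size, 14)
  expect_equal(fm$source_resolution, 1036)
})

test_that("classical descriptors are deterministic and shift-equivariant", {
  set.seed(40)
  side <- 14 * 8
  img <- array(1, c(side, side, 3))
  img[29:70, 29:70, ] <- runif(42 * 42 * 3, 0, 0.8)
  be <- feature_backend("classical")
  f1 <- extract_global_features(img, be, side = side, patch = 14)
  f2 <- extract_global_features(img, be, side = side, patch = 14)
  expect_identical(f1$grid, f2$grid)
  # translate content by exactly 2 cells (28 px) in x
  img2 <- array(1, c(side, side, 3))
  img2[29:70, (29 + 28):(70 + 28), ] <- img[29:70, 29:70, ]
  f3 <- extract_global_features(img2, be, side = side, patch = 14)
  # interior cells shift by 2 in the x (first grid) axis
  expect_equal(f3$grid[4:7, 2:7, ], f1$grid[2:5, 2:7, ], tolerance = 1e-12)
})

test_that("cosine similarity matches the hand-computed formula", {
  be <- feature_backend("classical")
  set.seed(41)
  mk <- function() {
    structure(list(grid = array(rnorm(6 * 6 * 5), c(6, 6, 5)),
                   patch_size = 14, source_resolution = 84,
                   backend_id = "classical"), class = "feature_map")
  }
  a <- mk(); b <- mk()
  expect_equal(cosine_similarity(a, a), 1, tolerance = 1e-12)
  neg <- a; neg$grid <- -a$grid
  expect_equal(cosine_similarity(a, neg), -1, tolerance = 1e-12)
  va <- as.vector(a$grid); vb <- as.vector(b$grid)
  expect_equal(cosine_similarity(a, b),
               sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2))),
               tolerance = 1e-12)
  small <- a; small$grid <- a$grid[1:5, 1:5, , drop = FALSE]
  expect_error(cosine_similarity(a, small), class = "histostack_config_error")
})

test_that("oracle matching emits planted correspondences with exact outlier bookkeeping", {
  sl <- tiny_stack(seed = 3, perturb = FALSE)
  gt <- sl$ground_truth
  img <- slide_pixels(sl$stack$slides[[1]])
  be <- feature_backend("oracle", ground_truth = gt, n_matches = 100,
                        outlier_fraction = 0)
  va <- slide_view(img, 1); vb <- slide_view(img, 1)
  ms <- dense_match(va, vb, be, seed = 7)
  expect_equal(ms$points_a, ms$points_b, tolerance = 1e-9)  # identical pose

  # pose b = a rotated 30 degrees about the center: planted inliers obey
  # the rotation to 1e-6, outliers are planted off it
  rot <- rigid_transform(30, 0, 0, center = gt$sample_center)
  vb2 <- slide_view(img, 2, map_orig = function(p) apply_rigid(rot, p))
  be2 <- feature_backend("oracle", ground_truth = gt, n_matches = 100,
                         outlier_fraction = 0.2)
  ms2 <- dense_match(slide_view(img, 1), vb2, be2, seed = 7)
  pred <- apply_rigid(rot, ms2$points_a)
  resid <- sqrt(rowSums((pred - ms2$points_b)^2))
  expect_equal(sum(resid < 1e-6), 80)
  expect_equal(sum(resid >= 1e-6), 20)
  expect_equal(which(resid >= 1e-6), which(!attr(ms2, "planted_inlier")))

  # determinism across calls at a fixed seed
  ms3 <- dense_match(slide_view(img, 1), vb2, be2, seed = 7)
  expect_identical(ms2$points_b, ms3$points_b)
})

test_that("classical matching signals insufficiency on disjoint textures", {
  blank_a <- array(1, c(84, 84, 3)); blank_a[10:20, 10:20, ] <- 0.3
  blank_b <- array(1, c(84, 84, 3)); blank_b[60:75, 60:75, ] <- runif(768)
  be <- feature_backend("classical")
  expect_warning(
    ms <- dense_match(slide_view(blank_a), slide_view(blank_b), be, seed = 1,
                      min_confidence = 0.99),
    class = "histostack_insufficient_matches")
  expect_lt(ms$m, 3)
})

test_that("backends declare and enforce their capabilities", {
  be <- feature_backend("classical")
  expect_setequal(be$capabilities, c("global_descriptor", "dense_match"))
  expect_error(feature_backend("pretrained"),
               class = "histostack_capability_error")
  expect_error(feature_backend("oracle"), class = "histostack_config_error")
  crippled <- be; crippled$capabilities <- "dense_match"
  expect_error(extract_global_features(disk_image(64)$image, crippled),
               class = "histostack_capability_error")
  crippled2 <- be; crippled2$capabilities <- "global_descriptor"
  expect_error(dense_match(slide_view(disk_image(64)$image),
                           slide_view(disk_image(64)$image), crippled2),
               class = "histostack_capability_error")
})

test_that("PCA renderings are deterministic, shared-scale, and handle rank deficiency", {
  be <- feature_backend("classical")
  set.seed(42)
  imgs <- lapply(1:3, function(i) {
    im <- array(1, c(84, 84, 3))
    im[20:60, 20:60, ] <- runif(41 * 41 * 3, 0, 0.9)
    im
  })
  maps <- lapply(imgs, extract_global_features, backend = be, side = 84,
                 patch = 14)
  rgb <- pca_rgb(maps)
  expect_equal(length(rgb), 3)
  for (r in rgb) {
    expect_equal(dim(r), c(6, 6, 3))
    expect_true(all(r >= 0 & r <= 1))
  }
  # identical maps render identically
  rgb2 <- pca_rgb(list(maps[[1]], maps[[1]]))
  expect_identical(rgb2[[1]], rgb2[[2]])
  # rank-2 tokens: the third component collapses to the 0.5 guard
  flat <- structure(list(grid = array(0, c(4, 4, 3)), patch_size = 14,
                         source_resolution = 56, backend_id = "x"),
                    class = "feature_map")
  set.seed(43)
  u <- rnorm(16); v <- rnorm(16)
  flat$grid <- array(c(u, v, u + v), c(4, 4, 3))
  out <- pca_rgb(list(flat))
  expect_true(all(abs(out[[1]][, , 3] - 0.5) < 1e-9))
  expect_error(pca_rgb(list(structure(list(
    grid = array(0, c(4, 4, 2)), patch_size = 14, source_resolution = 56,
    backend_id = "x"), class = "feature_map"))),
    class = "histostack_config_error")
})
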