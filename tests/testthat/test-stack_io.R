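quantized <- function(dim) {
  round(array(runif(prod(dim)), dim) * 255) / 255
}

test_that("pyramidal write/read round-trips pixels at every level", {
  set.seed(20)
  img <- quantized(c(96, 128, 3))
  path <- file.path(withr_tempdir <- tempfile("io"), "slide.tif")
  dir.create(withr_tempdir)
  res <- write_slide(img, path, spacing = 20, n_levels = 3)
  s <- read_slide(path)
  expect_equal(s$spacing, 20)
  expect_equal(nrow(s$ladder), 3)
  expect_equal(s$ladder$downsample, c(1, 2, 4))
  expect_identical(slide_pixels(s, 1), img)
  # re-writing what was read reproduces every level bit-exactly
  path2 <- file.path(withr_tempdir, "slide2.tif")
  write_slide(slide_pixels(s, 1), path2, spacing = 20, n_levels = 3)
  s2 <- read_slide(path2)
  for (l in 1:3) expect_identical(slide_pixels(s2, l), slide_pixels(s, l))
  unlink(withr_tempdir, recursive = TRUE)
})

test_that("plain images need a declared spacing and get a single level", {
  dir <- tempfile("png"); dir.create(dir)
  img <- quantized(c(64, 64, 3))
  png::writePNG(img, file.path(dir, "a.png"))
  s <- read_slide(file.path(dir, "a.png"), spacing = 20)
  expect_equal(s$ladder$downsample, 1)
  expect_equal(dim(slide_pixels(s)), c(64, 64, 3))
  expect_error(read_slide(file.path(dir, "a.png")),
               class = "histostack_config_error")
  expect_error(read_slide(file.path(dir, "missing.png"), spacing = 20),
               class = "histostack_io_error")
  unlink(dir, recursive = TRUE)
})

test_that("truncated files raise an I/O error, not a partial slide", {
  dir <- tempfile("trunc"); dir.create(dir)
  good <- file.path(dir, "good.tif")
  write_slide(quantized(c(64, 64, 3)), good, spacing = 20, n_levels = 1)
  bad <- file.path(dir, "bad.tif")
  bytes <- readBin(good, "raw", file.size(good))
  writeBin(bytes[1:40], bad)
  expect_error(read_slide(bad, spacing = 20), class = "histostack_io_error")
  unlink(dir, recursive = TRUE)
})

test_that("tile streams are assembled exactly and coverage is enforced", {
  set.seed(21)
  img <- quantized(c(128, 128, 3))
  tiles <- list()
  for (y0 in seq(0, 96, by = 32)) for (x0 in seq(0, 96, by = 32)) {
    tiles[[length(tiles) + 1]] <-
      list(tile = img[y0 + 1:32, x0 + 1:32, , drop = FALSE], x0 = x0, y0 = y0)
  }
  dir <- tempfile("tiles"); dir.create(dir)
  path <- file.path(dir, "tiled.tif")
  res <- write_slide(tiles, path, spacing = 20, out_shape = c(128, 128),
                     n_levels = 1)
  expect_lte(attr(res, "max_live_tiles"), 1)
  expect_identical(slide_pixels(read_slide(path)), img)
  # a missing tile is an error, never a silent black tile
  expect_error(
    write_slide(tiles[-5], file.path(dir, "missing.tif"), spacing = 20,
                out_shape = c(128, 128)),
    class = "histostack_io_error")
  # overlapping tiles are rejected too
  expect_error(
    write_slide(c(tiles, tiles[3]), file.path(dir, "dup.tif"), spacing = 20,
                out_shape = c(128, 128)),
    class = "histostack_io_error")
  unlink(dir, recursive = TRUE)
})

test_that("streamed and monolithic writes of a gradient agree", {
  side <- 256
  g <- outer(seq(0, 1, length.out = side), seq(0, 1, length.out = side), "+") / 2
  img <- round(array(rep(g, 3), c(side, side, 3)) * 255) / 255
  dir <- tempfile("grad"); dir.create(dir)
  mono <- file.path(dir, "mono.tif")
  write_slide(img, mono, spacing = 10, n_levels = 2)
  gen <- local({
    pos <- expand.grid(x0 = seq(0, side - 1, 64), y0 = seq(0, side - 1, 64))
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > nrow(pos)) return(NULL)
      list(tile = img[pos$y0[i] + 1:64, pos$x0[i] + 1:64, , drop = FALSE],
           x0 = pos$x0[i], y0 = pos$y0[i])
    }
  })
  streamed <- file.path(dir, "streamed.tif")
  res <- write_slide(gen, streamed, spacing = 10, out_shape = c(side, side),
                     n_levels = 2)
  expect_lte(attr(res, "max_live_tiles"), 1)
  a <- read_slide(mono); b <- read_slide(streamed)
  for (l in 1:2) expect_identical(slide_pixels(a, l), slide_pixels(b, l))
  unlink(dir, recursive = TRUE)
})

test_that("stacks validate size, color model and record order as z-index", {
  dir <- tempfile("stack"); dir.create(dir)
  for (i in 1:3) {
    png::writePNG(quantized(c(32, 32, 3)), file.path(dir, sprintf("s%d.png", i)))
  }
  paths <- file.path(dir, sprintf("s%d.png", 1:3))
  st <- load_stack(paths, slice_interval = 4000, spacing = 20)
  expect_equal(st$k, 3)
  expect_equal(vapply(st$slides, function(s) s$z_index, 0L), 0:2)
  rev_st <- load_stack(rev(paths), slice_interval = 4000, spacing = 20)
  expect_equal(rev_st$slides[[1]]$id, st$slides[[3]]$id)

  expect_error(load_stack(paths[1], slice_interval = 4000, spacing = 20),
               class = "histostack_config_error")
  png::writePNG(matrix(runif(32 * 32), 32), file.path(dir, "gray.png"))
  err <- tryCatch(
    load_stack(c(paths[1:2], file.path(dir, "gray.png")),
               slice_interval = 4000, spacing = 20),
    error = function(e) e)
  expect_s3_class(err, "histostack_config_error")
  expect_match(conditionMessage(err), "gray")
  unlink(dir, recursive = TRUE)
})

test_that("landmark CSVs round-trip and are validated", {
  lm <- data.frame(slide_id = c("a", "a", "b"), x = c(1.5, 2, 3),
                   y = c(4, 5.25, 6))
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  expect_equal(read_landmarks(f), lm)
  utils::write.csv(data.frame(u = 1), f, row.names = FALSE)
  expect_error(read_landmarks(f), class = "histostack_config_error")
  unlink(f)
})
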