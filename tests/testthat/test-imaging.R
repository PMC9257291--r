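test_that("greyscale conversion uses BT.601 luma on real values", {
  px <- function(r, g, b) {
    arr <- array(0, c(1, 1, 3)); arr[1, 1, ] <- c(r, g, b)
    to_grayscale(rgb_image(arr))[1, 1]
  }
  expect_equal(px(255, 255, 255), 255)
  expect_equal(px(0, 0, 0), 0)
  expect_equal(px(255, 0, 0), 76.245)       # 0.299 * 255, unrounded
  expect_equal(px(0, 255, 0), 0.587 * 255)
  expect_error(to_grayscale(rgb_image(array(1, c(2, 2, 3))),
                            weights = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("background removal by key colour and by alpha channel", {
  # 10x10, left half key magenta, right half red: mask = 50 pixels
  arr <- array(0, c(10, 10, 3))
  arr[, 1:5, 1] <- 255; arr[, 1:5, 3] <- 255       # key colour
  arr[, 6:10, 1] <- 255                             # red wing
  mask <- remove_background(rgb_image(arr), c(255, 0, 255), tolerance = 0)
  expect_equal(sum(mask), 50)
  expect_true(all(which(mask, arr.ind = TRUE)[, 2] >= 6))

  # fully key-coloured image is an error
  allkey <- array(0, c(4, 4, 3)); allkey[, , 1] <- 255; allkey[, , 3] <- 255
  expect_error(remove_background(rgb_image(allkey), c(255, 0, 255), 0),
               "empty mask")

  # RGBA: mask count equals the number of nonzero-alpha pixels (37 here)
  set.seed(42)
  rgba <- array(runif(8 * 8 * 4) * 255, c(8, 8, 4))
  alpha <- matrix(0, 8, 8)
  alpha[sample.int(64, 37)] <- 200
  rgba[, , 4] <- alpha
  expect_equal(sum(remove_background(rgb_image(rgba), "alpha")), 37)

  # requesting alpha on a 3-channel image is a format error
  expect_error(remove_background(rgb_image(arr), "alpha"), "alpha")
})

test_that("RMS contrast equals the sample standard deviation of masked pixels", {
  g <- matrix(128, 5, 5)
  m <- matrix(TRUE, 5, 5)
  expect_warning(res <- rms_contrast(g, m), "uniform")
  expect_equal(res$rms, 0)
  expect_equal(res$log_rms, log(1e-6))

  g2 <- matrix(c(0, 255, 7, 7), 2, 2)
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  r2 <- rms_contrast(g2, m2)
  expect_equal(r2$rms, sqrt(2 * 127.5^2 / 1))       # 180.312...
  expect_equal(r2$n_pixels, 2)

  g4 <- matrix(c(0, 0, 255, 255), 2, 2)
  expect_equal(rms_contrast(g4)$rms, sqrt(65025 / 3))  # 147.224...

  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_error(rms_contrast(g4, m1), "insufficient pixels")
})

test_that("RMS matches a two-pass oracle, is shift-invariant and scale-equivariant", {
  two_pass_sd <- function(x) {
    mu <- sum(x) / length(x)
    sqrt(sum((x - mu)^2) / (length(x) - 1))
  }
  set.seed(7)
  for (i in 1:10) {
    g <- matrix(runif(400, 0, 255), 20, 20)
    m <- matrix(runif(400) < 0.6, 20, 20)
    if (sum(m) < 2) next
    base <- rms_contrast(g, m)$rms
    expect_equal(base, two_pass_sd(g[m]), tolerance = 1e-9)
    # shift invariance (synthetic, no clipping applied)
    expect_equal(rms_contrast(g - min(g[m]) , m)$rms, base, tolerance = 1e-9)
    # scale equivariance
    expect_equal(rms_contrast(g * 0.5, m)$rms, 0.5 * base, tolerance = 1e-9)
    # mask independence: fuzzing background pixels changes nothing
    g2 <- g; g2[!m] <- runif(sum(!m), 0, 255)
    expect_identical(rms_contrast(g2, m)$rms, base)
  }
})

test_that("PNG round trip and manifest batch scoring work", {
  td <- withr::local_tempdir()
  set.seed(3)
  w1 <- generate_wing_image(size = 32, grid = 8, second_fraction = 0.5,
                            seed = 11)
  w2 <- generate_wing_image(size = 32, grid = 8, second_fraction = 0,
                            seed = 12)
  p1 <- file.path(td, "a.png"); p2 <- file.path(td, "b.png")
  write_wing_image(w1$image, p1); write_wing_image(w2$image, p2)
  back <- read_wing_image(p1)
  expect_equal(back$data, w1$image$data, tolerance = 1 / 255)

  manifest <- data.frame(species_id = c("spA", "spB"),
                         image_id = c("i1", "i2"), path = c(p1, p2))
  res <- suppressWarnings(score_images(manifest, background = c(255, 0, 255)))
  expect_equal(nrow(res$images), 2)
  expect_equal(nrow(res$species), 2)
  # contrasting wing scores strictly above the uniform one
  expect_gt(res$images$rms[1], res$images$rms[2])
  expect_true(all(res$images$n_pixels > 2))
})
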