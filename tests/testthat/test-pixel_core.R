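test_that("background rule accepts bright uniform pixels and rejects tissue", {
  expect_true(is_background(c(255, 255, 255)))   # perfect white
  expect_true(is_background(c(235, 240, 238)))   # min 235, spread 5
  expect_false(is_background(c(175, 175, 125)))  # tissue: min below 230
  expect_false(is_background(c(0, 0, 0)))        # perfect black is sample
  # bright but chromatic: spread beyond the uniformity bound
  expect_false(is_background(c(255, 255, 228)))
  # boundary behaviour: exactly at bg_min and at the max spread counts
  expect_true(is_background(c(230, 230, 255)))
  expect_false(is_background(c(229, 255, 255)))
})

test_that("stain rule reproduces the worked pixel examples", {
  expect_true(is_stained(c(75, 175, 100)))    # red-dominant sample pixel
  expect_false(is_stained(c(175, 175, 125)))  # no channel strictly below 125
  expect_false(is_stained(c(100, 100, 160)))  # blue-dominant: 160 >= 125
  expect_true(is_stained(c(120, 80, 60)))     # dark, 60 < 1.00 * 120
})

test_that("stain rule boundaries follow the documented strictness", {
  # dark test is strict: min exactly at 125 is not dark
  expect_false(is_stained(c(125, 125, 125)))
  expect_true(is_stained(c(124, 124, 124)))  # not blue-dom: 124 < 1.25*124
  # blue dominance uses >=: equality with both alpha*R and beta*G is
  # blue-dominant, hence unstained
  expect_false(is_stained(c(100, 80, 100)))  # b = 1.00*r and b = 1.25*g
  expect_true(is_stained(c(101, 80, 100)))   # b just below alpha*r
})

test_that("classify_pixel composes the rules with background first", {
  labs <- classify_pixel(rbind(c(255, 255, 255),
                               c(75, 175, 100),
                               c(175, 175, 125)))
  expect_equal(as.character(labs), c("background", "stained", "unstained"))
  expect_equal(levels(labs), c("background", "unstained", "stained"))
})

test_that("classify_image tallies the documented 2x2 example", {
  img <- array(0L, dim = c(2, 2, 3))
  img[1, 1, ] <- c(255, 255, 255)
  img[1, 2, ] <- c(255, 255, 255)
  img[2, 1, ] <- c(75, 175, 100)
  img[2, 2, ] <- c(100, 100, 160)
  q <- classify_image(img)$quant
  expect_equal(q$background_pixels, 2)
  expect_equal(q$sample_pixels, 2)
  expect_equal(q$stained_pixels, 1)
  expect_equal(q$unstained_pixels, 1)
})

test_that("all-white image is pure background", {
  img <- array(255L, dim = c(10, 10, 3))
  q <- classify_image(img)$quant
  expect_equal(q$background_pixels, 100)
  expect_equal(q$sample_pixels, 0)
  expect_true(is.na(q$stain_fraction))
})

test_that("tallies conserve the pixel count on random images", {
  set.seed(11)
  for (i in 1:20) {
    img <- random_rgb_image(32, 48)
    q <- classify_image(img)$quant
    expect_equal(q$background_pixels + q$stained_pixels +
                   q$unstained_pixels, 32 * 48)
    expect_equal(q$background_pixels + q$sample_pixels, q$total_pixels)
    expect_equal(q$stained_pixels + q$unstained_pixels, q$sample_pixels)
  }
})

test_that("classification is deterministic and stateless", {
  set.seed(7)
  img <- random_rgb_image(40, 40)
  a <- classify_image(img)
  b <- classify_image(img)
  expect_identical(a$labels, b$labels)
  expect_identical(unclass(a$quant), unclass(b$quant))
})

test_that("flipping one unstained pixel to a stained color moves one tally", {
  set.seed(3)
  img <- random_rgb_image(16, 16)
  q0 <- classify_image(img)
  idx <- which(q0$labels == 1L, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  img[idx[1, 1], idx[1, 2], ] <- c(120, 80, 60)  # satisfies is_stained
  q1 <- classify_image(img)$quant
  expect_equal(q1$stained_pixels, q0$quant$stained_pixels + 1)
  expect_equal(q1$unstained_pixels, q0$quant$unstained_pixels - 1)
  expect_equal(q1$background_pixels, q0$quant$background_pixels)
})

test_that("vectorized classifier matches the scalar per-pixel oracle", {
  set.seed(42)
  for (i in 1:25) {
    img <- random_rgb_image(24, 24)
    expect_identical(classify_image(img)$labels, naive_classify(img))
  }
})

test_that("degenerate image inputs are rejected", {
  expect_error(classify_image(array(0, dim = c(0, 5, 3))), "degenerate")
  expect_error(classify_image(matrix(0, 5, 5)), "H x W x 3")
  expect_error(classify_image(array(0, dim = c(5, 5, 4))), "3 channels")
})

test_that("parameter constructor validates its invariants", {
  expect_error(pixel_class_params(bg_min = 0))
  expect_error(pixel_class_params(dark_threshold = 255))
  expect_error(pixel_class_params(alpha = -1))
  expect_error(pixel_class_params(bg_uniformity = -5))
  p <- pixel_class_params(bg_min = 200, beta = 1.5)
  expect_s3_class(p, "pixel_class_params")
  expect_equal(p$beta, 1.5)
})
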