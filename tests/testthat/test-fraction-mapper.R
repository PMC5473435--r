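test_that("fractions divide first-component intensity by the total", {
  i1 <- matrix(c(5, 7, 0, 0), 2, 2)
  i2 <- matrix(c(5, 0, 3, 0), 2, 2)
  fm <- fraction_map(maps_from_planes(i1, i2))
  expect_equal(fm$fraction[1, 1], 0.5)
  expect_equal(fm$fraction[2, 1], 1.0)
  expect_equal(fm$fraction[1, 2], 0.0)
  expect_true(is.na(fm$fraction[2, 2]))       # 0/0 stays undefined
  expect_false(fm$defined[2, 2])
  expect_equal(fm$total_intensity, i1 + i2)
  # three components are rejected
  bad <- maps_from_planes(i1, i2)
  bad$values <- array(0, dim = c(2, 2, 3))
  expect_error(fraction_map(bad), "two components")
})

test_that("the two fractions sum to one at every defined pixel", {
  set.seed(41)
  i1 <- matrix(runif(400, 0, 100), 20, 20)
  i2 <- matrix(runif(400, 0, 100), 20, 20)
  i1[1:3, 1] <- 0; i2[1:3, 1] <- 0
  fm1 <- fraction_map(maps_from_planes(i1, i2))
  fm2 <- fraction_map(maps_from_planes(i2, i1))
  s <- fm1$fraction + fm2$fraction
  expect_equal(max(abs(s[fm1$defined] - 1)), 0)
})

test_that("GP conversion is 2f - 1 with strict domain checks", {
  expect_equal(fraction_to_gp(0.5), 0)
  expect_equal(fraction_to_gp(1), 1)
  expect_equal(fraction_to_gp(0), -1)
  expect_equal(fraction_to_gp(0.75), 0.5)
  expect_true(is.na(fraction_to_gp(NA_real_)))
  expect_error(fraction_to_gp(1.2), "\\[0, 1\\]")
  expect_error(fraction_to_gp(-0.1), "\\[0, 1\\]")
})

test_that("channel GP equals the fraction route algebraically", {
  g <- grid17()
  set.seed(42)
  counts <- array(rpois(32 * 32 * 17, 60), dim = c(32, 32, 17))
  st <- lambda_stack(counts, g)
  ib <- channel_index(g, 440); ig <- channel_index(g, 490)
  expect_error(gp_map_from_channels(st, ib, ib), "distinct")
  gp <- gp_map_from_channels(st, ib, ig)
  expect_equal(gp[1, 1],
               (counts[1, 1, ib] - counts[1, 1, ig]) /
                 (counts[1, 1, ib] + counts[1, 1, ig]))
  fm <- fraction_map(maps_from_planes(counts[, , ib], counts[, , ig], g))
  d <- abs(gp - fraction_to_gp(fm$fraction))
  expect_lt(max(d, na.rm = TRUE), 1e-12)
  # (3, 1) -> 0.5
  one <- lambda_stack(array(c(3, 1), dim = c(1, 1, 2)),
                      channel_grid(435, 50, 2))
  expect_equal(gp_map_from_channels(one, 1, 2)[1, 1], 0.5)
})

test_that("the six-colour LUT partitions [0,1] with 2,3,3,3,3,2 widths", {
  lut <- lut_six_colour()
  expect_equal(lut$edges, c(0, 2, 5, 8, 11, 14, 16) / 16)
  # exhaustive and non-overlapping: every fraction lands in exactly one bin
  f <- seq(0, 1, by = 1 / 512)
  bins <- findInterval(f, lut$edges, rightmost.closed = TRUE)
  expect_true(all(bins >= 1 & bins <= 6))
  # half-open convention: an edge belongs to the upper bin, 1 to the last
  expect_equal(findInterval(2 / 16, lut$edges, rightmost.closed = TRUE), 2)
  expect_equal(findInterval(1, lut$edges, rightmost.closed = TRUE), 6)
  expect_error(discrete_lut(c("red", "blue"), c(1, 0)), "positive")
})

test_that("colour rendering scales with total intensity and blacks undefined", {
  lut <- lut_six_colour()
  i1 <- matrix(c(10, 0, 25), 1, 3)
  i2 <- matrix(c(90, 0, 25), 1, 3)
  fm <- fraction_map(maps_from_planes(i1, i2))
  img <- colorize_fraction(fm, lut, intensity_ceiling = 100)
  # pixel 2 is undefined -> black
  expect_equal(as.numeric(img[1, 2, ]), c(0, 0, 0))
  # pixel 1: fraction 0.1 -> first bin colour at full ceiling intensity
  expect_equal(as.numeric(img[1, 1, ]), as.numeric(lut$rgb[1, ]))
  # pixel 3: fraction 0.5 -> bin 4, at half intensity
  expect_equal(as.numeric(img[1, 3, ]), as.numeric(lut$rgb[4, ] * 0.5))
  # auto ceiling equals max total over defined pixels
  img2 <- colorize_fraction(fm, lut)
  expect_equal(as.numeric(img2[1, 1, ]), as.numeric(lut$rgb[1, ]))
  # degenerate all-undefined map warns and returns black
  z <- matrix(0, 2, 2)
  expect_warning(img3 <- colorize_fraction(fraction_map(
    maps_from_planes(z, z)), lut), "black")
  expect_true(all(img3 == 0))
})

test_that("2D histograms conserve the included pixel count", {
  set.seed(43)
  i1 <- matrix(runif(256, 10, 200), 16, 16)
  i2 <- matrix(runif(256, 10, 200), 16, 16)
  bg <- matrix(FALSE, 16, 16); bg[1, 1:4] <- TRUE
  maps <- maps_from_planes(i1, i2, background = bg)
  h <- intensity_histogram_2d(maps, n_bins = 8)
  expect_equal(sum(h$counts), 256 - 4)
  expect_equal(h$n_included, 252)
  hl <- intensity_histogram_2d(maps, n_bins = 8, scale = "log")
  expect_equal(sum(hl$counts), 252)
  # a single included pixel occupies exactly one bin
  one <- maps_from_planes(matrix(5, 1, 1), matrix(7, 1, 1))
  h1 <- intensity_histogram_2d(one, n_bins = 4)
  expect_equal(sum(h1$counts), 1)
  expect_equal(sum(h1$counts > 0), 1)
  # a uniform image lands in one bin with count N
  uni <- maps_from_planes(matrix(30, 5, 5), matrix(60, 5, 5))
  hu <- intensity_histogram_2d(uni, n_bins = 6)
  expect_equal(max(hu$counts), 25)
  expect_equal(sum(hu$counts > 0), 1)
  expect_error(intensity_histogram_2d(maps, n_bins = 1), ">= 2")
})

test_that("point-in-polygon matches a half-plane oracle on rectangles", {
  rect <- rbind(c(10, 10), c(40, 10), c(40, 30), c(10, 30))
  set.seed(44)
  x <- runif(300, 0, 50); y <- runif(300, 0, 40)
  got <- point_in_polygon(x, y, rect)
  want <- x >= 10 & x <= 40 & y >= 10 & y <= 30
  expect_equal(got, want)
  # boundary points are inside
  expect_true(all(point_in_polygon(c(10, 40, 25), c(20, 30, 10), rect)))
  # and a triangle vs the sign-of-cross-product oracle
  tri <- rbind(c(0, 0), c(10, 0), c(5, 8))
  inside_tri <- function(px, py) {
    s1 <- (10 - 0) * (py - 0) - (px - 0) * (0 - 0)
    s2 <- (5 - 10) * (py - 0) - (px - 10) * (8 - 0)
    s3 <- (0 - 5) * (py - 8) - (px - 5) * (0 - 8)
    (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  xt <- runif(200, -2, 12); yt <- runif(200, -2, 10)
  expect_equal(point_in_polygon(xt, yt, tri), inside_tri(xt, yt))
})

test_that("gates select intensity-space populations and render them", {
  i1 <- matrix(c(20, 120, 60), 1, 3)
  i2 <- matrix(c(80, 40, 60), 1, 3)
  maps <- maps_from_planes(i1, i2)
  # axis-aligned rectangle holding only the second pixel
  gt <- gate_polygon(rbind(c(100, 20), c(140, 20), c(140, 60), c(100, 60)))
  res <- gate_to_image(maps, gt)
  expect_equal(as.vector(res$mask), c(FALSE, TRUE, FALSE))
  expect_true(all(res$image[1, 1, ] == 0) && all(res$image[1, 3, ] == 0))
  expect_gt(sum(res$image[1, 2, ]), 0)
  # bounding rectangle of the data captures every included pixel
  bb <- gate_polygon(rbind(c(20, 40), c(120, 40), c(120, 80), c(20, 80)))
  expect_true(all(gate_to_image(maps, bb)$mask))
  # far-away gate selects nothing
  far <- gate_polygon(rbind(c(1e4, 1e4), c(2e4, 1e4), c(2e4, 2e4)))
  expect_false(any(gate_to_image(maps, far)$mask))
  expect_error(gate_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  expect_error(gate_polygon(rbind(c(0, 0), c(1, 1))), ">= 3")
})
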