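test_that("Otsu threshold equals exhaustive within-class-variance search", {
  half <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  thr <- otsu_threshold(half)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)

  set.seed(61)
  for (i in 1:4) {
    img <- matrix(runif(64 * 64), 64, 64)
    expect_equal(otsu_threshold(img), exhaustive_otsu(img))
  }
  img_bi <- matrix(pmin(1, pmax(0, c(rnorm(5000, 0.3, 0.05),
                                     rnorm(5000, 0.7, 0.05)))), 100, 100)
  expect_equal(otsu_threshold(img_bi), exhaustive_otsu(img_bi))
  thr_bi <- otsu_threshold(img_bi)
  expect_gt(thr_bi, 0.45); expect_lt(thr_bi, 0.55)

  expect_error(otsu_threshold(matrix(0.5, 5, 5)), "constant")
})

test_that("connected labeling is 8-connected with area filtering", {
  m <- matrix(FALSE, 8, 8)
  m[2:3, 2:3] <- TRUE; m[4, 4] <- TRUE; m[5, 5] <- TRUE  # diagonal chain
  lab <- label_regions(m)
  expect_equal(max(lab), 1L)
  m[7, 7] <- TRUE
  expect_equal(max(label_regions(m)), 2L)
  expect_equal(max(label_regions(m, min_area = 2)), 1L)
})

test_that("white/gray classification counts lumen vs stained tissue", {
  fx <- annulus_fixture()
  # pure-white disk on a mid-gray field
  img <- array(0.5, c(40, 40, 3))
  disk <- (matrix(1:40, 40, 40) - 20)^2 +
    (matrix(1:40, 40, 40, byrow = TRUE) - 20)^2 <= 8^2
  for (c in 1:3) img[, , c][disk] <- 0.95
  lab <- matrix(0L, 40, 40); lab[disk] <- 1L
  cp <- classify_pixels(img, lab, dilation_radius = 4)
  expect_equal(cp$area_px, sum(disk))
  expect_equal(cp$white_px, sum(disk), tolerance = 0.05)
  expect_gt(cp$gray_px, 0)  # the dilation ring is darker

  # all-gray region yields no white pixels
  gimg <- array(0.3, c(20, 20, 3))
  glab <- matrix(0L, 20, 20); glab[8:12, 8:12] <- 1L
  gcp <- classify_pixels(gimg, glab, dilation_radius = 3)
  expect_equal(gcp$white_px, 0)

  # bisected disk: white and gray halves within 10% of each other
  # (disk centered on the half-pixel boundary so the split is symmetric)
  bdisk <- (matrix(1:40, 40, 40) - 20.5)^2 +
    (matrix(1:40, 40, 40, byrow = TRUE) - 20.5)^2 <= 8^2
  bimg <- array(0.9, c(40, 40, 3))
  for (c in 1:3) bimg[, , c][, 1:20] <- 0.2
  blab <- matrix(0L, 40, 40); blab[bdisk] <- 1L
  bcp <- classify_pixels(bimg, blab, dilation_radius = 0)
  expect_lt(abs(bcp$white_px - bcp$gray_px) / max(bcp$white_px, bcp$gray_px),
            0.1)
})

test_that("region typing bands the white fraction into five types", {
  expect_equal(region_type(100, 0), 1L)
  expect_equal(region_type(0, 100), 5L)
  expect_equal(region_type(50, 50), 3L)
  # the bands partition [0, 1]: exactly one type per composition
  for (w in seq(0, 1, by = 0.01)) {
    ty <- region_type(round(1000 * w), 1000 - round(1000 * w))
    expect_true(ty %in% 1:5)
  }
  expect_equal(region_type(960, 40), 1L)   # w = 0.96 > 0.95
  expect_equal(region_type(950, 50), 2L)   # w = 0.95 on the boundary
  expect_error(region_type(0, 0), "empty")
  expect_error(region_type(1, 1, cuts = c(0.5, 0.4, 0.6, 0.9)), "increasing")
})

test_that("aspect-ratio test applies the three criteria", {
  rec <- data.frame(label = 1:3, area_px = c(250, 100, 400),
                    white_px = c(300, 0, 410), gray_px = c(150, 260, 400),
                    type = c(3L, 5L, 2L))
  out <- aspect_ratio_test(rec, image_size = 100 * 100)
  # criterion 1: Type 5 becomes background with SAR = 1
  expect_equal(out$sar[2], 1)
  expect_false(out$accepted[2])
  # criterion 2: direct arithmetic
  expect_equal(out$sar[1], 150 / 250)
  expect_equal(out$sar[3], 400 / 400)
  # criterion 3: AIR by hand
  expect_equal(out$air[1], 0.025)
  expect_true(out$accepted[1])
  expect_false(out$accepted[3])        # SAR = 1 lies outside the band
  expect_true(out$needs_refinement[1]) # Type 3 routed to refinement
  expect_false(out$needs_refinement[3])
  expect_error(aspect_ratio_test(rec, 0), "positive")
})

test_that("refinement recovers the lumen of an annulus from a solid disk", {
  fx <- annulus_fixture()
  rf <- refine_region(fx$img, fx$disk, needs_refinement = TRUE)
  expect_gte(sum(rf$lumen & fx$lumen) / sum(fx$lumen), 0.9)
  expect_gte(sum(rf$mask & fx$disk) / sum(fx$disk), 0.9)
  # not flagged: a strict no-op on the mask
  noop <- refine_region(fx$img, fx$disk, needs_refinement = FALSE)
  expect_identical(noop$mask, fx$disk)
})

test_that("segmentation pipeline finds vessels, rejects clutter, repeats", {
  blank <- generate_vessel_image(synthetic_spec(height = 96, width = 96,
                                                n_vessels = 0,
                                                clutter_density = 0,
                                                seed = 3))
  seg0 <- segment_pipeline(blank$image)
  expect_equal(sum(seg0$records$accepted), 0)
  expect_false(any(seg0$mask))

  sy <- generate_vessel_image(synthetic_spec(seed = 17))
  seg <- segment_pipeline(sy$image)
  expect_equal(sum(seg$records$accepted), 5)
  expect_equal(count_error(seg$labels, sy$truth), 0)

  seg2 <- segment_pipeline(sy$image)
  expect_identical(seg$records, seg2$records)
  expect_identical(seg$mask, seg2$mask)

  # SAR / AIR are exact count ratios for every record
  r <- seg$records
  expect_equal(r$sar, ifelse(r$type == 5L, 1, r$gray_px / r$area_px))
  expect_equal(r$air, r$area_px / length(seg$mask))
  # every region got exactly one type
  expect_true(all(r$type %in% 1:5))
})
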