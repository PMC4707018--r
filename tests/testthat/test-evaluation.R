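# build a truth object from a list of disjoint disk masks
make_truth <- function(masks) {
  list(vessel_mask = Reduce(`|`, masks), n_vessels = length(masks),
       per_vessel_masks = masks)
}

disk_mask <- function(H, W, cy, cx, r) {
  (matrix(1:H, H, W) - cy)^2 + (matrix(1:W, H, W, byrow = TRUE) - cx)^2 <= r^2
}

test_that("count error follows XOR counting with IoU matching", {
  H <- 100; W <- 100
  disks <- lapply(seq(10, 90, by = 20), function(cx)
    disk_mask(H, W, 50, cx, 6))
  truth <- make_truth(disks)

  expect_equal(count_error(truth$vessel_mask, truth), 0)
  # four of five found
  expect_equal(count_error(Reduce(`|`, disks[1:4]), truth), 20)
  # all five plus one spurious region
  spur <- truth$vessel_mask | disk_mask(H, W, 15, 50, 4)
  expect_equal(count_error(spur, truth), 20)
  # nothing found: every truth vessel unmatched
  expect_equal(count_error(matrix(FALSE, H, W), truth), 100)
  expect_error(count_error(truth$vessel_mask, list(n_vessels = 0)), "empty")
})

test_that("area error is the XOR count relative to ground truth", {
  gt <- matrix(FALSE, 100, 100)
  gt[1:10, 1:10] <- TRUE  # |gt| = 100
  expect_equal(area_error(gt, gt), 0)
  pred <- gt
  pred[50, 1:10] <- TRUE  # 10 extra pixels
  expect_equal(area_error(pred, gt), 10)
  expect_equal(area_error(!gt, gt), (9900 + 100) / 100 * 100)
  expect_error(area_error(gt, matrix(FALSE, 100, 100)), "empty")

  # asymmetric only through the denominator
  a <- gt; b <- pred
  expect_equal(area_error(a, b) * sum(b), area_error(b, a) * sum(a))
})

test_that("both metrics are invariant to joint translation", {
  H <- 60; W <- 60
  masks <- list(disk_mask(H, W, 20, 20, 5), disk_mask(H, W, 40, 40, 7))
  truth <- make_truth(masks)
  pred <- disk_mask(H, W, 20, 20, 5) | disk_mask(H, W, 40, 41, 7)
  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, H, W)
    out[(1 + dy):H, (1 + dx):W] <- m[1:(H - dy), 1:(W - dx)]
    out
  }
  truth_s <- make_truth(lapply(masks, shift, dy = 5, dx = 3))
  pred_s <- shift(pred, 5, 3)
  expect_equal(count_error(pred, truth), count_error(pred_s, truth_s))
  expect_equal(area_error(pred, truth$vessel_mask),
               area_error(pred_s, truth_s$vessel_mask))
})

test_that("fuzzy c-means recovers separable structure deterministically", {
  two <- matrix(rep(c(0.2, 0.8), each = 200), 20, 20)
  fc <- fcm_cluster(two, n_classes = 2, seed = 5, stain_color = 0.2)
  expect_equal(sort(as.numeric(fc$centers)), c(0.2, 0.8), tolerance = 1e-4)
  expect_true(all(fc$labels[two == 0.2] == fc$vessel_class))
  expect_true(all(fc$labels[two == 0.8] != fc$vessel_class))

  # fuzzifier -> 1 approximates k-means on separable data
  set.seed(71)
  img <- matrix(c(rnorm(200, 0.25, 0.03), rnorm(200, 0.75, 0.03)), 20, 20)
  img <- pmin(1, pmax(0, img)); dim(img) <- c(20, 20)
  fc1 <- fcm_cluster(img, n_classes = 2, fuzzifier = 1.05, seed = 2,
                     stain_color = 0.2)
  km <- kmeans(as.numeric(img), centers = c(0.25, 0.75))
  km_lab <- matrix(km$cluster, 20, 20)
  agree <- mean((fc1$labels == fc1$vessel_class) ==
                  (km_lab == which.min(km$centers)))
  expect_gte(agree, 0.99)

  fc2 <- fcm_cluster(img, n_classes = 2, fuzzifier = 1.05, seed = 2,
                     stain_color = 0.2)
  expect_identical(fc1$labels, fc2$labels)
})

test_that("fcm objective does not increase with more iterations", {
  set.seed(72)
  x <- matrix(runif(400), 200, 2)
  obj <- function(fit) {
    d2 <- outer(seq_len(nrow(x)), seq_len(nrow(fit$centers)),
                Vectorize(function(i, k) sum((x[i, ] - fit$centers[k, ])^2)))
    sum(fit$membership^2 * d2)
  }
  init <- x[c(10, 150), ]
  f1 <- e1071::cmeans(x, centers = init, m = 2, iter.max = 1)
  f50 <- e1071::cmeans(x, centers = init, m = 2, iter.max = 50)
  expect_lte(obj(f50), obj(f1) + 1e-9)
})

test_that("filtering benchmark emits one row per image, clean is easy", {
  clean_spec <- synthetic_spec(height = 128, width = 128, n_vessels = 3,
                               clutter_density = 0, noise_sigma = 0.005,
                               texture_sd = 0.01, illumination_ramp = 0.05,
                               seed = 41)
  suite <- generate_suite(clean_spec, 1)
  res <- filtering_benefit_experiment(suite)
  expect_equal(nrow(res), 1)
  expect_lt(res$error_unfiltered_pct, 5)
  expect_lt(res$error_filtered_pct, 5)
  expect_named(res, c("image_id", "error_unfiltered_pct",
                      "error_filtered_pct"))
})
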