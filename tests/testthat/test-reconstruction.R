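test_that("TSVD solves match a truncated pseudoinverse oracle", {
  b7 <- rnorm(7, 0, 1)
  expect_equal(tsvd_solve(diag(7), b7, 0), b7, ignore_attr = TRUE,
               tolerance = 1e-12)

  A <- rmat(20, 15, 41)
  b <- rnorm(20)
  sv <- svd(A)
  for (t in c(0, 0.3, 0.8)) {
    k <- sum(sv$d >= t * sv$d[1])
    Ak <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    x_or <- MASS::ginv(Ak) %*% b
    x <- tsvd_solve(A, b, t)
    expect_equal(drop(x), drop(x_or), tolerance = 1e-10, ignore_attr = TRUE)
    expect_identical(attr(x, "rank"), k)
  }
  expect_error(tsvd_solve(A, b, 1.5), "rel_threshold")
  expect_error(tsvd_solve(matrix(0, 3, 3), rnorm(3), 0), "zero matrix")
})

test_that("TSVD solution norm is non-increasing in the threshold", {
  A <- rmat(12, 10, 42)
  b <- rnorm(12)
  norms <- vapply(seq(0, 1, by = 0.05), function(t)
    sqrt(sum(tsvd_solve(A, b, t)^2)), 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("contrast is the anomaly/background mean difference", {
  img <- numeric(20)
  expect_identical(contrast(img, 1:3, 10:20), 0)
  img[1:3] <- 2.5
  expect_identical(contrast(img, 1:3, 10:20), 2.5)
  img[10:20] <- 1
  expect_equal(contrast(img, 1:3, 10:20), 1.5)
  expect_error(contrast(img, integer(0), 10:20), "nonempty")
  expect_error(contrast(img, 1:3, 3:5), "disjoint")
})

test_that("threshold_search brackets and matches attainable targets", {
  A <- rmat(15, 12, 43)
  b <- rnorm(15)
  an <- 1:3
  bg <- 7:12
  c0 <- contrast(tsvd_solve(A, b, 0), an, bg)
  ts <- threshold_search(A, b, c0, an, bg, tolerance = 0.01)
  expect_true(ts$converged)
  expect_equal(ts$contrast, c0, tolerance = 0.011 * abs(c0))
  expect_lt(ts$threshold, 0.05)

  ## zero data: contrast 0 for every threshold; target 0 is degenerate
  ts0 <- threshold_search(A, rep(0, 15), 0, an, bg)
  expect_identical(ts0$contrast, 0)

  ## unattainable target is flagged, not an error
  tsu <- threshold_search(A, b, 1e6, an, bg)
  expect_false(tsu$attainable)
  expect_false(tsu$converged)
})

test_that("rank_for_contrast finds the minimal component count", {
  A <- rmat(15, 12, 44)
  b <- rnorm(15)
  an <- 1:3
  bg <- 7:12
  full <- contrast(tsvd_solve(A, b, 0), an, bg)
  rf <- rank_for_contrast(A, b, 0.9 * full, an, bg)
  expect_false(is.na(rf$rank))
  expect_gte(abs(rf$contrast), abs(0.9 * full))
  ## minimality: one component fewer must not reach the target
  sv <- svd(A)
  x <- drop(sv$v[, seq_len(rf$rank - 1), drop = FALSE] %*%
              (crossprod(sv$u[, seq_len(rf$rank - 1), drop = FALSE], b) /
                 sv$d[seq_len(rf$rank - 1)]))
  prev <- contrast(x, an, bg)
  expect_lt(abs(prev), abs(0.9 * full))
})

test_that("local maxima and localization errors behave on indicator images", {
  grid <- build_pixel_grid(disk_domain(1), 24)
  ctrs <- rbind(c(0.4, 0.3), c(-0.5, -0.1))
  img <- numeric(grid$N)
  for (i in 1:2) {
    d2 <- (grid$centers[, 1] - ctrs[i, 1])^2 +
      (grid$centers[, 2] - ctrs[i, 2])^2
    img[d2 < 0.15^2] <- 3 - i          # two peaks of different height
  }
  res <- recon <- structure(list(image = img, grid = grid, threshold = 0,
                                 rank = 0, method = "test"),
                            class = "eit_recon")
  le <- localization_error(res, ctrs)
  expect_true(all(le < 0.15))
  ## shifted indicator reports the shift distance
  shift <- c(0.2, 0)
  le_s <- localization_error(res, sweep(ctrs, 2, -shift))
  expect_equal(le_s, le + sqrt(sum(shift^2)), tolerance = 0.1)
  ## negative polarity finds conductivity drops
  res$image <- -img
  le_n <- localization_error(res, ctrs, polarity = "negative")
  expect_true(all(le_n < 0.15))
})

test_that("single-anomaly reconstruction peaks at the true anomaly location", {
  cs <- single_case("model1_single")
  rec <- reconstruct_conventional(cs$sens, cs$dv, 0.01)
  pk <- find_local_maxima(rec, n_max = 1)
  d <- sqrt((pk[1, "x"] - 0.8)^2 + pk[1, "y"]^2)
  expect_lt(d, 2 * cs$grid$side)
  ## doubling the perturbation (within the linear regime) doubles the image
  rec2 <- reconstruct_conventional(cs$sens,
                                   voltage_vector(2 * cs$dv$values,
                                                  cs$dv$protocol), 0.01)
  expect_equal(rec2$image, 2 * rec$image, tolerance = 1e-10)
})

test_that("local-ROI images are supported inside the ROI only", {
  cs <- single_case("model1_single")
  rec <- reconstruct_local(cs$filter, cs$sens, cs$dv, 0.01)
  outside <- !cs$grid$roi_mask
  expect_true(all(rec$image[outside] == 0))
  expect_gt(max(abs(rec$image)), 0)
})

test_that("outside_influence is zero for the reference case itself", {
  rp <- radish_potato_case()
  oi <- outside_influence(rp$dvs$case0, rp$dvs["case0"], rp$filter)
  expect_equal(oi$raw_norm, 0)
  expect_equal(oi$filt_norm, 0)
})
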