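test_that("with no outside sensitivity the filter returns the ROI column itself", {
  S <- cbind(rmat(6, 2, 21), matrix(0, 6, 3))
  sens <- fake_sens(S, R = 2)
  for (k in 1:2)
    expect_equal(filter_vector(sens, k, alpha = 0.37), S[, k],
                 tolerance = 1e-12)
})

test_that("phi_k approaches s_k monotonically as alpha grows", {
  sens <- fake_sens(rmat(12, 9, 22), R = 3)
  sk <- sens$S[, 2]
  dist <- vapply(10^seq(-2, 6, by = 1), function(a) {
    sqrt(sum((filter_vector(sens, 2, a) - sk)^2))
  }, 0)
  expect_true(all(diff(dist) < 1e-12))
  expect_lt(dist[length(dist)], 1e-4 * sqrt(sum(sk^2)))
})

test_that("as alpha -> 0 phi_k tends to the projection of s_k on null(t(S_out))", {
  sens <- fake_sens(rmat(8, 6, 23), R = 3)
  p <- partition_columns(sens)
  sv <- svd(p$S_out)
  rk <- sum(sv$d > 1e-10 * sv$d[1])
  Q <- sv$u[, seq_len(rk), drop = FALSE]
  proj <- drop((diag(nrow(sens$S)) - tcrossprod(Q)) %*% sens$S[, 1])
  phi <- filter_vector(sens, 1, alpha = 1e-10)
  expect_equal(phi, proj, tolerance = 1e-5)
})

test_that("the closed-form minimizer beats or ties a general-purpose optimizer", {
  worst_gap <- -Inf
  for (i in 1:20) {
    sens <- fake_sens(rmat(12, 9, 100 + i), R = 3)
    p <- partition_columns(sens)
    k <- (i %% 3) + 1
    sk <- p$S_D[, k]
    alpha <- 1
    obj <- function(phi) sum(drop(crossprod(p$S_out, phi))^2) +
      alpha * sum((phi - sk)^2)
    grad <- function(phi) 2 * drop(p$S_out %*% crossprod(p$S_out, phi)) +
      2 * alpha * (phi - sk)
    phi_cf <- filter_vector(sens, k, alpha)
    opt <- optim(sk, obj, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    worst_gap <- max(worst_gap, obj(phi_cf) - opt$value)
  }
  expect_lt(worst_gap, 1e-8)
})

test_that("build_filter columns equal individually computed filter vectors", {
  sens <- fake_sens(rmat(10, 7, 31), R = 3)
  fl <- build_filter(sens, alpha = 0.5)
  for (k in 1:3)
    expect_equal(fl$Phi[, k], filter_vector(sens, k, 0.5), tolerance = 1e-11)
  sens1 <- fake_sens(rmat(6, 4, 32), R = 1)
  expect_identical(ncol(build_filter(sens1, 1)$Phi), 1L)
  expect_error(build_filter(sens, alpha = -1), "positive")
  expect_error(filter_vector(sens, 99, 1), "ROI pixel")
})

test_that("orthogonal ROI/outside columns give an exactly leakage-free filter", {
  ## ROI columns live on the first 4 coordinates, outside columns on the rest
  set.seed(33)
  S <- cbind(rbind(matrix(rnorm(4 * 3), 4, 3), matrix(0, 8, 3)),
             rbind(matrix(0, 4, 5), matrix(rnorm(8 * 5), 8, 5)))
  sens <- fake_sens(S, R = 3)
  for (alpha in c(1e-3, 1, 1e3)) {
    fl <- build_filter(sens, alpha)
    expect_equal(fl$Phi, S[, 1:3], tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(max(abs(crossprod(fl$Phi, S[, 4:8]))), 1e-10)
    dv_out <- S[, 4:8] %*% runif(5)
    lk <- leakage(fl, dv_out, S[, 1:3] %*% c(1, 1, 1))
    expect_lt(lk$leakage, 1e-10)
  }
})

test_that("apply_filter reproduces direct matrix products", {
  sens <- fake_sens(rmat(9, 6, 34), R = 2)
  fl <- build_filter(sens, 2)
  v <- rnorm(9)
  ap <- apply_filter(fl, sens, v)
  expect_equal(ap$A_full, t(fl$Phi) %*% sens$S, tolerance = 1e-13)
  expect_equal(ap$A_roi, t(fl$Phi) %*% sens$S[, 1:2], tolerance = 1e-13)
  expect_equal(ap$b, drop(t(fl$Phi) %*% v), tolerance = 1e-13)
  expect_equal(apply_filter(fl, sens, rep(0, 9))$b, rep(0, 2))
  expect_error(apply_filter(fl, sens, rnorm(5)), "dimension")
})

test_that("leakage reports zero for absent outside signal and the raw ratio", {
  sens <- fake_sens(rmat(7, 5, 35), R = 2)
  fl <- build_filter(sens, 1)
  lk <- leakage(fl, rep(0, 7), rnorm(7))
  expect_identical(lk$leakage, 0)
  expect_identical(lk$ratio, 0)
  lk2 <- leakage(fl, rnorm(7), rep(0, 7))
  expect_true(is.na(lk2$ratio))
})

test_that("default alpha scales with the squared data scale and has a fallback", {
  sens <- fake_sens(rmat(8, 6, 36), R = 2)
  a1 <- default_alpha(sens)
  sens3 <- fake_sens(3 * sens$S, R = 2)
  expect_equal(default_alpha(sens3), 9 * a1, tolerance = 1e-10)
  szero <- fake_sens(cbind(rmat(8, 2, 37), matrix(0, 8, 4)), R = 2)
  expect_identical(default_alpha(szero), 1)
})
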