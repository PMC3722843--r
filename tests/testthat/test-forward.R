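test_that("protocols enumerate the expected drive/measurement combinations", {
  lay <- make_layout(E = 16, mode = "equidistant", internal_position = c(0.5, 0))
  p_adj <- make_protocol(lay, "boundary_adjacent")
  expect_identical(nrow(p_adj$drives) * nrow(p_adj$meas), 256L)
  p_full <- make_protocol(lay, "internal_augmented", "both")
  expect_identical(dim(p_full$drives), c(32L, 2L))
  expect_identical(dim(p_full$meas), c(32L, 2L))
  p_drv <- make_protocol(lay, "internal_augmented", "drive")
  expect_identical(dim(p_drv$drives), c(32L, 2L))
  expect_identical(dim(p_drv$meas), c(16L, 2L))
  expect_error(make_protocol(make_layout(E = 16), "internal_augmented"),
               "internal electrode")
})

test_that("gap-model loads conserve current and electrode averages are exact on constants", {
  cs <- coarse_case()
  w <- eitroi:::electrode_weights(cs$mesh)
  for (we in w) expect_equal(sum(we), 1, tolerance = 1e-12)
  load <- eitroi:::drive_load(w, 1, 5, current = 2.5)
  expect_equal(sum(load), 0, tolerance = 1e-14)
  u_const <- rep(3.25, nrow(cs$mesh$nodes))
  for (e in seq_along(w))
    expect_equal(electrode_voltage(u_const, cs$mesh, e), 3.25,
                 tolerance = 1e-12)
  expect_error(electrode_voltage(u_const, cs$mesh, 99), "electrode")
})

test_that("potentials scale as 1/sigma and have zero mean", {
  cs <- coarse_case()
  pot1 <- solve_forward(cs$mesh, 1, c(1, 3))
  pot2 <- solve_forward(cs$mesh, 2, c(1, 3))
  expect_equal(mean(pot1$u), 0, tolerance = 1e-10)
  expect_equal(pot2$u, pot1$u / 2, tolerance = 1e-9)
})

test_that("a mirror-symmetric drive yields antisymmetric electrode voltages", {
  lay <- make_layout(E = 16, mode = "equidistant")
  mesh <- build_mesh(lay, 0.08)
  ## drive between electrodes at pi/2 and 3*pi/2: reflection y -> -y swaps
  ## source and sink, so mirrored electrodes see opposite voltages
  pot <- solve_forward(mesh, 1, c(5, 13))
  ev <- vapply(1:16, function(e) electrode_voltage(pot, mesh, e), 0)
  mirror <- c(1, 16:2)        # angle theta -> -theta
  expect_equal(ev, -ev[mirror], tolerance = 0.05 * max(abs(ev)),
               ignore_attr = TRUE)
})

test_that("collected data satisfy reciprocity and the telescoping ring sum", {
  cs <- coarse_case()
  pr <- make_protocol(cs$layout, "boundary_adjacent")
  v <- collect_data(cs$mesh, cs$sigma, pr)
  E <- cs$layout$E
  V <- matrix(v$values, E, E, byrow = TRUE)
  expect_lt(max(abs(V - t(V))) / max(abs(V)), 1e-10)
  expect_lt(max(abs(rowSums(V))) / max(abs(V)), 1e-10)
})

test_that("difference data vanish for identical fields and scale linearly", {
  cs <- coarse_case()
  dv0 <- difference_data(cs$mesh, cs$sigma, cs$sigma, cs$protocol)
  expect_equal(max(abs(dv0$values)), 0, tolerance = 1e-13)

  sig_eps <- function(eps) {
    s <- as.numeric(cs$sigma)
    gx <- (cs$mesh$nodes[cs$mesh$triangles[, 1], 1] +
             cs$mesh$nodes[cs$mesh$triangles[, 2], 1] +
             cs$mesh$nodes[cs$mesh$triangles[, 3], 1]) / 3
    gy <- (cs$mesh$nodes[cs$mesh$triangles[, 1], 2] +
             cs$mesh$nodes[cs$mesh$triangles[, 2], 2] +
             cs$mesh$nodes[cs$mesh$triangles[, 3], 2]) / 3
    s[(gx - 0.5)^2 + gy^2 < 0.1^2] <- 1 + eps
    conductivity_field(cs$mesh, s)
  }
  n1 <- sqrt(sum(difference_data(cs$mesh, cs$sigma, sig_eps(1e-3),
                                 cs$protocol)$values^2))
  n2 <- sqrt(sum(difference_data(cs$mesh, cs$sigma, sig_eps(5e-4),
                                 cs$protocol)$values^2))
  expect_equal(n1 / n2, 2, tolerance = 0.01)
})

test_that("added noise is reproducible and matches the requested SNR", {
  v <- voltage_vector(rep(c(1, -1), 5000))
  expect_identical(add_noise(v, Inf, 1)$values, v$values)
  n1 <- add_noise(v, 20, seed = 42)
  n2 <- add_noise(v, 20, seed = 42)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_noise(v, 20, seed = 43)$values, n1$values))
  snr_emp <- 10 * log10(mean(v$values^2) / mean((n1$values - v$values)^2))
  expect_lt(abs(snr_emp - 20), 0.5)
})

test_that("voltage CSV files round-trip in protocol order", {
  cs <- coarse_case()
  v <- collect_data(cs$mesh, cs$sigma, cs$protocol)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voltages(v, path)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "drive_pos,drive_neg,meas_pos,meas_neg,value")
  back <- read_voltages(path)
  expect_equal(back$values, v$values, tolerance = 1e-12)
})
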