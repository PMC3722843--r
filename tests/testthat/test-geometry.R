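test_that("equidistant layouts place electrodes at 2*pi*j/E and rotate onto themselves", {
  lay <- make_layout(E = 16, mode = "equidistant")
  expect_equal(lay$angles, 2 * pi * (0:15) / 16)
  rot <- sort((lay$angles + 2 * pi / 16) %% (2 * pi))
  expect_equal(rot, lay$angles, tolerance = 1e-12)
  expect_equal(lay$arc_width, pi / 16)
})

test_that("clustered layouts follow the two-density scheme", {
  lay <- make_layout(E = 16, mode = "clustered", internal_position = c(0.5, 0),
                     cluster_fraction = 1 / 2, cluster_sector = 2 * pi / 3)
  in_sector <- abs(((lay$angles + pi) %% (2 * pi)) - pi) < pi / 3
  expect_equal(sum(in_sector), 8)
  gaps_in <- diff(sort(((lay$angles[in_sector] + pi) %% (2 * pi)) - pi))
  expect_equal(gaps_in, rep(2 * pi / 3 / 8, 7), tolerance = 1e-12)
  out_ang <- sort(lay$angles[!in_sector])
  expect_equal(diff(out_ang), rep((2 * pi - 2 * pi / 3) / 8, 7),
               tolerance = 1e-12)
  expect_equal(lay$arc_width, (2 * pi / 3 / 8) / 2, tolerance = 1e-12)
})

test_that("layout preconditions are enforced", {
  expect_error(make_layout(E = 3), "E must be")
  expect_error(make_layout(E = 8, mode = "clustered"), "internal electrode")
  expect_error(make_layout(E = 8, internal_position = c(1.1, 0)),
               "strictly inside")
  expect_error(make_layout(E = 16, arc_width = pi), "overlap")
})

test_that("ROI radius follows the 5/6-of-nearest-electrode rule", {
  lay <- make_layout(E = 16, mode = "equidistant", domain = disk_domain(0.07),
                     internal_position = c(0.035, 0))
  roi <- compute_roi(lay)
  expect_equal(roi$radius, 5 / 6 * 0.035, tolerance = 1e-12)
  expect_equal(roi$center, c(0.035, 0))

  lay0 <- make_layout(E = 16, mode = "equidistant",
                      internal_position = c(0, 0))
  expect_equal(compute_roi(lay0)$radius, 5 / 6, tolerance = 1e-12)

  lay5 <- make_layout(E = 16, mode = "equidistant",
                      internal_position = c(0.5, 0))
  expect_equal(compute_roi(lay5)$radius, 5 / 12, tolerance = 1e-12)

  expect_error(compute_roi(make_layout(E = 16)), "no internal electrode")
})

test_that("the 5/6-rule ROI stays strictly inside the domain", {
  for (r in c(0.1, 0.4, 0.7)) for (th in c(0, 1.1, 2.5)) {
    lay <- make_layout(E = 16, mode = "equidistant",
                       internal_position = r * c(cos(th), sin(th)))
    roi <- compute_roi(lay)
    expect_gt(roi$radius, 0)
    expect_lt(sqrt(sum(roi$center^2)) + roi$radius, 1)
  }
})

test_that("meshes conform to electrode arcs and the internal-electrode hole", {
  lay <- make_layout(E = 16, mode = "clustered", internal_position = c(0.5, 0))
  mesh <- build_mesh(lay, 0.08)
  expect_length(mesh$electrode_edges, 17)
  expect_true(all(vapply(mesh$electrode_edges, nrow, 1L) >= 2))
  ## triangles positively oriented
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  t <- mesh$triangles
  a2 <- (x[t[, 2]] - x[t[, 1]]) * (y[t[, 3]] - y[t[, 1]]) -
    (y[t[, 2]] - y[t[, 1]]) * (x[t[, 3]] - x[t[, 1]])
  expect_true(all(a2 > 0))
  ## hole edges lie on the internal electrode circle
  hole_nodes <- unique(as.vector(mesh$electrode_edges[[17]]))
  d <- sqrt((mesh$nodes[hole_nodes, 1] - 0.5)^2 + mesh$nodes[hole_nodes, 2]^2)
  expect_equal(d, rep(lay$internal$radius, length(d)), tolerance = 1e-9)
  ## no mesh node strictly inside the hole
  dall <- sqrt((mesh$nodes[, 1] - 0.5)^2 + mesh$nodes[, 2]^2)
  expect_true(all(dall >= lay$internal$radius - 1e-9))
})

test_that("mesh text files round-trip exactly", {
  lay <- make_layout(E = 8, mode = "equidistant", internal_position = c(0.4, 0.1))
  mesh <- build_mesh(lay, 0.15)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_equal(back$nodes, mesh$nodes, ignore_attr = TRUE)
  expect_equal(back$triangles, mesh$triangles, ignore_attr = TRUE)
  expect_equal(back$electrode_edges, mesh$electrode_edges,
               ignore_attr = TRUE)
})

test_that("pixel grids clip to the disk and count ROI pixels correctly", {
  g <- build_pixel_grid(disk_domain(1), 32)
  expect_lte(g$N, 32^2)
  expect_true(all(rowSums(g$centers^2) < 1))

  roi <- roi_region(c(0.5, 0), 5 / 12)
  g64 <- build_pixel_grid(disk_domain(1), 64, roi)
  brute <- sum((g64$centers[, 1] - 0.5)^2 + g64$centers[, 2]^2 < (5 / 12)^2)
  expect_identical(g64$R, brute)
  ## ROI-first ordering is a permutation of the full pixel set
  expect_identical(sort(g64$order_roi_first), seq_len(g64$N))
  expect_true(all(g64$roi_mask[g64$order_roi_first[seq_len(g64$R)]]))

  ## ROI covering every pixel center gives R = N
  gall <- build_pixel_grid(disk_domain(1), 16, roi_region(c(0, 0), 0.999))
  expect_identical(gall$R, gall$N)

  expect_error(build_pixel_grid(disk_domain(1), 16,
                                roi_region(c(0.9, 0), 1e-4)),
               "no pixel center")
  expect_error(build_pixel_grid(disk_domain(1), 4), "pixels_per_diameter")
})
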