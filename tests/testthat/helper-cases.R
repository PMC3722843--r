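## Shared simulation fixtures, built once per test run and cached.

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .case_cache)) assign(key, builder(), .case_cache)
  get(key, .case_cache)
}

## coarse unit-disk configuration with an internal electrode (fast checks)
coarse_case <- function() cached("coarse", function() {
  lay <- make_layout(E = 8, mode = "equidistant", internal_position = c(0.5, 0))
  mesh <- build_mesh(lay, 0.12)
  roi <- compute_roi(lay)
  grid <- build_pixel_grid(disk_domain(1), 16, roi)
  protocol <- make_protocol(lay, "internal_augmented", "drive")
  sigma <- conductivity_field(mesh, 1, reference = TRUE)
  sens <- suppressWarnings(compute_sensitivity(mesh, sigma, protocol, grid))
  list(layout = lay, mesh = mesh, roi = roi, grid = grid,
       protocol = protocol, sigma = sigma, sens = sens)
})

## one of the single-anomaly phantoms at study resolution
single_case <- function(name) cached(name, function() {
  s <- scenario(name)
  lay <- scenario_layout(s)
  mesh <- build_mesh(lay, 0.05 * s$radius)
  roi <- if (!is.null(lay$internal)) compute_roi(lay) else
    compute_roi(make_layout(E = s$E, mode = "equidistant",
                            domain = disk_domain(s$radius),
                            internal_position = s$roi_reference))
  grid <- build_pixel_grid(disk_domain(s$radius), 32, roi)
  protocol <- scenario_protocol(s, lay)
  sigma_ref <- conductivity_field(mesh, s$background, reference = TRUE)
  dv <- difference_data(mesh, sigma_ref, scenario_sigma(mesh, s), protocol)
  sens <- compute_sensitivity(mesh, sigma_ref, protocol, grid)
  filt <- if (!is.null(lay$internal)) build_filter(sens) else NULL
  list(scenario = s, layout = lay, mesh = mesh, roi = roi, grid = grid,
       protocol = protocol, sigma_ref = sigma_ref, dv = dv, sens = sens,
       filter = filt)
})

## four-anomaly simulation at the resolution used for localization claims
four_anomaly_case <- function() cached("four", function() {
  s <- scenario("model2_four_anomaly_sim")
  lay <- scenario_layout(s)
  mesh <- build_mesh(lay, 0.035 * s$radius)
  roi <- compute_roi(lay)
  grid <- build_pixel_grid(disk_domain(s$radius), 40, roi)
  protocol <- scenario_protocol(s, lay)
  sigma_ref <- conductivity_field(mesh, s$background, reference = TRUE)
  dv <- difference_data(mesh, sigma_ref, scenario_sigma(mesh, s), protocol)
  sens <- compute_sensitivity(mesh, sigma_ref, protocol, grid)
  filt <- build_filter(sens)
  list(scenario = s, mesh = mesh, roi = roi, grid = grid,
       protocol = protocol, sigma_ref = sigma_ref, dv = dv, sens = sens,
       filter = filt)
})

## radish/potato influence study: shared mesh/filter, per-case data
radish_potato_case <- function() cached("rp", function() {
  s0 <- scenario("model2_radish_potato_case0")
  lay <- scenario_layout(s0)
  mesh <- build_mesh(lay, 0.04 * s0$radius)
  roi <- compute_roi(lay)
  grid <- build_pixel_grid(disk_domain(s0$radius), 32, roi)
  protocol <- scenario_protocol(s0, lay)
  sigma_ref <- conductivity_field(mesh, s0$background, reference = TRUE)
  sens <- compute_sensitivity(mesh, sigma_ref, protocol, grid)
  filt <- build_filter(sens)
  dvs <- lapply(0:3, function(i) {
    si <- scenario(paste0("model2_radish_potato_case", i))
    difference_data(mesh, sigma_ref, scenario_sigma(mesh, si), protocol)
  })
  names(dvs) <- paste0("case", 0:3)
  list(mesh = mesh, roi = roi, grid = grid, protocol = protocol,
       sens = sens, filter = filt, dvs = dvs)
})

## synthetic sensitivity container for algebra-level tests
fake_sens <- function(S, R, grid = NULL) {
  structure(list(S = S, pixel_ids = seq_len(ncol(S)), R = R, grid = grid,
                 protocol = NULL),
            class = "eit_sens")
}

## deterministic random matrix
rmat <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}
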