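## Phantom scenario registry, anomaly rasterization, percent contrast, and
## the end-to-end pipeline driver.

scenario_names <- c("model0_single", "model1_single", "model2_single",
                    "model2_four_anomaly_sim", "model2_four_carrot",
                    paste0("model2_radish_potato_case", 0:3))

#' Simulated phantom scenarios
#'
#' Registry of the disk phantoms the package reproduces in silico.
#'
#' Single-anomaly phantoms (normalized units): unit disk, 1 S/m background,
#' one 2 S/m anomaly of diameter 0.1428 at (0.8, 0); the internal electrode
#' (Models 1 and 2) sits at (0.5, 0). Model 0 = equidistant surface
#' electrodes only; Model 1 = equidistant + internal electrode; Model 2 =
#' ROI-clustered surface electrodes + internal electrode.
#'
#' Four-anomaly simulation (meters): disk radius 0.07 m, 0.0418 S/m saline,
#' four 0.029 S/m objects of diameter 0.01 m at (0.02, +-0.015) and
#' (0.05, +-0.015), internal electrode at (0.035, 0), Model 2 electrodes.
#'
#' Four-carrot phantom (meters): 0.06 S/m saline, four 0.04 S/m objects of
#' diameter 0.02 m at (0.015, 0.02), (0.055, 0.02), (0.055, -0.02),
#' (0.015, -0.02).
#'
#' Radish/potato cases (meters): 0.042 S/m saline, a radish (0.038 S/m,
#' diameter 0.012 m) inside the ROI at (0.056, 0); cases 1-3 add a potato
#' (0.029 S/m, diameter 0.012 m) outside the ROI at (-0.056, 0),
#' (-0.035, -0.04) and (0, -0.056) respectively; case 0 has the radish only.
#'
#' @param name One of `scenario_names()`.
#' @return Object of class `eit_scenario`: `name`, `units`, `radius`,
#'   `background` (S/m), `anomalies` (data frame `x`, `y`, `diameter`,
#'   `sigma`, `in_roi`), `internal_position` (or NULL), `mode`, `scheme`,
#'   `E`.
#' @export
scenario <- function(name) {
  if (!name %in% scenario_names)
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(scenario_names, collapse = ", ")))
  an <- function(x, y, diameter, sigma, in_roi)
    data.frame(x = x, y = y, diameter = diameter, sigma = sigma,
               in_roi = in_roi)
  s <- switch(
    name,
    model0_single = list(units = "normalized", radius = 1, background = 1,
                         anomalies = an(0.8, 0, 0.1428, 2, TRUE),
                         internal_position = NULL, mode = "equidistant",
                         scheme = "boundary_adjacent",
                         roi_reference = c(0.5, 0)),
    model1_single = list(units = "normalized", radius = 1, background = 1,
                         anomalies = an(0.8, 0, 0.1428, 2, TRUE),
                         internal_position = c(0.5, 0),
                         mode = "equidistant",
                         scheme = "internal_augmented",
                         internal_role = "drive"),
    model2_single = list(units = "normalized", radius = 1, background = 1,
                         anomalies = an(0.8, 0, 0.1428, 2, TRUE),
                         internal_position = c(0.5, 0), mode = "clustered",
                         scheme = "internal_augmented",
                         internal_role = "drive"),
    model2_four_anomaly_sim = list(
      units = "m", radius = 0.07, background = 0.0418,
      anomalies = an(c(0.02, 0.02, 0.05, 0.05),
                     c(0.015, -0.015, -0.015, 0.015),
                     0.01, 0.029, TRUE),
      internal_position = c(0.035, 0), mode = "clustered",
      scheme = "internal_augmented", internal_role = "drive"),
    model2_four_carrot = list(
      units = "m", radius = 0.07, background = 0.06,
      anomalies = an(c(0.015, 0.055, 0.055, 0.015),
                     c(0.02, 0.02, -0.02, -0.02),
                     0.02, 0.04, c(TRUE, TRUE, TRUE, TRUE)),
      internal_position = c(0.035, 0), mode = "clustered",
      scheme = "internal_augmented", internal_role = "drive"),
    model2_radish_potato_case0 = radish_potato(NULL),
    model2_radish_potato_case1 = radish_potato(c(-0.056, 0)),
    model2_radish_potato_case2 = radish_potato(c(-0.035, -0.04)),
    model2_radish_potato_case3 = radish_potato(c(0, -0.056)))
  s$name <- name
  s$E <- 16L
  s <- structure(s, class = "eit_scenario")
  validate_scenario(s)
  s
}

radish_potato <- function(potato_pos) {
  anomalies <- data.frame(x = 0.056, y = 0, diameter = 0.012, sigma = 0.038,
                          in_roi = TRUE)
  if (!is.null(potato_pos))
    anomalies <- rbind(anomalies,
                       data.frame(x = potato_pos[1], y = potato_pos[2],
                                  diameter = 0.012, sigma = 0.029,
                                  in_roi = FALSE))
  list(units = "m", radius = 0.07, background = 0.042, anomalies = anomalies,
       internal_position = c(0.035, 0), mode = "clustered",
       scheme = "internal_augmented", internal_role = "drive")
}

#' @rdname scenario
#' @export
list_scenarios <- function() scenario_names

validate_scenario <- function(s) {
  r_an <- s$anomalies$diameter / 2
  d_an <- sqrt(s$anomalies$x^2 + s$anomalies$y^2)
  if (any(d_an + r_an >= s$radius))
    stop(sprintf("scenario %s: anomaly outside the domain", s$name))
  if (any(s$anomalies$sigma <= 0) || s$background <= 0)
    stop(sprintf("scenario %s: non-positive conductivity", s$name))
  if (!is.null(s$internal_position)) {
    roi <- compute_roi(scenario_layout(s))
    din <- sqrt((s$anomalies$x - roi$center[1])^2 +
                  (s$anomalies$y - roi$center[2])^2)
    if (any(s$anomalies$in_roi & din >= roi$radius))
      stop(sprintf("scenario %s: an in-ROI anomaly center lies outside the ROI",
                   s$name))
    if (any(!s$anomalies$in_roi & din < roi$radius))
      stop(sprintf("scenario %s: an outside anomaly center lies inside the ROI",
                   s$name))
  }
  invisible(s)
}

#' @export
print.eit_scenario <- function(x, ...) {
  cat(sprintf("<eit_scenario> %s (%s units): radius %g, background %g S/m, %d anomaly(ies)%s\n",
              x$name, x$units, x$radius, x$background, nrow(x$anomalies),
              if (is.null(x$internal_position)) ""
              else sprintf(", internal electrode (%g, %g)",
                           x$internal_position[1], x$internal_position[2])))
  invisible(x)
}

#' Drive/measurement protocol of a scenario
#' @param s An `eit_scenario`.
#' @param layout The scenario layout (built if omitted).
#' @return An `eit_protocol`.
#' @export
scenario_protocol <- function(s, layout = scenario_layout(s)) {
  if (s$scheme == "boundary_adjacent") make_protocol(layout, s$scheme)
  else make_protocol(layout, s$scheme,
                     if (is.null(s$internal_role)) "both" else s$internal_role)
}

#' Electrode layout of a scenario
#' @param s An `eit_scenario`.
#' @param E Electrode count override.
#' @return An `eit_layout`.
#' @export
scenario_layout <- function(s, E = s$E) {
  make_layout(E = E, mode = s$mode, domain = disk_domain(s$radius),
              internal_position = s$internal_position)
}

#' Rasterize a scenario's conductivity onto a mesh
#'
#' A triangle takes an anomaly's conductivity iff its centroid lies inside
#' the anomaly disk; all other triangles take the background value.
#'
#' @param mesh An `eit_mesh`.
#' @param s An `eit_scenario`.
#' @param which_anomalies Indices of the anomalies to paint (default all);
#'   use a subset to simulate the in-ROI / outside-ROI components
#'   separately.
#' @return An `eit_sigma`.
#' @export
scenario_sigma <- function(mesh, s, which_anomalies = seq_len(nrow(s$anomalies))) {
  tri <- mesh$triangles
  gx <- (mesh$nodes[tri[, 1], 1] + mesh$nodes[tri[, 2], 1] +
           mesh$nodes[tri[, 3], 1]) / 3
  gy <- (mesh$nodes[tri[, 1], 2] + mesh$nodes[tri[, 2], 2] +
           mesh$nodes[tri[, 3], 2]) / 3
  sig <- rep(s$background, nrow(tri))
  for (a in which_anomalies) {
    r <- s$anomalies$diameter[a] / 2
    hit <- (gx - s$anomalies$x[a])^2 + (gy - s$anomalies$y[a])^2 < r^2
    sig[hit] <- s$anomalies$sigma[a]
  }
  conductivity_field(mesh, sig)
}

#' Percent conductivity contrast of an object against background
#'
#' `100 * (sigma_background - sigma_object) / sigma_background`: positive for
#' an object less conductive than the background.
#'
#' @param sigma_object,sigma_background Conductivities (S/m, > 0).
#' @param digits Rounding for reporting (`NULL` = no rounding).
#' @return Percent contrast.
#' @export
percent_contrast <- function(sigma_object, sigma_background, digits = 1) {
  if (sigma_object <= 0 || sigma_background <= 0)
    stop("conductivities must be > 0")
  pc <- 100 * (sigma_background - sigma_object) / sigma_background
  if (is.null(digits)) pc else round(pc, digits)
}

#' Run the full local-ROI imaging pipeline for a scenario
#'
#' Meshes the scenario, simulates reference and perturbed data, computes the
#' time-difference data, sensitivity matrix, ROI filter, conventional and
#' local-ROI reconstructions, and the diagnostic metrics, writing every
#' artifact plus a machine-readable manifest into `config$outdir`. The run is
#' deterministic for a fixed config (noise uses `config$seed`).
#'
#' Config keys (unknown keys are rejected): `scenario` (registry name) or
#' `scenario_inline` (an `eit_scenario`), `mesh_h_rel` (target edge length
#' relative to the domain radius; default 0.06), `pixels_per_diameter`
#' (default 32), `alpha` (default: [default_alpha()]), `rel_threshold`
#' (default 0.01), `snr_db` (default `Inf` = noiseless), `seed` (default 1),
#' `E` (default 16), `outdir`, `stages` (subset of
#' `c("simulate", "sens", "filter", "recon", "metrics")`; default all).
#'
#' @param config Named list (or path to a JSON file with the same keys).
#' @return Invisibly, a list with the computed objects and the metrics table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(scenario = NULL, scenario_inline = NULL,
                   mesh_h_rel = 0.05, pixels_per_diameter = 32,
                   alpha = NULL, rel_threshold = 0.01, snr_db = Inf,
                   seed = 1, E = 16,
                   outdir = file.path(tempdir(), "eitroi_run"),
                   stages = c("simulate", "sens", "filter", "recon",
                              "metrics"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  s <- if (!is.null(cfg$scenario_inline)) cfg$scenario_inline
       else scenario(cfg$scenario)
  stages <- match.arg(cfg$stages,
                      c("simulate", "sens", "filter", "recon", "metrics"),
                      several.ok = TRUE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)

  layout <- scenario_layout(s, cfg$E)
  mesh <- build_mesh(layout, cfg$mesh_h_rel * s$radius)
  roi <- if (!is.null(layout$internal)) compute_roi(layout)
         else if (!is.null(s$roi_reference)) {
           tmp <- make_layout(E = cfg$E, mode = "equidistant",
                              domain = disk_domain(s$radius),
                              internal_position = s$roi_reference)
           compute_roi(tmp)
         } else NULL
  grid <- build_pixel_grid(disk_domain(s$radius), cfg$pixels_per_diameter, roi)
  protocol <- scenario_protocol(s, layout)
  res <- list(config = cfg, scenario = s, layout = layout, mesh = mesh,
              roi = roi, grid = grid, protocol = protocol)

  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if ("simulate" %in% stages) stage_err("simulate", {
    write_mesh(mesh, out("mesh.txt"))
    sigma_ref <- conductivity_field(mesh, s$background, reference = TRUE)
    sigma_pert <- scenario_sigma(mesh, s)
    v_ref <- collect_data(mesh, sigma_ref, protocol)
    v_pert <- collect_data(mesh, sigma_pert, protocol)
    dv <- voltage_vector(v_pert$values - v_ref$values, protocol)
    if (is.finite(cfg$snr_db)) dv <- add_noise(dv, cfg$snr_db, cfg$seed)
    write_voltages(v_ref, out("v_reference.csv"))
    write_voltages(v_pert, out("v_perturbed.csv"))
    write_voltages(dv, out("dv.csv"))
    res$sigma_ref <- sigma_ref
    res$dv <- dv
  })

  if ("sens" %in% stages) stage_err("sens", {
    sens <- compute_sensitivity(mesh, res$sigma_ref, protocol, grid)
    write_matrix(sens, out("sensitivity.csv"))
    res$sens <- sens
  })

  has_roi <- !is.null(roi) && grid$R > 0 && grid$R < grid$N
  if ("filter" %in% stages && has_roi && !is.null(layout$internal))
    stage_err("filter", {
      filt <- build_filter(res$sens, cfg$alpha)
      write_filter(filt, out("filter.csv"))
      res$filter <- filt
    })

  if ("recon" %in% stages) stage_err("recon", {
    rec_c <- reconstruct_conventional(res$sens, res$dv, cfg$rel_threshold)
    write.csv(data.frame(pixel = seq_len(grid$N),
                         x = grid$centers[, 1], y = grid$centers[, 2],
                         dgamma = rec_c$image),
              out("image_conventional.csv"), row.names = FALSE)
    res$recon_conventional <- rec_c
    if (!is.null(res$filter)) {
      rec_l <- reconstruct_local(res$filter, res$sens, res$dv,
                                 cfg$rel_threshold)
      write.csv(data.frame(pixel = seq_len(grid$N),
                           x = grid$centers[, 1], y = grid$centers[, 2],
                           dgamma = rec_l$image),
                out("image_local.csv"), row.names = FALSE)
      res$recon_local <- rec_l
    }
  })

  if ("metrics" %in% stages) stage_err("metrics", {
    metrics <- list(scenario = s$name, E = cfg$E, scheme = s$scheme,
                    alpha = if (!is.null(res$filter)) res$filter$alpha else NA,
                    rel_threshold = cfg$rel_threshold,
                    snr_db = cfg$snr_db, seed = cfg$seed,
                    mesh_nodes = nrow(mesh$nodes),
                    pixels = grid$N, roi_pixels = grid$R)
    if (has_roi) {
      mu <- cross_correlation(res$sens)
      nr <- norm_ratio(res$sens)
      metrics$mu_mean <- mean(mu, na.rm = TRUE)
      metrics$in_ratio_S <- unname(nr["in_ratio"])
      metrics$out_ratio_S <- unname(nr["out_ratio"])
      if (!is.null(res$filter)) {
        ap <- apply_filter(res$filter, res$sens, res$dv)
        nrf <- norm_ratio(ap$A_full, res$filter$R)
        metrics$in_ratio_filtered <- unname(nrf["in_ratio"])
        metrics$out_ratio_filtered <- unname(nrf["out_ratio"])
        if (any(s$anomalies$in_roi) && any(!s$anomalies$in_roi)) {
          sigma_ref <- res$sigma_ref
          dv_roi <- difference_data(mesh, sigma_ref,
                                    scenario_sigma(mesh, s, which(s$anomalies$in_roi)),
                                    protocol)
          dv_out <- difference_data(mesh, sigma_ref,
                                    scenario_sigma(mesh, s, which(!s$anomalies$in_roi)),
                                    protocol)
          lk <- leakage(res$filter, dv_out, dv_roi)
          metrics$leakage <- lk$leakage
          metrics$leakage_ratio <- lk$ratio
          metrics$raw_ratio <- lk$raw_ratio
        }
      }
    }
    if (!is.null(res$recon_local)) {
      ctr <- cbind(s$anomalies$x, s$anomalies$y)[s$anomalies$in_roi, , drop = FALSE]
      metrics$localization_error <-
        localization_error(res$recon_local, ctr)
    }
    jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    manifest <- list(package = "eitroi",
                     version = as.character(utils::packageVersion("eitroi")),
                     config = cfg[setdiff(names(cfg), "scenario_inline")],
                     scenario = s$name)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
    res$metrics <- metrics
  })

  invisible(res)
}
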