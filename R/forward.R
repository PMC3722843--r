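## Forward problem: P1 FEM for the conductivity equation with gap-model
## electrodes, drive/measurement protocols, and voltage data vectors.

#' Per-triangle conductivity field
#'
#' @param mesh An `eit_mesh`.
#' @param values Either a single positive conductivity (S/m) applied to every
#'   triangle, or a vector with one value per triangle.
#' @param reference Logical flag marking this field as the reference
#'   (background) conductivity of a time-difference pair.
#' @return Object of class `eit_sigma` (numeric vector with attributes).
#' @export
conductivity_field <- function(mesh, values, reference = FALSE) {
  stopifnot(inherits(mesh, "eit_mesh"))
  nt <- nrow(mesh$triangles)
  if (length(values) == 1) values <- rep(values, nt)
  if (length(values) != nt) stop("one conductivity value per triangle required")
  if (!all(is.finite(values)) || any(values <= 0))
    stop("conductivities must be finite and > 0")
  structure(as.numeric(values), class = "eit_sigma", reference = reference)
}

## --- FEM internals ----------------------------------------------------------

## P1 gradient coefficients: grad(u)|_T = (sum_i b_i u_i, sum_i c_i u_i)
mesh_fem <- function(mesh) {
  if (!is.null(mesh$.fem)) return(mesh$.fem)
  tri <- mesh$triangles
  x <- matrix(mesh$nodes[tri, 1], ncol = 3)
  y <- matrix(mesh$nodes[tri, 2], ncol = 3)
  a2 <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
    (y[, 2] - y[, 1]) * (x[, 3] - x[, 1])
  area <- a2 / 2
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / a2
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / a2
  list(area = area, b = b, c = cc, n = nrow(mesh$nodes))
}

assemble_stiffness <- function(mesh, sigma, fem = mesh_fem(mesh)) {
  tri <- mesh$triangles
  w <- as.numeric(sigma) * fem$area
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, i]
    jj[[k]] <- tri[, j]
    vv[[k]] <- w * (fem$b[, i] * fem$b[, j] + fem$c[, i] * fem$c[, j])
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
               dims = c(fem$n, fem$n))
}

## per-electrode averaging weights (trapezoid over boundary edges):
## w_e^T u = arc-averaged potential on electrode e; sum(w_e) = 1
electrode_weights <- function(mesh) {
  n <- nrow(mesh$nodes)
  lapply(mesh$electrode_edges, function(ed) {
    len <- sqrt(rowSums((mesh$nodes[ed[, 1], , drop = FALSE] -
                           mesh$nodes[ed[, 2], , drop = FALSE])^2))
    w <- numeric(n)
    for (k in seq_along(len)) {
      w[ed[k, 1]] <- w[ed[k, 1]] + len[k] / 2
      w[ed[k, 2]] <- w[ed[k, 2]] + len[k] / 2
    }
    w / sum(len)
  })
}

## gap-model load vector: +I uniformly over source arc, -I over sink arc
drive_load <- function(weights, source, sink, current = 1) {
  if (source < 1 || source > length(weights) ||
      sink < 1 || sink > length(weights) || source == sink)
    stop("invalid drive electrode pair")
  current * (weights[[source]] - weights[[sink]])
}

## Solve the FE system for several drives at once with a zero-mean gauge,
## via the bordered (Lagrange-multiplier) system [[K, 1], [1', 0]].
solve_fields <- function(mesh, sigma, patterns, currents = 1,
                         weights = electrode_weights(mesh)) {
  fem <- mesh_fem(mesh)
  K <- assemble_stiffness(mesh, sigma, fem)
  n <- fem$n
  one <- rep(1, n)
  Kb <- rbind(cbind(K, one), c(one, 0))
  P <- nrow(patterns)
  currents <- rep_len(currents, P)
  B <- matrix(0, n + 1, P)
  for (p in seq_len(P))
    B[1:n, p] <- drive_load(weights, patterns[p, 1], patterns[p, 2],
                            currents[p])
  U <- as.matrix(Matrix::solve(Kb, B))
  U[1:n, , drop = FALSE]
}

#' Solve the forward problem for one drive pattern
#'
#' Galerkin P1 solution of `div(sigma grad u) = 0` on the meshed disk with
#' gap-model Neumann data: uniform inward current density `I/|E|` on the
#' source electrode arc, `-I/|E|` on the sink arc, insulating elsewhere.
#' The additive constant is fixed by a zero-mean gauge over all nodes.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma An `eit_sigma` (or numeric vector/scalar of conductivities).
#' @param drive List or vector `(source, sink)` of electrode indices
#'   (internal electrode = E + 1), plus optional `current` (default 1 A).
#' @return Object of class `eit_potential`: `u` (nodal values), `drive`.
#' @export
solve_forward <- function(mesh, sigma, drive) {
  if (!inherits(sigma, "eit_sigma")) sigma <- conductivity_field(mesh, sigma)
  if (is.list(drive)) {
    src <- drive$source; snk <- drive$sink
    cur <- if (is.null(drive$current)) 1 else drive$current
  } else {
    src <- drive[1]; snk <- drive[2]
    cur <- if (length(drive) > 2) drive[3] else 1
  }
  if (cur <= 0) stop("drive current must be > 0")
  u <- solve_fields(mesh, sigma, matrix(c(src, snk), 1), cur)
  structure(list(u = drop(u), drive = c(source = src, sink = snk,
                                        current = cur)),
            class = "eit_potential")
}

#' Arc-averaged electrode voltage
#'
#' Trapezoidal arc-length-weighted mean of the nodal potential over the
#' electrode's marked boundary edges.
#'
#' @param potential An `eit_potential` (or plain nodal vector).
#' @param mesh The mesh the potential was computed on.
#' @param electrode_index Electrode marker (1..E, internal = E + 1).
#' @return Scalar voltage.
#' @export
electrode_voltage <- function(potential, mesh, electrode_index) {
  u <- if (inherits(potential, "eit_potential")) potential$u else potential
  if (electrode_index < 1 || electrode_index > length(mesh$electrode_edges))
    stop("no such electrode marker in the mesh")
  sum(electrode_weights(mesh)[[electrode_index]] * u)
}

#' Drive/measurement protocol
#'
#' `boundary_adjacent`: adjacent-pair drives `(j, j+1 mod E)` and adjacent
#' measurements `(k, k+1 mod E)`, collecting all E^2 combinations.
#' `internal_augmented`: additionally involves the internal electrode
#' (index E + 1) according to `internal_role`: `"both"` adds drives
#' `(E+1, j)` and measurements `(k, E+1)` for all surface electrodes,
#' giving `(2E)^2` data; `"drive"` adds the internal drives only (boundary
#' measurements, `2E * E` data); `"measure"` the transposed counterpart.
#' The registry scenarios use `"drive"`: injecting current through the
#' internal electrode while measuring between surface-electrode pairs is
#' the configuration whose sensitivity diagnostics (cross-correlation,
#' norm ratios) reproduce the published behavior of internal-electrode EIT.
#'
#' @param layout An `eit_layout`.
#' @param scheme `"boundary_adjacent"` or `"internal_augmented"`.
#' @param internal_role How the internal electrode participates in the
#'   augmented scheme: `"both"` (default), `"drive"`, or `"measure"`.
#' @return Object of class `eit_protocol`: `drives` (J x 2), `meas` (K x 2),
#'   `scheme`, `E`.
#' @export
make_protocol <- function(layout,
                          scheme = c("boundary_adjacent", "internal_augmented"),
                          internal_role = c("both", "drive", "measure")) {
  scheme <- match.arg(scheme)
  internal_role <- match.arg(internal_role)
  stopifnot(inherits(layout, "eit_layout"))
  E <- layout$E
  adj <- cbind(1:E, c(2:E, 1L))
  if (scheme == "boundary_adjacent") {
    drives <- adj
    meas <- adj
  } else {
    if (is.null(layout$internal))
      stop("internal_augmented protocol requires an internal electrode")
    drives <- adj
    meas <- adj
    if (internal_role %in% c("both", "drive"))
      drives <- rbind(adj, cbind(rep(E + 1L, E), 1:E))
    if (internal_role %in% c("both", "measure"))
      meas <- rbind(adj, cbind(1:E, rep(E + 1L, E)))
  }
  structure(list(drives = drives, meas = meas, scheme = scheme, E = E),
            class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("<eit_protocol> %s: %d drives x %d measurements = %d data\n",
              x$scheme, nrow(x$drives), nrow(x$meas),
              nrow(x$drives) * nrow(x$meas)))
  invisible(x)
}

#' Construct a voltage data vector
#'
#' Wraps raw values (e.g. user-supplied measurements) in the package's
#' voltage-vector container; entries are in drive-major order
#' `m = (j - 1) * K + k`.
#'
#' @param values Numeric data values.
#' @param protocol The `eit_protocol` the ordering refers to (or `NULL`).
#' @return An `eit_voltage`.
#' @export
voltage_vector <- function(values, protocol = NULL) {
  structure(list(values = as.numeric(values), protocol = protocol),
            class = "eit_voltage")
}

#' @export
print.eit_voltage <- function(x, ...) {
  cat(sprintf("<eit_voltage> %d entries (%s), max |V| = %.4g\n",
              length(x$values),
              if (is.null(x$protocol)) "no protocol" else x$protocol$scheme,
              max(abs(x$values))))
  invisible(x)
}

#' Collect the full voltage data vector
#'
#' Solves one forward problem per drive and assembles the data vector in
#' drive-major order: entry `m = (j - 1) * K + k` is, for drive `j`, the
#' arc-averaged potential on the first electrode of measurement pair `k`
#' minus that on the second.
#'
#' @param mesh,sigma,protocol Mesh, conductivity field, and protocol.
#' @param current Drive current amplitude (applied to every drive).
#' @return An `eit_voltage`.
#' @export
collect_data <- function(mesh, sigma, protocol, current = 1) {
  if (!inherits(sigma, "eit_sigma")) sigma <- conductivity_field(mesh, sigma)
  w <- electrode_weights(mesh)
  U <- solve_fields(mesh, sigma, protocol$drives, current, w)
  Wm <- do.call(rbind, lapply(seq_len(nrow(protocol$meas)), function(k) {
    w[[protocol$meas[k, 1]]] - w[[protocol$meas[k, 2]]]
  }))
  V <- Wm %*% U                      # K x J
  voltage_vector(as.vector(V), protocol)   # column-major = drive-major
}

#' Time-difference data
#'
#' Entrywise difference `collect_data(perturbed) - collect_data(reference)`;
#' the linearized data of the sensitivity system.
#'
#' @param mesh Mesh shared by both fields.
#' @param sigma_ref,sigma_perturbed Reference and perturbed conductivities.
#' @param protocol An `eit_protocol`.
#' @param current Drive current amplitude.
#' @return An `eit_voltage` of differences.
#' @export
difference_data <- function(mesh, sigma_ref, sigma_perturbed, protocol,
                            current = 1) {
  if (length(sigma_ref) != length(sigma_perturbed) &&
      length(sigma_ref) > 1 && length(sigma_perturbed) > 1)
    stop("conductivity fields live on different meshes")
  v1 <- collect_data(mesh, sigma_ref, protocol, current)
  v2 <- collect_data(mesh, sigma_perturbed, protocol, current)
  voltage_vector(v2$values - v1$values, protocol)
}

#' Add measurement noise at a prescribed SNR
#'
#' Additive zero-mean Gaussian noise scaled so signal power / noise power
#' equals `10^(snr_db / 10)`. `snr_db = Inf` returns the data unchanged.
#' The RNG state is restored afterwards, so results depend only on `seed`.
#'
#' @param data An `eit_voltage`.
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Integer seed (reproducible).
#' @return An `eit_voltage`.
#' @export
add_noise <- function(data, snr_db, seed) {
  stopifnot(inherits(data, "eit_voltage"), !is.na(snr_db))
  if (is.infinite(snr_db) && snr_db > 0) return(data)
  v <- data$values
  sd_n <- sqrt(mean(v^2) / 10^(snr_db / 10))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  voltage_vector(v + rnorm(length(v), sd = sd_n), data$protocol)
}

#' Write / read a voltage vector as CSV
#'
#' Columns `drive_pos,drive_neg,meas_pos,meas_neg,value`, rows in protocol
#' (drive-major) order; the internal electrode is encoded as index E + 1.
#'
#' @param data An `eit_voltage` (with protocol).
#' @param path File path.
#' @return `write_voltages` returns `path` invisibly; `read_voltages` returns
#'   an `eit_voltage` (protocol reduced to the stored pairs).
#' @export
write_voltages <- function(data, path) {
  stopifnot(inherits(data, "eit_voltage"), !is.null(data$protocol))
  p <- data$protocol
  J <- nrow(p$drives)
  K <- nrow(p$meas)
  df <- data.frame(
    drive_pos = rep(p$drives[, 1], each = K),
    drive_neg = rep(p$drives[, 2], each = K),
    meas_pos = rep(p$meas[, 1], times = J),
    meas_neg = rep(p$meas[, 2], times = J),
    value = data$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voltages
#' @export
read_voltages <- function(path) {
  df <- read.csv(path)
  stopifnot(identical(names(df),
                      c("drive_pos", "drive_neg", "meas_pos", "meas_neg",
                        "value")))
  drives <- unique(cbind(df$drive_pos, df$drive_neg))
  meas <- unique(cbind(df$meas_pos, df$meas_neg))
  proto <- structure(list(drives = drives, meas = meas, scheme = "file",
                          E = max(drives, meas)),
                     class = "eit_protocol")
  voltage_vector(df$value, proto)
}
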