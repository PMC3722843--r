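## Geometry: disk domain, electrode layouts, ROI, FE mesh, pixel grid.

#' Circular imaging domain
#'
#' The 2-D cross-section of the cylindrical phantom: a disk of given radius.
#' All other geometry (electrodes, ROI, mesh, pixel grid) lives inside it.
#'
#' @param radius Disk radius (any consistent length unit; > 0).
#' @param center Numeric length-2 disk center (defaults to the origin).
#' @return An object of class `eit_domain`.
#' @export
disk_domain <- function(radius = 1, center = c(0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1, is.finite(radius),
            radius > 0, is.numeric(center), length(center) == 2,
            all(is.finite(center)))
  structure(list(radius = radius, center = as.numeric(center)),
            class = "eit_domain")
}

#' @export
print.eit_domain <- function(x, ...) {
  cat(sprintf("<eit_domain> disk, radius %g, center (%g, %g)\n",
              x$radius, x$center[1], x$center[2]))
  invisible(x)
}

norm2 <- function(v) sqrt(sum(v^2))

#' Electrode layout on the disk
#'
#' Places `E` surface electrodes on the boundary circle, either equidistantly
#' or clustered with a higher density in an angular sector facing the internal
#' electrode, and optionally a small circular internal electrode strictly
#' inside the disk.
#'
#' In clustered mode, `ceiling(cluster_fraction * E)` electrodes are spread
#' uniformly over a sector of width `cluster_sector` centered on the internal
#' electrode's azimuth; the remainder are spread uniformly over the
#' complementary sector. The electrode arc width defaults to half the minimal
#' center-to-center gap, so electrodes can never overlap.
#'
#' @param E Number of surface electrodes (>= 4).
#' @param mode `"equidistant"` or `"clustered"`.
#' @param domain An [disk_domain()].
#' @param internal_position Numeric length-2 position of the internal
#'   electrode center, or `NULL` for none. Required for clustered mode.
#' @param internal_radius Radius of the internal electrode. Defaults to
#'   `domain$radius * 0.125 / 7` (a 0.25 cm diameter probe in a 14 cm tank,
#'   scaled to domain units).
#' @param cluster_fraction Fraction of electrodes placed inside the dense
#'   sector (clustered mode).
#' @param cluster_sector Angular width (radians) of the dense sector.
#' @param arc_width Optional electrode arc width (radians) overriding the
#'   half-minimal-gap default; must not cause overlap.
#' @return An object of class `eit_layout` with fields `domain`, `angles`
#'   (electrode center angles, sorted), `arc_width`, `internal` (list with
#'   `position`, `radius`, or `NULL`), `mode`, `E`.
#' @export
make_layout <- function(E = 16, mode = c("equidistant", "clustered"),
                        domain = disk_domain(),
                        internal_position = NULL, internal_radius = NULL,
                        cluster_fraction = 0.5, cluster_sector = 2 * pi / 3,
                        arc_width = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(E) || length(E) != 1 || E != round(E) || E < 4)
    stop("E must be an integer >= 4")
  E <- as.integer(E)
  stopifnot(inherits(domain, "eit_domain"))

  internal <- NULL
  if (!is.null(internal_position)) {
    stopifnot(is.numeric(internal_position), length(internal_position) == 2)
    if (is.null(internal_radius))
      internal_radius <- domain$radius * 0.125 / 7
    d <- norm2(internal_position - domain$center)
    if (!(internal_radius > 0) || d + internal_radius >= domain$radius)
      stop("internal electrode must lie strictly inside the domain")
    internal <- list(position = as.numeric(internal_position),
                     radius = internal_radius)
  }

  if (mode == "equidistant") {
    angles <- 2 * pi * (0:(E - 1)) / E
  } else {
    if (is.null(internal))
      stop("clustered mode requires an internal electrode (it defines the dense sector)")
    stopifnot(cluster_fraction > 0, cluster_fraction < 1,
              cluster_sector > 0, cluster_sector < 2 * pi)
    az <- atan2(internal$position[2] - domain$center[2],
                internal$position[1] - domain$center[1])
    n_in <- ceiling(cluster_fraction * E)
    n_out <- E - n_in
    if (n_out < 1) stop("cluster_fraction leaves no electrodes outside the sector")
    a_in <- az - cluster_sector / 2 + cluster_sector * ((1:n_in) - 0.5) / n_in
    a_out <- az + cluster_sector / 2 +
      (2 * pi - cluster_sector) * ((1:n_out) - 0.5) / n_out
    angles <- sort(c(a_in, a_out) %% (2 * pi))
  }
  gaps <- diff(c(angles, angles[1] + 2 * pi))
  if (min(gaps) <= 0) stop("electrode centers coincide; reduce E or widen sector")
  if (is.null(arc_width)) arc_width <- min(gaps) / 2
  if (arc_width <= 0 || arc_width >= min(gaps))
    stop("electrode arcs overlap: E too large for the requested arc width")

  structure(list(domain = domain, angles = angles, arc_width = arc_width,
                 internal = internal, mode = mode, E = E),
            class = "eit_layout")
}

#' @export
print.eit_layout <- function(x, ...) {
  cat(sprintf("<eit_layout> E = %d (%s), arc width %.4f rad%s\n",
              x$E, x$mode, x$arc_width,
              if (is.null(x$internal)) ""
              else sprintf(", internal electrode at (%g, %g), r = %g",
                           x$internal$position[1], x$internal$position[2],
                           x$internal$radius)))
  invisible(x)
}

#' Electrode center positions on the boundary circle
#' @param layout An `eit_layout`.
#' @return E x 2 matrix of electrode center points.
#' @export
electrode_centers <- function(layout) {
  stopifnot(inherits(layout, "eit_layout"))
  r <- layout$domain$radius
  cbind(layout$domain$center[1] + r * cos(layout$angles),
        layout$domain$center[2] + r * sin(layout$angles))
}

#' Region of interest around the internal electrode
#'
#' The ROI is the disk centered at the internal electrode whose radius is 5/6
#' of the distance from the internal electrode to the closest surface
#' electrode center (on the boundary circle).
#'
#' @param layout An `eit_layout` with an internal electrode.
#' @return An object of class `eit_roi` with fields `center`, `radius`.
#' @export
compute_roi <- function(layout) {
  stopifnot(inherits(layout, "eit_layout"))
  if (is.null(layout$internal))
    stop("ROI undefined: layout has no internal electrode")
  ec <- electrode_centers(layout)
  d <- sqrt(rowSums((ec - matrix(layout$internal$position, nrow(ec), 2,
                                 byrow = TRUE))^2))
  roi_region(layout$internal$position, 5 / 6 * min(d), layout$domain)
}

#' Construct an ROI disk directly
#'
#' Mostly used to apply the ROI of an internal-electrode layout to a matched
#' layout without one (for like-for-like comparisons).
#'
#' @param center Numeric length-2 ROI center.
#' @param radius ROI radius (> 0).
#' @param domain Optional [disk_domain()]; if given, the ROI must lie strictly
#'   inside it.
#' @return An object of class `eit_roi`.
#' @export
roi_region <- function(center, radius, domain = NULL) {
  stopifnot(is.numeric(center), length(center) == 2, radius > 0)
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "eit_domain"))
    if (norm2(center - domain$center) + radius >= domain$radius)
      stop("ROI disk must lie strictly inside the domain")
  }
  structure(list(center = as.numeric(center), radius = radius),
            class = "eit_roi")
}

#' @export
print.eit_roi <- function(x, ...) {
  cat(sprintf("<eit_roi> center (%g, %g), radius %g\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

## deterministic per-index jitter in [-0.5, 0.5] (splitmix-style hash)
.hash_unit <- function(ix) {
  x <- (as.numeric(ix) * 2654435761) %% 4294967296
  x <- (x * 40503 + 2654435769) %% 4294967296
  x / 4294967296 - 0.5
}

#' Triangulate the phantom
#'
#' Builds a conforming triangular mesh of the disk: boundary nodes placed on
#' electrode arc endpoints with local refinement on the arcs, a circular hole
#' with graded rings around the internal electrode (if present), and a jittered
#' hexagonal lattice in the interior, triangulated by Delaunay insertion.
#' Electrode arcs are recovered as marked boundary edge chains (surface
#' electrodes 1..E; the internal electrode boundary carries marker E + 1).
#'
#' @param layout An `eit_layout`.
#' @param target_edge_length Interior target edge length, in domain units.
#'   Electrode arcs are resolved at half this length (and always with >= 2
#'   edges).
#' @return An object of class `eit_mesh`: `nodes` (n x 2), `triangles`
#'   (T x 3, positively oriented), `electrode_edges` (list of edge node-pair
#'   matrices, one per marker), `layout`, `h`.
#' @export
build_mesh <- function(layout, target_edge_length) {
  stopifnot(inherits(layout, "eit_layout"),
            is.numeric(target_edge_length), target_edge_length > 0)
  h <- target_edge_length
  dom <- layout$domain
  R <- dom$radius
  ctr <- dom$center
  E <- layout$E
  if (h > R) stop("target_edge_length larger than the domain radius")

  ## --- boundary ring: angles + per-segment electrode label -----------------
  w <- layout$arc_width
  seg_ang <- numeric(0)   # segment start angles (node angles in order)
  seg_lab <- integer(0)   # label of segment starting at that node
  for (j in seq_len(E)) {
    a0 <- layout$angles[j] - w / 2
    a1 <- layout$angles[j] + w / 2
    n_e <- max(2, ceiling((a1 - a0) * R / (h / 2)))
    seg_ang <- c(seg_ang, a0 + (a1 - a0) * (0:(n_e - 1)) / n_e)
    seg_lab <- c(seg_lab, rep.int(j, n_e))
    jn <- if (j < E) j + 1 else 1
    g0 <- a1
    g1 <- layout$angles[jn] - w / 2 + if (j == E) 2 * pi else 0
    n_g <- max(1, ceiling((g1 - g0) * R / h))
    seg_ang <- c(seg_ang, g0 + (g1 - g0) * (0:(n_g - 1)) / n_g)
    seg_lab <- c(seg_lab, rep.int(0L, n_g))
  }
  ord <- order(seg_ang %% (2 * pi))
  seg_ang <- (seg_ang %% (2 * pi))[ord]
  seg_lab <- seg_lab[ord]
  B <- length(seg_ang)
  ring <- cbind(ctr[1] + R * cos(seg_ang), ctr[2] + R * sin(seg_ang))

  nodes <- ring
  ## --- internal electrode hole ring + graded transition rings --------------
  hole_idx <- integer(0)
  n_hole <- 0L
  if (!is.null(layout$internal)) {
    ci <- layout$internal$position
    ri <- layout$internal$radius
    n_hole <- max(12, ceiling(2 * pi * ri / h))
    th <- 2 * pi * (0:(n_hole - 1)) / n_hole
    hole_idx <- nrow(nodes) + seq_len(n_hole)
    nodes <- rbind(nodes, cbind(ci[1] + ri * cos(th), ci[2] + ri * sin(th)))
    s <- 2 * pi * ri / n_hole
    rho <- ri
    k <- 0
    repeat {
      s_next <- min(s * 1.7, h)
      rho_next <- rho + s_next
      if (s_next >= 0.95 * h) break
      k <- k + 1
      n_k <- max(8, ceiling(2 * pi * rho_next / s_next))
      thk <- 2 * pi * ((0:(n_k - 1)) + 0.5 * (k %% 2)) / n_k
      pk <- cbind(ci[1] + rho_next * cos(thk), ci[2] + rho_next * sin(thk))
      keep <- sqrt((pk[, 1] - ctr[1])^2 + (pk[, 2] - ctr[2])^2) < R - 0.6 * h
      nodes <- rbind(nodes, pk[keep, , drop = FALSE])
      rho <- rho_next
      s <- s_next
    }
    rho_excl <- rho + 0.6 * h
  }

  ## --- interior hexagonal lattice (deterministically jittered) -------------
  dy <- h * sqrt(3) / 2
  jr <- seq(ceiling((-R) / dy), floor(R / dy))
  lat <- NULL
  for (j in jr) {
    y <- ctr[2] + j * dy
    off <- (j %% 2) * h / 2
    i0 <- ceiling((-R - off) / h)
    i1 <- floor((R - off) / h)
    if (i1 < i0) next
    ii <- i0:i1
    x <- ctr[1] + off + ii * h
    idx <- (j + 5000) * 20011 + (ii + 5000)
    x <- x + 0.12 * h * .hash_unit(idx)
    y2 <- y + 0.12 * h * .hash_unit(idx + 7919)
    lat <- rbind(lat, cbind(x, y2))
  }
  keep <- sqrt((lat[, 1] - ctr[1])^2 + (lat[, 2] - ctr[2])^2) < R - 0.6 * h
  if (!is.null(layout$internal)) {
    ci <- layout$internal$position
    keep <- keep &
      sqrt((lat[, 1] - ci[1])^2 + (lat[, 2] - ci[2])^2) > rho_excl
  }
  nodes <- rbind(nodes, lat[keep, , drop = FALSE])
  colnames(nodes) <- NULL

  ## --- Delaunay (on unit-scaled coordinates) --------------------------------
  pts <- cbind((nodes[, 1] - ctr[1]) / R, (nodes[, 2] - ctr[2]) / R)
  tri <- .delaunay_cpp(pts)

  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  area2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  flip <- area2 < 0
  if (any(flip)) {
    tmp <- tri[flip, 2]
    tri[flip, 2] <- tri[flip, 3]
    tri[flip, 3] <- tmp
  }
  gx <- (ax + bx + cx) / 3
  gy <- (ay + by + cy) / 3
  keep_t <- abs(area2) > 1e-14 * R^2 &
    sqrt((gx - ctr[1])^2 + (gy - ctr[2])^2) < R
  if (!is.null(layout$internal)) {
    ci <- layout$internal$position
    keep_t <- keep_t &
      sqrt((gx - ci[1])^2 + (gy - ci[2])^2) >= layout$internal$radius
  }
  tri <- tri[keep_t, , drop = FALSE]

  ## --- boundary edge recovery & electrode markers ---------------------------
  ee <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ek <- paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
  cnt <- table(ek)
  bnd <- names(cnt)[cnt == 1]
  bset <- strsplit(bnd, " ", fixed = TRUE)
  bmat <- matrix(as.integer(unlist(bset)), ncol = 2, byrow = TRUE)

  is_ring <- bmat[, 1] <= B & bmat[, 2] <= B
  is_hole <- n_hole > 0 & bmat[, 1] > B & bmat[, 1] <= B + n_hole &
    bmat[, 2] > B & bmat[, 2] <= B + n_hole
  if (!all(is_ring | is_hole))
    stop("infeasible refinement: mesh boundary does not conform to the geometry")

  ## outer ring edges must be exactly the constructed segments
  ring_exp <- cbind(1:B, c(2:B, 1L))
  exp_keys <- paste(pmin(ring_exp[, 1], ring_exp[, 2]),
                    pmax(ring_exp[, 1], ring_exp[, 2]))
  got_keys <- paste(pmin(bmat[is_ring, 1], bmat[is_ring, 2]),
                    pmax(bmat[is_ring, 1], bmat[is_ring, 2]))
  if (!setequal(exp_keys, got_keys))
    stop("infeasible refinement: outer boundary segments were not recovered")

  electrode_edges <- vector("list", E + (n_hole > 0))
  for (j in seq_len(E))
    electrode_edges[[j]] <- ring_exp[seg_lab == j, , drop = FALSE]
  if (n_hole > 0) {
    hm <- bmat[is_hole, , drop = FALSE]
    i1 <- hm[, 1] - B
    i2 <- hm[, 2] - B
    consec <- (i2 - i1) %% n_hole == 1 | (i1 - i2) %% n_hole == 1
    if (nrow(hm) != n_hole || !all(consec))
      stop("infeasible refinement: internal electrode boundary was not recovered")
    electrode_edges[[E + 1]] <- hm
  }
  if (any(vapply(electrode_edges, nrow, 1L) < 2))
    stop("infeasible refinement: an electrode has fewer than 2 boundary edges")

  structure(list(nodes = nodes, triangles = tri,
                 electrode_edges = electrode_edges,
                 layout = layout, h = h),
            class = "eit_mesh")
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("<eit_mesh> %d nodes, %d triangles, %d marked electrodes, h = %g\n",
              nrow(x$nodes), nrow(x$triangles), length(x$electrode_edges), x$h))
  invisible(x)
}

#' Regular pixel grid clipped to the disk
#'
#' Lays a `pixels_per_diameter` x `pixels_per_diameter` square lattice over
#' the domain's bounding box and keeps the pixels whose centers fall strictly
#' inside the disk. Pixels are ordered row-major (y ascending, then x
#' ascending). If an ROI is supplied, `roi_mask` flags pixels whose centers
#' fall inside the ROI disk, and `order_roi_first` is the permutation that
#' re-indexes ROI pixels first (the ordering used for sensitivity-matrix
#' columns).
#'
#' @param domain An [disk_domain()].
#' @param pixels_per_diameter Integer >= 8.
#' @param roi Optional `eit_roi`.
#' @return An object of class `eit_grid`: `centers` (N x 2, row-major),
#'   `side` (pixel side length), `nx`, `index` (nx x nx matrix of pixel ids,
#'   NA outside the disk), `roi_mask`, `R`, `order_roi_first`.
#' @export
build_pixel_grid <- function(domain, pixels_per_diameter, roi = NULL) {
  stopifnot(inherits(domain, "eit_domain"),
            pixels_per_diameter == round(pixels_per_diameter),
            pixels_per_diameter >= 8)
  P <- as.integer(pixels_per_diameter)
  R <- domain$radius
  side <- 2 * R / P
  cs <- domain$center[1] - R + (seq_len(P) - 0.5) * side
  ys <- domain$center[2] - R + (seq_len(P) - 0.5) * side
  xx <- rep(cs, times = P)          # row-major: y outer, x inner
  yy <- rep(ys, each = P)
  inside <- (xx - domain$center[1])^2 + (yy - domain$center[2])^2 < R^2
  centers <- cbind(xx[inside], yy[inside])
  N <- nrow(centers)
  index <- matrix(NA_integer_, P, P)  # [ix, iy]
  ids <- integer(P * P)
  ids[inside] <- seq_len(N)
  for (iy in seq_len(P))
    for (ix in seq_len(P))
      if (inside[(iy - 1) * P + ix]) index[ix, iy] <- ids[(iy - 1) * P + ix]

  roi_mask <- NULL
  Rn <- 0L
  order_roi_first <- seq_len(N)
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "eit_roi"))
    roi_mask <- (centers[, 1] - roi$center[1])^2 +
      (centers[, 2] - roi$center[2])^2 < roi$radius^2
    Rn <- sum(roi_mask)
    if (Rn == 0) stop("ROI contains no pixel center; refine the grid")
    order_roi_first <- c(which(roi_mask), which(!roi_mask))
  }
  structure(list(centers = centers, side = side, nx = P, index = index,
                 domain = domain, roi = roi, roi_mask = roi_mask, R = Rn,
                 N = N, order_roi_first = order_roi_first),
            class = "eit_grid")
}

#' @export
print.eit_grid <- function(x, ...) {
  cat(sprintf("<eit_grid> %d pixels (%d per diameter, side %g)%s\n",
              x$N, x$nx, x$side,
              if (is.null(x$roi)) "" else sprintf(", %d in ROI", x$R)))
  invisible(x)
}

#' Write / read a mesh in the package's plain-text format
#'
#' Format: header `nodes N elements M`; N lines `x y`; M lines `i j k`
#' (0-based node indices); then per electrode a block
#' `electrode <idx> <edge-count>` followed by 0-based node-pair lines.
#'
#' @param mesh An `eit_mesh`.
#' @param path Output file path.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns an
#'   `eit_mesh` (without the generating layout).
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "eit_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("nodes %d elements %d", nrow(mesh$nodes),
                     nrow(mesh$triangles)), con)
  writeLines(sprintf("%.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("%d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  for (j in seq_along(mesh$electrode_edges)) {
    ed <- mesh$electrode_edges[[j]]
    writeLines(sprintf("electrode %d %d", j, nrow(ed)), con)
    writeLines(sprintf("%d %d", ed[, 1] - 1L, ed[, 2] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ln <- readLines(path)
  hd <- strsplit(ln[1], " ", fixed = TRUE)[[1]]
  stopifnot(hd[1] == "nodes", hd[3] == "elements")
  n <- as.integer(hd[2])
  m <- as.integer(hd[4])
  num <- function(rows) {
    matrix(as.numeric(unlist(strsplit(rows, " ", fixed = TRUE))),
           ncol = length(strsplit(rows[1], " ", fixed = TRUE)[[1]]),
           byrow = TRUE)
  }
  nodes <- num(ln[2:(1 + n)])
  tri <- num(ln[(2 + n):(1 + n + m)])
  storage.mode(tri) <- "integer"
  tri <- tri + 1L
  pos <- 2 + n + m
  electrode_edges <- list()
  while (pos <= length(ln)) {
    hd <- strsplit(ln[pos], " ", fixed = TRUE)[[1]]
    stopifnot(hd[1] == "electrode")
    idx <- as.integer(hd[2])
    k <- as.integer(hd[3])
    ed <- num(ln[(pos + 1):(pos + k)])
    storage.mode(ed) <- "integer"
    electrode_edges[[idx]] <- ed + 1L
    pos <- pos + k + 1
  }
  structure(list(nodes = nodes, triangles = tri,
                 electrode_edges = electrode_edges, layout = NULL, h = NA),
            class = "eit_mesh")
}
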