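## Sensitivity (Jacobian) matrix, ROI column partition, and the diagnostic
## statistics used to compare electrode configurations.

#' Compute the sensitivity matrix
#'
#' Entry `(m, n)` for data index `m = (j-1)*K + k` is
#' `-integral over pixel q_n of grad(u^j) . grad(u~^k)`, where `u^j` is the
#' reference-field solution for drive `j` and `u~^k` the adjoint field
#' obtained by driving measurement pair `k` with unit current (reciprocity).
#' With this sign, `S %*% dgamma` approximates the time-difference data
#' `collect_data(perturbed) - collect_data(reference)` to first order.
#'
#' Triangles are assigned to the pixel whose center is nearest their
#' centroid (identical to square-cell membership away from the rim; rim
#' triangles whose cell has no pixel center fold into the nearest kept
#' pixel, so the pixel images tile the whole disk).
#'
#' Columns are ordered ROI-first when the grid carries an ROI: the first `R`
#' columns are the ROI pixels.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma_ref Reference conductivity field (`eit_sigma` or numeric).
#' @param protocol An `eit_protocol`.
#' @param grid An `eit_grid`.
#' @return Object of class `eit_sens`: `S` ((J*K) x N), `pixel_ids`
#'   (row-major pixel id of each column), `R`, `grid`, `protocol`.
#' @export
compute_sensitivity <- function(mesh, sigma_ref, protocol, grid) {
  if (!inherits(sigma_ref, "eit_sigma"))
    sigma_ref <- conductivity_field(mesh, sigma_ref, reference = TRUE)
  stopifnot(inherits(grid, "eit_grid"), inherits(protocol, "eit_protocol"))
  fem <- mesh_fem(mesh)
  w <- electrode_weights(mesh)

  pats <- rbind(protocol$drives, protocol$meas)
  key <- paste(pats[, 1], pats[, 2])
  upat <- !duplicated(key)
  pat_id <- match(key, key[upat])
  U <- solve_fields(mesh, sigma_ref, pats[upat, , drop = FALSE], 1, w)
  tri <- mesh$triangles
  ## per-triangle gradients of every distinct field
  U1 <- U[tri[, 1], , drop = FALSE]
  U2 <- U[tri[, 2], , drop = FALSE]
  U3 <- U[tri[, 3], , drop = FALSE]
  Gx <- fem$b[, 1] * U1 + fem$b[, 2] * U2 + fem$b[, 3] * U3
  Gy <- fem$c[, 1] * U1 + fem$c[, 2] * U2 + fem$c[, 3] * U3

  pid <- assign_triangles_to_pixels(mesh, fem, grid)
  Agg <- sparseMatrix(i = seq_along(pid), j = pid, x = fem$area,
                      dims = c(length(pid), grid$N))

  J <- nrow(protocol$drives)
  K <- nrow(protocol$meas)
  di <- pat_id[seq_len(J)]
  mi <- pat_id[J + seq_len(K)]
  S <- matrix(0, J * K, grid$N)
  for (j in seq_len(J)) {
    dots <- Gx[, mi, drop = FALSE] * Gx[, di[j]] +
      Gy[, mi, drop = FALSE] * Gy[, di[j]]          # T x K
    S[(j - 1) * K + seq_len(K), ] <- -t(as.matrix(Matrix::crossprod(Agg, dots)))
  }

  perm <- grid$order_roi_first
  S <- S[, perm, drop = FALSE]
  zero_cols <- colSums(S != 0) == 0
  if (any(zero_cols))
    warning(sprintf("%d pixel(s) received no triangle: zero sensitivity columns",
                    sum(zero_cols)))
  structure(list(S = S, pixel_ids = perm, R = grid$R, grid = grid,
                 protocol = protocol),
            class = "eit_sens")
}

## nearest-pixel-center assignment of triangle centroids (square-cell
## membership in the interior, Voronoi fold-in at the clipped rim)
assign_triangles_to_pixels <- function(mesh, fem, grid) {
  tri <- mesh$triangles
  gx <- (mesh$nodes[tri[, 1], 1] + mesh$nodes[tri[, 2], 1] +
           mesh$nodes[tri[, 3], 1]) / 3
  gy <- (mesh$nodes[tri[, 1], 2] + mesh$nodes[tri[, 2], 2] +
           mesh$nodes[tri[, 3], 2]) / 3
  dom <- grid$domain
  ix <- pmin(grid$nx, pmax(1, ceiling((gx - dom$center[1] + dom$radius) /
                                        grid$side)))
  iy <- pmin(grid$nx, pmax(1, ceiling((gy - dom$center[2] + dom$radius) /
                                        grid$side)))
  pid <- grid$index[cbind(ix, iy)]
  miss <- which(is.na(pid))
  if (length(miss)) {
    for (t in miss) {
      d2 <- (grid$centers[, 1] - gx[t])^2 + (grid$centers[, 2] - gy[t])^2
      pid[t] <- which.min(d2)
    }
  }
  pid
}

#' @export
print.eit_sens <- function(x, ...) {
  cat(sprintf("<eit_sens> %d x %d (R = %d ROI columns)\n",
              nrow(x$S), ncol(x$S), x$R))
  invisible(x)
}

#' Split sensitivity columns into ROI and outside blocks
#'
#' @param sens An `eit_sens` whose grid has an ROI.
#' @return List with `S_D` (the first R, ROI, columns) and `S_out`.
#' @export
partition_columns <- function(sens) {
  stopifnot(inherits(sens, "eit_sens"))
  R <- sens$R
  N <- ncol(sens$S)
  if (R == 0 || R == N)
    stop("ROI partition undefined: R must satisfy 0 < R < N")
  list(S_D = sens$S[, seq_len(R), drop = FALSE],
       S_out = sens$S[, (R + 1):N, drop = FALSE])
}

#' Cross-correlation of ROI sensitivity columns with outside columns
#'
#' For each ROI pixel `j`, the mean over outside pixels `i` of
#' `|s_i . s_j| / (||s_i|| ||s_j||)`. Values lie in `[0, 1]`; small values
#' mean ROI columns are nearly orthogonal to outside columns, i.e. the local
#' system is easier to separate. Zero outside columns are dropped from the
#' average; a zero ROI column yields `NA`.
#'
#' @param sens An `eit_sens` with an ROI.
#' @return Numeric vector of length R (one value per ROI pixel).
#' @export
cross_correlation <- function(sens) {
  p <- partition_columns(sens)
  n_d <- sqrt(colSums(p$S_D^2))
  n_o <- sqrt(colSums(p$S_out^2))
  ok_o <- n_o > 0
  if (!all(ok_o))
    message(sprintf("cross_correlation: excluding %d zero outside column(s)",
                    sum(!ok_o)))
  C <- abs(crossprod(p$S_out[, ok_o, drop = FALSE], p$S_D))  # n_out x R
  C <- C / outer(n_o[ok_o], n_d)
  mu <- colMeans(C)
  mu[n_d == 0] <- NA_real_
  mu
}

spectral_norm <- function(A) {
  if (all(A == 0)) return(0)
  svd(A, nu = 0, nv = 0)$d[1]
}

#' Spectral-norm ratios of the ROI and outside column blocks
#'
#' `in_ratio = ||A_in|| / ||A||` and `out_ratio = ||A_out|| / ||A||`, where
#' `A_in` holds the ROI columns, `A_out` the rest, and `||.||` is the
#' spectral (operator 2-) norm. Each ratio is at most 1.
#'
#' @param A A matrix whose first `R` columns are the ROI block, or an
#'   `eit_sens`.
#' @param R Number of ROI columns (ignored when `A` is an `eit_sens`).
#' @return Named vector `c(in_ratio, out_ratio)`.
#' @export
norm_ratio <- function(A, R = NULL) {
  if (inherits(A, "eit_sens")) {
    R <- A$R
    A <- A$S
  }
  stopifnot(is.matrix(A), !is.null(R), R >= 1, R <= ncol(A))
  nA <- spectral_norm(A)
  if (nA == 0) stop("norm_ratio undefined for the zero matrix")
  out <- if (R == ncol(A)) 0
         else spectral_norm(A[, (R + 1):ncol(A), drop = FALSE]) / nA
  c(in_ratio = spectral_norm(A[, seq_len(R), drop = FALSE]) / nA,
    out_ratio = out)
}

#' Write / read a dense matrix as CSV with a shape/permutation header
#'
#' Line 1: `rows,<J*K>,cols,<N>`; line 2: `pixel_ids,<id1>,<id2>,...`
#' (row-major pixel id of each column; empty when not applicable); then the
#' matrix rows as plain CSV numbers.
#'
#' @param M Matrix (or `eit_sens`, whose pixel map is stored).
#' @param path File path.
#' @param pixel_ids Optional integer column map stored in the header.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   list `M`, `pixel_ids`.
#' @export
write_matrix <- function(M, path, pixel_ids = NULL) {
  if (inherits(M, "eit_sens")) {
    pixel_ids <- M$pixel_ids
    M <- M$S
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rows,%d,cols,%d", nrow(M), ncol(M)), con)
  writeLines(paste(c("pixel_ids", pixel_ids), collapse = ","), con)
  writeLines(apply(M, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = ",")), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  ln <- readLines(path)
  hd <- strsplit(ln[1], ",", fixed = TRUE)[[1]]
  stopifnot(hd[1] == "rows", hd[3] == "cols")
  nr <- as.integer(hd[2])
  nc <- as.integer(hd[4])
  ids <- strsplit(ln[2], ",", fixed = TRUE)[[1]]
  pixel_ids <- if (length(ids) > 1) as.integer(ids[-1]) else NULL
  M <- matrix(as.numeric(unlist(strsplit(ln[3:(2 + nr)], ",", fixed = TRUE))),
              nrow = nr, ncol = nc, byrow = TRUE)
  list(M = M, pixel_ids = pixel_ids)
}
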