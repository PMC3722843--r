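## TSVD inversion of the conventional and localized systems, the singular
## value threshold search, and image-quality metrics.

#' Truncated-SVD solve
#'
#' `x = sum over singular triplets with d_i >= rel_threshold * d_1 of
#' (u_i' b / d_i) v_i`. Numerically zero singular values
#' (`d_i < d_1 * 1e-12`) are always dropped.
#'
#' @param A Nonzero matrix.
#' @param b Right-hand side (length `nrow(A)`).
#' @param rel_threshold Truncation level relative to the largest singular
#'   value, in `[0, 1]`.
#' @return Solution vector with attribute `rank` (number of retained
#'   triplets).
#' @export
tsvd_solve <- function(A, b, rel_threshold) {
  stopifnot(is.matrix(A), length(b) == nrow(A))
  if (!is.numeric(rel_threshold) || rel_threshold < 0 || rel_threshold > 1)
    stop("rel_threshold must lie in [0, 1]")
  sv <- svd(A)
  if (sv$d[1] == 0) stop("tsvd_solve: A is the zero matrix")
  keep <- sv$d >= rel_threshold * sv$d[1] & sv$d > sv$d[1] * 1e-12
  x <- numeric(ncol(A))
  if (any(keep)) {
    k <- which(keep)
    x <- sv$v[, k, drop = FALSE] %*%
      (crossprod(sv$u[, k, drop = FALSE], b) / sv$d[k])
  }
  structure(drop(x), rank = sum(keep))
}

recon_result <- function(image, grid, threshold, rank, method) {
  structure(list(image = image, grid = grid, threshold = threshold,
                 rank = rank, method = method),
            class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat(sprintf("<eit_recon> %s: %d pixels, rel threshold %.4g, rank %d\n",
              x$method, length(x$image), x$threshold, x$rank))
  invisible(x)
}

#' Conventional TSVD reconstruction on the full pixel set
#'
#' Solves `S dgamma = dV` by truncated SVD and maps the solution back to
#' row-major grid order.
#'
#' @param sens An `eit_sens`.
#' @param data An `eit_voltage` (time-difference data).
#' @param rel_threshold Relative singular value threshold in `[0, 1]`.
#' @return An `eit_recon` whose `image` is the per-pixel conductivity change
#'   in row-major pixel order.
#' @export
reconstruct_conventional <- function(sens, data, rel_threshold) {
  v <- if (inherits(data, "eit_voltage")) data$values else as.numeric(data)
  x <- tsvd_solve(sens$S, v, rel_threshold)
  img <- numeric(ncol(sens$S))
  img[sens$pixel_ids] <- x
  recon_result(img, sens$grid, rel_threshold, attr(x, "rank"), "conventional")
}

#' Local-ROI reconstruction through the filter
#'
#' Solves the localized system `(t(Phi) S_D) dgamma_D = t(Phi) dV` by
#' truncated SVD and embeds the ROI solution into the full grid with zeros
#' outside the ROI.
#'
#' @param filter An `eit_filter` built from `sens`.
#' @param sens The matching `eit_sens`.
#' @param data An `eit_voltage`.
#' @param rel_threshold Relative singular value threshold in `[0, 1]`.
#' @return An `eit_recon` (row-major image, zero outside the ROI).
#' @export
reconstruct_local <- function(filter, sens, data, rel_threshold) {
  ap <- apply_filter(filter, sens, data)
  x <- tsvd_solve(ap$A_roi, ap$b, rel_threshold)
  img <- numeric(ncol(sens$S))
  img[ap$pixel_ids] <- x
  recon_result(img, sens$grid, rel_threshold, attr(x, "rank"), "local_roi")
}

#' Anomaly/background contrast of a reconstructed image
#'
#' Mean image value over the anomaly pixel set minus the mean over the
#' background pixel set (both in row-major pixel ids).
#'
#' @param result An `eit_recon` or a row-major image vector.
#' @param anomaly_pixels,background_pixels Disjoint nonempty pixel id sets.
#' @return Scalar contrast.
#' @export
contrast <- function(result, anomaly_pixels, background_pixels) {
  img <- if (inherits(result, "eit_recon")) result$image else as.numeric(result)
  if (length(anomaly_pixels) == 0 || length(background_pixels) == 0)
    stop("anomaly and background pixel sets must be nonempty")
  if (length(intersect(anomaly_pixels, background_pixels)))
    stop("anomaly and background pixel sets must be disjoint")
  mean(img[anomaly_pixels]) - mean(img[background_pixels])
}

#' Pixel sets for contrast evaluation
#'
#' The anomaly set holds the pixels whose centers fall inside any of the
#' true anomaly disks; the background set is the complement of the 2x-dilated
#' anomaly disks (pixels farther than twice the anomaly radius from every
#' anomaly center).
#'
#' @param grid An `eit_grid`.
#' @param centers Anomaly centers (n x 2 matrix).
#' @param radii Anomaly radii (recycled).
#' @return List `anomaly`, `background` of row-major pixel ids.
#' @export
anomaly_pixel_sets <- function(grid, centers, radii) {
  centers <- matrix(centers, ncol = 2)
  radii <- rep_len(radii, nrow(centers))
  inside <- dilated <- rep(FALSE, grid$N)
  for (a in seq_len(nrow(centers))) {
    d2 <- (grid$centers[, 1] - centers[a, 1])^2 +
      (grid$centers[, 2] - centers[a, 2])^2
    inside <- inside | d2 < radii[a]^2
    dilated <- dilated | d2 < (2 * radii[a])^2
  }
  list(anomaly = which(inside), background = which(!dilated))
}

#' Bisection search for the singular value threshold matching a contrast
#'
#' Reconstructs repeatedly (from one cached SVD), bisecting the relative
#' threshold until the image contrast matches `target_contrast` to the
#' requested relative tolerance. Because the TSVD image is piecewise
#' constant in the threshold, the search may stop on the best bracketing
#' threshold with `converged = FALSE`; an unattainable target (outside the
#' contrast range spanned by thresholds 0 and 1) is returned flagged, not as
#' an error.
#'
#' @param A System matrix.
#' @param b Data vector.
#' @param target_contrast Desired contrast value.
#' @param anomaly_pixels,background_pixels Row-major pixel id sets.
#' @param tolerance Relative tolerance on the contrast match.
#' @param image_map Function mapping a TSVD solution vector to the row-major
#'   image (defaults to identity, i.e. pixel ids index the solution
#'   directly).
#' @param max_iter Bisection iteration cap.
#' @return List `threshold`, `contrast`, `converged`, `iterations`,
#'   `attainable`.
#' @export
threshold_search <- function(A, b, target_contrast, anomaly_pixels,
                             background_pixels, tolerance = 0.02,
                             image_map = identity, max_iter = 60) {
  sv <- svd(A)
  if (sv$d[1] == 0)
    return(list(threshold = NA_real_, contrast = 0, converged = FALSE,
                iterations = 0L, attainable = FALSE))
  ub <- crossprod(sv$u, b)
  con_at <- function(t) {
    keep <- sv$d >= t * sv$d[1] & sv$d > sv$d[1] * 1e-12
    x <- numeric(ncol(A))
    if (any(keep)) {
      k <- which(keep)
      x <- drop(sv$v[, k, drop = FALSE] %*% (ub[k] / sv$d[k]))
    }
    contrast(image_map(x), anomaly_pixels, background_pixels)
  }
  c0 <- con_at(0)
  c1 <- con_at(1)
  tol_abs <- tolerance * abs(target_contrast)
  if (abs(c0 - target_contrast) <= tol_abs)
    return(list(threshold = 0, contrast = c0, converged = TRUE,
                iterations = 0L, attainable = TRUE))
  if (abs(c1 - target_contrast) <= tol_abs)
    return(list(threshold = 1, contrast = c1, converged = TRUE,
                iterations = 0L, attainable = TRUE))
  if ((target_contrast - c0) * (target_contrast - c1) > 0)
    return(list(threshold = if (abs(c0 - target_contrast) <
                                abs(c1 - target_contrast)) 0 else 1,
                contrast = if (abs(c0 - target_contrast) <
                               abs(c1 - target_contrast)) c0 else c1,
                converged = FALSE, iterations = 0L, attainable = FALSE))
  lo <- 0; hi <- 1
  clo <- c0
  best_t <- 0; best_c <- c0
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    cm <- con_at(mid)
    if (abs(cm - target_contrast) < abs(best_c - target_contrast)) {
      best_t <- mid; best_c <- cm
    }
    if (abs(cm - target_contrast) <= tol_abs)
      return(list(threshold = mid, contrast = cm, converged = TRUE,
                  iterations = it, attainable = TRUE))
    if ((target_contrast - clo) * (target_contrast - cm) <= 0) {
      hi <- mid
    } else {
      lo <- mid; clo <- cm
    }
  }
  list(threshold = best_t, contrast = best_c, converged = FALSE,
       iterations = it, attainable = TRUE)
}

#' Singular values required to reach a target contrast
#'
#' Adds TSVD components in decreasing singular-value order until the image
#' contrast first reaches `target_contrast`; reports that component count
#' (the figure of merit for noise robustness: fewer, larger singular values
#' mean a better-conditioned reconstruction) together with the relative
#' threshold `d_k / d_1` that retains exactly those components.
#'
#' @inheritParams threshold_search
#' @return List `rank` (minimal component count, `NA` if the target is not
#'   attainable at full rank), `rel_threshold` (of the last retained
#'   component), `contrast` (achieved), `max_contrast` (at full rank).
#' @export
rank_for_contrast <- function(A, b, target_contrast, anomaly_pixels,
                              background_pixels, image_map = identity) {
  sv <- svd(A)
  if (sv$d[1] == 0) stop("rank_for_contrast: A is the zero matrix")
  ub <- drop(crossprod(sv$u, b))
  r <- sum(sv$d > sv$d[1] * 1e-12)
  x <- numeric(ncol(A))
  cc <- numeric(r)
  hit <- NA_integer_
  for (k in seq_len(r)) {
    x <- x + sv$v[, k] * ub[k] / sv$d[k]
    cc[k] <- contrast(image_map(x), anomaly_pixels, background_pixels)
    if (is.na(hit) && abs(cc[k]) >= abs(target_contrast) &&
        sign(cc[k]) == sign(target_contrast)) hit <- k
  }
  list(rank = hit,
       rel_threshold = if (is.na(hit)) NA_real_ else sv$d[hit] / sv$d[1],
       contrast = if (is.na(hit)) cc[r] else cc[hit],
       max_contrast = cc[r])
}

#' Influence of an outside-ROI anomaly on the data, before and after filtering
#'
#' For each scenario data vector, the norm of its deviation from the
#' reference data, raw and filtered: `||dV_i - dV_ref||` and
#' `||t(Phi)(dV_i - dV_ref)||`, both also normalized by the corresponding
#' reference norms.
#'
#' @param ref_data Reference `eit_voltage` (anomaly in ROI only).
#' @param case_data Named list of `eit_voltage` for the perturbed cases.
#' @param filter An `eit_filter`.
#' @return Data frame with one row per case: `raw_norm`, `filt_norm`,
#'   `raw_ratio`, `filt_ratio`.
#' @export
outside_influence <- function(ref_data, case_data, filter) {
  vr <- ref_data$values
  fr <- drop(crossprod(filter$Phi, vr))
  nr <- sqrt(sum(vr^2))
  nfr <- sqrt(sum(fr^2))
  rows <- lapply(case_data, function(d) {
    if (length(d$values) != length(vr))
      stop("case and reference data use different protocols")
    dv <- d$values - vr
    fdv <- drop(crossprod(filter$Phi, dv))
    data.frame(raw_norm = sqrt(sum(dv^2)),
               filt_norm = sqrt(sum(fdv^2)),
               raw_ratio = sqrt(sum(dv^2)) / nr,
               filt_ratio = sqrt(sum(fdv^2)) / nfr)
  })
  out <- do.call(rbind, rows)
  out$case <- if (is.null(names(case_data))) seq_along(case_data)
              else names(case_data)
  out[, c("case", "raw_norm", "filt_norm", "raw_ratio", "filt_ratio")]
}

## image as nx x nx matrix (NA outside the disk), row-major ids
image_matrix <- function(img, grid) {
  m <- matrix(NA_real_, grid$nx, grid$nx)   # [ix, iy]
  m[!is.na(grid$index)] <- img[grid$index[!is.na(grid$index)]]
  m
}

#' Detect local maxima of a reconstructed image
#'
#' 3x3 mean smoothing (over available in-disk neighbors) followed by strict
#' 8-neighbor local maximum detection; ties are broken deterministically by
#' pixel index. Returns maxima sorted by decreasing smoothed value.
#'
#' @param result An `eit_recon` (or row-major image with a `grid`).
#' @param grid Grid (taken from `result` when absent).
#' @param n_max Number of maxima to return.
#' @param polarity Search for `"positive"` peaks, `"negative"` ones
#'   (conductivity drops, detected on the negated image), or `"abs"`.
#' @return Matrix with columns `x`, `y`, `value` (one row per maximum;
#'   `value` is on the possibly negated/absolute scale searched).
#' @export
find_local_maxima <- function(result, grid = NULL, n_max = 4,
                              polarity = c("positive", "negative", "abs")) {
  polarity <- match.arg(polarity)
  if (inherits(result, "eit_recon")) {
    grid <- result$grid
    img <- result$image
  } else img <- as.numeric(result)
  img <- switch(polarity, positive = img, negative = -img, abs = abs(img))
  m <- image_matrix(img, grid)
  P <- grid$nx
  sm <- m
  for (ix in seq_len(P)) for (iy in seq_len(P)) {
    if (is.na(m[ix, iy])) next
    xs <- max(1, ix - 1):min(P, ix + 1)
    ys <- max(1, iy - 1):min(P, iy + 1)
    sm[ix, iy] <- mean(m[xs, ys], na.rm = TRUE)
  }
  peaks <- NULL
  for (ix in seq_len(P)) for (iy in seq_len(P)) {
    v <- sm[ix, iy]
    if (is.na(v)) next
    xs <- max(1, ix - 1):min(P, ix + 1)
    ys <- max(1, iy - 1):min(P, iy + 1)
    nb <- sm[xs, ys]
    nbid <- grid$index[xs, ys]
    id <- grid$index[ix, iy]
    self <- which(nbid == id)
    nb[self] <- NA
    ## a peak dominates its neighborhood; on a flat plateau the pixel with
    ## the smallest row-major index wins (deterministic tie-break)
    is_peak <- all(is.na(nb)) ||
      (v >= max(nb, na.rm = TRUE) &&
         !any(nb == v & nbid < id, na.rm = TRUE))
    if (is_peak)
      peaks <- rbind(peaks, c(grid$centers[id, 1], grid$centers[id, 2], v))
  }
  if (is.null(peaks)) return(matrix(numeric(0), 0, 3,
                                    dimnames = list(NULL, c("x", "y", "value"))))
  colnames(peaks) <- c("x", "y", "value")
  peaks <- peaks[order(-peaks[, "value"]), , drop = FALSE]
  peaks[seq_len(min(n_max, nrow(peaks))), , drop = FALSE]
}

#' Localization error against known anomaly centers
#'
#' Greedy matching of the strongest detected local maxima to the true
#' centers (repeatedly pairing the globally closest maximum/center pair);
#' reports the Euclidean distances. Missing maxima yield `NA` distances.
#'
#' @param result An `eit_recon`.
#' @param true_centers n x 2 matrix of true anomaly centers.
#' @param polarity Passed to [find_local_maxima()]; use `"negative"` for
#'   anomalies less conductive than the background.
#' @return Numeric vector of distances, one per true center.
#' @export
localization_error <- function(result, true_centers,
                               polarity = c("positive", "negative", "abs")) {
  polarity <- match.arg(polarity)
  true_centers <- matrix(true_centers, ncol = 2)
  n <- nrow(true_centers)
  peaks <- find_local_maxima(result, n_max = n, polarity = polarity)
  dists <- rep(NA_real_, n)
  if (nrow(peaks) == 0) return(dists)
  D <- outer(seq_len(nrow(peaks)), seq_len(n), Vectorize(function(i, j) {
    sqrt((peaks[i, 1] - true_centers[j, 1])^2 +
           (peaks[i, 2] - true_centers[j, 2])^2)
  }))
  D <- matrix(D, nrow(peaks), n)
  for (rep_i in seq_len(min(nrow(peaks), n))) {
    ij <- which(D == min(D, na.rm = TRUE), arr.ind = TRUE)[1, ]
    dists[ij[2]] <- D[ij[1], ij[2]]
    D[ij[1], ] <- NA
    D[, ij[2]] <- NA
    if (all(is.na(D))) break
  }
  dists
}
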