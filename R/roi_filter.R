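## ROI filter: the matrix Phi whose columns are near-parallel to ROI
## sensitivity columns and near-orthogonal to outside columns. Multiplying
## the linearized system by t(Phi) localizes it to the ROI.

#' Filter vector for one ROI pixel
#'
#' Exact minimizer of the strictly convex quadratic
#' `sum_{j outside} (s_j . phi)^2 + alpha * ||phi - s_k||^2`, solved from the
#' normal equations `(S_out %*% t(S_out) + alpha I) phi = alpha s_k`.
#'
#' @param sens An `eit_sens` with an ROI.
#' @param k ROI pixel index (1..R, in ROI-first column order).
#' @param alpha Positive regularization parameter balancing suppression of
#'   outside sensitivity against fidelity to `s_k`.
#' @return Numeric filter vector of length J*K.
#' @export
filter_vector <- function(sens, k, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive scalar")
  p <- partition_columns(sens)
  if (k < 1 || k > ncol(p$S_D)) stop("k must index an ROI pixel")
  M <- nrow(sens$S)
  A <- tcrossprod(p$S_out) + diag(alpha, M)
  drop(solve(A, alpha * p$S_D[, k]))
}

#' Build the full ROI filter matrix
#'
#' One Cholesky factorization of `S_out %*% t(S_out) + alpha I`, reused for
#' all R right-hand sides; column `k` of the result is the [filter_vector()]
#' of ROI pixel `k`.
#'
#' @param sens An `eit_sens` with an ROI.
#' @param alpha Positive scalar; defaults to [default_alpha()].
#' @return Object of class `eit_filter`: `Phi` ((J*K) x R), `alpha`, `R`,
#'   `pixel_ids` (row-major ids of the ROI columns).
#' @export
build_filter <- function(sens, alpha = NULL) {
  if (is.null(alpha)) alpha <- default_alpha(sens)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive scalar")
  p <- partition_columns(sens)
  M <- nrow(sens$S)
  A <- tcrossprod(p$S_out) + diag(alpha, M)
  ch <- chol(A)
  Phi <- backsolve(ch, backsolve(ch, alpha * p$S_D, transpose = TRUE))
  structure(list(Phi = Phi, alpha = alpha, R = sens$R,
                 pixel_ids = sens$pixel_ids[seq_len(sens$R)]),
            class = "eit_filter")
}

#' @export
print.eit_filter <- function(x, ...) {
  cat(sprintf("<eit_filter> %d x %d, alpha = %.4g\n",
              nrow(x$Phi), x$R, x$alpha))
  invisible(x)
}

#' Default filter regularization parameter
#'
#' `alpha = ||S_out %*% t(S_out)||_2 / 100` (i.e. the squared spectral norm
#' of the outside block, scaled down two decades), which is dimensionally
#' consistent with the suppression term; falls back to 1 when the outside
#' block is zero. Override freely.
#'
#' @param sens An `eit_sens` with an ROI.
#' @return Positive scalar.
#' @export
default_alpha <- function(sens) {
  p <- partition_columns(sens)
  s1 <- spectral_norm(p$S_out)
  if (s1 == 0) return(1)
  s1^2 * 1e-2
}

#' Apply the filter to the linearized system
#'
#' Returns the localized system pieces of the filtered equation
#' `t(Phi) S dgamma = t(Phi) dV`: the filtered full matrix (for diagnostics),
#' the filtered ROI block (the local reconstruction operator), and the
#' filtered data.
#'
#' @param filter An `eit_filter`.
#' @param sens The `eit_sens` the filter was built from.
#' @param data An `eit_voltage` (time-difference data).
#' @return List `A_full` (R x N), `A_roi` (R x R), `b` (length R),
#'   `pixel_ids` (ROI column map).
#' @export
apply_filter <- function(filter, sens, data) {
  stopifnot(inherits(filter, "eit_filter"), inherits(sens, "eit_sens"))
  v <- if (inherits(data, "eit_voltage")) data$values else as.numeric(data)
  if (nrow(filter$Phi) != nrow(sens$S) || nrow(filter$Phi) != length(v))
    stop("filter, sensitivity matrix and data dimensions disagree")
  p <- partition_columns(sens)
  list(A_full = crossprod(filter$Phi, sens$S),
       A_roi = crossprod(filter$Phi, p$S_D),
       b = drop(crossprod(filter$Phi, v)),
       pixel_ids = filter$pixel_ids)
}

#' Leakage of out-of-ROI signal through the filter
#'
#' Given the simulated decomposition of the data into the component caused
#' by conductivity change inside the ROI (`data_roi`) and outside
#' (`data_out`), reports how much of the outside component survives the
#' filter: `||t(Phi) data_out||` and the ratio against the filtered ROI
#' component. Only available in simulation, where the two components can be
#' generated separately.
#'
#' @param filter An `eit_filter`.
#' @param data_out,data_roi `eit_voltage` (or numeric) components.
#' @return List `leakage` (`||t(Phi) data_out||_2`), `ratio`
#'   (`||t(Phi) data_out|| / ||t(Phi) data_roi||`, `NA` if the ROI component
#'   is zero), plus the unfiltered `raw_ratio` for comparison.
#' @export
leakage <- function(filter, data_out, data_roi) {
  vo <- if (inherits(data_out, "eit_voltage")) data_out$values else as.numeric(data_out)
  vr <- if (inherits(data_roi, "eit_voltage")) data_roi$values else as.numeric(data_roi)
  lo <- sqrt(sum(crossprod(filter$Phi, vo)^2))
  lr <- sqrt(sum(crossprod(filter$Phi, vr)^2))
  list(leakage = lo,
       ratio = if (lr > 0) lo / lr else NA_real_,
       raw_ratio = if (sqrt(sum(vr^2)) > 0)
         sqrt(sum(vo^2)) / sqrt(sum(vr^2)) else NA_real_)
}

#' Write an ROI filter in the matrix CSV container
#'
#' Same layout as [write_matrix()], with `alpha` recorded on an extra header
#' line `alpha,<value>` before the matrix rows.
#'
#' @param filter An `eit_filter`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_filter <- function(filter, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rows,%d,cols,%d", nrow(filter$Phi), ncol(filter$Phi)),
             con)
  writeLines(paste(c("pixel_ids", filter$pixel_ids), collapse = ","), con)
  writeLines(sprintf("alpha,%.17g", filter$alpha), con)
  writeLines(apply(filter$Phi, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}
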