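#' Fit a 3-D thin-plate-spline interpolant
#'
#' Radial basis interpolation with the thin-plate kernel
#' \eqn{\phi(r) = r^2 \log r} (\eqn{\phi(0) = 0}) plus a full first-order
#' polynomial (affine) part. The coefficients solve the standard TPS block
#' system with orthogonality side conditions (kernel weights orthogonal to
#' constants and to the source coordinates), which makes the interpolant
#' reproduce affine maps exactly and interpolate the control points exactly
#' at `ridge = 0`.
#'
#' @param sources m x 3 matrix of control-point source positions (m >= 5;
#'   non-coplanar unless `ridge > 0`).
#' @param targets m x 3 matrix of control-point target positions.
#' @param ridge non-negative regularisation added to the kernel diagonal
#'   (units: squared length). Default 0 (exact interpolation). A singular
#'   system at `ridge = 0` is retried once with
#'   `1e-10 * (mean pairwise distance)^2` and a warning.
#' @return a `tps_model`: `sources`, `kernel_coefficients` (m x 3),
#'   `affine` (4 x 3: intercept row then linear map), `ridge`.
#' @export
fit_tps <- function(sources, targets, ridge = 0) {
  sources <- as.matrix(sources); targets <- as.matrix(targets)
  m <- nrow(sources)
  if (m < 5L) stop("TPS needs at least 5 control points in 3-D")
  if (nrow(targets) != m) stop("sources/targets row mismatch")
  if (any(!is.finite(sources)) || any(!is.finite(targets)))
    stop("non-finite control coordinates")

  K <- .tps_kernel_matrix(sources, sources)
  P <- cbind(1, sources)
  zero <- matrix(0, 4L, 4L)
  rhs <- rbind(targets, matrix(0, 4L, 3L))
  solve_once <- function(lambda, full = 0) {
    A <- rbind(cbind(K + diag(lambda, m), P), cbind(t(P), zero))
    if (full > 0) A <- A + diag(full, m + 4L) # degenerate affine block too
    solve(A, rhs)
  }
  sol <- tryCatch(solve_once(ridge), error = function(e) NULL)
  if (is.null(sol)) {
    bump <- 1e-10 * mean(stats::dist(sources))^2
    warning("singular TPS system; retrying with ridge = ",
            format(bump, digits = 3))
    sol <- solve_once(ridge + bump, full = bump)
    ridge <- ridge + bump
  }
  structure(list(sources = sources,
                 kernel_coefficients = sol[seq_len(m), , drop = FALSE],
                 affine = sol[m + 1:4, , drop = FALSE],
                 ridge = ridge),
            class = "tps_model")
}

.tps_kernel_matrix <- function(x, y) {
  # phi(r) = r^2 log r, phi(0) = 0
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  K <- 0.5 * d2 * log(pmax(d2, .Machine$double.xmin))
  K[d2 == 0] <- 0
  K
}

#' Evaluate a fitted thin-plate spline at query points
#'
#' @param object a `tps_model` from [fit_tps()].
#' @param newdata q x 3 matrix of query positions.
#' @param ... unused.
#' @return q x 3 matrix of mapped positions.
#' @export
predict.tps_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(dim(newdata))) x <- matrix(newdata, ncol = 3L)
  K <- .tps_kernel_matrix(x, object$sources)
  out <- K %*% object$kernel_coefficients + cbind(1, x) %*% object$affine
  dimnames(out) <- NULL
  out
}

#' @export
print.tps_model <- function(x, ...) {
  cat("<tps_model> ", nrow(x$sources), " control points, ridge = ",
      format(x$ridge), "\n", sep = "")
  invisible(x)
}

#' Exact k-nearest-neighbour indices
#'
#' Brute-force Euclidean nearest neighbours, vectorised and chunked over
#' queries. Exact by construction (used both by the extra-constraint
#' predictor and as its own oracle in tests).
#'
#' @param query q x 3 matrix of query points.
#' @param ref n x 3 matrix of reference points.
#' @param k neighbours per query (k <= n).
#' @return q x k integer matrix of row indices into `ref`, nearest first.
#' @export
knn_indices <- function(query, ref, k) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  n <- nrow(ref)
  if (k > n) stop("k exceeds the number of reference points")
  q <- nrow(query)
  out <- matrix(0L, q, k)
  ref2 <- rowSums(ref^2)
  chunk <- max(1L, floor(2e7 / n))
  for (from in seq(1L, q, by = chunk)) {
    to <- min(q, from + chunk - 1L)
    d2 <- outer(rowSums(query[from:to, , drop = FALSE]^2), ref2, "+") -
      2 * tcrossprod(query[from:to, , drop = FALSE], ref)
    out[from:to, ] <- t(apply(d2, 1L, function(r)
      order(r)[seq_len(k)]))
  }
  out
}
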