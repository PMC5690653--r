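#' Minimum-area enclosing ellipse of a planar point set
#'
#' Computes the Loewner-John (minimum-area) ellipse containing all points,
#' by Khachiyan's barycentric coordinate-descent on the lifted 3D problem.
#' After convergence the ellipse is inflated by the largest Mahalanobis
#' value of the inputs, so every generating point is contained up to
#' floating-point rounding. The minor axis of this ellipse, measured on a
#' tubule cross-section, is the pipeline's diameter estimator: an oblique
#' plane cuts a circular tubule in an ellipse whose *minor* axis equals the
#' true diameter, so the estimate is tilt-invariant.
#'
#' Degenerate inputs (a single point, or collinear points) have no
#' full-rank enclosing ellipse; they are returned as a needle ellipse whose
#' major axis spans the points and whose minor axis is floored at
#' `min_width` (callers measuring pixel centers pass one pixel width, since
#' a pixel has unit physical extent).
#'
#' @param points numeric matrix (n x 2) of planar coordinates, or an object
#'   coercible to one.
#' @param tolerance Khachiyan convergence tolerance (default 1e-4).
#' @param max_iter iteration cap (default 10000).
#' @param min_width floor on the minor-axis *length* for degenerate sets
#'   (default 0: degenerate sets keep a zero minor axis unless floored).
#' @return an object of class `Ellipse2D`: list with `center`, `semi_axes`
#'   (`a >= b`), `angle_rad` (major-axis orientation), `shape_matrix` (A
#'   with interior `(x-c)' A (x-c) <= 1`), `degenerate`, `iterations`.
#' @export
min_enclosing_ellipse <- function(points, tolerance = 1e-4, max_iter = 10000,
                                  min_width = 0) {
  P <- as.matrix(points)
  if (length(P) == 0 || nrow(P) == 0)
    stop("point set is empty", call. = FALSE)
  if (ncol(P) != 2) stop("`points` must be n x 2", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  P <- unique(P)
  n <- nrow(P)

  # rank check: single point or collinear set -> needle ellipse
  ctr0 <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr0))$d
  if (n < 3 || sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    if (n == 1) {
      dirv <- c(1, 0); half <- 0; center <- P[1, ]
    } else {
      dirv <- svd(sweep(P, 2, ctr0))$v[, 1]
      proj <- as.numeric(sweep(P, 2, ctr0) %*% dirv)
      center <- ctr0 + dirv * (max(proj) + min(proj)) / 2
      half <- (max(proj) - min(proj)) / 2
    }
    a <- max(half, min_width / 2)
    b <- min_width / 2
    return(.ellipse2d(center, a, b, atan2(dirv[2], dirv[1]), degenerate = TRUE,
                      iterations = 0L))
  }

  # work in centered coordinates: the lifted 3x3 system is ill-conditioned
  # when the point cloud sits far from the origin
  fit <- cpp_khachiyan(sweep(P, 2, ctr0), tolerance, max_iter)
  fit$center <- fit$center + ctr0
  if (fit$degenerate)
    stop("ellipse fit degenerate despite full-rank input", call. = FALSE)
  if (!fit$converged)
    stop(sprintf("MVEE did not converge within %d iterations", fit$iterations),
         call. = FALSE)
  A <- fit$A
  ctr <- fit$center
  # inflate so all points are inside (Khachiyan guarantees <= 1 + O(tol))
  d <- sweep(P, 2, ctr)
  q <- rowSums((d %*% A) * d)
  m <- max(q)
  if (m > 1) A <- A / m
  eg <- eigen(A, symmetric = TRUE)
  a <- 1 / sqrt(eg$values[2])   # smaller eigenvalue -> major semi-axis
  b <- 1 / sqrt(eg$values[1])
  vmaj <- eg$vectors[, 2]
  ell <- .ellipse2d(ctr, a, max(b, min_width / 2),
                    atan2(vmaj[2], vmaj[1]), degenerate = FALSE,
                    iterations = fit$iterations)
  ell
}

.ellipse2d <- function(center, a, b, angle, degenerate, iterations) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  Ainv_diag <- c(a^2, max(b, 1e-300)^2)
  A <- R %*% diag(1 / Ainv_diag) %*% t(R)
  structure(list(center = as.numeric(center),
                 semi_axes = c(a = a, b = b),
                 angle_rad = angle,
                 shape_matrix = A,
                 degenerate = degenerate,
                 iterations = iterations),
            class = "Ellipse2D")
}

#' @export
print.Ellipse2D <- function(x, ...) {
  cat(sprintf("Ellipse2D: center (%.3f, %.3f), semi-axes (%.4f, %.4f), angle %.3f rad%s\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$angle_rad, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Minor-axis length of an ellipse, in micrometres
#'
#' @param e an [min_enclosing_ellipse()] result (axes in pixel units).
#' @param spacing_um physical size of one pixel (um).
#' @return `2 * b * spacing_um`.
#' @export
minor_axis_length <- function(e, spacing_um = 1) {
  stopifnot(inherits(e, "Ellipse2D"))
  2 * e$semi_axes[["b"]] * spacing_um
}

#' Area of an ellipse (pixel units squared)
#'
#' @param e an `Ellipse2D`.
#' @return `pi * a * b`.
#' @export
ellipse_area <- function(e) {
  stopifnot(inherits(e, "Ellipse2D"))
  pi * e$semi_axes[["a"]] * e$semi_axes[["b"]]
}

#' Do all points lie inside an ellipse?
#'
#' @param e an `Ellipse2D`.
#' @param points n x 2 matrix.
#' @param tol relative slack on the quadratic form (default 1e-6).
#' @return logical vector, one per point.
#' @export
ellipse_contains <- function(e, points, tol = 1e-6) {
  P <- as.matrix(points)
  d <- sweep(P, 2, e$center)
  q <- rowSums((d %*% e$shape_matrix) * d)
  q <= 1 + tol
}
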