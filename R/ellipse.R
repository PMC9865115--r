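#' Tolerance-ellipse radius multiplier
#'
#' The ellipse boundary lies at Mahalanobis radius `r` from the sample
#' mean. The default `"f"` convention, `r = sqrt(2 * qf(level, 2, n - 1))`,
#' matches the classical data-ellipse routine for bivariate samples; the
#' `"chisq"` convention `r = sqrt(qchisq(level, 2))` is its large-sample
#' limit.
#'
#' @param level Coverage probability in (0, 1).
#' @param n Sample size (used by the `"f"` convention).
#' @param method `"f"` (default) or `"chisq"`.
#' @return Scalar radius multiplier.
#' @export
tolerance_radius <- function(level, n, method = c("f", "chisq")) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  switch(method,
         f = sqrt(2 * qf(level, 2, n - 1)),
         chisq = sqrt(qchisq(level, 2)))
}

#' Fit a bivariate tolerance ellipse
#'
#' Fits the ellipse expected to contain a fraction `level` of the points
#' under a bivariate-normal model: center = sample mean, shape = unbiased
#' sample covariance, semi-axes `a = r * sqrt(lambda1)`,
#' `b = r * sqrt(lambda2)` from the covariance eigen-decomposition, with
#' `r` from [tolerance_radius()]. Collinear point clouds yield a
#' degenerate ellipse (`b = 0`, flagged) rather than an error.
#'
#' @param points Numeric `n x 2` matrix (or data frame) of 2D points,
#'   `n >= 3`.
#' @param level Coverage level in (0, 1); default 0.75.
#' @param method Radius convention, see [tolerance_radius()].
#' @return Object of class `tolerance_ellipse`: `center`, semi-axes
#'   `a >= b >= 0`, `tilt` (radians of the major axis vs +x, in
#'   `(-pi/2, pi/2]`; exactly-circular fits use 0), `level`, `n`, `r`,
#'   `sigma` (2x2 covariance), `degenerate` flag.
#' @export
fit_tolerance_ellipse <- function(points, level = 0.75, method = c("f", "chisq")) {
  method <- match.arg(method)
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("points must be an n x 2 numeric matrix")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to fit a tolerance ellipse")
  center <- colMeans(pts)
  sigma <- cov(pts)
  r <- tolerance_radius(level, n, method)
  eg <- eigen(sigma, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  a <- r * sqrt(lambda[1L])
  b <- r * sqrt(lambda[2L])
  eps <- .Machine$double.eps^0.5
  degenerate <- lambda[2L] <= eps * max(lambda[1L], eps)
  if (degenerate) b <- 0
  circular <- (lambda[1L] - lambda[2L]) <= eps * max(lambda[1L], eps)
  if (circular) {
    tilt <- 0  # deterministic tie-break: major axis along +x
  } else {
    v <- eg$vectors[, 1L]
    tilt <- atan2(v[2L], v[1L])
    if (tilt <= -pi / 2) tilt <- tilt + pi
    if (tilt > pi / 2) tilt <- tilt - pi
  }
  structure(list(center = setNames(center, c("x", "y")),
                 a = a, b = b, tilt = tilt, level = level, n = n,
                 r = r, sigma = sigma, degenerate = degenerate,
                 method = method),
            class = "tolerance_ellipse")
}

#' @export
print.tolerance_ellipse <- function(x, ...) {
  cat(sprintf(
    "<tolerance_ellipse> level %.2f, n = %d%s\n  center (%.4f, %.4f), a = %.4f, b = %.4f, tilt = %.1f deg\n",
    x$level, x$n, if (x$degenerate) " [degenerate]" else "",
    x$center[1L], x$center[2L], x$a, x$b, x$tilt * 180 / pi))
  invisible(x)
}

#' Ellipse area
#'
#' Default `"semi"` convention: `pi * a * b` (semi-axis lengths). The
#' `"full"` convention, `pi * (2a) * (2b) = 4 pi a b`, multiplies the full
#' axis lengths instead.
#'
#' @param e A [fit_tolerance_ellipse()] result.
#' @param convention `"semi"` (default) or `"full"`.
#' @return Scalar area.
#' @export
ellipse_area <- function(e, convention = c("semi", "full")) {
  convention <- match.arg(convention)
  stopifnot(inherits(e, "tolerance_ellipse"))
  switch(convention, semi = pi * e$a * e$b, full = 4 * pi * e$a * e$b)
}

#' Major-axis endpoints of an ellipse
#'
#' @param e A [fit_tolerance_ellipse()] result.
#' @return 2 x 2 matrix; rows are `center +/- a * (cos tilt, sin tilt)`.
#'   A fully degenerate ellipse (`a = 0`) returns both endpoints at the
#'   center.
#' @export
major_axis_endpoints <- function(e) {
  stopifnot(inherits(e, "tolerance_ellipse"))
  u <- c(cos(e$tilt), sin(e$tilt))
  rbind(e$center + e$a * u, e$center - e$a * u)
}

#' Ellipse membership test
#'
#' A point is inside the ellipse iff its squared Mahalanobis distance from
#' the center is at most `r^2` (boundary inclusive). Degenerate ellipses
#' contain only their major-axis segment (the center alone when `a = 0`).
#'
#' @param e A [fit_tolerance_ellipse()] result.
#' @param p Numeric 2-vector, or an `n x 2` matrix of points.
#' @return Logical scalar or vector.
#' @export
ellipse_contains <- function(e, p) {
  stopifnot(inherits(e, "tolerance_ellipse"))
  pts <- if (is.matrix(p)) p else matrix(p, ncol = 2L)
  d <- sweep(pts, 2L, e$center)
  tol <- 1e-9
  if (e$degenerate) {
    u <- c(cos(e$tilt), sin(e$tilt))
    along <- d %*% u
    perp <- d %*% c(-u[2L], u[1L])
    res <- abs(perp) <= tol & abs(along) <= e$a + tol
    return(as.vector(res))
  }
  q <- rowSums((d %*% solve(e$sigma)) * d)
  as.vector(q <= e$r^2 * (1 + 1e-12) + tol^2)
}

#' Vertical (y-axis) extent of an ellipse
#'
#' Full height of the ellipse's bounding box: `2 * r * sqrt(sigma_yy)`.
#'
#' @param e A [fit_tolerance_ellipse()] result.
#' @return Scalar length.
#' @export
ellipse_y_width <- function(e) {
  stopifnot(inherits(e, "tolerance_ellipse"))
  2 * e$r * sqrt(max(e$sigma[2L, 2L], 0))
}

# one-row summary used by the ellipse table export
.ellipse_row <- function(e, plane, keypoint, area_convention = "semi") {
  data.frame(plane = plane, keypoint = keypoint,
             center_x = e$center[[1L]], center_y = e$center[[2L]],
             a = e$a, b = e$b, tilt_deg = e$tilt * 180 / pi,
             area = ellipse_area(e, area_convention), n = e$n,
             stringsAsFactors = FALSE)
}
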