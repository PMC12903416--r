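# Constant-curvature space primitives.
#
# Points on curved spaces are stored in ambient coordinates (d+1 columns):
# the Lorentz (hyperboloid) model for hyperbolic space, the round sphere of
# radius 1/sqrt(K) for hyperspherical space. Euclidean points use d columns.
# All operations are vectorised over rows, so a single point may be given as
# a plain numeric vector or as a 1-row matrix.

.err_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("curvae_invalid_argument", "error", "condition")))
}

.err_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("curvae_degenerate_input", "error", "condition")))
}

.as_mat <- function(x, width = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (!is.null(width) && ncol(x) != width)
    .err_invalid(sprintf("expected %d coordinate columns, got %d", width, ncol(x)))
  if (!all(is.finite(x))) .err_invalid("non-finite coordinates")
  x
}

#' Define a constant-curvature latent space
#'
#' @param kind One of `"euclidean"`, `"hyperspherical"`, `"hyperbolic"`.
#' @param K Curvature. Must be 0 for Euclidean, positive for hyperspherical,
#'   negative for hyperbolic. Defaults to 0, +1, -1 by kind.
#' @param d Intrinsic dimension (the ambient representation has `d + 1`
#'   coordinates for the curved spaces).
#'
#' @return An object of class `curvature_space` with fields `kind`, `K`, `d`
#'   and `ambient` (number of ambient coordinates).
#' @export
curvature_space <- function(kind = c("euclidean", "hyperspherical", "hyperbolic"),
                            K = NULL, d = 2L) {
  kind <- match.arg(kind)
  if (is.null(K)) K <- switch(kind, euclidean = 0, hyperspherical = 1, hyperbolic = -1)
  if (kind == "euclidean" && K != 0) .err_invalid("euclidean space requires K = 0")
  if (kind == "hyperspherical" && K <= 0) .err_invalid("hyperspherical space requires K > 0")
  if (kind == "hyperbolic" && K >= 0) .err_invalid("hyperbolic space requires K < 0")
  d <- as.integer(d)
  if (d < 1L) .err_invalid("dimension must be >= 1")
  structure(
    list(kind = kind, K = K, d = d,
         ambient = if (kind == "euclidean") d else d + 1L),
    class = "curvature_space")
}

#' @export
print.curvature_space <- function(x, ...) {
  cat(sprintf("<curvature_space> %s, K = %g, d = %d (ambient %d)\n",
              x$kind, x$K, x$d, x$ambient))
  invisible(x)
}

#' Origin of a constant-curvature space
#'
#' For curved spaces the origin is `(1/sqrt(|K|), 0, ..., 0)`; for Euclidean
#' space it is the zero vector.
#'
#' @param space A [curvature_space()].
#' @return A numeric vector of length `space$ambient`.
#' @export
space_origin <- function(space) {
  if (space$kind == "euclidean") return(numeric(space$d))
  c(1 / sqrt(abs(space$K)), numeric(space$d))
}

#' Lorentz (Minkowski) inner product
#'
#' Computes `-a0*b0 + sum_{i>=1} ai*bi` row-wise.
#'
#' @param a,b Numeric vectors or matrices with equal ambient dimension >= 2.
#' @return A numeric vector of row-wise inner products.
#' @export
lorentz_inner <- function(a, b) {
  a <- .as_mat(a); b <- .as_mat(b)
  if (ncol(a) != ncol(b)) .err_invalid("dimension mismatch in lorentz_inner")
  if (ncol(a) < 2L) .err_invalid("lorentz_inner needs ambient dimension >= 2")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  rowSums(a * b) - 2 * a[, 1L] * b[, 1L]
}

# Row-wise ambient inner product under the space's metric signature.
.sp_inner <- function(space, a, b) {
  if (space$kind == "hyperbolic") lorentz_inner(a, b) else {
    a <- .as_mat(a); b <- .as_mat(b)
    if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    rowSums(a * b)
  }
}

# Residual of the manifold constraint <x,x> = 1/K, per row.
.constraint_residual <- function(space, x) {
  if (space$kind == "euclidean") return(numeric(nrow(.as_mat(x))))
  abs(.sp_inner(space, x, x) - 1 / space$K)
}

# Re-project near-manifold points exactly onto the manifold; error if the
# residual exceeds `tol_reject`. Guards against float drift accumulating over
# long chains of operations.
.project_points <- function(space, x, tol_reject = getOption("curvae.project_tol", 1e-4)) {
  x <- .as_mat(x, if (space$kind == "euclidean") NULL else space$d + 1L)
  if (space$kind == "euclidean") return(x)
  res <- .constraint_residual(space, x)
  if (any(res > tol_reject))
    .err_invalid(sprintf("point off the manifold (max residual %.3g)", max(res)))
  c0 <- abs(space$K)
  if (space$kind == "hyperbolic") {
    x[, 1L] <- sqrt(1 / c0 + rowSums(x[, -1L, drop = FALSE]^2))
  } else {
    nrm <- sqrt(rowSums(x^2))
    x <- x / (nrm * sqrt(c0))
  }
  x
}

# Unified curved-space trig: cosine-like / sine-like functions of sqrt(c)*r.
.cs <- function(space, a) if (space$kind == "hyperbolic") cosh(a) else cos(a)
.sn <- function(space, a) if (space$kind == "hyperbolic") sinh(a) else sin(a)

# sinc-like factor sn(a)/a with the a -> 0 limit handled.
.snc <- function(space, a) {
  out <- ifelse(abs(a) < 1e-8, 1, .sn(space, a) / ifelse(a == 0, 1, a))
  out
}

#' Exponential map
#'
#' Maps a tangent vector `u` at `base` onto the manifold along the geodesic
#' with initial velocity `u`. For Euclidean space this is `base + u`.
#'
#' @param base Point(s) on the manifold (rows).
#' @param u Tangent vector(s) at `base` (rows, ambient coordinates).
#' @param space A [curvature_space()].
#' @return Matrix of points on the manifold (or a vector if both inputs were
#'   vectors).
#' @export
exp_map <- function(base, u, space) {
  vec_in <- is.null(dim(base)) && is.null(dim(u))
  base <- .as_mat(base); u <- .as_mat(u)
  if (space$kind == "euclidean") {
    out <- sweep_rows_add(base, u)
  } else {
    base <- .project_points(space, base)
    if (nrow(base) == 1L && nrow(u) > 1L) base <- base[rep(1L, nrow(u)), , drop = FALSE]
    if (nrow(u) == 1L && nrow(base) > 1L) u <- u[rep(1L, nrow(base)), , drop = FALSE]
    c0 <- abs(space$K)
    r <- sqrt(pmax(.sp_inner(space, u, u), 0))
    a <- sqrt(c0) * r
    out <- .cs(space, a) * base + .snc(space, a) * u
    out <- .project_points(space, out, tol_reject = Inf)
  }
  if (vec_in) drop(out) else out
}

# base + u with single-row recycling.
sweep_rows_add <- function(a, b) {
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  a + b
}

#' Logarithmic map
#'
#' Inverse of [exp_map()]: returns the tangent vector at `base` whose
#' exponential is `target`. For the hypersphere, antipodal pairs have no
#' unique geodesic and raise a degenerate-input condition.
#'
#' @inheritParams exp_map
#' @param target Point(s) on the manifold.
#' @return Tangent vector(s) at `base`.
#' @export
log_map <- function(base, target, space) {
  vec_in <- is.null(dim(base)) && is.null(dim(target))
  base <- .as_mat(base); target <- .as_mat(target)
  if (space$kind == "euclidean") {
    out <- sweep_rows_add(target, -base)
  } else {
    base <- .project_points(space, base)
    target <- .project_points(space, target)
    if (nrow(base) == 1L && nrow(target) > 1L) base <- base[rep(1L, nrow(target)), , drop = FALSE]
    if (nrow(target) == 1L && nrow(base) > 1L) target <- target[rep(1L, nrow(base)), , drop = FALSE]
    c0 <- abs(space$K)
    if (space$kind == "hyperbolic") {
      alpha <- pmax(-c0 * lorentz_inner(base, target), 1)
      a <- acosh(alpha)
      w <- sqrt(pmax(alpha^2 - 1, 0))
    } else {
      alpha <- pmin(pmax(c0 * .sp_inner(space, base, target), -1), 1)
      if (any(alpha < -1 + 1e-10))
        .err_degenerate("antipodal points on the hypersphere: no unique geodesic")
      a <- acos(alpha)
      w <- sqrt(pmax(1 - alpha^2, 0))
    }
    coef <- ifelse(a < 1e-8, 1, a / pmax(w, 1e-300))
    out <- coef * (target - alpha * base)
  }
  if (vec_in) drop(out) else out
}

#' Geodesic distance
#'
#' @inheritParams exp_map
#' @param x,y Points on the manifold (rows).
#' @return Numeric vector of row-wise distances.
#' @export
geodesic_distance <- function(x, y, space) {
  if (space$kind == "euclidean") {
    x <- .as_mat(x); y <- .as_mat(y)
    return(sqrt(rowSums(sweep_rows_add(x, -y)^2)))
  }
  c0 <- abs(space$K)
  if (space$kind == "hyperbolic") {
    acosh(pmax(-c0 * lorentz_inner(x, y), 1)) / sqrt(c0)
  } else {
    acos(pmin(pmax(c0 * .sp_inner(space, x, y), -1), 1)) / sqrt(c0)
  }
}

#' Parallel transport between tangent spaces
#'
#' Transports tangent vector(s) `v` at `from` to the tangent space at `to`
#' along the connecting geodesic. Inner products between transported vectors
#' are preserved. Euclidean transport is the identity.
#'
#' @inheritParams exp_map
#' @param from,to Points on the manifold.
#' @param v Tangent vector(s) at `from`.
#' @param check_tangent Error if `v` is not tangent at `from` beyond
#'   tolerance (default on).
#' @return Tangent vector(s) at `to`.
#' @export
parallel_transport <- function(from, to, v, space, check_tangent = TRUE) {
  vec_in <- is.null(dim(v))
  v <- .as_mat(v)
  if (space$kind == "euclidean") return(if (vec_in) drop(v) else v)
  from <- .project_points(space, from)
  to <- .project_points(space, to)
  n <- max(nrow(from), nrow(to), nrow(v))
  if (nrow(from) == 1L) from <- from[rep(1L, n), , drop = FALSE]
  if (nrow(to) == 1L) to <- to[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  c0 <- abs(space$K)
  if (check_tangent) {
    resid <- abs(.sp_inner(space, from, v))
    scale <- pmax(sqrt(abs(.sp_inner(space, v, v))), 1) / sqrt(c0)
    if (any(resid > getOption("curvae.tangent_tol", 1e-5) * pmax(scale, 1)))
      .err_invalid("v is not tangent at `from`")
  }
  if (space$kind == "hyperbolic") {
    alpha <- -c0 * lorentz_inner(from, to)
    coef <- c0 * lorentz_inner(to, v) / (1 + alpha)
  } else {
    alpha <- c0 * .sp_inner(space, from, to)
    coef <- -c0 * .sp_inner(space, to, v) / (1 + alpha)
  }
  out <- v + coef * (from + to)
  if (vec_in) drop(out) else out
}

#' Project Lorentz coordinates onto the Poincare disk/ball
#'
#' `p = x_spatial / (1 + sqrt(|K|) * x0)`, mapping the hyperboloid sheet onto
#' the open ball of radius `1/sqrt(|K|)`.
#'
#' @param x Hyperbolic point(s) in Lorentz coordinates (rows).
#' @param space A hyperbolic [curvature_space()].
#' @return Matrix (or vector) of `d`-dimensional ball coordinates.
#' @export
lorentz_to_poincare <- function(x, space) {
  if (space$kind != "hyperbolic") .err_invalid("lorentz_to_poincare needs a hyperbolic space")
  vec_in <- is.null(dim(x))
  x <- .project_points(space, .as_mat(x, space$d + 1L))
  c0 <- abs(space$K)
  out <- x[, -1L, drop = FALSE] / (1 + sqrt(c0) * x[, 1L])
  if (vec_in) drop(out) else out
}

#' Lift Poincare ball coordinates back to the Lorentz model
#'
#' Inverse of [lorentz_to_poincare()].
#'
#' @param p Ball point(s), rows, Euclidean norm < `1/sqrt(|K|)`.
#' @param space A hyperbolic [curvature_space()].
#' @return Lorentz-model point(s).
#' @export
poincare_to_lorentz <- function(p, space) {
  if (space$kind != "hyperbolic") .err_invalid("poincare_to_lorentz needs a hyperbolic space")
  vec_in <- is.null(dim(p))
  p <- .as_mat(p, space$d)
  c0 <- abs(space$K)
  m2 <- rowSums(p^2)
  if (any(c0 * m2 >= 1)) .err_invalid("point on or outside the Poincare ball")
  den <- 1 - c0 * m2
  out <- cbind((1 + c0 * m2) / (sqrt(c0) * den), 2 * p / den, deparse.level = 0)
  if (vec_in) drop(out) else out
}

.check_in_ball <- function(p, c0) {
  if (any(c0 * rowSums(p^2) >= 1))
    .err_invalid("point on or outside the Poincare ball boundary")
}

#' Mobius addition on the Poincare ball
#'
#' Gyrovector-space addition with curvature `K < 0`:
#' `x (+) y = ((1 - 2K<x,y> - K|y|^2) x + (1 + K|x|^2) y) /
#'            (1 - 2K<x,y> + K^2 |x|^2 |y|^2)`.
#'
#' @param x,y Ball point(s), rows; either may be a single row recycled
#'   against the other.
#' @param K Negative curvature.
#' @return Ball point(s).
#' @export
mobius_add <- function(x, y, K) {
  if (K >= 0) .err_invalid("mobius_add requires K < 0")
  vec_in <- is.null(dim(x)) && is.null(dim(y))
  x <- .as_mat(x); y <- .as_mat(y)
  if (ncol(x) != ncol(y)) .err_invalid("dimension mismatch in mobius_add")
  n <- max(nrow(x), nrow(y))
  if (nrow(x) == 1L) x <- x[rep(1L, n), , drop = FALSE]
  if (nrow(y) == 1L) y <- y[rep(1L, n), , drop = FALSE]
  c0 <- abs(K)
  .check_in_ball(x, c0); .check_in_ball(y, c0)
  xy <- rowSums(x * y); nx <- rowSums(x^2); ny <- rowSums(y^2)
  num <- (1 + 2 * c0 * xy + c0 * ny) * x + (1 - c0 * nx) * y
  den <- 1 + 2 * c0 * xy + c0^2 * nx * ny
  out <- num / den
  if (vec_in) drop(out) else out
}

#' Recenter Poincare-ball points at a new origin
#'
#' Applies the gyro-translation `(-o) (+) p` to every point, which maps the
#' chosen `new_origin` to 0 while preserving hyperbolic distances.
#'
#' @param points Ball point(s), rows.
#' @param new_origin Single ball point that becomes the new origin.
#' @param K Negative curvature.
#' @return Recentered points.
#' @export
recenter <- function(points, new_origin, K) {
  o <- .as_mat(new_origin)
  if (nrow(o) != 1L) .err_invalid("new_origin must be a single point")
  mobius_add(-o, points, K)
}

#' Bounding-box centre of cycling cells on the disk
#'
#' Estimates the centre of a ring of cycling cells as the midpoint of the
#' axis-aligned bounding box of their 2-D disk coordinates.
#'
#' @param cycling_points Matrix of 2-D disk coordinates (>= 1 row).
#' @return Length-2 numeric vector.
#' @export
estimate_cycling_center <- function(cycling_points) {
  p <- .as_mat(cycling_points, 2L)
  if (nrow(p) < 1L) .err_invalid("no cycling points supplied")
  c((min(p[, 1L]) + max(p[, 1L])) / 2, (min(p[, 2L]) + max(p[, 2L])) / 2)
}

#' Suggest a recentering origin opposite the cycling-cell centre
#'
#' Returns a point near the edge of the disk diagonally across from the
#' estimated cycling centre `p_c`: `-r * p_c / |p_c|`. Advisory only; the
#' published analyses chose their origins manually and any ball point may be
#' passed to [recenter()].
#'
#' @param p_c Estimated centre of the cycling cells (length-2).
#' @param K Negative curvature.
#' @param r Radius at which to place the origin; default `0.9 / sqrt(|K|)`.
#' @return Length-2 numeric vector inside the ball.
#' @export
suggest_new_origin <- function(p_c, K, r = 0.9 / sqrt(abs(K))) {
  p_c <- as.numeric(p_c)
  nrm <- sqrt(sum(p_c^2))
  if (nrm < 1e-12) .err_degenerate("cycling centre at the origin: direction undefined")
  -r * p_c / nrm
}

# Random on-manifold points for tests and demos: tangent Gaussian at the
# origin pushed through the exponential map.
.random_points <- function(space, n, sd = 1) {
  t0 <- matrix(stats::rnorm(n * space$d, sd = sd), n, space$d)
  if (space$kind == "euclidean") return(t0)
  exp_map(matrix(space_origin(space), 1L), cbind(0, t0), space)
}
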