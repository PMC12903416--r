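# Wrapped normal distributions on constant-curvature spaces, the rotated
# (radially aligned) variant on hyperbolic space, and Monte-Carlo KL.
#
# Sampling follows the wrapping construction: draw a tangent Gaussian at the
# origin, parallel-transport it to the location, and push it through the
# exponential map. Densities use the reverse procedure and subtract the
# log-determinant of the wrapping map's Jacobian.

#' Wrapped normal parameter bundle
#'
#' @param mu Location: a point on the manifold (ambient coordinates for
#'   curved spaces, intrinsic for Euclidean).
#' @param sigma Positive vector of length `d`: diagonal tangent standard
#'   deviations at the origin.
#' @param rown If `TRUE`, the diagonal covariance is rotated so that its
#'   first principal axis points along the radial direction through `mu`
#'   before sampling or density evaluation (hyperbolic spaces with `d >= 2`
#'   only; elsewhere the rotation is the identity).
#' @return An object of class `wn_params`.
#' @export
wn_params <- function(mu, sigma, rown = FALSE) {
  sigma <- as.numeric(sigma)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    .err_invalid("sigma must be strictly positive and finite")
  structure(list(mu = as.numeric(mu), sigma = sigma, rown = isTRUE(rown)),
            class = "wn_params")
}

#' Radial-alignment rotation for the rotated wrapped normal
#'
#' Builds the `d x d` rotation `R = I + A + A^2 / (1 + <x, y>)` with
#' `A = y^T x - x^T y`, where `y` is the normalised spatial part of `mu` and
#' `x` is the signed first basis vector `(sign(y_1), 0, ..., 0)`. `R` maps
#' `x` onto `y`, so a diagonal covariance with a large first entry becomes
#' radially aligned at `mu`. When `mu` sits at the origin (zero spatial
#' part), the identity is returned.
#'
#' @param mu Hyperbolic point in ambient (Lorentz) coordinates, or just its
#'   spatial part of length `d` when `spatial = TRUE`.
#' @param spatial Set to `TRUE` if `mu` is already the spatial part.
#' @return A `d x d` orthonormal rotation matrix.
#' @export
rown_rotation <- function(mu, spatial = FALSE) {
  mu <- as.numeric(mu)
  y <- if (spatial) mu else mu[-1L]
  d <- length(y)
  nrm <- sqrt(sum(y^2))
  if (nrm < 1e-12 || d < 2L) return(diag(d))
  y <- y / nrm
  s <- if (y[1L] < 0) -1 else 1
  x <- c(s, numeric(d - 1L))
  A <- outer(y, x) - outer(x, y)
  R <- diag(d) + A + (A %*% A) / (1 + sum(x * y))
  R
}

# Apply R (or its transpose) rowwise to an n x d matrix of tangent spatial
# vectors, vectorised over per-row directions `y` (n x d, unnormalised
# spatial parts). Uses Rw = w + A w + A(Aw)/(1 + <x,y>) without forming any
# per-row matrix.
.rown_apply <- function(w, y_raw, transpose = FALSE) {
  d <- ncol(w)
  nrm <- sqrt(rowSums(y_raw^2))
  ok <- nrm > 1e-12
  y <- y_raw / pmax(nrm, 1e-12)
  s <- ifelse(y[, 1L] < 0, -1, 1)
  # A w = y (x.w) - x (y.w) with x = s * e1
  aw_of <- function(v) {
    xv <- s * v[, 1L]
    yv <- rowSums(y * v)
    out <- y * xv
    out[, 1L] <- out[, 1L] - s * yv
    out
  }
  sgn <- if (transpose) -1 else 1
  denom <- 1 + s * y[, 1L]        # 1 + <x,y> = 1 + |y1| >= 1
  a1 <- aw_of(w)
  a2 <- aw_of(a1)
  out <- w + sgn * a1 + a2 / denom
  out[!ok, ] <- w[!ok, ]
  out
}

# Gradient of the rotation application through the direction y = t/||t||:
# given upstream gradient `dvt` on vt = R(y) w, returns the gradient with
# respect to the raw (unnormalised) location t. Used by the trainer.
.rown_backward_t <- function(dvt, w, tloc) {
  nrm <- sqrt(rowSums(tloc^2))
  ok <- nrm > 1e-12
  y <- tloc / pmax(nrm, 1e-12)
  s <- ifelse(y[, 1L] < 0, -1, 1)
  beta <- s * y[, 1L]
  p <- s * w[, 1L]
  q <- rowSums(y * w)
  D <- 1 + beta
  gy_dot <- rowSums(dvt * y)
  gx <- s * dvt[, 1L]
  # d(Aw)/dy part: p*g - (g.x) w
  gty <- p * dvt - gx * w
  # d(A^2 w / D)/dy part
  c1 <- (beta * p - q) / D
  gty <- gty + c1 * dvt
  add <- gy_dot * (-w / D) - gx * (-beta * w / D)
  add1 <- gy_dot * (p / D - c1 / D) - gx * (-q / D - (p - beta * q) / D^2)
  gty <- gty + add
  gty[, 1L] <- gty[, 1L] + s * add1
  # project onto the tangent of the unit sphere and divide by ||t||
  out <- (gty - y * rowSums(gty * y)) / pmax(nrm, 1e-12)
  out[!ok, ] <- 0
  out
}

#' Sample from a wrapped normal distribution
#'
#' Draws `v ~ N(0, Sigma)` in the tangent space at the origin (rotating
#' `Sigma` first when `rown` is set), parallel-transports to `mu`, and maps
#' through the exponential map. Uses R's global random number generator;
#' seed with [set.seed()] for reproducibility.
#'
#' @param params A [wn_params()].
#' @param space A [curvature_space()].
#' @param n Number of samples.
#' @return An `n x ambient` matrix of points on the manifold.
#' @export
sample_wrapped_normal <- function(params, space, n) {
  n <- as.integer(n)
  if (n < 1L) .err_invalid("n must be >= 1")
  d <- space$d
  if (length(params$sigma) != d) .err_invalid("sigma length must equal the intrinsic dimension")
  eps <- matrix(stats::rnorm(n * d), n, d)
  w <- eps * rep(params$sigma, each = n)
  if (space$kind == "euclidean") {
    return(w + rep(params$mu, each = n))
  }
  mu <- .project_points(space, matrix(params$mu, 1L))
  if (params$rown && space$kind == "hyperbolic" && d >= 2L) {
    R <- rown_rotation(drop(mu))
    w <- w %*% t(R)
  }
  v <- cbind(0, w)
  u <- parallel_transport(matrix(space_origin(space), 1L), mu, v, space, check_tangent = FALSE)
  exp_map(mu[rep(1L, n), , drop = FALSE], u, space)
}

#' Log-density of a wrapped normal distribution
#'
#' Reverse of the sampling procedure: pull `z` back to the tangent space at
#' the origin and evaluate the Gaussian density there, minus the
#' log-determinant of the wrapping map's Jacobian,
#' `(d - 1) * log(sinh(sqrt(|K|) r) / (sqrt(|K|) r))` on hyperbolic space
#' (`sin` on the hypersphere), with `r` the tangent norm of the pullback.
#'
#' @param z Point(s) on the manifold, rows.
#' @inheritParams sample_wrapped_normal
#' @return Numeric vector of log-densities.
#' @export
log_prob_wrapped_normal <- function(z, params, space) {
  d <- space$d
  sigma <- params$sigma
  if (space$kind == "euclidean") {
    z <- .as_mat(z, d)
    dev <- sweep(z, 2L, params$mu)
    return(-0.5 * d * log(2 * pi) - sum(log(sigma)) -
             0.5 * rowSums(sweep(dev, 2L, sigma, "/")^2))
  }
  z <- .project_points(space, .as_mat(z, d + 1L))
  mu <- .project_points(space, matrix(params$mu, 1L))
  o <- matrix(space_origin(space), 1L)
  u <- log_map(mu[rep(1L, nrow(z)), , drop = FALSE], z, space)
  v <- parallel_transport(mu, o, u, space, check_tangent = FALSE)
  w <- v[, -1L, drop = FALSE]
  r <- sqrt(rowSums(w^2))
  if (params$rown && space$kind == "hyperbolic" && d >= 2L) {
    R <- rown_rotation(drop(mu))
    w <- w %*% R          # R^T w
  }
  gauss <- -0.5 * d * log(2 * pi) - sum(log(sigma)) -
    0.5 * rowSums(sweep(w, 2L, sigma, "/")^2)
  a <- sqrt(abs(space$K)) * r
  logdet <- (d - 1) * log(.snc(space, a))
  gauss - logdet
}

#' Monte-Carlo KL divergence between wrapped normals
#'
#' Estimates `KL(q || p) = E_q[log q(z) - log p(z)]` by sampling from `q`.
#' The estimator is unbiased; its Monte-Carlo standard error is attached as
#' attribute `"se"`.
#'
#' @param q,p [wn_params()] on the same `space`.
#' @param space A [curvature_space()].
#' @param n_samples Number of Monte-Carlo samples (>= 1).
#' @return Scalar estimate with attribute `se`.
#' @export
kl_monte_carlo <- function(q, p, space, n_samples = 1000L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) .err_invalid("n_samples must be >= 1")
  z <- sample_wrapped_normal(q, space, n_samples)
  lq <- log_prob_wrapped_normal(z, q, space)
  lp <- log_prob_wrapped_normal(z, p, space)
  diff <- lq - lp
  est <- mean(diff)
  attr(est, "se") <- stats::sd(diff) / sqrt(n_samples)
  est
}
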