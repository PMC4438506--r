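#' Kernel specification for the SPH discretization
#'
#' Bundles the smoothing lengths used by every SPH interpolation and discrete
#' operator. The cubic spline kernel (see [kernel_value()]) has compact support
#' `kappa * h`; with `kappa = 2` interactions vanish beyond `2 h`.
#'
#' The package convention ties the smoothing length to the lattice spacing,
#' `h = 1.3 * dx`, and uses the same length `h_r` for the boundary
#' (color-function) operators. Both can be overridden.
#'
#' @param dx lattice spacing (Angstrom).
#' @param h smoothing length (Angstrom); default `1.3 * dx`.
#' @param h_r boundary smoothing length for color-function normals and the
#'   surface-delta sink (Angstrom); default equal to `h`.
#' @param kappa support multiplier; 2 for the cubic spline.
#' @return An object of class `kernel_spec`: a list with fields `dx`, `h`,
#'   `h_r`, `kappa` and the derived support radius `cutoff = kappa * h`.
#' @examples
#' ks <- kernel_spec(dx = 8)
#' ks$h          # 10.4
#' ks$cutoff     # 20.8
#' @export
kernel_spec <- function(dx, h = 1.3 * dx, h_r = h, kappa = 2) {
  stopifnot(is.numeric(dx), length(dx) == 1L, is.finite(dx), dx > 0,
            is.numeric(h), length(h) == 1L, is.finite(h), h > 0,
            is.numeric(h_r), length(h_r) == 1L, is.finite(h_r), h_r > 0,
            kappa > 0)
  structure(list(dx = dx, h = h, h_r = h_r, kappa = kappa,
                 cutoff = kappa * max(h, h_r)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("SPH kernel: cubic spline, dx = %g A, h = %g A, h_r = %g A, support %g A\n",
              x$dx, x$h, x$h_r, x$kappa * x$h))
  invisible(x)
}

check_rh <- function(r, h) {
  if (!is.numeric(r) || anyNA(r) || any(!is.finite(r)) || any(r < 0))
    stop("distances 'r' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("smoothing length 'h' must be a positive finite scalar", call. = FALSE)
}

#' Cubic spline SPH kernel
#'
#' The normalized cubic spline weighting function
#' \deqn{w(r,h) = \frac{1}{\pi h^3}\begin{cases}
#'   1 - \tfrac{3}{2}q^2 + \tfrac{3}{4}q^3 & 0 \le q \le 1\\
#'   \tfrac{1}{4}(2-q)^3 & 1 < q \le 2\\
#'   0 & q > 2\end{cases}}
#' with \eqn{q = r/h}. It integrates to 1 over three-dimensional space
#' (\eqn{4\pi\int_0^{2h} w r^2 dr = 1}) and is continuously differentiable.
#'
#' @param r distance(s), Angstrom; vectorized.
#' @param h smoothing length, Angstrom (positive scalar).
#' @return Kernel weight density, Angstrom^-3.
#' @seealso [kernel_radial_derivative()], [kernel_gradient()]
#' @examples
#' kernel_value(0, 1)    # 1/pi
#' kernel_value(1, 1)    # 1/(4*pi)
#' kernel_value(2.5, 1)  # 0 (outside support)
#' @export
kernel_value <- function(r, h) {
  check_rh(r, h)
  q <- r / h
  v <- numeric(length(q))
  a <- q <= 1
  b <- q > 1 & q <= 2
  v[a] <- 1 - 1.5 * q[a]^2 + 0.75 * q[a]^3
  v[b] <- 0.25 * (2 - q[b])^3
  v / (pi * h^3)
}

#' Radial derivative of the cubic spline kernel
#'
#' Analytic \eqn{dw/dr} of [kernel_value()]. Non-positive everywhere (the
#' kernel is monotone non-increasing in r) and continuous across the branch
#' points q = 1 and q = 2.
#'
#' @inheritParams kernel_value
#' @return dw/dr, Angstrom^-4.
#' @examples
#' kernel_radial_derivative(0, 1)  # 0
#' kernel_radial_derivative(1, 1)  # -0.75/pi
#' @export
kernel_radial_derivative <- function(r, h) {
  check_rh(r, h)
  q <- r / h
  v <- numeric(length(q))
  a <- q <= 1
  b <- q > 1 & q <= 2
  v[a] <- -3 * q[a] + 2.25 * q[a]^2
  v[b] <- -0.75 * (2 - q[b])^2
  v / (pi * h^4)
}

#' Gradient of the cubic spline kernel
#'
#' \eqn{\nabla w(\mathbf{r}, h) = \hat{\mathbf{r}}\, dw/dr}. Antisymmetric
#' under \eqn{\mathbf{r} \to -\mathbf{r}}, which is what makes pairwise SPH
#' operators conservative. The gradient at zero separation is excluded by the
#' pair-sum convention (all discrete operators sum over \eqn{i \ne j}).
#'
#' @param rvec numeric 3-vector, or an n x 3 matrix of separation vectors
#'   \eqn{\mathbf{r}_i - \mathbf{r}_j} (Angstrom).
#' @inheritParams kernel_value
#' @return Gradient vector(s) with the shape of `rvec`, Angstrom^-4.
#' @export
kernel_gradient <- function(rvec, h) {
  if (is.null(dim(rvec))) {
    stopifnot(length(rvec) == 3L)
    rvec <- matrix(rvec, 1L, 3L)
    drop_dim <- TRUE
  } else drop_dim <- FALSE
  r <- sqrt(rowSums(rvec^2))
  if (any(r == 0))
    stop("kernel gradient undefined at zero separation (self-pairs are excluded)",
         call. = FALSE)
  g <- rvec * (kernel_radial_derivative(r, h) / r)
  if (drop_dim) drop(g) else g
}
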