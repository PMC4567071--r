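# The HDTV2 functional: second-degree total variation over all orientations.
#
# Directional form: the L1-L2 mixed norm, over pixels, of the second
# directional derivative f_{theta,2} across theta in [0, 2pi). Weighted form:
# the same quantity written as sum_i ||W2 (V2 f)_i||_2 where W2 is the
# symmetric PSD square root of the 3 x 3 Gram matrix C2 of the steering
# vector S2(theta) = (cos^2, 2 cos sin, sin^2). The two agree because
# |S2' g|^2 averaged over theta equals g' C2 g = ||W2 g||^2.

s2_steering <- function(theta) {
  rbind(cos(theta)^2, 2 * cos(theta) * sin(theta), sin(theta)^2)
}

#' Second directional derivative from a derivative 3-vector
#'
#' Contracts a per-pixel second-derivative vector `(f_xx, f_xy, f_yy)` with
#' the degree-2 steering vector `(cos^2 t, 2 cos t sin t, sin^2 t)` to give
#' the second derivative of the image along direction `theta`.
#'
#' @param g2 numeric 3-vector `(xx, xy, yy)`.
#' @param theta angle(s) in radians; vectorized.
#' @return Numeric vector of directional second derivatives, one per angle.
#' @examples
#' second_directional_derivative(c(1, 0, 0), 0)      # 1
#' second_directional_derivative(c(0, 0, 1), pi / 2) # 1
#' @export
second_directional_derivative <- function(g2, theta) {
  stopifnot(length(g2) == 3L, all(is.finite(g2)), all(is.finite(theta)))
  as.numeric(crossprod(s2_steering(theta), g2))
}

#' Orientation Gram matrix C2 by quadrature
#'
#' Computes the 3 x 3 matrix `C2[i, j] = (1/2pi) integral S2_i(t) S2_j(t) dt`
#' over a full turn by uniform midpoint quadrature, which is exact for these
#' trigonometric polynomials once 8 or more nodes are used. The closed form
#' is `(1/8) * rbind(c(3, 0, 1), c(0, 4, 0), c(1, 0, 3))`.
#'
#' @param quadrature_nodes number of uniform midpoint nodes on `[0, 2pi)`;
#'   at least 8.
#' @return A symmetric positive definite 3 x 3 matrix.
#' @export
build_C2 <- function(quadrature_nodes = 360L) {
  if (quadrature_nodes < 8L)
    stop("quadrature_nodes must be at least 8 for exactness")
  theta <- (seq_len(quadrature_nodes) - 0.5) * 2 * pi / quadrature_nodes
  S <- s2_steering(theta)
  C <- tcrossprod(S) / quadrature_nodes
  (C + t(C)) / 2
}

#' Symmetric square root of a positive semidefinite matrix
#'
#' Eigendecomposition-based square root: for `C = Q L Q'`, returns
#' `W = Q L^{1/2} Q'`, which is symmetric PSD and satisfies `W %*% W = C`.
#' Applied to C2 this yields the HDTV2 weight matrix W2.
#'
#' @param C symmetric positive semidefinite matrix.
#' @return Symmetric PSD matrix `W` with `W %*% W == C` to rounding.
#' @export
spectral_sqrt <- function(C) {
  if (!isSymmetric(C, tol = 1e-10))
    stop("C must be symmetric")
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values)))
    stop("C must be positive semidefinite")
  W <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  (W + t(W)) / 2
}

.hdtv2_cache <- new.env(parent = emptyenv())

#' The HDTV2 weight matrix W2
#'
#' `W2 = sqrt(C2)` computed numerically (cached). Satisfies
#' `t(W2) %*% W2 == C2`; its closed form is
#' `(1/4) * rbind(c(sqrt(2)+1, 0, sqrt(2)-1), c(0, 2*sqrt(2), 0),
#' c(sqrt(2)-1, 0, sqrt(2)+1))`.
#'
#' @return A symmetric positive definite 3 x 3 matrix.
#' @export
hdtv2_weight_matrix <- function() {
  if (is.null(.hdtv2_cache$W2))
    .hdtv2_cache$W2 <- spectral_sqrt(build_C2(360L))
  .hdtv2_cache$W2
}

#' HDTV2 value of an image (weighted-norm form)
#'
#' Sum over pixels of the Euclidean norm of `W2 %*% (V2 f)_i`: the discrete
#' second-degree total variation. Zero exactly when all second differences
#' vanish (images affine in the interior under the Neumann convention), and
#' positively homogeneous of degree 1.
#'
#' @param img numeric matrix.
#' @param W weighting matrix, defaults to [hdtv2_weight_matrix()].
#' @return A nonnegative scalar.
#' @export
hdtv2_value_weighted <- function(img, W = hdtv2_weight_matrix()) {
  wf <- apply_weighting(apply_V2(img), W)
  sum(sqrt(wf[, , 1L]^2 + wf[, , 2L]^2 + wf[, , 3L]^2))
}

#' HDTV2 value of an image (directional-quadrature form)
#'
#' Direct evaluation of the defining integral: per pixel, the root mean
#' square of the second directional derivative over quadrature nodes on
#' `[0, 2pi)`, summed over pixels. Serves as the independent cross-check of
#' the weighted-norm form.
#'
#' @param img numeric matrix.
#' @param quadrature_nodes number of uniform midpoint nodes (at least 8).
#' @return A nonnegative scalar equal to [hdtv2_value_weighted()] up to
#'   quadrature exactness.
#' @export
hdtv2_value_directional <- function(img, quadrature_nodes = 360L) {
  if (quadrature_nodes < 8L)
    stop("quadrature_nodes must be at least 8")
  g <- apply_V2(img)
  theta <- (seq_len(quadrature_nodes) - 0.5) * 2 * pi / quadrature_nodes
  acc <- matrix(0, nrow(img), ncol(img))
  for (t in theta) {
    d <- cos(t)^2 * g[, , 1L] + 2 * cos(t) * sin(t) * g[, , 2L] +
      sin(t)^2 * g[, , 3L]
    acc <- acc + d^2
  }
  sum(sqrt(acc / quadrature_nodes))
}
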