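# Proximal map of alpha * HDTV2 under box constraints, solved in the dual.
#
# The constrained denoising problem
#   min_{f in [a,b]^N} 1/2 ||f - z||^2 + alpha ||H2 f||_{1,2}
# is solved through its dual: maximize h(w) = E(PS(z - alpha H2' w), w) over
# the per-pixel unit-ball set B2, by projected gradient ascent with Nesterov
# momentum. grad h(w) = alpha H2 PS(z - alpha H2' w) is Lipschitz with
# constant at most 24 alpha^2 (||H2||^2 <= 24), so the fixed ascent step
# 1/(24 alpha) on the scaled gradient is safe.

#' Projection onto a box
#'
#' Componentwise clamp onto `[a, b]`; the orthogonal projection onto the
#' intensity constraint set, firmly non-expansive.
#'
#' @param img numeric matrix (or vector).
#' @param bounds length-2 numeric `c(a, b)` with `a < b`.
#' @return `img` with every value clamped into `[a, b]`.
#' @export
project_box <- function(img, bounds = c(0, 1)) {
  if (length(bounds) != 2L || !(bounds[1L] < bounds[2L]))
    stop("bounds must be c(a, b) with a < b")
  pmin(pmax(img, bounds[1L]), bounds[2L])
}

#' Projection onto the per-pixel Euclidean unit-ball set
#'
#' Projects a derivative field onto B2, the set of fields whose per-pixel
#' 3-vectors have Euclidean norm at most 1 (the unit ball of the l-inf/l2
#' norm, dual to the l1/l2 norm HDTV2 uses).
#'
#' @param field an `r x c x 3` derivative field.
#' @return A field with every per-pixel norm at most 1; pixels already
#'   inside the ball are unchanged.
#' @export
project_ball <- function(field) {
  check_field(field)
  nrm <- sqrt(field[, , 1L]^2 + field[, , 2L]^2 + field[, , 3L]^2)
  scale <- 1 / pmax(1, nrm)
  out <- field
  for (k in 1:3) out[, , k] <- field[, , k] * scale
  out
}

#' Gradient of the dual denoising objective
#'
#' `alpha * H2 %*% PS(z - alpha * H2' w)`: the gradient of the concave dual
#' objective maximized by the inner solver. Lipschitz in `w` with constant
#' at most `24 * alpha^2`.
#'
#' @param omega dual derivative field.
#' @param z noisy image (the prox argument).
#' @param alpha prox weight (`tau * lambda` in the reconstruction loop).
#' @param bounds box constraints `c(a, b)`.
#' @param W weighting matrix.
#' @return A derivative field.
#' @export
dual_gradient <- function(omega, z, alpha, bounds = c(0, 1),
                          W = hdtv2_weight_matrix()) {
  check_field(omega)
  if (alpha == 0) return(array(0, dim = dim(omega), dimnames = dimnames(omega)))
  alpha * apply_H2(project_box(z - alpha * apply_H2_adjoint(omega, W), bounds), W)
}

zero_field <- function(r, c) {
  array(0, dim = c(r, c, 3L), dimnames = list(NULL, NULL, c("xx", "xy", "yy")))
}

prox_objective <- function(f, z, alpha, W) {
  0.5 * sum((f - z)^2) + alpha * hdtv2_value_weighted(f, W)
}

#' Proximal map of the box-constrained HDTV2 regularizer
#'
#' Solves `min_f 1/2 ||f - z||^2 + alpha * HDTV2(f)` subject to
#' `f` in `[a, b]` per pixel, by `iters` iterations of Nesterov-accelerated
#' projected ascent on the dual: with `w0 = v1 = 0`, `t1 = 1`,
#' `w_m = PB2(v_m + 1/(24 alpha) H2 PS(z - alpha H2' v_m))`,
#' `t_{m+1} = (1 + sqrt(1 + 4 t_m^2))/2`,
#' `v_{m+1} = w_m + (t_m - 1)/t_{m+1} (w_m - w_{m-1})`,
#' and returns `PS(z - alpha H2' w_iters)`.
#'
#' @param z numeric matrix, the noisy image.
#' @param alpha nonnegative prox weight; `alpha = 0` reduces to the box
#'   projection.
#' @param bounds box constraints `c(a, b)`.
#' @param iters number of dual iterations (at least 1).
#' @param omega0 optional warm-start dual field (defaults to zero, the
#'   literal restart of the algorithm; passing the previous outer
#'   iteration's dual variable makes repeated inexact calls increasingly
#'   accurate).
#' @param track_objective if `TRUE`, record the primal objective at every
#'   dual iteration in the returned `objective` trace (costs one extra
#'   primal evaluation per iteration).
#' @param W weighting matrix.
#' @return A list of class `hdtv2_prox` with elements `f` (the denoised
#'   image, always inside the box), `omega` (final dual field), and
#'   `objective` (numeric vector: per-iteration primal objective when
#'   tracked, else the final value).
#' @export
prox_hdtv2 <- function(z, alpha, bounds = c(0, 1), iters = 15L, omega0 = NULL,
                       track_objective = FALSE, W = hdtv2_weight_matrix()) {
  check_image(z)
  if (alpha < 0) stop("alpha must be nonnegative")
  if (alpha == 0) {
    f <- project_box(z, bounds)
    return(structure(list(f = f, omega = zero_field(nrow(z), ncol(z)),
                          objective = prox_objective(f, z, 0, W)),
                     class = "hdtv2_prox"))
  }
  if (iters < 1L) stop("iters must be at least 1")
  step <- 1 / (24 * alpha)
  a <- bounds[1L]; b <- bounds[2L]
  # The loop works on the three field components as plain matrices; the W
  # action is unrolled (W2 couples only the xx/yy pair and scales xy).
  if (is.null(omega0)) {
    o1p <- o2p <- o3p <- matrix(0, nrow(z), ncol(z))
  } else {
    check_field(omega0)
    o1p <- omega0[, , 1L]; o2p <- omega0[, , 2L]; o3p <- omega0[, , 3L]
  }
  v1 <- o1p; v2 <- o2p; v3 <- o3p
  t_m <- 1
  obj <- if (track_objective) numeric(iters) else NULL
  o1 <- o1p; o2 <- o2p; o3 <- o3p
  Wt <- t(W)
  primal_from_dual <- function(p1, p2, p3) {
    # f = PS(z - alpha * H2' omega) with H2' = V2' W'
    q1 <- Wt[1, 1] * p1 + Wt[1, 2] * p2 + Wt[1, 3] * p3
    q2 <- Wt[2, 1] * p1 + Wt[2, 2] * p2 + Wt[2, 3] * p3
    q3 <- Wt[3, 1] * p1 + Wt[3, 2] * p2 + Wt[3, 3] * p3
    bt <- z - alpha * (diff_fwd_x_adj(diff_fwd_x_adj(q1)) +
                         diff_fwd_x_adj(diff_fwd_y_adj(q2)) +
                         diff_fwd_y_adj(diff_fwd_y_adj(q3)))
    pmin(pmax(bt, a), b)
  }
  for (m in seq_len(iters)) {
    ft <- primal_from_dual(v1, v2, v3)
    dxx <- diff_fwd_x(diff_fwd_x(ft))
    dxy <- diff_fwd_y(diff_fwd_x(ft))
    dyy <- diff_fwd_y(diff_fwd_y(ft))
    c1 <- v1 + step * (W[1, 1] * dxx + W[1, 2] * dxy + W[1, 3] * dyy)
    c2 <- v2 + step * (W[2, 1] * dxx + W[2, 2] * dxy + W[2, 3] * dyy)
    c3 <- v3 + step * (W[3, 1] * dxx + W[3, 2] * dxy + W[3, 3] * dyy)
    s <- 1 / pmax(1, sqrt(c1^2 + c2^2 + c3^2))
    o1 <- c1 * s; o2 <- c2 * s; o3 <- c3 * s
    t_next <- (1 + sqrt(1 + 4 * t_m^2)) / 2
    mom <- (t_m - 1) / t_next
    v1 <- o1 + mom * (o1 - o1p)
    v2 <- o2 + mom * (o2 - o2p)
    v3 <- o3 + mom * (o3 - o3p)
    o1p <- o1; o2p <- o2; o3p <- o3
    t_m <- t_next
    if (track_objective) {
      f_m <- primal_from_dual(o1, o2, o3)
      obj[m] <- prox_objective(f_m, z, alpha, W)
    }
  }
  f <- primal_from_dual(o1, o2, o3)
  omega <- zero_field(nrow(z), ncol(z))
  omega[, , 1L] <- o1; omega[, , 2L] <- o2; omega[, , 3L] <- o3
  structure(list(f = f, omega = omega,
                 objective = if (track_objective) obj
                             else prox_objective(f, z, alpha, W)),
            class = "hdtv2_prox")
}
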