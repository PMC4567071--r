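# Conventions used throughout the package:
#  * an image is a plain numeric r x c matrix; rows run along the vertical
#    (y) axis, columns along the horizontal (x) axis;
#  * vectorization, where needed, is R's column-major order;
#  * a derivative field is an r x c x 3 array whose slices hold the (xx, xy,
#    yy) second differences of an image (the X2 space);
#  * the DC Fourier coefficient sits at matrix index [1, 1].

#' Euclidean norm of a numeric or complex array
#' @param x numeric or complex vector/matrix/array.
#' @return The Frobenius norm `sqrt(sum(|x|^2))`.
#' @keywords internal
frob_norm <- function(x) sqrt(sum(Mod(x)^2))

check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3 x 3: second differences need 3 samples")
  if (!all(is.finite(img)))
    stop("image contains non-finite values")
  invisible(img)
}

# First-degree forward differences with Neumann (reflexive) truncation:
# the difference at the trailing boundary is zero.
diff_fwd_x <- function(f) {
  c <- ncol(f)
  cbind(f[, -1, drop = FALSE] - f[, -c, drop = FALSE], 0)
}

diff_fwd_y <- function(f) {
  r <- nrow(f)
  rbind(f[-1, , drop = FALSE] - f[-r, , drop = FALSE], 0)
}

# Exact adjoints of the truncated forward differences (negative backward
# difference with boundary rows/columns adjusted; the trailing slot of the
# input never enters because the forward difference there is identically 0).
diff_fwd_x_adj <- function(p) {
  c <- ncol(p)
  out <- matrix(0, nrow(p), c)
  out[, 1] <- -p[, 1]
  if (c > 2L)
    out[, 2:(c - 1L)] <- p[, 1:(c - 2L), drop = FALSE] - p[, 2:(c - 1L), drop = FALSE]
  out[, c] <- p[, c - 1L]
  out
}

diff_fwd_y_adj <- function(p) {
  r <- nrow(p)
  out <- matrix(0, r, ncol(p))
  out[1, ] <- -p[1, ]
  if (r > 2L)
    out[2:(r - 1L), ] <- p[1:(r - 2L), , drop = FALSE] - p[2:(r - 1L), , drop = FALSE]
  out[r, ] <- p[r - 1L, ]
  out
}

#' Discrete second differences of an image
#'
#' Applies one of the three second-degree forward-difference operators
#' \eqn{\Delta_{xx}}, \eqn{\Delta_{xy}}, \eqn{\Delta_{yy}} used by the HDTV2
#' functional. Each is the composition of two first-degree forward
#' differences with the reflexive (Neumann) convention that the difference at
#' the trailing boundary is zero. Under this convention each first-difference
#' operator has norm at most 2, hence each second difference has norm at
#' most 4.
#'
#' @param img numeric matrix (at least 3 x 3).
#' @param axis_pair one of `"xx"`, `"xy"`, `"yy"`; `x` runs along columns,
#'   `y` along rows.
#' @return A matrix of the same shape as `img`.
#' @examples
#' f <- outer(1:5, 1:5, function(i, j) j)  # horizontal ramp
#' second_difference(f, "xx")              # zero away from the boundary
#' @export
second_difference <- function(img, axis_pair = c("xx", "xy", "yy")) {
  check_image(img)
  axis_pair <- match.arg(axis_pair)
  switch(axis_pair,
    xx = diff_fwd_x(diff_fwd_x(img)),
    yy = diff_fwd_y(diff_fwd_y(img)),
    xy = diff_fwd_y(diff_fwd_x(img))
  )
}

#' Adjoint of a discrete second difference
#'
#' Exact adjoint of [second_difference()] under the real Euclidean inner
#' product: `sum(second_difference(u, ap) * p) == sum(u *
#' second_difference_adjoint(p, ap))` up to floating rounding.
#'
#' @param field numeric matrix, same shape as the image it pairs with.
#' @param axis_pair one of `"xx"`, `"xy"`, `"yy"`.
#' @return A matrix of the same shape as `field`.
#' @export
second_difference_adjoint <- function(field, axis_pair = c("xx", "xy", "yy")) {
  check_image(field)
  axis_pair <- match.arg(axis_pair)
  switch(axis_pair,
    xx = diff_fwd_x_adj(diff_fwd_x_adj(field)),
    yy = diff_fwd_y_adj(diff_fwd_y_adj(field)),
    xy = diff_fwd_x_adj(diff_fwd_y_adj(field))
  )
}

#' Stack the three second differences of an image
#'
#' The discrete vectorial operator V2 maps an image to its derivative field:
#' an r x c x 3 array holding (xx, xy, yy) second differences. The adjoint
#' sums the three component adjoints.
#'
#' @param img numeric matrix.
#' @return An `r x c x 3` array with `dimnames` `(NULL, NULL, c("xx", "xy",
#'   "yy"))`.
#' @export
apply_V2 <- function(img) {
  check_image(img)
  out <- array(0, dim = c(nrow(img), ncol(img), 3L),
               dimnames = list(NULL, NULL, c("xx", "xy", "yy")))
  out[, , 1L] <- second_difference(img, "xx")
  out[, , 2L] <- second_difference(img, "xy")
  out[, , 3L] <- second_difference(img, "yy")
  out
}

check_field <- function(field) {
  if (!is.array(field) || length(dim(field)) != 3L || dim(field)[3L] != 3L)
    stop("derivative field must be an r x c x 3 array")
  invisible(field)
}

#' @rdname apply_V2
#' @param field an `r x c x 3` derivative field.
#' @export
apply_V2_adjoint <- function(field) {
  check_field(field)
  second_difference_adjoint(field[, , 1L], "xx") +
    second_difference_adjoint(field[, , 2L], "xy") +
    second_difference_adjoint(field[, , 3L], "yy")
}

#' Per-pixel weighting of a derivative field
#'
#' Applies a 3 x 3 matrix `W` to the 3-vector at every pixel of a derivative
#' field (the discrete operator \eqn{\Lambda_2} when `W` is the HDTV2 weight
#' matrix W2). The adjoint applies `t(W)`; for the symmetric W2 the operator
#' is self-adjoint.
#'
#' @param field an `r x c x 3` derivative field.
#' @param W a 3 x 3 numeric matrix.
#' @return A derivative field of the same shape.
#' @export
apply_weighting <- function(field, W) {
  check_field(field)
  if (!is.matrix(W) || any(dim(W) != 3L))
    stop("W must be a 3 x 3 matrix")
  out <- array(0, dim = dim(field), dimnames = dimnames(field))
  for (k in 1:3) {
    out[, , k] <- W[k, 1L] * field[, , 1L] + W[k, 2L] * field[, , 2L] +
      W[k, 3L] * field[, , 3L]
  }
  out
}

# H2 = Lambda2 V2 and its adjoint; the workhorses of the dual prox solver.
apply_H2 <- function(img, W = hdtv2_weight_matrix()) {
  apply_weighting(apply_V2(img), W)
}

apply_H2_adjoint <- function(field, W = hdtv2_weight_matrix()) {
  apply_V2_adjoint(apply_weighting(field, t(W)))
}

#' Fourier sampling mask
#'
#' A boolean r x c matrix marking which 2-D DFT coefficients are measured.
#' The DC coefficient (matrix index `[1, 1]`) is always selected: sampling DC
#' is what makes the reconstruction objective coercive (constant images are
#' invisible to the second differences but not to the DC measurement).
#'
#' @param selected logical matrix of sampled frequencies.
#' @return An object of class `fourier_mask` (a logical matrix with the DC
#'   entry forced to `TRUE`).
#' @export
fourier_mask <- function(selected) {
  if (!is.matrix(selected) || !is.logical(selected))
    stop("selected must be a logical matrix")
  selected[1L, 1L] <- TRUE
  structure(selected, class = c("fourier_mask", class(selected)))
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (!mask[1L, 1L])
    stop("mask must select the DC (index [1,1]) coefficient")
  invisible(mask)
}

#' @rdname fourier_mask
#' @param mask a `fourier_mask`.
#' @export
mask_count <- function(mask) {
  check_mask(mask)
  sum(mask)
}

#' Partial Fourier sensing operator and its adjoint
#'
#' `forward_model()` computes `A f = P F f`: the unitary 2-D DFT of a real
#' image, restricted to the frequencies selected by `mask` (column-major scan
#' order). The unitary normalization makes `||A|| <= 1`, so the gradient of
#' the data term has Lipschitz constant at most 1 and the forward-backward
#' step size can range over (0, 2). `forward_adjoint()` embeds measurements
#' at the selected frequencies, applies the inverse unitary DFT, and keeps
#' the real part (the adjoint of the real-to-complex map under the real
#' inner product).
#'
#' @param img real numeric matrix.
#' @param mask a `fourier_mask` of the same shape.
#' @return `forward_model()`: a complex vector of length `sum(mask)`;
#'   `forward_adjoint()`: a real matrix shaped like the mask.
#' @export
forward_model <- function(img, mask) {
  check_image(img)
  check_mask(mask)
  if (!all(dim(img) == dim(mask)))
    stop("image and mask shapes differ")
  Fh <- stats::fft(img) / sqrt(length(img))
  Fh[mask]
}

#' @rdname forward_model
#' @param meas complex measurement vector, ordered as `which(mask)`.
#' @export
forward_adjoint <- function(meas, mask) {
  check_mask(mask)
  if (length(meas) != sum(mask))
    stop("measurement length does not match mask count")
  G <- matrix(0 + 0i, nrow(mask), ncol(mask))
  G[mask] <- meas
  Re(stats::fft(G, inverse = TRUE) / sqrt(length(G)))
}

#' Operator norm by power iteration
#'
#' Estimates the largest singular value of a linear operator from a seeded
#' random start by power iteration on `adjoint(apply(x))`. Used to verify
#' the analytic bounds `||Dxx||, ||Dxy||, ||Dyy|| <= 4` and `||H2||^2 <= 24`
#' that underpin the dual step size of the proximal solver.
#'
#' @param apply_op function mapping the domain to the range.
#' @param adjoint_op exact adjoint of `apply_op`.
#' @param init a starting element of the domain (any numeric array), or a
#'   pair `c(r, c)` in which case a seeded standard-normal image is drawn.
#' @param iters number of power iterations.
#' @param seed integer seed for the random start (ignored when `init` is a
#'   full array).
#' @return The estimated operator norm (a scalar); 0 for the zero operator.
#' @export
operator_norm_estimate <- function(apply_op, adjoint_op, init, iters = 100L,
                                   seed = 1L) {
  x <- if (is.numeric(init) && length(init) == 2L && is.null(dim(init))) {
    with_seed(seed, matrix(stats::rnorm(init[1L] * init[2L]), init[1L], init[2L]))
  } else {
    init
  }
  nx <- frob_norm(x)
  if (nx == 0) return(0)
  x <- x / nx
  for (i in seq_len(iters)) {
    y <- adjoint_op(apply_op(x))
    ny <- frob_norm(y)
    if (ny == 0) return(0)
    x <- y / ny
  }
  frob_norm(apply_op(x))
}

# Evaluate expr with a private, restored RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
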