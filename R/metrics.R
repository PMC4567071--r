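# Image quality metrics: PSNR, the global-moment SSIM index, and the
# relative error used in convergence traces.

#' Peak signal-to-noise ratio
#'
#' `10 log10(max |ref|^2 / mean((ref - recon)^2))` in dB: peak intensity of
#' the reference over the mean squared reconstruction error. Identical
#' images give `Inf`.
#'
#' @param ref reference image (nonzero).
#' @param recon reconstructed image, same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, recon) {
  if (!all(dim(ref) == dim(recon))) stop("image shapes differ")
  peak <- max(abs(ref))^2
  if (peak == 0) stop("reference image is identically zero")
  mse <- mean((ref - recon)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak / mse)
}

#' Global structural similarity index
#'
#' Single SSIM index computed from whole-image means, variances and
#' covariance:
#' `(2 mu_x mu_y + c1)(2 cov + c2) / ((mu_x^2 + mu_y^2 + c1)(var_x + var_y + c2))`.
#' Defaults follow the common SSIM constants `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2` with dynamic range `L`. A mean-of-local-windows variant
#' is available behind `windowed` for cross-checks; the global form is the
#' reported metric.
#'
#' @param ref,recon images of equal shape.
#' @param c1,c2 stabilizing constants; computed from `dynamic_range` when
#'   `NULL`.
#' @param dynamic_range intensity range `L` (1 for images in `[0, 1]`).
#' @param windowed if `TRUE`, average the index over sliding square windows
#'   instead of using global moments.
#' @param window_size side of the sliding window (windowed form only).
#' @return SSIM index; equals 1 iff the images are identical, and lies in
#'   (0, 1] for nonnegative images.
#' @export
ssim_global <- function(ref, recon, c1 = NULL, c2 = NULL, dynamic_range = 1,
                        windowed = FALSE, window_size = 8L) {
  if (!all(dim(ref) == dim(recon))) stop("image shapes differ")
  if (is.null(c1)) c1 <- (0.01 * dynamic_range)^2
  if (is.null(c2)) c2 <- (0.03 * dynamic_range)^2
  ssim_moments <- function(x, y) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    (2 * mx * my + c1) * (2 * cxy + c2) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (!windowed) return(ssim_moments(ref, recon))
  r <- nrow(ref); c <- ncol(ref)
  w <- min(window_size, r, c)
  vals <- numeric(0)
  for (i in seq(1L, r - w + 1L)) {
    for (j in seq(1L, c - w + 1L)) {
      vals <- c(vals, ssim_moments(ref[i:(i + w - 1L), j:(j + w - 1L)],
                                   recon[i:(i + w - 1L), j:(j + w - 1L)]))
    }
  }
  mean(vals)
}

#' Relative reconstruction error
#'
#' `||iterate - ref||_F / ||ref||_F`; the quantity plotted in the
#' convergence traces.
#'
#' @param iterate current image.
#' @param ref nonzero reference image.
#' @return A nonnegative scalar, 0 iff the images coincide.
#' @export
relative_error <- function(iterate, ref) {
  if (!all(dim(iterate) == dim(ref))) stop("image shapes differ")
  nref <- frob_norm(ref)
  if (nref == 0) stop("reference image is identically zero")
  frob_norm(iterate - ref) / nref
}
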