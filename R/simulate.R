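# Synthetic experiment generation: variable-density Fourier sampling masks,
# SNR-calibrated complex measurement noise, and phantoms that emulate the
# salient structure of the study's test images (piecewise-smooth
# anatomy-like regions with edges; elongated filament-like strokes).

#' Variable-density random Fourier sampling mask
#'
#' Draws `M = round(ratio * r * c)` frequencies without replacement with
#' probability proportional to `(1 + |k| / k_max)^(-decay)` in centered
#' coordinates, biasing selection toward low frequencies, then forces the DC
#' coefficient on (required for a coercive objective). By default a centered
#' 8 x 8 low-frequency block is fully sampled first (counted within `M`),
#' mirroring the fully sampled calibration region of variable-density
#' k-space schemes.
#'
#' @param r,c mask dimensions.
#' @param ratio fraction of coefficients to sample, in (0, 1].
#' @param decay nonnegative radial density exponent; 0 gives uniform
#'   sampling.
#' @param seed integer seed; the draw is deterministic given it.
#' @param center_block side length of the fully sampled centered
#'   low-frequency block (0 disables; automatically skipped when `M` is too
#'   small to contain it).
#' @return A [fourier_mask()] with exactly `M` entries selected.
#' @export
variable_density_mask <- function(r, c, ratio, decay = 2, seed = 1L,
                                  center_block = 8L) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  if (decay < 0) stop("decay must be nonnegative")
  N <- r * c
  M <- max(1L, as.integer(round(ratio * N)))
  if (M >= N) return(fourier_mask(matrix(TRUE, r, c)))
  # centered frequency coordinates of the standard DFT layout (DC at [1,1])
  kx <- ifelse(seq_len(c) - 1L <= c %/% 2, seq_len(c) - 1L, seq_len(c) - 1L - c)
  ky <- ifelse(seq_len(r) - 1L <= r %/% 2, seq_len(r) - 1L, seq_len(r) - 1L - r)
  kr <- sqrt(outer(ky^2, kx^2, `+`))
  prob <- (1 + kr / max(kr))^(-decay)
  sel <- matrix(FALSE, r, c)
  block_idx <- integer(0)
  if (center_block > 0L && M > center_block^2) {
    half <- center_block %/% 2
    bx <- which(kx >= -half & kx < center_block - half)
    by <- which(ky >= -half & ky < center_block - half)
    block <- as.matrix(expand.grid(row = by, col = bx))
    block_idx <- (block[, "col"] - 1L) * r + block[, "row"]
    sel[block_idx] <- TRUE
  }
  remaining <- setdiff(seq_len(N), block_idx)
  n_draw <- M - length(block_idx)
  draw <- with_seed(seed,
                    sample(remaining, n_draw, replace = FALSE,
                           prob = prob[remaining]))
  sel[draw] <- TRUE
  if (!sel[1L, 1L]) {
    # swap one drawn frequency for DC so M stays exact
    sel[draw[1L]] <- FALSE
    sel[1L, 1L] <- TRUE
  }
  fourier_mask(sel)
}

#' Add complex Gaussian noise at a target SNR
#'
#' Perturbs a clean measurement vector with i.i.d. circular complex Gaussian
#' noise whose standard deviation sigma is calibrated so that
#' `10 log10(||g_clean||^2 / E||e||^2)` equals `snr_db` (measurement-domain
#' SNR; `E||e||^2 = M sigma^2`).
#'
#' @param clean complex measurement vector (nonzero).
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns the
#'   clean vector unchanged.
#' @param seed integer seed.
#' @return The noisy complex vector, with the calibrated sigma attached as
#'   attribute `"sigma"`.
#' @export
add_noise_snr <- function(clean, snr_db, seed = 1L) {
  p_sig <- sum(Mod(clean)^2)
  if (p_sig == 0) stop("clean measurement vector must be nonzero")
  if (is.infinite(snr_db)) {
    attr(clean, "sigma") <- 0
    return(clean)
  }
  M <- length(clean)
  sigma <- sqrt(p_sig / M * 10^(-snr_db / 10))
  e <- with_seed(seed, complex(real = stats::rnorm(M, sd = sigma / sqrt(2)),
                               imaginary = stats::rnorm(M, sd = sigma / sqrt(2))))
  out <- clean + e
  attr(out, "sigma") <- sigma
  out
}

#' Synthetic phantoms
#'
#' Deterministic (seeded) test images in `[0, 1]`:
#' \describe{
#'   \item{piecewise_linear}{random affine gradients on a random Voronoi
#'     partition of the plane — exactly the images the HDTV2 prior is sparse
#'     on (second differences vanish off the region edges).}
#'   \item{blobs}{smooth Gaussian bumps plus sharp-edged ellipses,
#'     emulating piecewise-smooth anatomy-like structure.}
#'   \item{filaments}{anti-aliased random curved strokes 1-3 px wide,
#'     emulating elongated filament-like cell features.}
#' }
#'
#' @param kind phantom family.
#' @param r,c image dimensions (at least 32).
#' @param seed integer seed.
#' @return A numeric `r x c` matrix with values in `[0, 1]`.
#' @export
make_phantom <- function(kind = c("piecewise_linear", "blobs", "filaments"),
                         r = 64L, c = 64L, seed = 1L) {
  kind <- match.arg(kind)
  if (r < 32L || c < 32L) stop("phantom dimensions must be at least 32")
  with_seed(seed, switch(kind,
    piecewise_linear = phantom_piecewise_linear(r, c),
    blobs = phantom_blobs(r, c),
    filaments = phantom_filaments(r, c)
  ))
}

# normalized pixel-center coordinates in [0,1]
pixel_coords <- function(r, c) {
  list(x = matrix(rep((seq_len(c) - 0.5) / c, each = r), r, c),
       y = matrix(rep((seq_len(r) - 0.5) / r, times = c), r, c))
}

phantom_piecewise_linear <- function(r, c, n_regions = 8L) {
  co <- pixel_coords(r, c)
  sx <- stats::runif(n_regions)
  sy <- stats::runif(n_regions)
  best <- matrix(Inf, r, c)
  lab <- matrix(1L, r, c)
  for (k in seq_len(n_regions)) {
    d <- (co$x - sx[k])^2 + (co$y - sy[k])^2
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- k
  }
  img <- matrix(0, r, c)
  for (k in seq_len(n_regions)) {
    a <- stats::runif(1, 0.1, 0.9)
    bx <- stats::runif(1, -0.6, 0.6)
    by <- stats::runif(1, -0.6, 0.6)
    m <- lab == k
    img[m] <- a + bx * (co$x[m] - sx[k]) + by * (co$y[m] - sy[k])
  }
  pmin(pmax(img, 0), 1)
}

phantom_blobs <- function(r, c, n_bumps = 6L, n_ellipses = 3L) {
  co <- pixel_coords(r, c)
  img <- matrix(0.1, r, c)
  for (k in seq_len(n_bumps)) {
    cx <- stats::runif(1, 0.15, 0.85)
    cy <- stats::runif(1, 0.15, 0.85)
    s <- stats::runif(1, 0.05, 0.2)
    a <- stats::runif(1, 0.2, 0.6)
    img <- img + a * exp(-((co$x - cx)^2 + (co$y - cy)^2) / (2 * s^2))
  }
  for (k in seq_len(n_ellipses)) {
    cx <- stats::runif(1, 0.2, 0.8)
    cy <- stats::runif(1, 0.2, 0.8)
    ax <- stats::runif(1, 0.05, 0.2)
    ay <- stats::runif(1, 0.05, 0.2)
    phi <- stats::runif(1, 0, pi)
    a <- stats::runif(1, -0.4, 0.4)
    xr <- (co$x - cx) * cos(phi) + (co$y - cy) * sin(phi)
    yr <- -(co$x - cx) * sin(phi) + (co$y - cy) * cos(phi)
    img[(xr / ax)^2 + (yr / ay)^2 <= 1] <-
      img[(xr / ax)^2 + (yr / ay)^2 <= 1] + a
  }
  img <- img - min(img)
  img / max(img)
}

phantom_filaments <- function(r, c, n_strokes = 10L) {
  co <- pixel_coords(r, c)
  img <- matrix(0.05, r, c)
  for (k in seq_len(n_strokes)) {
    # quadratic Bezier stroke sampled densely, rendered with a Gaussian pen
    p0 <- stats::runif(2)
    p1 <- stats::runif(2)
    p2 <- stats::runif(2)
    width <- stats::runif(1, 0.6, 1.5) / max(r, c)  # 1-3 px wide
    amp <- stats::runif(1, 0.5, 0.9)
    t <- seq(0, 1, length.out = 4L * max(r, c))
    bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
    by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
    stroke <- matrix(0, r, c)
    # distance to the polyline via per-pixel min over sampled points,
    # restricted to a bounding window for speed
    for (s in seq_along(t)) {
      jx <- round(bx[s] * c + 0.5)
      jy <- round(by[s] * r + 0.5)
      win <- 3L
      ix <- max(1L, jx - win):min(c, jx + win)
      iy <- max(1L, jy - win):min(r, jy + win)
      if (length(ix) == 0L || length(iy) == 0L) next
      d2 <- (co$x[iy, ix, drop = FALSE] - bx[s])^2 +
        (co$y[iy, ix, drop = FALSE] - by[s])^2
      stroke[iy, ix] <- pmax(stroke[iy, ix], exp(-d2 / (2 * width^2)))
    }
    img <- pmax(img, amp * stroke)
  }
  pmin(pmax(img, 0), 1)
}

#' Simulate a full compressive-sensing measurement
#'
#' Convenience wrapper composing phantom, mask and noise: returns the exact
#' triple used by the reconstruction experiments, with `g = A f + e`.
#'
#' @param kind phantom family (see [make_phantom()]).
#' @param r,c image dimensions.
#' @param ratio sampling ratio.
#' @param snr_db measurement SNR in dB (`Inf` for noiseless).
#' @param seed master seed; phantom, mask and noise draws are derived from
#'   it deterministically.
#' @param decay mask density exponent.
#' @return A list with `f_true`, `mask`, `g` (noisy measurements, sigma in
#'   `attr(g, "sigma")`), `g_clean`, and the generation parameters.
#' @export
simulate_cs_instance <- function(kind = "piecewise_linear", r = 64L, c = 64L,
                                 ratio = 0.3, snr_db = 30, seed = 1L,
                                 decay = 2) {
  f_true <- make_phantom(kind, r, c, seed = seed)
  mask <- variable_density_mask(r, c, ratio, decay = decay, seed = seed + 1L)
  g_clean <- forward_model(f_true, mask)
  g <- add_noise_snr(g_clean, snr_db, seed = seed + 2L)
  list(f_true = f_true, mask = mask, g = g, g_clean = g_clean,
       params = list(kind = kind, r = r, c = c, ratio = ratio,
                     snr_db = snr_db, seed = seed, decay = decay,
                     sigma = attr(g, "sigma")))
}
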