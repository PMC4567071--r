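# Solver behavior on small seeded instances (32 x 32 keeps runtimes modest;
# the heavier 64 x 64 convergence protocol lives in test-acceptance.R).

small_instance <- function(seed = 1, kind = "blobs", ratio = 0.4) {
  simulate_cs_instance(kind, 32, 32, ratio, 30, seed = seed)
}

test_that("cost matches a term-by-term recomputation", {
  inst <- small_instance(3)
  f <- make_phantom("blobs", 32, 32, seed = 8)
  lam <- 0.01
  direct <- 0.5 * sum(Mod(inst$g - forward_model(f, inst$mask))^2) +
    lam * hdtv2_value_directional(f, 360L)
  expect_equal(cost(f, inst$g, inst$mask, lam), direct, tolerance = 1e-8)
  expect_equal(cost(matrix(0, 4, 4) + 0,
                    forward_model(matrix(0, 4, 4), fourier_mask(matrix(TRUE, 4, 4))),
                    fourier_mask(matrix(TRUE, 4, 4)), 1), 0)
  expect_error(cost(f, inst$g, inst$mask, -1), "nonnegative")
})

test_that("exact data with no regularization is recovered through FBS", {
  f <- make_phantom("blobs", 32, 32, seed = 2)
  full <- fourier_mask(matrix(TRUE, 32, 32))
  g <- forward_model(f, full)
  res <- fbs_reconstruct(g, full, lambda = 0, max_outer = 5)
  expect_lt(max(abs(res$image - f)), 1e-10)
})

test_that("FBS validates its step size and improves on the zero-fill", {
  inst <- small_instance(5, ratio = 0.3)
  expect_error(fbs_reconstruct(inst$g, inst$mask, 1e-3, tau = 2.5), "tau")
  expect_error(fbs_reconstruct(inst$g, inst$mask, 1e-3, tau = 0), "tau")
  res <- fbs_reconstruct(inst$g, inst$mask, 2e-3, max_outer = 80,
                         inner_iters = 15, warm_start = TRUE,
                         f_ref = inst$f_true)
  zf_psnr <- psnr(inst$f_true, project_box(forward_adjoint(inst$g, inst$mask)))
  expect_gt(utils::tail(res$trace$psnr, 1), zf_psnr)
  expect_true(all(res$image >= 0 & res$image <= 1))
  expect_equal(nrow(res$trace), length(res$trace$cost))
})

test_that("a converged FBS iterate is a fixed point of the outer map", {
  inst <- small_instance(7, ratio = 0.4)
  res <- fbs_reconstruct(inst$g, inst$mask, 2e-3, max_outer = 600,
                         inner_iters = 25, warm_start = TRUE, tol = 1e-7)
  f_hat <- res$image
  z <- f_hat - forward_adjoint(forward_model(f_hat, inst$mask) - inst$g,
                               inst$mask)
  f_next <- prox_hdtv2(z, 2e-3, iters = 2000)$f
  expect_lt(field_norm(f_next - f_hat) / field_norm(f_hat), 1e-4)
})

test_that("FBS fixed-point residuals trend to zero", {
  inst <- small_instance(9, ratio = 0.3)
  res <- fbs_reconstruct(inst$g, inst$mask, 2e-3, max_outer = 150,
                         inner_iters = 20, warm_start = TRUE, tol = 0)
  r <- res$trace$fp_residual
  expect_lt(r[150], r[10])
  expect_lt(r[150], 1e-3)
  # within-tolerance monotone decay: allow small transients
  late <- r[50:150]
  expect_lt(max(diff(late)), 0.05 * r[50])
})

test_that("sampling DC makes constant shifts strictly increase the cost", {
  inst <- small_instance(4)
  f <- make_phantom("blobs", 32, 32, seed = 4)
  base <- cost(f, inst$g, inst$mask, 1e-3)
  for (c_shift in c(0.5, 1, 2))
    expect_gt(cost(f + c_shift, inst$g, inst$mask, 1e-3), base)
})

test_that("final HDTV2 value shrinks as lambda grows", {
  inst <- small_instance(6, ratio = 0.3)
  vals <- sapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(lam) {
    res <- fbs_reconstruct(inst$g, inst$mask, lam, max_outer = 120,
                           inner_iters = 20, warm_start = TRUE, tol = 1e-6)
    hdtv2_value_weighted(res$image)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("MM with lambda = 0 and full sampling returns the zero-fill", {
  f <- make_phantom("blobs", 32, 32, seed = 11)
  full <- fourier_mask(matrix(TRUE, 32, 32))
  g <- forward_model(f, full)
  res <- mm_reconstruct(g, full, lambda = 0)
  expect_equal(nrow(res$trace), 1L)
  expect_lt(max(abs(res$image - f)), 1e-8)
  expect_error(mm_reconstruct(g, full, 1e-3, smoothing_eps = 0), "positive")
})

test_that("MM descends the objective and agrees with FBS at convergence", {
  inst <- small_instance(12, ratio = 0.4)
  lam <- 3e-3
  mm <- mm_reconstruct(inst$g, inst$mask, lam, max_outer = 60, tol = 1e-7,
                       f_ref = inst$f_true)
  expect_lt(utils::tail(mm$trace$cost, 1), mm$trace$cost[1])
  fbs <- fbs_reconstruct(inst$g, inst$mask, lam, max_outer = 500,
                         inner_iters = 25, warm_start = TRUE, tol = 1e-7)
  # both minimize the same functional; their converged costs must nearly
  # agree (MM's is evaluated at the box-clipped image, so it sits slightly
  # above the unconstrained CG solution's value)
  expect_lt(abs(utils::tail(mm$trace$cost, 1) - utils::tail(fbs$trace$cost, 1)) /
              utils::tail(fbs$trace$cost, 1), 0.01)
})

test_that("TV-FISTA: zero-fill limit and monotone cost", {
  f <- make_phantom("piecewise_linear", 32, 32, seed = 13)
  full <- fourier_mask(matrix(TRUE, 32, 32))
  g <- forward_model(f, full)
  res0 <- tv_fista_reconstruct(g, full, lambda = 0, max_outer = 5)
  expect_lt(max(abs(res0$image - f)), 1e-10)
  inst <- small_instance(14, kind = "piecewise_linear", ratio = 0.3)
  res <- tv_fista_reconstruct(inst$g, inst$mask, 3e-3, max_outer = 80,
                              inner_iters = 15, f_ref = inst$f_true)
  expect_true(all(diff(res$trace$cost) <= 1e-12))
  zf_psnr <- psnr(inst$f_true, project_box(forward_adjoint(inst$g, inst$mask)))
  expect_gt(utils::tail(res$trace$psnr, 1), zf_psnr)
})

test_that("solver results print a readable summary", {
  inst <- small_instance(1)
  res <- fbs_reconstruct(inst$g, inst$mask, 1e-3, max_outer = 3,
                         f_ref = inst$f_true)
  expect_output(print(res), "hdtv2-fbs")
  expect_output(print(res), "PSNR")
})

test_that("HDTV2 denoising outperforms TV on gradient-dominated images", {
  # a smooth ramp plus one soft bump: strong gradients, no sharp edges --
  # the regime where first-order TV staircases and second-degree TV should
  # not
  co <- hdtv2:::pixel_coords(64, 64)
  f <- 0.2 + 0.5 * co$x + 0.2 * co$y +
    0.15 * exp(-((co$x - 0.5)^2 + (co$y - 0.4)^2) / 0.02)
  f <- pmin(pmax(f, 0), 1)
  z <- f + hdtv2:::with_seed(3, matrix(rnorm(4096, sd = 0.1), 64, 64))
  best_h <- best_t <- -Inf
  for (a in c(0.1, 0.2, 0.4)) {
    best_h <- max(best_h, psnr(f, prox_hdtv2(z, a, iters = 200)$f))
    best_t <- max(best_t, psnr(f, hdtv2:::tv_prox(z, a, iters = 200)))
  }
  expect_gt(best_h, best_t + 2)  # several-dB margin, not a squeaker
})
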