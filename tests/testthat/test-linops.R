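test_that("second differences of constant and affine images vanish", {
  const <- matrix(0.7, 6, 6)
  for (ap in c("xx", "xy", "yy"))
    expect_equal(second_difference(const, ap), matrix(0, 6, 6))

  ramp <- outer(1:5, 1:5, function(i, j) j)  # affine in x
  d <- second_difference(ramp, "xx")
  # interior columns are exactly affine; only the Neumann truncation at the
  # trailing boundary leaves nonzeros
  expect_true(all(d[, 1:(ncol(ramp) - 2)] == 0))
  expect_true(any(d[, (ncol(ramp) - 1):ncol(ramp)] != 0))
})

test_that("second differences match the dense impulse-built matrix", {
  r <- 8; c <- 8
  u <- random_image(r, c, seed = 11)
  for (ap in c("xx", "xy", "yy")) {
    Mop <- dense_operator_matrix(function(x) second_difference(x, ap), r, c)
    expect_equal(as.numeric(second_difference(u, ap)),
                 as.numeric(Mop %*% as.numeric(u)), tolerance = 1e-12)
    # adjoint equals the explicit transpose, probed by unit impulses
    Madj <- dense_operator_matrix(function(x) second_difference_adjoint(x, ap), r, c)
    expect_equal(Madj, t(Mop), tolerance = 1e-12)
  }
})

test_that("all adjoint pairs satisfy the inner-product identity", {
  for (dims in list(c(4L, 4L), c(5L, 7L), c(32L, 32L))) {
    r <- dims[1]; c <- dims[2]
    for (s in 1:10) {
      u <- random_image(r, c, seed = 100 + s)
      p <- random_image(r, c, seed = 200 + s)
      for (ap in c("xx", "xy", "yy")) {
        lhs <- sum(second_difference(u, ap) * p)
        rhs <- sum(u * second_difference_adjoint(p, ap))
        expect_equal(lhs, rhs, tolerance = 1e-10)
      }
      fld <- random_field(r, c, seed = 300 + s)
      expect_equal(sum(apply_V2(u) * fld),
                   sum(u * apply_V2_adjoint(fld)), tolerance = 1e-10)
      W <- hdtv2_weight_matrix()
      q <- random_field(r, c, seed = 400 + s)
      expect_equal(sum(apply_weighting(fld, W) * q),
                   sum(fld * apply_weighting(q, t(W))), tolerance = 1e-12)
      # sensing operator: real inner product against Re(A^H g)
      mask <- variable_density_mask(r, c, 0.5, seed = s)
      g <- hdtv2:::with_seed(500 + s,
        complex(real = rnorm(sum(mask)), imaginary = rnorm(sum(mask))))
      lhs <- Re(sum(Conj(g) * forward_model(u, mask)))
      rhs <- sum(u * forward_adjoint(g, mask))
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("operators are linear", {
  u <- random_image(6, 5, seed = 1)
  v <- random_image(6, 5, seed = 2)
  for (ap in c("xx", "xy", "yy")) {
    expect_equal(second_difference(2.5 * u - 1.3 * v, ap),
                 2.5 * second_difference(u, ap) - 1.3 * second_difference(v, ap),
                 tolerance = 1e-12)
  }
})

test_that("V2 stacks the component impulse responses", {
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  fld <- apply_V2(imp)
  expect_equal(fld[, , "xx"], second_difference(imp, "xx"))
  expect_equal(fld[, , "xy"], second_difference(imp, "xy"))
  expect_equal(fld[, , "yy"], second_difference(imp, "yy"))
  expect_equal(apply_V2(matrix(1, 4, 4)), hdtv2:::zero_field(4, 4))
})

test_that("weighting by W2 reproduces the closed-form column action", {
  W2 <- hdtv2_weight_matrix()
  fld <- hdtv2:::zero_field(3, 3)
  fld[1, 1, 1] <- 1  # the (1,0,0) per-pixel vector
  out <- apply_weighting(fld, W2)
  expect_equal(out[1, 1, ], c(xx = (sqrt(2) + 1) / 4, xy = 0,
                              yy = (sqrt(2) - 1) / 4), tolerance = 1e-12)
  expect_equal(apply_weighting(fld, diag(3)), fld)
})

test_that("unitary sensing operator behaves as expected", {
  f <- make_phantom("blobs", 32, 32, seed = 3)
  full <- fourier_mask(matrix(TRUE, 32, 32))
  expect_equal(forward_adjoint(forward_model(f, full), full), f,
               tolerance = 1e-12)
  # constant image, DC-only mask -> single measurement c * sqrt(N)
  dc_only <- fourier_mask(matrix(FALSE, 8, 8))
  g <- forward_model(matrix(0.5, 8, 8), dc_only)
  expect_length(g, 1L)
  expect_equal(as.complex(g), 0.5 * sqrt(64) + 0i, tolerance = 1e-12)
})

test_that("mask invariants hold and mismatches error", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  msk <- fourier_mask(m)
  expect_true(msk[1, 1])          # DC forced on
  expect_equal(mask_count(msk), 2L)
  expect_error(forward_adjoint(complex(3), msk), "length")
  expect_error(forward_model(matrix(0, 5, 5), msk), "shapes")
  expect_error(second_difference(matrix(1, 2, 2), "xx"), "3 x 3")
})

test_that("power iteration certifies the operator norm bounds", {
  for (dims in list(c(32L, 32L), c(64L, 64L), c(128L, 96L))) {
    for (ap in c("xx", "xy", "yy")) {
      nrm <- operator_norm_estimate(
        function(x) second_difference(x, ap),
        function(x) second_difference_adjoint(x, ap),
        dims, iters = 200L, seed = 7L)
      expect_lte(nrm, 4 + 1e-8)
      expect_gt(nrm, 3)  # the bound is nearly attained on these grids
    }
    h2 <- operator_norm_estimate(
      function(x) hdtv2:::apply_H2(x),
      function(x) hdtv2:::apply_H2_adjoint(x),
      dims, iters = 200L, seed = 7L)
    expect_lte(h2^2, 24 + 1e-6)
  }
  expect_equal(operator_norm_estimate(identity, identity, c(8L, 8L),
                                      iters = 20L, seed = 1L), 1)
  expect_equal(operator_norm_estimate(function(x) 0 * x, function(x) 0 * x,
                                      c(8L, 8L), iters = 5L, seed = 1L), 0)
  expect_lte(operator_norm_estimate(
    function(x) forward_model(x, variable_density_mask(16, 16, 0.4, seed = 2)),
    function(g) forward_adjoint(g, variable_density_mask(16, 16, 0.4, seed = 2)),
    c(16L, 16L), iters = 100L, seed = 3L), 1 + 1e-10)
})
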