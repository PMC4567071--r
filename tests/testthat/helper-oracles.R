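# Shared oracles and generators for the test suite.

# Assemble the dense matrix of a linear operator on r x c images by probing
# it with unit impulses; the independent oracle for operator/adjoint tests.
dense_operator_matrix <- function(apply_op, r, c) {
  N <- r * c
  cols <- vector("list", N)
  for (j in seq_len(N)) {
    e <- matrix(0, r, c)
    e[j] <- 1
    cols[[j]] <- as.numeric(apply_op(e))
  }
  do.call(cbind, cols)
}

random_image <- function(r, c, seed) {
  hdtv2:::with_seed(seed, matrix(stats::rnorm(r * c), r, c))
}

random_field <- function(r, c, seed) {
  hdtv2:::with_seed(seed, array(stats::rnorm(3 * r * c), dim = c(r, c, 3L),
                                dimnames = list(NULL, NULL, c("xx", "xy", "yy"))))
}

field_norm <- function(f) sqrt(sum(f^2))

# Independent primal oracle for the box-constrained HDTV2 prox: minimize the
# smoothed objective 1/2||f-z||^2 + alpha * sum_i sqrt(||W2 (V2 f)_i||^2 + eps^2)
# with L-BFGS-B (box constraints native), warm-starting through a decreasing
# smoothing schedule. As eps -> 0 the smoothed minimum approaches the true
# one from below within alpha * N * eps, so the final unsmoothed objective is
# accurate to ~1e-6 on 6 x 6 problems.
prox_primal_oracle <- function(z, alpha, bounds = c(0, 1),
                               eps_schedule = c(1e-2, 1e-4, 1e-6, 1e-8)) {
  r <- nrow(z); c <- ncol(z)
  W <- hdtv2_weight_matrix()
  obj_sm <- function(fv, eps) {
    f <- matrix(fv, r, c)
    wf <- hdtv2:::apply_H2(f, W)
    nrm <- sqrt(wf[, , 1]^2 + wf[, , 2]^2 + wf[, , 3]^2 + eps^2)
    0.5 * sum((f - z)^2) + alpha * sum(nrm)
  }
  grad_sm <- function(fv, eps) {
    f <- matrix(fv, r, c)
    wf <- hdtv2:::apply_H2(f, W)
    nrm <- sqrt(wf[, , 1]^2 + wf[, , 2]^2 + wf[, , 3]^2 + eps^2)
    scaled <- wf
    for (k in 1:3) scaled[, , k] <- wf[, , k] / nrm
    as.numeric(f - z + alpha * hdtv2:::apply_H2_adjoint(scaled, W))
  }
  fv <- as.numeric(project_box(z, bounds))
  for (eps in eps_schedule) {
    fit <- stats::optim(fv, fn = obj_sm, gr = grad_sm, eps = eps,
                        method = "L-BFGS-B",
                        lower = bounds[1], upper = bounds[2],
                        control = list(maxit = 2000L, factr = 10))
    fv <- fit$par
  }
  f <- matrix(fv, r, c)
  list(f = f, objective = 0.5 * sum((f - z)^2) +
         alpha * hdtv2_value_weighted(f, W))
}
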