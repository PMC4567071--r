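# hdtv2: second-degree total variation reconstruction from undersampled Fourier data

`hdtv2` reconstructs a real, intensity-bounded image from noisy,
undersampled 2-D Fourier measurements — the compressive-sensing MRI /
microscopy setting — using a **second-degree total variation (HDTV2)**
regularizer. It is written for researchers who want a transparent,
fully-tested reference implementation of higher-degree TV reconstruction
with its convergence machinery exposed: every operator has an exact
adjoint, every bound used by the solver is verified numerically, and the
whole pipeline (sampling → noise → reconstruction → metrics) is seeded and
reproducible.

## The model

The measurement model is `g = A f + e`, with `A = P F` the unitary 2-D DFT
restricted to a sampled frequency set (DC always included) and `e` complex
Gaussian noise. Reconstruction solves

```
min_{f in [a,b]^N}  1/2 ||g - A f||^2  +  lambda * HDTV2(f)
```

where the second-degree total variation is the L1–L2 mixed norm of second
directional derivatives over all orientations,

```
HDTV2(f) = sum_i sqrt( (1/2pi) int_0^2pi |f_theta,2(i)|^2 dtheta )
         = sum_i || W2 (V2 f)_i ||_2 ,
```

with `V2 f = (f_xx, f_xy, f_yy)` the stack of discrete second differences
and `W2 = sqrt(C2)` the spectral square root of the orientation Gram matrix
`C2 = (1/8)[[3,0,1],[0,4,0],[1,0,3]]`. Unlike first-order TV, which favors
piecewise-constant images and produces staircase artifacts in smooth
regions, HDTV2 vanishes on affine patches and favors piecewise-linear
images.

The main solver is **forward–backward splitting**: a gradient step on the
data term alternated with the HDTV2 proximal map, which is itself solved by
Nesterov-accelerated projected ascent on its dual (per-pixel unit-ball
constraints, fixed step `1/(24 alpha)` justified by the verified bound
`||H2||^2 <= 24`). Two baselines ship alongside: an iteratively reweighted
majorization–minimization solver (conjugate-gradient inner solves) for the
same objective, and a first-order TV solver (monotone FISTA with a
dual-projected prox).

## Worked example

```r
library(hdtv2)

# a 64 x 64 piecewise-smooth phantom, 30% variable-density Fourier
# sampling, 30 dB measurement noise — all seeded
inst <- simulate_cs_instance("blobs", 64, 64, ratio = 0.3, snr_db = 30, seed = 5)

zf <- project_box(forward_adjoint(inst$g, inst$mask))   # zero-filled recon
psnr(inst$f_true, zf)
#> [1] 33.34495

res <- fbs_reconstruct(inst$g, inst$mask, lambda = 8e-3, tau = 1,
                       max_outer = 400, inner_iters = 30, warm_start = TRUE,
                       f_ref = inst$f_true)
res
#> <hdtv2_recon: hdtv2-fbs, 64 x 64 image, 96 iterations>
#>   final cost 0.38442, PSNR 38.61 dB

tail(res$trace[, c("cost", "psnr", "fp_residual")], 1)
#>         cost     psnr  fp_residual
#> 96 0.3844201 38.60685 0.0001896584

ssim_global(inst$f_true, res$image)
#> [1] 0.9982568
```

The reconstruction gains several dB over the zero-filled inverse; the trace
records per-iteration cost (non-increasing), PSNR, relative error and the
fixed-point residual `||f_k+1 - f_k||`, which decays to zero as the
iteration approaches a fixed point of the splitting operator.

A command-line front end (`inst/cli/hdtv2.R`) exposes `simulate`,
`denoise`, `reconstruct`, `metrics` and `benchmark` subcommands over the
same functions, and `run_benchmark()` drives the full factorial
phantom × sampling-ratio × method comparison.

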