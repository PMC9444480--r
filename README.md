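# dictSR

Coupled dictionary learning for single-image super-resolution of grayscale
(e.g. magnetic-resonance) images, with a training loss that separates the
high- and low-resolution reconstruction errors.

## The problem

A low-resolution (LR) image `y` is modeled as a degraded high-resolution
(HR) image `x`: `y = L x`, with `L` bicubic downsampling by an integer
factor (×2 or ×4). Patch-based sparse-coding super-resolution assumes each
HR patch admits a sparse representation `x ≈ D_h α` against an overcomplete
dictionary, and that the *same* code `α` can be found from the LR data by
solving the lasso problem

    α = argmin_a ‖F y − D_l a‖₂² + λ‖a‖₁

in a gradient feature space `F` (first- and second-order derivatives of the
bicubic-interpolated LR image). Reconstruction codes every overlapping
patch against `D_l`, maps the codes through `D_h`, overlap-averages the
patches, and enforces the global reconstruction constraint `L x̂ ≈ y` by
iterative back-projection.

The classical way to obtain the coupled pair `(D_h, D_l)` is *cascade*
training: stack each HR patch over its LR feature vector, weighted by the
reciprocal dimensions `1/N` and `1/M`, and learn a single dictionary for
the stacked samples

    min_{D_c, α} ‖X_c − D_c α‖₂² + λ(1/N + 1/M)‖α‖₁ ,
    X_c = [X_h / N ; Y_l / M] .

The cascade controls only the *summed* stacked error: nothing guarantees
that the HR part reconstructs the HR patches well from codes computed on
LR data. This package additionally implements the loss-optimized
refinement that targets exactly that gap. With codes defined by the LR
lasso problem, the separated-error joint loss

    L(D_h, D_l) = mean_i ½ [ γ‖D_h c_i − x_i‖² + (1−γ)‖D_l c_i − y_i‖² ],
    c_i = argmin_a ‖y_i − D_l a‖² + λ‖a‖₁,   0 < γ ≤ 1,

is minimized by alternating (1) a closed-form constrained least-squares
update of `D_h` (codes fixed) and (2) projected gradient steps on `D_l`,
where `∂L/∂D_l` is obtained by implicit differentiation of the lasso
stationarity conditions on each sample's active set — a bilevel
optimization, since the codes themselves depend on `D_l`.

On generative synthetic data the refinement roughly halves the HR residual
`R_x` of the cascade fit, and end-to-end it beats bicubic interpolation on
every seeded phantom (about +1.2 dB PSNR at ×2 under the tuned regime:
dictionary size 512, λ = 0.1, 5×5 patches with overlap 4 at ×2, 10×10 with
overlap 9 at ×4, 150 000 training patches; the examples below use reduced
sizes that run in seconds).

## Worked example

```r
library(dictSR)

# two seeded phantoms as HR training material
train_imgs <- lapply(1:2, function(i) make_phantom(phantom_spec(96, "mixed", seed = i)))
pairs <- sample_training_pairs(train_imgs, scale = 2, patch_size = 5,
                               n_samples = 4000, seed = 10)
fit <- sr_train(pairs, method = "loss_optimized", K = 64, lambda = 0.1,
                cascade_iter = 15, outer_iter = 4, lr_steps = 3, seed = 10)
print(fit)
#> Coupled dictionary (loss_optimized)
#>   atoms: 64   HR dim: 25   LR dim: 100
#>   scale: x2   patch: 5x5   overlap: 4
#>   lambda: 0.1   gamma: 0.7
#>   trace: 5 recorded iterations (final loss 0.00937015)

hr  <- make_phantom(phantom_spec(96, "mixed", seed = 99))
lr  <- degrade(hr, 2)                 # simulate LR acquisition
res <- predict(fit, lr)               # super-resolve back to 96x96
print(res)
#> <sr_result> 96x96 reconstruction (x2, patch 5, overlap 4, lambda 0.1)
#>   dictionary: loss_optimized;  mean code sparsity: 9.60;  backprojection: 20 accepted steps

evaluate_pair(hr, upscale_bicubic(lr, 2))   # bicubic: PSNR 32.81, SSIM 0.9444
evaluate_pair(hr, res)                      # dictSR : PSNR 33.47, SSIM 0.9548
```

The final loss in the printout is the separated-error joint loss `L`; the
trace (`fit$trace`) records `L`, `R_x`, `R_y`, the mean code sparsity and
the accepted step size per outer iteration, and is non-increasing by
construction. `fit$cascade_init` holds the cascade fit the refinement
started from, so the HR-residual improvement is directly inspectable:

```r
joint_loss(fit$cascade_init, pairs, gamma = 0.7, lambda = 0.1)$R_x  # cascade
joint_loss(fit,              pairs, gamma = 0.7, lambda = 0.1)$R_x  # refined
```

A command-line interface wrapping the same functions lives at
`inst/cli/dictSR` (`train`, `super-resolve`, `evaluate`, `sweep`,
`simulate`).

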