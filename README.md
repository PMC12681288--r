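# unrolledmri

Memory-efficient unrolled neural networks for the reconstruction of
undersampled 3D Dixon MRI, in pure R (+ Rcpp kernels).

## Who this is for

Quantitative muscle MRI tracks neuromuscular disease through the Dixon fat
fraction FF = F/(W+F) of individual thigh muscles. Accelerating the 3D
gradient-echo acquisition by undersampling k-space aliases the images;
unrolled networks remove the aliasing while keeping the FF biomarker
trustworthy. This package implements four such networks — VarNet, DIRCN and
their Half U-Net simplifications HalfVarNet and HalfDIRCN — plus the entire
surrounding pipeline: centered orthonormal FFT operators, variable-density
Poisson-disc sampling masks, three-point Dixon fat–water separation,
reconstruction / FF / segmentation-agreement metrics with Bland–Altman
analysis, a synthetic thigh phantom generator (so everything is testable
with no data download), a CPU training loop with a built-in reverse-mode
autodiff engine, and a deterministic parameter/FLOP complexity audit.

## The model

Each cascade `it` of an unrolled network performs one learned gradient step
on the compressed-sensing objective
`argmin_k ||k_us - D k||^2 + lambda R(F^H k)`:

    k^{it+1} = k^{it} - mu_it * D (k^{it} - k_us) + F Net(F^H k^{it})

where `D` is the binary phase-encode-plane mask, `F` the unitary FFT,
`mu_it` a learned scalar and `Net` a 3D U-Net (VarNet/DIRCN) or 3D Half
U-Net (HalfVarNet/HalfDIRCN) acting on two-channel (real/imaginary) images.
DIRCN variants add dense input connections (cascade `it` sees all previous
image iterates) and decoder interconnections. The Half U-Net keeps a
constant channel width and replaces the decoder by upsampling + summation,
cutting FLOPs ~2.7x and parameters ~74x per regularizer.

## Worked example

```r
library(unrolledmri)

# a 32x32x8 synthetic thigh with 10 muscles, 2% noise, 50 Hz B0
spec <- phantom_spec(matrix = c(32, 32, 8), seed = 7)
ph   <- make_thigh_phantom(spec)
acq  <- acquisition_spec(matrix = c(32, 32, 8))
st   <- simulate_dixon_echoes(ph$water, ph$fat, spec = spec, acq = acq)

# retrospective 4x variable-density Poisson-disc undersampling
mask <- generate_vd_poisson_mask(32, 8, accel = 4, seed = 0)
mask$accel_empirical
#> [1] 4

# zero-filled baseline vs fully sampled reference FF in one muscle
fg    <- background_mask(Mod(st$echoes[[1]]))
rec   <- lapply(st$echoes[1:3], function(e)
           ifft3c(apply_mask_zero_fill(fft3c(e), mask)))
ff_zf <- three_point_dixon(echo_stack(rec, st$TE_list[1:3]), foreground = fg)
ff_ref<- three_point_dixon(echo_stack(st$echoes[1:3], st$TE_list[1:3]),
                           foreground = fg)
roi_mean_ff(ff_ref, ph$labels, 10); roi_mean_ff(ff_zf, ph$labels, 10)
#> [1] 83.09003
#> [1] 78.3464   # zero filling biases the most infiltrated muscle by ~4.7 FF points

# complexity audit of the reference architectures (128x128x36 input)
complexity_audit(list(network_config("varnet", 8),
                      network_config("halfvarnet", 8)))
#>      variant cascades parameters   gflops checkpoint_mb
#> 1     varnet        8  180609816 3211.118    2167.31779
#> 2 halfvarnet        8    2450456 1173.463      29.40547
```

The audit reproduces the reference complexity figures: one 3D U-Net costs
401.39 GFLOPs (2D analogue 6.86), one 3D Half U-Net 146.68; 8-cascade
VarNet/HalfVarNet/DIRCN/HalfDIRCN have 180.6M / 2.45M / 197.1M / 2.69M
parameters. Training a 2-cascade HalfVarNet on twenty 32x32x8 phantoms at
R=4 takes a few minutes on one CPU and beats the zero-filled baseline on
FF-map SSIM and MSE on every held-out volume (see
`tests/testthat/test-acceptance.R`).

## Command line

```sh
exec/unrolledmri mask --ny 128 --nz 36 --accel 4 --center-frac 0.04 --seed 0 --out mask.tsv
exec/unrolledmri audit --shape 128,128,36 --out audit.tsv
exec/unrolledmri simulate --accel 4 --seed 0 --out data.h5
exec/unrolledmri ff --echoes data.h5 --out ff.nii.gz --rois data_labels.nii.gz --report ff.tsv
exec/unrolledmri reconstruct --ckpt ckpt.rds --in data.h5 --out recon.h5
```

K-space containers are HDF5 (h5py-compatible complex64), FF and label maps
are NIfTI-1 (`.nii` / `.nii.gz`), configs are JSON. See
`vignettes/unrolled-dixon-reconstruction.Rmd` for the science, conventions
and design decisions.
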