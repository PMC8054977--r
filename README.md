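# sdrsim

Super-resolution image reconstruction for linear structured illumination
microscopy (SIM), performed **directly in the spatial domain** — for
microscopists and methods developers who want a fast, transparent, fully
testable alternative to the classical frequency-domain pipeline, plus the
simulation and metrology tools to validate it without a microscope.

## The method

A linear SIM acquisition records nine raw frames
`D_j = (O · I_j) ∗ H` — the object `O` under a shifted sinusoidal excitation
`I_j(r) = I0 [1 + m cos(2π k0·r + φ0 − ψ_j)]`, blurred by the detection PSF
`H` (three phase steps `ψ_j ∈ {0, −2π/3, +2π/3}` × three orientations).

The spatial-domain reconstruction (SDR) forms the SR image without a single
forward Fourier transform. Each frame is multiplied by an analytic raised
cosine coefficient field

```
c_j(r) = (1 / 3 I0) · [1 + (2/m) cos(2π k0·r + φ0 − ψ_j)],
```

and the nine products are summed. The weights are constructed so that the
superposition equals the object imaged through the *compressed* effective PSF

```
P(x) = [1 + cos(2π k0·x)] · H(x),
```

whose FWHM drops from 200 nm (the widefield limit) to ≈ 90 nm at the
diffraction-limited pattern period. One Wiener deconvolution with `P`
finishes the job: multiplication, summation, deconvolution — nothing else.
(The factor is `2/m`, not `2m`: only the reciprocal satisfies the defining
superposition identity for `m ≠ 1`; see the vignette.)

The package also provides:

* `fdr_reconstruct()` — the classical frequency-domain pipeline (band
  separation, spectrum shifting, generalized Wiener recombination) as the
  in-package reference for equivalence checks;
* a seeded forward simulator (`make_bead_field()`, `make_two_point()`,
  `make_bar_target()`, `make_uniform_field()`, `simulate_sim_stack()`) with
  Poisson + read noise;
* resolution metrology (`bead_fwhm_report()`, `two_point_dip()`,
  `image_similarity()`, `psf_fwhm_curve()`);
* TIFF + JSON-sidecar I/O and a CLI (`inst/cli/sdrsim.R`) with
  `simulate`, `reconstruct`, `psf-analyze`, `calibrate` and `bench`
  subcommands.

## Worked example

Simulate a 20-bead field under default conditions (200 nm PSF, 32.5 nm
pixels, 220 nm patterns at 0°/60°/120°, m = 0.9), reconstruct, and calibrate:

```r
library(sdrsim)

g     <- grid2d(512, 512, 32.5)
psf   <- gaussian_psf(200)
pats  <- default_patterns(g)
beads <- make_bead_field(g, 20, min_separation_nm = 700, seed = 11,
                         margin_nm = 700)
stack <- simulate_sim_stack(beads, pats, psf)

sdr <- sdr_reconstruct(stack, wiener_w = 0.05)
wf  <- widefield_reconstruct(stack)

ctrs <- data.frame(x_nm = beads$truth$x_nm, y_nm = beads$truth$y_nm)
glance(bead_fwhm_report(wf$sr_image, g, ctrs))
#> # A tibble: 1 × 4
#>   n_beads mean_fwhm_nm sd_fwhm_nm n_excluded
#>     <int>        <dbl>      <dbl>      <int>
#> 1      20         206.      0.270          0
glance(bead_fwhm_report(sdr$sr_image, g, ctrs))
#> # A tibble: 1 × 4
#>   n_beads mean_fwhm_nm sd_fwhm_nm n_excluded
#>     <int>        <dbl>      <dbl>      <int>
#> 1      20         96.0      0.212          0
```

The fitted bead FWHM falls from ≈ 206 nm (widefield; 204 nm expected for
40 nm beads through a 200 nm PSF, plus ~2 nm interpolation bias) to ≈ 96 nm —
a resolution ratio of 0.465. A 130 nm two-point target shows dip contrast 0
in widefield (unresolved) and ≈ 0.49 after SDR:

```r
tp   <- make_two_point(g, 130, 0)
stk2 <- simulate_sim_stack(tp, pats, psf)
ctr  <- data.frame(x_nm = tp$truth$x_nm, y_nm = tp$truth$y_nm)
two_point_dip(widefield_reconstruct(stk2)$sr_image, g, ctr)   # 0
two_point_dip(sdr_reconstruct(stk2)$sr_image, g, ctr)         # 0.485
```

`autoplot(sdr)` renders the SR image; `autoplot(psf_fwhm_curve(psf,
seq(200, 1000, 50)))` draws the effective-PSF FWHM versus pattern period.

From the shell:

```sh
Rscript inst/cli/sdrsim.R simulate --scene beads --seed 11 --out stack.tif
Rscript inst/cli/sdrsim.R reconstruct --method sdr --in stack.tif --out sr.tif
Rscript inst/cli/sdrsim.R calibrate --image sr.tif --truth stack_truth.json --out report.csv
```

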