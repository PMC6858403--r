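# srtrack

Variational tracking of moving objects in grayscale medical video —
surgical instruments, the operating field, or a cardiac structure in cine
MRI — for researchers who need a transparent, fully scriptable reference
tracker with ground-truthed synthetic benchmarks rather than a black-box
deep model.

The pipeline has four stages, run per frame:

1. **Stochastic-resonance denoising in the MODWT domain.** Each frame is
   decomposed by the undecimated 2-D maximal-overlap discrete wavelet
   transform; every coefficient grid drives the discrete bistable
   double-well iteration

   x(n+1) = x(n) + Δt [ (a·x(n) − e·x(n)³) + Input(n) ],  x(0) = 0,

   with a = w·2σ₀², e = z·√(4a³/27), z < 1. The tuned coefficients are
   reconstructed by the inverse transform. The distribution separation
   measure DSM = |μ_T^E − μ_B^E| − |μ_T^O − μ_B^O| scores the enhancement
   and selects the stopping iteration.

2. **Region modeling.** The target is a level set φ (φ ≥ 0 inside); r-bin
   intensity histograms of the foreground (fd) and of the background band
   −th < φ < 0 (bd) are built on the first frame.

3. **Affine registration.** Inter-frame motion is a 6-parameter warp
   x′ = (1+p₁)x + p₃y + p₅, y′ = p₂x + (1+p₄)y + p₆, estimated by
   maximizing the Bhattacharyya matching energy
   En₁ = Σ_fs ( √(fg·fd) + γ·√(bg·bd) ) of the warped candidate region.

4. **Level-set refinement.** The registered contour evolves under a
   combined local/global region energy (windowed Chan–Vese-style means
   c₁, c₂ and difference-image means d₁, d₂, both normalized by their
   squares), a length penalty μ and area penalty ν, plus the per-pixel
   Bhattacharyya weights h_f = √(fd_b(x)/fg_b(x)), h_b = √(bd_b(x)/bg_b(x)).

A synthetic sequence generator with exact ground-truth masks and the
standard overlap metrics (OI = Jaccard × 100, Dice = 2|X∩Y|/(|X|+|Y|))
close the loop for benchmarking.

## Worked example

```r
library(srtrack)

spec <- sequence_spec(size = c(64, 64), shape = "square", center = c(18, 32),
                      radius = 8, vx = 1.4, noise_sigma = 0.05,
                      n_frames = 10, seed = 42)
seq <- make_sequence(spec)
res <- track_sequence(seq$frames, seq$masks[[1]], tracker_config())
print(res)
#> track result: 10 frame(s), config fef78a21

oi <- mapply(overlap_index, res$masks, seq$masks)
dc <- mapply(dice, res$masks, seq$masks)
cat(sprintf("mean OI = %.1f%%, mean Dice = %.3f\n", mean(oi), mean(dc)))
#> mean OI = 97.1%, mean Dice = 0.985

round(res$poses[2:4, ], 3)
#>          p1     p2     p3     p4    p5     p6
#> [1,]  0.001 -0.008  0.004 -0.025 0.841  1.136
#> [2,] -0.058  0.000 -0.002  0.010 2.521 -0.198
#> [3,]  0.000  0.000  0.000  0.000 1.862 -0.155
```

The mean overlap index (97.1%) and Dice (0.985) compare each emitted mask
with the exact rasterized ground truth; the pose rows show the per-frame
affine estimates — the p₅ column tracks the ~1.4 px/frame horizontal
motion while the linear terms p₁..p₄ stay near zero (rigid translation).

Denoising pieces can be used stand-alone:

```r
bistable_params(0.5)
#> bistable params: a = 0.5, e = 3.67423e-06 (sigma0 = 0.5, w = 1,
#>   z = 2.7e-05, dt = 0.007, n_iter = 200)
estimate_sigma0(seq$frames[[1]])
#> [1] 0.0513      # true noise level: 0.05
```

## Command-line use

`inst/scripts/srtrack` drives the pipeline over directories of ASCII PGM
(P2) frames, with JSON configs:

```sh
srtrack synth   --spec spec.json --out seq/
srtrack denoise --in frames/ --out den/ --iters 200
srtrack segment --in img.pgm --init-mask m.pgm --out out.pgm
srtrack track   --frames frames/ --init-mask m.pgm --out-dir pred/
srtrack score   --pred pred/ --gt gt/ --out scores.csv
```

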