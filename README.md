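# impulsets

Estimation of **impulsive time series**: signals produced by a cascade of
two first-order eliminations driven by a sparse train of instantaneous
secretion impulses, observed only through sampled, noisy concentration
measurements. The motivating application is pulsatile hormone data —
luteinizing hormone (LH) driven by unmeasurable GnRH bursts, or cortisol
driven by ACTH — where both the secretion events *and* the elimination
rates of the two hormones must be recovered from a single record.

## The problem and the method

The observed concentration follows

```
y(t) = x2(t1) e^{-b2 (t - t1)} + Σ_n d_n z(b1, b2, t - τ_n),
z(b1, b2, t) = (e^{-b2 t} - e^{-b1 t}) / (b1 - b2) · H(t),
```

with elimination rates `b1` (upstream, e.g. GnRH) and `b2` (observed,
e.g. LH) in 1/min, impulse times `τ_n` (min) and weights `d_n`
(concentration units, gain-normalised). Joint estimation is ill-posed:
fast rates with one impulse per sample fit anything, and under noise many
`(b1, b2)` pairs along a curve fit almost equally well.

The package provides two estimators and tools to compare them:

* **A non-negative least-squares curve estimator.** For fixed rates, the
  impulses solve an NNLS problem with one candidate impulse per sampling
  time; the residual `g(b1, b2)` is approximately quadratic in `b2` below
  the boundary `γ_P` of the perfect-fit region, and the vertex of that
  quadratic is recovered — without evaluating near it — via the
  Newton-step functional `N_g = -g / (∂g/∂b2)`: its minimiser plus its
  minimum is the boundary point (`estimate_gamma_curve()`). Impulse
  estimates along the curve are sparsified by thresholding, constrained
  refitting and exact moment-matched merging.
* **An adaptive Metropolis sampler** of the joint posterior over impulse
  times, weights and rates (Gaussian likelihood, uniform priors,
  over-parameterised impulse count with merge/drop post-processing,
  Gelman–Rubin convergence gating), plus diagnostics that measure the
  signed perpendicular distance of each posterior sample to the estimated
  curve (`curve_distance_stats()`).
* **A seeded synthetic-data generator** with LH-like and cortisol-like
  presets standing in for restricted clinical data.

## Worked example

```r
library(impulsets)

# LH-like record: 10-min sampling over 18 h, 3 secretion impulses
ds <- generate_dataset(generator_config("lh_like", n_impulses = 3, seed = 7))
ds
#> Synthetic impulsive dataset (lh_like preset, seed 7)
#>   3 impulses, (b1*, b2*) = (0.46, 0.011), noise sd 0.02
#> Sampled series: K = 109 samples over [0, 1080] min
#>   concentration range [-0.02776, 2.383]

cur <- estimate_gamma_curve(ds$series, default_curve_config(ds$series, n_b1 = 12))
cur
#> Estimated feasibility-boundary curve: 12 points, b1 in [0.23, 0.69]
#>   b2_hat in [0.01087, 0.01137]; impulse counts 3-3; 0 discontinuities

i <- which.min(abs(cur$points$b1 - 0.46))
cur$points[i, ]
#>          b1   b2_tilde     b2_hat   residual n_impulses discontinuity
#> 6 0.4390909 0.01025775 0.01093436 0.03662577          3         FALSE

cur$impulses[[i]]        # estimated impulses at that curve point
#> Impulse train: 3 impulses
#>  time_min    weight
#>       300 0.4453438
#>       460 0.6151296
#>       920 1.1332416

ds$impulses              # ground truth
#> Impulse train: 3 impulses
#>  time_min    weight
#>       300 0.4697487
#>       460 0.6437494
#>       920 1.1920104

check_rate_bounds(cur$points$b1[i], cur$points$b2_hat[i])
#>   b1: inside theoretical range [0.23, 0.69] (signed margin -0.2091)
#>   b2: inside theoretical range [0.0087, 0.014] (signed margin -0.002234)
```

The curve estimate `b2_hat ≈ 0.0109/min` (observed-hormone half-life
63.4 min) tracks the generating `b2* = 0.011` to about 1%, every curve
point carries exactly the three generating impulses, and the recovered
rates fall inside the biochemically established boxes. The curve rather
than a single `(b1, b2)` point is the honest estimand: points along it
fit the data nearly equally well, and the sampler's posterior cloud
concentrates along the same ridge.

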