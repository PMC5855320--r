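# nucdyn

Quantifying the nuclear dynamics of DNA-binding transcription factors
from live fluorescence microscopy.

Transcription factors inside a nucleus split into a freely diffusing
pool and a chromatin-bound pool, and the two exchange on timescales from
tenths of a second to minutes. `nucdyn` implements the two complementary
measurements that resolve this partition, together with the synthetic
data needed to validate them end to end:

- **FRAP (fluorescence recovery after photobleaching).** After a bleach
  pulse, the recovery of the double-normalized signal

  `value_t = (T_pre − BG)(B_t − BG) / ((T_t − BG)(B_pre − BG))`

  is fitted with a spatially resolved reaction-diffusion model on the
  nucleus mask,

  `∂F/∂t = D ∇²F − k1(x) F + koff C`,  `∂C/∂t = k1(x) F − koff C`,

  where the local binding rate follows from the steady-state image under
  the equilibrium assumption, `k1 = (koff/Free)(i_st/i_avg_st − Free)`.
  A grid search over residence time (`1/koff`) and bound fraction
  (which sets `Free = 1 − bound/100`), fitted simultaneously at the
  bleach spot and at the opposite end of the nucleus and summed over
  replicates, yields the best-fit cell and all parameter combinations
  within 1% of its error.

- **Single-molecule tracking (SMT).** Sparse photoconverted molecules
  are detected per frame with an à-trous B3-spline wavelet transform,
  linked into strictly gap-free tracks by optimal assignment, and their
  displacements fitted with a variational-Bayes hidden Markov model:
  each diffusive state k emits isotropic Gaussian displacements with
  per-axis variance `2 D_k dt + 2 σ_loc²`, states switch with a
  transition matrix `A`, and the evidence lower bound selects the number
  of states. Mean dwell times follow as `τ_k = dt/(1 − A_kk)`.

Smaller quantifications round out the toolkit: band/control intensity
ratios, min-max-normalized locus-aligned enrichment profiles,
ATAC-qPCR fold enrichment (`2^[(ΔCp_test) − (ΔCp_negative)]`) and
ΔΔCt relative expression.

Every estimator can be exercised against the package's own synthetic
microscopy: nucleus masks, equilibrium intensity maps, bleach geometries
and full FRAP movies; multi-state trajectories with confinement,
spatial discretization and localization error; and camera frames with a
Gaussian PSF, motion blur, Poisson shot noise and Gaussian readout
noise.

## Worked example

Simulate three replicate FRAP movies of a transiently binding factor
(30% bound, 1 s residence, D = 2.2 µm²/s), then refit residence time
and bound fraction from the movies alone:

```r
library(nucdyn)

bench <- frap_benchmark_binding(seed = 1, bound_fraction = 30,
                                residence_s = 1)
glance(bench$fit)
#> # A tibble: 1 × 8
#>   model              D_fixed D_best residence_s bound_pct        mse n_region n_experiments
#>   <chr>                <dbl>  <dbl>       <dbl>     <dbl>      <dbl>    <int>         <int>
#> 1 reaction-diffusion     2.2    2.2       0.750        35 0.00000999        1             3
```

The best-fit cell sits one grid step from the generating parameters on
both axes (the residence grid is log-spaced, so 0.75 s neighbours 1 s);
`autoplot(bench$fit)` draws the error surface with the ≤1% region — the
elongated valley shows the residence/bound trade-off inherent to FRAP.

The four-state single-molecule benchmark simulates 20,000 tracks from
the canonical model (D = 0.09/0.22/0.50/1.89 µm²/s) and refits them:

```r
bench <- smt_benchmark_four_state(seed = 1)
bench$states
#> # A tibble: 4 × 5
#>   state D_um2_s occupancy  tau_s self_transition
#>   <int>   <dbl>     <dbl>  <dbl>           <dbl>
#> 1     1  0.0736     0.173 0.0852           0.883
#> 2     2  0.212      0.286 0.119            0.916
#> 3     3  0.487      0.332 0.160            0.938
#> 4     4  1.89       0.209 0.131            0.924
```

State 1 is the specifically DNA-bound population (D ≈ 0.07–0.09 µm²/s)
and state 4 the freely diffusing one. The fast-state quantities land on
the generating values (21%, 1.89 µm²/s); the slow state runs a few
percent low because the 33 nm localization noise makes successive
displacements of bound molecules anticorrelated, a violation of the
independent-step emission model that the methods vignette discusses.

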