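# lowvoltcount

Electron counting and detector characterization for low-acceleration-voltage
cryo-EM movies, in R.

Direct-detection cameras record cryo-EM movies fast enough that individual
electrons appear as isolated groups of charged pixels ("clusters") in each
raw frame. Counting replaces every cluster with a normalized representation
— a sub-pixel point or a unit-sum pattern — so that each electron
contributes exactly one count to the image. At 120–200 kV this matters more
than at 300 kV: slower electrons scatter laterally and backscatter inside
the sensor, producing large, asymmetric clusters whose centre of mass is a
poor estimate of the true impact position, which degrades the detector's
DQE exactly where the dose-starved low-voltage imaging needs it most.

`lowvoltcount` is for detector physicists and cryo-EM methods developers
who want to prototype and evaluate counting strategies without microscope
time. It provides:

- **Cluster detection** — negated Laplacian-of-Gaussian filtering, robust
  (MAD-based) thresholding, connected-component labelling with selectable
  4/8 connectivity, and size classification (small = 1–2 px, medium =
  3–4 px, large = ≥ 5 px).
- **Counting filters** — mass centre (MCF), peak value (PVF), geometric
  centre (GCF), pattern counting (PCA) with an adjustable `pow` exponent
  (`pattern_i = v_i^pow / Σ v_j^pow`; `pow = 0` is a uniform footprint),
  an SNR-weighted point filter (WPF), and a Hybrid route (MCF for
  small/medium clusters, uniform patterns for large ones). Native or
  super-resolution rendering.
- **Frequency-resolved metrics** — Fourier ring correlation, the
  conversion `SNR = 2·FSC / (1 − FSC)`, noise power spectra, slanted
  knife-edge MTF, DQE, and linear SNR-gain fits. The per-shell weight that
  maximizes the SNR of a two-class sum is
  `w = sqrt(SNR₂/SNR₁) · sqrt(NPS₁/NPS₂)`.
- **Optics calculators** — relativistic wavelength and β², the chromatic
  (temporal-coherence) envelope `E(u) = exp(−0.5 (πλδ)² u⁴)` with
  `δ = Cc · sqrt(4(ΔI/I)² + (ΔE/V)² + (ΔV/V)²)`, SNR/FSC depression
  between voltages, radiation-damage regression `y = a + b/β²`, and the
  information coefficient `IFC = T · σe/σi`.
- **Backscatter Monte Carlo** — screened-Rutherford single scattering with
  Bethe (Berger–Seltzer) continuous slowing down in a silicon slab,
  implemented in C++ with per-electron RNG substreams; reports
  backscatter/transmission/absorption counts and exit-radius
  distributions.
- **A synthetic frame generator** — Poisson electron arrivals,
  integrated-Gaussian charge clouds with a heavy-tailed amplitude spread,
  optional displaced backscatter blobs, read noise, gain, ground-truth
  positions, knife-edge fixtures, and per-voltage presets tuned to
  measured cluster-size statistics — so the whole pipeline is testable
  with no real data.

## Worked example

The demo pipeline simulates a 120-kV-like movie (96 × 96 px, 40 frames,
backscatter enabled), counts it with every filter, and scores each result
against the generator's ground truth:

```r
library(lowvoltcount)
rep <- run_demo(seed = 1)
print(rep)
#> counting demo (preset 120kv, seed 1):
#>   method n_events  rmse rmse_small rmse_medium rmse_large match_rate
#> 1    MCF     3030 0.584      0.240       0.538      0.843      0.920
#> 2    PVF     3030 0.516      0.408       0.502      0.628      0.910
#> 3    GCF     3030 0.670      0.309       0.622      0.952      0.921
#> 4    PCA     3030 0.584      0.240       0.538      0.843      0.920
#> 5 Hybrid     3030 0.584      0.240       0.538      0.843      0.920
#> 6    WPF     3030 0.499      0.240       0.538      0.628      0.912
```

Reading the table: `rmse_*` are position errors in pixels against the true
impact positions, split by cluster size class; `match_rate` is the
fraction of true electrons recovered. The orderings are the point of the
exercise: the peak-value rule localizes corrupted **large** clusters much
better than the mass centre (0.628 vs 0.843 px) because the backscatter
blob drags the centroid but not the peak, while the mass centre wins on
compact **small** clusters (0.240 vs 0.408 px) where sub-pixel
interpolation is reliable. WPF and Hybrid route each class to its better
estimator. (PCA and Hybrid record centroid positions for scoring; their
real advantage — spreading each large cluster's count over its footprint,
which suppresses high-frequency noise — shows up in half-set FRC
comparisons, see the vignette.)

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/lowvolt-count.R simulate --preset 120kv --frames 40 \
    --dose 0.01 --seed 1 --out stack.mrcs --truth truth.json
Rscript inst/cli/lowvolt-count.R count --in stack.mrcs --method hybrid \
    --sr 2 --out counted.mrc --events counted.evt
Rscript inst/cli/lowvolt-count.R bse --kv 120 --thickness-um 40 \
    --n 10000 --runs 5 --seed 7 --out bse.json
```

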