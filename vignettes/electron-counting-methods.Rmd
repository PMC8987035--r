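---
title: "Electron counting for low-voltage DDD movies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron counting for low-voltage DDD movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lowvoltcount)
```

This vignette is the package's own account of the science it implements:
the detection and counting models, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

A monolithic direct-detection camera (DDD) records movies fast enough that
single electrons arrive sparsely. Each electron deposits charge in a small
connected group of pixels — a *cluster*. Counting replaces the cluster
with a normalized representation so every electron contributes exactly one
count. At low acceleration voltage (120–200 kV) electrons scatter more
inside the sensor and backscatter off the substrate more often (a
backscattered electron re-exits the entrance surface and deposits a
second, displaced patch of charge). Clusters therefore grow and become
asymmetric, the centre of mass drifts away from the true impact point, and
the detector's high-frequency DQE collapses — precisely where dose-starved
low-voltage imaging needs signal most. The package implements counting
strategies that mitigate this, plus the metrology to quantify them.

## Coordinate conventions

Pixel indices are 0-based. A pixel's **centre** sits at integer
coordinates; its footprint is $[i-0.5, i+0.5)$. The synthetic generator
integrates charge clouds over these footprints, and all position
estimators are plain value-weighted arithmetic on pixel indices, so an
electron at an integer position yields a symmetric cluster whose centroid
is exactly that integer.

Rendering uses the fixed mapping $j = \lfloor x \cdot s \rfloor$ from a
continuous position $x$ to a sub-pixel of the $s\times$ super-resolution
grid. Relative to the centre convention this mapping carries a uniform
half-sub-pixel offset; because it is applied identically to every image
(counted images, ground-truth references, half-set splits), it cancels in
every difference-based metric (FRC, RMSE, block aggregation). We preferred
keeping the simple floor mapping over shifting every rendered grid by half
a sub-pixel.

## Cluster detection

The detector runs four steps per frame:

1. Convolve with a **negated Laplacian-of-Gaussian** kernel (default
   $\sigma = 0.8$ px, radius 1, i.e. $3\times3$), sampled at integer
   offsets and shifted to zero sum. The zero-sum shift makes the response
   to any constant background exactly zero; the negation makes bright
   blobs respond positively. A $3\times3$ kernel matches the
   single-pixel-scale of primary charge clouds; both parameters are
   configurable.
2. Estimate the noise scale of the filtered frame robustly as
   $1.4826 \cdot \mathrm{MAD}$, floored at `min_sigma` (default **1
   detector count**, the quantization scale of any real readout). The
   floor matters only for idealized noiseless input, where the MAD of a
   sparse frame is zero; without it the threshold would collapse and mark
   arbitrarily faint charge tails.
3. Mark pixels whose filtered value exceeds `threshold_k` (default 4)
   times that scale. Thresholding the *filtered* frame, not the raw one,
   is deliberate: the kernel exists to suppress uncorrelated readout noise
   and flatten background before the decision.
4. Group marked pixels into connected components (default 8-connectivity —
   diagonal charge sharing is physical) and keep each interior component
   as one cluster. Components touching the frame border are discarded:
   a truncated footprint biases every position estimator. Cluster pixel
   values are raw values minus the frame median, floored at $10^{-6}$ so
   that negative `pow` exponents in pattern counting stay defined.

Clusters are classed **small** (1–2 px), **medium** (3–4 px), **large**
(≥ 5 px), the empirical break between well-localized and
backscatter-corrupted events.

Two electrons landing adjacently in one frame merge into one cluster; no
de-coincidence is attempted (no counting camera resolves it at finite dose
rate). Closed-loop tests therefore score recall on *isolated* events, and
the generator warns when more than 20 % of events overlap within 2 px.

## Counting filters

- **MCF** — value-weighted centroid; sub-pixel accurate for compact,
  symmetric clusters.
- **PVF** — maximum-value pixel. Ties are broken by distance to the
  centroid, then lexicographically by $(y, x)$; the tie rule is our
  choice, made deterministic so counting is reproducible.
- **GCF** — unweighted mean of pixel coordinates.
- **PCA** — the whole cluster becomes a unit-sum pattern,
  $p_i = v_i^{pow} / \sum_j v_j^{pow}$. `pow = 0` spreads the count
  uniformly over the footprint; large `pow` approaches PVF. Defaults:
  `pow = 1` for small/medium, `pow = 0` for large clusters. Patterns are
  deposited at native granularity (in the central sub-pixel of each
  aligned block when super-resolution is on): sub-pixel pattern placement
  is not defined by the method.
- **WPF** — MCF points for small/medium, PVF points for large (flagged
  with a single *weight bit* in the event stream), then the large-cluster
  partial image is multiplied in Fourier space by the radial profile
  $w(u) = \sqrt{SNR_2/SNR_1}\,\sqrt{NPS_1/NPS_2}$ before summation.
  $w(0)$ is forced to 1 so the total dose is conserved; the profile is
  frequency-resolved, with a flat profile as the scalar fallback.
- **Hybrid** — MCF for small/medium, uniform (`pow = 0`) patterns for
  large; no explicit SNR weighting. The uniform pattern acts as a
  *natural* per-event weight: a large cluster's count is spread over its
  own footprint, which damps exactly the high-frequency components where
  its position information is unreliable.

Every method normalizes each electron's total contribution to 1, so the
unweighted counted image sums to the event count — asserted for all
methods in the test suite.

Why pattern counting helps is worth spelling out: a per-shell *normalized*
correlation is blind to radial amplitude damping, so depositing patterns
cannot improve the correlation of one image against ground truth. What it
improves is the **half-set** correlation: the damping suppresses the noise
power contributed by badly-localized large clusters while the
well-localized small/medium points keep full amplitude, so the FSC between
two half-sets — the quantity practitioners actually report — rises at high
frequency. The acceptance suite tests exactly this, counting a structured
synthetic scene (a binary random mask, which has power at all
frequencies) and comparing half-set FRCs of MCF, PCA and Hybrid.

## Frequency metrics

- **FRC** on rings 1 Fourier pixel wide, $u$ in cycles/pixel up to Nyquist
  (0.5); `fsc_to_snr()` implements $SNR = 2\,FSC/(1-FSC)$ with FSC = 1 an
  error and values within $10^{-9}$ of 1 clamped. Threshold readouts
  (0.143, 0.5) interpolate linearly.
- **NPS** — radially averaged power of mean-subtracted flat realizations,
  normalized per pixel, so ideal Poisson point counting gives a flat NPS
  at the dose level. The DC term of a mean-subtracted spectrum is
  identically zero; `dqe()` extrapolates it from the first two shells and
  records that it did.
- **Knife-edge MTF** — per-row edge crossings (coarse half-max pass, then
  a gradient centroid within ±5 px; rows are pre-averaged along the edge,
  which is unbiased because the crossing is linear in the row index), a
  least-squares edge line, an ESF binned at 4× oversampling (default,
  standard slanted-edge practice; edge tilt default 3°), finite-difference
  LSF, and the magnitude of its Fourier transform normalized at DC. Both
  the binning aperture and the finite difference multiply the spectrum by
  $\mathrm{sinc}(\pi u/os)$; the returned MTF divides that factor out
  squared. An ideal pixel-aperture edge then lands on $|\mathrm{sinc}|$,
  hitting $2/\pi$ at Nyquist (tested to 2 %).
- **DQE** $= f \cdot MTF^2(u) \cdot d / NPS(u)$ with counted dose $d$ and
  detected fraction $f$ — the standard detector-theory combination,
  normalized so an ideal counter gives DQE(0) = 1.
- **SNR gain fits** — per-shell SNR ratios with a least-squares line over
  a fit window (fractions of Nyquist), reported at 0.5× and 1× Nyquist.
  Nyquist means the stored grid's Nyquist; windows beyond it only make
  sense for super-resolution grids, and the caller supplies that Nyquist
  explicitly.

## Optics calculators

Fixed constants: electron rest energy 510998.95 eV;
$\lambda = 12.2643/\sqrt{V(1 + 0.978476\times10^{-6}V)}$ Å. The chromatic
envelope is $E(u) = \exp[-0.5(\pi\lambda\delta)^2u^4]$ with defocus spread
$\delta = C_c\sqrt{4(\Delta I/I)^2 + (\Delta E/V)^2 + (\Delta V/V)^2}$
($C_c$ in mm converted to Å). $\Delta I/I$ and $\Delta V/V$ default to 0 —
the energy-spread term dominates for the configurations of interest, and
both are user-settable. SNR depression between optical configurations is
$SNR' = E'^2(u)\,SNR/E^2(u)$ evaluated at the same physical frequency (we
found no meaningful alternative reading of the primed frequency and use
$u' = u$). The damage fit regresses relative damage on $1/\beta^2$ by
ordinary least squares; with the three measured voltages it reproduces the
published slope and intercept to better than 1 % (asserted in the tests).
$IFC = T\sigma_e/\sigma_i$ is provided as a calculator only — computing
cross-sections from scattering theory is out of scope.

## Backscatter Monte Carlo

Single-scattering model standard to CASINO-class simulators: elastic
events with free paths $s\sim\mathrm{Exp}(\lambda_{el})$ from the
relativistically corrected screened-Rutherford total cross-section
(screening $\alpha = 3.4\times10^{-3}Z^{0.67}/E$), polar angles from its
closed-form inverse CDF, and continuous energy loss between events from
the relativistic Bethe (Berger–Seltzer) collision stopping power with the
Joy–Luo effective ionization potential ($k = 0.731 + 0.0688\log_{10}Z$;
$J_{Si} = 173$ eV). Electrons start at the centre of the top face of a
1400 µm square slab, normally incident; termination: re-exit through the
entrance surface (backscattered, exit radius recorded at the crossing
point), exit through the bottom (transmitted), drop below 0.5 keV or leave
laterally (absorbed). Bookkeeping is conservative by construction and
tested. Each electron consumes its own counter-based RNG substream derived
from `(seed, index)` (splitmix64 → xorshift128+), so results are exactly
reproducible and independent of execution order.

Model limitations we know about: screened Rutherford underrepresents the
large-angle Mott tail, so backscatter arises relatively more from
accumulated small deflections. The headline coefficients are robust to
this (≈ 15 % at 120 kV / 40 µm, with a ≈ 5–6× ratio over 300 kV,
recomputed by `scripts/acceptance.R`), but the *exit radii* are broader
than Mott-based simulators report — our median exit radius at 120 kV/40 µm
is ≈ 30 µm, not within the ~20 µm a Mott-based code attributes to the
majority of BSEs — and the "back-thinning" comparison (120 kV/10 µm vs
300 kV/30 µm) agrees only to about a factor of two, not within Monte-Carlo
error. Tests assert the orderings and absolute gaps this model actually
supports; we chose not to paper over the discrepancy by re-tuning the
cross-sections.

We also note one correction made while validating the stopping power: at
100 keV in silicon the collision stopping power is ≈ 3.3 MeV·cm²/g, i.e.
≈ 0.76 keV/µm at 2.33 g/cm³. (A value near 0.35–0.45 keV/µm corresponds to
the mass stopping power with the density factor dropped.) The test anchors
the ESTAR-scale value.

## Synthetic frames

`generate_frame_stack()` emulates, per frame: Poisson event counts
(`dose_rate` × pixels), uniform — or intensity-map-driven — continuous
positions, an integrated-Gaussian charge cloud per event
(`charge_cloud_sigma`), a log-normal amplitude spread (mean preserved;
`amp_sdlog`) standing in for the heavy-tailed Landau energy-loss
distribution, an optional displaced backscatter blob (probability
`bse_probability`, offset from an exponential, gamma, or user-supplied
empirical radius distribution — e.g. Monte-Carlo exit radii scaled to
pixels), Gaussian read noise, and a multiplicative gain map. Ground truth
records every true position.

The blob is as sharp as the primary cloud by default-preset design
(`bse_sigma` ≈ 0.5 px): a re-entering electron deposits charge through the
same collection physics, just weaker and displaced. Broad smooth blobs
would be largely invisible to a band-pass detection kernel — and indeed
are, which is itself a faithful property of the pipeline.

What the generator does **not** emulate: actual charge transport and
sharing, energy-dependent per-class SNR, detector nonlinearity or
defects, beam-induced motion, or any specimen contrast beyond the optional
intensity map. Passing closed-loop tests therefore demonstrates the
correctness and the *relative* behaviour of the algorithms under
controlled conditions, not absolute performance on any physical camera.

**Presets.** `preset_model("120kv" | "200kv" | "300kv")` freezes the
output of `tune_to_class_fractions()` against the measured per-voltage
small/medium/large fractions (33.8/38.6/27.6 % at 120 kV, 59.0/30.2/10.8 %
at 200 kV, 60.2/31.9/7.9 % at 300 kV). The tuner is a coarse grid plus
coordinate refinement over (`charge_cloud_sigma`, `bse_probability`,
`cloud_amplitude`) minimizing the L1 distance of detected fractions, with
the remaining fields fixed at the preset base (amp_sdlog 0.5, bse_sigma
0.55, gamma(9, 0.2) offsets — the gamma concentrates the blob offset in
the 1–2.5 px band where merging into the primary cluster is geometrically
possible, matching the near-field core of the simulated exit-radius
distribution at 14 µm pixels). The acceptance suite re-runs the tuner for
all three targets and requires L1 ≤ 0.05; the presets reach ≤ 0.02. The
preset parameters are emulation targets, not physical backscatter rates —
at 300 kV the tuner happily uses frequent but weak blobs that mostly stay
below threshold.

## Problem sizes

Desk-scale throughout, chosen so the full suite runs in minutes: frames of
96²–128² pixels, 6–150 frames per stack, doses of 0.002–0.02
events/px/frame (2 × 10⁴–3 × 10⁴ events in the largest fixtures);
Monte-Carlo runs of 5 × 10,000 trajectories; 60-realization noise stacks
for NPS. Statistical tolerances in the tests were set from the expected
sampling error at these sizes (e.g. band-averaged NPS whiteness at 5 %,
knife-edge density at 3 %).

## Known limitations

- Event streams use a bespoke versioned text format (`.evt`); it preserves
  the semantics of event-based representations (position, frame, class,
  weight bit, optional pattern) but is not any camera vendor's format.
- MRC I/O covers modes 0/1/2, little-endian, no extended header on write —
  sufficient for movie stacks and counted images, not a general MRC
  library.
- 2-D rings only; the shell logic would generalize to 3-D but volume FSC
  is out of scope.
- The Monte Carlo models primary trajectories only (no secondaries, no
  X-rays, no in-sensor charge spreading), and its exit-radius tails are
  model-limited as described above.
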