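---
title: "Growth-zone kinematics in three dimensions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-zone kinematics in three dimensions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisokin)
```

## The kinematic framework

A growing grass leaf elongates from a basal growth zone hidden inside the
sheaths of older leaves: a **meristem** (division zone) of length $L_{mer}$
where cells divide and stay near a size equilibrium, followed by an
**elongation zone** where cells expand without dividing, reaching their
mature size at the end of the growth zone $L_{gz}$. Under steady state —
profiles stationary in time while material moves through them — the spatial
cell-length profile $l(x)$ and the leaf elongation rate together determine
the complete division and expansion kinematics:

* cell production rate $P = \mathrm{LER}/l_{mat}$ — each mature cell
  emerging from the growth zone accounts for $l_{mat}$ of length gain;
* average division rate $D = P/N_{mer}$ and cell cycle duration
  $T_c = \ln 2 / D$ (the $\ln 2$ reflects exponential doubling);
* meristem residence time $T_{mer} = \log_2(N_{mer})\,T_c$;
* cell flux $F(x)$: zero at the leaf base, rising linearly to $P$ at the
  end of the meristem, constant at $P$ beyond it;
* velocity $v(x) = l(x)\,F(x)$ and relative elemental growth rate
  $\mathrm{RGR}(x) = dv/dx$;
* cell numbers by the continuity form $N = \int dx / l(x)$, and the
  elongation-zone residence time $T_{el} = N_{el}/P$;
* zone-averaged relative growth rates
  $\mathrm{RGR} = \ln(\mathrm{size}_2/\mathrm{size}_1)/\Delta t$ between
  zone boundary sizes, with $\Delta t = T_{mer}$ or $T_{el}$.

Growth **anisotropy** is quantified by applying the zone-average formula to
the width and thickness profiles (cell and whole-organ level) and taking
ratios against the longitudinal rate. The meristem length and meristem
timing are shared across the three directions; the width- and
thickness-specific growth-zone lengths only change the upper limit of the
$N_{el}$ integral.

Two points deserve emphasis:

* **The zone-average form.** A "relative growth rate" must carry units of
  h$^{-1}$ and agree with $dv/dx$ in the uniform-growth limit, which the
  log-ratio form does; `zone_rgr()` therefore defaults to
  $\ln(s_2/s_1)/\Delta t$ and offers the plain difference quotient
  (`"difference"`) and $((s_2-s_1)/s_1)/\Delta t$ (`"simple-relative"`) as
  alternatives. The spatial profile from $dv/dx$ is reported separately in
  the pipeline's profile table.
* **Whole-leaf longitudinal rates.** There is no organ-level length
  profile (organ length enters through LER), so organ- and cell-level
  longitudinal zone RGRs are both computed from the cell-length profile
  and coincide by construction.

## Profile smoothing

Raw measurements — roughly 20 cells per sampled position per replicate
plant — are averaged per position, smoothed per replicate with a tricube
local polynomial (loess, `surface = "direct"`), resampled onto a regular
1-mm grid clipped to the sampled range (no extrapolation), and then
averaged across replicates with a pointwise SE. The `bandwidth` parameter
is the loess span: the fraction of data points in each local
neighbourhood, default 0.3, with local degree 2. Thickness profiles, which
come from sparse fixed section positions (0.5–17 cm), default to a wider
span of 0.5.

Smoothing per replicate *before* averaging preserves the usual SE
semantics of mean ± SE profile plots; the opposite order is available by
aggregating raw replicates upstream. Local quadratics reproduce
polynomials up to their own degree exactly (tested to 1e-9), but near a
sharp bend they over- or under-shoot. This matters at the meristem
boundary, where the cell-length profile turns abruptly from its division
plateau into the elongation ramp, and motivates two estimator choices
below.

## Growth-zone delimitation

The growth zone ends where the profile reaches 95% of the mature size, and
the mature size is the mean of the profile distal to the growth zone. The
two quantities define each other, so `estimate_growth_zone()` resolves
them by fixed-point iteration: initialise the mature size from the distal
20% of grid points; find the smallest grid position from which the profile
*stays* at or above the threshold (robust to isolated noise dips, unlike
first-touch); refine the crossing below the grid step by linear
interpolation; recompute the mature size distal to the new boundary;
repeat until the boundary moves by less than one grid step (it typically
converges in 2 iterations; 50 are allowed). Profiles whose distal 20%
still rises by more than 5% are flagged `plateau_detected = FALSE` — the
estimate is then a lower bound, mirroring field cases where (for example)
cell width never plateaus within the sampled region — rather than
rejected.

An important subtlety, exposed by the simulator: when a profile approaches
its plateau tangentially, the 95% criterion systematically crosses
*before* growth actually ceases. The threshold rule defines an
*operational* growth-zone length; it is that estimand (carried in the
simulator ground truth as `L_gz`, alongside the generative cutoff
`L_gz_model`) that recovery should be judged against.

## The synthetic steady-state experiment

`simulate_growth_zone()` draws complete experiments from a fully known
steady-state model, because the real raw measurements behind analyses of
this kind are rarely deposited and every estimator here needs a truth to
be validated against.

The deterministic core: in the meristem, cell length is constant at
$l_{div}$ and flux ramps linearly, so $v(x) = l_{div} P x / L_{mer}$; in
the elongation zone the RGR declines linearly from its peak at the
meristem boundary to zero at $L_{gz}$ — the simplest shape with the
correct boundary behaviour and a closed-form velocity — which fixes the
peak at $R_{el} = 2P(l_{mat}-l_{div})/(L_{gz}-L_{mer})$, and
$l(x) = v(x)/P$. Cell width and height stay constant in the meristem
(division maintains lateral size equilibrium) and grow along material
trajectories at `aniso_w` and `aniso_h` times an RGR ramp of the same
shape scaled to their own growth-zone length; with equal growth-zone
lengths the true elongation-zone length:width RGR ratio is exactly
$1/\texttt{aniso\_w}$. Organ width is `n_files` times cell width; blade
thickness is $(1+\texttt{thickness\_factor})$ times epidermal cell height,
default factor 4 so that a ~18-µm epidermis sits in a ~90–110-µm blade.

Default conditions describe a vigorously growing maize fourth leaf and are
fixed once: $L_{mer}$ = 10 mm, $L_{gz}$ = 30 mm, $l_{div}$ = 20 µm,
$l_{mat}$ = 147 µm, $P$ = 16 cells h$^{-1}$ (so LER = 2.352 mm h$^{-1}$),
`aniso_w` = 0.5, `aniso_h` = 0.25, cell width/height 9/11 µm at the base,
950 cell files, 5 replicate plants. Sampling mimics the field protocol:
cell length/width and leaf width every 5 mm over the basal 10 cm (~20
cells per position), thickness at nine fixed section positions between 0.5
and 17 cm, leaf length on four consecutive days. Noise is multiplicative
lognormal with mean 1 (sizes are positive), CV 0.05; daily leaf lengths
get 1 mm additive error (ruler precision); measured meristem lengths get
the same lognormal CV. An optional `midvein_artifact` depresses basal
organ-width measurements as happens when rolled leaves cannot be spread.

What the generator does *not* emulate: non-steady-state growth, discrete
division placement, cell-file heterogeneity, spatially correlated
measurement error, and any curvature smoother than its exact kink at
$L_{mer}$. Passing recovery tests therefore demonstrates correctness of
the estimation chain under the stated model, not performance on real
leaves — though the kink makes the simulator *harder* than real, smoothly
bending profiles for any local-polynomial step.

## Estimator choices driven by the meristem boundary

Two defaults deviate from the naive "read everything off the smoothed
profile" recipe, both because the local polynomial is biased exactly at
the sparsely sampled, sharply bending meristem boundary:

* **Meristem cell number.** `analyze_genotype()` defaults to
  $N_{mer} = L_{mer} / \bar l_{mer}$ with $\bar l_{mer}$ the mean of raw
  cell lengths observed within the meristem — division-zone cells sit at a
  size equilibrium, so the mean is the natural estimator and is unbiased
  where $\int dx/\hat l(x)$ on the smoothed profile is not
  (`nmer_method = "integral"` remains available).
* **Zone-boundary sizes.** Zone-averaged RGRs default to boundary sizes
  interpolated from the cross-replicate mean of per-position measurement
  means (`boundary_sizes = "raw"`; SE ≈ cv/√(cells × replicates) ≈ 1% at
  the default design), rather than the smoothed values
  (`boundary_sizes = "smoothed"`), whose overshoot at the meristem
  boundary propagates directly into the anisotropy ratios. Growth-zone
  delimitation, cell counting and the spatial profiles always use the
  smoothed profile.

## Numerical choices

* **Cell counting.** $\int dx/l(x)$ treats the gridded profile as
  piecewise linear; each segment integrates in closed form to
  $\Delta x \, \ln(l_2/l_1)/(l_2-l_1)$ (flat segments reduce to
  $\Delta x / l$). The count is exact on linear profiles, where plain
  trapezoid quadrature at a 1-mm grid carries a ~0.4% Euler–Maclaurin
  error.
* **Differentiation.** $dv/dx$ uses central differences (one-sided at the
  ends), exact for the piecewise-quadratic simulator velocity away from
  its two kink points.
* **Fixed point.** Interpolated growth-zone boundaries are snapped to the
  grid within a 1e-6 float tolerance so that "distal to $L_{gz}$" is
  stable; convergence is declared when the boundary moves less than one
  grid step.
* **Percent differences.** Rounded to the nearest integer with ties away
  from zero, the convention of published dimension tables
  (`rounded = FALSE` gives the raw value).
* **Problem sizes.** Validation runs use the default design (5 replicates
  × 20 positions × 20 cells, 1-mm analysis grid) and a 256×256 phantom for
  the thickness probe; the material-point trajectory oracle steps at
  dt = 0.001 h.

## Blade thickness from cross-section images

For leaves still rolled inside the pseudostem, blade thickness is measured
on grayscale cross-section images (e.g. MRI): the noise level is the mean
intensity of a user-designated background region, the signal level the
mean over pixels in the middle of leaf segments, and their midpoint is the
cut-off — a binarisation that compensates partial-volume effects, so no
sub-pixel interpolation is applied on top. A line probe crossing at least
six leaf segments is traversed by Bresenham stepping; the filled-sample
count times the per-sample physical length, divided by the number of
crossed segments, is the mean thickness, repeated over slices and
averaged. On a noiseless 3-px-band phantom at 39 µm/pixel the measurement
is exact (117 µm); each misclassified pixel moves it by one pixel-share
(39/6 µm per probe at six segments). Measured thickness is monotone
non-increasing in the cut-off and scales linearly with pixel size.

## Known limitations

* Everything rests on steady state; leaves in transient phases (emergence,
  stress responses) violate it in ways none of these estimators detect.
* The 95% rule underestimates the position where growth truly ceases for
  any profile that approaches its plateau tangentially (see above); treat
  $L_{gz}$ as operational, and compare only like with like.
* The smoothing span is a genuine tuning parameter: the default 0.3 is
  stable for 9–20 support points but too aggressive for very finely
  sampled basal regions; no automatic span selection is attempted.
* Genotype comparison is descriptive (means, SE, rounded percent
  differences); inferential statistics are deliberately out of scope.
* The midvein width artifact is available in the simulator but no
  correction estimator is provided.
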