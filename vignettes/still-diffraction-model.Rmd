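---
title: "Gaussian modelling of still diffraction: prediction, partiality and merging"
author: "stillgauss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian modelling of still diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A still (snapshot) diffraction pattern records a crystal in a single,
unknown rotational state. Each reflection is then caught at an arbitrary
offset from its ideal diffraction condition and delivers only a fraction
of the intensity it would deliver at the optimum — the *partiality*
problem of serial snapshot crystallography. Plain averaging of redundant
observations (Monte Carlo merging) works when partialities are
identically distributed and each reflection is measured many times, but
fails to use most of the information in each pattern, and breaks down for
polychromatic ("pink-beam") sources and mosaic crystals where peaks are
elongated and displaced.

`stillgauss` models every distribution in the experiment as a
three-dimensional Gaussian kernel in reciprocal space and exploits that
products, convolutions, projections and cut integrals of Gaussians have
closed forms. One model then serves three tasks:

1. pixel-wise prediction of complete still patterns,
2. closed-form integrated intensities and partialities per reflection,
3. maximum-likelihood merging of serial data sets with partiality
   correction (merging Gaussian-partiality-corrected integrated
   intensities).

## The model

**Conventions.** Wavenumbers are reciprocal wavelengths without a factor
of $2\pi$ ($\nu = 1/\lambda$, in nm$^{-1}$); the Ewald sphere has radius
$\nu$ and passes through the reciprocal origin. The lab frame is
right-handed with the beam along $+z$; detector panels map fast/slow
pixel indices to lab positions through a $3\times 2$ basis and a corner
offset, with pixel centres at half-integer indices.

**Illumination.** The incident wavevector distribution has covariance
$\nu_0^2[\sigma_\mathrm{div}^2(I - ww^\top) + \beta^2 ww^\top]$ for beam
direction $w$, relative bandwidth $\beta$ and divergence
$\sigma_\mathrm{div}$ (angular distribution isotropic and uncorrelated
with wavelength). Because diffraction preserves the wavelength, the
outgoing and incident radial components are perfectly correlated: with a
shared relative wavenumber deviation the bandwidth contribution to the
diffraction vector $\Delta k = k_\mathrm{out} - k_\mathrm{in}$ is the
rank-one matrix $\nu_0^2\beta^2 (w_\mathrm{out}-w_\mathrm{in})
(w_\mathrm{out}-w_\mathrm{in})^\top$ — the correlated difference of the
two radial factors — while the divergence part enters independently.
This reproduces the classic sheared covariance: the projection of
$\Delta k$ on $w_\mathrm{in}$ is $\nu(\cos 2\theta - 1)$, which is also
how the per-pixel photon energy is estimated (below). The polarization
correction uses the standard partially-polarized Thomson factor
$C = p\,[1-(w_\mathrm{out}\!\cdot\! n)^2] +
(1-p)\,[1+(w_\mathrm{out}\!\cdot\! w_\mathrm{in})^2]/2$
evaluated at the mean beam direction (an adopted convention — the form
satisfies $C(w_\mathrm{in}) = 1$ and the unpolarized right-angle value
$1/2$).

**Crystal.** Lattice point $x = R\,(h,k,l)^\top$ carries covariance
$\Sigma_\mathrm{shape} + \sigma_m^2(|x|^2 I - xx^\top) +
\sigma_s^2\,xx^\top$: an intrinsic peak shape (for a crystal of size $L$
the default is an isotropic Gaussian with
$\sigma = 0.886/(2.355\,L)$, FWHM-matched to the sinc$^2$ central lobe),
tangential mosaic broadening and radial strain broadening. The mosaic
term is the exact second moment of an isotropic rotation-vector
distribution with per-axis standard deviation $\sigma_m$ (valid for
$\sigma_m \ll 1$). The geometry kernel of a crystal has 17 independent
parameters (9 cell + 6 shape + mosaicity + strain), 19 with the linear
scale and $B$ factor; a source kernel has 9.

**Flux.** The incoherent flux density in direction $w$ is the overlap
integral of the $\Delta k$ kernel with each excited peak kernel, summed
with weights $J_0\, C\, |F_{hkl}|^2$. Densities are squared amplitudes:
the incoherent integral is $\int \rho_a\rho_b$, the coherent one
$[\int\sqrt{\rho_a\rho_b}]^2$; for single Gaussians the two differ only
by the mean-independent factor
$2^3 (2\pi)^{3/2}\sqrt{\det\Sigma_a\det\Sigma_b}/\sqrt{\det(\Sigma_a+\Sigma_b)}$
(derived symbolically from the two orderings and verified against 3-D
quadrature), which is why incoherent integration is the default.

**Detector and smoothing.** Solid angles come from the cross product of
the pixel-edge direction derivatives. Predicted peaks can be much
narrower than a pixel, so the flux density is smoothed analytically with
a Gaussian detector point spread of $1/2$ pixel extent before sampling at
pixel centres; the constant $1/2$ minimizes the maximum Kullback–Leibler
divergence between the exact pixel-integrated (error-function) profile
and the variance-inflated sampled Gaussian, the worst case being a very
narrow peak just inside a pixel edge (`kl_smoothing_study()` reproduces
the calibration numerically; the same $+1/4$ variance inflation is
applied whenever a continuous density is sampled at integer counts).
Smoothing redistributes but does not create or destroy flux: on a fully
recorded reflection the frame sums with and without smoothing agree to
well under 0.1%.

**Readings and errors.** Integrating detectors respond to total photon
energy, so the expected reading is $g\,\bar\nu\,\Phi\,\Omega$ with the
per-pixel mean wavenumber $\bar\nu$ obtained by projecting the mean of
the product (joint) kernel on the beam axis and rescaling by
$1/(\cos 2\theta - 1)$; the wavenumber variance follows the same path
and the counting variance carries the exact compound-Poisson inflation
$\mathbb{E}[\nu^2]/\mathbb{E}[\nu]$. The two-parameter error model
$\alpha\,(\text{counting}) + \beta\,(\text{reading})^2$ is combined with
a super-heavy-tailed outlier density — a smoothed variant of the
universal-prior construction,
$o(x) \propto 1/[(|x|+es)\log^2((|x|+es)/s)]$, normalized in closed form
— so no finite measurement, not even a dead pixel, has zero likelihood.

**Integrated intensities and partiality.** Near one reflection the
distribution of Ewald spheres is a planar Gaussian slab; projecting both
slab and peak onto the optimal outgoing direction $w_\mathrm{max}$
collapses the angular integral to
$\phi(\delta; 0, \sigma_\mathrm{proj}^2)/\nu_0^2$, with $\delta$ the
projected offset of the peak from the slab and $\sigma_\mathrm{proj}^2$
the projected variance of peak plus $\Delta k$ kernels (the slab width).
Because the slab width varies noticeably across the wide tangential
footprint of a mosaic crystal in a strongly polychromatic beam, the
default factor adds an importance-weighted 3-point Gauss–Hermite
correction along each tangential principal axis; it reduces exactly to
the planar form for a frozen kernel and brings the worst-case deviation
from dense angular quadrature (5% bandwidth, 0.5° mosaicity) from ~7%
to below 1%. Partiality is the ratio of the factor at the current
orientation to its maximum over rigid reorientations; rotating the peak
onto the sphere along the geodesic with unchanged covariance magnitudes
gives the closed form $\exp(-\delta^2/2\sigma_\mathrm{proj}^2) \in
[0,1]$. Over uniformly random orientations its histogram has its mode at
0 with a faint integrable pile-up at 1, as expected for the smoothed
value distribution of a Gaussian with a flat top.

**Excitation.** A reflection is "excited" when the Mahalanobis distance
between peak and diffraction condition (the exponent of the incoherent
overlap at the closest approach to the sphere) is below a cutoff within
the resolution sphere. Generous cutoffs (overprediction) add many weak
measurements which strongly constrain peak shape, mosaicity and strain
during merging. The region-growing enumeration walks the integer lattice
with 26-neighbour connectivity from seeds on the Ewald sphere and prunes
cells that cannot intersect the diffraction condition (the admission
margin is the lattice-step diagonal over the smallest shape-covariance
standard deviation, which is conservative); it returns exactly the
exhaustive set and is tested for set equality.

## Merging (maximum likelihood with partiality correction)

Observations are integrated intensities $I_i$ with counting sigmas
$\sigma_i$, indexed by crystal and Miller index. The model prediction is
$a_c\, e^{-B_c q/2}\, C\, p \cdot I_{hkl}$ with per-crystal scale and
$B$ factor, polarization and the closed-form partiality $p$; the
likelihood per observation is the mixture of a Gaussian with variance
$\alpha\sigma_i^2 + \beta(\text{pred})^2 + 1/4$ and a zero-centred
Cauchy of weight $\varepsilon = 1/16$ whose scale is fitted once to the
pooled intensity histogram. Maximization alternates blocks — global
bandwidth scale (optional), per-crystal quasi-Newton refinement, gauge
fixing, merged-intensity updates, global error model — each accepting a
change only if the exact objective improves, so the outer iteration is
monotone.

Numerical choices that proved essential, stated here because they are
easy to get wrong:

* **Variance floor.** The $+1/4$ discretization inflation keeps the
  Gaussian component proper; without it the likelihood is unbounded
  (variance collapse onto near-zero residuals).
* **Wilson prior.** A weak exponential (acentric Wilson) intensity prior
  with per-resolution-shell means, estimated robustly once before
  iteration, regularizes sparsely observed reflections. Pure
  per-reflection mixture ML is pathological: a single heavy-tailed
  outlier on a reflection observed once is best explained by an
  arbitrarily large merged intensity (the quadratic variance term makes
  large predictions cheap). The reported objective (and its
  monotonicity) is the penalized one.
* **Candidate updates.** The responsibility-weighted least-squares
  update alone can freeze: a reflection far below its true intensity
  assigns its own observations responsibility ~0. Every sweep therefore
  also proposes a median-of-ratios estimate and the three most
  informative single-observation ratios, and keeps per reflection
  whichever candidate maximizes the exact penalized objective.
* **Gauges.** Two exact flat directions are pinned each iteration: the
  mean linear scale (against a global intensity scale) and the mean $B$
  factor (against the resolution-dependent factor $e^{\Delta B q/2}$ on
  the intensities); the prior means are co-transformed so the objective
  is invariant.
* **Degeneracy of strain and bandwidth.** Per-crystal strain and the
  global source bandwidth enter the projected slab width identically
  ($\propto x^4/4\nu_0^2$), so they cannot be refined together; the
  bandwidth-recovery study holds strain fixed. The bandwidth itself sits
  on a ridge with the merged intensities and is refined by a profile
  search (intensities re-adapted for every candidate), wide in the first
  iterations and local afterwards.
* **Reported reflections.** A reflection whose merged standard error
  exceeds 1/8 of the local Wilson prior mean carries essentially no
  measurement (it was only seen at partiality ~0) and is flagged absent
  by `merged_table(..., well_measured_only = TRUE)` rather than reported
  as a number; at the default study conditions ~81% of reflections are
  reported.

## The synthetic study conditions

The generator (`simulation_config()`) emulates a pink-beam microcrystal
data set and defines the package's reference conditions: 200 crystals in
uniformly random orientations of an 8 nm cubic cell; 0.13 nm photons
with 2% wavenumber spread — the regime the model is for, and the one in
which bandwidth ($\propto x^4$) and mosaicity ($\propto x^2$) are
separable in the data; 0.15° mosaicity and $5\times10^{-4}$ strain; a
500 nm crystal; resolution 0.4 nm with overprediction cutoff 5, giving
~450 observations per crystal at multiplicity ~5; exponential (acentric
Wilson) true intensities of mean 500 counts; log-normal crystal scales
(sd 0.3 in the log) and per-crystal $B$ factors $0.2\pm0.05$ nm$^2$;
noise with $\alpha = 1$ on counting sigmas
$\sqrt{\max(I,0)+25}$ and $\beta = 10^{-3}$; 3% outliers from a
zero-centred Cauchy of scale 2000 (four times the Wilson mean, the scale
ratio of the Cauchy outlier model to the bulk histogram in real
integrated serial data — a much narrower outlier scale would concentrate
draws near zero, where they mimic absent reflections and defeat any
estimator at this multiplicity). The parameter-recovery study starts the
disorder and bandwidth 50% high and the scales at their nominal values,
and recovers the truth correlation of the reported merged intensities
(>0.99), the mosaicity and the bandwidth (both within 10%, with a small
stable downward/upward bias of ~4% from the incidental per-crystal
parameters), while the Monte Carlo mean baseline is destroyed by the
Cauchy contamination it cannot reject.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: indexing errors (cells are exact), detector
geometry errors, pixel-level integration (noise is drawn at the
reflection level from the same error model the merge assumes),
correlated backgrounds, saturation and panel-gap shadowing, and
anisotropic mosaicity. The recovery study demonstrates that the
estimator inverts its own forward model under realistic noise, not that
the forward model captures every property of real detectors.

## Other numerical choices

* Degenerate (rank-deficient) covariances are legal inputs to
  convolution and projection but rejected, with the null direction
  named, where a density is required; PSD is restored after subtractions
  by eigenvalue clipping at zero (tolerance $-10^{-12}$ trace).
* The matrix square root is the symmetric PSD root via eigen
  decomposition; the correlated-difference covariance is
  $SS^\top$ with $S$ the difference of the roots, re-symmetrized and
  clipped.
* `optimal_direction()` runs BFGS in a tangent chart followed by Newton
  polish; stationarity is verified with a fine-step central-difference
  gradient (the coarse-step gradient is curvature-bias limited) and the
  scaled gradient must fall below $10^{-8}$.
* Pattern fitting is local: BFGS with positive parameters
  log-transformed, analytic gradients for the scaling-side parameters
  (scale, $B$, $\alpha$, $\beta$) via the exact chain rule, central
  finite differences for mosaicity/strain (their analytic derivatives
  would have to thread through the per-pixel wavenumber statistics; the
  cost/benefit did not justify it). Scale and $B$ are only jointly
  identifiable across several resolutions — a single spot constrains
  only their product.
* The per-pixel energy factor used in the variance model is
  flux-weighted with $B$-independent weights so the analytic gradients
  stay exact.
* Problem sizes in the test suite are chosen to make each oracle's Monte
  Carlo or quadrature error a small fraction of the tested tolerance
  (e.g. $3\times10^5$ draws for covariance oracles, 64–72-point tensor
  Gauss–Legendre grids boxed at 10 posterior sigmas, 201² angular grids
  aligned to the footprint's principal axes).

## Worked example

```{r, eval = FALSE}
library(stillgauss)

cfg <- simulation_config(n_crystals = 40, seed = 7)
beam <- simulation_beam(cfg)
crystals <- simulate_crystals(cfg)
truth <- simulate_truth_intensities(cfg)
obs <- simulate_observations(crystals, beam, truth, cfg)

init <- lapply(crystals, function(cr) {
  cr$mosaicity <- cr$mosaicity * 1.5
  cr$scale_a <- 1
  cr$b_factor <- cfg$b_factor_mean
  cr
})
res <- merge_intensities(obs, beam, init, merge_config(max_outer = 8))
merged <- merged_table(res$state, obs, well_measured_only = TRUE)
head(merged)
```

The same pipeline is scriptable from a shell through the thin wrapper in
`system.file("cli", "stillgauss", package = "stillgauss")`
(`simulate`, `predict`, `partiality`, `merge`, `fit-pattern`).

## Known limitations

* Only local refinement is promised: the pixel-wise likelihood has many
  local minima and plateaus, and merging is block-coordinate ascent from
  an indexing-informed start.
* Anisotropic mosaicity tensors, the full strain tensor, partial
  coherence and per-direction polarization corrections are out of scope;
  mosaicity is isotropic and strain scalar.
* The planar-slab partiality used inside the merge (for speed) is the
  uncorrected closed form; the Gauss–Hermite-refined factor is used for
  the per-reflection prediction API.
* Backgrounds are inputs, not modelled.
* Laue symmetries beyond Friedel pairing ("-1") and no reduction ("1")
  must be applied upstream.
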