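# stillgauss

Gaussian modelling of still-crystal diffraction: pattern prediction,
partiality estimation and maximum-likelihood merging for serial snapshot
crystallography.

## The problem

In serial snapshot crystallography every crystal is exposed exactly once,
without rotation. Each recorded reflection is then caught at a random
offset from its ideal diffraction condition and delivers only a fraction
— its *partiality* — of the intensity it would deliver at the optimum.
With monochromatic beams and well-ordered crystals the classic remedy is
redundancy (Monte Carlo merging: average many partial observations), but
for polychromatic "pink-beam" sources, mosaic crystals and finite crystal
sizes the peaks become elongated and displaced, and plain averaging wastes
most of the information in each pattern.

`stillgauss` models every distribution in the experiment — source
bandwidth and divergence, reciprocal peak shape, mosaicity, strain, the
detector point spread — as a 3-D Gaussian kernel in reciprocal space.
Products, convolutions, projections and cut integrals of Gaussians have
closed forms, so one analytic model yields:

* **pixel-wise prediction** of complete still patterns: the incoherent
  flux in direction $w$ is
  $j(w) = \sum_{hkl} J_0\, C\, |F_{hkl}|^2 \int \rho_{\Delta k}\,
  \rho_{hkl}\, \mathrm{d}^3x$,
  with the diffraction-vector kernel
  $\rho_{\Delta k} \sim \mathcal{N}(\nu_0(w - w_\mathrm{in}),\,
  \Sigma_{\Delta k})$ and the peak kernel
  $\rho_{hkl} \sim \mathcal{N}(R\,h,\; \Sigma_\mathrm{shape} +
  \sigma_m^2(|x|^2 I - xx^\top) + \sigma_s^2 xx^\top)$;
* **integrated intensities and partialities** per reflection: the angular
  integral collapses to the 1-D projection
  $\phi(\delta;\, 0,\, \sigma_\mathrm{proj}^2)/\nu_0^2$ onto the optimal
  outgoing direction ($\delta$ = offset of the peak from the Ewald slab,
  $\sigma_\mathrm{proj}^2$ = projected width of peak + slab), and the
  partiality is $\exp(-\delta^2 / 2\sigma_\mathrm{proj}^2) \in [0, 1]$;
* **merging** (maximum likelihood, Gaussian-partiality-corrected
  integrated intensities): per-crystal scales, $B$ factors, mosaicity and
  optionally a global bandwidth are fitted jointly with the merged
  intensities under a Gaussian + zero-centred-Cauchy mixture likelihood
  (outlier weight $1/16$), robust to arbitrarily wild outliers.

A synthetic-data generator reproduces the assumed statistical structure
of an indexed pink-beam stills data set (uniform orientations, acentric
Wilson intensities, log-normal scales, two-parameter noise, Cauchy
outliers), so the whole pipeline can be exercised and validated without
any external data.

## Worked example

Simulate 40 crystals of an 8 nm cubic cell in a 2%-bandwidth pink beam,
predict per-reflection partialities, then merge with partiality
correction:

```r
library(stillgauss)

cfg      <- simulation_config(n_crystals = 40, seed = 7)
beam     <- simulation_beam(cfg)
crystals <- simulate_crystals(cfg)
truth    <- simulate_truth_intensities(cfg)
obs      <- simulate_observations(crystals, beam, truth, cfg)  # 17979 rows

predict_reflections(crystals[[1]], beam,
                    obs[obs$crystal_id == 1, c("h", "k", "l")][1:3, ])
#>   crystal_id   h   k   l  factor partiality nu_mean    nu_var      wx     wy
#> 1          1 -14 -11  -9 0.33487    0.51440   7.698 2.568e-05 -0.2209 0.2310
#> 2          1 -14 -10 -10 0.37554    0.57591   7.687 2.565e-05 -0.2037 0.2459
#> 3          1 -14  -9 -11 0.01113    0.01716   7.679 2.552e-05 -0.1863 0.2608
```

The first two reflections sit close to their diffraction condition
(partialities 0.51 and 0.58) and arrive with slightly different mean
wavenumbers selected out of the bandwidth; the third is a weak
overpredicted tail observation at partiality 0.02. Merging starts from
the indexing cells with disorder deliberately 50% off:

```r
init <- lapply(crystals, function(cr) {
  cr$mosaicity <- cr$mosaicity * 1.5
  cr$scale_a   <- 1
  cr$b_factor  <- cfg$b_factor_mean
  cr
})
res <- merge_intensities(obs, beam, init, merge_config(max_outer = 8))
res$state
#> Merge state: 40 crystals, 10881 merged intensities
#>   alpha = 0.4144, beta = 1.079e-08, epsilon = 0.0625, gamma = 28.43

merged <- merged_table(res$state, obs, well_measured_only = TRUE)
head(merged)
#>    h  k  l I_merged sigma_merged n_obs
#> 1 14 10 10  782.401       37.118     1
#> 2 14  8 11  458.269       22.865     2
#> 3 14  7 12  415.620       17.989     2
#> 4 13 13  7  996.091       37.378     4
#> 5 13 11  8   68.564        9.243     3
```

At this deliberately small size (multiplicity ≈ 1.7) the reported merged
intensities correlate with the generating truth at 0.91; at the reference
study size (200 crystals, multiplicity ≈ 5) the correlation exceeds 0.99
and the mosaicity and source bandwidth are recovered to a few percent —
see the methods vignette (`vignettes/still-diffraction-model.Rmd`) for
the full account of the model, the estimator and its guard rails.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "stillgauss", package = "stillgauss")` with
subcommands `simulate`, `predict`, `partiality`, `merge` and
`fit-pattern`, driven by a YAML run configuration.

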