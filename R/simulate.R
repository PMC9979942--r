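#' Configuration of the synthetic indexed-stills generator
#'
#' Defines the statistical structure of a simulated serial snapshot
#' experiment: uniformly random crystal orientations, Wilson-like
#' (acentric exponential) true intensities, log-normal per-crystal scale
#' variation, the two-parameter noise model on integrated intensities and
#' a stated fraction of heavy-tailed (Cauchy) outliers. The defaults
#' emulate a pink-beam microcrystal data set: an 8 nm cubic cell, 0.13 nm
#' photons with 2% wavenumber spread (the regime where partiality
#' modelling matters most and where bandwidth and mosaicity are both
#' identifiable), 0.15 deg mosaicity, 5e-4 strain, a 500 nm crystal
#' (sinc-squared-matched Gaussian shape transform) and generous
#' overprediction (Mahalanobis cutoff 5) to 0.4 nm resolution, giving on
#' the order of 450 observations per crystal. Outliers are drawn from a
#' zero-centred Cauchy whose scale is four times the Wilson mean,
#' mirroring the scale ratio of the Cauchy outlier model to the bulk
#' intensity histogram in real integrated serial data.
#'
#' @param n_crystals Number of crystals.
#' @param cell_nm Real-space cubic cell edge (nm).
#' @param cell_jitter Relative jitter of the cell edge per crystal.
#' @param crystal_size_nm Crystal size L; the Gaussian shape-transform
#'   sigma is `0.886 / (2.355 L)` (FWHM-matched to the sinc-squared
#'   central lobe).
#' @param wavelength_nm Mean wavelength.
#' @param bandwidth Relative wavenumber spread.
#' @param divergence Incidence-angle spread (rad).
#' @param polarization_p Degree of polarization.
#' @param mosaicity True rotational disorder (rad).
#' @param strain True relative cell-size variation.
#' @param wilson_mean Mean of the exponential true-intensity prior.
#' @param scale_sdlog Log-normal sd of per-crystal linear scales.
#' @param b_factor_mean,b_factor_sd Per-crystal B factors (nm^2).
#' @param alpha,beta Error-model truth used to draw noise.
#' @param outlier_fraction Fraction of observations replaced by Cauchy
#'   draws.
#' @param outlier_gamma Cauchy scale of the outliers (counts).
#' @param counting_floor Additive floor (counts^2) of the counting sigma,
#'   emulating background subtraction.
#' @param sigma_cutoff Excitation (overprediction) cutoff.
#' @param d_min Resolution limit (nm).
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_crystals = 200L, cell_nm = 8,
                              cell_jitter = 0, crystal_size_nm = 500,
                              wavelength_nm = 0.13, bandwidth = 0.02,
                              divergence = 1e-4, polarization_p = 0.99,
                              mosaicity = 2.618e-3, strain = 5e-4,
                              wilson_mean = 500, scale_sdlog = 0.3,
                              b_factor_mean = 0.2, b_factor_sd = 0.05,
                              alpha = 1, beta = 1e-3,
                              outlier_fraction = 0.03,
                              outlier_gamma = 2000, counting_floor = 25,
                              sigma_cutoff = 5, d_min = 0.4, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_crystals >= 1, cell_nm > 0, crystal_size_nm > 0,
            bandwidth >= 0, divergence >= 0, mosaicity >= 0, strain >= 0,
            wilson_mean > 0, scale_sdlog >= 0, alpha >= 0, beta >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            outlier_gamma > 0, sigma_cutoff > 0, d_min > 0)
  structure(as.list(environment()), class = "simulation_config")
}

# uniform random rotation matrices via normalized quaternions
random_rotation <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    a <- q[i, 1]; b <- q[i, 2]; c <- q[i, 3]; d <- q[i, 4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d),
             2 * (b * d - a * c),
             2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2,
             2 * (c * d + a * b),
             2 * (b * d + a * c), 2 * (c * d - a * b),
             a^2 - b^2 - c^2 + d^2), 3, 3)
  })
}

#' Beam implied by a simulation configuration
#'
#' @param cfg A [simulation_config()].
#' @return A [beam_model()].
#' @export
simulation_beam <- function(cfg) {
  beam_model(wavelength = cfg$wavelength_nm, bandwidth = cfg$bandwidth,
             divergence = cfg$divergence,
             polarization_p = cfg$polarization_p)
}

#' Simulate randomly oriented crystals
#'
#' Orientations are uniform over rotations; every crystal shares the base
#' cubic cell (optionally jittered), the shape transform of the configured
#' crystal size, and the true mosaicity/strain; linear scales are
#' log-normal and B factors normal. The generating parameter table is
#' attached as attribute `truth`.
#'
#' @param cfg A [simulation_config()].
#' @return List of [crystal_model()] objects with attribute `truth`
#'   (`data.frame` of per-crystal scale and B factor).
#' @export
simulate_crystals <- function(cfg) {
  set.seed(cfg$seed)
  rot <- random_rotation(cfg$n_crystals)
  astar <- 1 / cfg$cell_nm
  sig_shape <- 0.886 / (2.355 * cfg$crystal_size_nm)
  scales <- stats::rlnorm(cfg$n_crystals, 0, cfg$scale_sdlog)
  scales <- scales / mean(scales)  # the merge gauge: mean scale 1
  bfac <- stats::rnorm(cfg$n_crystals, cfg$b_factor_mean, cfg$b_factor_sd)
  bfac <- pmax(bfac, 0)
  jit <- 1 + cfg$cell_jitter * stats::rnorm(cfg$n_crystals)
  crystals <- lapply(seq_len(cfg$n_crystals), function(i) {
    crystal_model(R = rot[[i]] %*% diag(rep(astar * jit[i], 3)),
                  shape_cov = diag(3) * sig_shape^2,
                  mosaicity = cfg$mosaicity, strain = cfg$strain,
                  scale_a = scales[i], b_factor = bfac[i])
  })
  attr(crystals, "truth") <- data.frame(
    crystal_id = seq_len(cfg$n_crystals), scale_a = scales,
    b_factor = bfac, mosaicity = cfg$mosaicity, strain = cfg$strain)
  crystals
}

#' Simulate Wilson-like true intensities
#'
#' Acentric-Wilson (exponential) intensities for every asymmetric-unit
#' reflection inside the resolution sphere of the base cell.
#'
#' @param cfg A [simulation_config()].
#' @return Named numeric vector keyed by [asu_key()] strings.
#' @export
simulate_truth_intensities <- function(cfg) {
  set.seed(cfg$seed + 1L)
  astar <- 1 / cfg$cell_nm
  hmax <- ceiling(1 / (cfg$d_min * astar))
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax)
  q2 <- (g$h^2 + g$k^2 + g$l^2) * astar^2
  g <- g[q2 <= (1 / cfg$d_min)^2 & !(g$h == 0 & g$k == 0 & g$l == 0), ]
  keys <- unique(asu_key(g$h, g$k, g$l, "-1"))
  stats::setNames(stats::rexp(length(keys), 1 / cfg$wilson_mean), keys)
}

#' Simulate an observation table
#'
#' For every crystal the excited reflections under the configured cutoff
#' are found, the predicted integrated intensity is computed from the
#' closed-form partiality (`I = a exp(-B q/2) C p I_true`), Gaussian noise
#' with the two-parameter variance is added, and a fraction of
#' observations is replaced by Cauchy outliers. Negative intensities are
#' retained. Detector location columns are filled with the panel name and
#' fractional coordinates of the diffracted ray for the single synthetic
#' panel convention (panel "sim", fs = ss = 0) -- merging does not use
#' them.
#'
#' @param crystals Output of [simulate_crystals()].
#' @param beam A [beam_model()] (e.g. [simulation_beam()]).
#' @param truth Named intensity vector from
#'   [simulate_truth_intensities()].
#' @param cfg A [simulation_config()].
#' @return `data.frame` with columns `crystal_id, h, k, l, intensity,
#'   sigma, panel, fs, ss` and attribute `truth_pred` (noise-free
#'   predicted intensities).
#' @export
simulate_observations <- function(crystals, beam, truth, cfg) {
  set.seed(cfg$seed + 2L)
  out <- vector("list", length(crystals))
  for (i in seq_along(crystals)) {
    cr <- crystals[[i]]
    ex <- excited_reflections(cr, beam, cfg$sigma_cutoff, cfg$d_min,
                              method = "exhaustive")
    if (nrow(ex) == 0) next
    H <- as.matrix(ex[, c("h", "k", "l")])
    gf <- crystal_geom_factors(cr, beam, H)
    keys <- asu_key(ex$h, ex$k, ex$l, "-1")
    I_true <- truth[keys]
    I_true[is.na(I_true)] <- 0
    pred <- gf$kgeom * I_true
    sigma <- sqrt(pmax(pred, 0) + cfg$counting_floor)
    noise_sd <- sqrt(cfg$alpha * sigma^2 + cfg$beta * pred^2)
    I_obs <- pred + stats::rnorm(length(pred), 0, noise_sd)
    is_out <- stats::runif(length(pred)) < cfg$outlier_fraction
    I_obs[is_out] <- stats::rcauchy(sum(is_out), 0, cfg$outlier_gamma)
    out[[i]] <- data.frame(crystal_id = i, h = ex$h, k = ex$k, l = ex$l,
                           intensity = I_obs, sigma = sigma,
                           panel = "sim", fs = 0, ss = 0,
                           truth_pred = pred)
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  tp <- obs$truth_pred
  obs$truth_pred <- NULL
  attr(obs, "truth_pred") <- tp
  obs
}

#' Generate a toy still image with known ground truth
#'
#' [predict_pattern()] output plus a flat background and optional Gaussian
#' pixel noise drawn from the error model.
#'
#' @param crystal,beam,detector,intensities As [predict_pattern()].
#' @param background Flat background level (counts).
#' @param em [error_model()] used for the noise; `NULL` for a noise-free
#'   image.
#' @param seed Integer seed (used only when noise is drawn).
#' @param ... Passed to [predict_pattern()].
#' @return List with `images` (per-panel matrices), `clean` (noise-free
#'   readings) and `background`.
#' @export
generate_toy_image <- function(crystal, beam, detector, intensities,
                               background = 10, em = NULL, seed = 1L,
                               ...) {
  clean <- predict_pattern(crystal, beam, detector, intensities,
                           background = background, ...)
  images <- clean
  if (!is.null(em)) {
    set.seed(seed)
    for (pn in names(images)) {
      r <- clean[[pn]]
      v <- em$alpha * beam$nu0 * pmax(r, 0) + em$beta * r^2
      images[[pn]] <- r + matrix(stats::rnorm(length(r), 0, sqrt(v)),
                                 nrow = nrow(r))
    }
  }
  list(images = images, clean = clean, background = background)
}
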