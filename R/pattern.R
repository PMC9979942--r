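#' Two-parameter error model with outlier mixture
#'
#' Variance of a detector reading is modelled as a counting term scaling
#' linearly with the expected reading (inflated by the per-photon energy
#' spread in polychromatic beams) plus a systematic term scaling
#' quadratically: `alpha * k * reading + beta * reading^2`. Readings are
#' connected to measurements through a mixture of a smoothed Gaussian and a
#' super-heavy-tailed outlier density so that even defective pixels keep a
#' finite log-likelihood.
#'
#' @param alpha Linear (counting) variance coefficient (>= 0). With
#'   `alpha` equal to the detector gain the counting term is the exact
#'   compound-Poisson variance of an integrating detector.
#' @param beta Quadratic (systematic) variance coefficient (>= 0).
#' @param epsilon_outlier Outlier mixture weight in \[0, 1); default 1/16.
#' @param outlier_scale Scale (counts) of the outlier density.
#' @return Object of class `error_model`.
#' @export
error_model <- function(alpha = 1, beta = 0, epsilon_outlier = 1 / 16,
                        outlier_scale = 10) {
  stopifnot(alpha >= 0, beta >= 0, epsilon_outlier >= 0,
            epsilon_outlier < 1, outlier_scale > 0)
  structure(list(alpha = alpha, beta = beta,
                 epsilon_outlier = epsilon_outlier,
                 outlier_scale = outlier_scale),
            class = "error_model")
}

#' Heavy-tailed outlier density for detector readings
#'
#' A smoother relative of the universal-prior-for-integers construction:
#' `o(x) = 1 / (2 s t log(t)^2)` with `t = (|x| + e*s)/s`. The density is
#' symmetric, finite at 0, integrates to exactly 1 (the antiderivative of
#' `1/(t log^2 t)` is `-1/log(t)`), and decays slower than any power, so no
#' finite measurement can drive the mixture likelihood to -Inf.
#'
#' @param x Reading(s) (counts).
#' @param scale Scale parameter s (counts).
#' @return Density value(s).
#' @seealso [outlier_mass()] for the closed-form mass of `|x| <= q`.
#' @export
outlier_density <- function(x, scale = 10) {
  t <- (abs(x) + exp(1) * scale) / scale
  1 / (2 * scale * t * log(t)^2)
}

#' Closed-form central mass of the outlier density
#'
#' @param q Nonnegative half-width (counts).
#' @param scale Scale parameter s (counts).
#' @return `P(|X| <= q) = 1 - 1/log((q + e*s)/s)`.
#' @export
outlier_mass <- function(q, scale = 10) {
  1 - 1 / log((q + exp(1) * scale) / scale)
}

#' Per-pixel prediction container
#'
#' @param expected_reading Expected detector counts.
#' @param variance Reading variance (counts^2), > 0 for finite readings.
#' @param mean_wavenumber Mean photon wavenumber at the pixel (nm^-1).
#' @param wavenumber_var Wavenumber variance (nm^-2, >= 0).
#' @param flux Photon flux reaching the pixel.
#' @return Object of class `pixel_prediction` (fields vectorized).
#' @export
pixel_prediction <- function(expected_reading, variance, mean_wavenumber,
                             wavenumber_var, flux = NA_real_) {
  stopifnot(all(variance > 0 | !is.finite(expected_reading)),
            all(wavenumber_var >= 0))
  structure(list(expected_reading = expected_reading, variance = variance,
                 mean_wavenumber = mean_wavenumber,
                 wavenumber_var = wavenumber_var, flux = flux),
            class = "pixel_prediction")
}

#' Expected detector reading
#'
#' Integrating detectors respond proportionally to the total photon energy:
#' `reading = gain * mean_wavenumber * flux * solid_angle` (counts).
#'
#' @param flux Photon flux density at the pixel.
#' @param mean_wavenumber Mean wavenumber (nm^-1).
#' @param solid_angle Pixel solid angle (sr).
#' @param gain Detector counts per wavenumber per photon.
#' @return Expected counts.
#' @export
expected_reading <- function(flux, mean_wavenumber, solid_angle, gain) {
  gain * mean_wavenumber * flux * solid_angle
}

#' Reading variance from the two-parameter error model
#'
#' `alpha * (mean_wavenumber + wavenumber_var / mean_wavenumber) * reading
#'  + beta * reading^2`. The first factor is `E[nu^2]/E[nu]`, the exact
#' per-photon energy inflation of the compound-Poisson counting variance.
#'
#' @param em An [error_model()].
#' @param reading Expected reading (counts).
#' @param mean_wavenumber,wavenumber_var Per-pixel wavenumber statistics.
#' @return Variance (counts^2).
#' @export
pixel_variance <- function(em, reading, mean_wavenumber, wavenumber_var) {
  em$alpha * (mean_wavenumber + wavenumber_var / mean_wavenumber) *
    pmax(reading, 0) + em$beta * reading^2
}

# variance inflation for sampling a discrete/continuous reading at integer
# counts: the same 1/2-extent rule as the detector point spread
READING_SMOOTH_VAR <- 0.25

#' Log-likelihood of a measured pixel value
#'
#' Mixture of a smoothed Gaussian around the prediction (variance inflated
#' by the discretization term, the 1-D analogue of the detector point
#' spread) and the heavy-tailed outlier density:
#' `log((1-eps) * N(m; r, v + 1/4) + eps * o(m))`. Finite for every finite
#' measurement.
#'
#' @param measured Measured reading(s) (counts).
#' @param pred A [pixel_prediction()] (vectorized fields recycled).
#' @param em An [error_model()].
#' @return Log-likelihood value(s).
#' @export
pixel_loglikelihood <- function(measured, pred, em) {
  v <- pred$variance + READING_SMOOTH_VAR
  eps <- em$epsilon_outlier
  g <- stats::dnorm(measured, pred$expected_reading, sqrt(v))
  log((1 - eps) * g + eps * outlier_density(measured, em$outlier_scale))
}

# --- batched symmetric 3x3 algebra -----------------------------------------
# entries given as vectors (a11, a12, a13, a22, a23, a33); adjugate is
# symmetric for symmetric input
adj3 <- function(a11, a12, a13, a22, a23, a33) {
  A11 <- a22 * a33 - a23^2
  A22 <- a11 * a33 - a13^2
  A33 <- a11 * a22 - a12^2
  A12 <- a13 * a23 - a12 * a33
  A13 <- a12 * a23 - a13 * a22
  A23 <- a12 * a13 - a11 * a23
  list(A11 = A11, A12 = A12, A13 = A13, A22 = A22, A23 = A23, A33 = A33,
       det = a11 * A11 + a12 * A12 + a13 * A13)
}

# bilinear form r' S^-1 s from the adjugate
bilin3 <- function(A, r1, r2, r3, s1, s2, s3) {
  (A$A11 * r1 * s1 + A$A22 * r2 * s2 + A$A33 * r3 * s3 +
     A$A12 * (r1 * s2 + r2 * s1) + A$A13 * (r1 * s3 + r3 * s1) +
     A$A23 * (r2 * s3 + r3 * s2)) / A$det
}

# S^-1 r, componentwise
solve3 <- function(A, r1, r2, r3) {
  list(y1 = (A$A11 * r1 + A$A12 * r2 + A$A13 * r3) / A$det,
       y2 = (A$A12 * r1 + A$A22 * r2 + A$A23 * r3) / A$det,
       y3 = (A$A13 * r1 + A$A23 * r2 + A$A33 * r3) / A$det)
}

# per-pixel incoherent flux integral, mean wavenumber and wavenumber
# variance for one reflection over a set of sampling directions.
# W: n x 3 outgoing directions; sm: optional list of 6 smoothing-covariance
# entry vectors (reciprocal space).
hkl_direction_terms <- function(crystal, beam, hkl, W, sm = NULL) {
  pk <- reciprocal_peak(crystal, hkl)
  x <- pk$mean
  Sp <- pk$cov
  nu0 <- beam$nu0
  win <- beam$w_in
  d1 <- W[, 1] - win[1]; d2 <- W[, 2] - win[2]; d3 <- W[, 3] - win[3]
  bb <- nu0^2 * beam$bandwidth^2
  dv <- nu0^2 * beam$divergence^2
  k11 <- bb * d1^2 + dv * (1 - win[1]^2)
  k22 <- bb * d2^2 + dv * (1 - win[2]^2)
  k33 <- bb * d3^2 + dv * (1 - win[3]^2)
  k12 <- bb * d1 * d2 - dv * win[1] * win[2]
  k13 <- bb * d1 * d3 - dv * win[1] * win[3]
  k23 <- bb * d2 * d3 - dv * win[2] * win[3]
  # residual peak - mean(delta_k)
  r1 <- x[1] - nu0 * d1; r2 <- x[2] - nu0 * d2; r3 <- x[3] - nu0 * d3
  # flux covariance: peak + delta_k (+ smoothing)
  f11 <- Sp[1, 1] + k11; f12 <- Sp[1, 2] + k12; f13 <- Sp[1, 3] + k13
  f22 <- Sp[2, 2] + k22; f23 <- Sp[2, 3] + k23; f33 <- Sp[3, 3] + k33
  if (!is.null(sm)) {
    f11 <- f11 + sm$s11; f12 <- f12 + sm$s12; f13 <- f13 + sm$s13
    f22 <- f22 + sm$s22; f23 <- f23 + sm$s23; f33 <- f33 + sm$s33
  }
  Af <- adj3(f11, f12, f13, f22, f23, f33)
  qf <- bilin3(Af, r1, r2, r3, r1, r2, r3)
  incoh <- exp(-0.5 * pmax(qf, 0)) / ((2 * pi)^1.5 * sqrt(pmax(Af$det, 1e-300)))
  # wavenumber statistics from the product of delta_k and peak kernels
  cw <- W[, 1] * win[1] + W[, 2] * win[2] + W[, 3] * win[3]
  denom <- cw - 1
  if (beam$bandwidth <= 0) {
    nu_bar <- rep(nu0, nrow(W))
    nu_var <- rep(0, nrow(W))
  } else {
    As <- adj3(f11 - if (is.null(sm)) 0 else sm$s11,
               f12 - if (is.null(sm)) 0 else sm$s12,
               f13 - if (is.null(sm)) 0 else sm$s13,
               f22 - if (is.null(sm)) 0 else sm$s22,
               f23 - if (is.null(sm)) 0 else sm$s23,
               f33 - if (is.null(sm)) 0 else sm$s33)
    y <- solve3(As, r1, r2, r3)
    m1 <- nu0 * d1 + k11 * y$y1 + k12 * y$y2 + k13 * y$y3
    m2 <- nu0 * d2 + k12 * y$y1 + k22 * y$y2 + k23 * y$y3
    m3 <- nu0 * d3 + k13 * y$y1 + k23 * y$y2 + k33 * y$y3
    nu_bar <- (m1 * win[1] + m2 * win[2] + m3 * win[3]) / denom
    nu_bar[abs(denom) < 1e-9] <- nu0
    a1 <- k11 * win[1] + k12 * win[2] + k13 * win[3]
    a2 <- k12 * win[1] + k22 * win[2] + k23 * win[3]
    a3 <- k13 * win[1] + k23 * win[2] + k33 * win[3]
    b <- drop(Sp %*% win)
    nu_var <- bilin3(As, a1, a2, a3, b[1], b[2], b[3]) / denom^2
    nu_var[abs(denom) < 1e-9] <- 0
    nu_var <- pmin(pmax(nu_var, 0), nu0^2 * beam$bandwidth^2)
  }
  list(incoh = incoh, nu_bar = nu_bar, nu_var = nu_var)
}

# smoothing covariance entries (reciprocal space) for sampling directions
smoothing_entries <- function(p, fs, ss, nu0, oversample) {
  dd <- direction_derivatives(p, fs, ss)
  sp2 <- (0.5 / oversample)^2 * nu0^2
  a <- dd$d_fs
  b <- dd$d_ss
  list(s11 = sp2 * (a[, 1]^2 + b[, 1]^2),
       s12 = sp2 * (a[, 1] * a[, 2] + b[, 1] * b[, 2]),
       s13 = sp2 * (a[, 1] * a[, 3] + b[, 1] * b[, 3]),
       s22 = sp2 * (a[, 2]^2 + b[, 2]^2),
       s23 = sp2 * (a[, 2] * a[, 3] + b[, 2] * b[, 3]),
       s33 = sp2 * (a[, 3]^2 + b[, 3]^2))
}

hkl_key <- function(h, k, l) paste(h, k, l)

# intensities: data.frame(h, k, l, F2) -> named lookup vector
intensity_lookup <- function(intensities) {
  stopifnot(all(c("h", "k", "l", "F2") %in% names(intensities)))
  stats::setNames(intensities$F2,
                  hkl_key(intensities$h, intensities$k, intensities$l))
}

#' Photon flux density at detector pixels
#'
#' Sum over the excited reflections of `J0 * C * |F|^2` times the
#' incoherent overlap of the diffraction-vector kernel (convolved with the
#' detector point spread) with the reciprocal peak kernel. Returned per
#' steradian; multiply by the pixel solid angle for the per-pixel flux.
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param p A [panel()].
#' @param fs,ss Pixel indices (vectors allowed).
#' @param intensities `data.frame` with columns `h`, `k`, `l`, `F2`
#'   (structure-factor moduli squared, >= 0).
#' @param excited Optional precomputed excited-reflection `data.frame`
#'   (from [excited_reflections()]); computed if `NULL`.
#' @param sigma_cutoff,d_min Passed to [excited_reflections()].
#' @param smoothing Apply the analytic detector point spread?
#' @param oversample Sub-pixel oversampling factor.
#' @param missing How to treat an excited reflection without an intensity:
#'   `"skip"` (with a warning) or `"error"`.
#' @return Vector of flux densities, one per pixel.
#' @export
pixel_flux <- function(crystal, beam, p, fs, ss, intensities,
                       excited = NULL, sigma_cutoff = 4, d_min = 0.4,
                       smoothing = TRUE, oversample = 1L,
                       missing = c("skip", "error")) {
  missing <- match.arg(missing)
  stopifnot(all(intensities$F2 >= 0))
  if (is.null(excited)) {
    excited <- excited_reflections(crystal, beam, sigma_cutoff, d_min)
  }
  lk <- intensity_lookup(intensities)
  W <- pixel_direction(p, fs, ss)
  if (!is.matrix(W)) W <- matrix(W, ncol = 3L)
  sm <- if (smoothing) {
    smoothing_entries(p, fs, ss, beam$nu0, oversample)
  } else {
    NULL
  }
  C <- polarization_factor(beam, W)
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(excited))) {
    key <- hkl_key(excited$h[i], excited$k[i], excited$l[i])
    F2 <- if (key %in% names(lk)) lk[[key]] else NA_real_
    if (is.na(F2)) {
      if (missing == "error") stop("no intensity for reflection ", key)
      warning("no intensity for reflection ", key, "; skipped")
      next
    }
    hk <- c(excited$h[i], excited$k[i], excited$l[i])
    terms <- hkl_direction_terms(crystal, beam, hk, W, sm)
    out <- out + beam$flux * C * F2 * terms$incoh
  }
  out
}

#' Mean wavenumber of photons reaching a pixel from one reflection
#'
#' The radial (beam-collinear) component of the mean of the joint (product)
#' distribution of the diffraction-vector and peak kernels, rescaled by the
#' shear factor `1/(cos(2 theta) - 1)` of the correlated-difference
#' geometry. Reduces to `nu0` for a monochromatic beam.
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param w_out Unit outgoing direction (e.g. from [pixel_direction()]).
#' @param hkl Miller index.
#' @return Mean wavenumber (nm^-1).
#' @export
expected_wavenumber <- function(crystal, beam, w_out, hkl) {
  W <- matrix(as.numeric(w_out), ncol = 3L)
  hkl_direction_terms(crystal, beam, hkl, W)$nu_bar
}

#' Wavenumber variance at a pixel from one reflection
#'
#' Projected variance of the product kernel on the incident beam direction
#' with the same rescaling as [expected_wavenumber()]; 0 for a
#' monochromatic beam and never larger than the source variance
#' `nu0^2 bandwidth^2`.
#'
#' @inheritParams expected_wavenumber
#' @return Variance (nm^-2).
#' @export
wavenumber_variance <- function(crystal, beam, w_out, hkl) {
  W <- matrix(as.numeric(w_out), ncol = 3L)
  hkl_direction_terms(crystal, beam, hkl, W)$nu_var
}

# --- pattern assembly -------------------------------------------------------

# footprint of one reflection on one panel: centre pixel coordinates and a
# bounding box of ellipse_sigma Mahalanobis radii (in pixel units), or NULL
# if the diffracted ray misses the panel
reflection_footprint <- function(crystal, beam, p, hkl, ellipse_sigma) {
  pk <- reciprocal_peak(crystal, hkl)
  v <- pk$mean + beam$nu0 * beam$w_in
  r <- sqrt(sum(v^2))
  if (r < 1e-12) return(NULL)
  w0 <- v / r
  A <- cbind(p$D, -w0)
  sol <- tryCatch(solve(A, -p$origin), error = function(e) NULL)
  if (is.null(sol) || sol[3] <= 0) return(NULL)
  fs0 <- sol[1]
  ss0 <- sol[2]
  dk <- delta_k_kernel(beam, w0)
  Sig <- pk$cov + dk$cov + beam$nu0^2 *
    smoothing_covariance(p, fs0 - 0.5, ss0 - 0.5)
  dd <- direction_derivatives(p, fs0 - 0.5, ss0 - 0.5)
  J <- beam$nu0 * cbind(as.numeric(dd$d_fs), as.numeric(dd$d_ss))
  M <- t(J) %*% solve(Sig, J)
  C2 <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(C2)) return(NULL)
  hw <- ellipse_sigma * sqrt(pmax(diag(C2), 0)) + 1
  lo_fs <- floor(fs0 - hw[1]); hi_fs <- ceiling(fs0 + hw[1])
  lo_ss <- floor(ss0 - hw[2]); hi_ss <- ceiling(ss0 + hw[2])
  if (hi_fs < 0 || lo_fs > p$n_fs - 1 || hi_ss < 0 || lo_ss > p$n_ss - 1) {
    return(NULL)
  }
  list(fs = max(lo_fs, 0):min(hi_fs, p$n_fs - 1L),
       ss = max(lo_ss, 0):min(hi_ss, p$n_ss - 1L),
       centre = c(fs0, ss0))
}

# model bases for a pattern: for each panel and excited reflection, the
# footprint pixel indices, the reading contribution per unit scale at B = 0
# (J0 C F2 incoh g nu_bar Omega), and |x|^2; plus the per-pixel energy
# factor k = E[nu^2]/E[nu] aggregated with flux weights.
pattern_model_bases <- function(crystal, beam, detector, intensities,
                                sigma_cutoff = 4, d_min = 0.4,
                                ellipse_sigma = 4, smoothing = TRUE,
                                oversample = 1L, excited = NULL) {
  if (is.null(excited)) {
    excited <- excited_reflections(crystal, beam, sigma_cutoff, d_min)
  }
  lk <- intensity_lookup(intensities)
  os <- as.integer(oversample)
  sub <- (seq_len(os) - (os + 1) / 2) / os
  panels <- detector$panels
  out <- vector("list", length(panels))
  names(out) <- names(panels)
  for (pn in names(panels)) {
    p <- panels[[pn]]
    npix <- p$n_fs * p$n_ss
    wsum <- numeric(npix)
    nsum <- numeric(npix)
    esum <- numeric(npix)
    entries <- list()
    for (i in seq_len(nrow(excited))) {
      hk <- c(excited$h[i], excited$k[i], excited$l[i])
      key <- hkl_key(hk[1], hk[2], hk[3])
      F2 <- if (key %in% names(lk)) lk[[key]] else NA_real_
      if (is.na(F2)) next
      fp <- reflection_footprint(crystal, beam, p, hk, ellipse_sigma)
      if (is.null(fp)) next
      g <- expand.grid(fs = fp$fs, ss = fp$ss)
      # oversampled sampling positions, averaged back per pixel
      gg <- expand.grid(ofs = sub, oss = sub)
      fs_s <- rep(g$fs, each = nrow(gg)) + rep(gg$ofs, times = nrow(g))
      ss_s <- rep(g$ss, each = nrow(gg)) + rep(gg$oss, times = nrow(g))
      W <- pixel_direction(p, fs_s, ss_s)
      if (!is.matrix(W)) W <- matrix(W, ncol = 3L)
      sm <- if (smoothing) {
        smoothing_entries(p, fs_s, ss_s, beam$nu0, os)
      } else {
        NULL
      }
      terms <- hkl_direction_terms(crystal, beam, hk, W, sm)
      C <- polarization_factor(beam, W)
      Om <- solid_angle(p, fs_s, ss_s)
      contrib <- beam$flux * C * F2 * terms$incoh * p$gain *
        terms$nu_bar * Om
      grp <- rep(seq_len(nrow(g)), each = nrow(gg))
      base <- as.numeric(rowsum(contrib, grp)) / nrow(gg)
      flx <- as.numeric(rowsum(beam$flux * C * F2 * terms$incoh, grp)) /
        nrow(gg)
      nb <- as.numeric(rowsum(beam$flux * C * F2 * terms$incoh *
                                terms$nu_bar, grp)) / nrow(gg)
      e2 <- as.numeric(rowsum(beam$flux * C * F2 * terms$incoh *
                                (terms$nu_bar^2 + terms$nu_var), grp)) /
        nrow(gg)
      idx <- g$fs + p$n_fs * g$ss + 1L
      wsum[idx] <- wsum[idx] + flx
      nsum[idx] <- nsum[idx] + nb
      esum[idx] <- esum[idx] + e2
      x <- reciprocal_position(crystal, hk)
      entries[[length(entries) + 1L]] <-
        list(idx = idx, base = base, q = sum(x^2))
    }
    k_energy <- rep(beam$nu0, npix)
    hit <- wsum > 0
    k_energy[hit] <- (esum[hit] / wsum[hit]) / (nsum[hit] / wsum[hit])
    out[[pn]] <- list(entries = entries, k_energy = k_energy,
                      n_fs = p$n_fs, n_ss = p$n_ss)
  }
  out
}

# assemble expected readings from bases for given scale/B
assemble_readings <- function(bases, scale_a, b_factor, background) {
  out <- list()
  for (pn in names(bases)) {
    b <- bases[[pn]]
    r <- numeric(b$n_fs * b$n_ss)
    for (e in b$entries) {
      r[e$idx] <- r[e$idx] + exp(-b_factor * e$q / 2) * e$base
    }
    r <- scale_a * r
    bg <- if (is.list(background)) as.numeric(background[[pn]]) else background
    out[[pn]] <- matrix(r + bg, nrow = b$n_fs, ncol = b$n_ss)
  }
  out
}

#' Predict a full still diffraction pattern
#'
#' Expected detector readings for every pixel: the excited reflections are
#' found by region growing, each is projected onto the detector, and only
#' pixels inside the `ellipse_sigma` Mahalanobis ellipse of a reflection
#' are touched; all other pixels contain only background.
#'
#' @param crystal A [crystal_model()] (its `scale_a` and `b_factor` scale
#'   the pattern).
#' @param beam A [beam_model()].
#' @param detector A [detector_geometry()].
#' @param intensities `data.frame(h, k, l, F2)`.
#' @param background Scalar or named list of per-panel matrices (counts).
#' @param sigma_cutoff,d_min Excitation cutoffs.
#' @param ellipse_sigma Mahalanobis radius of the projected footprint.
#' @param smoothing,oversample Detector point-spread controls.
#' @return Named list of `n_fs x n_ss` matrices of expected readings.
#' @export
predict_pattern <- function(crystal, beam, detector, intensities,
                            background = 0, sigma_cutoff = 4, d_min = 0.4,
                            ellipse_sigma = 4, smoothing = TRUE,
                            oversample = 1L) {
  bases <- pattern_model_bases(crystal, beam, detector, intensities,
                               sigma_cutoff, d_min, ellipse_sigma,
                               smoothing, oversample)
  assemble_readings(bases, crystal$scale_a, crystal$b_factor, background)
}

# pack/unpack the free parameters of fit_pattern; positive quantities are
# log-parameterized
FIT_PARAMS <- c("scale_a", "b_factor", "alpha", "beta", "mosaicity", "strain")

pack_fit_params <- function(crystal, em, free) {
  full <- c(scale_a = log(crystal$scale_a), b_factor = crystal$b_factor,
            alpha = log(max(em$alpha, 1e-12)),
            beta = log(max(em$beta, 1e-12)),
            mosaicity = log(max(crystal$mosaicity, 1e-9)),
            strain = log(max(crystal$strain, 1e-9)))
  full[free]
}

unpack_fit_params <- function(theta, crystal, em, free) {
  get <- function(nm, dflt) if (nm %in% free) theta[[nm]] else dflt
  cr <- crystal
  cr$scale_a <- exp(get("scale_a", log(crystal$scale_a)))
  cr$b_factor <- get("b_factor", crystal$b_factor)
  cr$mosaicity <- exp(get("mosaicity", log(max(crystal$mosaicity, 1e-9))))
  cr$strain <- exp(get("strain", log(max(crystal$strain, 1e-9))))
  e2 <- em
  e2$alpha <- exp(get("alpha", log(max(em$alpha, 1e-12))))
  e2$beta <- exp(get("beta", log(max(em$beta, 1e-12))))
  list(crystal = cr, em = e2)
}

# total pattern log-likelihood given bases; returns gradient pieces needed
# for the analytic derivatives w.r.t. scale_a, b_factor, alpha, beta
pattern_loglik_core <- function(bases, images, background, scale_a,
                                b_factor, em, want_grad = FALSE) {
  ll <- 0
  grad <- c(scale_a = 0, b_factor = 0, alpha = 0, beta = 0)
  for (pn in names(bases)) {
    b <- bases[[pn]]
    npix <- b$n_fs * b$n_ss
    t_p <- numeric(npix)
    u_p <- numeric(npix)
    for (e in b$entries) {
      eb <- exp(-b_factor * e$q / 2) * e$base
      t_p[e$idx] <- t_p[e$idx] + eb
      u_p[e$idx] <- u_p[e$idx] + (e$q / 2) * eb
    }
    bg <- if (is.list(background)) as.numeric(background[[pn]]) else background
    r <- scale_a * t_p + bg
    k <- b$k_energy
    v <- em$alpha * k * pmax(r, 0) + em$beta * r^2 + READING_SMOOTH_VAR
    m <- as.numeric(images[[pn]])
    eps <- em$epsilon_outlier
    gdens <- stats::dnorm(m, r, sqrt(v))
    dens <- (1 - eps) * gdens + eps * outlier_density(m, em$outlier_scale)
    ll <- ll + sum(log(dens))
    if (want_grad) {
      z <- m - r
      dll_dr <- (1 - eps) * gdens * (z / v) / dens
      dll_dv <- (1 - eps) * gdens * ((z^2 / v - 1) / (2 * v)) / dens
      dv_dr <- em$alpha * k * (r > 0) + 2 * em$beta * r
      bracket <- dll_dr + dll_dv * dv_dr
      grad["scale_a"] <- grad["scale_a"] + sum(bracket * t_p)
      grad["b_factor"] <- grad["b_factor"] -
        scale_a * sum(bracket * u_p)
      grad["alpha"] <- grad["alpha"] + sum(dll_dv * k * pmax(r, 0))
      grad["beta"] <- grad["beta"] + sum(dll_dv * r^2)
    }
  }
  if (want_grad) list(ll = ll, grad = grad) else ll
}

#' Pattern log-likelihood and analytic scaling gradients
#'
#' Total pixel log-likelihood of measured images under the model, plus the
#' analytic gradient with respect to the scaling-side parameters (linear
#' scale, B factor, error-model alpha and beta). Gradients for the
#' geometry-side parameters are obtained by finite differences inside
#' [fit_pattern()].
#'
#' @param crystal,beam,detector,intensities,background As in
#'   [predict_pattern()].
#' @param images Named list of measured panel matrices.
#' @param em An [error_model()].
#' @param sigma_cutoff,d_min,ellipse_sigma,smoothing,oversample Prediction
#'   controls.
#' @param bases Optional precomputed output of the internal base builder
#'   (reused across evaluations that share the geometry).
#' @return List with `ll` and `grad` (named vector: `scale_a`, `b_factor`,
#'   `alpha`, `beta`; derivatives w.r.t. the natural, untransformed
#'   parameters).
#' @export
pattern_loglik <- function(crystal, beam, detector, images, intensities,
                           background = 0, em = error_model(),
                           sigma_cutoff = 4, d_min = 0.4,
                           ellipse_sigma = 4, smoothing = TRUE,
                           oversample = 1L, bases = NULL) {
  if (is.null(bases)) {
    bases <- pattern_model_bases(crystal, beam, detector, intensities,
                                 sigma_cutoff, d_min, ellipse_sigma,
                                 smoothing, oversample)
  }
  pattern_loglik_core(bases, images, background, crystal$scale_a,
                      crystal$b_factor, em, want_grad = TRUE)
}

#' Fit model parameters to a measured pattern
#'
#' Local maximum-likelihood refinement of the per-image parameters against
#' pixel values, starting from `crystal`/`em`. Scaling-side parameters use
#' the analytic gradient of [pattern_loglik()]; mosaicity and strain (when
#' freed) are refined with central finite differences, which requires
#' rebuilding the Gaussian model each step. Parameters not listed in
#' `free` are held fixed. The optimizer is BFGS with positive parameters
#' log-transformed; convergence is local -- initial values must lie within
#' the basin of the optimum.
#'
#' @inheritParams pattern_loglik
#' @param free Character vector from `scale_a`, `b_factor`, `alpha`,
#'   `beta`, `mosaicity`, `strain`.
#' @param maxit Maximum BFGS iterations.
#' @return List with `crystal`, `em` (refined), `loglik`, `counts`,
#'   `convergence`.
#' @export
fit_pattern <- function(images, crystal, beam, detector, intensities,
                        background = 0, em = error_model(),
                        free = c("scale_a", "b_factor", "alpha", "beta"),
                        sigma_cutoff = 4, d_min = 0.4, ellipse_sigma = 4,
                        smoothing = TRUE, oversample = 1L, maxit = 200L) {
  free <- match.arg(free, FIT_PARAMS, several.ok = TRUE)
  geom_free <- intersect(free, c("mosaicity", "strain"))
  theta0 <- pack_fit_params(crystal, em, free)
  base_cache <- new.env(parent = emptyenv())
  get_bases <- function(cr) {
    key <- paste(format(cr$mosaicity, digits = 17),
                 format(cr$strain, digits = 17))
    if (is.null(base_cache[[key]])) {
      base_cache[[key]] <- pattern_model_bases(
        cr, beam, detector, intensities, sigma_cutoff, d_min,
        ellipse_sigma, smoothing, oversample)
    }
    base_cache[[key]]
  }
  nll <- function(theta) {
    th <- stats::setNames(theta, names(theta0))
    st <- unpack_fit_params(as.list(th), crystal, em, free)
    v <- pattern_loglik_core(get_bases(st$crystal), images, background,
                             st$crystal$scale_a, st$crystal$b_factor,
                             st$em)
    if (!is.finite(v)) return(1e12)
    -v
  }
  v0 <- pattern_loglik_core(get_bases(crystal), images, background,
                            crystal$scale_a, crystal$b_factor, em)
  if (!is.finite(v0)) {
    bad <- character(0)
    for (pn in names(images)) {
      nf <- which(!is.finite(images[[pn]]))
      if (length(nf)) {
        bad <- c(bad, paste0(pn, "[", nf[seq_len(min(5, length(nf)))],
                             "]"))
      }
    }
    stop("non-finite likelihood at the starting parameters; ",
         "offending pixels: ",
         if (length(bad)) paste(bad, collapse = ", ") else "(model)")
  }
  gr <- function(theta) {
    th <- stats::setNames(theta, names(theta0))
    st <- unpack_fit_params(as.list(th), crystal, em, free)
    res <- pattern_loglik_core(get_bases(st$crystal), images, background,
                               st$crystal$scale_a, st$crystal$b_factor,
                               st$em, want_grad = TRUE)
    g <- numeric(length(theta))
    names(g) <- names(theta0)
    # chain rule through the log transforms
    if ("scale_a" %in% free) {
      g["scale_a"] <- -res$grad["scale_a"] * st$crystal$scale_a
    }
    if ("b_factor" %in% free) g["b_factor"] <- -res$grad["b_factor"]
    if ("alpha" %in% free) g["alpha"] <- -res$grad["alpha"] * st$em$alpha
    if ("beta" %in% free) g["beta"] <- -res$grad["beta"] * st$em$beta
    for (nm in geom_free) {
      h <- 1e-4
      tp <- theta; tp[names(theta0) == nm] <- th[[nm]] + h
      tm <- theta; tm[names(theta0) == nm] <- th[[nm]] - h
      g[nm] <- (nll(tp) - nll(tm)) / (2 * h)
    }
    g
  }
  opt <- stats::optim(theta0, nll, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  st <- unpack_fit_params(as.list(stats::setNames(opt$par, names(theta0))),
                          crystal, em, free)
  list(crystal = st$crystal, em = st$em, loglik = -opt$value,
       counts = opt$counts, convergence = opt$convergence)
}
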