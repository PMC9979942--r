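beam_std <- beam_model(wavelength = 0.13, bandwidth = 0.01,
                       divergence = 1e-4, polarization_p = 0.9)

test_that("pixel flux vanishes without intensity and peaks on the spot", {
  fx <- on_sphere_fixture(beam_std, mosaicity = 4e-3)
  ex <- data.frame(h = 1, k = 0, l = 0)
  zero <- data.frame(h = 1, k = 0, l = 0, F2 = 0)
  f0 <- pixel_flux(fx$crystal, beam_std, fx$panel, 95:105, rep(100, 11),
                   zero, excited = ex)
  expect_equal(f0, rep(0, 11))
  # flux is maximal at the predicted centre over a 5x5 neighbourhood
  F2 <- data.frame(h = 1, k = 0, l = 0, F2 = 100)
  g <- expand.grid(fs = 97:102, ss = 97:102)
  f <- pixel_flux(fx$crystal, beam_std, fx$panel, g$fs, g$ss, F2,
                  excited = ex)
  ctr <- which.max(f)
  expect_true(abs(g$fs[ctr] - 99.5) <= 1.5 && abs(g$ss[ctr] - 99.5) <= 1.5)
  # reading is linear in F2, flux and gain
  f2 <- pixel_flux(fx$crystal, beam_std, fx$panel, g$fs, g$ss,
                   transform(F2, F2 = 200), excited = ex)
  expect_equal(f2, 2 * f, tolerance = 1e-12)
})

test_that("per-pixel wavenumber statistics match rejection sampling", {
  mono <- beam_model(wavelength = 0.13, bandwidth = 0,
                     divergence = 1e-4)
  fx <- on_sphere_fixture(mono)
  w <- pixel_direction(fx$panel, 104, 99)
  expect_equal(expected_wavenumber(fx$crystal, mono, w, c(1, 0, 0)),
               mono$nu0)
  expect_equal(wavenumber_variance(fx$crystal, mono, w, c(1, 0, 0)), 0)
  # polychromatic beam, peak displaced radially: the mean shifts toward
  # the wavelength satisfying Bragg for the displaced peak
  beam <- beam_model(wavelength = 0.13, bandwidth = 0.02, divergence = 0)
  fx2 <- on_sphere_fixture(beam, theta = 0.3, mosaicity = 2e-3)
  w0 <- fx2$w
  pk <- reciprocal_peak(fx2$crystal, c(1, 0, 0))
  set.seed(31)
  nu <- beam$nu0 * (1 + 0.02 * rnorm(4e5))
  dk <- nu %o% w0 - nu %o% beam$w_in
  wgt <- kernel_evaluate(pk, dk)
  nu_bar_mc <- sum(wgt * nu) / sum(wgt)
  nu_var_mc <- sum(wgt * (nu - nu_bar_mc)^2) / sum(wgt)
  nu_bar <- expected_wavenumber(fx2$crystal, beam, w0, c(1, 0, 0))
  nu_var <- wavenumber_variance(fx2$crystal, beam, w0, c(1, 0, 0))
  expect_equal(nu_bar, nu_bar_mc, tolerance = 0.005)
  expect_equal(nu_var, nu_var_mc, tolerance = 0.02 * nu_var_mc +
                 0.02 * beam$nu0^2 * 4e-4)
  # conditioning can only narrow the source distribution
  expect_lte(nu_var, beam$nu0^2 * 0.02^2)
})

test_that("readings are energy-weighted and the variance is compound", {
  expect_equal(expected_reading(0, 7.7, 1e-6, 2), 0)
  expect_equal(expected_reading(5, 7.7, 1e-6, 4),
               2 * expected_reading(5, 7.7, 1e-6, 2))
  # photon-sampling oracle for the counting variance of an integrating
  # detector: reading = gain * sum of photon wavenumbers
  set.seed(32)
  gain <- 3
  nu0 <- 7.7
  bw <- 0.03
  n_mean <- 40
  reps <- 4e4
  n <- rpois(reps, n_mean)
  reading <- vapply(n, function(ni) {
    gain * sum(rnorm(ni, nu0, nu0 * bw))
  }, numeric(1))
  em <- error_model(alpha = gain, beta = 0)
  v <- pixel_variance(em, mean(reading), nu0, (nu0 * bw)^2)
  expect_equal(var(reading), v, tolerance = 0.03)
  # monochromatic limit: pure scaled Poisson
  em2 <- error_model(alpha = gain, beta = 0)
  expect_equal(pixel_variance(em2, 100, nu0, 0), gain * nu0 * 100)
  # alpha = 0: constant relative error sqrt(beta)
  em3 <- error_model(alpha = 0, beta = 4e-4)
  expect_equal(sqrt(pixel_variance(em3, 50, nu0, 0)) / 50, 0.02)
})

test_that("the pixel mixture likelihood is proper and heavy-tailed", {
  em <- error_model(alpha = 1, beta = 1e-3, epsilon_outlier = 1 / 16,
                    outlier_scale = 10)
  pred <- pixel_prediction(50, 60, 7.7, 0)
  ll_at <- function(m) pixel_loglikelihood(m, pred, em)
  # the prediction maximizes the likelihood over measured values
  ms <- seq(0, 100, by = 0.5)
  expect_equal(ms[which.max(ll_at(ms))], 50, tolerance = 1)
  # an extreme outlier keeps a finite bounded log-likelihood
  extreme <- 50 + 1e6 * sqrt(60)
  expect_gt(ll_at(extreme),
            log(em$epsilon_outlier * outlier_density(extreme, 10)) - 1e-9)
  expect_true(is.finite(ll_at(-1e8)))
  # normalization: grid mass plus the closed-form outlier tail
  grid <- seq(-2000, 3000, by = 0.25)
  mass <- sum(exp(ll_at(grid))) * 0.25 +
    em$epsilon_outlier *
      (1 - (outlier_mass(3000 - 0, 10) + outlier_mass(2000, 10)) / 2)
  expect_equal(mass, 1, tolerance = 1e-3)
  # the outlier density integrates to 1 by its closed-form antiderivative
  expect_equal(outlier_mass(0, 10), 0)
  expect_equal(outlier_mass(Inf, 10), 1)
  dmass <- integrate(outlier_density, -50, 50, scale = 10)$value
  expect_equal(dmass, outlier_mass(50, 10), tolerance = 1e-6)
})

test_that("patterns contain background only outside projected ellipses", {
  fx <- on_sphere_fixture(beam_std, mosaicity = 3e-3)
  empty <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                      F2 = numeric(0))
  img <- predict_pattern(fx$crystal, beam_std, fx$detector, empty,
                         background = 7, d_min = 0.2)
  expect_equal(img[[1]], matrix(7, 200, 200))
  # a recorded reflection deposits >= 99% of its flux inside 4 sigma
  F2 <- data.frame(h = 1, k = 0, l = 0, F2 = 100)
  in4 <- sum(predict_pattern(fx$crystal, beam_std, fx$detector, F2, 0,
                             d_min = 0.2, ellipse_sigma = 4)[[1]])
  in8 <- sum(predict_pattern(fx$crystal, beam_std, fx$detector, F2, 0,
                             d_min = 0.2, ellipse_sigma = 8)[[1]])
  expect_gt(in4 / in8, 0.99)
})

test_that("pink-beam peaks elongate radially with increasing bandwidth", {
  elong <- vapply(c(0.005, 0.02, 0.05), function(bw) {
    beam <- beam_model(wavelength = 0.13, bandwidth = bw,
                       divergence = 1e-4)
    fx <- on_sphere_fixture(beam, theta = 0.35, mosaicity = 1e-3)
    F2 <- data.frame(h = 1, k = 0, l = 0, F2 = 100)
    img <- predict_pattern(fx$crystal, beam, fx$detector, F2, 0,
                           d_min = 0.2, ellipse_sigma = 6)[[1]]
    g <- expand.grid(fs = seq_len(nrow(img)) - 1,
                     ss = seq_len(ncol(img)) - 1)
    w <- as.vector(img)
    mfs <- sum(w * g$fs) / sum(w)
    mss <- sum(w * g$ss) / sum(w)
    cfs <- sum(w * (g$fs - mfs)^2) / sum(w)
    css <- sum(w * (g$ss - mss)^2) / sum(w)
    cxy <- sum(w * (g$fs - mfs) * (g$ss - mss)) / sum(w)
    ev <- eigen(matrix(c(cfs, cxy, cxy, css), 2))$values
    sqrt(ev[1] / ev[2])
  }, numeric(1))
  expect_true(all(diff(elong) > 0))
  expect_gt(elong[3], 2)
})

test_that("analytic scaling gradients match finite differences", {
  set.seed(33)
  fx <- on_sphere_fixture(beam_std, mosaicity = 3e-3, npix = 100L)
  cr <- fx$crystal
  cr$scale_a <- 2
  cr$b_factor <- 0.15
  F2 <- data.frame(h = 1, k = 0, l = 0, F2 = 100)
  em <- error_model(alpha = 2, beta = 1e-4)
  toy <- generate_toy_image(cr, beam_std, fx$detector, F2, background = 5,
                            em = em, seed = 7, d_min = 0.2)
  ll <- pattern_loglik(cr, beam_std, fx$detector, toy$images, F2,
                       background = 5, em = em, d_min = 0.2)
  num <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
  ll_with <- function(cr2, em2) {
    pattern_loglik(cr2, beam_std, fx$detector, toy$images, F2,
                   background = 5, em = em2, d_min = 0.2)$ll
  }
  g_a <- num(function(v) { c2 <- cr; c2$scale_a <- v; ll_with(c2, em) },
             cr$scale_a, 1e-5)
  g_b <- num(function(v) { c2 <- cr; c2$b_factor <- v; ll_with(c2, em) },
             cr$b_factor, 1e-6)
  g_al <- num(function(v) { e2 <- em; e2$alpha <- v; ll_with(cr, e2) },
              em$alpha, 1e-5)
  g_be <- num(function(v) { e2 <- em; e2$beta <- v; ll_with(cr, e2) },
              em$beta, 1e-8)
  expect_equal(unname(ll$grad["scale_a"]), g_a, tolerance = 1e-5)
  expect_equal(unname(ll$grad["b_factor"]), g_b, tolerance = 1e-5)
  expect_equal(unname(ll$grad["alpha"]), g_al, tolerance = 1e-5)
  expect_equal(unname(ll$grad["beta"]), g_be, tolerance = 1e-5)
})

test_that("refitting a noiseless self-generated image recovers the truth", {
  # many reflections across resolution: scale and B factor are then both
  # identifiable (a single spot only constrains their product)
  set.seed(34)
  cr <- rand_crystal(mosaicity = 4e-3, strain = 5e-4,
                     shape_sigma = 2e-3)
  cr$scale_a <- 2
  cr$b_factor <- 0.1
  p <- panel(D = cbind(c(1e-4, 0, 0), c(0, 1e-4, 0)),
             origin = c(-0.01, -0.01, 0.08), n_fs = 200, n_ss = 200)
  fx <- list(detector = detector_geometry(p))
  ex <- excited_reflections(cr, beam_std, 4, 0.4)
  F2 <- data.frame(h = ex$h, k = ex$k, l = ex$l, F2 = 100)
  # weak error model: the variance-model shift of the noiseless optimum
  # is then far below the recovery tolerance
  em <- error_model(alpha = 1e-4, beta = 1e-8)
  clean <- predict_pattern(cr, beam_std, fx$detector, F2, background = 5,
                           d_min = 0.4)
  start <- cr
  start$scale_a <- cr$scale_a * 1.02
  start$b_factor <- cr$b_factor * 0.98
  fit <- fit_pattern(clean, start, beam_std, fx$detector, F2,
                     background = 5, em = em,
                     free = c("scale_a", "b_factor"), d_min = 0.4)
  expect_equal(fit$crystal$scale_a, cr$scale_a, tolerance = 1e-3)
  expect_equal(fit$crystal$b_factor, cr$b_factor, tolerance = 1e-3)
  # masked parameters are untouched
  expect_equal(fit$crystal$mosaicity, cr$mosaicity)
  expect_identical(fit$em$epsilon_outlier, em$epsilon_outlier)
  # a non-finite start is refused
  bad <- clean
  bad[[1]][1, 1] <- NaN
  expect_error(fit_pattern(bad, start, beam_std, fx$detector, F2,
                           background = 5, em = em, d_min = 0.4),
               "non-finite")
})
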