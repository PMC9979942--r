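beam_pk <- beam_model(wavelength = 0.13, bandwidth = 0.01,
                      divergence = 1e-4)

test_that("the optimal direction is stationary and geometric", {
  fx <- on_sphere_fixture(beam_pk, mosaicity = 2e-3)
  wm <- optimal_direction(fx$crystal, beam_pk, c(1, 0, 0))
  expect_lt(attr(wm, "grad_norm"), 1e-8)
  # on-sphere peak: w_max is the direction through the peak (up to the
  # slow direction dependence of the diffraction-vector covariance)
  want <- (fx$x + beam_pk$nu0 * beam_pk$w_in)
  want <- want / sqrt(sum(want^2))
  expect_lt(sqrt(sum((as.numeric(wm) - want)^2)), 1e-4)
  expect_error(optimal_direction(fx$crystal, beam_pk, c(0, 0, 0)),
               "direct beam")
  # slightly off-sphere isotropic peak: the maximum lies along the
  # closest approach to the sphere
  set.seed(41)
  beam_iso <- beam_model(wavelength = 0.13, bandwidth = 0,
                         divergence = 0)
  cr <- rand_crystal(mosaicity = 0, strain = 0)
  ex <- excited_reflections(cr, beam_iso, 2, 0.4)
  hkl <- as.numeric(ex[1, c("h", "k", "l")])
  x <- reciprocal_position(cr, hkl)
  v <- x + beam_iso$nu0 * beam_iso$w_in
  w_ca <- v / sqrt(sum(v^2))
  wm2 <- optimal_direction(cr, beam_iso, hkl)
  expect_lt(acos(min(1, sum(as.numeric(wm2) * w_ca))), 1e-6)
  # symmetric configuration: x in the xz plane keeps w_max in it
  expect_lt(abs(as.numeric(wm)[2]), 1e-9)
})

test_that("the integrated factor matches dense angular quadrature", {
  set.seed(42)
  for (rep in 1:6) {
    bw <- runif(1, 0, 0.05)
    mos <- runif(1, 0, 0.5) * pi / 180
    beam <- beam_model(wavelength = 0.13, bandwidth = bw,
                       divergence = 1e-4)
    cr <- rand_crystal(mosaicity = mos, strain = 5e-4)
    ex <- excited_reflections(cr, beam, 2, 0.4)
    if (nrow(ex) == 0) next
    hkl <- as.numeric(ex[sample(nrow(ex), 1), c("h", "k", "l")])
    wm <- optimal_direction(cr, beam, hkl)
    fac <- integrated_intensity_factor(cr, beam, hkl, as.numeric(wm))
    quad <- angular_quadrature_factor(cr, beam, hkl, as.numeric(wm))
    expect_equal(fac / quad, 1, tolerance = 0.02)
  }
})

test_that("the factor is maximal on the slab and decays off it", {
  beam <- beam_pk
  fx <- on_sphere_fixture(beam, mosaicity = 2e-3)
  f0 <- integrated_intensity_factor(fx$crystal, beam, c(1, 0, 0))
  # small rigid rotations of the crystal can only decrease the factor
  for (ang in c(2e-3, -3e-3, 5e-3)) {
    Q <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0),
               c(-sin(ang), 0, cos(ang)))
    cr2 <- fx$crystal
    cr2$R <- Q %*% fx$crystal$R
    expect_lt(integrated_intensity_factor(cr2, beam, c(1, 0, 0)), f0)
  }
  # ten projected sigmas off the slab the factor is negligible
  x <- fx$x
  st <- stillgauss:::ewald_offset_stats(fx$crystal, beam, matrix(x, 1))
  sig <- sqrt(st$sig2[1])
  u <- (x + beam$nu0 * beam$w_in)
  u <- u / sqrt(sum(u^2))
  cr3 <- fx$crystal
  cr3$R[, 1] <- x + 10 * sig * u   # ten projected sigmas off the slab
  expect_lt(integrated_intensity_factor(cr3, beam, c(1, 0, 0)),
            1e-20 * f0)
})

test_that("predicted intensities scale physically", {
  beam <- beam_model(wavelength = 0.13, bandwidth = 0.01,
                     divergence = 1e-4, flux = 3)
  fx <- on_sphere_fixture(beam, mosaicity = 2e-3)
  cr <- fx$crystal
  fac <- integrated_intensity_factor(cr, beam, c(1, 0, 0))
  nu <- reflection_wavenumber_stats(cr, beam, c(1, 0, 0))
  w <- fx$x + beam$nu0 * beam$w_in
  w <- w / sqrt(sum(w^2))
  want <- 3 * 100 * polarization_factor(beam, w) * fac * 2 * nu$mean
  expect_equal(predicted_intensity(cr, beam, c(1, 0, 0), F2 = 100,
                                   gain = 2),
               want, tolerance = 1e-6)
  # linear in F2 and in the crystal scale
  expect_equal(predicted_intensity(cr, beam, c(1, 0, 0), 200),
               2 * predicted_intensity(cr, beam, c(1, 0, 0), 100))
  cr2 <- cr
  cr2$scale_a <- 5
  expect_equal(predicted_intensity(cr2, beam, c(1, 0, 0), 100),
               5 * predicted_intensity(cr, beam, c(1, 0, 0), 100))
  # B decay: doubling |x| quadruples the exponent argument
  cr3 <- cr
  cr3$b_factor <- 0.3
  q1 <- sum(fx$x^2)
  r1 <- predicted_intensity(cr3, beam, c(1, 0, 0), 100) /
    predicted_intensity(cr, beam, c(1, 0, 0), 100)
  expect_equal(r1, exp(-0.3 * q1 / 2), tolerance = 1e-9)
})

test_that("integrated predictions agree with frame summation", {
  # cross-module consistency: the closed-form reading of an isolated
  # reflection matches the pixel-wise frame sum within 2%
  for (bw in c(0.002, 0.02, 0.05)) {
    beam <- beam_model(wavelength = 0.13, bandwidth = bw,
                       divergence = 1e-4)
    fx <- on_sphere_fixture(beam, theta = 0.3, mosaicity = 3e-3,
                            pixel = 6e-5, npix = 300L)
    F2 <- data.frame(h = 1, k = 0, l = 0, F2 = 100)
    frame <- sum(predict_pattern(fx$crystal, beam, fx$detector, F2, 0,
                                 d_min = 0.2, ellipse_sigma = 6)[[1]])
    pred <- predicted_intensity(fx$crystal, beam, c(1, 0, 0), 100,
                                gain = 1)
    expect_equal(pred / frame, 1, tolerance = 0.02)
  }
})

test_that("partiality is a normalized orientation ratio", {
  beam <- beam_pk
  fx <- on_sphere_fixture(beam, mosaicity = 2e-3)
  p_on <- partiality(fx$crystal, beam, c(1, 0, 0))
  expect_equal(as.numeric(p_on), 1, tolerance = 1e-6)
  # monotone decay with radial offset
  x <- fx$x
  offs <- c(1.001, 1.003, 1.01, 1.03)
  ps <- vapply(offs, function(s) {
    cr <- fx$crystal
    cr$R[, 1] <- x * s
    as.numeric(partiality(cr, beam, c(1, 0, 0)))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1 + 1e-9))
  # unreachable reflections are flagged
  cr_far <- crystal_model(R = diag(3) * beam$nu0)
  p_far <- partiality(cr_far, beam, c(3, 0, 0))
  expect_equal(as.numeric(p_far), 0)
  expect_true(attr(p_far, "unreachable"))
  # invariant under a simultaneous rigid rotation of the whole setup
  set.seed(43)
  cr <- rand_crystal()
  H <- as.matrix(excited_reflections(cr, beam, 3, 0.4)[, c("h", "k", "l")])
  p1 <- partiality(cr, beam, H)
  ang <- 0.7
  Q <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))  # rotation about the beam axis
  cr2 <- cr
  cr2$R <- Q %*% cr$R
  p2 <- partiality(cr2, beam, H)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-9)
  # mirror symmetry across a plane containing the beam axis (the beam
  # is rotationally symmetric about w_in when unpolarized)
  M <- diag(c(-1, 1, 1))
  crm <- cr
  crm$R <- M %*% cr$R
  f1 <- predict_reflections(cr, beam, H)
  f2 <- predict_reflections(crm, beam, H)
  expect_equal(f1$factor, f2$factor, tolerance = 1e-9)
  expect_equal(f1$partiality, f2$partiality, tolerance = 1e-9)
})

test_that("partialities over random orientations pile up at 0 and near 1", {
  set.seed(44)
  beam <- beam_model(wavelength = 0.13, bandwidth = 5e-3,
                     divergence = 1e-4)
  ps <- numeric(0)
  hmax <- 16
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax,
                             l = -hmax:hmax))
  g <- g[rowSums(g^2) > 0 & rowSums((g / 8)^2) <= (1 / 0.5)^2, ]
  for (rep in 1:12) {
    cr <- rand_crystal()
    ps <- c(ps, as.numeric(partiality(cr, beam, g)))
  }
  h <- hist(ps, breaks = seq(0, 1, by = 0.05), plot = FALSE)$counts
  expect_equal(which.max(h), 1L)       # global mode at zero
  expect_gt(h[20], h[19])              # faint pile-up against 1
})
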