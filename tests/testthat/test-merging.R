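# small shared fixture: a handful of crystals with noise-free or lightly
# noisy observations built through the package's own forward model
small_sim <- function(n_crystals = 6, seed = 51, noisy = TRUE,
                      outliers = 0) {
  cfg <- simulation_config(n_crystals = n_crystals, d_min = 0.5,
                           outlier_fraction = outliers,
                           alpha = if (noisy) 1 else 0,
                           beta = if (noisy) 1e-3 else 0,
                           seed = seed)
  beam <- simulation_beam(cfg)
  crystals <- simulate_crystals(cfg)
  truth <- simulate_truth_intensities(cfg)
  obs <- simulate_observations(crystals, beam, truth, cfg)
  list(cfg = cfg, beam = beam, crystals = crystals, truth = truth,
       obs = obs)
}

test_that("asu keys merge Friedel pairs lexicographically", {
  expect_identical(asu_key(1, -2, 3), asu_key(-1, 2, -3))
  expect_identical(asu_key(0, 0, -4), "0 0 4")
  expect_false(asu_key(1, 2, 3, laue = "1") == asu_key(-1, -2, -3,
                                                       laue = "1"))
  expect_identical(asu_key(c(1, -1), c(2, -2), c(3, -3)),
                   c("1 2 3", "1 2 3"))
})

test_that("the observation mixture is proper, robust and responsive", {
  s <- small_sim(2)
  state <- merge_state(s$crystals, s$beam,
                       stats::setNames(500, "1 0 0"), gamma = 300)
  one <- data.frame(crystal_id = 1L, h = 1, k = 0, l = 0,
                    intensity = 0, sigma = 10)
  # normalization on a transformed grid plus the Cauchy tail mass
  grid <- seq(-2e4, 2e4, by = 1)
  dens <- vapply(c(-5e3, 0, 5e3), function(shift) 0, numeric(1))
  obs_grid <- one[rep(1, length(grid)), ]
  obs_grid$intensity <- grid
  d <- exp(observation_loglikelihood(obs_grid, state))
  tail_mass <- state$epsilon *
    (1 - (atan(2e4 / state$gamma) * 2 / pi))
  expect_equal(sum(d) * 1 + tail_mass, 1, tolerance = 1e-3)
  # a million-count outlier is bounded below by the Cauchy floor
  one$intensity <- 1e6
  ll <- observation_loglikelihood(one, state)
  expect_gte(ll, log(state$epsilon * dcauchy(1e6, 0, state$gamma)) - 1e-9)
  expect_true(is.finite(observation_loglikelihood(
    transform(one, intensity = -1e8), state)))
})

test_that("noise-free observations at the truth are a fixed point", {
  s <- small_sim(4, noisy = FALSE)
  res <- merge_intensities(s$obs, s$beam, s$crystals,
                           merge_config(max_outer = 3, beta = 1e-6))
  st <- res$state
  # trace is monotone and parameters stay at the generating values
  expect_true(all(diff(res$trace) >= -1e-9 * abs(res$trace[-1])))
  mos <- vapply(st$crystals, function(c) c$mosaicity, numeric(1))
  expect_equal(unname(mos), rep(s$cfg$mosaicity, 4), tolerance = 0.02)
  # exactness holds on reflections carrying real information; a single
  # noise-free observation at partiality ~0.01 is still (correctly)
  # vetoed by the Wilson prior
  mt <- merged_table(st, s$obs)
  mk <- asu_key(mt$h, mt$k, mt$l)
  keep <- mt$sigma_merged <= 5 & mk %in% names(s$truth)
  expect_gt(sum(keep), 200)
  expect_gt(cor(mt$I_merged[keep], s$truth[mk[keep]]), 0.999)
  # measured partialities of noise-free data equal the model partiality
  d <- res$diagnostics
  ok <- is.finite(d$partiality_measured) & d$partiality_model > 0.1 &
    asu_key(d$h, d$k, d$l) %in% mk[keep]
  expect_equal(d$partiality_measured[ok], d$partiality_model[ok],
               tolerance = 0.02)
})

test_that("with gaussian errors and known geometry the merge is weighted
           least squares", {
  s <- small_sim(6, noisy = TRUE, outliers = 0)
  # epsilon ~ 0, beta = 0: the block update solves precision-weighted LS
  res <- merge_intensities(s$obs, s$beam, s$crystals,
                           merge_config(free = "scale_a",
                                        epsilon = 1e-12, beta = 1e-12,
                                        gamma = 1000, max_outer = 4))
  st <- res$state
  keys <- asu_key(s$obs$h, s$obs$k, s$obs$l)
  kg <- numeric(nrow(s$obs))
  for (cid in unique(s$obs$crystal_id)) {
    r <- which(s$obs$crystal_id == cid)
    kg[r] <- stillgauss:::crystal_geom_factors(
      st$crystals[[cid]], st$beam,
      as.matrix(s$obs[r, c("h", "k", "l")]))$kgeom
  }
  w <- 1 / (st$alpha * s$obs$sigma^2 + 0.25)
  num <- tapply(w * kg * s$obs$intensity, keys, sum)
  den <- tapply(w * kg^2, keys, sum)
  ls <- pmax(num / den, 0)
  # compare on reflections where the data dominate the weak prior
  strong <- names(which(den > 5e-3))
  expect_gt(length(strong), 50)
  expect_equal(unname(st$intensities[strong]),
               as.numeric(ls[strong]), tolerance = 5e-3)
})

test_that("merging is invariant under observation permutation and gauge", {
  s <- small_sim(4, seed = 53)
  cfgm <- merge_config(max_outer = 2)
  res1 <- merge_intensities(s$obs, s$beam, s$crystals, cfgm)
  perm <- sample(nrow(s$obs))
  res2 <- merge_intensities(s$obs[perm, ], s$beam, s$crystals, cfgm)
  keys <- sort(names(res1$state$intensities))
  expect_equal(res1$state$intensities[keys],
               res2$state$intensities[keys], tolerance = 1e-8)
  # gauge: the mean linear scale is pinned at 1, and rescaling scales and
  # intensities in opposition leaves every observation's likelihood alone
  st <- res1$state
  expect_equal(mean(vapply(st$crystals[unique(s$obs$crystal_id)],
                           function(c) c$scale_a, numeric(1))), 1,
               tolerance = 1e-9)
  st2 <- st
  for (i in seq_along(st2$crystals)) {
    st2$crystals[[i]]$scale_a <- st2$crystals[[i]]$scale_a / 3
  }
  st2$intensities <- st2$intensities * 3
  expect_equal(observation_loglikelihood(s$obs, st),
               observation_loglikelihood(s$obs, st2), tolerance = 1e-10)
})

test_that("the Monte Carlo baseline is the per-reflection mean", {
  obs <- data.frame(crystal_id = c(1, 1, 2, 3),
                    h = c(1, 2, -1, 1), k = c(0, 1, 0, 0),
                    l = c(0, 0, 0, 0),
                    intensity = c(10, 7, 20, 30), sigma = 1)
  mc <- monte_carlo_merge(obs)
  expect_equal(mc$I_merged[mc$h == 1 & mc$k == 0 & mc$l == 0], 20)
  expect_equal(mc$n_obs[mc$h == 1 & mc$k == 0 & mc$l == 0], 3L)
  expect_equal(mc$I_merged[mc$h == 2], 7)
})

test_that("the merged table flags unmeasured reflections as absent", {
  s <- small_sim(4, seed = 54)
  res <- merge_intensities(s$obs, s$beam, s$crystals,
                           merge_config(max_outer = 2))
  full <- merged_table(res$state, s$obs)
  meas <- merged_table(res$state, s$obs, well_measured_only = TRUE)
  expect_lt(nrow(meas), nrow(full))
  expect_true(all(c("h", "k", "l", "I_merged", "sigma_merged",
                    "n_obs") %in% names(full)))
  expect_true(all(meas$sigma_merged <= max(res$state$prior_mean) / 8))
})
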