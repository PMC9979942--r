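#' Map Miller indices to asymmetric-unit keys
#'
#' Symmetry reduction used when merging. `laue = "-1"` merges Friedel
#' pairs (the Laue group of a P1 cell): the representative of
#' \{(h,k,l), (-h,-k,-l)\} is the lexicographically larger triple.
#' `laue = "1"` applies no reduction.
#'
#' @param h,k,l Integer vectors.
#' @param laue `"-1"` (default) or `"1"`.
#' @return Character vector of asu keys (`"h k l"`).
#' @export
asu_key <- function(h, k, l, laue = c("-1", "1")) {
  laue <- match.arg(laue)
  if (laue == "1") return(paste(h, k, l))
  flip <- (h < 0) | (h == 0 & k < 0) | (h == 0 & k == 0 & l < 0)
  paste(ifelse(flip, -h, h), ifelse(flip, -k, k), ifelse(flip, -l, l))
}

# per-observation geometry factor of one crystal: a * exp(-B q/2) * C * p
# (and its partiality-free part for measured partialities)
crystal_geom_factors <- function(crystal, beam, H, mosaicity = NULL,
                                 strain = NULL, scale_a = NULL,
                                 b_factor = NULL) {
  a <- if (is.null(scale_a)) crystal$scale_a else scale_a
  B <- if (is.null(b_factor)) crystal$b_factor else b_factor
  X <- reciprocal_position(crystal, H)
  st <- ewald_offset_stats(crystal, beam, X, mosaicity, strain)
  p <- exp(-st$delta^2 / (2 * st$sig2))
  p[sqrt(st$s2) > 2 * beam$nu0] <- 0
  C <- polarization_factor(beam, st$u)
  scale_part <- a * exp(-B * st$s2 / 2) * C
  list(kgeom = scale_part * p, scale_part = scale_part, p = p, q = st$s2)
}

#' Merge state: per-crystal models plus global parameters
#'
#' @param crystals Named or indexed list of [crystal_model()] objects.
#' @param beam Shared [beam_model()] (held fixed during merging except for
#'   the optional global bandwidth scale).
#' @param intensities Named numeric vector of merged intensities (asu keys
#'   from [asu_key()]), all >= 0.
#' @param alpha,beta Global error-model coefficients.
#' @param epsilon Outlier mixture weight in \[0, 1); default 1/16.
#' @param gamma Cauchy outlier scale (counts).
#' @param laue Symmetry used for the asu mapping.
#' @return Object of class `merge_state`.
#' @export
merge_state <- function(crystals, beam, intensities, alpha = 1,
                        beta = 1e-3, epsilon = 1 / 16, gamma = 100,
                        laue = "-1") {
  stopifnot(all(intensities >= 0), epsilon >= 0, epsilon < 1, gamma > 0)
  structure(list(crystals = crystals, beam = beam,
                 intensities = intensities, alpha = alpha, beta = beta,
                 epsilon = epsilon, gamma = gamma, laue = laue),
            class = "merge_state")
}

#' @export
print.merge_state <- function(x, ...) {
  cat(sprintf(
    "Merge state: %d crystals, %d merged intensities\n",
    length(x$crystals), length(x$intensities)))
  cat(sprintf("  alpha = %.4g, beta = %.4g, epsilon = %.4g, gamma = %.4g\n",
              x$alpha, x$beta, x$epsilon, x$gamma))
  invisible(x)
}

# predicted intensity and variance for observation rows of one crystal
predict_obs <- function(state, cid, H, keys, sigma) {
  gf <- crystal_geom_factors(state$crystals[[cid]], state$beam, H)
  I_h <- state$intensities[keys]
  I_h[is.na(I_h)] <- 0
  pred <- gf$kgeom * I_h
  var <- obs_variance(state$alpha, state$beta, sigma, pred)
  list(pred = pred, var = var, kgeom = gf$kgeom,
       scale_part = gf$scale_part, p = gf$p)
}

# reflection-level variance: two-parameter error model plus the
# discretization inflation of sampling a counts-valued reading (the 1-D
# analogue of the detector point spread); the floor also keeps the
# Gaussian component proper, removing the classic variance-collapse
# degeneracy of mixture likelihoods
obs_variance <- function(alpha, beta, sigma, pred) {
  alpha * sigma^2 + beta * pred^2 + READING_SMOOTH_VAR
}

mixture_loglik <- function(I, pred, var, epsilon, gamma) {
  g <- stats::dnorm(I, pred, sqrt(var))
  log((1 - epsilon) * g + epsilon * stats::dcauchy(I, 0, gamma))
}

#' Log-likelihood of observations under a merge state
#'
#' Mixture of a Gaussian around the predicted intensity (two-parameter
#' error model variance, with the counting sigma from integration and the
#' quadratic term on the predicted intensity) and a Cauchy outlier
#' distribution centred at zero. Finite for every finite intensity,
#' including large negatives -- the slow asymptotic decay of the outlier
#' component is what makes the maximum-likelihood merge robust.
#'
#' @param observations `data.frame` with columns `crystal_id, h, k, l,
#'   intensity, sigma`.
#' @param state A [merge_state()].
#' @return Vector of per-observation log-likelihoods.
#' @export
observation_loglikelihood <- function(observations, state) {
  out <- numeric(nrow(observations))
  keys_all <- asu_key(observations$h, observations$k, observations$l,
                      state$laue)
  for (cid in unique(observations$crystal_id)) {
    rows <- which(observations$crystal_id == cid)
    H <- as.matrix(observations[rows, c("h", "k", "l")])
    pr <- predict_obs(state, cid, H, keys_all[rows],
                      observations$sigma[rows])
    out[rows] <- mixture_loglik(observations$intensity[rows], pr$pred,
                                pr$var, state$epsilon, state$gamma)
  }
  out
}

#' Measured partialities
#'
#' Observed intensity divided by the predicted fully-recorded intensity
#' (`a exp(-B q/2) C I_merged`) of the same reflection; may leave \[0, 1\]
#' because of noise.
#'
#' @inheritParams observation_loglikelihood
#' @return Numeric vector (NA where the merged intensity is absent or 0).
#' @export
measured_partiality <- function(observations, state) {
  out <- rep(NA_real_, nrow(observations))
  keys_all <- asu_key(observations$h, observations$k, observations$l,
                      state$laue)
  for (cid in unique(observations$crystal_id)) {
    rows <- which(observations$crystal_id == cid)
    H <- as.matrix(observations[rows, c("h", "k", "l")])
    gf <- crystal_geom_factors(state$crystals[[cid]], state$beam, H)
    I_h <- state$intensities[keys_all[rows]]
    denom <- gf$scale_part * I_h
    ok <- !is.na(denom) & denom > 0
    out[rows[ok]] <- observations$intensity[rows][ok] / denom[ok]
  }
  out
}

#' Monte Carlo merging baseline
#'
#' Plain per-reflection arithmetic mean of the observed intensities -- the
#' classical serial-crystallography baseline that the partiality-corrected
#' maximum-likelihood merge is compared against.
#'
#' @param observations `data.frame` with columns `h, k, l, intensity`.
#' @param laue Symmetry for the asu mapping.
#' @return `data.frame` with columns `h, k, l, I_merged, n_obs`.
#' @export
monte_carlo_merge <- function(observations, laue = "-1") {
  key <- asu_key(observations$h, observations$k, observations$l, laue)
  dt <- data.table::data.table(akey = key, I = observations$intensity)
  agg <- dt[, list(I_merged = mean(I), n_obs = .N), by = "akey"]
  hkl <- do.call(rbind, strsplit(agg$akey, " ", fixed = TRUE))
  data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
             l = as.integer(hkl[, 3]), I_merged = agg$I_merged,
             n_obs = agg$n_obs)
}

#' Control settings for [merge_intensities()]
#'
#' @param free Per-crystal parameters refined in the crystal block; subset
#'   of `mosaicity`, `strain`, `scale_a`, `b_factor`.
#' @param refine_bandwidth Refine a global source bandwidth scale? Note
#'   that per-crystal strain and the global bandwidth are exactly
#'   degenerate in the projected slab width (both contribute
#'   `x^4/(4 nu0^2)` radially), so bandwidth refinement is only
#'   meaningful with `strain` removed from `free`.
#' @param profile_bandwidth_iters Outer iterations that use the wide
#'   profile search for the bandwidth (later iterations use a narrow
#'   local profile).
#' @param refine_gamma Refit the Cauchy scale each outer iteration?
#' @param epsilon Outlier probability (default 1/16).
#' @param gamma Cauchy scale; `NULL` fits it from the pooled intensity
#'   histogram at start.
#' @param alpha,beta Error-model initials.
#' @param max_outer Maximum outer iterations.
#' @param tol Relative likelihood-change stopping tolerance.
#' @param intensity_floor Small positive floor for merged intensities.
#' @param min_obs Minimum observations per crystal for the crystal block.
#' @param laue Symmetry for the asu mapping.
#' @return List of class `merge_config`.
#' @export
merge_config <- function(free = c("mosaicity", "strain", "scale_a",
                                  "b_factor"),
                         refine_bandwidth = FALSE,
                         profile_bandwidth_iters = 4L,
                         refine_gamma = FALSE,
                         epsilon = 1 / 16, gamma = NULL, alpha = 1,
                         beta = 1e-3, max_outer = 12L, tol = 1e-6,
                         intensity_floor = 1e-8, min_obs = 8L,
                         laue = "-1") {
  free <- match.arg(free, c("mosaicity", "strain", "scale_a", "b_factor"),
                    several.ok = TRUE)
  structure(list(free = free, refine_bandwidth = refine_bandwidth,
                 profile_bandwidth_iters =
                   as.integer(profile_bandwidth_iters),
                 refine_gamma = refine_gamma, epsilon = epsilon,
                 gamma = gamma, alpha = alpha, beta = beta,
                 max_outer = as.integer(max_outer), tol = tol,
                 intensity_floor = intensity_floor,
                 min_obs = as.integer(min_obs), laue = laue),
            class = "merge_config")
}

# ML fit of the Cauchy scale to the pooled intensities
fit_cauchy_scale <- function(I) {
  f <- function(lg) -sum(stats::dcauchy(I, 0, exp(lg), log = TRUE))
  exp(stats::optimize(f, c(log(1e-3), log(max(abs(I)) + 1)))$minimum)
}

#' Maximum-likelihood merging of integrated still intensities
#'
#' Joint local maximization of the mixture likelihood over merged
#' intensities, per-crystal disorder and scaling parameters, and the
#' global error model, by alternating blocks:
#' (1) per-crystal quasi-Newton refinement of the free parameters;
#' (2) gauge fixing (mean linear scale held at 1 by rescaling the merged
#' intensities, which leaves the likelihood invariant);
#' (3) closed-form responsibility-weighted least-squares update of each
#' merged intensity under a weak acentric-Wilson (exponential) intensity
#' prior -- its per-resolution-shell means are estimated robustly from the
#' data once, before iteration -- accepted per reflection only if the
#' exact penalized objective improves; (4) refinement of alpha/beta
#' (optionally the global bandwidth scale and Cauchy scale). Every block
#' accepts a change only if the objective does not decrease, so the outer
#' iteration is monotone. Stops when the relative objective change falls
#' below `config$tol`. The Wilson prior regularizes sparsely observed
#' reflections: without it, a single heavy-tailed outlier on a reflection
#' observed once is best explained by an arbitrarily large merged
#' intensity.
#'
#' @param observations `data.frame` with columns `crystal_id, h, k, l,
#'   intensity, sigma` (a counting sigma > 0 per observation); negative
#'   intensities are retained -- they constrain the fit.
#' @param beam Shared [beam_model()].
#' @param crystals List of initial [crystal_model()] objects indexed by
#'   `crystal_id` (cells from indexing).
#' @param config A [merge_config()].
#' @param verbose Print the likelihood trace?
#' @return List with `state` (a [merge_state()]), `trace` (the penalized
#'   objective per outer iteration), and `diagnostics` (per-observation `data.frame`
#'   with predicted intensity, model and measured partiality, and Gaussian
#'   responsibility).
#' @export
merge_intensities <- function(observations, beam, crystals,
                              config = merge_config(), verbose = FALSE) {
  stopifnot(all(observations$sigma > 0))
  obs <- observations
  cids <- unique(obs$crystal_id)
  if (!all(as.character(cids) %in% c(as.character(seq_along(crystals)),
                                     names(crystals)))) {
    stop("every crystal_id must index into `crystals`")
  }
  keys <- asu_key(obs$h, obs$k, obs$l, config$laue)
  rows_by_cid <- split(seq_len(nrow(obs)), obs$crystal_id)
  H_by_cid <- lapply(rows_by_cid, function(r) {
    as.matrix(obs[r, c("h", "k", "l")])
  })
  gamma <- if (is.null(config$gamma)) {
    fit_cauchy_scale(obs$intensity)
  } else {
    config$gamma
  }
  b_gauge <- mean(vapply(crystals[unique(obs$crystal_id)],
                         function(c) c$b_factor, numeric(1)))
  state <- merge_state(crystals, beam, numeric(0), config$alpha,
                       config$beta, config$epsilon, gamma, config$laue)

  kg <- numeric(nrow(obs))       # cached geometry factors
  refresh_kgeom <- function(cid) {
    r <- rows_by_cid[[as.character(cid)]]
    gf <- crystal_geom_factors(state$crystals[[cid]], state$beam,
                               H_by_cid[[as.character(cid)]])
    kg[r] <<- gf$kgeom
  }
  for (cid in cids) refresh_kgeom(cid)

  # Wilson intensity prior: exponential (acentric) with per-resolution-
  # shell means estimated once, robustly (trimmed mean of per-observation
  # fully-recorded estimates), before the loop. The prior regularizes
  # sparsely observed reflections -- without it a single heavy-tailed
  # outlier on a singleton reflection is best explained by an arbitrarily
  # large merged intensity (the quadratic variance term makes large
  # predictions cheap), a hijack basin the local optimization must avoid.
  q_obs <- numeric(nrow(obs))
  for (cid in cids) {
    r <- rows_by_cid[[as.character(cid)]]
    X <- reciprocal_position(state$crystals[[cid]],
                             H_by_cid[[as.character(cid)]])
    q_obs[r] <- rowSums(X^2)
  }
  n_shell <- 10L
  shell_breaks <- stats::quantile(q_obs, probs = seq(0, 1,
                                                     length.out = n_shell + 1))
  shell_breaks[1] <- -Inf
  shell_breaks[n_shell + 1] <- Inf
  shell_of_obs <- findInterval(q_obs, shell_breaks,
                               rightmost.closed = TRUE)
  ratio <- ifelse(kg > 1e-4, obs$intensity / pmax(kg, 1e-4), NA_real_)
  shell_mean <- vapply(seq_len(n_shell), function(s) {
    v <- ratio[shell_of_obs == s & is.finite(ratio)]
    if (!length(v)) return(1)
    max(mean(v, trim = 0.1), 1e-6)
  }, numeric(1))
  dtm <- data.table::data.table(akey = keys, s = shell_of_obs, q = q_obs)
  asu_shell <- dtm[, list(s = s[1], q = mean(q)), by = "akey"]
  prior_mean <- stats::setNames(shell_mean[asu_shell$s], asu_shell$akey)
  q_asu <- stats::setNames(asu_shell$q, asu_shell$akey)

  # initial intensities: prior-penalized weighted least squares with the
  # counting variance, capped at a few prior means (strong reflections
  # recover in the first update; outlier singletons must not start in the
  # hijack basin)
  v0 <- obs_variance(state$alpha, state$beta, obs$sigma, 0)
  dt <- data.table::data.table(akey = keys, I = obs$intensity, kg = kg,
                               w = 1 / v0)
  init <- dt[, list(v = {
    den <- sum(w * kg^2)
    if (den > 0) sum(w * kg * I) / den else 0
  }), by = "akey"]
  iv <- stats::setNames(init$v, init$akey)
  iv <- pmin(iv, 8 * prior_mean[names(iv)])
  state$intensities <- pmax(iv, config$intensity_floor)

  prior_ll <- function() {
    -sum(state$intensities / prior_mean[names(state$intensities)])
  }
  total_ll <- function() {
    pred <- kg * state$intensities[keys]
    var <- obs_variance(state$alpha, state$beta, obs$sigma, pred)
    sum(mixture_loglik(obs$intensity, pred, var, state$epsilon,
                       state$gamma)) + prior_ll()
  }

  # merged-intensity update: responsibility-weighted least squares with
  # the exponential-prior shift, accepted per reflection only where the
  # exact penalized objective improves. Cheap and vectorized, so it is
  # interleaved after every other block -- the intensities and the
  # geometry parameters sit on a strongly coupled ridge and must move
  # together for the alternating scheme to converge at a useful rate.
  # per-asu objective sums for a candidate intensity vector
  asu_objective <- function(I_cand) {
    pred <- kg * I_cand[keys]
    var <- obs_variance(state$alpha, state$beta, obs$sigma, pred)
    row <- mixture_loglik(obs$intensity, pred, var, state$epsilon,
                          state$gamma)
    dl <- data.table::data.table(akey = keys, d = row)
    agg <- dl[, list(d = sum(d)), by = "akey"]
    stats::setNames(agg$d, agg$akey) -
      I_cand[agg$akey] / prior_mean[agg$akey]
  }

  intensity_block <- function(sweeps = 1L, rich = TRUE) {
    for (s in seq_len(sweeps)) {
      pred <- kg * state$intensities[keys]
      var <- obs_variance(state$alpha, state$beta, obs$sigma, pred)
      g <- stats::dnorm(obs$intensity, pred, sqrt(var))
      resp <- (1 - state$epsilon) * g /
        ((1 - state$epsilon) * g +
           state$epsilon * stats::dcauchy(obs$intensity, 0, state$gamma))
      dt <- data.table::data.table(akey = keys, I = obs$intensity,
                                   kg = kg, w = resp / pmax(var, 1e-300))
      upd <- dt[, list(num = sum(w * kg * I), den = sum(w * kg^2)),
                by = "akey"]
      I_ls <- stats::setNames(
        ifelse(upd$den > 0, upd$num / pmax(upd$den, 1e-300), 0),
        upd$akey)
      shift <- 1 / (prior_mean[names(I_ls)] * pmax(upd$den, 1e-300))
      I_ls <- pmax(I_ls - shift, config$intensity_floor)
      # robust direct candidate: median of I/kgeom over informative
      # observations. The responsibility-weighted update alone can freeze
      # (a reflection far below its true intensity gives its own
      # observations responsibility ~0), so each sweep also proposes this
      # responsibility-free estimate and keeps whichever candidate
      # maximizes the exact penalized objective per reflection.
      if (rich) {
        med <- dt[, list(v = {
          ok <- kg > 0.2 * max(kg)
          if (any(ok)) stats::median(I[ok] / kg[ok]) else 0
        }), by = "akey"]
        # single-observation ratio candidates from the three most
        # informative (largest-kgeom) observations: a corrupted
        # high-partiality observation must not be able to own the median
        rt <- dt[, {
          o <- order(-kg)[seq_len(min(3L, .N))]
          o <- o[kg[o] > 0.05]
          v <- if (length(o)) I[o] / kg[o] else numeric(0)
          list(r1 = if (length(v) >= 1) v[1] else NA_real_,
               r2 = if (length(v) >= 2) v[2] else NA_real_,
               r3 = if (length(v) >= 3) v[3] else NA_real_)
        }, by = "akey"]
      }
      obj_cur <- asu_objective(state$intensities)
      best_obj <- obj_cur
      best_val <- state$intensities
      consider <- function(vals, akeys) {
        cand <- state$intensities
        cand[akeys] <- pmax(vals, config$intensity_floor)
        obj <- asu_objective(cand)
        win <- names(which(obj > best_obj))
        best_val[win] <<- cand[win]
        best_obj[win] <<- obj[win]
      }
      consider(I_ls, names(I_ls))
      if (rich) {
        consider(stats::setNames(med$v, med$akey), med$akey)
        for (cc in c("r1", "r2", "r3")) {
          ok <- !is.na(rt[[cc]])
          if (any(ok)) consider(stats::setNames(rt[[cc]][ok],
                                                rt$akey[ok]),
                                rt$akey[ok])
        }
      }
      changed <- sum(best_val != state$intensities)
      state$intensities <<- best_val
      if (!changed) break
    }
  }

  ll <- total_ll()
  trace <- ll
  for (outer in seq_len(config$max_outer)) {
    # ---- global bandwidth scale (before the crystal block, so that the
    # per-crystal mosaicities cannot first absorb a bandwidth error).
    # The merged intensities co-adapt with the bandwidth, so a fixed-
    # intensity 1-D search stalls on the shared ridge: the early
    # iterations instead maximize the *profile* objective, re-updating
    # the intensities for every candidate bandwidth. ----
    if (config$refine_bandwidth) {
      lb0 <- log(max(state$beam$bandwidth, 1e-6))
      snap_I <- state$intensities
      snap_kg <- kg
      prof_bw <- function(lbw, keep = FALSE) {
        state$beam$bandwidth <<- exp(lbw)
        for (cid in cids) refresh_kgeom(cid)
        intensity_block(2L, rich = FALSE)
        v <- total_ll()
        if (!keep) {
          state$beam$bandwidth <<- exp(lb0)
          state$intensities <<- snap_I
          kg <<- snap_kg
        }
        v
      }
      if (outer <= config$profile_bandwidth_iters) {
        ob <- stats::optimize(prof_bw, lb0 + c(-0.8, 0.8),
                              maximum = TRUE, tol = 0.02)
        if (ob$objective >= prof_bw(lb0)) prof_bw(ob$maximum, keep = TRUE)
      } else {
        ob <- stats::optimize(prof_bw, lb0 + c(-0.2, 0.2),
                              maximum = TRUE, tol = 0.005)
        if (ob$objective >= prof_bw(lb0)) prof_bw(ob$maximum, keep = TRUE)
      }
    }
    # ---- per-crystal block ----
    for (cid in cids) {
      r <- rows_by_cid[[as.character(cid)]]
      if (length(r) < config$min_obs) next
      H <- H_by_cid[[as.character(cid)]]
      I_h <- state$intensities[keys[r]]
      I_h[is.na(I_h)] <- 0
      Iobs <- obs$intensity[r]
      s2 <- obs$sigma[r]^2
      cr <- state$crystals[[cid]]
      th0 <- c(mosaicity = log(max(cr$mosaicity, 1e-9)),
               strain = log(max(cr$strain, 1e-9)),
               scale_a = log(cr$scale_a), b_factor = cr$b_factor)
      th0 <- th0[config$free]
      obj <- function(th) {
        th <- stats::setNames(th, config$free)
        gf <- crystal_geom_factors(
          cr, state$beam, H,
          mosaicity = if ("mosaicity" %in% config$free) {
            exp(th[["mosaicity"]])
          },
          strain = if ("strain" %in% config$free) exp(th[["strain"]]),
          scale_a = if ("scale_a" %in% config$free) {
            exp(th[["scale_a"]])
          },
          b_factor = if ("b_factor" %in% config$free) th[["b_factor"]])
        pred <- gf$kgeom * I_h
        var <- obs_variance(state$alpha, state$beta, sqrt(s2), pred)
        v <- sum(mixture_loglik(Iobs, pred, var, state$epsilon,
                                state$gamma))
        if (!is.finite(v)) -1e12 else v
      }
      op <- stats::optim(th0, obj, method = "BFGS",
                         control = list(fnscale = -1, maxit = 40,
                                        reltol = 1e-10))
      if (op$value >= obj(th0)) {
        th <- stats::setNames(op$par, config$free)
        if ("mosaicity" %in% config$free) {
          cr$mosaicity <- exp(th[["mosaicity"]])
        }
        if ("strain" %in% config$free) cr$strain <- exp(th[["strain"]])
        if ("scale_a" %in% config$free) cr$scale_a <- exp(th[["scale_a"]])
        if ("b_factor" %in% config$free) cr$b_factor <- th[["b_factor"]]
        state$crystals[[cid]] <- cr
        refresh_kgeom(cid)
      }
    }
    # ---- gauge: mean scale factor to 1 ----
    # the prior means live on the same intensity scale, so they are
    # rescaled too and the penalized objective is exactly invariant
    if ("scale_a" %in% config$free) {
      s <- mean(vapply(state$crystals[cids], function(c) c$scale_a,
                       numeric(1)))
      for (cid in cids) {
        state$crystals[[cid]]$scale_a <- state$crystals[[cid]]$scale_a / s
        refresh_kgeom(cid)
      }
      state$intensities <- state$intensities * s
      prior_mean <- prior_mean * s
    }
    # ---- gauge: mean B factor held at its initial mean ----
    # a shared shift of all B factors trades exactly against the
    # resolution-dependent factor exp(dB q / 2) on the merged
    # intensities; pinning the mean removes the drift along this flat
    # direction (intensities and prior rescaled so predictions and the
    # penalized objective are exactly invariant)
    if ("b_factor" %in% config$free) {
      dB <- mean(vapply(state$crystals[cids], function(c) c$b_factor,
                        numeric(1))) - b_gauge
      if (abs(dB) > 0) {
        for (cid in cids) {
          state$crystals[[cid]]$b_factor <-
            state$crystals[[cid]]$b_factor - dB
          refresh_kgeom(cid)
        }
        fac <- exp(-dB * q_asu[names(state$intensities)] / 2)
        state$intensities <- state$intensities * fac
        prior_mean <- prior_mean *
          exp(-dB * q_asu[names(prior_mean)] / 2)
      }
    }
    # ---- merged-intensity block ----
    intensity_block(3L)
    # ---- global error model ----
    obj_ab <- function(th) {
      a <- exp(th[1]); b <- exp(th[2])
      pred <- kg * state$intensities[keys]
      var <- obs_variance(a, b, obs$sigma, pred)
      v <- sum(mixture_loglik(obs$intensity, pred, var, state$epsilon,
                              state$gamma))
      if (!is.finite(v)) -1e12 else v
    }
    th0 <- c(log(max(state$alpha, 1e-10)), log(max(state$beta, 1e-10)))
    op <- stats::optim(th0, obj_ab, method = "BFGS",
                       control = list(fnscale = -1, maxit = 40))
    if (op$value >= obj_ab(th0)) {
      state$alpha <- max(exp(op$par[1]), 1e-10)
      state$beta <- max(exp(op$par[2]), 1e-10)
    }
    if (config$refine_gamma) {
      obj_g <- function(lg) {
        pred <- kg * state$intensities[keys]
        var <- obs_variance(state$alpha, state$beta, obs$sigma, pred)
        sum(mixture_loglik(obs$intensity, pred, var, state$epsilon,
                           exp(lg)))
      }
      og <- stats::optimize(obj_g, log(state$gamma) + c(-2, 2),
                            maximum = TRUE)
      if (og$objective >= obj_g(log(state$gamma))) {
        state$gamma <- exp(og$maximum)
      }
    }
    intensity_block(1L)
    ll_new <- total_ll()
    if (ll_new < ll - 1e-9 * abs(ll)) {
      warning("likelihood decreased in outer iteration ", outer)
    }
    done <- abs(ll_new - ll) <= config$tol * abs(ll)
    ll <- ll_new
    trace <- c(trace, ll)
    if (verbose) {
      message(sprintf("outer %d: log-likelihood %.4f", outer, ll))
    }
    if (done) break
  }
  if (!all(is.finite(state$intensities))) {
    stop("merging diverged; last finite state returned in the error ",
         "condition")
  }
  state$prior_mean <- prior_mean
  # diagnostics
  pred <- kg * state$intensities[keys]
  var <- obs_variance(state$alpha, state$beta, obs$sigma, pred)
  g <- stats::dnorm(obs$intensity, pred, sqrt(var))
  resp <- (1 - state$epsilon) * g /
    ((1 - state$epsilon) * g +
       state$epsilon * stats::dcauchy(obs$intensity, 0, state$gamma))
  model_p <- numeric(nrow(obs))
  for (cid in cids) {
    r <- rows_by_cid[[as.character(cid)]]
    gf <- crystal_geom_factors(state$crystals[[cid]], state$beam,
                               H_by_cid[[as.character(cid)]])
    model_p[r] <- gf$p
  }
  diagnostics <- data.frame(
    crystal_id = obs$crystal_id, h = obs$h, k = obs$k, l = obs$l,
    intensity = obs$intensity, predicted = pred,
    partiality_model = model_p,
    partiality_measured = measured_partiality(obs, state),
    responsibility = resp)
  list(state = state, trace = trace, diagnostics = diagnostics)
}

#' Merged-intensity table
#'
#' @param state A [merge_state()] (e.g. from [merge_intensities()]).
#' @param observations The observation table used for the merge (supplies
#'   multiplicities and error propagation).
#' @param well_measured_only Report only reflections actually measured:
#'   those whose merged standard error is at most 1/8 of the local Wilson
#'   prior mean. A reflection observed only at partiality ~0 carries no
#'   measurement and its posterior is the prior; such reflections are
#'   flagged absent rather than reported as values. Requires a state from
#'   [merge_intensities()] (which stores the prior).
#' @return `data.frame` with columns `h, k, l, I_merged, sigma_merged,
#'   n_obs` (sigma from the inverse summed weights of the Gaussian
#'   component).
#' @export
merged_table <- function(state, observations, well_measured_only = FALSE) {
  keys <- asu_key(observations$h, observations$k, observations$l,
                  state$laue)
  kg <- numeric(nrow(observations))
  for (cid in unique(observations$crystal_id)) {
    r <- which(observations$crystal_id == cid)
    gf <- crystal_geom_factors(state$crystals[[cid]], state$beam,
                               as.matrix(observations[r, c("h", "k", "l")]))
    kg[r] <- gf$kgeom
  }
  pred <- kg * state$intensities[keys]
  var <- obs_variance(state$alpha, state$beta, observations$sigma, pred)
  dt <- data.table::data.table(akey = keys, w = kg^2 / pmax(var, 1e-300))
  agg <- dt[, list(sigma_merged = 1 / sqrt(sum(w)), n_obs = .N),
            by = "akey"]
  hkl <- do.call(rbind, strsplit(agg$akey, " ", fixed = TRUE))
  out <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]),
                    I_merged = as.numeric(state$intensities[agg$akey]),
                    sigma_merged = agg$sigma_merged, n_obs = agg$n_obs)
  if (well_measured_only) {
    if (is.null(state$prior_mean)) {
      stop("well_measured_only requires a state from merge_intensities()")
    }
    out <- out[out$sigma_merged <= state$prior_mean[agg$akey] / 8, ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
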