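# Seeded forward generators emulating the three gel measurement types:
# topoisomer mobility tables, digestion fragment observations, and
# cleavage time courses / rate-vs-sigma profiles.  Each generator is a
# pure function of (parameters, seed): identical inputs give identical
# output, and the caller's random state is left untouched.

# run code under a fixed seed without disturbing the global RNG stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a topoisomer mobility table from the V model
#'
#' Forward model for topoisomer gel ladders: relative mobility
#' `= base + v_slope * |Lk - N/h_true| + Gaussian(0, noise_sd)`, i.e. a
#' V in the linking difference with its apex at the true relaxed
#' linking number of each construct.
#'
#' @param h_true True helical repeat (bp/turn).
#' @param sizes Construct sizes in bp (one ladder per construct).
#' @param lks Integer linking numbers measured for every construct.
#' @param v_slope Mobility gain per turn of `|dLk|`.
#' @param noise_sd Gaussian mobility noise sd (same units as mobility).
#' @param seed Integer seed (mandatory; output is a pure function of
#'   arguments and seed).
#' @param base Apex mobility.
#' @return Data.frame with columns `construct_id`, `size_bp`, `lk`,
#'   `mobility` — the dialect [calibrate_helical_repeat()] consumes.
#' @examples
#' gen_mobility_table(seed = 1)
#' @export
gen_mobility_table <- function(h_true = 10.48, sizes = c(333, 336, 339),
                               lks = 31:33, v_slope = 1, noise_sd = 0,
                               seed, base = 0.2) {
  if (h_true <= 0) stop("'h_true' must be positive", call. = FALSE)
  with_seed(seed, {
    out <- do.call(rbind, lapply(sizes, function(N) {
      mob <- base + v_slope * abs(lks - N / h_true) +
        stats::rnorm(length(lks), 0, noise_sd)
      data.frame(construct_id = paste0("mc", N), size_bp = N, lk = lks,
                 mobility = pmax(mob, 0))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate digestion-fragment observations for known cleavage sites
#'
#' For every (true site, reference cut) pair, emits both circular
#' fragment lengths of the doubly cut circle with Gaussian length noise
#' (truncated to the open interval `(0, N)`), emulating sizing on
#' agarose gels. Band volume is proportional to `weight * length`
#' (stain reports mass), so molar recovery downstream requires the
#' length correction of [site_molar_fractions()].
#'
#' @param true_sites Data.frame with columns `position` (1..N) and
#'   `weight` (> 0, relative molar amount cleaved at that site).
#' @param map A [restriction_map()] providing the reference cuts.
#' @param length_sd Gaussian sd of measured fragment lengths in bp
#'   (default 5, within the ~10 bp sizing accuracy of agarose gels).
#' @param seed Integer seed.
#' @return Data.frame with columns `reference_enzyme`, `length_bp`,
#'   `length_sd_bp`, `band_volume`, `true_site` — the observation
#'   dialect [triangulate_sites()] consumes (the `true_site` column is
#'   bookkeeping for recovery tests and is ignored by the estimator).
#' @export
gen_fragment_observations <- function(true_sites, map, length_sd = 5, seed) {
  stopifnot(inherits(map, "restriction_map"))
  if (nrow(map$entries) == 0L)
    stop("invalid input: restriction map contains no cuts", call. = FALSE)
  if (!is.data.frame(true_sites) ||
      !all(c("position", "weight") %in% names(true_sites)))
    stop("'true_sites' needs columns 'position' and 'weight'", call. = FALSE)
  N <- map$sequence$length
  if (any(true_sites$position < 1 | true_sites$position > N))
    stop("site positions must lie in 1..N", call. = FALSE)
  if (any(true_sites$weight <= 0))
    stop("site weights must be positive", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(nrow(true_sites))) {
      x <- true_sites$position[s]
      w <- true_sites$weight[s]
      for (e in seq_len(nrow(map$entries))) {
        r <- map$entries$position[e]
        L1 <- ((x - r) %% N)
        if (L1 == 0) L1 <- N  # site coincides with the cut: skip as one fragment
        lens <- c(L1, N - L1)
        lens <- lens[lens > 0 & lens < N]
        for (L in lens) {
          Lobs <- L + stats::rnorm(1L, 0, length_sd)
          Lobs <- min(max(Lobs, 1e-6), N - 1e-6)
          rows[[length(rows) + 1L]] <- data.frame(
            reference_enzyme = map$entries$enzyme[e],
            length_bp = Lobs, length_sd_bp = max(length_sd, 1e-9),
            band_volume = w * L, true_site = x)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a cleavage time course
#'
#' Single-rate mode (`rates` a single number): uncut fraction
#' `= max(0, 1 - k t) + noise`. Mixture mode (`rates` a data.frame with
#' columns `weight` and `rate`): population-weighted sum of linear
#' decays, producing the multiphasic curves seen when nicked
#' intermediates carry a mixture of gap sizes (e.g. the ~6 nt gaps of
#' the "fast" enzyme species decaying faster than the ~3 nt gaps of the
#' "slow" species). Fractions are clamped to `[0, 1]`.
#'
#' @param rates Single rate (s^-1) or data.frame `weight`, `rate` with
#'   weights summing to 1.
#' @param times Sampling times in seconds, strictly increasing.
#' @param fraction_sd Gaussian noise sd on the fraction (default 0.02,
#'   typical densitometry repeatability).
#' @param seed Integer seed.
#' @param species Label carried into the result.
#' @return A [time_course()].
#' @examples
#' gen_timecourse(2.4e-5, times = seq(0, 3600, by = 600), seed = 1)
#' @export
gen_timecourse <- function(rates, times, fraction_sd = 0.02, seed,
                           species = "synthetic") {
  if (is.data.frame(rates)) {
    if (!all(c("weight", "rate") %in% names(rates)))
      stop("mixture 'rates' needs columns 'weight' and 'rate'", call. = FALSE)
    if (abs(sum(rates$weight) - 1) > 1e-9)
      stop("mixture weights must sum to 1", call. = FALSE)
    if (any(rates$rate < 0)) stop("rates must be >= 0", call. = FALSE)
    w <- rates$weight; k <- rates$rate
  } else {
    if (!is.numeric(rates) || length(rates) != 1L || rates < 0)
      stop("'rates' must be a single non-negative rate or a mixture table",
           call. = FALSE)
    w <- 1; k <- rates
  }
  with_seed(seed, {
    clean <- colSums(w * outer(k, times, function(k, t) pmax(0, 1 - k * t)))
    noisy <- clean + stats::rnorm(length(times), 0, fraction_sd)
    time_course(times, pmin(pmax(noisy, 0), 1), species = species)
  })
}

#' Generate a rate-versus-supercoiling profile with a threshold
#'
#' Logistic step in `|sigma|`:
#' `k(sigma) = k_floor + (k_plateau - k_floor) / (1 + exp(-(|sigma| - |sigma_threshold|)/width))`,
#' with multiplicative lognormal noise (`rel_noise` = sd of log-rate).
#' A small `width` gives the sharp onset of nuclease sensitivity seen
#' beyond a critical superhelical density.
#'
#' @param sigma_grid Superhelical densities to sample (distinct).
#' @param k_floor Basal rate below threshold (>= 0).
#' @param k_plateau Plateau rate beyond threshold (> `k_floor`; equal
#'   values give a flat, threshold-free profile).
#' @param sigma_threshold Centre of the transition (its `|sigma|` is
#'   used; sign is taken from the grid).
#' @param width Logistic width in `|sigma|` units (default 0.002:
#'   essentially a step at gel-grid resolution).
#' @param rel_noise Lognormal sd of the multiplicative noise (0 = none).
#' @param seed Integer seed.
#' @return A [rate_profile()].
#' @examples
#' gen_rate_sigma_profile(-c(0.011, 0.024, 0.033, 0.042, 0.056, 0.064),
#'                        k_floor = 1e-4, k_plateau = 1e-2,
#'                        sigma_threshold = -0.05, seed = 1)
#' @export
gen_rate_sigma_profile <- function(sigma_grid, k_floor, k_plateau,
                                   sigma_threshold, width = 0.002,
                                   rel_noise = 0, seed) {
  if (k_floor < 0 || k_plateau < k_floor)
    stop("need k_plateau >= k_floor >= 0", call. = FALSE)
  with_seed(seed, {
    x <- abs(sigma_grid)
    k <- k_floor + (k_plateau - k_floor) /
      (1 + exp(-(x - abs(sigma_threshold)) / width))
    if (rel_noise > 0)
      k <- k * exp(stats::rnorm(length(k), 0, rel_noise))
    rate_profile(sigma_grid, k)
  })
}
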