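# Steady-state nuclease cleavage kinetics.
#
# Cleavage is followed as the fraction of uncut substrate versus time.
# With enzyme far from saturation the disappearance of substrate is
# linear over the initial part of the course, so the rate is defined as
# k = -d(fraction)/dt on an initial window (fraction per second) — the
# convention the gel quantitation uses — not as an exponential rate
# constant.  Nicked-intermediate courses produced by a mixture of gap
# sizes decay in phases and are summarised by a continuous two-segment
# linear fit.

#' A cleavage time course
#'
#' @param times Observation times in seconds, strictly increasing, at
#'   least 3 points.
#' @param uncut_fraction Fraction of uncut substrate at each time, in
#'   `[0, 1]` (values within 1e-9 outside are clamped).
#' @param species Label for the substrate / condition.
#' @return Object of class `time_course`.
#' @export
time_course <- function(times, uncut_fraction, species = "substrate") {
  if (length(times) != length(uncut_fraction))
    stop("'times' and 'uncut_fraction' must have equal length", call. = FALSE)
  if (length(times) < 3L)
    stop("insufficient data: need >= 3 time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("invalid input: 'times' must be strictly increasing", call. = FALSE)
  f <- uncut_fraction
  if (any(f < -1e-9 | f > 1 + 1e-9))
    stop("'uncut_fraction' must lie in [0, 1]", call. = FALSE)
  f <- pmin(pmax(f, 0), 1)
  structure(list(species = as.character(species), times = as.numeric(times),
                 uncut_fraction = as.numeric(f)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time course '%s': %d points, t = %g..%g s, fraction %g..%g\n",
              x$species, length(x$times), min(x$times), max(x$times),
              min(x$uncut_fraction), max(x$uncut_fraction)))
  invisible(x)
}

#' Fit the initial cleavage rate of a time course
#'
#' Ordinary least squares of uncut fraction against time over an
#' initial window; the rate is `k = -slope` in fraction per second. The
#' default window is the longest prefix of points with uncut fraction
#' at or above `fraction_min` (0.5), but never fewer than `min_points`
#' (3) — a codification of fitting "the first few time points" while
#' the decay is still linear. Set `window` to fit an explicit time
#' range instead.
#'
#' A fitted slope of the wrong sign (fraction increasing) is reported
#' as `k = 0` with `flagged = TRUE` rather than a negative rate.
#'
#' @param tc A [time_course()].
#' @param window Optional numeric `c(t_first, t_last)` overriding the
#'   automatic prefix rule.
#' @param fraction_min Prefix rule threshold on the uncut fraction.
#' @param min_points Minimum points in the window.
#' @param exponential If `TRUE`, additionally fit a single-exponential
#'   decay over the same window and return its rate constant as
#'   `k_exp` (diagnostic; printed rates use the linear convention).
#' @return Object of class `rate_estimate`: `k` (s^-1), `stderr`,
#'   `n_used`, `window` (`c(t_first, t_last)`), `flagged`, and
#'   optionally `k_exp`.
#' @examples
#' tc <- time_course(c(0, 60, 120, 180, 240), 1 - 2.40e-5 * c(0, 60, 120, 180, 240))
#' fit_initial_rate(tc)$k  # 2.40e-5
#' @export
fit_initial_rate <- function(tc, window = NULL, fraction_min = 0.5,
                             min_points = 3L, exponential = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; f <- tc$uncut_fraction
  if (f[1L] < 0.8)
    warning("first uncut fraction is ", signif(f[1L], 3),
            " (< 0.8): the initial linear regime may already be over",
            call. = FALSE)
  if (is.null(window)) {
    # longest prefix satisfying the threshold
    n_prefix <- 0L
    for (i in seq_along(f)) {
      if (f[i] >= fraction_min) n_prefix <- i else break
    }
    n_use <- max(n_prefix, min(min_points, length(t)))
    idx <- seq_len(n_use)
  } else {
    idx <- which(t >= window[1L] & t <= window[2L])
  }
  if (length(idx) < 2L)
    stop("insufficient data: fewer than 2 points in the fit window",
         call. = FALSE)
  ti <- t[idx]; fi <- f[idx]
  fit <- stats::lm.fit(cbind(1, ti), fi)
  slope <- unname(fit$coefficients[2L])
  sxx <- sum((ti - mean(ti))^2)
  dof <- length(idx) - 2L
  se <- if (dof > 0) sqrt(sum(fit$residuals^2) / dof / sxx) else NA_real_
  flagged <- slope > 0
  out <- list(k = if (flagged) 0 else -slope, stderr = se,
              n_used = length(idx), window = range(t[idx]),
              flagged = flagged, species = tc$species)
  if (exponential) {
    pos <- idx[f[idx] > 0]
    efit <- stats::lm.fit(cbind(1, t[pos]), log(f[pos]))
    out$k_exp <- max(0, -unname(efit$coefficients[2L]))
  }
  structure(out, class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("cleavage rate '%s': k = %.3g s^-1 (se %.2g, %d points, t = %g..%g s)%s\n",
              x$species, x$k, x$stderr, x$n_used, x$window[1L], x$window[2L],
              if (x$flagged) " [wrong-sign slope, clamped to 0]" else ""))
  invisible(x)
}

#' Fit a continuous two-segment linear decay
#'
#' Piecewise-linear least squares with one breakpoint, continuous at
#' the break: `f(t) = a - k_fast * t` for `t <= t_break` continuing
#' with slope `-k_slow` after. The breakpoint is chosen by grid search
#' over the interior sample times (each candidate leaves at least two
#' points per segment), minimising the sum of squared residuals.
#' Intended for nicked-intermediate courses where subpopulations with
#' different gap sizes decay at different rates.
#'
#' @param tc A [time_course()] with at least 5 points.
#' @return Object of class `biphasic_fit`: `k_fast`, `k_slow` (s^-1,
#'   ordered `k_fast >= k_slow`, negatives clamped to 0), `t_break`
#'   (s), `sse`, and `sse_single` (single-line fit for comparison).
#' @examples
#' t <- c(0, 30, 60, 120, 300, 600, 1200)
#' f <- ifelse(t <= 120, 1 - 4.31e-3 * t,
#'             (1 - 4.31e-3 * 120) - 4.07e-4 * (t - 120))
#' fit_biphasic(time_course(t, f))
#' @export
fit_biphasic <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; f <- tc$uncut_fraction
  n <- length(t)
  if (n < 5L)
    stop("insufficient data: need >= 5 points for a two-segment fit",
         call. = FALSE)
  candidates <- t[2:(n - 1L)]
  best <- NULL
  for (tb in candidates) {
    X <- cbind(1, t, pmax(t - tb, 0))
    fit <- stats::lm.fit(X, f)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-15)
      best <- list(tb = tb, sse = sse, coef = unname(fit$coefficients))
  }
  s1 <- -best$coef[2L]                 # first-segment rate
  s2 <- -(best$coef[2L] + best$coef[3L])  # second-segment rate
  ks <- sort(pmax(c(s1, s2), 0), decreasing = TRUE)
  single <- stats::lm.fit(cbind(1, t), f)
  structure(list(k_fast = ks[1L], k_slow = ks[2L], t_break = best$tb,
                 sse = best$sse, sse_single = sum(single$residuals^2),
                 species = tc$species),
            class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("biphasic fit '%s': k_fast = %.3g, k_slow = %.3g s^-1, break at %g s (SSE %.3g)\n",
              x$species, x$k_fast, x$k_slow, x$t_break, x$sse))
  invisible(x)
}

#' Fold ratio of two cleavage rates
#'
#' @param k_num,k_den Rates (same units); `k_den` must be positive.
#' @return `k_num / k_den`.
#' @seealso [report_fold()] for the conventional 2-significant-figure
#'   presentation.
#' @examples
#' fold_ratio(4.31e-3, 2.40e-5)  # ~180
#' @export
fold_ratio <- function(k_num, k_den) {
  if (!is.numeric(k_den) || any(k_den <= 0))
    stop("'k_den' must be positive", call. = FALSE)
  k_num / k_den
}

#' Round a fold change for reporting
#'
#' Fold changes are conventionally quoted to 2 significant figures
#' (small folds effectively to the nearest integer).
#'
#' @param fold Numeric fold change(s).
#' @param digits Significant figures (default 2).
#' @return Rounded fold change.
#' @export
report_fold <- function(fold, digits = 2) signif(fold, digits)

#' A rate-versus-supercoiling profile
#'
#' @param sigma Superhelical densities (distinct).
#' @param k Cleavage rates (s^-1), same length.
#' @param k_stderr Optional standard errors.
#' @return Object of class `rate_profile`: a data.frame sorted by
#'   `sigma` with columns `sigma`, `k`, `k_stderr`.
#' @export
rate_profile <- function(sigma, k, k_stderr = NA_real_) {
  if (length(sigma) != length(k))
    stop("'sigma' and 'k' must have equal length", call. = FALSE)
  if (anyDuplicated(sigma))
    stop("'sigma' values must be distinct", call. = FALSE)
  if (any(k < 0)) stop("rates must be >= 0", call. = FALSE)
  out <- data.frame(sigma = sigma, k = k, k_stderr = k_stderr)
  out <- out[order(out$sigma), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_profile", class(out))
  out
}

#' Locate a supercoiling threshold in a rate profile
#'
#' Scans one sign branch of a rate-versus-sigma profile in order of
#' increasing `|sigma|` and finds the adjacent pair of sampled
#' densities with the largest fold increase in rate. If that fold
#' exceeds `min_fold` the pair is returned as the threshold bracket;
#' the method never interpolates between sampled densities, because the
#' data themselves only bracket the transition.
#'
#' Rates of exactly zero (below gel detection) are replaced by
#' `k_floor` before forming ratios so that an onset from undetectable
#' activity still registers as a finite fold.
#'
#' @param profile A [rate_profile()] (or data.frame with `sigma`, `k`).
#' @param min_fold Minimum fold increase to call a threshold (default 5).
#' @param side `"negative"` (default) or `"positive"`: which sigma
#'   branch to scan.
#' @param k_floor Detection floor substituted for zero rates.
#' @return Object of class `threshold_result` with `sigma_low`,
#'   `sigma_high` (the bracketing grid values, low = smaller `|sigma|`),
#'   and `fold_change`; or `NULL` if no adjacent pair exceeds
#'   `min_fold`.
#' @examples
#' prof <- rate_profile(sigma = -c(0.011, 0.024, 0.033, 0.042, 0.056, 0.064),
#'                      k = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-2, 1e-2))
#' detect_threshold(prof)
#' @export
detect_threshold <- function(profile, min_fold = 5,
                             side = c("negative", "positive"),
                             k_floor = 1e-7) {
  side <- match.arg(side)
  if (!is.data.frame(profile) || !all(c("sigma", "k") %in% names(profile)))
    stop("'profile' must have columns 'sigma' and 'k'", call. = FALSE)
  br <- if (side == "negative") profile[profile$sigma < 0, , drop = FALSE]
        else profile[profile$sigma > 0, , drop = FALSE]
  if (nrow(br) < 3L)
    stop("insufficient data: need >= 3 profile points on the ", side,
         " branch", call. = FALSE)
  br <- br[order(abs(br$sigma)), , drop = FALSE]
  k <- pmax(br$k, k_floor)
  folds <- k[-1L] / k[-length(k)]
  i <- which.max(folds)
  if (folds[i] <= min_fold) return(NULL)
  structure(list(sigma_low = br$sigma[i], sigma_high = br$sigma[i + 1L],
                 fold_change = folds[i]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold bracket: sigma in (%g, %g), %.3g-fold increase\n",
              x$sigma_low, x$sigma_high, x$fold_change))
  invisible(x)
}
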