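# Lk0 estimation from topoisomer gel mobilities.
#
# On native gels the electrophoretic mobility of topoisomers of one
# circle follows, to good approximation, a V-shaped dependence on the
# linking difference: mobility = apex + slope * |Lk - Lk0|, with the
# slowest band at the (generally non-integer) relaxed linking number.
# The abscissa of the V apex is therefore an estimate of Lk0, and
# N / Lk0 an estimate of the helical repeat under the gel buffer.

#' Fit the V-shaped mobility model to one construct's topoisomer ladder
#'
#' Estimates the relaxed linking number `Lk0` of a single circular
#' construct as the apex of a V fitted to relative mobility versus Lk,
#' with equal-magnitude, opposite-sign slopes on the two arms.
#'
#' For exactly three topoisomers the classical gel construction is used:
#' a line through the two points assigned to one arm, the reflected line
#' (equal and opposite slope) through the third, and the apex at their
#' intersection. Both candidate arm assignments are tried; a solution is
#' kept only if the apex falls inside the observed Lk range with the
#' arm points on consistent sides, ties broken by lower residual and
#' then apex proximity to the median Lk. For more than three points the
#' model `mobility = apex_mobility + slope * |Lk - Lk0|` is fitted by
#' least squares, profiling the apex position over the Lk range.
#'
#' The apex abscissa is invariant under affine transformations of the
#' mobility axis, so mobilities may be supplied in any consistent
#' relative units (e.g. migration distances normalised to the farthest
#' band).
#'
#' @param records A data.frame with columns `lk` (integer linking
#'   numbers, distinct) and `mobility` (non-negative; larger = migrated
#'   farther). Rows for a single construct.
#' @param equal_slopes If `TRUE` (default, and the model the estimator
#'   is defined by) the two arms share one slope magnitude. `FALSE`
#'   fits independent arm slopes around the same profiled apex — a
#'   diagnostic for asymmetric ladders only; the apex then no longer
#'   has the equal-slope interpretation.
#' @return An object of class `vfit` (a list): `lk0_hat` (apex
#'   abscissa, turns), `slope_mag` (shared slope magnitude, mobility
#'   per turn), `apex_mobility`, `residual` (sum of squared residuals),
#'   `n` (records used).
#' @examples
#' rec <- data.frame(lk = 31:33, mobility = c(1.0, 0.2, 1.0))
#' vfit_lk0(rec)$lk0_hat  # symmetric ladder: apex at 32
#' @export
vfit_lk0 <- function(records, equal_slopes = TRUE) {
  if (!is.data.frame(records) || !all(c("lk", "mobility") %in% names(records)))
    stop("'records' must be a data.frame with columns 'lk' and 'mobility'",
         call. = FALSE)
  records <- records[order(records$lk), , drop = FALSE]
  lk <- as.numeric(records$lk)
  m <- as.numeric(records$mobility)
  if (anyDuplicated(lk))
    stop("duplicate 'lk' values within one construct", call. = FALSE)
  if (length(lk) < 3L)
    stop("insufficient data: need >= 3 topoisomer records to place a V apex",
         call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("'mobility' must be finite and non-negative", call. = FALSE)
  if (diff(range(m)) == 0)
    stop("degenerate fit: all mobilities are equal, the V apex is undefined",
         call. = FALSE)

  fit <- if (length(lk) == 3L) vfit3(lk, m) else vfitn(lk, m, equal_slopes)
  structure(c(fit, list(n = length(lk))), class = "vfit")
}

# Exact three-point gel construction: line through a same-arm pair,
# reflected line through the remaining point, apex at the intersection.
vfit3 <- function(lk, m) {
  candidates <- list(c(1L, 2L, 3L), c(2L, 3L, 1L))  # (arm pair, other)
  sols <- list()
  for (cand in candidates) {
    i <- cand[1L]; j <- cand[2L]; k <- cand[3L]
    b <- (m[j] - m[i]) / (lk[j] - lk[i])     # slope of the pair's line
    if (!is.finite(b) || b == 0) next
    c1 <- m[i] - b * lk[i]
    # reflected line through the third point: m = m_k - b * (x - lk_k)
    x <- (m[k] + b * lk[k] - c1) / (2 * b)
    if (!is.finite(x) || x <= min(lk) || x >= max(lk)) next
    # arm-consistency: the pair may not straddle the apex, and the third
    # point may not lie on the pair's arm (sitting exactly at the apex
    # is fine — the slowest band can be a measured topoisomer)
    ps <- sign(lk[c(i, j)] - x)
    pk <- sign(lk[k] - x)
    if (any(ps > 0) && any(ps < 0)) next
    arm <- if (sum(ps) > 0) 1 else -1
    if (pk == arm) next
    slope_mag <- abs(b)
    apex_m <- c1 + b * x
    resid <- sum((m - (apex_m + slope_mag * abs(lk - x)))^2)
    sols[[length(sols) + 1L]] <-
      list(lk0_hat = x, slope_mag = slope_mag, apex_mobility = apex_m,
           residual = resid)
  }
  if (length(sols) == 0L)
    stop("insufficient data: no valid V apex inside the Lk range ",
         "(all topoisomers appear to lie on one arm)", call. = FALSE)
  if (length(sols) > 1L) {
    resid <- vapply(sols, `[[`, numeric(1L), "residual")
    apexd <- vapply(sols, function(s) abs(s$lk0_hat - stats::median(lk)),
                    numeric(1L))
    sols <- sols[order(resid, apexd)]
  }
  sols[[1L]]
}

# Least-squares V fit for > 3 points, apex profiled over the Lk range.
vfitn <- function(lk, m, equal_slopes) {
  sse_at <- function(x) {
    if (equal_slopes) {
      X <- cbind(1, abs(lk - x))
    } else {
      X <- cbind(1, pmax(x - lk, 0), pmax(lk - x, 0))
    }
    fit <- stats::lm.fit(X, m)
    sum(fit$residuals^2)
  }
  # SSE is smooth between consecutive Lk values; optimise per interval
  knots <- sort(unique(lk))
  best <- list(sse = Inf, x = NA_real_)
  for (i in seq_len(length(knots) - 1L)) {
    op <- stats::optimize(sse_at, c(knots[i], knots[i + 1L]), tol = 1e-10)
    for (cand in list(c(op$minimum, op$objective),
                      c(knots[i], sse_at(knots[i])),
                      c(knots[i + 1L], sse_at(knots[i + 1L])))) {
      if (cand[2L] < best$sse - 1e-15) best <- list(sse = cand[2L], x = cand[1L])
    }
  }
  x <- best$x
  X <- if (equal_slopes) cbind(1, abs(lk - x)) else
    cbind(1, pmax(x - lk, 0), pmax(lk - x, 0))
  fit <- stats::lm.fit(X, m)
  cf <- fit$coefficients
  slope_mag <- if (equal_slopes) abs(cf[2L]) else mean(abs(cf[2:3]))
  list(lk0_hat = x, slope_mag = unname(slope_mag),
       apex_mobility = unname(cf[1L]), residual = sum(fit$residuals^2))
}

#' @export
print.vfit <- function(x, ...) {
  cat(sprintf("V fit: Lk0 = %.3f  (slope %.4g per turn, apex mobility %.4g, SSE %.3g, n = %d)\n",
              x$lk0_hat, x$slope_mag, x$apex_mobility, x$residual, x$n))
  invisible(x)
}

#' Pool per-construct Lk0 estimates into a helical-repeat estimate
#'
#' Each construct of size `N` with apex estimate `lk0_hat` yields a
#' helical repeat `N / lk0_hat`; constructs are combined by their
#' arithmetic mean with the sample standard deviation as the spread.
#'
#' @param pairs A data.frame with columns `size_bp` and `lk0_hat`
#'   (optionally `construct_id`).
#' @return A list of class `helical_repeat_estimate`: `h_mean`, `h_sd`
#'   (`NA` for a single construct), and `per_construct` (data.frame with
#'   `construct_id`, `size_bp`, `lk0_hat`, `h`).
#' @examples
#' helical_repeat_from_lk0s(
#'   data.frame(size_bp = c(336, 333, 339), lk0_hat = c(32.06, 31.78, 32.35)))
#' @export
helical_repeat_from_lk0s <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) < 1L ||
      !all(c("size_bp", "lk0_hat") %in% names(pairs)))
    stop("insufficient data: need a data.frame with >= 1 row and columns ",
         "'size_bp' and 'lk0_hat'", call. = FALSE)
  if (any(pairs$lk0_hat <= 0))
    stop("'lk0_hat' must be positive", call. = FALSE)
  per <- data.frame(
    construct_id = if ("construct_id" %in% names(pairs)) pairs$construct_id
                   else as.character(pairs$size_bp),
    size_bp = pairs$size_bp,
    lk0_hat = pairs$lk0_hat,
    h = pairs$size_bp / pairs$lk0_hat)
  structure(list(
    h_mean = mean(per$h),
    h_sd = if (nrow(per) > 1L) stats::sd(per$h) else NA_real_,
    per_construct = per), class = "helical_repeat_estimate")
}

#' @export
print.helical_repeat_estimate <- function(x, ...) {
  cat(sprintf("helical repeat: %.2f bp/turn", x$h_mean))
  if (is.finite(x$h_sd)) cat(sprintf(" (+/- %.2f)", x$h_sd))
  cat(sprintf(", %d construct(s)\n", nrow(x$per_construct)))
  invisible(x)
}

#' Calibrate the helical repeat from a multi-construct mobility table
#'
#' Convenience wrapper: runs [vfit_lk0()] per construct and pools the
#' apex estimates with [helical_repeat_from_lk0s()].
#'
#' @param records A data.frame with columns `construct_id`, `size_bp`,
#'   `lk`, `mobility` (the mobility-table CSV dialect).
#' @return A `helical_repeat_estimate`; the per-construct table carries
#'   each V-fit's `lk0_hat`.
#' @export
calibrate_helical_repeat <- function(records) {
  need <- c("construct_id", "size_bp", "lk", "mobility")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  parts <- split(records, records$construct_id)
  pairs <- do.call(rbind, lapply(parts, function(df) {
    N <- unique(df$size_bp)
    if (length(N) != 1L)
      stop("construct '", df$construct_id[1L], "' has inconsistent size_bp",
           call. = FALSE)
    fit <- vfit_lk0(df[, c("lk", "mobility")])
    data.frame(construct_id = df$construct_id[1L], size_bp = N,
               lk0_hat = fit$lk0_hat)
  }))
  rownames(pairs) <- NULL
  helical_repeat_from_lk0s(pairs)
}
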