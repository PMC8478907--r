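# Linking-number arithmetic for covalently closed circular DNA.
#
# All quantities derive from the relaxed linking number Lk0 = N / h_B,
# where N is the circle size in base pairs and h_B the helical repeat of
# B-DNA in bp/turn under the buffer conditions of interest.  Lk0 is in
# general non-integer, so two delta-Lk conventions coexist: the exact
# difference Lk - Lk0 (real turns) and the nominal difference against the
# nearest-integer Lk0 (integer turns, the value usually printed on gels).
# Superhelical density always uses the exact difference.

#' Helical-repeat parameters
#'
#' Bundle of the two helical repeats used throughout the package: `h_B`,
#' the B-DNA repeat (bp/turn), and `h_P`, the repeat of the inside-out,
#' highly overwound P-DNA form (bp/turn). The default `h_B = 10.48`
#' corresponds to a high-salt nuclease reaction buffer (600 mM NaCl,
#' 12 mM CaCl2, 12 mM MgCl2); `10.5` is the textbook value under
#' physiological conditions. P-DNA has roughly 3 bp per turn.
#'
#' @param h_B B-DNA helical repeat in bp/turn; must be positive.
#' @param h_P P-DNA helical repeat in bp/turn; must be positive and,
#'   when both are used together, smaller than `h_B`.
#' @return An object of class `helix_params`: a list with elements
#'   `h_B` and `h_P`.
#' @examples
#' helix_params()            # calibrated defaults
#' helix_params(h_B = 10.5)  # physiological repeat
#' @export
helix_params <- function(h_B = 10.48, h_P = 3) {
  if (!is.numeric(h_B) || length(h_B) != 1L || !is.finite(h_B) || h_B <= 0)
    stop("'h_B' must be a single positive number", call. = FALSE)
  if (!is.numeric(h_P) || length(h_P) != 1L || !is.finite(h_P) || h_P <= 0)
    stop("'h_P' must be a single positive number", call. = FALSE)
  structure(list(h_B = as.numeric(h_B), h_P = as.numeric(h_P)),
            class = "helix_params")
}

as_helix_params <- function(helix) {
  if (inherits(helix, "helix_params")) return(helix)
  if (is.numeric(helix) && length(helix) == 1L) return(helix_params(h_B = helix))
  if (is.list(helix)) return(do.call(helix_params, helix))
  stop("'helix' must be helix_params(), a list, or a single h_B value",
       call. = FALSE)
}

#' Relaxed linking number of a circle
#'
#' The linking number a covalently closed circle of `size_bp` base pairs
#' would have if fully relaxed: `size_bp / h_B` turns. Generally
#' non-integer.
#'
#' @param size_bp Circle size in base pairs (positive).
#' @param helix A [helix_params()] object, or a bare numeric taken as `h_B`.
#' @return Lk0 in turns (numeric, vectorised over `size_bp`).
#' @examples
#' lk0_of(336)        # 32.06 turns at h_B = 10.48
#' lk0_of(336, 10.5)  # exactly 32
#' @export
lk0_of <- function(size_bp, helix = helix_params()) {
  helix <- as_helix_params(helix)
  if (!is.numeric(size_bp) || any(!is.finite(size_bp)) || any(size_bp < 1))
    stop("'size_bp' must be numeric and >= 1", call. = FALSE)
  size_bp / helix$h_B
}

#' Construct a topoisomer state
#'
#' Derives the full topological description of one topoisomer: the
#' relaxed linking number `lk0`, the exact linking difference
#' `dlk_exact = lk - lk0` (real turns), the nominal linking difference
#' `dlk_nominal = lk - round(lk0)` (integer turns, the value written on
#' gel lanes), and the superhelical density `sigma = dlk_exact / lk0`.
#' Sigma is always computed from the exact difference; using the nominal
#' one would not reproduce measured densities because `lk0` is not an
#' integer.
#'
#' @param size_bp Circle size in base pairs (positive integer).
#' @param lk Linking number (integer; covalently closed circles have
#'   integer Lk).
#' @param helix A [helix_params()] object or bare `h_B`.
#' @return An object of class `topoisomer`: a list with elements
#'   `size_bp`, `lk`, `lk0`, `dlk_exact`, `dlk_nominal`, `sigma`.
#' @examples
#' make_topoisomer(336, 26)  # hyper-negatively supercoiled, sigma = -0.189
#' make_topoisomer(336, 35)  # positively supercoiled, sigma = +0.092
#' @export
make_topoisomer <- function(size_bp, lk, helix = helix_params()) {
  helix <- as_helix_params(helix)
  if (length(size_bp) != 1L || length(lk) != 1L)
    stop("'size_bp' and 'lk' must be single values", call. = FALSE)
  if (!is.numeric(lk) || !is.finite(lk) || lk != round(lk))
    stop("'lk' must be an integer linking number", call. = FALSE)
  lk0 <- lk0_of(size_bp, helix)
  dlk_exact <- lk - lk0
  dlk_nominal <- as.integer(lk - round(lk0))
  structure(list(size_bp = as.integer(size_bp), lk = as.integer(lk),
                 lk0 = lk0, dlk_exact = dlk_exact,
                 dlk_nominal = dlk_nominal, sigma = dlk_exact / lk0,
                 helix = helix),
            class = "topoisomer")
}

#' @export
print.topoisomer <- function(x, ...) {
  cat(sprintf(
    "topoisomer: %d bp, Lk = %d  (Lk0 = %.2f, dLk = %+d nominal / %+.2f exact, sigma = %+.3f)\n",
    x$size_bp, x$lk, x$lk0, x$dlk_nominal, x$dlk_exact, x$sigma))
  invisible(x)
}

#' Topology table for a ladder of topoisomers
#'
#' Tabulates `Lk0`, nominal and exact delta-Lk, and sigma for a set of
#' linking numbers of one circle. This is the table usually reported
#' alongside topoisomer gel ladders.
#'
#' @param size_bp Circle size in base pairs.
#' @param lks Integer vector of linking numbers.
#' @param helix A [helix_params()] object or bare `h_B`.
#' @param digits If non-NULL, round for display: Lk0 to 2 decimals and
#'   sigma to 3 decimals (the conventional reporting precision). The
#'   default `NULL` keeps full precision.
#' @return A data.frame with columns `size_bp`, `lk`, `lk0`,
#'   `dlk_nominal`, `dlk_exact`, `sigma`.
#' @examples
#' topoisomer_table(336, 26:35)
#' @export
topoisomer_table <- function(size_bp, lks, helix = helix_params(),
                             digits = NULL) {
  rows <- lapply(lks, function(l) {
    t <- make_topoisomer(size_bp, l, helix)
    data.frame(size_bp = t$size_bp, lk = t$lk, lk0 = t$lk0,
               dlk_nominal = t$dlk_nominal, dlk_exact = t$dlk_exact,
               sigma = t$sigma)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    out$lk0 <- round(out$lk0, 2)
    out$dlk_exact <- round(out$dlk_exact, 2)
    out$sigma <- round(out$sigma, 3)
  }
  out
}

#' Rotational phase offset across a nick
#'
#' In a closed loop the base pairs flanking a nick can only stack
#' perfectly if the loop comprises an integer number of helical turns.
#' This returns the fractional-turn misalignment
#' `|Lk0 - round(Lk0)|`, in `[0, 0.5]`: 0 means in phase, 0.5 maximally
#' out of phase. Out-of-phase nicked circles expose strand ends and are
#' markedly better nuclease substrates.
#'
#' @inheritParams lk0_of
#' @return Fraction of a helical turn in `[0, 0.5]`.
#' @examples
#' phase_offset(336)  # ~0.06: nearly in phase
#' phase_offset(339)  # ~0.35: about a third of a turn out of phase
#' @export
phase_offset <- function(size_bp, helix = helix_params()) {
  lk0 <- lk0_of(size_bp, helix)
  abs(lk0 - round(lk0))
}

#' Base pairs that must melt to absorb a linking difference
#'
#' If torsional strain is absorbed purely by local denaturation (no
#' writhe), each turn of linking difference requires one helical
#' repeat's worth of base pairs to unpair: `|dlk| * h_B`.
#'
#' @param dlk Linking difference in turns (sign ignored).
#' @param helix A [helix_params()] object or bare `h_B`.
#' @return Base pairs of duplex that must fully melt.
#' @examples
#' melt_bp_equivalent(-1)  # ~10 bp per negative turn
#' @export
melt_bp_equivalent <- function(dlk, helix = helix_params()) {
  helix <- as_helix_params(helix)
  if (!is.numeric(dlk) || any(!is.finite(dlk)))
    stop("'dlk' must be numeric", call. = FALSE)
  abs(dlk) * helix$h_B
}

#' Base pairs of B-DNA whose conversion to P-DNA absorbs an overwinding
#'
#' P-DNA is an inside-out, highly overwound duplex form (about 3
#' bp/turn against ~10.5 for B-DNA). Converting `n` bp of B-DNA to
#' P-DNA gains `n * (1/h_P - 1/h_B)` turns of twist, so the base pairs
#' needed to absorb a positive linking difference `dlk_exact` are
#' `dlk_exact / (1/h_P - 1/h_B)`.
#'
#' @param dlk_exact Exact linking difference in turns; must be >= 0
#'   (P-DNA absorbs overwinding only).
#' @param helix A [helix_params()] object; requires `h_P < h_B`.
#' @return Base pairs of B-DNA to convert.
#' @examples
#' # overwinding of a 336 bp Lk = 35 circle, physiological h_B:
#' pdna_bp_required(35 - 336 / 10.48, helix_params(h_B = 10.5, h_P = 3))
#' @export
pdna_bp_required <- function(dlk_exact, helix = helix_params(h_B = 10.5)) {
  helix <- as_helix_params(helix)
  if (!is.numeric(dlk_exact) || any(!is.finite(dlk_exact)) || any(dlk_exact < 0))
    stop("'dlk_exact' must be numeric and >= 0", call. = FALSE)
  if (helix$h_P >= helix$h_B)
    stop("'h_P' must be smaller than 'h_B' (twist surplus requires a tighter repeat)",
         call. = FALSE)
  dlk_exact / (1 / helix$h_P - 1 / helix$h_B)
}
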