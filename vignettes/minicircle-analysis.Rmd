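---
title: "Supercoiled minicircle analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercoiled minicircle analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicircletools)
```

`minicircletools` analyses experiments in which small covalently closed
DNA circles ("minicircles", a few hundred base pairs) with defined
supercoiling levels are probed with structure-specific nucleases. Four
quantitative procedures recur in such work, and the package implements
each as a reusable, tested estimator: linking-number arithmetic, gel
calibration of the DNA helical repeat, triangulation of nuclease
cleavage sites on the circle, and cleavage kinetics with threshold
detection. A fifth module generates synthetic gel measurements so that
every estimator can be exercised against known ground truth.

## Topology arithmetic

A closed circular duplex is characterised by its integer linking number
$Lk$. The relaxed reference is $Lk_0 = N/h_B$, with $N$ the circle size
in bp and $h_B$ the B-DNA helical repeat in bp/turn; $Lk_0$ is in
general non-integer. Two linking-difference conventions coexist in
practice and the package stores both:

* `dlk_exact` $= Lk - Lk_0$, real turns — the physical torsional load;
* `dlk_nominal` $= Lk - \mathrm{round}(Lk_0)$, integer turns — the
  label conventionally written next to a gel lane.

Superhelical density is always $\sigma = (Lk - Lk_0)/Lk_0$ with the
*exact* difference; using the nominal one does not reproduce measured
densities. For the 336 bp circle at $h_B = 10.48$:

```{r}
topoisomer_table(336, c(26, 29, 30, 31, 35), digits = 2)
```

Two bp-accounting helpers translate torsional strain into structural
currency. `melt_bp_equivalent()` gives the bp that must fully unpair to
absorb a linking difference without writhe ($|\Delta Lk| \cdot h_B$,
about 10 bp per negative turn). `pdna_bp_required()` gives the bp of
B-DNA whose conversion to P-DNA — the inside-out, overwound form with
$h_P \approx 3$ bp/turn — absorbs a positive linking difference:
$\Delta Lk / (1/h_P - 1/h_B)$. This quantity *increases* with $h_P$ and
diverges as $h_P \to h_B$, since a P form barely tighter than B-DNA
stores almost no extra twist per bp.

`phase_offset()` returns $|Lk_0 - \mathrm{round}(Lk_0)| \in [0, 0.5]$,
the rotational misalignment of the base pairs flanking a nick in the
closed loop. Circles near an integer number of turns (336 bp at
$h_B = 10.48$: offset 0.06) hold the nicked ends stacked; out-of-phase
circles (339 bp: offset 0.35, about a third of a turn) expose them,
which is why they are far better nuclease substrates when nicked.

Defaults: `h_B = 10.48` bp/turn, the value calibrated under the
high-salt nuclease reaction buffer this package's gel models assume;
`h_P = 3`. Both are arguments everywhere, never constants inside
formulas; `h_B = 10.5` is the usual choice for physiological buffers.
Reports round $Lk_0$ to 2 decimals and $\sigma$ to 3, the conventional
display precision; full precision is always retained in the objects.

Two numerical footnotes. First, $333/10.48 = 31.7748$, which prints as
31.77 although gel estimates of the same quantity are typically quoted
as 31.78 — per-construct gel fits are made first and the pooled repeat
is derived from them, so the printed values need not equal the division
to the last digit. The package treats agreement to one unit in the
second decimal as exact for this quantity. Second, for the
double-length 672 bp circle at $Lk = 58$ the arithmetic gives
$\sigma = -0.0955$, sometimes quoted as $-0.096$; the identity
$\sigma(672, 58) = \sigma(336, 29)$ holds by construction and is the
invariant the package asserts.

## Helical-repeat calibration from topoisomer mobility

On native gels, topoisomer mobility is modelled as V-shaped in the
linking difference:
$m(Lk) = m_0 + s\,|Lk - Lk_0|$, slowest at the (non-integer) relaxed
state, with equal-magnitude slopes on both arms. `vfit_lk0()` estimates
the apex:

* **Exactly three topoisomers** (the classical design, $Lk \in
  \{31, 32, 33\}$): a line through the two points of one arm, the
  reflected line through the third, apex at the intersection. Both arm
  assignments are tried; a solution must place the apex strictly inside
  the $Lk$ range with the points on consistent arms (a point exactly at
  the apex is allowed), ties broken by lower residual, then apex
  proximity to the median $Lk$. Ladders with all mobilities on one arm
  cannot place an apex and raise an error rather than extrapolate.
* **More than three**: least squares in $(m_0, s)$ with the apex
  profiled over the $Lk$ range (the objective is smooth between
  integer knots, so each inter-knot interval is minimised separately).

The apex abscissa is invariant under affine transforms of the mobility
axis, so relative mobilities, migration distances in mm, or
normalised distances all give the same $Lk_0$. With zero noise the fit
is exact for any apex strictly inside the measured range.

`helical_repeat_from_lk0s()` converts each construct to $h = N/Lk_0$
and pools by arithmetic mean with the sample standard deviation:

```{r}
helical_repeat_from_lk0s(
  data.frame(size_bp = c(336, 333, 339), lk0_hat = c(32.06, 31.78, 32.35)))
```

The model assumes the V is symmetric in $|\Delta Lk|$; strongly
asymmetric gels can be inspected with `equal_slopes = FALSE`, which is
diagnostic only.

## Cleavage-site triangulation on the circle

Positions are 1-based, 1..N, circular; "cut at $p$" means top-strand
scission between bases $p$ and $p+1$ (mod $N$). `find_cut_positions()`
scans both strands (top only for nicking enzymes) for the IUPAC
recognition motif, including matches wrapping the origin, via
`Biostrings::matchPattern` on the doubled sequence; the built-in table
covers EcoRV, XmnI, NdeI, MseI, BbvCI and Nb.BbvCI with standard cut
chemistry, and user `enzyme_spec()` objects override it. On the
packaged 336 bp minicircle each marker cuts once, EcoRV at position 41:

```{r}
rmap <- restriction_map(minicircle_sequence("336"),
                        c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
rmap$entries
```

A fragment of measured length $L$ from a digest referenced to a cut at
$r$ places the unknown nuclease cut at $(r + L)$ or $(r - L)$ mod $N$ —
sizing gels do not reveal direction. `triangulate_sites()` pools both
candidates from every observation, clusters them on the circle, and
reports clusters supported by at least `min_support` distinct
reference enzymes (default 2). Cluster positions are circular means
(vector averaging of angles $2\pi p/N$) and `error_bp` is the circular
standard deviation $\sqrt{-2\ln \bar R}$ rescaled by $N/2\pi$ — the
dispersion of the supporting evidence, the same scale as the
"$\pm$ bp" quoted with mapped sites. Clustering is initialised by
splitting the sorted candidates at circular gaps above
`cluster_threshold` (default 15 bp, about 1.5 times the ~10 bp
sizing accuracy of agarose gels) and refined by reassignment to the
nearest circular centroid until convergence (at most 100 iterations),
which settles clusters straddling another's antipode.

Mirror candidates are deliberately never pre-filtered: with a single
reference enzyme the reflection ambiguity is unresolvable and both
mirror clusters are reported; with several references the mirrors
scatter while the true site accumulates support. Geometry imposes one
limit: a site whose mirror about some cut lands within the cluster
threshold (the site is within ~half a threshold of a cut *or of its
antipode*) merges with that mirror and the estimate is biased toward
the cut. Such configurations are below what fragment sizing can
resolve, as is sub-nucleotide localisation generally — nucleases that
nibble a few nt around their target blur the true position by design.

`site_molar_fractions()` converts band volumes to molar site
preferences: stains report mass, so moles $\propto$ volume / length,
normalised to 1. Aggregating fractions into per-site percentages of
total cleavage is left to the caller, since the choice of denominator
is experiment-specific.

## Cleavage kinetics

Cleavage is followed as the uncut fraction versus time. With substrate
in excess and the enzyme far from saturation the initial disappearance
is linear, so the rate is defined as $k = -d f/dt$ on an initial
window, in fraction s$^{-1}$ — the convention matching reported
magnitudes, not an exponential constant (an exponential variant is
available via `exponential = TRUE` for comparison). The default window
is the longest prefix with $f \ge 0.5$, at least 3 points — a concrete
codification of "the first few time points" — and can be overridden
with an explicit time range. Wrong-sign slopes are clamped to $k = 0$
and flagged rather than reported as negative rates.

`fit_biphasic()` summarises multiphasic decays (mixtures of gap sizes
in nicked intermediates) by a continuous two-segment linear fit, with
the breakpoint grid-searched over interior sample times. When the data
are single-phase the two slopes agree and the residual equals the
single-line fit. Note that for a 50/50 mixture of linear decays with
rates $k_1 > k_2$ the *segment slopes* are $(k_1 + k_2)/2$ before the
fast population is exhausted and $k_2/2$ after — the fit recovers
segment slopes, not component rates; component inference is out of
scope.

`fold_ratio()` and `report_fold()` (2 significant figures) express
rate comparisons the usual way, e.g. `fold_ratio(4.31e-3, 2.40e-5)`
$\approx 180$. `detect_threshold()` scans a rate-versus-$\sigma$
profile along one sign branch in increasing $|\sigma|$ and returns the
adjacent grid pair with the maximal fold increase, provided it exceeds
`min_fold` (default 5). The result is deliberately a *bracket* between
sampled densities, never an interpolated point: the measurements
themselves only bracket the transition. Rates of exactly zero (below
gel detection) are floored at `k_floor` ($10^{-7}$ s$^{-1}$) before
ratios are formed so that onset from undetectable activity registers.

```{r}
prof <- rate_profile(sigma = -c(0.011, 0.024, 0.033, 0.042, 0.056, 0.064),
                     k = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-2, 1e-2))
detect_threshold(prof)
```

## Synthetic data: what it emulates, and what it does not

The generators produce the three gel table types under simple noise
families, each a pure function of its parameters and an integer seed
(byte-identical on repeated calls, global RNG untouched):

* `gen_mobility_table()` — V model plus Gaussian mobility noise.
  Defaults are the study design the estimators target: constructs
  333/336/339 bp, $Lk \in \{31, 32, 33\}$, true repeat 10.48 bp/turn.
  The default noise in recovery tests is sd 0.025 on a dynamic range of
  ~1.2 mobility units (about 2%), a repeatability typical of band-
  position densitometry.
* `gen_fragment_observations()` — both circular fragments per (site,
  reference cut) with Gaussian length error truncated to $(0, N)$,
  default sd 5 bp, within the ~10 bp sizing accuracy of high-resolution
  agarose gels; band volume $\propto$ weight $\times$ length (stain
  reports mass).
* `gen_timecourse()` — linear decay clamped to $[0,1]$ with Gaussian
  fraction noise (default sd 0.02); mixture mode sums weighted linear
  decays, emulating "fast" (~6 nt gap) and "slow" (~3 nt gap) enzyme
  subpopulations that make nicked-intermediate kinetics multiphasic.
* `gen_rate_sigma_profile()` — logistic step in $|\sigma|$ (default
  width 0.002, a near-step at gel-grid resolution) with multiplicative
  lognormal noise, chosen to keep rates positive.

Gaussian/lognormal families are pragmatic stand-ins: the experiments
specify accuracies, not error distributions. The generators do not
emulate systematic sizing bias, curvature-dependent anomalous
migration on polyacrylamide, enzyme processivity, or sequence-dependent
denaturation — so passing recovery tests demonstrates estimator
correctness under the stated noise model, not robustness to every
artefact of real gels.

The packaged 336 bp sequence ships as a FASTA fixture; the 333/339 bp
variants (a 3 bp net deletion/insertion in the same region) and the
tandem-duplicated 666/672 bp circles are derived in code by
`minicircle_sequence()`.

## Problem sizes and reproducibility

The test-suite ensembles use 100 seeded replicates for recovery checks
(helical repeat within $\pm 0.02$ bp/turn in the mean; noisy site
localisation within $\pm 8$ bp in at least 95 of 100 runs; initial-rate
bias under 2%), 25-replicate sweeps for exactness properties, and
60-replicate ensembles for the $1/\sqrt{k}$ error-scaling trend —
sizes at which these checks are stable from seed to seed while the
whole suite runs in seconds. `run_pipeline()` threads a single seed
through every simulated input and excludes timestamps from its JSON
report, so identical configurations reproduce identical bytes.

## Limitations

* No twist/writhe decomposition, elastic energy, or denaturation
  thermodynamics: the package does arithmetic and estimation on
  measurable gel quantities only.
* Mapping resolution is bounded by fragment-sizing error and by the
  nucleases' own footprint; estimates carry the evidence dispersion,
  and nucleotide-level claims are out of reach.
* The threshold detector reports where the measured grid brackets a
  jump; it neither interpolates nor fits a transition model.
* Michaelis–Menten analysis, gel image quantitation and 3-D
  conformation analysis are out of scope.
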