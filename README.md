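# minicircletools

Quantitative analysis of supercoiled DNA minicircles probed with
structure-specific nucleases.

Small covalently closed DNA circles (a few hundred bp) with defined
linking numbers are a workhorse system for studying how supercoiling
and tight looping expose DNA bases. The measurements are gels: ladders
of topoisomers whose mobility calibrates the helical repeat, digestion
fragments whose lengths locate where a nuclease cleaved the circle,
and time courses whose slopes are cleavage rates. `minicircletools`
implements the estimators those measurements need:

* **Topology arithmetic.** For a circle of *N* bp with helical repeat
  *h*<sub>B</sub>, the relaxed linking number is
  *Lk*₀ = *N*/*h*<sub>B</sub>, the linking difference
  Δ*Lk* = *Lk* − *Lk*₀, and the superhelical density
  σ = Δ*Lk*/*Lk*₀. Both the exact (real) and nominal
  (nearest-integer) Δ*Lk* conventions are tracked; σ always uses the
  exact one. Helpers convert torsional strain into base-pair currency:
  bp melted per turn (|Δ*Lk*|·*h*<sub>B</sub>) and bp of B→P-DNA
  conversion needed to absorb an overwinding
  (Δ*Lk*/(1/*h*<sub>P</sub> − 1/*h*<sub>B</sub>)), plus the nick
  phase offset |*Lk*₀ − round(*Lk*₀)|.
* **Helical-repeat calibration.** Topoisomer gel mobility is V-shaped
  in Δ*Lk*: *m* = *m*₀ + *s*·|*Lk* − *Lk*₀|. `vfit_lk0()` finds the
  apex (the classical two-line intersection for three topoisomers,
  profiled least squares for more); `helical_repeat_from_lk0s()`
  pools constructs into *h* = mean(*N*/*Lk*₀) ± sd.
* **Cleavage-site triangulation.** A fragment of length *L* referenced
  to a restriction cut at *r* puts the unknown cut at (*r* ± *L*) mod
  *N*; candidates from several enzymes are clustered on the circle
  (circular mean ± circular sd) to localise the site and quantify the
  reflection ambiguity. Band volumes convert to molar site fractions
  (volume/length, normalised).
* **Cleavage kinetics.** Initial rates *k* = −d*f*/d*t* from linear
  fits on an uncut-fraction prefix window; continuous two-segment fits
  for multiphasic decays; fold ratios; and detection of the
  supercoiling threshold as the adjacent pair of sampled σ values with
  the largest fold jump in rate.
* **Synthetic data.** Seeded, deterministic generators for all three
  measurement types, used by the test suite for parameter-recovery
  checks against known truth.

The 336 bp minicircle sequence ships as a FASTA fixture together with
in-code derivation of its 333/339 bp variants and the tandem 666/672 bp
doubles.

## Worked example

```r
library(minicircletools)

# topology of the 336 bp topoisomer series at the calibrated repeat
topoisomer_table(336, c(26, 29, 31, 35), digits = 2)
#>   size_bp lk   lk0 dlk_nominal dlk_exact  sigma
#> 1     336 26 32.06          -6     -6.06 -0.189
#> 2     336 29 32.06          -3     -3.06 -0.095
#> 3     336 31 32.06          -1     -1.06 -0.033
#> 4     336 35 32.06           3      2.94  0.092
```

Each row gives the relaxed linking number (32.06 turns), the gel-label
and exact linking differences, and the superhelical density — Lk 26 is
hyper-negatively supercoiled (σ = −0.189), Lk 35 positively (+0.092).

```r
# calibrate the helical repeat from a synthetic three-construct ladder
calibrate_helical_repeat(gen_mobility_table(noise_sd = 0.02, seed = 42))
#> helical repeat: 10.48 bp/turn (+/- 0.01), 3 construct(s)

# map a cleavage site at position 143 from noisy fragment lengths
rmap <- restriction_map(minicircle_sequence("336"),
                        c("EcoRV", "XmnI", "BbvCI", "NdeI", "MseI"))
obs <- gen_fragment_observations(data.frame(position = 143, weight = 1),
                                 rmap, length_sd = 5, seed = 42)
triangulate_sites(obs, rmap)
#>     position  error_bp n_support n_candidates                    enzymes
#> 1 145.998529  3.873733         5           10 BbvCI,EcoRV,MseI,NdeI,XmnI
#> 2   5.258857 10.809424         2            4                  NdeI,XmnI
```

The top cluster recovers the true site (146 ± 3.9 bp, all five
reference enzymes agreeing); the weaker second cluster is an artefact
of two mirror images falling close together — exactly the ambiguity
the support count is there to rank down.

```r
# a 180-fold rate difference, as quoted
report_fold(fold_ratio(4.31e-3, 2.40e-5))
#> [1] 180
```

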