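---
title: "Modeling the genome-wide distribution of repeat tract lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the genome-wide distribution of repeat tract lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drldyn)
```

## The scientific problem

Simple tandem repeats (microsatellites; 1–6 nt motif units) are vastly
over-represented in mammalian genomes relative to a random sequence of the
same base composition, and the shape of the genome-wide *distribution of
repeat tract lengths* (DRL) is strikingly conserved across related species.
`drldyn` implements a complete modeling chain asking whether mutation alone —
no selection — can create and maintain that distribution:

1. **Extraction** (`extract_drl()` and friends): tally maximal uninterrupted
   tracts of each motif class from sequence, with motifs pooled over cyclic
   permutations and reverse complements.
2. **Rates** (`substitution_rates()`, `build_rate_table()`): length-resolved
   per-generation rates for every mutational process that changes a tract's
   length — boundary substitutions that lengthen or shorten it, interior
   substitutions and non-motif insertions that split it ("fission"),
   substitution or deletion of a single interrupting unit that rejoins two
   tracts ("fusion"), and the length-unstable expansion/contraction indels.
3. **Dynamics** (`evolve()`): a deterministic (optionally Poisson-stochastic)
   master-equation kernel that evolves the paired histograms of repeat
   tracts and non-repeat ("B") stretch lengths under those processes,
   with time-rescaling and a step-wise speed-up schedule.
4. **Inference** (`infer_grid()`): grid Approximate Bayesian Computation
   with a Kullback–Leibler rejection kernel, priors built from mid-length
   population rate estimates, Bayes-factor model comparison, HDRs, and
   posterior-weighted expectations.
5. **Steady state** (`solve_steady_ode()` etc.): analytic/numerical
   characterization of the equilibrium — the short-repeat geometric law,
   the crossing length `L*` where contraction overtakes expansion, the
   truncation length, and three nested continuum approximations of the
   long-repeat balance.

## The model

The genome is abstracted to a binary sequence of motif units ("A") and
everything else ("B").  The state is a pair of histograms: `a[L]`, the
number of A tracts of `L` units, and `b[k]`, the number of B strings of `k`
sites.  Per generation, expected per-bin fluxes are computed from the
start-of-generation state and applied simultaneously:

* lengthening substitutions (context BBA>BAA) move `L -> L+1` and shorten
  an adjacent B string; shortening (AAB>ABB) is the mirror image;
* fission substitutions (AAA>ABA) act on the `L-2` interior units and
  replace one tract by two fragments whose lengths sum to `L-1`, spread
  evenly over the eligible bins, creating a single-site B string;
* fusion (ABA>AAA) consumes a length-1 B string and joins its two flanking
  tracts; the consumed pair is drawn from the self-convolution of the
  normalized tract distribution, and the counts removed from the low bins
  follow the even-subtraction rule (see *Numerical choices*);
* expansions and contractions act at per-target rates `eps(L)` and
  `kap(L)` with target size `L`; non-motif insertions act at `iota(L) =
  eps(L)/100` on the `L-1` internal junctions and are a second fission
  channel; single-unit creation/destruction (BBB>BAB, BAB>BBB) and B-string
  indels complete the bookkeeping;
* a reflective boundary assigns any transition beyond the modeled range to
  the last bin.

Substitution rates are length independent (defaults are the printed mono-A
trio estimates); the instability rates rise steeply with length and are the
inference target.  Above `L = 8` they are parameterized by nested families
(symmetric, shared-constant, shared-exponent, multiplier-coupled and fully
decoupled power laws; logarithmic variants; and a fully parameterized
"pure" power law anchored on the substitution rates), all reproduced by
`build_rate_table()`.

### Tunable parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `eps(8)`, `kap(8)` | per target per generation | 1.1e-8 / 7.0e-9 | anchor of every multiplier family; slight expansion bias at `L = 8` |
| `m` | — | grid 1–10 | discrete jump of both rates at `L = 9` |
| `tau_eps`, `tau_kap` | — | grid 0–4 | power-law exponents; `delta_tau = tau_kap - tau_eps` governs stability |
| `iota/eps` | — | 1/100 | non-motif insertion fraction of insertions |
| `L_min`, pseudocount | — | 4, 1 | KL comparison window and regularization |
| saturation threshold | probability | 0.1 | single-event regime bound for the speed-up |
| `L_cap` | units | 200 | modeled length range |

## What the synthetic-data module emulates

`generate_genome()` draws i.i.d. sequence at a chosen unit fraction — the
null against which repeat excess is defined.  `sequence_level_simulate()`
applies the mutational processes literally to an explicit (circular,
run-length encoded) sequence with no bin bookkeeping; fission and fusion
*emerge* from the sequence, which is why it serves as the independent
correctness oracle for the kernel.  `generate_primate_ensemble()` draws
gamma-Poisson perturbed copies of a base DRL (default dispersion 100,
i.e. ~10% per-bin variation, a once-chosen stand-in for the tight spread
observed among related genomes) and applies the count-30 truncation rule,
standing in for an ensemble of related assemblies when setting the ABC
rejection scale.  `generate_trio_events()` emits labelled indel events with
flanking context for the classifier/estimator round trip.

What passing tests on these data do **not** show: real assemblies carry
correlated, non-Poisson bioinformatic error (collapsed or expanded repeat
regions, coverage-dependent dropout), interrupted/imperfect repeats are not
tolerated by the strict tract definition, and the per-length empirical
rates below `L = 9` shipped with the package are a synthetic stand-in
(`empirical_rates_mono_a()`), constructed once from printed constraints —
rapid rise between `L = 5` and `10`, expansion bias at `L = 8`, anchor
values compatible with the published maximum-posterior rate constants —
not measured data.

## Numerical choices

* **Context-exact lengthening target.**  The aggregate lengthening flux
  uses the exact number of BBA contexts, `2 x #{B strings of length >= 2}`,
  allocated over tract bins by occupancy, rather than a flat target of two
  per tract.  A flat target silently double-counts boundary sites adjacent
  to single-site B strings, which belong to the fusion context ABA>AAA.
  With the context-exact target (and two-way substitution rates) the
  geometric distribution is an *exact* fixed point of the kernel — we
  verified this analytically and to machine precision numerically — and
  the kernel agrees with the sequence-level oracle within Monte-Carlo
  error.  The flat variant remains available
  (`sim_config(context_lengthening = FALSE)`).
* **Fusion pairing.**  Only the subtraction side of fusion has a stated
  aggregate rule (even subtraction over eligible bins).  Product lengths
  are allocated by the self-convolution of the normalized tract
  distribution (flanks of a single-site B string are approximately
  independent draws from it).  At a geometric state the two choices
  coincide exactly: conditional on the pair sum, geometric pairs are
  uniform.  A count-weighted subtraction variant exists
  (`fusion_subtract = "weighted"`).
* **Non-motif insertion target `L - 1`.**  An interrupting insertion must
  land on one of the `L - 1` internal junctions; using `L` would count
  boundary insertions that do not split the tract.
* **Shape-steady state and the growth mode.**  Indels do not conserve
  genome size, so the late-time deterministic state is *shape*-steady with
  a uniform exponential drift of the overall scale (`net[L] = g a[L]`,
  `g ~ 1.6e-10` per generation at the reference parameters).  Convergence
  detection and the per-bin balance residual remove this common mode
  (`flux_decomposition()` reports `growth_rate` and `net_shape`); the raw
  residual plateaus near 1% however long the run.
* **Short-repeat law and context heterogeneity.**  The geometric law with
  ratio `mu/(mu+nu)` is exact for a two-way substitution process.  The
  empirical context rates are *not* two-way-consistent (e.g. the fusion
  and fission context rates are not in the `mu:nu` ratio), which shifts
  the short-repeat occupancy ratio by about 2% per bin; tests of the exact
  law therefore use `two_way_rates()`.
* **Divergence handling.**  Expansion-biased parameter combinations
  (`delta_tau <= 0`) grow without bound; `evolve()` stops such runs when
  the tract count exceeds `diverge_factor` times its start, or when the
  boundary bin is populated and growing, and flags them.  `infer_grid()`
  treats flagged combinations as hard-rejected (the late-time comparison
  the method calls for does not exist for them).
* **Speed.**  The kernel iteration is compiled; the fusion convolution
  drops bins below `conv_support_tol` (default 1e-14 relative) — set it to
  0 for exact-arithmetic checks.  The continuum boundary-value problems are
  linear in `P`, so they are solved exactly by superposing basis
  initial-value integrations (`deSolve::lsoda`, rtol 1e-10) and matching
  the point constraints at `round(L*)` and the integers bracketing
  `L_trunc` (plus `L_trunc - 1` for the third-order equation).

## Problem sizes used by the tests and acceptance script

Runs are scaled to desk size as the package's reference conditions: the
oracle-equivalence experiment uses a 1e5-nt genome, 1000 generations and
200 replicates with each process inflated to >= 100 expected events; the
recovery experiment uses a 5 x 9 x 9 grid with a fixed per-cell iteration
budget (2e5 iterations at the 10^3 speed-up stage plus 3e4 at each later
stage) shared between the truth run and every grid cell; regime runs use
the full step-wise schedule with steady-state early stopping at a 1e-4
shape residual.  The full four-stage reference schedule (1e6 iterations per
stage, 1.111e9 generations when every stage runs) is the default of
`sim_config()`.

## Design choices where the design was genuinely open

* The inference grids (ranges and spacing) are nowhere fully specified in
  the source material; defaults are log-spaced constants over 1e-9–1e-6,
  exponent grids 0–4 in steps of 0.1, the multiplier ladder
  1, 1.6, 2.5, 4, 6.4, 10, and integer onset lengths 4–20
  (`default_grid()`), all configurable.
* The ensemble scale rule keeps the maximum of the retained divergences
  (after dropping the largest ~5%) rather than a smoothed percentile.
* KL uses natural logarithms; the pseudocount applies to every length
  class of both distributions before conditional renormalization on
  `[L_min, L_max]`.
* Maximum-posterior ties break toward lexicographically smallest
  coordinates; HDRs accumulate rank-ordered cells with stable tie
  breaking.
* The median of an even-sized ensemble is the mean of the two central
  values.

## Known limitations

* The continuum steady-state equations carry a discreteness error of order
  `s^2/6` where `s` is the per-bin log-slope of the DRL; in strongly
  truncating regimes (`s ~ 1.2`) this is a 15–50% effect near the
  truncation point even though the *nesting pattern* of the approximations
  reproduces cleanly.  The weak-regime solutions also inherit a kink at
  `L = 9–12` from the multiplier jump in the rates.  See
  `analysis/05_steady_state.R` for the measured per-regime accuracy.
* Interrupted repeats, locus-level heterogeneity, selection and genetic
  drift (beyond the optional Poisson sampling of mutation counts) are out
  of scope by construction.
* B-string dynamics use length-independent per-unit rates; only the
  single-site B class feeds back on the tract dynamics (through fusion).

## A minimal end-to-end run

```{r example, eval = FALSE}
report <- run_pipeline(list(
  seed = 1,
  genome_length = 3.1e9,
  truth = c(m = 4, tau_eps = 1.6, tau_kap = 2.0),
  grid = expand.grid(m = c(2.5, 4, 6.4),
                     tau_eps = seq(1.2, 2.0, 0.4),
                     tau_kap = seq(1.6, 2.4, 0.4)),
  ensemble_n = 12))
str(report)
```

The numbered scripts under `analysis/` run the same stages at full
reference scale and leave their tables under `results/`.
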