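---
title: "Actual causes of protein corona remodeling: methods and design"
author: "CoronaCausality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actual causes of protein corona remodeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoronaCausality)
```

## The problem

When nanoparticles meet blood plasma they acquire a protein corona, and the
corona's composition — not the bare particle — is what cells see.  Spiking
small molecules (lipids, metabolites, vitamins) into plasma before
incubation remodels the corona: highly abundant proteins such as albumin
can be depleted from the particle surface, letting low-abundance proteins
attach and deepening proteome coverage.  Given per-protein log2 fold
changes (treated vs. untreated corona) across a panel of spiked molecules
and concentrations, the scientific question is *which* treatment actually
caused the desirable remodeling — a token-level causal question that
correlation screens cannot answer, because a molecule can co-occur with the
effect without producing it.

CoronaCausality implements a token-level (actual-causality) analysis in the
Halpern–Pearl tradition, with the probabilistic probability-raising
replacement for the counterfactual clause:

* **AC1** — the candidate assignment `X <- x` (e.g.
  `Small_Molecule <- PtdChos`) and the effect φ occur together in at least
  one record;
* **PC2** — the probability of φ among records where `X = x` strictly
  exceeds its probability in the *contingency-matched counterfactual
  worlds*: records with `X != x` whose every other variable equals that of
  some actual-world record;
* **AC3** — minimality, automatic here because only singleton assignments
  are searched.

An assignment is an actual cause iff all three hold.  Identified causes are
then *ranked* by the conditional probability
`P(phi | X = x) = count(X = x and phi) / count(X = x)`; ranking never
substitutes for the causal test itself.

## The empirical causal model

The model is a long-format table: one record per
(protein × molecule × concentration) carrying a log2FC value.  The schema
assigns roles: `Protein_ID` and `Concentration_of_Molecule` are context
variables, `Small_Molecule` is the candidate variable, `log2FC` is the
outcome.  Domains are empirical — the analysis quantifies only over
observed worlds, so conclusions are relative to the data set, which is the
method's central epistemic caveat: a larger table means better coverage of
counterfactual worlds.

Counterfactual matching is exact equality on all non-outcome variables
other than the one under test.  Contexts realized only outside the actual
world enter neither side of the comparison.

## The effect predicate

The desirable effect is class-conditional: depletion of the 25 highly
abundant plasma proteins (packaged fixture, albumin first) and enrichment
of everything else.  With thresholds θ_a and θ_r:

* `depletion_enrichment` (default): φ is true iff the protein is abundant
  and log2FC ≤ θ_a, or not abundant and log2FC > θ_r.
* `enrichment_only`: φ is true iff abundant and log2FC ≥ θ_a, or not
  abundant and log2FC ≤ θ_r.

Both orientations are implemented because both conventions circulate for
this design and they are mutually inconsistent; the default matches the
stated biology (albumin depletion opens proteome depth) and is what the
threshold sweep uses.  Boundary conventions are a
design choice, fixed and tested: `<=` on the abundant side, strict `>` on
the rest side (and `>=`/`<=` in the alternative orientation).  Records at
exactly the threshold therefore count for the abundant class and do not
count for the rest class.  Both thresholds default to 0.1 log2 units — a
deliberately small displacement from "no change" that still demands
movement in the desirable direction.

## Exact probabilities and PC2 aggregation

All probabilities are exact ratios of record counts, kept as reduced
integer numerator/denominator pairs; PC2 is decided by cross-multiplication
so no floating-point comparison can flip a verdict, and ties are never
causes (strict raising).

How per-context counterfactual probabilities combine into one number is
genuinely underdetermined, so both conventions are first-class:

* `pooled`: all matched counterfactual records form one pool,
  `p_cf = sum(k_c) / sum(m_c)`.
* `standardized` (default): per-context rates are averaged with weights
  proportional to each context's share of actual-world records,
  `p_cf = sum(w_c * k_c / m_c)`, `w_c ∝ n_c`.

The two coincide on balanced designs (a tested invariant) — in particular
on the full factorial design the corona study uses — but differ when
contexts are unbalanced: pooling lets a Simpson-type reversal smuggle a
confounded correlation through PC2, while standardization compares like
with like.  The packaged six-record season/ice-cream table
(`simulateConfounded()`) is the minimal demonstration: pooled PC2 calls
ice cream a cause of the outcome, standardized PC2 rejects it, and the
season is a cause under both.

One stated approximation: `p_actual` is computed over *all* records with
`X = x`, including those in contexts with no counterfactual counterpart;
such contexts contribute to `p_actual` but cannot contribute to `p_cf`.
The alternative (restricting `p_actual` to matched contexts) discards
actual-world evidence; we prefer keeping it and note that the
confounder-rejection guarantee of the standardized mode is exact when
every actual context has a counterpart.

Ranking ties are broken deterministically: conditional probability
(descending), then actual-world support (descending), then variable, then
value lexicographically — so output files are byte-stable.

## The threshold sweep

Because any single threshold pair is arbitrary, the analysis is repeated
over a 2-D grid: θ_a from the minimum observed log2FC up to 0.1, θ_r from
0.1 up to the maximum, endpoints included, linear spacing by default
(quantile spacing available).  Each cell runs the full cause search and
stores the top three causes or `None`.  The default resolution is 20 × 21
= 420 cells: the grid used for sweeps in this package's own summaries, a
size at which published occurrence percentages in this design resolve to
integer cell counts, and small enough that a full sweep on a
study-scale table runs in seconds.  `frequencyTable()` reports, per rank,
each molecule's share of cells with `None` tracked separately (shares sum
to 100% by construction; raw counts are kept alongside so either
denominator convention is recoverable), and `top3MembershipRate()` gives
the share of cells where a molecule appears at any of ranks 1–3.

As thresholds approach the data extremes the effect support shrinks to
the empty set and cells become `None`; this monotone degeneracy is tested.

## The synthetic generator

`simulateCorona()` emulates the study design so every stage is testable
without external data: one record per cell of the factorial design,

```
log2FC(p, m, c) = gain(c) * shift(m, class(p)) + N(0, noiseSd^2)
```

where the planted cause shifts abundant proteins by `depletionShift` (−1
by default) and the rest by `enrichmentShift` (+1), and each null molecule
draws a single nuisance shift from `N(0, nullShiftSd^2)`.  Defaults — 20
proteins with 5 abundant, 8 molecules, concentrations 10/100/1000, shifts
±1, both standard deviations 0.2, unit concentration gain — are chosen
once as a desk-scale caricature of the design: shifts of one log2 unit are
the order of magnitude a strongly remodeling molecule shows, nuisance and
record noise at 0.2 keep null molecules clearly inside the ±0.1 threshold
band most of the time while still overlapping it, and unit gain encodes
the concentration-independence the analysis should detect.  Under these
conditions the planted molecule is recovered at rank 1 in ≥ 90% of seeds
(in practice essentially always) and recovery is perfect at zero noise —
calibrated properties asserted by the tests.

What the generator does *not* emulate: mass-spec missingness, intensity-
dependent variance, correlated protein families, or any binding physics.
Passing tests demonstrate the correctness of the counting, matching, and
ranking machinery under a known ground truth — not that the method's
verdicts on real coronas are biologically final.

A note on one degenerate corner: at θ_a = 0.1 a noise-free *null* molecule
(shift 0) also satisfies the abundant-side clause (0 ≤ 0.1), so the
effect's support is larger than the planted records alone; the planted
molecule is nevertheless the unique identified cause because PC2 fails
for null molecules.  The support-equals-planted-records identity holds at
thresholds strictly inside the planted shifts (e.g. −0.5/0.5), which is
where the tests assert it.

## Numerical and degenerate-input choices

* Record counts and their ratios are exact; an overflow guard trips far
  above any realistic table size rather than losing exactness silently.
* A candidate value observed in only one variant (no counterfactual world
  at all) gets `p_cf` undefined and PC2 false, never an error.
* Rows with missing or non-finite outcome are rejected at read time and
  counted by reason; imputation is out of scope by design.
* A sweep on data whose log2FC range does not straddle 0.1 is refused as
  degenerate rather than silently producing an empty axis.
* Axes, value orderings, and file outputs are sorted with radix order so
  results are locale-independent.

## Reproducing a study-style analysis

`reproduceStudy()` (or the `reproduce` pipeline task) isolates the
external-data path: given a user-supplied long-format log2FC table it runs
the default 20 × 21 sweep and reports the focal molecule's rank-1 cell
percentage, its top-3 membership percentage, and the full rank-frequency
table.  The package's tests exercise this pathway end-to-end on a
synthetic stand-in with a planted focal molecule; applying it to the
original experiment requires that experiment's supplementary table, whose
exact column layout can be adapted via the reader's column mapping.

```{r example, eval = FALSE}
m <- simulateCorona(coronaSimConfig(seed = 7))
phi <- effectPredicate(abundantIds = modelMetadata(m)$abundant_ids)
findCauses(m, phi)

grid <- runSweep(m, phi, buildGrid(m))
head(frequencyTable(grid))
top3MembershipRate(grid, "M01")
```

## Known limitations

* Only singleton causes are searched; interactions between molecules are
  outside AC3's reach here (the two fixed "sauce" mixtures are treated as
  single candidate values, as in the source design).
* Verdicts are relative to the empirical table: unobserved counterfactual
  worlds simply do not exist for the analysis, so adding data can change
  conclusions.
* The sweep's grid resolution is a presentation choice; percentages are
  reported with their raw counts so other resolutions can be compared.
* Type-level (interventional) causality and time-series (Granger)
  causality are different questions and are intentionally not addressed.
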