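---
title: "Measuring mRNA half-lives with intron-anchored normalization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mRNA half-lives with intron-anchored normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druidr)
```

## The kinetic model

An approach-to-equilibrium labeling experiment incubates cells with a
nucleoside analog (typically 4-thiouridine) for increasing times `t` and
sequences the purified, labeled RNA. Under steady state — constant synthesis
`S` and first-order decay `lambda` per transcript — the labeled pool of a
transcript rises as

$$N(t) = N_0\,\bigl(1 - e^{-(\lambda+\gamma)t}\bigr),$$

where `N0 = S/(lambda + gamma)` is the steady-state level and
`gamma = ln(2)/delta` is the dilution contributed by cellular growth with
doubling time `delta`. Unstable transcripts approach their plateau quickly;
stable ones slowly. Fitting this curve per gene and converting
`hl = ln(2)/lambda` gives the half-life. Shutoff experiments (actinomycin D,
alpha-amanitin) are the complementary design: the pool decays as
`N0 * exp(-lambda*t)` from `t = 0` and is fit by `fit_exponential_decay()`.

Two assumptions are load-bearing. First, the system must be at steady state:
the package cannot describe settings where synthesis or decay rates change
during the course (differentiation, stress responses). Second, sequencing is
compositional — each library reports fractions of a fixed read total — so a
per-time-point normalization factor is required before any kinetics can be
read off.

## Why introns can replace spike-ins

The classical factor is an exogenous spike-in added at a constant ratio to
the extracted RNA. `druidr` also supports a fully endogenous factor: the
summed coverage of short-lived introns. Intron-containing species (excised
introns, co-transcriptional processing intermediates) decay within minutes,
so their labeled pool is at steady state before the first sample is taken;
from then on their summed signal is a constant anchor per cell-equivalent of
RNA, exactly like a spike-in — but measured in the same tube, subject to the
same losses, and available retroactively for any data set.

Not every annotated intron behaves this way: retained and misannotated
introns ride along with their mature mRNA and accumulate through the course.
The package therefore filters introns to a mean per-base coverage of at least
0.5, mean-scales each profile (shape, not magnitude), clusters the profiles
with k-means (`k = 4`), and scores each cluster centroid by its Spearman
correlation with time, breaking ties by the total positive increment
`sum(pmax(diff(centroid), 0))`. The most negative score — the cluster closest
to the expected non-increasing profile, since an equilibrated species' share
of a growing labeled library can only fall — supplies the normalization set.
The historical practice is to pick this cluster by eye; the score automates
that choice deterministically, and `select_cluster` overrides it when a
manual call is preferred. The full report (memberships, centroids, scores) is
always returned and written to disk so the choice is auditable.

## Growth correction and the two normalization modes

In spike-in mode the fit applies `gamma = ln(2)/delta`; in intron mode it
applies `gamma = 0`. The package treats the second convention as what it is:
an assumption that the intron factor, being synthesized by the same growing
transcriptome, absorbs the dilution term. A caveat deserves honesty here. In
a fully self-consistent steady-state model of an exponentially growing
culture, the summed equilibrated-intron signal and a constant-ratio spike-in
are proportional to each other, so the two normalizations yield the same
curve and the same `gamma` would apply to both; fitting intron-normalized
data from growing cells with `gamma = 0` then overestimates `lambda` by
exactly `gamma` — a negligible error for unstable transcripts but a
compression of the longest half-lives toward `delta/ln(2)`. This is visible
in practice as intron-normalized half-lives running slightly shorter than
spike-normalized ones for stable genes.

For this reason the simulator's reference configuration is a quiescent
culture (`doubling_time = Inf`, so `gamma = 0`): it validates the estimator
in the regime where the intron-mode assumption holds exactly, which is what
makes the noise-free end-to-end inversion test meaningful at a 1e-6
tolerance. Growth is a first-class simulator parameter (`doubling_time`), and
users studying fast-growing cells should either supply spike-ins (where the
correction is explicit) or read intron-mode half-lives of
near-doubling-time transcripts as lower bounds.

## The simulator

`simulation_truth()` plus `simulate_labeling_experiment()` generate complete
experiments with known ground truth:

* per-cell labeled pools follow the bounded-growth closed form; culture
  totals scale as `exp(gamma*t)`; unlabeled pools decay at `lambda`;
* introns are attached to host genes at 5–50% of the host's abundance
  (log-uniform), putting intron-mapping reads at roughly a fifth of early
  libraries; well-behaved introns have 2-minute half-lives (equilibration
  residual below 1e-9 at 1 h), and 60% of introns are "misbehaving" —
  retained or misannotated, decaying at mRNA-like rates (half-lives 2–36 h)
  so that they accumulate and must be excluded by the clustering step;
* a labeled and an unlabeled spike-in are added at 2% of total RNA mass each;
  purification keeps the labeled pool plus a 1% unlabeled carryover
  (`enrichment_qc()` should therefore read about 100);
* each library is a fixed-depth multinomial draw (default 2e6 reads) over the
  resulting composition — the compositional constraint of sequencing —
  with `sampling = "expected"` available to disable counting noise; intron
  read counts become mean coverage through a read-length/intron-length
  divisor (50 nt / 1000 nt defaults).

Default gene-level truth: 500 genes, decay constants log-uniform between
`ln(2)/36` and `ln(2)/0.25` per hour (half-lives 15 min – 36 h), steady-state
abundances log-uniform over two decades, sampled at the standard 1, 2, 4, 8,
12, 24 h design.

`simulate_recalcitrant()` reproduces the two failure signatures that make
real experiments unusable under spike-in normalization: spike-in mass scaled
down 100-fold (`few_spikein_reads`, which trips the "insufficient spike-in
reads" floor), and a time-dependent distortion of the spike-in mass,
`exp(0.15*t)` by default (`biased_spikein`), which leaves roughly half the
genes unfittable in spike-in mode and skews the rest while the intron factors
are untouched. A note on that choice: any gene-independent factor distortion
maps true to fitted decay constants monotonically (the bounded-growth family
is pointwise ordered in `lambda`), so mild distortions bend half-lives
without scrambling their ranks; the default drift is strong enough to destroy
the information content of the late time points, which is what actually
degrades rank agreement, robustly across random seeds.

What the simulator does **not** model: read-level effects (sequence content,
GC, mappability), isoform structure, label-incorporation efficiency, UMI or
duplication artifacts, batch effects between replicates, or cell-cycle
structure beyond smooth exponential growth. Passing the simulation-based
tests therefore demonstrates that the estimator inverts its own generative
model and tolerates counting noise and corrupted spike-ins — not that any
particular real library is free of alignment or annotation pathology. The
annotation and quantification stages (longest-transcript feature model,
ambiguity-discarding union counts, per-base intron coverage) are tested
separately against brute-force oracles.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `time_points` | 1, 2, 4, 8, 12, 24 | h | log-spaced coverage of 15 min – 36 h half-lives; three points (1, 8, 24 h) already determine the two-parameter model |
| `doubling_time_hours` | 24 | h | typical cultured mammalian line; `Inf` for quiescent cells |
| `min_count_all` / `min_count_any` | 1 / 5 | reads | genes with a zero time point or never 5 reads carry no usable kinetic signal |
| `min_intron_coverage` | 0.5 | mean reads/base | below this the intron profile is dominated by counting noise |
| `k` | 4 | clusters | separates decreasing / flat / increasing / transient profile families |
| `min_spikein_reads` | 1000 | reads/time point | below ~1000 reads the factor's Poisson CV exceeds ~3% and normalization noise rivals fit noise; zero always fails |
| `weights` | `"poisson"` | — | `w = 1/max(fitted, 1e-8)`, iteratively reweighted twice: count-derived signal is heteroscedastic; `"uniform"` available |
| `lambda_bounds` | 1e-5 – 50 | /h | half-lives 50 s – 8 years; a fit on a bound is flagged, not reported |
| `saturation_limit` | 0.99 | — | if the first sample sits above 99% of plateau only a lower bound on `lambda` exists; the gene is excluded rather than misreported |

## Numerical choices

* **Optimizer.** `minpack.lm::nlsLM` (Levenberg–Marquardt with box bounds),
  `ftol = 1e-13`, `ptol = 1e-11`, 500 iterations. Starting values are
  deterministic: `N0` from the series maximum, `lambda` from a log-linear
  regression of `-log(1 - y/(1.05*N0))` on `t` (fallback
  `ln(2)/median(t)`). Noise-free series are recovered to better than 1e-6
  relative error across the full parameter grid.
* **Per-gene failure is data, not an exception.** Optimizer failures, bound
  hits, and saturated (information-free) series yield `converged = FALSE`
  rows; such genes simply carry no half-life, mirroring how poorly normalized
  genes drop out of real analyses.
* **`t = 0` points** are excluded from bounded-growth fits (no labeled
  measurement exists before labeling) but required by decay fits (they anchor
  `N0`).
* **k-means determinism.** Profiles are sorted by intron id before
  clustering, and restarts (25) use explicitly sampled *distinct* initial
  centers under a fixed seed with Lloyd iterations — robust to the many
  duplicate profiles an equilibrated intron set produces, and invariant to
  input order. Degenerate cases (fewer introns or distinct profiles than `k`)
  reduce `k` with a warning, down to a single all-intron cluster; constant
  centroids receive a monotonicity score of 0.
* **Coordinates.** Intervals live in `GRanges` (1-based, closed), the native
  convention of the R genomics stack; GTF input is read by `rtracklayer` and
  BED6 output is written half-open by the same library. An intron and an
  exon that merely abut share no base and never trigger the overlap filter.
* **Intron overlap scope.** An intron is removed if it overlaps an exon of
  *any* gene's isoform (strand-agnostic) — the conservative reading, since
  mature-mRNA contamination is the concern; `scope = "same_gene"` restricts
  the check to the intron's own gene.
* **Strandedness** defaults to `"reverse"` (dUTP-style stranded chemistry);
  exon counting is union mode with ambiguous reads discarded and
  off-annotation chromosomes tallied in an explicit `unassigned` bucket.
* **Correlation scales.** Replicate comparisons report Spearman on
  half-lives and Pearson on log10 half-lives (the distribution is
  heavy-tailed; linear-scale Pearson is a flag away). The Fisher r-to-z test
  is exposed as the standard two-correlation comparison; applying it to
  Spearman coefficients treats them as Pearson correlations, which is the
  conventional, slightly approximate practice.
* **Reported precision.** Half-lives are written to TSV with 4 significant
  figures; in-memory values are full precision.

## Problem sizes used by the test suite

The packaged checks run 500-gene simulations at 2e6 reads per time point
(one noise-free, several multinomial draws, two recalcitrant variants), a
200-fit parameter grid, and 1000-row filter oracles — sizes at which every
stage's behavior is already asymptotic while a full run of the suite stays
near a minute on a laptop. Larger simulations change none of the measured
properties, only the sampling error around them.

## Known limitations

* Steady state is assumed throughout; time-varying synthesis or decay is out
  of scope by construction.
* Intron normalization needs enough expressed, well-behaved introns to pass
  the coverage filter; in intron-poor genomes (budding yeast) the selected
  set is small and the factor correspondingly noisier.
* Intron-mode fits of transcripts with half-lives near or beyond the
  doubling time inherit the `gamma = 0` convention discussed above.
* The quantifier assigns reads to one representative transcript per gene; no
  isoform-level quantification (or EM read reassignment) is attempted.
* No hierarchical shrinkage across genes: each gene is fit independently,
  so very low-abundance genes have wide half-life uncertainty rather than
  borrowed strength.
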