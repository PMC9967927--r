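---
title: "Methods: diversity statistics, null-allele correction and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics, null-allele correction and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdiv)
```

## What the package models

`markerdiv` analyses panels of co-dominant nuclear markers — bi-allelic SNPs
and multi-allelic SSRs (microsatellites, scored as PCR fragment lengths in
base pairs) — typed on individuals grouped into populations. The motivating
use case is assessing inbreeding and population structure in introduced
insect populations (for example, biological-control or pollinator species
founded from a small number of released individuals), where the question is
whether heterozygosity has been eroded by a founder effect, and where SSR
panels are vulnerable to a specific artefact: *null alleles* that fail to
amplify in PCR, so heterozygotes carrying one null allele are mis-scored as
homozygotes and null homozygotes appear as missing calls. The package
implements the full chain: marker QC, diversity statistics, a null-allele
diagnosis and correction, and distance/ordination views of population
structure — plus a generative simulator so every stage can be validated
against known truth.

## Diversity statistics

All statistics are computed over *called* genotypes only; missing calls are
excluded from both numerators and denominators. For a locus with allele
frequencies $p_1, \dots, p_k$:

* **MAF** (major allele frequency): $\max_i p_i$.
* **Expected heterozygosity** (gene diversity): $H_e = 1 - \sum_i p_i^2$.
  No small-sample correction is applied by default: the classical unbiased
  correction multiplies by $2n/(2n-1)$, and which convention legacy
  marker-analysis programs used is rarely stated, so the plain estimator is
  the transparent default and the convention is recorded in every run
  manifest.
* **Observed heterozygosity**: $H_o$ = fraction of called genotypes that are
  heterozygous.
* **PIC** (polymorphism information content, Botstein):
  $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$. For a
  bi-allelic locus its maximum is $0.375$ at $p = 0.5$; PIC $\le H_e$ always
  (property-tested on random frequency simplexes).
* **Inbreeding coefficient** (Wright): $F_{is} = 1 - H_o / H_e$, undefined
  at monomorphic loci ($H_e = 0$). Undefined values propagate as `NA` flags
  and are excluded from means — never coerced to zero.

At the population level the package reports, per population, the unweighted
means over loci (with at least one called genotype) of MAF, $N_A$, $H_e$,
$H_o$ and PIC. Population $F_{is}$ is the **unweighted mean of per-locus
$F_{is}$ over loci with $H_e > 0$**, not $1 - \bar H_o / \bar H_e$. The two
aggregations differ; published per-population tables in this literature are
generally consistent with per-locus averaging, and the choice is logged in
the run manifest. A grand `Mean` row is the unweighted mean of the
population rows.

### Hardy-Weinberg and linkage screens

The HWE test is a Monte-Carlo exact test: the $2n$ called alleles are pooled
and re-paired uniformly at random (default 10,000 permutations); the test
statistic is the heterozygote count, and the two-sided p-value is
$2\min(\text{tail fractions})$ capped at 1, with the observed panel counted
in its own tail (add-one smoothing). A heterozygote-count statistic is
simpler than a full genotype-probability ordering and is adequate for
screening deficiency or excess; it is deterministic under a seed.

Linkage disequilibrium between two loci is the squared Pearson correlation
of major-allele dosages (0/1/2) over individuals called at both loci. The
dosage collapse is a convention for multi-allelic SSR pairs — published
panel screens report a single $r^2$ per pair without stating a
multi-allelic method — and it is logged per run.

## Null alleles: estimation and correction

With a null allele segregating at frequency $r$ in a random-mating
population, visible/null heterozygotes are scored as homozygotes and
null/null genotypes as missing, so apparent $H_o$ is deflated and $F_{is}$
is biased upward — spurious evidence of inbreeding. The package estimates
$r$ per locus with the **Brookfield-1** estimator

$$ r = \max\!\left(0, \frac{H_e - H_o}{1 + H_e}\right), $$

clamping at zero on heterozygote excess (no null-allele evidence), and
classifies it as negligible ($r < 0.05$), moderate ($0.05 \le r < 0.20$) or
large ($r \ge 0.20$), with the boundaries closed/open exactly as stated.

Correction rescales each visible allele frequency by $1 - r$ and appends a
`NULL` pseudo-allele at $r$. Both heterozygosities are then re-expressed on
the all-individuals scale:

$$ H_e^{adj} = 1 - (1-r)^2 (1 - H_e) - r^2, \qquad
   H_o^{adj} = H_o (1 - r^2) + 2 r (1 - r), $$

and $F_{is}^{adj} = 1 - H_o^{adj} / H_e^{adj}$. The $H_o$ term rescales the
called-genotype heterozygosity by the called fraction $1 - r^2$ and restores
the visible-by-null heterozygotes that were mis-scored as homozygotes. When
the *true* $r$ is supplied, this adjustment is an algebraic identity: for a
random-mating population the adjusted $F_{is}$ is exactly 0 (the test suite
proves this to $10^{-6}$ over random spectra). Under Brookfield-1
*estimation* the correction is approximate — the estimator itself is biased
at finite $n$ — so the correction should be read as bias reduction, not
exact recovery, and the package's validation asserts exactly that (median
absolute adjusted $F_{is}$ below half the median raw $F_{is}$).

Estimates are available globally (the per-marker report default) and per
population (feeding the adjusted-$F_{is}$ column of the population table).
The $H_e$/$H_o$ inputs use called genotypes only; how legacy null-allele
software handled blanks is not verifiable, so the convention is recorded in
the output metadata.

## Population structure

**Nei's standard genetic distance** (1972) between two populations uses
locus-averaged identities: $J_x = \overline{\sum_i x_{li}^2}$, $J_y$
likewise, $J_{xy} = \overline{\sum_i x_{li} y_{li}}$ (averages over loci,
then the ratio — the classical form, not per-locus ratios averaged);
$I = J_{xy} / \sqrt{J_x J_y}$ and $D = -\ln I$. Loci with no data in either
population are dropped pairwise. $I = 0$ (disjoint allele sets) is an
infinite-distance flag; for clustering it is replaced by
$1 + \max(\text{finite } D)$ with a warning, preserving the "farthest" rank
while keeping the agglomeration finite. Nei's $D$ is not a metric (no
triangle inequality), which is why a flag rather than an error is the right
degenerate behaviour.

**UPGMA** phenograms merge the closest pair of clusters at height
$d/2$, with cluster-to-cluster distances the size-weighted arithmetic mean
of member distances. Ties are broken by smallest (row, column) position in
the input matrix, making trees deterministic. The output is ultrametric by
construction; on ultrametric input the tree reproduces the input distances
exactly, and merge heights agree with `hclust(method = "average")` (the
independent cross-check used in the tests).

**PCA** operates on an allele-dosage design: one column per registry allele
minus one per locus (the dropped column is linearly redundant), entries the
0/1/2 count of that allele. Missing dosages are mean-imputed per column —
the simplest convention that keeps centred columns at zero mean — and
columns are centred but not scaled, since dosage columns share a scale; a
scaling option exists for users who want correlation-based ordination. The
published analyses this mirrors did not state their dosage coding or
missing-data handling, so ours is documented rather than asserted
identical.

## The synthetic panel generator

The generator exists so that every estimator above can be tested against
known truth without any external download. It uses the **Balding-Nichols**
parameterisation: ancestral allele frequencies $p$ are drawn uniformly on
the simplex; each population's frequencies are drawn from
$\mathrm{Dirichlet}\!\big(p \,(1 - F_{st})/F_{st}\big)$, so $F_{st}$ is an
interpretable differentiation knob and $F_{st} = 0$ means all populations
share $p$ exactly. Genotypes are drawn with within-population inbreeding
$f$: $P(\text{homozygote } i) = p_i^2 + f p_i (1 - p_i)$,
$P(\text{heterozygote } ij) = 2 p_i p_j (1 - f)$.

Null alleles are modelled **at the generative-frequency level**, not by
post-hoc relabelling: a null allele at frequency $r$ is inserted into the
frequency vector (visible frequencies rescaled by $1 - r$) and genotypes
are redrawn, with visible/null pairs recorded as visible homozygotes and
null/null pairs as missing. This makes closed-form expectations available
for estimator tests — e.g. the called-genotype heterozygosity is
$((1-r)^2 - \sum q_i^2)/(1 - r^2)$ for absolute visible frequencies $q_i$ —
which is what lets the test suite prove the exact-$r$ adjustment identity.

Defaults mirror the study design the package was built around: 12
populations of 15 individuals; 220 SNP and 8 SSR loci; per-SSR null-allele
frequencies equal to the panel's observed per-marker estimates (0.0341 to
0.3361) and visible allele counts equal to the observed per-marker counts
(4 to 13); SSR fragment lengths are arithmetic progressions stepping by the
repeat-motif length, mimicking published size ranges. The base missing-call
rate defaults to 0.02, consistent with a panel that survived a >95%
call-rate screen. No differentiation magnitude is published for the
motivating populations, so the default $F_{st} = 0.05$ is a one-time choice
representing modest differentiation (mean Nei's $D$ of a few hundredths,
the regime the motivating study reports); it is a demonstration default,
not a calibrated estimate. A dedicated introduction design
(`simulate_introduction_panel()`) draws two strongly diverged native
populations and several mildly drifted derivatives of one of them, for
testing that clustering attaches derived populations to their true source.

What the generator does **not** emulate: linkage between loci (loci are
independent by construction), mutation processes and allele-size
constraints (no stepwise-mutation realism), genotyping error other than
nulls and uniform missingness, and coalescent demographic history. Passing
tests therefore demonstrate estimator correctness under the stated
generative model, not robustness to every artefact of real fragment data.
One consequence worth noting: under this model a null allele at rate $r$
produces at least $r^2$ missing calls, so SSR loci with large $r$ can fail
a strict >95% call-rate screen — whereas real panels are reported with
large estimated NAF *and* high call rates, suggesting real null
homozygotes are not always blank. The pipeline keeps both behaviours
honest: filters apply as stated, and reports are computed on whatever
survives.

Sequence fixtures for the repeat scanner are random-background contigs with
planted perfect tandem repeats. Backgrounds are built with a rejection rule
that forbids any unplanted perfect run reaching three unit copies (below
every reporting threshold for units 1-6 nt) and guards the junction
characters so a planted repeat can neither extend nor shift phase; the
planted truth set is therefore exactly the reportable hit set.

## Marker-discovery QC

The discovery-stage filters mirror the published thresholds and their
wording: calls with fewer than 8 supporting reads are set missing *first*,
then loci are removed if the minor allele frequency is not **strictly**
above 5% (computed from exact allele counts to avoid floating-point
boundary artefacts; for multi-allelic loci "minor" is the combined
non-major mass) or if called in fewer than 32 of 48 samples; a separate
call-rate filter retains loci **strictly** above the threshold (a locus at
exactly 95% is removed), with threshold 1 meaning "complete loci only".
Flank checks require at least 75 bases on both sides of a variant,
1-based inclusive. Filters are idempotent and their reports reconcile
exactly with matrix dimensions at every stage.

The SSR scanner reports all maximal perfect tandem repeats with unit length
1-6 nt meeting per-unit minimum copy numbers (defaults 10, 5, 5, 4, 4, 4
— inferred from the shortest motifs in the motivating panel, and
configurable). A run is reported once, under its leftmost phase, truncated
to whole copies; periodic units (`TT`, `ATAT`) and hits wholly contained in
a longer hit with a shorter unit are suppressed, so `(T)12` is never also
`(TT)6`.

Primer screening checks each constraint independently (lengths 18-23 nt,
product 100-280 bp, $T_m$ 54-60 °C, $\Delta T_m \le 0.5$ °C, all ranges
inclusive per the "ranging from ... to" wording) and lists every violation.
$T_m$ uses the fixed GC-fraction approximation
$T_m = 64.9 + 41\,(GC - 16.4)/L$. This is a deliberate, documented choice:
commercial design tools use proprietary nearest-neighbour models whose
parameters are unpublished, and no simple formula reproduces their printed
annealing temperatures. The formula is a swappable strategy, and its
verdicts should be read as reproducible constraint screening, not
thermodynamic prediction.

## Numerical conventions and problem sizes

Rendered tables round to 4 decimals with round-half-even, with unweighted
`Mean` and sample (n-1) standard-deviation rows. Frequency vectors are
validated to sum to 1 within $10^{-6}$; ultrametricity within $10^{-9}$.
All randomness flows through explicit seeds (`withr::with_seed`, leaving
the session RNG untouched); identical configurations produce byte-identical
report bundles. The validation suite exercises recovery at $n = 500$
individuals and 100-200 loci (inbreeding recovery within $\pm 0.05$;
null-bias halving), structure recovery with 150-200 SNP panels at
$F_{st} = 0.3$, and scanner equivalence against a regex oracle on 1,000
planted contigs — sizes chosen to make Monte-Carlo error comfortably
smaller than the tested tolerances while keeping the suite quick.

## Known limitations

* Brookfield-1 assumes missing calls at a locus are null homozygotes; when
  missingness has other causes the estimate is inflated. The estimator
  family (Chakraborty, Oosterhout, ML joint estimation of $r$ and $f$) is
  deliberately out of scope.
* Population $F_{is}$ aggregation and the $H_e$ correction convention can
  make per-population tables differ in the third decimal from legacy
  programs whose conventions are unstated.
* The LD dosage collapse discards allele-specific association for
  multi-allelic loci.
* PCA mean-imputation shrinks individuals with much missing data toward
  the origin.
* The generator's null-allele model ties blank rates to $r^2$, which is a
  lower bound on how real panels behave (see above).
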