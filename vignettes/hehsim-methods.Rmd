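---
title: "Modelling the origin of high-hyperdiploid karyotypes"
author: "hehsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the origin of high-hyperdiploid karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hehsim)
```

## The question

High hyperdiploidy (HeH) — a karyotype of 51–67 chromosomes dominated by
whole-chromosome gains of X, 4, 6, 10, 14, 17, 18 and especially 21 — is
the most common cytogenetic class of childhood acute lymphoblastic
leukaemia. Two families of explanations compete: the extra chromosomes
could be acquired **gradually** (sequential nondisjunction events under
selection, or losses from an initially tetraploid cell) or
**punctually**, in one catastrophic division (a tripolar mitosis of a
diploid or tetraploid cell, or a complete loss of sister-chromatid
cohesion). These mechanisms leave different fingerprints in the
homologue structure of the resulting karyotypes: the ratio of 2:2 to
3:1 tetrasomies, the frequency of uniparental isodisomies (UPIDs, two
copies of the same parental homologue), and the apparent age of
trisomies as read from the variant-allele fractions of somatic SNVs.

`hehsim` implements a forward-time population simulator of these five
initiation mechanisms under explicit clonal selection, plus the
cohort-level statistics, mutation-timing analyses and single-cell clone
bookkeeping used to compare the mechanisms against data. Synthetic-data
generators stand in for patient-level data, which are access-controlled.

## The simulator

### State

A cell is a homologue-resolved karyotype over 23 chromosome pairs
(1–22, X; the model is 46,XX and chromosome Y is not simulated). A
population is a pair of 23-by-n integer matrices (the `hom1`, `hom2`
slots of a `CellPopulation`); 50,000 cells take about 9 MB, and all
per-generation operations are vectorised over the matrix.

### Initiation

Each mechanism defines a founder distribution
(see `?initiationModels`). The tripolar mechanics deserve a note, since
whole-chromosome segregation on a three-poled spindle is not uniquely
determined by the phenomenology: we assume every replicated homologue's
two sister chromatids disjoin to two *distinct* poles chosen uniformly
among the three pole pairs, independently per homologue. The
diploid/tripolar founder keeps two fixed poles (bipolar cytokinesis of
a tripolar spindle), giving per-chromosome totals 2 : 3 : 4 with
probabilities 4/9 : 4/9 : 1/9 — a near-HeH expected MCN of
23·8/3 ≈ 61.3, abundant trisomies, no losses and **no UPIDs**. The
tetraploid/tripolar founder keeps a single pole (per homologue 0, 1 or
2 copies with probabilities 1/9, 4/9, 4/9), and mitotic catastrophe
segregates all 92 chromatids independently (per homologue
Binomial(2, ½)). This is the simplest rule that simultaneously yields
(i) a viable hyperdiploid founder for the diploid case with zero
initial UPIDs, and (ii) initial UPID frequencies far above the 2.5%
stopping threshold for the two tetraploid-origin mechanisms.
Founders with a nullisomic chromosome are redrawn rather than admitted
and culled, so the initial population size is exact.

### Missegregation

At each generation every cell divides into two daughters. Each
chromosome missegregates with probability $P = M \cdot N$ where
$M = 15\times10^{-4}$ per chromosome copy per mitosis and $N$ is the
chromosome's copy number; at most one event per chromosome per
division. The moved copy belongs to a homologue chosen proportionally
to its copy number and lands in a uniformly chosen daughter (+1/−1).
Totals across the two daughters are always conserved. This is the only
route to UPIDs in the diploid-origin models: a 2:1 trisomy that loses
its single-copy homologue (probability 1/3 of losses) leaves a 2:0
disomy. For the tetraploid/sequential model an additional loss process
removes one copy of each chromosome with probability 0.35 per division.

### Selection

Survival is Bernoulli with probability equal to the clamped score
$$S = 0.5 + \frac{NT_{g1} + 2\,NT_{g2} - NT_{g3}}{23} - S_{aneuploidy},$$
where $NT_{g1}$ counts gained chromosomes among X, 4, 6, 10, 14, 17,
18; $NT_{g2}$ indicates a gain of chromosome 21 (double weight); and
$NT_{g3}$ counts aberrant (gained *or* lost; switchable to
trisomy-only) chromosomes of the remaining set. An extended four-group
form splits the remainder into a negatively selected majority and a
weakly rewarded group (5, 8, 11, 12, 22; weight 0.02). A diploid cell
scores exactly 0.5, so an unperturbed diploid population is stationary
in expectation. Nullisomic cells never survive. For the
tetraploid/sequential model the aneuploidy penalty is omitted — no
initial tetraploid cell would survive it.

### The aneuploidy penalty — a design decision

$S_{aneuploidy}$ is a beta law in the excess-ploidy variable
$x = (MCN-46)/46$ with location 0 and scale 1.8. The shape values in
circulation for this model class are 0.18 and 0.65, and the package had
to decide both the *form* (density versus cumulative) and the *role
assignment* of the two shapes. The decision was forced by an
internal-consistency argument:

* With first shape 0.18, the beta law concentrates essentially all its
  mass at $x=0$. The scaled **density** at MCN 47 is 3.3 and the
  **CDF** is 0.40 — both larger than the largest attainable selection
  bonus, $9/23 \approx 0.39$. Every first gain is then effectively
  lethal: the sequential model can never leave diploidy, no model
  produces hyperdiploid endpoint populations, and the UPID stopping
  rule is never reached. We verified this both by a mutation–selection
  balance estimate and by simulation under all four combinations of
  form and replenishment mode.
* With the roles exchanged — CDF with shapes (0.65, 0.18) — the
  penalty is 0.014 at MCN 47, rising smoothly to about 0.11 at MCN 67:
  single gains of favoured chromosomes are net-beneficial, hyperdiploid
  sweeps occur, and the endpoint populations sit at MCN 54–58. Under
  this default the model reproduces, without further adjustment, the
  expected behaviour of all five mechanisms: stop-generation medians of
  roughly 70–80 (diploid/tripolar, at 50,000 cells) versus roughly
  500–600 (diploid/sequential), stopping within a few generations for
  tetraploid/sequential, UPID plateaus above 30% by generation 1000 for
  the tetraploid-origin mechanisms, and a tetrasomy-21 3:1 share near
  2/3 at the diploid/sequential endpoint.

The package therefore defaults to `penaltyForm = "cumulative"` with
`penaltyShape1 = 0.65, penaltyShape2 = 0.18`; both the density form and
the printed-order shapes remain available as configuration options.

```{r penalty}
cfg <- SelectionConfig()
round(sAneuploidy(c(47, 51, 55, 62, 67), cfg), 3)
```

### Stopping rule and bookkeeping

After selection, populations above 50,000 cells are uniformly
subsampled; populations below are topped up with fresh founder draws of
the mechanism (replenishment by resampling survivors is available as an
option). The run stops when the UPID frequency of the 14 passively
tracked chromosomes (1–3, 5, 7, 8, 11–13, 15, 16, 19, 20, 22) reaches
2.5%, or after 2000 generations. The stop statistic divides UPID counts
by *all disomic* tracked chromosomes, matching the patient-side
"UPIDs/all disomies" ratio; dividing by all tracked slots is available
via `upidDenominator = "allTracked"` and shifts stop times upward by
roughly 5–10%. Both daughters of every division enter the selection
pool (the population transiently doubles); with every cell at score
0.5 this reduces to a stationary population, and it is the simplest
bookkeeping consistent with synchronous generations.

Why do the mechanisms separate so cleanly on this statistic? The
tetraploid-origin founders are born with UPID frequencies far above the
threshold (roughly 20% and 33% of founder disomies). Diploid/tripolar
founders have none, but carry ~6 tracked trisomies per cell, each
converting to a UPID at rate $\approx M \cdot 3 \cdot 1/3$ per division
— and the conversion is selectively *favoured* (it removes a penalised
trisomy), so the threshold is typically reached within ~60–80
generations at full population size. The diploid/sequential model must
first generate tracked trisomies by missegregation before any can
convert, which is why it takes roughly an order of magnitude longer and
why its stop-generation distribution is extremely broad (roughly
150–900 across seeds).

### Determinism, sizes, and numerical details

Each run seeds R's RNG once (`set.seed(seed)`) and is bit-reproducible
given `(model, config, seed)`. Division, loss, survival and
replenishment consume randomness in a fixed order, so earlier
generations are unaffected by when a run stops. Missegregation events
are sampled sparsely (only event positions draw homologue and daughter
assignments), keeping a 50,000-cell generation at ~100 ms. The density
form of the penalty clamps its argument to $[10^{-12}, 1-10^{-12}]$
because the beta density diverges at both support edges for shapes
below 1; the cumulative form needs no clamp. Telemetry stores only
per-generation summaries (survivor count, UPID frequency, median MCN of
a ≤10,000-cell subsample), never full populations.

The test suite runs all of its replicate simulations at 5,000–10,000
cells; the acceptance script additionally runs the diploid/tripolar
endpoint at the full 50,000. Across 5,000–50,000 cells the
stop-generation medians of the scaled analyses vary by less than the
between-seed spread, while the diploid/tripolar median is the quantity
most sensitive to population size (clonal takeover is faster in small
populations), so that one is kept at full scale where the budget
allows. Statistics whose single-run value is decided by which founder
lineage happens to fix — the 1000-generation UPID plateau of the
tetraploid-origin mechanisms, and the tetrasomy-21 homologue
composition — are summarised as replicate means, in the same spirit as
the stop-generation medians.

## Cohort statistics

`copyStateSpectrum()`, `tetrasomyTypeFractions()`, `upidDisomyRatio()`
and `mcnProfiles()` summarise homologue-resolved cohort tables the way
HeH cohorts are summarised: copy-state fractions over all chromosome
pairs, 2:2/3:1 tetrasomy typing, per-chromosome UPID/disomy ratios, and
per-MCN mean trisomy/tetrasomy counts split at MCN 62. The per-case
identity $MCN = 46 + \#tri + 2\#tetra + 3\#penta - \#mono$ holds
exactly and is enforced in tests. `subclonalityRatioTest()` is the
two-sided exact binomial test (minimum-likelihood convention, as
implemented by `binom.test`) of observed heterodisomy/trisomy versus
UPID/trisomy subclonality against the 2:1 loss-from-trisomy
expectation. Records with a subclonal fraction below 0.5 are subclone
records; the synthetic generator never emits subclones below the 0.2
bulk detectability floor.

`compareModels()` ranks simulated mechanisms against a cohort by RMSE
on two profile families — per-MCN trisomy/tetrasomy curves and
per-chromosome aberration-class frequencies. The two families are
reported separately; their sum is this package's convenience ranking
score. MCN bins absent from the cohort are skipped rather than
zero-filled so that empty bins cannot dominate the error.

## Mutation timing

`classifyTiming()` labels SNVs on trisomic chromosomes BTRI (expected
VAF $2p/(3p+2(1-p))$ at tumour purity $p$; 2 of 3 copies) or B/ATRI
($p/(3p+2(1-p))$; 1 of 3) by comparing binomial read-count
likelihoods, with an ambiguity band (log-likelihood ratio < 2, or depth
< 10). At depth 60 and purity ≥ 0.8 the classifier recovers ≥95% of
synthetic truth labels. A fixed-window variant (VAF threshold 0.5) is
available for replicating threshold-style analyses.
`assignHomologue()` applies the 0.6/0.4 allele-fraction rule for
phasing heterozygous variants to homologues, and
`homologueConcordance()` majority-votes matched variants between
diagnosis and relapse samples (with the BAF > 0.8 screen in UPID mode).

## Single-cell clone bookkeeping

Clones are ≥2 cells with identical whole-chromosome profiles
(`callClones()`); singleton profiles are "unique genomes". Pairwise
cell distances are Manhattan (`manhattanMatrix()`, via `dist()`).
`heterogeneityScore()` — mean per-cell Manhattan distance to the
per-chromosome modal profile, divided by 23 — is a surrogate defined by
this package for relative comparisons; it is *not* numerically
comparable to heterogeneity scores produced by bin-level copy-number
callers, and published per-case scores are therefore not targets of
this package's validation.

## What the synthetic data do and do not show

`generateCohort()` samples chromosome gains **independently** at the
reported marginal frequencies (gain, tetrasomy and pentasomy rates per
chromosome, 5% 3:1 tetrasomies, 2.5% UPID per disomy with chromosome 9
at 17%, male Y gains/losses). Real HeH karyotypes are certainly not
independent across chromosomes; the generator's purpose is parameter
*recovery* — the cohort statistics must read back the frequencies the
generator was given, within binomial error — not realism of the joint
distribution. Likewise `generateVariants()` draws read counts from the
exact binomial model the classifier assumes, so the ≥95% recovery
result validates the classifier's decision rule, not its robustness to
mapping artefacts or purity mis-estimation; and `generateCellMatrix()`
perturbs clone profiles with independent ±1 noise, unlike the
correlated segmentation errors of real single-cell callers. Passing
tests on these data demonstrate internal consistency of the pipeline,
not fidelity to any patient cohort.

## Known limitations

* Whole-chromosome resolution only; structural events enter cohort and
  single-cell tables as annotations, never as simulator state.
* The model is 46,XX; male cohorts are handled only by the synthetic
  generator and the cohort statistics.
* Generations are synchronous, with no cell death by age, no spatial
  structure and no explicit cell-cycle timing.
* The exact chromatid mechanics of the tripolar founders (and hence
  their precise initial UPID percentages) are a modelling choice; only
  their position relative to the 2.5% threshold is asserted.
* The stop-generation distributions are heavy-tailed; medians over ~10
  seeded replicates still move by tens of generations between seed
  sets, especially for the diploid/sequential model.
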