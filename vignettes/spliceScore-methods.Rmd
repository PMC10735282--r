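---
title: "Models, calibration and design choices in spliceScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in spliceScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spliceScore compares cassette-exon regulation across splicing-factor (SF)
knockdown experiments. This vignette is the package's own account of the
statistics it implements: what each model assumes, which tunable parameters
matter and why their defaults are what they are, how the two empirical
p-values behave under their nulls, and where the design was genuinely open
and what we chose.

## The data model

An exon record is a genomic interval (chromosome, start, end, strand) plus
optional regulation statistics: ΔPSI, the change in percent-spliced-in
between knockdown and control, in percent on [−100, 100], and an adjusted
p-value. The two statistics are always both present (mode-1 records) or both
absent (mode-2, coordinate-only records). User ΔPSI values on a 0–1 scale
must be multiplied by 100 before import; the package standardizes on percent
throughout.

Exon **identity is the coordinate tuple** (chromosome, start, end, strand).
Gene symbols and exon numbers are carried as annotation and are repaired, not
trusted: `validateAgainstAnnotation()` classifies every input record as
recognized (coordinates and labels match the annotation), correctable
(coordinates match an annotated exon whose labels differ — the annotation's
identity is proposed), or unknown. Coordinates are the critical detail a
query must get right.

Internally all intervals live in `GRanges`, i.e. 1-based, closed intervals —
the host ecosystem's convention. The tab-separated exon dialect is 1-based
inclusive and maps directly; BED input (0-based, half-open) is converted at
the reader (`rtracklayer`). One internal convention, conversions only at the
boundaries.

A dataset (`SFDataset`) stores only exons passing the differential-inclusion
filter **|ΔPSI| ≥ 10 % and adjusted p ≤ 0.05** (both boundaries inclusive);
this is enforced by the class validity, so everything downstream may assume
it. The same thresholds are the defaults applied to user queries, but they
are arguments everywhere (`deltaPsiThreshold`, `pvalueThreshold`), since
nothing forces a user upload to have been filtered the same way. A registry
carries one genome build tag and refuses cross-build comparisons outright;
coordinate conversion is out of scope and must happen upstream.

## Mode 1: the correlation query

For each registry dataset the query is reduced to the shared exon set
(coordinate-identity intersection, ordered by position so everything
downstream is deterministic). On *n* shared pairs we compute the Pearson
correlation *r* of the two ΔPSI vectors, and two one-sided empirical
p-values from a permutation null: the pairing between query and dataset
values is shuffled (one side permuted), which models "randomly associated
exons" while preserving both marginal ΔPSI distributions exactly. With *B*
permutations,

- `p_pos = max(#{r* ≥ r}, 1) / B` and `p_neg = max(#{r* ≤ r}, 1) / B`,

with inclusive comparisons (a permuted correlation exactly as high counts)
and a floor of 1/*B*: at the default *B* = 10⁴ the smallest reportable p is
10⁻⁴, which is the resolution of the null ECDF. Floating-point ties are
handled with a 10⁻⁹ tolerance on the comparison, which matters only in
degenerate fixtures. For *n* ≤ 9 an exhaustive mode enumerates all *n*!
pairings and returns the exact permutation tail (the observed pairing is one
of them, so the floor is automatic); tests verify the sampled p converges to
this exact tail.

The composite Score is

Score = mean(1 − p, percent.sig.input/100, percent.sig.SF/100),

in [0, 1]: one part correlation evidence, two parts extent of overlap. It
deliberately rewards breadth — a tiny but perfectly correlated intersection
cannot exceed 1/3 plus its overlap terms. Both directions are reported
(`score_pos` with `p_pos`, `score_neg` with `p_neg`); pairing each tail with
its own Score is the only self-consistent reading of a single "p-value" slot
in the formula, and the ranking uses the larger of the two, ties broken by
dataset id. `percent.common.*` report the same membership fractions without
the significance filter; for in-registry queries the SF-side fractions
coincide because datasets store only significant exons, but they differ for
arbitrary uploads.

Two computability guards: Pearson *r* requires at least `minShared` exons
(default 10 — below that a correlation is numerically legal but
scientifically meaningless; real knockdown datasets share hundreds) and
non-zero variance on both sides. Datasets failing either are reported with
`computable = FALSE` and NA statistics rather than dropped, so the output
always has one row per dataset.

The up/down breakdown partitions shared exons by regulation direction on
each side ("up" = ΔPSI > 0, more included upon knockdown). Exons with ΔPSI
exactly 0 belong to neither class and are counted separately
(`n_zero_excluded`). Percentages are relative to the query's up and down
subset sizes over the full query list, so they answer "what fraction of my
up-regulated exons does this SF also up-regulate?".

### Calibration

Under the null (independent ΔPSI vectors), the number of permuted
correlations exceeding the observed one is uniform on {0, …, B} by
exchangeability, so `p_pos` is uniform up to the 1/*B* floor. The acceptance
suite verifies this with a Kolmogorov–Smirnov test at α = 0.01 over 500 null
replicates at *B* = 2000.

## Mode 2: the coordinate-only overlap test

For a query of *m* exons, the observed count *N* regulated by an SF is
compared against *B* = 10⁴ control sets of size *m* sampled uniformly
without replacement from the universe of detected exons (default: the union
of all registry datasets; an annotation-wide universe is available). With
*k* = #{control counts ≥ N} and *l* = #{control counts ≤ N},

P_emp = (min(k, l) + 1) / (B + 1),

BH-corrected across all SFs of the run — the only test family involved. Ties
count in both tails, so k + l ≥ B always, and P_emp ∈ [1/(B+1), 1]. The
formula does not encode a direction, so the label (enriched / depleted /
none) is assigned by comparing *N* to the control median. One batch of
control sets is shared across all SFs of a run, which makes a 160-dataset
sweep as cheap as a single test and the per-SF counts positively coupled
(harmless for BH under positive dependence). Query exons outside the
universe are dropped with a warning — they cannot be enriched in datasets
that never detected them; a query larger than the universe is an error.

### Calibration, and a caveat worth knowing

`min(k, l)` is a two-sided empirical tail **without doubling**: if the count
distribution were continuous, P(P_emp ≤ α) would approach 2α, not α. What
rescues the test in practice is discreteness — the hypergeometric count mass
at the observed value inflates both k and l, and for small coordinate-only
queries (tens of exons, the typical mode-2 upload) the realized type-I error
at α = 0.05 sits near the nominal level. The acceptance suite measures it at
a desk-scale design (universe 3000, dataset 900, query of 60, 2000 control
sets, 1000 replicates) and requires it within [0.03, 0.07]. For queries of
many hundreds of exons the counts are nearly continuous and the size drifts
toward 2α; treat borderline q-values from very large mode-2 queries with
that in mind, or halve α.

## CLIP-peak enrichment

Peaks from experiments targeting the same SF are pooled and coalesced
(overlapping *and abutting* intervals merge — the default behaviour of
interval-merging tools; strand is ignored). Regulated classes per SF pool
all its knockdown samples: `up` = exons with ΔPSI > 0 in at least one
sample, `down` likewise; exons regulated in *opposite directions in
different samples* are conflicted and excluded from every class including
the controls; controls are all other detected exons. SFs need at least 100
exons in **both** classes to be scored (`minClassSize`), matching the rule
that underpowered factors are not displayed.

Each (class, region) cell tests peak overlap — ≥ 1 bp intersection, since no
minimum overlap is defined for a CLIP peak — in one of seven regions: the
exon body and three consecutive 100-nt windows on each side, ordered
outward (`up1` adjacent to the exon, upstream meaning 5′ on the exon's
strand; on the minus strand "upstream" is genomically to the right). Windows
truncate at chromosome bounds and never skip over neighbouring exons'
coordinates — they are defined purely by distance. The effect size is

R = log2((P_reg + 0.01) / (P_ctrl + 0.01)),

antisymmetric in the two roles and bounded by |R| ≤ log2(1.01/0.01) ≈ 6.66
thanks to the pseudocount. Significance comes from a logistic regression of
the overlap indicator on the class indicator (two-sided Wald test on the
class coefficient) — a marginal, cell-wise model; when any cell of the 2×2
table is empty the Wald test is unreliable (separation) and the package
falls back to Fisher's exact test. BH correction is applied across all cells
of a run, i.e. one heat-map family. The synthetic planted-peak fixture
covers a chosen region window of each exon with class-specific
probabilities, so recovery of both proportions and R is tested against
binomial error bounds.

## Motif enrichment and the V statistic

Sequences are the exons extended by ±200 nt (strand-aware, reverse
complemented for minus-strand exons, truncated at chromosome ends), compared
between a regulated class and the control exons (all other detected exons
minus the SF's regulated ones). The enrichment engine is sequence-level: a
sequence either contains ≥ 1 motif match or not, and a one-sided Fisher
exact test compares the containment fractions. Depletion (`p_i`) is the same
test with the sequence roles swapped. The engine sits behind a stable
(primary, control, motif) → p-value interface, so an adapter for an external
enrichment program can replace it without touching the V computation.

Matching has two modes. Consensus mode counts IUPAC-degenerate exact hits.
PWM mode scores log-odds against a 0-order background estimated from the
control set, with the match threshold calibrated on the control sequences so
the expected background rate is ≤ 1 hit per 1000 nt (configurable); the two
modes agree on sequences containing exact consensus hits, which is tested.
Motifs load from MEME minimal files or plain IUPAC strings; RNA alphabets
are mapped to DNA (U→T) at read time, and a consensus is derived from a
matrix (letters with probability ≥ 0.25 per position) when only a matrix is
given.

The signed summary is built from the enrichment p-value `p_e` and the
impoverishment p-value `p_i`, with sign s = −1 if `p_i` < `p_e`, +1 if
`p_i` > `p_e`. At a tie the sign is +1 and the result is flagged ambiguous —
the sign rule is genuinely undefined at equality, and flagging beats
guessing. Two variants are provided:

- **consistent** (default): V = (1 − min(p_e, p_i)) × s. A strong effect in
  either direction drives |V| → 1, so the 0.95 display threshold is
  attainable.
- **as printed**: V = min(1 − p_e, 1 − p_i) × s. Note the degeneracy: a
  maximally significant enrichment (p_e → 0) forces p_i → 1 and hence
  V → 0 — the more significant the signal, the smaller |V|, which
  contradicts a "|V| > 0.95 is significant" display rule. We therefore
  default to the consistent form and keep the printed form behind a flag for
  comparison; which form any particular external implementation used cannot
  be assumed.

Display follows the heat-map convention: red above +0.95, blue below −0.95,
grey between, white (not computed) for classes under 100 exons.

## The synthetic-data generator

The generator emulates the statistical structure of an SF-knockdown
collection, not its biology. Defaults: datasets of 500 exons over a universe
of 3000 detected exons, |ΔPSI| uniform-ish on [10, 60] % with an even
up/down split, adjusted p-values below 0.05 — so every generated dataset
satisfies the SFDataset invariants by construction. Universe exons are
placed non-overlapping on synthetic chromosomes with realistic cassette-exon
lengths (50–300 nt) and inter-exon gaps ≥ 700 nt, so the six 100-nt windows
of the CLIP module never collide with a neighbouring exon.

Pairwise structure is controlled by two matrices: target shared-exon
fractions and target Pearson correlations of ΔPSI on shared exons.
Membership is built greedily (each dataset draws its target share from each
earlier dataset, preferring exons exclusive to that dataset to limit
spillover, and fills up from untouched universe exons; infeasible
combinations of sizes and overlaps are rejected before generation).
Correlation is induced by a Gaussian one-factor copula: each exon carries a
global latent value, dataset *i* mixes it with idiosyncratic noise with
loading a_i, so shared-exon latent correlations realize a_i·a_j — exact for
exchangeable or rank-1 target patterns, least-squares approximated
otherwise. Two numerical refinements keep realized values on target: the
latent correlation is calibrated by inverting the Hermite expansion of the
monotone map from the latent Gaussian onto the ΔPSI scale (the map's sign
gap would otherwise attenuate correlations by 2–4 %), and the idiosyncratic
noise is orthogonalized and standardized in-sample so dataset-level loadings
are realized exactly. Realized pairwise overlaps land within ±2 percentage
points and correlations within ±0.05 of targets at the default sizes; the
realized matrices are returned as ground truth alongside the registry.

What the generator does **not** emulate: real sequence composition
(backgrounds are i.i.d. uniform ACGT), GC- or length-matching between
regulated and control sets, cell-line structure or batch effects, correlated
regulation beyond the one-factor structure, and real genome coordinates.
Passing tests on these fixtures therefore demonstrate the statistics are
implemented and calibrated as specified — not that the biology of any
particular SF will behave as cleanly.

## Numerical choices and degenerate inputs

- Empirical p floors: 1/B (mode 1), 1/(B+1) (mode 2); never 0.
- Inclusive tie handling in both nulls ("as high or higher"), with a 1e-9
  epsilon against floating-point ties in mode 1.
- BH correction via `stats::p.adjust(method = "BH")`; the test suite checks
  it against an independently written step-up implementation at 1e-12.
- Pearson and permutations require `minShared` ≥ 10 shared exons by default
  and non-degenerate variance; failures are flagged, not dropped.
- Empty denominators in overlap fractions return 0 with a flag rather than
  NaN; empty exon classes make enrichment cells not-computable.
- Logistic-regression separation falls back to Fisher's exact test.
- Window/flank truncation at chromosome bounds yields zero-width windows
  (which simply never overlap) and shortened sequences.
- All randomness flows through per-call seeds; callers' RNG state is saved
  and restored, and derived seeds stay below 2³¹.

## Problem sizes in the test suite

The shipped tests run desk-scale versions of every analysis: registries of
2–4 datasets with 60–500 exons over universes of 150–3000, 10⁴ permutations
where a p-value floor is asserted, 150–2000 permutations in the fuzz and
calibration batteries (1000 fuzz comparisons; 500 KS replicates; 1000
type-I replicates at 2000 control sets; 100 ranking-recovery trials; 50
motif-panel runs). These sizes were chosen so the full suite exercises every
statistical claim in minutes on a laptop while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

- Mode-2's printed formula is anti-conservative for very large queries (see
  above); the package implements it as defined and documents the behaviour.
- Greedy membership construction cannot hit arbitrary overlap matrices
  exactly when targets conflict; realized overlaps are returned so callers
  can check.
- The one-factor copula cannot represent arbitrary correlation matrices
  (only products a_i·a_j); general targets are fitted in least squares.
- Control exons are not GC- or length-matched in either binding module;
  with real data this can confound enrichment and should be handled
  upstream or with a custom control universe.
- No liftover: cross-build queries are refused, not converted.
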