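# spliceScore

Tools for asking, of a list of cassette exons, *which splicing factors (SFs)
regulate them* — by comparing the list against a registry of SF-knockdown
RNA-seq datasets, each one a list of exons whose inclusion changed
significantly when that SF was depleted (|ΔPSI| ≥ 10 %, adjusted p ≤ 0.05,
where ΔPSI is the change in percent-spliced-in between knockdown and
control). The package also scores two kinds of orthogonal binding evidence:
CLIP-seq peak enrichment around the regulated exons, and binding-motif
enrichment in their extended sequences.

It is aimed at splicing researchers who have either (a) an exon list with
ΔPSI and p-values from their own differential-splicing analysis, or (b) a
bare list of exon coordinates, and who want a ranked, statistically
calibrated shortlist of candidate regulators.

## The statistics at the core

**Mode 1 — correlation query.** For a query list with ΔPSI values, each
registry dataset is compared on the exons the two lists share (matched by
genomic coordinates — the authoritative identity; gene symbols and exon
numbers are annotation). On the shared set the package computes the Pearson
correlation *r* of the ΔPSI values, then empirical one-sided p-values from a
permutation null that re-pairs the two ΔPSI vectors at random (10⁴ shuffles
by default, so the smallest attainable p is 10⁻⁴), and the composite
confidence Score

```
Score = mean( 1 − p,  percent.sig.input / 100,  percent.sig.SF / 100 )
```

where `percent.sig.input` is the share of significantly regulated query
exons found in the dataset and `percent.sig.SF` the share of the dataset's
exons found in the query. The Score ranges between 0 and 1; both directions
(positive and negative correlation) are scored, each with its own tail
p-value, and results are ranked by the larger of the two.

**Mode 2 — coordinate-only overlap test.** For a query without ΔPSI, the
observed count *N* of query exons regulated by an SF is compared against the
counts of 10⁴ same-sized control sets drawn from the universe of detected
exons:

```
P_emp = (min(k, l) + 1) / (10⁴ + 1)
```

with *k* = number of control sets with count ≥ N and *l* = number with
count ≤ N, Benjamini–Hochberg corrected across all SFs.

**Binding evidence.** For each SF with CLIP peaks, the package computes, on
the exon body and on three 100-nt windows on each side,
`R = log2((P_reg + 0.01) / (P_ctrl + 0.01))` — the pseudocounted log-ratio of
peak-overlap proportions in regulated versus control exons — with a
logistic-regression test and BH correction. For each SF with a known binding
motif, exon sequences extended by ±200 nt are scanned and a signed statistic
`V ∈ [−1, 1]` combines the motif-enrichment and motif-depletion p-values
(sequence-level Fisher exact tests); |V| > 0.95 flags significant enrichment
(positive) or depletion (negative), and SFs with fewer than 100 regulated
exons per class are not scored.

A seeded synthetic-data module generates everything the analyses consume —
annotations, dataset registries with controlled pairwise overlap and ΔPSI
correlation, CLIP peaks with planted overlap rates, and genomes with planted
motif instances — so the whole stack is testable offline.

## Worked example

```r
library(spliceScore)

# a synthetic registry: 4 SF-knockdown datasets of 500 exons each, pairwise
# overlap 0.3 and shared-exon delta-PSI correlation 0.5
gen <- generateRegistry(registrySpec(nSF = 4, exonsPerDataset = 500,
                                     universeSize = 3000, overlap = 0.3,
                                     correlation = 0.5, seed = 11))
reg <- gen$registry

# mode 1: query the registry with one of its own datasets
query <- exons(reg[["SF02_SYN"]])
res <- runQueryMode1(query, reg, nPermutations = 10000, seed = 42)
res[, c("dataset", "pearson_r", "p_pos", "score_pos", "n_shared")]
#>    dataset pearson_r p_pos score_pos n_shared
#> 1 SF02_SYN     1.000 1e-04     1.000      500
#> 2 SF01_SYN     0.467 1e-04     0.533      150
#> 3 SF03_SYN     0.447 1e-04     0.533      150
#> 4 SF04_SYN     0.479 1e-04     0.533      150
```

The query's own source dataset ranks first with a Score that rounds to 1:
r = 1 on all 500 shared exons, the permutation p sits at the 10⁻⁴ floor, and
both overlap fractions are 100 %. The sibling datasets follow with r between
0.45 and 0.48 on their 150 shared exons (the generator's target was 0.5) and
Scores ≈ 0.53 driven by their 30 % overlap.

```r
# mode 2: a 40-exon coordinate-only list drawn from SF02's exons
m2 <- runQueryMode2(query[1:40], reg, nControlSets = 10000, seed = 42)
m2[, c("dataset", "n_observed", "expected_count", "p_emp", "q_bh", "direction")]
#>    dataset n_observed expected_count  p_emp   q_bh direction
#> 1 SF02_SYN         40           18.2 0.0001 0.0004  enriched
#> 2 SF01_SYN          8           18.2 0.0009 0.0018  depleted
#> 3 SF04_SYN         11           18.2 0.0129 0.0172  depleted
#> 4 SF03_SYN         17           18.1 0.4242 0.4242  depleted
```

All 40 exons are regulated by SF02 against an expectation of ~18, giving the
minimal attainable `p_emp = 1/10001`; SF01 regulates fewer of them than
chance would predict (8 vs 18) and is called depleted.

A thin command-line wrapper is installed under `inst/cli/splicescore`
(subcommands `simulate`, `query1`, `query2`, `clip`, `motifs`, `validate`);
every output file carries a provenance header with the seed and a config
hash, and identical seeds give byte-identical outputs.

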