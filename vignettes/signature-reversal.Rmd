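---
title: "Methods: directional overlap, signature reversal and pathway scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional overlap, signature reversal and pathway scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The procedure

`sigreverse` scores whether a drug-response gene set counteracts a disease
expression signature. The chain is:

1. **Normalize and pool.** Each disease study contributes a directional
   signature (an up-list and a down-list of gene symbols). Symbols are
   upper-cased and whitespace-stripped; the human gene-symbol convention
   makes UPPER the canonical case. Studies are pooled by set union per
   direction. A gene reported up by one study and down by another stays in
   *both* pooled directional sets but counts *once* in the pooled universe
   (up ∪ down). This is the only reading of pooling under which the
   directional set sizes can exceed the universe size (419 + 301 > 716 in
   the motivating configuration: four genes conflict); the original
   analysis does not state its convention, so we adopt the one that makes
   the arithmetic consistent.
2. **Map homologs.** The drug genes live in another species; a local
   two-column table maps each source gene to zero or more target symbols.
   Every target of a mapped source is kept (no "best homolog" selection —
   no selection rule is defensible without sequence-level evidence, and
   the union is the conservative superset); sources sharing a target
   collapse to one gene; unmapped sources are dropped from the statistics
   but enumerated in the mapping report, since the overlap universe is
   disease-side and unmapped drug genes cannot participate in it either
   way. Mapped multiplicity is deduplicated: two fly genes hitting the
   same human symbol contribute one gene, because the tests operate on
   sets, not on multisets.
3. **Directional overlap test.** Universe N = |up ∪ down|; the sample is
   the n mapped drug genes *inside* that universe (drug genes outside it
   are excluded from n — the overlap is framed as drawing the common genes
   from the disease universe). The up-test asks for enrichment
   (P[X ≥ k], K = |up|, k = |up ∩ drug|); the down-test for depletion
   (P[X ≤ k]). A reversal signature shows the first significant and the
   second significant in the depleted direction.
4. **Commonality extraction.** up ∩ drug, sorted: the genes the disease
   raises and the drug lowers — the candidate therapeutic mediators.
5. **Pathway scan.** Each pathway in a GMT collection is tested for
   over-representation of the commonality genes against the
   disease-upregulated set as background. K is the pathway membership
   *within the background*: the background is the 419 upregulated genes,
   not the genome and not the array, because the commonality genes were
   drawn from exactly that set — using a larger universe would manufacture
   enrichment for any pathway expressed in brain.

## Probability conventions

Every test reports three numbers: the point mass P[X = k], the upper tail
P[X ≥ k] and the lower tail P[X ≤ k]. Spreadsheet-era analyses used
`HYPGEOMDIST`, which returns the **point mass**, as a p-value; the pathway
values such a workflow prints match `p_point` here (for the 3-of-41 vs
9-of-419 configuration: point 0.0413, upper tail 0.0482). Tails are the
statistically defensible choice, so significance calls default to the tail
convention; `convention = "point"` reproduces legacy numbers. For the
directional test on the motivating counts, neither convention reproduces
the two printed legend p-values exactly (upper tail 0.0131 / point 0.0073
for enrichment; lower tail 0.0220 / point 0.0116 for depletion, against
printed 0.011 and 0.008 — possibly transposed or computed under a mixed
convention); the package asserts only the below-0.05 significance calls
for those two tests and reports all three probabilities so the reader can
judge. Likewise, the reported value for the largest pathway in the
original scan (6 foreground vs 36 background hits) is not consistent with
any hypergeometric convention on the stated background; the scan simply
reports its computed probabilities for those counts.

A call is `enriched` only if the driving probability is below α **and**
k exceeds the expectation nK/N (mirrored for `depleted`): without the
directional guard, a point mass below α in the depleted tail would be
mislabelled.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | nominal significance level; nominal (uncorrected) p-values are the default throughout |
| `convention` | `"tail"` | probability driving calls; `"point"` for legacy compatibility |
| `min_hits` | 3 | pathway-scan eligibility: fewer foreground hits than this is never called, because point-mass "enrichment" at k ≤ 2 is dominated by single-gene noise |
| `bh` | `FALSE` | Benjamini–Hochberg across eligible pathways; off by default to match the nominal-p convention of the motivating analysis |

## Numerical choices

All probabilities are computed in log space from `lchoose`, with
log-sum-exp accumulation for tails, so universes in the thousands cannot
overflow or underflow. The test suite checks the engine against an exact
rational oracle built from prime factorizations of factorials (Legendre's
formula) — exhaustively for every (N, K, n, k) with N ≤ 60, about 6×10⁵
instances — and against the distribution functions in `stats` on random
draws; pmf normalization and the identity
P[X ≥ k] + P[X ≤ k] − P[X = k] = 1 are enforced to 1e−12. Tail
monotonicity in k is strict except where consecutive values differ by less
than double precision can represent (both numerically 1 deep in the
opposite tail). Degenerate inputs: an empty pooled universe is an error;
an empty mapped drug set yields p = 1 and neutral calls with a prominent
warning rather than an error, so a pipeline over bad homology input still
produces a diagnosable report. Scan ordering is a total order (p, then
pathway name) so output files are reproducible.

## The synthetic generator

The generator **plants cardinalities exactly** (partition, then assign)
rather than sampling memberships from distributions, because every
statistic downstream depends only on set counts and the tests need them
exact. It emulates:

* fixed-size directional DEG lists with low inter-study overlap (each
  pooled gene has one primary study and a 15% chance of a second);
* direction conflicts between studies (the planted up ∩ down genes are
  reported up in one study and down in a different one);
* lossy many-to-many homology (0/1/2 targets per source with default
  probabilities 0.15/0.70/0.15, a realistic shape for insect-to-human
  symbol mapping where many genes have no clean homolog and some have
  paralog pairs);
* pathway membership concentrated in the up-set, with decoy members
  outside the background to give pathways realistic sizes.

The default configuration (`inst/extdata/paper_like.yaml`) is the study
condition: three studies pooling to 419/301/716, drug overlaps 56/41/16
(hence exactly one gene in up ∩ down ∩ drug, forced by inclusion–
exclusion), a 150-gene drug source set with 30 mapped targets outside the
universe, and a ten-pathway plan with hit counts 9/3, 36/6, 9/3, 7/3, 7/3,
5/3, 7/3 plus three null pathways at their expected hit rate. Three real
symbols (BRAF, PAK1, PRKCA) are injected as the MAPK-like pathway's
foreground hits for documentation fidelity; all other identifiers carry
reserved `SYN*` prefixes.

What the generator does **not** emulate: expression levels, fold-changes,
probe-level structure, annotation errors, or the biological correlation
between pathways and true differential expression. Passing tests therefore
demonstrate that the *computational chain* is exact and calibrated on
list-structured data — they say nothing about whether a given real
drug–disease pair reverses. The real supplementary gene lists behind the
motivating counts are not redistributable, so the gene-level overlaps are
exercised only through exact synthetic planting.

## Calibration checks and problem sizes

The null calibration test builds a 1000-gene background, a random 200-gene
foreground per replicate and ten random pathways of 100–300 members, over
200 replicates (2000 tests): the tail-convention false-positive rate is
compared, at binomial-error resolution, with the *exact attainable level*
of the discrete test (the largest achievable P[X ≥ k*] below α, averaged
over the pathway sizes — about 0.044 here). Discreteness makes the
hypergeometric test conservative, so the attainable level, not α itself,
is the correct yardstick; the test additionally bounds the rate by α plus
noise. The round-trip property is exercised over dozens of random feasible
planting configurations per run; infeasible configurations must fail
validation with a constructive message, and any configuration that passes
validation must generate.

## Known limitations

* Symbol normalization is case/whitespace only; synonym and alias
  resolution (which the original web-service conversions handled) is out
  of scope — inputs are expected to be symbol-harmonized already.
* The homology table is a required input; no orthology inference is
  attempted.
* The directional test treats genes exchangeably; no weighting by effect
  size or study quality.
* `min_hits` interacts with BH correction: ineligible pathways are
  excluded from the correction set, which is a choice, not a theorem.
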