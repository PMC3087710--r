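---
title: "Methods: copy-number variation analysis of miRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number variation analysis of miRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircnv)
```

## The scientific question

Copy number variants (CNVs) — genomic segments of roughly 1 kb to 1 Mb present
at variable copy number due to deletion or duplication — can change the dosage
of the genes they span. For microRNA genes the unit of annotation is the
pre-miRNA hairpin locus (~60–150 bp), and two questions arise:

1. **Which miRNA loci are copy number variable?** A miRNA locus overlapping a
   CNV region ("CNV-miRNA") is a candidate functional variant: its mature
   miRNA dosage, and hence the expression of its many target genes, may vary
   between individuals.
2. **Are miRNA loci depleted in CNVs?** If miRNAs are under purifying
   selection against dosage change, the fraction of miRNA loci covered by
   well-validated polymorphic CNVs should fall below the fraction of the
   genome those CNVs cover.

`mircnv` implements the full pipeline: interval algebra, file ingestion,
CNV-miRNA calling and classification, the depletion and SNP-density tests,
capture–recapture extrapolation of total polymorphic coverage, and a
synthetic-data generator that makes every stage testable without any frozen
database download.

## Coordinate model

All printed genomic coordinates ("chrN:a-b", and `start`/`end` columns of TSV
inputs) are 1-based inclusive, the dialect of 2009-era genome browsers and CNV
databases; internally everything is 0-based half-open (the BED convention), so
lengths are `end - start` and a printed region of `a..b` has length
`b - a + 1`. The choice is forced by the data: the mir-384 locus
chrX:76056092-76056179 must have length 88 nt — a pre-miRNA hairpin — which
only inclusive arithmetic yields. Zero-length intervals are rejected at parse
time (no zero-length feature exists in this domain). Mitochondrial chromosome
aliases (`chrM`, `chrMT`, `M`, `MT`) collapse onto one label so the
mitochondrial exclusion filter is dialect-robust; mitochondrial pre-miRNA
loci are excluded from all nuclear analyses because the depletion null is
defined on the nuclear genome.

## The depletion test

Let $p$ be the fraction of the (non-excluded) genome covered by the merged
CNV region set, and $n$ the number of distinct nuclear miRNA loci. Under the
null hypothesis that CNV placement is indifferent to miRNA loci, the number
of covered loci is $X \sim \mathrm{Binomial}(n, p)$, and the reported
probability is the exact lower tail

$$P(X \le k) = \sum_{i=0}^{k} \binom{n}{i} p^i (1-p)^{n-i},$$

computed exactly (`stats::pbinom`; tests verify equality with direct
log-space summation to 1e-10). Two deliberate simplifications define this
null:

* **Features are points.** The per-locus success probability is the genome
  coverage fraction, ignoring locus length. This is accurate when loci
  (~100 bp) are negligible against CNV scale (kb–Mb); when that premise is
  violated the test becomes slightly conservative, which matters for
  synthetic calibration (below) but not for real data.
* **Loci are independent.** True when inter-locus spacing is much larger than
  CNV length (the real genome: ~4 Mb average spacing vs ≤1 Mb CNVs). Shared
  CNVs covering several clustered loci would positively correlate their
  coverage indicators and make the test anti-conservative.

A locus counts as covered with ≥1 bp of overlap against the *merged* region
set (`min_overlap_bp` is configurable; every reference locus is in fact fully
contained in its region, so the threshold is untestable on the bundled tables
but must be fixed somewhere). Locus identity is `(id, chrom, start, end)` —
the same miRNA name can occupy two distinct loci (mir-1233 on chr15), and
near-identical paralogues are tracked via the `dupl` annotation, never
collapsed.

No multiple-testing correction is applied across narrowing strata; raw
lower-tail probabilities are reported, matching the analysis this package
reproduces.

## Narrowing by validation support

Deposited CNV records are heterogeneous in quality. Two validation factors
are used to narrow a region set: the number of overlapping deposited records
and the number of distinct reporting publications. The default semantics are
**base-depth**: the narrowed set at threshold $k$ is the set of genomic bases
supported by ≥ $k$ records (or by records from ≥ $k$ distinct publications,
each publication contributing at most one layer per base), which shrinks
monotonically base-wise as $k$ grows. This reading was chosen because the
narrowing is described as acting on regions, implying base-wise shrinkage; it
is not the only possible reading, so the record-level alternative (keep whole
records whose own support annotation reaches $k$, then merge) is exposed as
`method = "filter"`. Reference-wise narrowing requires per-record publication
identity (a `reference` column); an aggregate per-region publication count
cannot produce base-wise depth, and the function says so rather than guess.

## SNP density as a purifying-selection control

Conservation of pre-miRNA sequence predicts fewer SNPs per bp inside loci
than outside. The comparison is a two-sided Fisher's exact test on the
base-level 2×2 table `[[snps_in, bp_in − snps_in], [snps_out, bp_out −
snps_out]]`, with rates reported per 1,000 bp. The p-value is the classic
sum of hypergeometric probabilities not exceeding the observed table's,
computed directly from `dhyper` over the table's support: `fisher.test`
agrees on small tables (asserted in tests, along with brute-force
enumeration) but cannot handle genome-scale margins (~2.8 × 10⁹ bases),
which this analysis needs. Sidedness is not dictated by the source analysis;
two-sided is used and the depletion direction is read from the rates.

## Capture–recapture extrapolation

Two independently ascertained polymorphic CNV surveys cover fractions
$c_A, c_B$ of the genome, and fractions $f_{A\subset B}$ of A's bases are
also in B (and vice versa). Treating base coverage like a mark–recapture
census (Lincoln–Petersen), the full polymorphic CNV complement covers

$$\hat{C} = \frac{c_A\, c_B}{\widehat{o}}, \qquad
  \widehat{o} = \tfrac12\!\left(f_{A\subset B}\, c_A + f_{B\subset A}\, c_B\right),$$

with the two single-sided estimates $c_B / f_{A\subset B}$ and
$c_A / f_{B\subset A}$ reported as a bracketing range. With the printed
inputs (1.2%, 2.3%, 0.39, 0.20) the point estimate is 5.95% (range
5.90–6.00%), below the 10% upper bound quoted for this extrapolation. The
expected genome-wide count of polymorphic CNV-miRNAs is then
`n_loci × coverage × depletion_ratio` — the coverage-based expectation
discounted by the observed purifying deficit.

## Dosage classification

For a miRNA gene sketched as (primary transcript span, pre-miRNA hairpin,
promoter/TSS anchor at the 5′ end), the predicted dosage effect of an
overlapping CNV follows a rule table:

| CNV kind    | geometry                                           | effect |
|-------------|----------------------------------------------------|--------|
| deletion    | removes the hairpin                                | decrease |
| deletion    | removes the promoter, hairpin intact               | decrease (transcript unlikely to be made) |
| deletion    | crosses only the 3′ boundary, hairpin+promoter intact | indeterminate (depends on truncated-transcript stability) |
| deletion    | wholly intragenic, spares hairpin and promoter     | none |
| duplication | whole gene                                         | increase |
| duplication | tandem segment with hairpin, promoter included or segment wholly intra-transcript | increase (extra hairpins per primary transcript) |
| duplication | segment without the hairpin                        | none |

"5′/3′-portion" CNVs are operationalized as CNVs crossing the corresponding
transcript boundary and "intragenic" as wholly inside the transcript — the
only reading that makes the deletion rules disjoint. A strand is required
(default "+") because a 5′ anchor is undefined without orientation.
Duplications are assumed tandem; dispersed duplications would need sequence
context this package does not model. Enlarging a CNV to the whole gene never
flips increase↔decrease relative to a partial CNV of the same kind (tested
as a property).

Flank geometry of fully contained loci is classified from the two
locus-to-boundary distances: `short_both` below 5 kb on both sides (tandem
copies likely transcribed from one promoter), `large_both` at ≥20 kb on both
sides (locus embedded deep in the CNV, likely co-expressed with its host
span), `mixed` otherwise, `partial_overlap` when not contained. The
published grouping additionally uses protein-coding gene context, which
requires a gene annotation this package takes only as optional input —
without it, no intergenic/intragenic claim is made.

The **minimal CNV region** of a locus is the common intersection of all
deposited records overlapping it (with the record count attached). The
alternative reading — maximal-depth segment — is not equivalent in general;
intersection was chosen because published minimal regions are far narrower
than their parent regions in a way consistent with intersecting record
stacks. When records do not all contain the locus the result is flagged, and
an empty common intersection falls back to the deepest common segment.

A call is **multiallelic** when its genotype list contains at least two
states above 2 copies or spans more than 3 states. This is an
operationalization (the source material gives examples, not a definition);
note it also flags {2,3,4} genotype lists, which the narrative examples call
plain duplications.

## The synthetic world

`simulate_dataset()` generates the structure the analysis assumes, with a
known truth for recovery tests:

* **Genome**: 5 × 2 Mb by default — large enough for stable fractions, small
  enough for fast tests.
* **miRNA loci**: `n_mirnas` non-overlapping spans of 60–150 bp (the
  pre-miRNA hairpin scale), uniform placement by batch rejection.
* **CNVs**: lengths log-uniform on 1 kb–1 Mb by default (the field's working
  definition of CNV scale; tests use narrower ranges for speed and premise
  control), uniform placement with **rejection thinning**: a candidate CNV
  overlapping ≥1 locus is kept with probability ρ (ρ = 1 neutral, ρ < 1
  depletion). Thinning, unlike hard exclusion, reaches any target
  observed/expected ratio and keeps the binomial null approximately exact at
  ρ = 1. For small coverage the recovered ratio ≈ ρ; at coverage λ it is
  $(1 - e^{-\rho\lambda})/(1 - e^{-\lambda})$, slightly above ρ.
* **SNPs**: independent per-bp Bernoulli, rates 3.7/1,000 bp inside loci and
  4.8/1,000 bp outside by default (the observed pre-miRNA vs genome-background
  densities), implemented exactly as a binomial count plus
  without-replacement uniform offsets mapped through the locus/gap segment
  structure.
* **Record stacks and genotypes**: each CNV receives 1 + Poisson(3) jittered
  deposited records tagged with simulated study identifiers, and a genotype
  list drawn from a configurable copy-number state distribution (default
  centred on 2 copies with deletion and duplication tails).

One seed governs the dataset; per-component sub-streams (loci, CNVs, records,
SNPs) are derived deterministically, so enabling SNPs does not perturb CNV
placement. Identical config + seed is bit-identical.

What the generator does **not** emulate: assembly gaps, GC/repeat-driven CNV
clustering, linkage between nearby variants, ascertainment bias of CNV
discovery platforms, and population genotype sampling. A green synthetic test
therefore establishes correctness of the *computations* under the stated
model, not robustness to real-data artefacts.

### Calibration of the null

The depletion test's null is checked two ways. Parameter recovery: at
ρ = 0.5 the mean recovered observed/expected ratio over 20 replicates lies in
[0.4, 0.6] (measured ≈ 0.55; the excess over 0.5 is the predicted
finite-coverage effect above), and the mean ratio is monotone in ρ over
{0.25, 0.5, 1}. Null calibration: over 500 neutral (ρ = 1) datasets the
fraction of lower-tail probabilities ≤ 0.05 must lie in [0.02, 0.09]. The
calibration world must satisfy the null's own premises — locus length
negligible against CNV length, and locus spacing large against CNV length —
so it uses coverage ≈ 0.30 with 5–20 kb CNVs, 250 loci spaced ~50 kb apart
on a 12.5 Mb genome. Measured: 4.0% of datasets at p ≤ 0.05 (8.4% at
p ≤ 0.10), i.e. near-uniform and mildly conservative, exactly as the
point-feature null predicts. An earlier candidate world with 1–10 kb CNVs
measured 1.6% — below the band — because a ~105 bp locus is not negligible
against a ~4 kb CNV; the fix was restoring the stated premise, not loosening
the band.

## Numerical and degenerate-input choices

* Binomial tails: exact, no normal approximation (the regime is n ≤ 10⁴).
* Fisher two-sided ties: probabilities within a relative 1e-7 of the observed
  table's count as "as extreme", mirroring `fisher.test`.
* `capture_recapture_union` errors on zero overlap (the estimate diverges)
  rather than returning infinity.
* `observed_vs_expected_ratio` errors when the expected count is zero.
* Merging joins book-ended intervals; all set operations are closed over
  empty inputs (empty in, empty out; coverage of an empty set is 0).
* Genome fractions and locus totals can be supplied explicitly in the
  pipeline config (printed-value route) and then win over computed values
  with a logged notice — required to reproduce published arithmetic when the
  frozen source databases cannot be redistributed.
* Tie-break in call tables: the reported region for a multiply-hit locus is
  the record with the largest overlap, then coordinate order; output rows
  are sorted (chrom, start, set label), making every TSV byte-reproducible.

## Known limitations

* The bundled reference tables transcribe printed coordinates only; the
  full deposited-CNV universe (29,133 records), the SNP catalogue and the
  disease-region set are not redistributable, so genome-scale quantities
  (e.g. the 30%/1.2%/2.3% coverages) enter as explicit inputs, and the
  corresponding correctness claims rest on the property-based tests against
  exact oracles.
* Flank-group classification without a gene annotation reports geometry
  only; dosage classification requires a user-supplied gene model sketch.
* Strand is ignored everywhere except dosage classification (the coordinate
  data carry no strand).
* The capture–recapture estimator assumes the two surveys ascertain
  independently; shared platform bias would inflate the overlap and deflate
  the estimate.
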