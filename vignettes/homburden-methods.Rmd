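---
title: "Homozygous rare-variant burden analysis with homburden"
author: "homburden maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygous rare-variant burden analysis with homburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homburden)
```

## The scientific problem

Recessive-acting risk alleles are invisible to case-control tests that
count heterozygous carriers: their phenotypic effect requires two copies.
For a rare allele at frequency $q$, homozygotes occur at frequency $q^2$
under random mating — so even in cohorts of thousands of exomes, any
single gene contributes at most a handful of homozygous carriers of
ultra-rare variants. The natural response is *collapsing*: pool a
biologically coherent gene set (here, genes of GABAergic synaptic
transmission and GABA metabolism, motivated by a loss-of-function
mutation found homozygous in a patient with schizophrenia) and ask
whether **more cases than controls are homozygous for at least one
qualifying rare variant anywhere in the set**.

`homburden` implements that screen end to end for case-control exome
data: genotype-level quality control, nested rarity/impact variant
categories, a subject-level homozygous-carrier burden test, an
empirical null built from random gene sets, the genome-complement
control analysis, and an exact power calculation. A companion module
reproduces one-way ANOVA with Fisher's LSD from either raw replicates
or printed group summaries, as used for functional-assay readouts
(enzymatic activity, proximity-ligation spot counts). A synthetic
exome-cohort generator supplies data with the statistical structure the
analysis assumes, so every stage is testable without access-controlled
genotypes.

## The data model

A cohort is a `HomCohort`, an extension of
`RangedSummarizedExperiment`: rows are biallelic variants, columns are
subjects, and four assays carry the per-call quantities the filters
need — the genotype `GT` (alt-allele count 0/1/2, `NA` when missing),
the phred-scaled genotype quality `GQ`, and the reference/alternate
read depths `RD`/`AD`. Variant annotations (gene symbol, consequence
class, CADD phred, maximum population allele frequency, indel flag)
live in `rowData()`; the case/control label in `colData()$group`.
Multi-allelic sites are expected to be decomposed upstream into
independent biallelic records, the convention of common annotation
tools.

VCF v4.2 is the interchange format (`writeCohortVcf()` /
`readCohortVcf()`, the latter built on `VariantAnnotation`), with
`FORMAT GT:GQ:AD` and INFO keys `GENE`, `CSQ_CLASS`, `CADD`,
`POPMAX_AF`, `INDEL`. Plain VCF has no case-control field, so the
labels travel in a `##SAMPLE_GROUPS` header line (or are inferred from
`case_`/`ctrl_` sample-id prefixes, or passed explicitly).

## Quality control

Four filters, composed in a fixed order by `runQC()`:

1. **Genotype quality** — calls with `GQ < 20` become missing. The
   inequality is strict: a call at exactly 20 survives.
2. **Homozygous-call contamination** — a homozygous-alt call whose
   reference reads exceed 5% of its total depth is likely a
   miscalled heterozygote; the *call* is invalidated. The filter acts
   per genotype, not per variant: removing the whole site would also
   discard valid heterozygous calls, while the stated aim is only to
   purge false homozygotes. Zero-depth homozygous calls are
   unverifiable and invalidated conservatively.
3. **Per-group missingness** — variants missing in more than 10% of
   filtered genotypes in cases *or* in controls are dropped. This comes
   after the genotype-level filters because the fractions are defined
   over filtered calls; it is the only step whose outcome depends on
   the order.
4. **Indel exclusion** — indels are removed wholesale (high
   false-positive call rates and ambiguous allele representation make
   them incomparable across datasets).

QC is idempotent, never resurrects a missing call, and never changes a
genotype except to missing; `qcSummary()` reports what each filter
removed.

## Variant categories

`classifyVariants()` computes the **dataset MAF** — the minor-allele
frequency over all non-missing calls, cases and controls pooled (the
screen conditions on overall rarity, not group-specific rarity, which
would bias the test) — and assigns four nested categories with strict
`<` thresholds:

| category | definition |
|---|---|
| A | dataset MAF < 0.001 |
| B | A, and population MAF < 0.01 |
| C | A, and population MAF < 0.001 |
| D | C, and likely disruptive |

"Population MAF" is the precomputed maximum across external reference
panels (ExAC, ESP, 1000 Genomes), consumed as the `POPMAX_AF`
annotation. Strictness at the boundary matters in practice: a variant
with population MAF exactly $10^{-3}$ belongs to B but not C.

**Likely disruptive** means: missense with CADD phred strictly above
20, nonsense, or splice-junction (within 3 bp of an exon/intron
boundary, as annotated upstream). Whether a *low-CADD* splice-junction
variant should count is genuinely ambiguous — the rule as stated says
yes, but gating splice variants on CADD as well is a defensible
stricter reading, and on the bundled example table the two readings
give 4 vs 3 category-D carriers. `isLikelyDisruptive()` therefore
exposes both as `rule = "asStated"` (default) and
`rule = "strictSplice"`, and nothing downstream silently prefers one.

## The burden test

`countHomCarriers()` collapses at the subject level: a subject is a
carrier if homozygous-alt for at least one qualifying variant in the
gene set, and counts once no matter how many such genotypes it has.
`burdenTest()` then computes the one-tailed Fisher exact p — the
upper tail of the hypergeometric distribution with the table margins
fixed, direction hard-coded as enrichment in cases:

$$P = \sum_{k \ge a} \frac{\binom{n_1}{k}\binom{n_2}{K-k}}{\binom{N}{K}},$$

with $a$ carrier cases among $n_1$ cases, $K$ carriers in total,
$N = n_1 + n_2$. With zero control carriers this reduces to
$\prod_{i=0}^{a-1}(n_1-i)/(N-i)$, a useful hand check. The
implementation uses `stats::phyper`; the test suite verifies it
against brute-force enumeration of the table support and against
`fisher.test(alternative = "greater")`.

Two companion analyses guard the interpretation:

* `complementBurden()` runs the identical test on every gene *not* in
  the target set — a significant target set with a null complement
  argues against a genome-wide excess of homozygotes in cases.
* `fisherPower()` computes the power of the one-tailed test when
  carrier counts arise binomially at given carrier frequencies,
  either by exact enumeration of the joint binomial over the
  rejection region or by seeded Monte Carlo. For the scenario of 3
  carrier cases in 4,225 vs none in 5,834 controls at
  $\alpha = 0.05$, rejection requires at least 4 carrier cases (3
  give $p = 0.074$), and the exact power is
  $1 - F_{\mathrm{Bin}(4225,\,3/4225)}(3) \approx 0.35$ — a
  reminder that a non-significant category-D row is expected even
  under a real effect of that size.

## The random-gene-set null

A gene set picked for biological reasons could score well simply
because gene sets of its size tend to: `simulateNull()` draws
`nSims` sets of `setSize` genes uniformly without replacement from the
cohort's gene universe (default 5,000 sets of 120 genes), computes
each set's case-minus-control difference in homozygous-carrier
*proportion*, and `empiricalP()` reports the fraction of replicates
whose difference equals or exceeds the observed one (inclusive ties;
the $(k+1)/(n+1)$ correction is reported alongside). Design choices,
each matching the plain-resampling description the method follows:
no matching on gene length or variant count; independent draws, so
replicate sets may overlap; and a universe of *all* genes present in
the matrix, including genes that can never contribute a carrier —
they are legitimate draws of the sampling scheme.

### Rarity thresholds at reduced scale

One arithmetic fact shapes all desk-scale testing: in a cohort of
$n$ called subjects a single homozygote already contributes
$2/(2n)$ to the dataset MAF, so with $n \le 2000$ **no variant
carrying a homozygote can be below the 0.001 ultra-rare threshold**.
The category system is meaningful only at biobank scale. The burden
and null functions therefore accept `category = NULL` (no rarity
filter), and `classifyVariants()` exposes the thresholds as
arguments; the distributional checks in the test suite run
unfiltered, which tests the machinery without pretending small
cohorts have ultra-rare homozygotes.

## The synthetic cohort generator

`simulateCohort()` emulates the structure the analysis assumes — not
any particular real dataset, whose per-gene variant counts and
frequency spectrum are not public. Defaults: 18,024 genes (scalable),
a mean of 2 variants per gene (every gene gets at least one, so the
resampling universe equals the gene list), per-variant alt-allele
frequencies log-uniform on $[10^{-5}, 0.2]$ (roughly uniform per
frequency decade, placing substantial mass below $10^{-3}$),
genotypes per variant drawn Binomial$(2, q)$ — Hardy–Weinberg, the
simplest exchangeable null consistent with the test's assumptions —
GQ normal around 60 (clamped to $[20, 99]$ for clean calls), total
depth negative-binomial around 30x, and injected artefacts at
configurable rates: a fraction of calls given GQ below 20, and a
fraction of homozygous-alt calls given reference reads exceeding 5%
of depth. Clean calls are generated so they *cannot* cross a QC
boundary (clean hom-alt reference reads are capped at 5% of depth);
the injected artefacts are then exactly the calls QC must remove,
making the generator's `truthRecord()` an exact oracle for filter
tests rather than a statistical approximation.

Planted enrichment converts `plantedCaseHomExcess` randomly chosen
case subjects into clean homozygotes at ultra-rare variants of a
designated target set — the alternative hypothesis realized
directly. Planted calls are excluded from artefact injection so the
plant survives QC by construction.

What the generator does **not** model: linkage disequilibrium,
relatedness, population structure, ancestry gradients, read-level
errors, or batch effects. Passing tests on synthetic cohorts
therefore demonstrate the statistical machinery is correct under the
test's own assumptions; they cannot show robustness to stratification
or call-set artefacts beyond the two injected kinds.

## ANOVA with Fisher's LSD

Functional follow-up data often arrive only as printed group
summaries. `anovaFromSummary()` rebuilds the one-way ANOVA exactly
from $(n_i, \bar x_i, s_i)$: between mean square from means and
sizes, within mean square as the df-weighted mean of the variances —
algebraically identical to `anovaRaw()` on any raw data with those
summaries (verified to machine precision in the tests). SDs are read
as sample standard deviations ($n-1$), the convention of "(SD)"
columns; `sdIsPopulation = TRUE` switches the reading. LSD p-values
are unadjusted pairwise $t$-tests on the pooled within mean square,
as Fisher's LSD prescribes. Reproduction of printed tables is limited
by the rounding of the printed summaries — e.g. the bundled
proximity-ligation example gives $F_{2,6} = 23.92$ against a printed
24.094 (0.7% off), entirely attributable to means printed to one
decimal. Exactly-zero within variance (possible with integer-valued
replicates) is flagged degenerate, with $F = \infty$ and LSD p of 0
or 1 by mean equality, rather than propagating NaNs.

## Numerical and scale choices

* All seeds are explicit arguments; seeded code restores the caller's
  RNG state.
* The null simulation precomputes per-gene carrier lists once
  ($O(\text{hom calls})$) and reuses them across replicates, so 5,000
  replicates cost seconds.
* Test-suite problem sizes: the null-uniformity property uses 200
  cohorts of 500 + 500 subjects and 2,000 single-variant genes with
  1,000 replicate sets each — large enough that the carrier-frequency
  differences take ~180 distinct values and the empirical p is
  effectively continuous; the planted-detection property uses the
  ultra-rare regime (spectrum capped at $10^{-2}$) with 8 planted
  carriers, whose Fisher p $\approx 0.5^8 \approx 0.004$ matches the
  published effect-size scenario while standing ~5 null SDs above the
  sparse background.
* The bundled six-variant table expands deterministically to a full
  cohort (`cohortFromVariantTable()`): each printed homozygote goes to
  a distinct subject, remaining alt alleles become heterozygous
  control calls, and uncalled individuals become missing genotypes, so
  the printed dataset MAFs and carrier counts are reproduced from raw
  genotypes rather than asserted.

## Known limitations

* Gene matching is by case-sensitive symbol; no alias resolution.
* The power calculation treats carriers as binomial draws, ignoring
  that carrier status is itself an aggregate over variants.
* The category-D definition is ambiguous at low-CADD splice variants;
  both readings are exposed, neither endorsed.
* No covariate adjustment, relatedness handling, or multiple-testing
  correction across categories (the screen reports all four rows).
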