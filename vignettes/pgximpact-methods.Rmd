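---
title: "Methods: actionable pharmacogenetic variants and projected prescription impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actionable pharmacogenetic variants and projected prescription impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgximpact)
```

## The problem

Exome sequencing performed for rare-disease diagnosis or research can be
reused, at no sequencing cost, to answer a pharmacogenetic question: what
fraction of a population carries genotypes that should change prescribing,
and how much prescribing do those genotypes touch? `pgximpact` implements
that secondary analysis as a reusable pipeline: cataloging actionable
variants, calling star-allele diplotypes, translating diplotypes to
CPIC-style phenotypes, projecting population phenotype frequencies under
Hardy–Weinberg equilibrium (HWE), classifying rare predicted-deleterious
variants, and multiplying phenotype frequencies into prescription
headcounts and expenditure.

Because cohort-level genotype data of this kind is protected and not
generally redistributable, the package treats the synthetic-data generator
as a first-class module: every stage runs end to end on seeded simulated
inputs with the statistical structure the analysis assumes.

## Catalog and registry

The actionable catalog is a flat TSV: one record per (gene, identifier)
with an entry class (`snv_marker`, `star_allele`, `hla_allele`,
`noncoding`), a functional class from a closed vocabulary (`no_function`,
`decreased`, `normal`, `increased`, `risk`, `favorable`), a
semicolon-joined drug list, and an `exome_ascertainable` flag. Non-coding
entries are by definition not ascertainable from exome data; the loader
enforces this, along with vocabulary membership and (gene, identifier)
uniqueness. The high-confidence pharmacogene registry carries one row per
gene with its transcript length and a gnomAD-style loss-of-function o/e
constraint score.

The packaged catalog has 133 entries in 19 genes (four non-coding) and the
registry 108 genes, matching the structure of the published curation these
shapes come from. Only the entries printed in the published
phenotype-frequency table could be reproduced faithfully; the remainder are
synthetic stand-ins with realistic identifiers, marked
`provenance = "synthetic"`, and the file names carry a `_synthetic` suffix.
Registry transcript lengths and o/e scores are likewise synthetic values of
realistic magnitude. Users with access to a curated list supply their own
files; all loaders accept a path.

HLA loci (HLA-A, HLA-B) appear in the catalog but deliberately not in the
registry: they are analyzed through typing tables, not variant calls, and
`validate_catalog()` treats them as a permitted exception.

## Star-allele calling

A star allele is defined by the set of marker variants on its haplotype;
the allele with an empty marker set is the reference. Given unphased
genotypes `g` (alt-allele counts) over a gene's markers, the caller
enumerates allele pairs `(i, j)` and keeps those whose combined marker
indicator vectors reproduce `g` exactly; for males at an X-linked gene it
enumerates single alleles. Ambiguity is resolved in two steps:

1. **Maximum parsimony** — keep the solutions with the fewest non-reference
   alleles. An observed heterozygous marker shared by a one-marker and a
   two-marker allele (the classic nested-definition situation, e.g.
   *3C ⊂ *3A in TPMT) is thereby attributed to the smaller explanation
   only when the larger one is not forced by the data.
2. **Definition-file order** — a deterministic tie-break. If more than one
   minimal solution remains, the call is flagged `ambiguous` and the
   candidate set reported.

Ambiguous calls and samples with any missing marker genotype (no-calls)
are excluded from phenotype tallies rather than guessed; this is
conservative and logged in the output. Marker variants entirely absent
from the matrix are treated as homozygous reference — "explicitly absent
from the cohort" — which is the correct reading for a jointly-called
cohort VCF, though not for a single-sample VCF.

The test suite checks the caller against an independently written
exhaustive-enumeration oracle over all genotype inputs for definitions
with up to four alleles and markers, including nested marker sets.

CYP2D6 is deliberately **not** called: its copy-number and hybrid alleles
are not reliably derivable from exome genotypes, so its phenotype
frequencies enter the pipeline as external published estimates
(`source = "external"` in the rules file), never from genotype calls.

## Genotype-definition rules

Diplotype-to-phenotype translation is data, not code: a rules TSV mirrors
the published frequency table, one row per (gene, phenotype) with a
pattern over functional classes — `"normal/no_function"` (unordered
multiset), `"decreased"` under `sex_mode = "x_linked_male"`, or
`"carrier:risk"` (at least one allele of the class). Within a gene and sex
mode, patterns must be mutually exclusive; the loader verifies this by
enumerating all class multisets, and the assigner errors if two rules ever
match. Diplotypes matching no rule get a configurable label
(default `"Normal/indeterminate"`) and are not actionable — whether such
samples should be reported as normal or indeterminate is a presentation
choice the published table leaves open, so the label is a flag rather than
a fixed string.

## Hardy–Weinberg projection

Phenotype frequencies are projected from summed allele-class frequencies
`q` (the summed frequency of all alleles of a class):

* `{A, B}`, A ≠ B: `2·q_A·q_B`; `{A, A}`: `q_A²`
* carrier of A: `1 − (1 − q_A)²`; inverse `q = 1 − sqrt(1 − c)`
* X-linked: `q_A` for males, `q_A²` for females; population rate
  `m·q + (1 − m)·q²` at male fraction `m` (default 0.456, the Hong Kong
  ratio 45.6 : 54.4)

By-gene aggregation is declared per gene in the rules file because the two
published row types behave differently: metabolizer phenotypes partition
diplotype space and simply add (`disjoint`, e.g. CYP2C19
45.25 + 11.96 = 57.21), whereas multiple risk alleles at one HLA locus
overlap in compound heterozygotes, so carrier frequencies are converted
back to allele frequencies, summed, and re-projected
(`carrier_union`, reproducing HLA-B's non-additive 33.88 from 18.42,
0.18, and 17.04).

### Back-derivation of the packaged frequencies

The packaged Hong Kong allele-class frequencies are derived in closed form
from the published phenotype percentages rather than copied: for a gene
with printed heterozygote frequency `h`, `q = (1 − sqrt(1 − 2h))/2`; for
carrier rows, `q = 1 − sqrt(1 − c)`; G6PD's male frequency is `q`
directly. The heterozygote row is inverted (rather than the homozygote)
because it is printed with more relative precision; with this choice every
printed percentage in the table — including the homozygote rows and the
CYP3A5 pair 6.13 / 37.25, which cannot both be exact under any single `q`
— is reproduced to the printed two decimals. Frequencies are carried at
full precision internally; rounding to percent happens only in
`format_phenotype_table()` and the report writers, so rounding error never
compounds.

## Rare deleterious variants

Classification is total and deterministic. Rare means gnomAD global
AF < 1% **or missing**: variants absent from gnomAD are treated as rare by
convention, which is required for never-reported (novel) variants to be
countable. Deleteriousness is an OR over the evidence available for the
consequence group — missense: CADD ≥ 20, REVEL ≥ 0.7, PREDICT ≥ 0.6; LoF
(frameshift, stop-gain, start-loss, canonical ±1,2 splice): CADD ≥ 20 or
LOFTEE high-confidence; anything else never qualifies. A missing score is
non-supporting rather than disqualifying. The "PREDICT" column is treated
as an opaque third missense score with threshold 0.6; its exact provenance
does not affect the machinery. All thresholds are configurable
(`classification_thresholds()`), and raising any threshold can only shrink
the deleterious set (a tested monotonicity property).

Burden counts **variants, not alleles**: a homozygote contributes one,
matching the per-variant counting convention of burden histograms in this
literature. Disease-cohort exclusions (respiratory samples for CFTR,
neuromuscular for RYR1) avoid double-counting disease-ascertained alleles
in exactly the genes they were ascertained for.

The variant-count regression is ordinary least squares of per-gene total
variant count on transcript length in kilobases and the o/e constraint
score, with two-sided t-tests per coefficient — the standard small
multiple-regression this analysis calls for, via `stats::lm()`.

## Prescription impact

Unique patient headcounts are computed by deduplicating raw prescription
rows per (drug, year) over patient identifiers (routes, doses, repeat
prescriptions collapse); expenditure sums over all rows. Drug-level
actionable frequency assumes independence across a drug's implicated
genes, `f_drug = 1 − Π(1 − f_gene)` — an assumption, not a fact, but one
validated by reproducing the published warfarin figure (43.13% from 39.89%
and 5.39%). Projections are `round(n·f)` patients and `HKD·f / 7.8` USD,
rounded only at the report layer. X-linked genes enter drug-level
frequencies as the sex-mixed population rate.

Expected prevented adverse events split an actionable headcount across
genotype groups by their HWE proportions and apply each group's published
cumulative risk, assuming the intervention removes the excess risk
entirely — the implicit assumption in this style of projection. Because
the published genotype frequencies are printed at two decimals, the
reconstruction is exact only to within a few cases; the package derives
the allele frequency from the heterozygote row (see above), and the test
tolerance is ±5 cases. Published per-drug figures computed from two
inconsistent denominators (the azathioprine dose-reduction vs alternative-
therapy counts imply different totals) are not replicated; the package
computes all of a drug's phenotype groups from one denominator.

The clopidogrel indication caveat — guideline support only in acute
coronary syndrome with percutaneous intervention, an indication
prescription extracts do not record — is surfaced as a per-drug warning
flag in the impact report, not as a computation.

## Synthetic data: what it does and does not emulate

`simulate_cohort()` draws gene haplotypes independently per sample from
the spec's allele frequencies (two per autosomal gene; one for males at
X-linked genes) and derives marker genotypes from haplotype marker
content; HLA typings are two independent draws per locus. This realizes
exactly the HWE model the projection assumes, so observed phenotype
frequencies converge on the closed forms (tested at n = 10,000 within
three binomial standard errors), and a chi-square goodness-of-fit against
p², 2pq, q² rarely rejects.

The packaged `hk_cohort_spec()` uses 1,116 samples, male fraction 0.456,
and allele frequencies whose class sums equal the packaged Hong Kong
values, with class mass split across a gene's defined alleles by fixed
halving weights (1/2, 1/4, ... normalized) — the per-allele split is not
printed in the published table, so any split consistent with the class
sums is admissible; the halving choice is arbitrary but fixed and
documented. Under this spec the demonstration pipeline reports ~99.6% of
samples carrying at least one actionable variant with a median of four.

What the generator does **not** emulate: linkage disequilibrium between
markers (haplotypes are drawn independently per gene; within a gene the
marker correlation implied by allele structure is preserved, across genes
there is none), copy-number variation (hence CYP2D6's external treatment),
sequencing error, depth-dependent missingness (QC paths are exercised with
constructed fixtures instead), population substructure, and relatedness.
Passing tests therefore demonstrate the correctness of the machinery under
its stated model, not robustness to real-data pathologies.

Randomness derives from one root seed with fixed per-component offsets
(sex/labels, gene haplotypes, HLA, annotations, rare-variant genotypes,
prescriptions), so components are individually reproducible and rerunning
the pipeline with one seed reproduces every report byte for byte.

## Numerical choices and degenerate inputs

* QC filtering iterates variant and sample removal to a fixed point, which
  makes `apply_qc()` idempotent regardless of filter interactions.
  Default thresholds (genotype depth ≥ 8X, variant call rate ≥ 0.90,
  sample missingness ≤ 0.10) are documented stand-ins for cohort-specific
  cut-offs and are fully overridable.
* An allele frequency with zero called allele slots is `NA` (undefined),
  never 0: "absent among called samples" and "uncallable" are different
  statements.
* Class-frequency maps must sum to at most 1 + 1e-9; the
  carrier-frequency inverse is exact to 1e-12 (tested across [0, 1]).
* Sex is taken from metadata, never inferred from genotypes.
* Regression requires ≥ 3 genes and errors on collinear designs rather
  than silently dropping coefficients.
* Report-layer rounding: percent to 1–2 decimals, USD figures at full
  precision in objects (round to the nearest 1,000 for display).

## Problem sizes

The test suite simulates cohorts of up to 10,000 samples, annotation
tables of up to 4,000 variants, 100-replicate null-regression studies on
40–50 genes, and 40-seed HWE goodness-of-fit batteries; the demonstration
pipeline runs at the study scale of 1,116 samples. These sizes were chosen
to hold three-standard-error statistical checks comfortably while keeping
the full suite fast on a single CPU.

## Known limitations

* Star-allele calling assumes markers are either present in the matrix or
  genuinely absent from the cohort; on single-sample inputs, absent
  markers are indistinguishable from uncovered ones.
* Phenotype frequency estimation from a cohort uses called, unambiguous
  diplotypes only; at very small cohort sizes rare classes may be entirely
  unobserved and project to zero.
* The independence assumptions (across genes for drug frequencies, across
  variants for burden closed forms) are modelling choices inherited from
  the analysis design, not estimated from data.
* The packaged catalog beyond the published frequency-table rows is
  synthetic; analyses of those entries exercise machinery, not biology.
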