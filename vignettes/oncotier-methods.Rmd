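---
title: "Methods and design of the oncotier interpretation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the oncotier interpretation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotier)
```

# The problem

A tumor's somatic mutations are only useful clinically once each call is
placed in context: is this exact allele a known drug-sensitivity biomarker,
does it hit a recurrently mutated codon, does it merely alter the protein of
a known cancer gene, or is it noise? `oncotier` implements that
interpretation layer. Its inputs are deliberately minimal — a single-sample
VCF whose INFO field carries per-transcript consequence blocks from an
upstream annotator (VEP-style), an optional copy-number segment table with
log2 ratios, and a knowledge bundle of plain TSV reference tables — and its
output is a tiered, machine- and human-readable report.

Consequence prediction itself is out of scope by design: the engine consumes
the picked consequence block rather than recomputing transcript effects, so
it slots in behind any annotator that can emit the standard block format.

# Data model and normalization

All coordinates are 1-based inclusive, for the VCF (where this is the
standard) and for the segment and gene tables (where conventions vary in the
wild; we declare one and normalize on ingest). Chromosome names are compared
after stripping a leading `chr`.

Exact-allele joins require a canonical allele representation. `normalize_allele()`
trims the shared suffix first, then the shared prefix, always retaining at
least one base on each side, and advances the position by the trimmed prefix
length. Suffix-first trimming makes the result left-aligned among the
minimal anchored forms, matching the convention used by VCF normalizers; the
test suite checks the result against an independent enumeration oracle over
all legal trim orders and verifies idempotence on random alleles.

Multi-allelic records are split before normalization; consequence blocks are
assigned to each split allele via the `Allele` subfield where present. A
record is admitted only with FILTER `PASS` or `.`; the count of excluded
records is surfaced in the report metadata rather than silently dropped.
MNVs (equal-length multi-base substitutions) are kept as a class but only
ever matched by exact allele — decomposing them into SNVs would fabricate
phase information the caller did not assert.

# The knowledge bundle

The bundle is a directory of headered TSVs plus a FASTA — transparent,
diffable, and trivially generatable — with a JSON manifest carrying a
version string and per-file row counts. Evidence items carry an A–E level,
one of four assertion types, and one of three key granularities: a full
allele key, a gene + protein-position (codon) key, or a gene symbol alone.
The literature-derived gene–cancer association score is consumed as a
bundle column, not computed; citation mining is out of scope. All
invariants (level domain, predictive-implies-drug, score ranges, signature
columns summing to one in canonical context order, allele refs agreeing
with the genome) are validated at load time with file and line in the error.

`generate_fixture_bundle()` emits a complete synthetic bundle:
a uniform-ACGT genome, non-overlapping transcript spans, evidence and
hotspot tables whose allele keys are genome-consistent by construction, and
Dirichlet-drawn signatures. It is byte-deterministic for a fixed seed. The
paired `simulate_somatic_vcf()` can place variants exactly on bundle
evidence alleles (a closure property the annotation tests rely on), on
hotspot codons, or on genome positions carrying a trinucleotide context
drawn from a chosen signature mixture.

What the generator does *not* emulate: realistic genome composition
(uniform base usage, no repeats or GC structure), linked multi-nucleotide
events, realistic transcript structure (one span per gene, no introns for
the CNA overlap), or correlated evidence across databases. Green tests
therefore demonstrate the correctness of the joins, the estimators and the
report plumbing under controlled conditions — not calibration against real
tumor cohorts.

# Annotation joins

Evidence matches are collected at all granularities and kept, with the
granularity recorded, so the tier rules can weight them: curated evidence is
heterogeneous in resolution and discarding gene-level assertions outright
would lose signal, while treating them as allele-level would overcall.
Codon-granularity matching goes through a total HGVSp parser (one- and
three-letter codes); indels never codon-match, because protein-position
semantics for frameshifts are ambiguous. Tumor-type concordance between the
sample and each evidence item is recorded but never filters — cancer-type
restriction changes tier content and belongs to the consumer of the report,
not the join.

Consensus pathogenicity over the per-algorithm calls is labelled
`damaging` when at least two algorithms report and at least two-thirds of
them call damaging, `unknown` with no algorithms, `tolerated` with zero
damaging calls, and `mixed` otherwise. The threshold and minimum are
configuration keys; no aggregation convention is standard across tools, so
the rule is explicit and overridable.

# Tier rules

The five-tier ladder follows AMP/ASCO-style practice: actionability first,
then tumorigenesis relevance, then unknown significance. The concrete gates
— levels A–B at exact-allele or codon granularity for Tier 1, levels C–E at
any granularity or a hotspot/driver overlap for Tier 2, protein-altering in
a flagged cancer gene for Tier 3 — are the package's own rendering and every
gate is a configuration key. Two consequences of reading the rules
literally are worth noting: a gene-granularity level-A/B match does *not*
reach Tier 1 or 2 (it lacks allele resolution, and level C–E is what the
Tier-2 evidence gate names), and a synonymous variant in an oncogene stays
in Tier 5 regardless of flags. Both behaviors are pinned by the golden
fixture.

Within tiers 1–2 variants sort by evidence level, then granularity; within
3–5 by descending literature score. The input index is the final tie-break,
making the ordering a total order that is stable under permutation of
distinct variants.

# Whole-profile measures

**Catalog.** SNVs are classified over the 96 contexts with purine
references reverse-complemented onto the pyrimidine strand. Variants at
position 1 or at a contig end are skipped (counted, not padded — padding
would invent sequence), and a disagreement between a variant's ref allele
and the genome base is a hard data-integrity error rather than a skip.

**Signature fit.** Non-negative least squares of the normalized catalog
against all reference signatures, then prune-and-refit: signatures below a
6% fraction are dropped and the NNLS repeated until stable, because
unconstrained refits spread multinomial noise over many near-zero
signatures. The 6% threshold and the 50-mutation low-confidence floor are
configuration keys. The per-fit residual is exposed, and the test suite
verifies the fit never loses to any single-signature least-squares solution
(a brute-force oracle), recovers a known 0.6/0.3/0.1 mixture from
2,000-mutation catalogs to within 0.05 mean absolute error, and reaches a
mean reconstruction cosine of at least 0.99 in that experiment.

**MSI.** The classifier is a logistic model on indel fraction, indels/Mb
and SNVs/Mb. The training distributions (MSI-high indel fraction
N(0.25, 0.05), MSS N(0.04, 0.02), total rates around 30/Mb and 5/Mb) encode
the defining biology — mismatch-repair deficiency elevates the indel load —
and make the classes nearly separable by construction. Two numerical
consequences: the glm emits a benign perfect-separation warning (suppressed
at the call site), and a *single* label-permuted control fit is unstable —
its decision boundary lands on an arbitrary side of the two tight feature
clusters, so its held-out accuracy is near 0, 0.5 or 1 rather than near 0.5.
The permutation control is therefore computed as the mean over 100 label
permutations, which concentrates at 0.5 for a signal-free model; this is the
standard permutation-test reading of such a control. Calls below 20 variants
are `undetermined`: rate features on a handful of calls are noise.

**TMB.** Mutations per megabase with a 36 Mb default denominator
(a typical exome's interrogated coding territory) and a numerator counting
protein-altering plus splice variants. Both are configuration keys; TMB
definitions vary across assays, so the report records the denominator it
used.

# Copy-number events

Segments are called gain at log2 ≥ 0.8 and loss at ≤ −0.8 (roughly
single-copy changes in a diploid, pure sample; purity and ploidy correction
is out of scope, and both thresholds are configuration keys). Called
segments intersect transcript spans through `GenomicRanges`; a brute-force
all-pairs scan serves as the test oracle, and the reported overlap fraction
(overlap bp over transcript length, 1 bp minimum) lets consumers impose
their own stringency. CNA events are reported in their own section rather
than forced into the SNV tier ladder, with gene-granularity evidence
attached.

# Reporting and determinism

The report payload is assembled once, with the tier-partition invariant
(tier counts sum to the PASS variant count) enforced as an internal guard,
and rendered to schema-versioned JSON, per-tier TSVs and a single
self-contained static HTML page. Interactivity frameworks are deliberately
absent — the interpretable content is the substance, not the widgets.
Outputs carry no wall-clock timestamps; together with seeded generators
this makes a rerun on identical inputs byte-identical, which the test suite
asserts end-to-end. Multi-element configuration values are serialized as
JSON arrays of scalars so that serialize–parse–serialize is byte-stable.

# Problem sizes used in the test suite

The suite runs entirely on generated data: a shared 100 kb / 20-gene
bundle, tumors of 20–200 variants, 50 random tumors for the tier partition
and monotonicity properties, 100 replicates of 2,000-mutation catalogs for
signature recovery, 1,000 segments × 500 transcripts for the interval
oracle, 10,000 random cases each for normalization idempotence and strand
collapse, and a 1,000-profile MSI cohort with 200 held-out draws. These
sizes make every property decisively testable while keeping a full run in
well under a minute on one core.

# Known limitations

The engine trusts the upstream consequence annotation and the bundle's
curation quality; it does not recompute effects, does not liftover, and
does not model tumor purity, subclonal structure, or paired-normal
genotypes. The synthetic generator's simplifications (above) mean
performance numbers from the test harness should not be quoted as expected
real-data performance. Indel signature classes and de-novo signature
extraction are out of scope; the fitter refits known signatures only.
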