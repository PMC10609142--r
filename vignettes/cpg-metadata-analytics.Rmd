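---
title: "Curating and summarising complete prokaryotic genome metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and summarising complete prokaryotic genome metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgmeta)
```

## The problem

Public prokaryote genome metadata arrives as one tab-delimited report
row per assembly, covering complete and draft genomes alike. Three
things stand between that file and the questions a comparative
microbiologist asks of *complete* genomes:

1. completeness is a free-text assembly level, not a flag;
2. the number of chromosomes and plasmids is buried in a single
   free-text `Replicons` field;
3. taxonomy is only a `TaxID`, so rank-based selection (e.g. "all
   complete bacterial genomes", "genus *Vibrio*") needs a lineage.

`cpgmeta` solves the three in one pass (`curate()`) and then provides
the descriptive layer: summaries, correlations, distribution tables,
prevalence percentages, and a chi-square independence test.

## The curation procedure and its assumptions

**Completeness.** A record is kept iff its status equals
`"Complete Genome"` after whitespace trimming, case-insensitively. The
source dialect's assembly-level vocabulary also contains `"Chromosome"`,
`"Scaffold"`, and `"Contig"`; none of these is complete. The selector is
a single documented constant, so a future change in the source
vocabulary is a one-line fix. Records lacking an FTP path are kept — the
path is provenance, not evidence of completeness.

**Replicon classification.** The field is split on `;`; each entry has
an optional `descriptor:accessions` shape with `/`-separated accessions.
The descriptor is lowercased and matched by substring rules: containing
`plasmid` anywhere → plasmid (this catches `megaplasmid` and
`plasmid pXO1`); otherwise starting with `chromosome` → chromosome (this
counts `chromosome 2` and chromosome-segment descriptors as
chromosomes); everything else → `other`, never silently dropped. The
source gives no grammar for this field, so substring rules over the
observed vocabulary are an assumption; the `other` bucket and the entry
table keep every classification auditable. Counting segment-style
descriptors as chromosomes is a deliberate choice — they begin with the
word, and a genome split across labelled chromosome segments is
multipartite for the prevalence questions the counts feed.

**Lineage.** Parent pointers are walked from the query taxid to the
root; the first node of each canonical rank (superkingdom, phylum,
class, order, family, genus, species) on the path fills that slot.
Unfilled slots get the visible sentinel `"unclassified"` rather than
`NA`, so distribution tables show the unresolved mass as a bucket. The
rank string `domain` — the newer NCBI name for the top prokaryote
rank — is accepted for the superkingdom slot. A taxid absent from the
dump (even via `merged.dmp`) leaves the record in the table with an
all-unclassified lineage and an entry in the curation log: dropping it
would silently change every denominator downstream.

**Schema.** The curated table has 18 columns: eleven feature/provenance
fields (name, taxid, size, GC%, raw replicons, chromosome and plasmid
counts, genes, proteins, release date, FTP path) plus the seven ranks.
Descriptions of this kind of table sometimes quote "17 metadata fields";
enumerating the documented fields yields 18, and this package fixes the
18-column schema rather than guess which pair was merged. Genome size
stays in Mb as published; no unit conversion.

## Statistical choices

* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile` type 7). No convention is universal; this one is
  pinned so `boxplot_stats()` is reproducible bit-for-bit.
* **Correlations** use pairwise-complete observations, so one feature
  with missing values does not shrink every pair's sample; the per-pair
  n matrix is returned alongside r to keep that auditable. Pairs with
  fewer than two complete cases or zero variance are `NA` (undefined),
  never silently 0.
* **Percentages** are rounded half-up (`floor(x·10^d + 0.5)/10^d`), the
  convention of reported prevalence figures; R's default half-even
  rounding would disagree on exact .5 boundaries.
* **Chi-square** on the 2×2 multichromosomal × plasmid-bearing table is
  Pearson's statistic with df = 1; the Yates continuity correction is
  exposed but off by default — at the sample sizes this table is built
  from (tens of thousands of genomes) the correction is immaterial, and
  the uncorrected statistic is the closed form tests verify against.
* **Filter semantics.** Clauses conjoin; numeric bounds are inclusive;
  a record missing a value for a filtered feature *fails* that clause.
  The alternative (letting missing pass) would make prevalence
  numerators and the visible filtered table disagree. Rank matching is
  case-insensitive and exact; a single rank selection mirrors the
  two-dropdown interaction the filter model comes from, and multi-value
  selection is an extension point, not implemented.
* **Distribution tables** sort by count descending, then taxon name
  ascending — a deterministic tie-break so `top_n` truncation is
  reproducible.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` emits a report in the exact input dialect, a
matched taxdump covering every taxid used, and a ground-truth manifest.
Its defaults are the package's standing picture of the complete-genome
collection:

| parameter | default | why |
|---|---|---|
| size distribution | lognormal, median 4.24 Mb, σ = 0.45 | observed median for complete bacterial genomes; σ chosen so the 0.11–16.04 Mb clamp (the observed extremes) is hit with negligible probability |
| GC% | truncated normal, mean 50.7, sd 8, bounds 13.5–75.6 | observed central value and extremes |
| chromosomes | P(1)=0.95, P(2)=0.04, P(3)=0.01 | ≈5% multichromosomal prevalence |
| plasmids | P(0)=0.56, rest over 1–3 | ≈44% plasmid-bearing prevalence |
| fraction complete | 0.4, allocated deterministically | exact complete counts (first ⌊f·n⌋ after a seeded shuffle), so the manifest is an oracle, not an estimate |
| taxonomy | 8 phyla / 30 genera / 90 species under Bacteria + Archaea | small enough to read, deep enough to exercise every rank path |
| years | 1995–2023 | the complete-genome era |
| adversarial fraction | 0.15 | replicon entries rendered with messy spellings ("Chromosome 2", "megaplasmid", descriptor-only plasmids, stray whitespace) that must still classify correctly |

Replicon strings are rendered *from* the ground-truth counts through the
same descriptor vocabulary the parser accepts, so parser recovery can be
checked exactly. Class, order, and family nodes are deliberately absent
from the generated taxonomy: their slots must come back
`"unclassified"`, which exercises the sentinel path that real dumps also
produce for incompletely ranked lineages.

The generator does **not** emulate phylogenetic structure in the
features: size, GC%, and replicon counts are drawn independently of the
lineage and of each other (genes and proteins are the exception — they
scale with size, as they do in real genomes). Passing tests therefore
demonstrate correctness of parsing, counting, joining, filtering, and
summarising; they do not demonstrate that real taxa differ in GC%, nor
can they reproduce snapshot-dependent values from any particular date's
live report (those require that day's file). On fixtures the
chromosome-multiplicity and plasmid traits are independent by
construction, so the chi-square p-value is typically large; that is the
correct behaviour of the test under its null, not a claim about real
genomes.

## Numerical and degenerate-input behaviour

* Lenient parsing is total: any text input yields records plus a parse
  log; only strict mode (meant for controlled fixtures) aborts on
  malformed cells. Rows with an unusable taxid are rejected (the curated
  invariant requires a positive taxid) and logged.
* Dates parse as `YYYY/MM/DD` or `YYYY-MM-DD`; anything else is missing
  plus a log entry.
* `boxplot_stats()` of a single value returns that value for all five
  summary positions; zero non-missing values is an error.
* `chi_square_2x2()` refuses tables with a zero marginal — the statistic
  is undefined there.
* Taxdump loading validates the tree: a dangling parent or a cycle
  aborts with the offending taxid, rather than hanging a later walk.
* CSV round-trips cannot distinguish an empty string from a missing
  character field; both read back as missing.

## Problem sizes

The test-suite scale is the package's own choice of demonstration size:
pipeline-versus-manifest equality is checked on fixtures up to 10,000
records, parameter recovery on 5,000 (size median within 5% of the
configured lognormal median; GC mean within 3·sd/√n of the configured
mean at a fixed seed), oracle equivalences on 100-leaf samples, and the
whole suite runs in well under a minute on one CPU. Real reports are a
few times larger than the largest fixture, and every step is linear in
the number of records.

## Limitations

* Replicon classification is vocabulary-based; a descriptor outside the
  observed dialect lands in `other` (visible, but uncounted as
  chromosome or plasmid).
* No deduplication of multiple assemblies per strain, no quality
  scoring, no name-based (reverse) taxonomy lookup, and no GTDB
  taxonomy.
* Only prokaryote-report columns are mapped; eukaryote/virus report
  dialects are out of scope.
* The statistics layer is deliberately descriptive: no confidence
  intervals, multiple-testing control, or regression modelling.
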