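---
title: "The pgannotate annotation engine: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pgannotate annotation engine: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgannotate)
```

## The annotation problem

A gene predictor run on a eukaryotic genome emits thousands of protein
sequences of three very different kinds: proteins whose function can be
confidently borrowed from a well-characterized homolog, proteins that are
clearly real but whose homologs are themselves undescribed, and predictions
that may not correspond to a real gene at all. `pgannotate` separates these
three classes from similarity-search output, then uses two orthogonal lines
of experimental evidence — transcript abundance and peptide-spectrum
matches — to say which calls are supported by data rather than by database
content alone.

The engine deliberately does *not* run the upstream tools. Similarity
searches, domain scans, RNA-seq quantification and spectral searches are
mature, heavily optimized programs; `pgannotate` consumes their standard
tabular outputs and owns only the decision layer. `adapter_commands()`
renders ready-to-run command lines with the configured parameters for users
who need them.

## The decision procedure

Per query protein, per database, each hit is tested against four inclusive
cutoffs: e-value at most `evalue_cutoff`, and query coverage, identity and
positivity at least their respective minima. Inclusive comparison is a
design choice: the cutoffs are documented as *minimum thresholds*, and a
hit sitting exactly on a published threshold should not silently fail it.
Coverage is computed on the query (`100 * alignment_length /
query_length`, clamped to 100): annotation is transferred *to* the query,
so it is the query that must be substantially covered; alignment columns
can exceed the query length when gaps are counted, hence the clamp.
Positivity is taken from the search tool's positive-substitution column,
never recomputed — the engine has no alignments.

Hits passing the thresholds are then split by the keyword filter: a
description containing any configured keyword as a case-insensitive
substring (databases mix "Uncharacterized" and "uncharacterized") is
uninformative and is disregarded *per hit*, not per query — a query with
one keyworded and one clean passing hit is annotated from the clean one.
This per-hit reading is a deliberate resolution of an ambiguity in the
informal rule "disregard annotations if a description contains a keyword":
the alternative (discarding the whole query) would throw away perfectly
transferable annotations whenever a single uninformative homolog appears,
which contradicts the purpose of the filter.

Among surviving hits the highest bitscore wins. Bitscore ties are broken by
lower e-value, then higher identity, then input order; only the first
criterion is part of the published procedure, the rest make the decision a
deterministic total order (the property suite checks order-invariance
whenever bitscores are distinct).

The two database stages are merged with curated priority: if the curated
stage annotates, its description and source are kept regardless of the
specific stage. This matches the published per-protein single-source
accounting ("annotated by curated" and "annotated by specific" partition
the annotated set). A stage whose passing hits were all keyworded
contributes "hypothetical", which dominates "no hit" in the merge:
similarity evidence exists even though no name is transferable. Merged
hypothetical decisions carry `source_db = "none"` — no annotation was
transferred, so no database is credited.

## Functional terms and routing

GO and InterPro ids from the whole-proteome scan TSV are attached to every
protein as deduplicated, lexicographically sorted sets (sorted so that
serialized outputs are byte-stable). The deeper profile-HMM and reverse
PSI-BLAST scans are routed exclusively to the hypothetical/no-hit group;
rows for annotated proteins present in those files are ignored rather than
rejected, because the routing rule belongs in the engine, not in the file
producer. Hypothetical descriptions are *not* renamed from domain evidence:
the description stays "hypothetical protein" and the terms ride along in
headers and the TSV, supporting manual curation without overstating what a
domain hit proves.

On scan-TSV strictness: the standard scan TSV legally omits trailing
columns when a signature is not integrated, so rows with at least 11
columns are accepted (columns 12–14 optional, `-` treated as absent) and
only shorter rows are line-numbered parse errors.

## Evidence integration

**Transcript evidence.** The threshold is derived from the quantification
itself: the arithmetic mean TPM over *all* quantified targets, zeros
included. Zeros are included because excluding them would raise the
threshold on sparsely transcribed datasets in a way that depends on the
zero fraction, which is exactly the artifact signal being tested. A target
has evidence when its TPM reaches the mean (inclusive) *and* is strictly
positive; the positivity guard exists for the degenerate all-zero
quantification, where the mean is 0 and everything would otherwise be
flagged. Evidence is decided once per protein per run over the
concatenated experiment set, not per experiment.

**Peptide evidence.** PSM-level: at least one PSM at q-value at or below
`psm_qvalue_cutoff` (default 0.05). Shared peptides credit every mapped
protein — protein-level FDR control is out of scope, and the count and
minimum q-value are reported so users can apply stricter rules downstream.

**Categories.** The cross of (hypothetic annotation, transcript evidence,
peptide evidence) gives 8 categories; the mapping is fixed (see
`assign_category()`). Categories are assigned to *all* classified proteins:
no-hit proteins are grouped with hypothetical for the hypothetic flag, as
the two groups are processed together downstream. True negatives are the
no-hit proteins with neither kind of evidence.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `evalue_cutoff` | 1e-5 | – | maximum similarity-hit e-value |
| `min_coverage_pct` | 30 | % of query | minimum query coverage |
| `min_identity_pct` | 40 | % | minimum identity |
| `min_positivity_pct` | 60 | % | minimum positivity |
| `keywords` | 6 terms | – | uninformative-description markers |
| `hmm_evalue`, `rps_evalue` | 1e-5 | – | domain-scan cutoffs (hmm: both sequence and domain e-value) |
| `tpm_threshold_mode` | mean | – | transcript-evidence threshold rule |
| `psm_qvalue_cutoff` | 0.05 | – | peptide-evidence FDR level |
| `threads`, `max_target_seqs` | 4, 10 | – | recorded for adapter command lines only |

Raising any similarity threshold can only shrink the annotated set
(monotonicity, tested); the keyword list is a free parameter and the one
most worth tuning per database, since database-specific boilerplate
("putative", "predicted protein") is not in the default six.

## The synthetic cohort generator

`generate_cohort()` writes a complete input set with planted truth: exact
status proportions (largest-remainder apportionment, so a 70/20/10 mix at
n = 100 is exactly 70/20/10), planted source databases, keyworded decoys
that sometimes outscore the intended clean hit (exercising the disregard
rule), sub-threshold noise hits for no-hit proteins, and planted evidence.
Transcript evidence is planted constructively: flagged proteins share TPM
150 while unflagged ones get 0 or values below `50 * n_flagged / n`, which
provably brackets the dataset mean between the groups for every feasible
mix, so recovery is exact by construction rather than with high
probability. Sequences are random residues and hit metrics are written
directly into the tables: the engine never re-aligns, so
sequence/metric consistency is not required.

What the generator does *not* emulate: real homology structure (hit metrics
are independent draws, not correlated families), multi-exon gene models
(one CDS per mRNA), noisy or adversarial tool output (truncated files,
inconsistent ids), protein inference ambiguity beyond simple shared
peptides, and realistic TPM distributions. Passing the recovery suite
therefore shows the decision logic is implemented exactly as specified, not
that the thresholds are well calibrated for any particular organism.

`table2_cohort()` is different in kind: a flags-only cohort of 19,651
proteins reproducing the published evidence-category histogram and status
marginals of a reannotated *Arabidopsis thaliana* proteome, used to
exercise the summary arithmetic at full printed scale.

## Numerical and formatting choices

* Percentages are rounded half away from zero to 2 decimals (1 where the
  published value prints 1), via `round_half_up()`; base `round()` rounds
  half to even and reproduces several published table entries incorrectly.
  A 1e-9 epsilon absorbs representation error in `x * 100`.
* Header fields are joined with `" | "`; GO then InterPro ids are appended
  as additional pipe-delimited fields, sorted. Without a structural GFF3
  the scaffold/coordinate/strand fields are absent (simplified mode).
* GFF3 rewriting is line-level text editing: matched `mRNA`/`transcript`
  features (by `ID`) and `CDS` features (by `Parent`), after stripping
  `.t1`-style suffixes from both sides, get `product=` added or replaced
  with percent-encoded text (`;`, `=`, `&`, `,`, `%`); every other byte of
  the file is preserved, which a parse/serialize round trip would not
  guarantee.
* The TSV column order is fixed and documented (13 columns) so reruns are
  byte-identical and diffable.
* Tie-breaks, inclusive thresholds and sorted term sets together make the
  whole pipeline deterministic: same inputs, same bytes out.

## Problem sizes in the test suite

The recovery suite runs five 1,000-protein cohorts; the brute-force
reference comparison runs 10,000 random hit sets of up to 6 hits (covering
every pass/keyword/tie combination with margin); property tests use
cohorts of 100–300. These sizes give exhaustive-feeling coverage of the
decision space while keeping the suite fast enough to run on every change.

## Known limitations

* The engine trusts the search tool's columns; corrupt metrics (e.g.
  identity above 100) are not sanity-checked beyond parse validation.
* Coverage is query-side only; subject coverage is not available in the
  consumed column set.
* GO terms are attached as given, without ontology-ancestry expansion.
* Gene prediction itself is out of scope: a genome-first workflow enters
  the engine as a precomputed protein FASTA + GFF3 pair.
* `tpm_threshold_mode` currently admits only the dataset mean; the field
  is an enum so that percentile-style rules can be added without breaking
  configurations.
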