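# pgannotate

Functional annotation of predicted proteomes with proteogenomic validation.

Automated genome annotation transfers each predicted protein's function from
its best similarity hit in a reference database, but a large fraction of
database entries carry uninformative descriptions ("hypothetical protein",
"uncharacterized", ...), and gene predictors emit artifacts that have no
database support at all. `pgannotate` is the decision engine for this
problem: given per-protein similarity-search results against a **curated**
database and a **user-specified** database, domain-scan results, transcript
quantification (RNA-seq) and peptide-spectrum matches (MS/MS), it decides
each protein's annotation, attaches functional terms, validates the calls
with experimental evidence, and writes the annotated outputs. It is aimed at
groups annotating or reannotating eukaryotic genomes who already run the
standard search tools and want a reproducible, testable decision layer.

## The decision model

For each query protein *q* with hits *h*:

1. **Threshold filter.** A hit may transfer annotation only if
   `E(h) <= 1e-5`, `cov(h) >= 30%`, `id(h) >= 40%` and `pos(h) >= 60%`
   (all configurable; coverage is query coverage,
   `100 * alignment_length / query_length`).
2. **Keyword disregard.** Hits whose description contains any keyword from
   {fragment, hypothetical, partial, uncharacterized, unknown, unspecified}
   (case-insensitive substring) are disregarded for transfer.
3. **Transfer.** Among surviving hits, the highest bitscore wins (ties:
   lower e-value, then higher identity, then input order); *q* is
   **annotated** with that description. If hits passed the thresholds but
   all were keyworded, *q* is **hypothetical**; with no passing hit in
   either database, *q* is **no-hit**. The curated database has priority:
   its transfer is kept whenever it annotates, so each annotated protein is
   credited to exactly one source.
4. **Functional terms.** GO and InterPro ids from a whole-proteome domain
   scan are attached to every protein; the hypothetical/no-hit group
   additionally receives profile-HMM and reverse PSI-BLAST domain hits
   (both filtered at e <= 1e-5) to support manual curation.
5. **Evidence.** Transcript evidence: TPM at or above the dataset mean (and
   > 0). Peptide evidence: at least one PSM with q-value <= 0.05 (shared
   peptides credit every mapped protein). The cross of (hypothetic
   annotation, transcript evidence, peptide evidence) places every protein
   in one of 8 categories; no-hit proteins with neither kind of evidence are
   flagged **true negatives** (candidate prediction artifacts).

## Worked example

The fixture generator writes a complete synthetic input set (protein/CDS
FASTA, structural GFF3, two hit tables, three scan tables, abundance and PSM
tables) with known planted truth:

```r
library(pgannotate)
fx  <- generate_cohort(100, seed = 7, outdir = "fixtures")
run <- run_pipeline(fx$config, "protein_plus_gff", outdir = "out")
print(run)
```

```
Annotation run 'cohort'

Predicted proteins               100
Annotated proteins               70 (70.00%)
  by curated database            49 (70.00%)  of annotated
  by specific database           21 (30.00%)  of annotated
Hypothetical proteins            20
No-hit proteins (true negative) 10 (4)
Total hypothetical               30 (30.00%)
With >=1 IPR term                90 (90.00%)
With >=1 GO term                 78 (78.00%)
With transcript evidence         35 (35.00%)
With peptide evidence            25 (25.00%)
```

70 proteins received a transferred description (49 from the curated
database, 21 from the specific one), 20 matched only uninformative database
entries, and 10 had no passing hit — 4 of those also lack transcript and
peptide evidence and are flagged as likely prediction artifacts. The run
directory contains `cohort_pgannotate_proteins.fasta` and `_cds.fasta`
(pipe-delimited annotated headers with GO/IPR terms),
`_annotations.gff3` (input GFF3 with `product=` set to the final
description on matched features), `_annotations.txt` (id/description
pairs), `_summary.tsv` (13 columns: status, source, terms, TPM, PSM counts,
category, true-negative flag) and a run log. `run$records` holds the same
table in R, `run$classification` the 8-category breakdown.

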