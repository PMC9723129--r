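full_record <- function() {
  list(protein_id = "p1", organism = "Toyus examplus",
       description = "Protein kinase ABC", scaffold = "scaffold_3",
       cds_start = 1200, cds_end = 2150, strand = "+",
       go_ids = "GO:0004672", ipr_ids = "IPR000719")
}

test_that("FASTA headers are pipe-delimited with terms appended", {
  expect_equal(
    build_fasta_header(full_record()),
    "p1 | Toyus examplus | scaffold_3 | 1200 | 2150 | + | Protein kinase ABC | GO:0004672 | IPR000719")
  # simplified mode without coordinates
  rec <- full_record()
  rec[c("scaffold", "cds_start", "cds_end", "strand")] <- NULL
  rec$go_ids <- character(0); rec$ipr_ids <- character(0)
  expect_equal(build_fasta_header(rec),
               "p1 | Toyus examplus | Protein kinase ABC")
  # hypothetical record, no terms
  rec$description <- "hypothetical protein"
  expect_equal(build_fasta_header(rec),
               "p1 | Toyus examplus | hypothetical protein")
  # partial coordinates violate the contract
  bad <- full_record(); bad$strand <- NA
  expect_error(build_fasta_header(bad), "all present or all absent")
})

test_that("GFF rewriting sets product on matched features only", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t100\t900\t.\t+\t0\tID=g1.t1.cds;Parent=g1.t1;product=old",
    "chr1\tsrc\tmRNA\t1000\t1900\t.\t-\t.\tID=g2.t1;Parent=g2"
  ), gff)
  out <- withr::local_tempfile(fileext = ".gff3")
  expect_warning(
    rewrite_gff(gff, c("g1.t1" = "Protein kinase; ABC", "missing.t1" = "X"), out),
    "no matching")
  lines <- readLines(out)
  # description percent-encoded on the mRNA and replacing old product on CDS
  expect_match(lines[3], "product=Protein kinase%3B ABC", fixed = TRUE)
  expect_match(lines[4], "product=Protein kinase%3B ABC", fixed = TRUE)
  expect_false(grepl("product=old", lines[4], fixed = TRUE))
  # unmatched feature and non-feature lines byte-identical
  expect_identical(lines[c(1, 2, 5)], readLines(gff)[c(1, 2, 5)])
})

test_that("output files carry the basename convention and round-trip", {
  fx <- generate_cohort(30, seed = 3, outdir = withr::local_tempdir())
  outdir <- withr::local_tempdir()
  run <- suppressWarnings(run_pipeline(fx$config, "protein_plus_gff", outdir))
  expect_true(all(file.exists(run$outputs)))
  expect_match(basename(run$outputs[["proteins"]]),
               "^cohort_pgannotate_proteins\\.fasta$")
  tsv <- read.delim(run$outputs[["tsv"]], stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), 30)
  expect_equal(names(tsv),
               c("protein_id", "status", "source_db", "description", "go_ids",
                 "ipr_ids", "tpm", "transcript_evidence", "psm_count",
                 "min_qvalue", "peptide_evidence", "category", "true_negative"))
  # TSV reconstructs the per-protein fields (lossless for serialized columns)
  expect_equal(tsv$status, run$records$status)
  expect_equal(tsv$category, run$records$category)
  expect_equal(tsv$go_ids[match(fx$truth$protein_id, tsv$protein_id)],
               fx$truth$go_ids)
  # TXT: two columns, id TAB description
  txt <- read.delim(run$outputs[["txt"]], header = FALSE)
  expect_equal(nrow(txt), 30)
  expect_equal(txt$V2, run$records$description)
  # FASTA headers re-parse to the same ids and descriptions
  fa <- Biostrings::readAAStringSet(run$outputs[["proteins"]])
  hdr <- strsplit(names(fa), " | ", fixed = TRUE)
  expect_equal(vapply(hdr, `[[`, "", 1), run$records$protein_id)
  ann <- which(run$records$status == "annotated")
  expect_equal(vapply(hdr[ann], `[[`, "", 7), run$records$description[ann])
  # rerun is byte-identical
  outdir2 <- withr::local_tempdir()
  run2 <- suppressWarnings(run_pipeline(fx$config, "protein_plus_gff", outdir2))
  for (k in setdiff(names(run$outputs), "log")) {
    expect_identical(readLines(run$outputs[[k]]), readLines(run2$outputs[[k]]),
                     label = k)
  }
})

test_that("protein-only mode writes simplified headers and no GFF", {
  fx <- generate_cohort(10, seed = 9, outdir = withr::local_tempdir(),
                        with_gff = FALSE)
  run <- suppressWarnings(run_pipeline(fx$config, "protein_only",
                                       withr::local_tempdir()))
  expect_false("gff" %in% names(run$outputs))
  fa <- Biostrings::readAAStringSet(run$outputs[["proteins"]])
  # simplified: id | organism | description (+ optional terms), no coordinates
  expect_false(any(grepl(" | scaffold_", names(fa), fixed = TRUE)))
  ann <- which(run$records$status == "annotated")
  hdr <- strsplit(names(fa)[ann], " | ", fixed = TRUE)
  expect_equal(vapply(hdr, `[[`, "", 3), run$records$description[ann])
})

test_that("classification tables reproduce printed-style percentages", {
  # uniform and degenerate cases
  ct <- classification_table(rep(1:8, each = 10))
  expect_equal(ct$percentage, rep(12.5, 8))
  expect_equal(sum(ct$count), attr(ct, "total"))
  ct1 <- classification_table(rep(4, 17))
  expect_equal(ct1$percentage[4], 100)
  expect_equal(sum(ct1$percentage), 100)
  expect_error(classification_table(integer(0)), "empty")
})

test_that("summary statistics respect their identities on fixtures", {
  fx <- generate_cohort(200, seed = 13, outdir = withr::local_tempdir())
  run <- suppressWarnings(run_pipeline(fx$config, "protein_plus_gff",
                                       withr::local_tempdir()))
  s <- run$stats
  expect_equal(s$n_annotated, s$n_by_curated + s$n_by_specific)
  expect_equal(s$n_predicted, s$n_annotated + s$n_hypothetical + s$n_no_hit)
  expect_lte(s$n_true_negative, s$n_no_hit)
  expect_equal(s$n_total_hypothetical, s$n_hypothetical + s$n_no_hit)
  expect_error(summary_stats(run$records[0, ]), "zero")
})

test_that("reduction percentages follow the reference-relative formula", {
  expect_equal(reduction_stat(2411, 217, digits = 1), 91.0)
  expect_equal(reduction_stat(2308, 28, digits = 2), 98.79)
  expect_equal(reduction_stat(100, 100), 0)
  expect_equal(reduction_stat(100, 150), -50)
  expect_error(reduction_stat(0, 10), "positive")
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(0.025, 2), 0.03)
  expect_equal(round_half_up(0.035, 2), 0.04)
  expect_equal(round_half_up(-0.025, 2), -0.03)
  expect_equal(round_half_up(12.345, 2), 12.35)
  expect_equal(round_half_up(91.0037, 1), 91.0)
})
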