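test_that("generation is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx1 <- generate_cohort(50, seed = 7, outdir = d1)
  fx2 <- generate_cohort(50, seed = 7, outdir = d2)
  expect_equal(fx1$truth, fx2$truth)
  for (k in names(fx1$files)) {
    expect_identical(readLines(fx1$files[[k]]), readLines(fx2$files[[k]]),
                     label = k)
  }
  fx3 <- generate_cohort(50, seed = 8, outdir = withr::local_tempdir())
  expect_false(identical(fx1$truth$status, fx3$truth$status) &&
                 identical(readLines(fx1$files[["blast_curated"]]),
                           readLines(fx3$files[["blast_curated"]])))
})

test_that("status proportions are realized exactly", {
  fx <- generate_cohort(100, status_mix = c(annotated = 0.7,
                                            hypothetical = 0.2, no_hit = 0.1),
                        seed = 7, outdir = withr::local_tempdir())
  expect_equal(as.integer(table(factor(fx$truth$status,
                                       c("annotated", "hypothetical", "no_hit")))),
               c(70L, 20L, 10L))
})

test_that("planted categories are consistent with planted flags", {
  fx <- generate_cohort(80, seed = 21, outdir = withr::local_tempdir())
  tr <- fx$truth
  expect_equal(tr$category,
               assign_category(tr$status != "annotated",
                               tr$transcript_evidence, tr$peptide_evidence))
  expect_true(all(tr$true_negative ==
                    (tr$status == "no_hit" & !tr$transcript_evidence &
                       !tr$peptide_evidence)))
})

test_that("a one-protein cohort with no evidence lands in category 2", {
  fx <- generate_cohort(1, status_mix = c(annotated = 1, hypothetical = 0,
                                          no_hit = 0),
                        evidence_mix = c(none = 1, transcript = 0,
                                         peptide = 0, both = 0),
                        seed = 4, outdir = withr::local_tempdir())
  expect_equal(fx$truth$category, 2L)
  run <- suppressWarnings(run_pipeline(fx$config, "protein_plus_gff",
                                       withr::local_tempdir()))
  expect_equal(run$records$category, 2L)
})

test_that("the engine recovers planted truth end to end", {
  fx <- generate_cohort(120, seed = 31, outdir = withr::local_tempdir())
  run <- suppressWarnings(run_pipeline(fx$config, "protein_plus_gff",
                                       withr::local_tempdir()))
  rec <- run$records[match(fx$truth$protein_id, run$records$protein_id), ]
  expect_equal(rec$status, fx$truth$status)
  expect_equal(rec$source_db, fx$truth$source_db)
  expect_equal(rec$description, fx$truth$description)
  expect_equal(rec$transcript_evidence, fx$truth$transcript_evidence)
  expect_equal(rec$peptide_evidence, fx$truth$peptide_evidence)
  expect_equal(rec$category, fx$truth$category)
  expect_equal(rec$true_negative, fx$truth$true_negative)
  # planted GO/IPR sets recovered through term attachment
  got_go <- vapply(fx$truth$protein_id,
                   function(id) paste(run$terms[[id]]$go_ids, collapse = ";"), "")
  expect_equal(unname(got_go), fx$truth$go_ids)
})

test_that("perturbing a planted hit's identity to cutoff - eps flips its protein", {
  fx <- generate_cohort(20, status_mix = c(annotated = 1, hypothetical = 0,
                                           no_hit = 0),
                        seed = 17, outdir = withr::local_tempdir())
  cfg <- fx$config
  cur <- parse_blast_table(fx$files[["blast_curated"]], "curated")
  spe <- parse_blast_table(fx$files[["blast_specific"]], "specific")
  # pick a curated-annotated protein and push all its hits below the
  # identity cutoff in both databases
  victim <- fx$truth$protein_id[fx$truth$source_db == "curated"][1]
  for (df_name in c("cur", "spe")) {
    df <- get(df_name)
    sel <- df$query_id == victim
    df$identity_pct[sel] <- cfg$min_identity_pct - 0.1
    assign(df_name, df)
  }
  expect_false(any(hit_passes_thresholds(cur[cur$query_id == victim, ], cfg)))
  res <- classify_proteome(cur, spe, fx$truth$protein_id, cfg)
  expect_equal(res$status[res$protein_id == victim], "no_hit")
  # everyone else keeps their planted status
  others <- res$protein_id != victim
  expect_equal(res$status[others], fx$truth$status[match(res$protein_id, fx$truth$protein_id)][others])
})

test_that("the printed-scale reference cohort matches its published marginals", {
  t2 <- table2_cohort()
  expect_equal(nrow(t2), 19651)
  expect_equal(as.integer(table(t2$category)),
               c(203L, 15417L, 5L, 7L, 2480L, 796L, 2L, 741L))
  expect_equal(sum(t2$status == "annotated"), 19434)
  expect_equal(sum(t2$source_db == "curated"), 13444)
  expect_equal(sum(t2$source_db == "specific"), 5990)
  expect_equal(sum(t2$status == "hypothetical"), 169)
  expect_equal(sum(t2$status == "no_hit"), 48)
  expect_equal(sum(t2$true_negative), 45)
  expect_equal(sum(t2$transcript_evidence), 3228)  # categories 3+5+7+8
  expect_equal(sum(t2$peptide_evidence), 1546)     # categories 4+6+7+8
  # flags consistent with categories
  expect_equal(t2$category,
               assign_category(t2$hypothetic, t2$transcript_evidence,
                               t2$peptide_evidence))
})

test_that("infeasible mixes are rejected", {
  expect_error(generate_cohort(10, status_mix = c(annotated = 0.5,
                                                  hypothetical = 0.2,
                                                  no_hit = 0.2),
                               outdir = withr::local_tempdir()),
               "sum to 1")
  expect_error(generate_cohort(0, outdir = withr::local_tempdir()))
})
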