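test_that("hit tables parse with derived coverage and preserved order", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "p1\tsp|Q9X|ABC\t45.0\t62.0\t120\t150\t1e-20\t250\tProtein kinase ABC",
    "p1\tsp|Q8Y|DEF\t50.0\t70.0\t300\t150\t1e-30\t300\tHelicase DEF"
  ), p)
  hits <- parse_blast_table(p, "curated")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$coverage_pct[1], 80)   # 100 * 120 / 150
  expect_equal(hits$coverage_pct[2], 100)  # clamped
  expect_equal(hits$identity_pct[1], 45)
  expect_equal(hits$positivity_pct[1], 62)
  expect_equal(hits$description[2], "Helicase DEF")
  expect_equal(unique(hits$database_tag), "curated")
})

test_that("empty and malformed hit tables are handled per contract", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), p)
  expect_equal(nrow(parse_blast_table(p, "curated")), 0)
  writeLines("p1\ts1\t45.0\t62.0\t120\t150\t1e-20\t250", p)  # 8 fields
  expect_error(parse_blast_table(p, "curated"), "line 1")
  writeLines("p1\ts1\tforty\t62.0\t120\t150\t1e-20\t250\tdesc", p)
  expect_error(parse_blast_table(p, "curated"), "non-numeric")
})

test_that("threshold filter is a conjunction of four inclusive cutoffs", {
  cfg <- default_config()
  mk <- function(id, pos, len, qlen, e) {
    h <- data.frame(query_id = "q", subject_id = "s", identity_pct = id,
                    positivity_pct = pos, alignment_length = len,
                    query_length = qlen, evalue = e, bitscore = 100,
                    description = "d", database_tag = "curated")
    h$coverage_pct <- pmin(100, 100 * len / qlen)
    h
  }
  expect_true(hit_passes_thresholds(mk(45, 62, 120, 150, 1e-20), cfg))
  expect_false(hit_passes_thresholds(mk(39.9, 62, 120, 150, 1e-20), cfg))
  expect_false(hit_passes_thresholds(mk(45, 59.9, 120, 150, 1e-20), cfg))
  expect_false(hit_passes_thresholds(mk(45, 62, 40, 150, 1e-20), cfg))
  expect_false(hit_passes_thresholds(mk(45, 62, 120, 150, 1e-4), cfg))
  # exact boundary passes on all four
  expect_true(hit_passes_thresholds(mk(40, 60, 45, 150, 1e-5), cfg))
})

test_that("keyword matching is a case-insensitive substring test", {
  kw <- default_keywords()
  expect_true(description_is_keyworded("hypothetical protein, conserved", kw))
  expect_false(description_is_keyworded("Protein kinase ABC", kw))
  expect_true(description_is_keyworded("Uncharacterized protein YJL222W", kw))
  expect_true(description_is_keyworded("PREDICTED PROTEIN FRAGMENT", kw))
  expect_equal(description_is_keyworded(c("unknown", "kinase"), kw),
               c(TRUE, FALSE))
})

test_that("decision logic: keyword disregard, bitscore choice, tie-breaks", {
  cfg <- default_config()
  base <- random_hits(2)
  base$identity_pct <- c(80, 75)
  base$positivity_pct <- c(90, 85)
  base$alignment_length <- base$query_length
  base$coverage_pct <- c(100, 100)
  base$evalue <- c(1e-30, 1e-25)
  # keyworded hit outscores the clean one: clean hit still wins
  base$bitscore <- c(300, 250)
  base$description <- c("uncharacterized protein", "Protein kinase ABC")
  d <- decide_from_hits(base, cfg)
  expect_equal(d$status, "annotated")
  expect_equal(d$description, "Protein kinase ABC")
  # all keyworded but passing: hypothetical
  base$description <- c("uncharacterized protein", "unknown protein")
  d <- decide_from_hits(base, cfg)
  expect_equal(d$status, "hypothetical")
  expect_equal(d$description, "hypothetical protein")
  expect_null(d$winning_hit)
  # empty hit set: stage no_hit
  expect_equal(decide_from_hits(base[0, ], cfg)$status, "no_hit")
  # bitscore tie broken by lower e-value
  base$description <- c("A", "B")
  base$bitscore <- c(250, 250)
  base$evalue <- c(1e-30, 1e-10)
  expect_equal(decide_from_hits(base, cfg)$description, "A")
  # then by higher identity
  base$evalue <- c(1e-10, 1e-10)
  base$identity_pct <- c(70, 80)
  expect_equal(decide_from_hits(base, cfg)$description, "B")
  # mixed queries violate the contract
  bad <- base
  bad$query_id <- c("q1", "q2")
  expect_error(decide_from_hits(bad, cfg), "single query")
})

test_that("database merge gives the curated stage priority", {
  ann_cur <- decide_from_hits(
    local({h <- random_hits(1); h$identity_pct <- 80; h$positivity_pct <- 90
           h$evalue <- 1e-20; h$coverage_pct <- 100
           h$alignment_length <- h$query_length
           h$description <- "Curated kinase"; h}), default_config())
  ann_spe <- decide_from_hits(
    local({h <- random_hits(1, db = "specific"); h$identity_pct <- 80
           h$positivity_pct <- 90; h$evalue <- 1e-20; h$coverage_pct <- 100
           h$alignment_length <- h$query_length
           h$description <- "Specific kinase"; h}), default_config())
  hyp <- structure(list(status = "hypothetical",
                        description = "hypothetical protein",
                        source_db = "none", winning_hit = NULL),
                   class = "annotation_decision")
  none <- structure(list(status = "no_hit", description = "",
                         source_db = "none", winning_hit = NULL),
                    class = "annotation_decision")
  expect_equal(merge_database_stages(ann_cur, ann_spe)$source_db, "curated")
  expect_equal(merge_database_stages(ann_cur, ann_spe)$description, "Curated kinase")
  expect_equal(merge_database_stages(hyp, ann_spe)$source_db, "specific")
  expect_equal(merge_database_stages(none, ann_spe)$status, "annotated")
  expect_equal(merge_database_stages(hyp, none)$status, "hypothetical")
  expect_equal(merge_database_stages(none, hyp)$status, "hypothetical")
  expect_equal(merge_database_stages(none, none)$status, "no_hit")
})

test_that("proteome classification partitions every input protein", {
  cfg <- default_config()
  cur <- random_hits(3, query = "p1")
  cur$identity_pct <- 80; cur$positivity_pct <- 90; cur$evalue <- 1e-20
  cur$alignment_length <- cur$query_length; cur$coverage_pct <- 100
  cur$description <- c("Kinase", "hypothetical protein", "Helicase")
  hyp_hits <- random_hits(1, query = "p2")
  hyp_hits$identity_pct <- 70; hyp_hits$positivity_pct <- 85
  hyp_hits$evalue <- 1e-15; hyp_hits$coverage_pct <- 100
  hyp_hits$alignment_length <- hyp_hits$query_length
  hyp_hits$description <- "unknown protein"
  res <- classify_proteome(cur, hyp_hits, c("p1", "p2", "p3"), cfg)
  expect_setequal(res$protein_id, c("p1", "p2", "p3"))
  expect_equal(res$status[match(c("p1", "p2", "p3"), res$protein_id)],
               c("annotated", "hypothetical", "no_hit"))
  expect_equal(sum(table(res$status)), 3)
  # hits for an unknown query warn but classify
  expect_warning(res2 <- classify_proteome(cur, hyp_hits, c("p1", "p3"), cfg),
                 "absent from the proteome")
  expect_true("p2" %in% res2$protein_id)
})

test_that("decisions are invariant under hit order with distinct bitscores", {
  set.seed(11)
  cfg <- default_config()
  for (rep in 1:20) {
    hits <- random_hits(sample(2:6, 1))
    hits$bitscore <- sample(seq(100, 400, by = 10), nrow(hits))
    d1 <- decide_from_hits(hits, cfg)
    perm <- hits[sample(nrow(hits)), , drop = FALSE]
    d2 <- decide_from_hits(perm, cfg)
    expect_equal(d1$status, d2$status)
    expect_equal(d1$description, d2$description)
  }
})

test_that("raising any threshold never increases the annotated count", {
  set.seed(23)
  base_cfg <- default_config()
  queries <- sprintf("q%d", 1:40)
  hits <- do.call(rbind, lapply(queries, function(q) random_hits(sample(1:5, 1), query = q)))
  class(hits) <- c("blast_hits", "data.frame")
  none <- hits[0, ]
  count_annotated <- function(cfg) {
    sum(classify_proteome(hits, none, queries, cfg)$status == "annotated")
  }
  base_n <- count_annotated(base_cfg)
  for (key in c("min_coverage_pct", "min_identity_pct", "min_positivity_pct")) {
    for (delta in c(10, 30)) {
      cfg <- base_cfg
      cfg[[key]] <- min(100, cfg[[key]] + delta)
      expect_lte(count_annotated(cfg), base_n)
    }
  }
  cfg <- base_cfg
  cfg$evalue_cutoff <- 1e-20  # stricter
  expect_lte(count_annotated(cfg), base_n)
})
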