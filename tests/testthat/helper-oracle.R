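# Independent reference implementations and small fixture builders used
# across the test files. The oracle deliberately shares no code with the
# engine: plain loops, no vectorization, no reuse of package predicates.

# Exhaustive filter-then-argmax reference for a single query's hits.
oracle_decide <- function(hits, config) {
  survivors <- list()
  saw_passing <- FALSE
  for (i in seq_len(nrow(hits))) {
    h <- as.list(hits[i, ])
    cov <- 100 * h$alignment_length / h$query_length
    if (cov > 100) cov <- 100
    passes <- h$evalue <= config$evalue_cutoff &&
      cov >= config$min_coverage_pct &&
      h$identity_pct >= config$min_identity_pct &&
      h$positivity_pct >= config$min_positivity_pct
    if (!passes) next
    saw_passing <- TRUE
    keyworded <- FALSE
    for (kw in config$keywords) {
      if (length(grep(kw, tolower(h$description), fixed = TRUE)) > 0) {
        keyworded <- TRUE
        break
      }
    }
    if (!keyworded) survivors[[length(survivors) + 1]] <- c(h, list(.row = i))
  }
  if (length(survivors) > 0) {
    best <- survivors[[1]]
    for (s in survivors[-1]) {
      if (s$bitscore > best$bitscore ||
          (s$bitscore == best$bitscore && s$evalue < best$evalue) ||
          (s$bitscore == best$bitscore && s$evalue == best$evalue &&
           s$identity_pct > best$identity_pct)) {
        best <- s
      }
    }
    return(list(status = "annotated", description = best$description,
                source_db = best$database_tag))
  }
  if (saw_passing) {
    return(list(status = "hypothetical", description = "hypothetical protein",
                source_db = "none"))
  }
  list(status = "no_hit", description = "", source_db = "none")
}

# Random hit set for one query; metrics straddle the default thresholds so
# pass/fail, keyword and tie cases all occur.
random_hits <- function(n_hits, query = "q1", db = "curated") {
  descs <- c("Protein kinase 1", "ABC transporter 2", "hypothetical protein",
             "Uncharacterized protein X", "DNA repair protein", "unknown protein")
  qlen <- sample(100:300, 1)
  hits <- data.frame(
    query_id = rep(query, n_hits),
    subject_id = sprintf("s%d", seq_len(n_hits)),
    identity_pct = round(runif(n_hits, 20, 90), 1),
    positivity_pct = round(runif(n_hits, 40, 99), 1),
    alignment_length = sample(20:300, n_hits, replace = TRUE),
    query_length = rep(qlen, n_hits),
    evalue = signif(10^runif(n_hits, -30, -3), 3),
    bitscore = sample(seq(50, 400, by = 10), n_hits, replace = TRUE),
    description = sample(descs, n_hits, replace = TRUE),
    database_tag = rep(db, n_hits),
    stringsAsFactors = FALSE
  )
  hits$coverage_pct <- pmin(100, 100 * hits$alignment_length / hits$query_length)
  class(hits) <- c("blast_hits", "data.frame")
  hits
}

# Write a hit table in the engine's 9-column dialect.
write_hits <- function(hits, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
                     hits$query_id, hits$subject_id, hits$identity_pct,
                     hits$positivity_pct, hits$alignment_length,
                     hits$query_length, hits$evalue, hits$bitscore,
                     hits$description),
             path)
  path
}

default_config <- function(...) pipeline_config(basename = "test", ...)
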