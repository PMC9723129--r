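# Similarity-based annotation transfer: parse tabular protein-vs-database
# hits, filter by coverage/identity/positivity/e-value, disregard hits whose
# descriptions are uninformative (keyworded), pick the best remaining hit by
# bitscore, and classify every protein as annotated / hypothetical / no_hit.

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "ppos", "length", "qlen",
                   "evalue", "bitscore", "stitle")

#' Parse a tabular similarity-hit file
#'
#' Reads a 9-column tab-separated hit table (the common `outfmt 6` dialect
#' extended with `ppos`, `qlen` and `stitle`): `qseqid, sseqid, pident, ppos,
#' length, qlen, evalue, bitscore, stitle`, one hit per line, `#` comment
#' lines ignored. Query coverage is derived as `100 * length / qlen`, clamped
#' to \[0, 100\].
#'
#' @param path hit-table location.
#' @param database_tag `"curated"` or `"specific"`; recorded on every hit so
#'   downstream merging knows which database donated an annotation.
#' @return A `data.frame` of class `blast_hits` with one row per hit, columns
#'   `query_id`, `subject_id`, `identity_pct`, `positivity_pct`,
#'   `alignment_length`, `query_length`, `evalue`, `bitscore`, `description`,
#'   `database_tag`, `coverage_pct`. Input order is preserved.
#' @export
parse_blast_table <- function(path, database_tag = c("curated", "specific")) {
  database_tag <- match.arg(database_tag)
  if (!file.exists(path)) {
    stop(sprintf("hit table not found: %s", path), call. = FALSE)
  }
  tab <- read_tab_lines(path)
  nf <- lengths(tab$fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop(sprintf("%s: expected 9 tab-separated fields but found %d on line %d",
                 basename(path), nf[bad], tab$lineno[bad]), call. = FALSE)
  }
  m <- do.call(rbind, tab$fields)
  if (is.null(m)) m <- matrix(character(0), ncol = 9)
  num <- function(col, what) as_numeric_checked(m[, col], what, tab$lineno, path)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = num(3, "pident"), positivity_pct = num(4, "ppos"),
    alignment_length = as.integer(num(5, "length")),
    query_length = as.integer(num(6, "qlen")),
    evalue = num(7, "evalue"), bitscore = num(8, "bitscore"),
    description = m[, 9], database_tag = rep(database_tag, nrow(m)),
    stringsAsFactors = FALSE
  )
  hits$coverage_pct <- pmin(100, 100 * hits$alignment_length / hits$query_length)
  class(hits) <- c("blast_hits", "data.frame")
  hits
}

#' Threshold filter for similarity hits
#'
#' A hit may transfer its annotation only when all four cutoffs hold, each
#' inclusive: `evalue <= evalue_cutoff`, `coverage >= min_coverage_pct`,
#' `identity >= min_identity_pct` and `positivity >= min_positivity_pct`.
#'
#' @param hits a `blast_hits` data frame (any number of rows).
#' @param config a [pipeline_config()].
#' @return Logical vector, one element per hit.
#' @export
hit_passes_thresholds <- function(hits, config) {
  hits$evalue <= config$evalue_cutoff &
    hits$coverage_pct >= config$min_coverage_pct &
    hits$identity_pct >= config$min_identity_pct &
    hits$positivity_pct >= config$min_positivity_pct
}

#' Keyword filter for hit descriptions
#'
#' A description is uninformative when any keyword occurs in it as a
#' case-insensitive substring; such hits are disregarded for annotation
#' transfer and instead mark their query as a hypothetical-protein candidate.
#'
#' @param description character vector of subject descriptions.
#' @param keywords lowercase keyword vector (see [default_keywords()]).
#' @return Logical vector parallel to `description`.
#' @examples
#' description_is_keyworded("Uncharacterized protein YJL222W", default_keywords())
#' @export
description_is_keyworded <- function(description, keywords) {
  low <- tolower(description)
  out <- rep(FALSE, length(low))
  for (kw in keywords) {
    out <- out | grepl(kw, low, fixed = TRUE)
  }
  out
}

new_decision <- function(status, description = "", source_db = "none",
                         winning_hit = NULL) {
  structure(list(status = status, description = description,
                 source_db = source_db, winning_hit = winning_hit),
            class = "annotation_decision")
}

#' @export
print.annotation_decision <- function(x, ...) {
  cat(sprintf("<%s>%s%s\n", x$status,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              if (x$source_db != "none") paste0(" [", x$source_db, "]") else ""))
  invisible(x)
}

#' Decide one protein's annotation from one database's hits
#'
#' Implements one database stage of the classification: among hits passing
#' [hit_passes_thresholds()], keyworded hits are disregarded; if informative
#' hits remain the protein is `annotated` with the highest-bitscore
#' survivor's description (ties broken by lower e-value, then higher
#' identity, then input order); if hits passed the thresholds but every one
#' was keyworded the protein is `hypothetical`; otherwise `no_hit` for this
#' stage.
#'
#' @param hits `blast_hits` rows for a single query (may be empty).
#' @param config a [pipeline_config()].
#' @return An `annotation_decision`: `status`, `description` (the transferred
#'   text, `"hypothetical protein"`, or `""`), `source_db`, and the winning
#'   hit row (or `NULL`).
#' @export
decide_from_hits <- function(hits, config) {
  if (nrow(hits) == 0) return(new_decision("no_hit"))
  if (length(unique(hits$query_id)) != 1) {
    stop("decide_from_hits() requires hits for a single query", call. = FALSE)
  }
  pass <- hit_passes_thresholds(hits, config)
  if (!any(pass)) return(new_decision("no_hit"))
  hits <- hits[pass, , drop = FALSE]
  clean <- !description_is_keyworded(hits$description, config$keywords)
  if (!any(clean)) return(new_decision("hypothetical", "hypothetical protein"))
  hits <- hits[clean, , drop = FALSE]
  best <- order(-hits$bitscore, hits$evalue, -hits$identity_pct,
                seq_len(nrow(hits)))[1]
  win <- hits[best, , drop = FALSE]
  new_decision("annotated", win$description, win$database_tag, win)
}

#' Merge the curated-database and specific-database stage decisions
#'
#' The curated database has priority: when it annotates, its transfer is
#' kept and the specific database is not consulted, so every annotated
#' protein is credited to exactly one source. A protein is hypothetical when
#' either stage found similarity but only to uninformative descriptions, and
#' `no_hit` only when neither database produced a passing hit.
#'
#' @param curated,specific `annotation_decision`s from the two stages.
#' @return The merged `annotation_decision`.
#' @export
merge_database_stages <- function(curated, specific) {
  if (curated$status == "annotated") return(curated)
  if (specific$status == "annotated") return(specific)
  if (curated$status == "hypothetical" || specific$status == "hypothetical") {
    return(new_decision("hypothetical", "hypothetical protein"))
  }
  new_decision("no_hit")
}

#' Classify a whole proteome from two hit tables
#'
#' Runs [decide_from_hits()] per query and database, merges the stages, and
#' guarantees exactly one decision per input protein: queries with no hits in
#' either file are `no_hit`. Hits for queries absent from `all_query_ids`
#' trigger a warning and are classified anyway.
#'
#' @param curated_hits,specific_hits `blast_hits` data frames (from
#'   [parse_blast_table()]).
#' @param all_query_ids character vector of every predicted protein id.
#' @param config a [pipeline_config()].
#' @return A `data.frame`, one row per protein, columns `protein_id`,
#'   `status`, `description`, `source_db`, `hit_subject_id`, `hit_bitscore`,
#'   `hit_evalue`, `hit_identity_pct`, `hit_coverage_pct`.
#' @export
classify_proteome <- function(curated_hits, specific_hits, all_query_ids,
                              config) {
  seen <- unique(c(curated_hits$query_id, specific_hits$query_id))
  extra <- setdiff(seen, all_query_ids)
  if (length(extra) > 0) {
    warning(sprintf("hits found for %d protein id(s) absent from the proteome (e.g. %s); included anyway",
                    length(extra), extra[1]), call. = FALSE)
    all_query_ids <- c(all_query_ids, extra)
  }
  cur_split <- split(seq_len(nrow(curated_hits)), curated_hits$query_id)
  spe_split <- split(seq_len(nrow(specific_hits)), specific_hits$query_id)
  empty <- curated_hits[0, , drop = FALSE]
  decisions <- lapply(all_query_ids, function(id) {
    cur <- if (id %in% names(cur_split)) {
      curated_hits[cur_split[[id]], , drop = FALSE]
    } else empty
    spe <- if (id %in% names(spe_split)) {
      specific_hits[spe_split[[id]], , drop = FALSE]
    } else empty
    merge_database_stages(decide_from_hits(cur, config),
                          decide_from_hits(spe, config))
  })
  hit_field <- function(d, field, default) {
    if (is.null(d$winning_hit)) default else d$winning_hit[[field]]
  }
  data.frame(
    protein_id = all_query_ids,
    status = vapply(decisions, `[[`, "", "status"),
    description = vapply(decisions, `[[`, "", "description"),
    source_db = vapply(decisions, `[[`, "", "source_db"),
    hit_subject_id = vapply(decisions, hit_field, "", "subject_id", NA_character_),
    hit_bitscore = vapply(decisions, hit_field, 0, "bitscore", NA_real_),
    hit_evalue = vapply(decisions, hit_field, 0, "evalue", NA_real_),
    hit_identity_pct = vapply(decisions, hit_field, 0, "identity_pct", NA_real_),
    hit_coverage_pct = vapply(decisions, hit_field, 0, "coverage_pct", NA_real_),
    stringsAsFactors = FALSE
  )
}
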