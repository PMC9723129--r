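# Report generation: pipe-delimited annotated FASTA headers, GFF3 product
# rewriting, the TXT/TSV output pair, and the printed summary tables
# (classification table, summary statistics, hypothetical-protein reduction).

#' Build an annotated FASTA header
#'
#' Fields are joined by `" | "`. Full mode (coordinates known):
#' `id | organism | scaffold | start | end | strand | description`; simplified
#' mode (no structural annotation supplied): `id | organism | description`.
#' GO then IPR ids, each its own trailing field, are appended when present.
#' Coordinates must be all present or all absent.
#'
#' @param record a list or one-row data frame with `protein_id`, `organism`,
#'   `description` and optionally `scaffold`, `cds_start`, `cds_end`,
#'   `strand`, plus character vectors `go_ids`, `ipr_ids`.
#' @return The header line (no leading `>`).
#' @examples
#' build_fasta_header(list(protein_id = "p1", organism = "Toyus examplus",
#'   description = "Protein kinase ABC", scaffold = "scaffold_3",
#'   cds_start = 1200, cds_end = 2150, strand = "+",
#'   go_ids = "GO:0004672", ipr_ids = "IPR000719"))
#' @export
build_fasta_header <- function(record) {
  coord_fields <- list(record$scaffold, record$cds_start, record$cds_end,
                       record$strand)
  absent <- vapply(coord_fields, function(x) is.null(x) || is.na(x), TRUE)
  if (any(absent) && !all(absent)) {
    stop(sprintf("protein '%s': coordinate fields must be all present or all absent",
                 record$protein_id), call. = FALSE)
  }
  fields <- c(record$protein_id, record$organism)
  if (!any(absent)) {
    if (record$cds_start > record$cds_end) {
      stop(sprintf("protein '%s': cds_start exceeds cds_end", record$protein_id),
           call. = FALSE)
    }
    fields <- c(fields, record$scaffold,
                format(record$cds_start, scientific = FALSE),
                format(record$cds_end, scientific = FALSE), record$strand)
  }
  fields <- c(fields, record$description)
  go <- record$go_ids
  ipr <- record$ipr_ids
  fields <- c(fields, sort(go[!is.na(go) & nzchar(go)]),
              sort(ipr[!is.na(ipr) & nzchar(ipr)]))
  paste(fields, collapse = " | ")
}

# Percent-encode characters reserved in GFF3 attribute values.
gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Rewrite transcript product attributes in a GFF3 file
#'
#' For every `mRNA`, `transcript` or `CDS` feature whose `ID` (or, for CDS
#' parts, `Parent`) matches a protein id — after stripping `.t1`-style
#' transcript suffixes from both sides — the `product=` attribute is set
#' (added or replaced) to the final annotation description, percent-encoded
#' per GFF3 attribute rules. Every other line is copied byte-identically.
#' Protein ids with no matching feature produce a warning.
#'
#' @param gff_in input GFF3 location.
#' @param descriptions named character vector: protein id to description.
#' @param gff_out output location.
#' @return `gff_out`, invisibly.
#' @export
rewrite_gff <- function(gff_in, descriptions, gff_out) {
  if (!file.exists(gff_in)) {
    stop(sprintf("GFF3 file not found: %s", gff_in), call. = FALSE)
  }
  norm_desc <- stats::setNames(descriptions, normalize_feature_id(names(descriptions)))
  matched <- stats::setNames(rep(FALSE, length(norm_desc)), names(norm_desc))
  lines <- readLines(gff_in, warn = FALSE)
  out <- vapply(lines, function(line) {
    if (grepl("^#", line)) return(line)
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) return(line)
    if (!f[3] %in% c("mRNA", "transcript", "CDS")) return(line)
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    key <- function(k) {
      hit <- grep(paste0("^", k, "="), attrs, value = TRUE)
      if (length(hit) == 0) NA_character_ else sub(paste0("^", k, "="), "", hit[1])
    }
    id <- if (f[3] == "CDS") key("Parent") else key("ID")
    if (is.na(id)) return(line)
    id <- normalize_feature_id(id)
    if (!id %in% names(norm_desc)) return(line)
    matched[id] <<- TRUE
    prod <- paste0("product=", gff3_encode(unname(norm_desc[id])))
    has <- grepl("^product=", attrs)
    attrs <- if (any(has)) replace(attrs, has, prod) else c(attrs, prod)
    f[9] <- paste(attrs, collapse = ";")
    paste(f, collapse = "\t")
  }, "", USE.NAMES = FALSE)
  if (!all(matched)) {
    warning(sprintf("%d protein id(s) had no matching GFF3 feature (e.g. %s)",
                    sum(!matched), names(matched)[!matched][1]), call. = FALSE)
  }
  writeLines(out, gff_out)
  invisible(gff_out)
}

serialize_ids <- function(ids) {
  ids <- sort(unique(ids[!is.na(ids) & nzchar(ids)]))
  if (length(ids) == 0) "" else paste(ids, collapse = ";")
}

#' Write the annotated output files
#'
#' Produces the standard output set, each named
#' `<basename>_pgannotate_<file>.<format>`:
#' annotated protein FASTA (60-column wrapped, pipe-delimited headers),
#' annotated CDS FASTA (omitted with a warning when no CDS sequences are
#' available), the rewritten GFF3 (when a structural annotation was
#' supplied), a two-column TXT (`id TAB description`) and a 13-column TSV
#' (`protein_id, status, source_db, description, go_ids, ipr_ids, tpm,
#' transcript_evidence, psm_count, min_qvalue, peptide_evidence, category,
#' true_negative`). Reruns on identical inputs are byte-identical.
#'
#' @param records data frame from [integrate_evidence()] (or
#'   [classify_proteome()]; missing evidence columns are emptied).
#' @param terms named list from [attach_functional_terms()] (optional).
#' @param proteins an `AAStringSet` of protein sequences named by protein id.
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param cds optional `DNAStringSet` of CDS sequences.
#' @param gff optional input GFF3 path; when given, coordinates are read from
#'   it for full headers and the rewritten GFF3 is emitted.
#' @return Named character vector of the paths written.
#' @export
write_outputs <- function(records, terms = NULL, proteins, config, outdir,
                          cds = NULL, gff = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stem <- function(what, ext) {
    file.path(outdir, sprintf("%s_pgannotate_%s.%s", config$basename, what, ext))
  }
  n <- nrow(records)
  get_terms <- function(id, field) {
    if (is.null(terms) || is.null(terms[[id]])) character(0) else terms[[id]][[field]]
  }
  coords <- if (!is.null(gff)) read_gff_coordinates(gff) else NULL
  headers <- vapply(seq_len(n), function(i) {
    id <- records$protein_id[i]
    rec <- list(protein_id = id, organism = config$organism_name,
                description = records$description[i],
                go_ids = get_terms(id, "go_ids"),
                ipr_ids = get_terms(id, "ipr_ids"))
    if (!is.null(coords)) {
      ci <- coords[normalize_feature_id(id), ]
      if (!is.na(ci$scaffold)) {
        rec$scaffold <- ci$scaffold; rec$cds_start <- ci$start
        rec$cds_end <- ci$end; rec$strand <- ci$strand
      }
    }
    build_fasta_header(rec)
  }, "")

  paths <- character(0)
  idx <- match(records$protein_id, names(proteins))
  if (anyNA(idx)) {
    stop(sprintf("no protein sequence for id '%s'",
                 records$protein_id[is.na(idx)][1]), call. = FALSE)
  }
  prot_out <- proteins[idx]
  names(prot_out) <- headers
  Biostrings::writeXStringSet(prot_out, stem("proteins", "fasta"), width = 60)
  paths["proteins"] <- stem("proteins", "fasta")

  if (!is.null(cds)) {
    cidx <- match(records$protein_id, names(cds))
    if (anyNA(cidx)) {
      warning("CDS sequences missing for some proteins; CDS FASTA omitted",
              call. = FALSE)
    } else {
      cds_out <- cds[cidx]
      names(cds_out) <- headers
      Biostrings::writeXStringSet(cds_out, stem("cds", "fasta"), width = 60)
      paths["cds"] <- stem("cds", "fasta")
    }
  } else {
    warning("no CDS sequences supplied; CDS FASTA omitted", call. = FALSE)
  }

  if (!is.null(gff)) {
    descs <- stats::setNames(records$description, records$protein_id)
    rewrite_gff(gff, descs, stem("annotations", "gff3"))
    paths["gff"] <- stem("annotations", "gff3")
  }

  txt <- sprintf("%s\t%s", records$protein_id, records$description)
  writeLines(txt, stem("annotations", "txt"))
  paths["txt"] <- stem("annotations", "txt")

  col_or <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE))
  tsv <- data.frame(
    protein_id = records$protein_id,
    status = records$status,
    source_db = records$source_db,
    description = records$description,
    go_ids = vapply(records$protein_id, function(id) serialize_ids(get_terms(id, "go_ids")), ""),
    ipr_ids = vapply(records$protein_id, function(id) serialize_ids(get_terms(id, "ipr_ids")), ""),
    tpm = fmt_num(col_or("tpm", NA_real_)),
    transcript_evidence = col_or("transcript_evidence", FALSE),
    psm_count = col_or("psm_count", 0L),
    min_qvalue = fmt_num(col_or("min_qvalue", NA_real_)),
    peptide_evidence = col_or("peptide_evidence", FALSE),
    category = col_or("category", NA_integer_),
    true_negative = col_or("true_negative", FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(tsv, stem("summary", "tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["tsv"] <- stem("summary", "tsv")
  paths
}

# Extract per-transcript coordinates (scaffold, start, end, strand) from a
# GFF3 file, keyed by normalized mRNA/transcript ID. For multi-part CDS the
# mRNA line's span is used.
read_gff_coordinates <- function(gff) {
  lines <- readLines(gff, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) == 9]
  rows <- Filter(Negate(is.null), lapply(fields, function(f) {
    if (!f[3] %in% c("mRNA", "transcript")) return(NULL)
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[9])
    if (identical(id, f[9])) return(NULL)
    data.frame(id = normalize_feature_id(id), scaffold = f[1],
               start = as.integer(f[4]), end = as.integer(f[5]),
               strand = f[7], stringsAsFactors = FALSE)
  }))
  if (length(rows) == 0) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  df <- do.call(rbind, rows)
  out <- df[!duplicated(df$id), c("scaffold", "start", "end", "strand")]
  rownames(out) <- df$id[!duplicated(df$id)]
  # lookups for unknown ids return an all-NA row
  out[nrow(out) + 1L, ] <- list(NA_character_, NA_integer_, NA_integer_, NA_character_)
  rownames(out)[nrow(out)] <- ".__absent__"
  out
}

#' Tabulate the eight evidence categories
#'
#' @param categories integer vector of categories in `1..8` (one per
#'   classified protein; non-empty).
#' @return A `data.frame` of class `classification_table` with one row per
#'   category: the three defining flags, `count`, and `percentage` of the
#'   total (rounded half-up to 2 decimals). The total is kept in attribute
#'   `total`.
#' @export
classification_table <- function(categories) {
  if (length(categories) == 0) {
    stop("cannot tabulate an empty category vector", call. = FALSE)
  }
  stopifnot(all(categories %in% 1:8))
  counts <- as.integer(table(factor(categories, levels = 1:8)))
  total <- length(categories)
  flags <- data.frame(
    category = 1:8,
    hypothetic = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    transcript_evidence = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    peptide_evidence = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  out <- cbind(flags, count = counts,
               percentage = round_half_up(100 * counts / total, 2))
  attr(out, "total") <- total
  class(out) <- c("classification_table", "data.frame")
  out
}

#' Summary statistics for an annotated proteome
#'
#' Counts and printed-style percentages: annotated / total-hypothetical /
#' evidence / term shares are percentages of all predicted proteins, while
#' the per-database shares are percentages of annotated proteins. All
#' percentages are rounded half-up to 2 decimals.
#'
#' @param records data frame with at least `status` and `source_db`;
#'   evidence columns (`transcript_evidence`, `peptide_evidence`,
#'   `true_negative`) and term columns (`go_ids`, `ipr_ids` as
#'   semicolon-joined strings, or a `terms` attribute) are used when present.
#' @param terms optional named list from [attach_functional_terms()] used to
#'   count proteins with at least one IPR / GO term.
#' @return An object of class `summary_stats`: a list of counts (`n_*`) and
#'   percentages (`pct_*`).
#' @export
summary_stats <- function(records, terms = NULL) {
  n <- nrow(records)
  if (n == 0) stop("cannot summarize zero records", call. = FALSE)
  n_annotated <- sum(records$status == "annotated")
  n_hypothetical <- sum(records$status == "hypothetical")
  n_no_hit <- sum(records$status == "no_hit")
  n_by_curated <- sum(records$status == "annotated" & records$source_db == "curated")
  n_by_specific <- sum(records$status == "annotated" & records$source_db == "specific")
  has_col <- function(col) col %in% names(records)
  n_transcript <- if (has_col("transcript_evidence")) sum(records$transcript_evidence) else NA_integer_
  n_peptide <- if (has_col("peptide_evidence")) sum(records$peptide_evidence) else NA_integer_
  n_true_negative <- if (has_col("true_negative")) sum(records$true_negative) else NA_integer_
  count_terms <- function(field) {
    if (!is.null(terms)) {
      sum(vapply(records$protein_id,
                 function(id) !is.null(terms[[id]]) && length(terms[[id]][[field]]) > 0,
                 TRUE))
    } else if (has_col(field)) {
      sum(nzchar(records[[field]]))
    } else NA_integer_
  }
  n_with_ipr <- count_terms("ipr_ids")
  n_with_go <- count_terms("go_ids")
  pct_of <- function(x, denom) {
    if (is.na(x)) NA_real_ else round_half_up(100 * x / denom, 2)
  }
  structure(list(
    n_predicted = n,
    n_annotated = n_annotated,
    n_by_curated = n_by_curated,
    n_by_specific = n_by_specific,
    n_hypothetical = n_hypothetical,
    n_no_hit = n_no_hit,
    n_true_negative = n_true_negative,
    n_total_hypothetical = n_hypothetical + n_no_hit,
    n_with_ipr = n_with_ipr,
    n_with_go = n_with_go,
    n_transcript_evidence = n_transcript,
    n_peptide_evidence = n_peptide,
    pct_annotated = pct_of(n_annotated, n),
    pct_by_curated = pct_of(n_by_curated, max(n_annotated, 1)),
    pct_by_specific = pct_of(n_by_specific, max(n_annotated, 1)),
    pct_total_hypothetical = pct_of(n_hypothetical + n_no_hit, n),
    pct_with_ipr = pct_of(n_with_ipr, n),
    pct_with_go = pct_of(n_with_go, n),
    pct_transcript_evidence = pct_of(n_transcript, n),
    pct_peptide_evidence = pct_of(n_peptide, n)
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  fmt <- function(n, p) {
    if (is.na(n)) "-" else if (is.na(p)) format(n, big.mark = ",")
    else sprintf("%s (%.2f%%)", format(n, big.mark = ","), p)
  }
  cat("Predicted proteins              ", format(x$n_predicted, big.mark = ","), "\n")
  cat("Annotated proteins              ", fmt(x$n_annotated, x$pct_annotated), "\n")
  cat("  by curated database           ", fmt(x$n_by_curated, x$pct_by_curated), " of annotated\n")
  cat("  by specific database          ", fmt(x$n_by_specific, x$pct_by_specific), " of annotated\n")
  cat("Hypothetical proteins           ", format(x$n_hypothetical, big.mark = ","), "\n")
  cat("No-hit proteins (true negative) ", format(x$n_no_hit, big.mark = ","),
      " (", ifelse(is.na(x$n_true_negative), "-", format(x$n_true_negative, big.mark = ",")), ")\n", sep = "")
  cat("Total hypothetical              ", fmt(x$n_total_hypothetical, x$pct_total_hypothetical), "\n")
  cat("With >=1 IPR term               ", fmt(x$n_with_ipr, x$pct_with_ipr), "\n")
  cat("With >=1 GO term                ", fmt(x$n_with_go, x$pct_with_go), "\n")
  cat("With transcript evidence        ", fmt(x$n_transcript_evidence, x$pct_transcript_evidence), "\n")
  cat("With peptide evidence           ", fmt(x$n_peptide_evidence, x$pct_peptide_evidence), "\n")
  invisible(x)
}

#' Hypothetical-protein reduction
#'
#' Percentage reduction in hypothetical-protein count relative to a reference
#' annotation: `100 * (reference - new) / reference`.
#'
#' @param reference_hypothetical hypothetical count in the reference
#'   annotation (positive).
#' @param new_hypothetical hypothetical count in the new annotation.
#' @param digits decimals to round (half-up) to; default 2.
#' @return The reduction percentage (negative when the count grew).
#' @examples
#' reduction_stat(2411, 217, digits = 1) # 91.0
#' @export
reduction_stat <- function(reference_hypothetical, new_hypothetical, digits = 2) {
  if (reference_hypothetical <= 0) {
    stop("reference hypothetical count must be positive", call. = FALSE)
  }
  round_half_up(100 * (reference_hypothetical - new_hypothetical) /
                  reference_hypothetical, digits)
}
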