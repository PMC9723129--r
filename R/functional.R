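# Functional annotation: aggregate GO / InterPro terms for every protein and
# domain-scan hits (profile HMM and reverse PSI-BLAST) for the hypothetical /
# no-hit group, which gets the deeper scans to support manual curation.

empty_terms <- function() {
  structure(list(ipr_ids = character(0), go_ids = character(0),
                 domain_hits = data.frame(source = character(0),
                                          accession = character(0),
                                          description = character(0),
                                          evalue = numeric(0),
                                          stringsAsFactors = FALSE),
                 superfamily = NA_character_),
            class = "functional_terms")
}

#' @export
print.functional_terms <- function(x, ...) {
  cat(sprintf("functional terms: %d IPR, %d GO, %d domain hit(s)%s\n",
              length(x$ipr_ids), length(x$go_ids), nrow(x$domain_hits),
              if (!is.na(x$superfamily)) paste0(", superfamily ", x$superfamily) else ""))
  invisible(x)
}

#' Parse a domain/family scan TSV (InterProScan 5 layout)
#'
#' Expects the standard 11-to-15-column TSV: protein id (column 1), analysis
#' (column 4), signature accession (column 5), integrated InterPro accession
#' (column 12) and pipe-separated GO terms (column 14). Columns 12-14 may be
#' absent or `'-'` when a signature is not integrated; rows with fewer than
#' 11 columns are a parse error (reported with the line number). Rows whose
#' analysis is `SUPERFAMILY` additionally record the superfamily accession.
#'
#' @param path TSV location.
#' @return Named list mapping protein id to a `functional_terms` object with
#'   sorted, deduplicated `ipr_ids` and `go_ids`.
#' @export
parse_interproscan_tsv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scan TSV not found: %s", path), call. = FALSE)
  }
  tab <- read_tab_lines(path)
  nf <- lengths(tab$fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop(sprintf("%s: expected at least 11 tab-separated fields but found %d on line %d",
                 basename(path), nf[bad], tab$lineno[bad]), call. = FALSE)
  }
  out <- list()
  get <- function(f, i) if (length(f) >= i) f[[i]] else "-"
  for (f in tab$fields) {
    id <- f[[1]]
    if (is.null(out[[id]])) out[[id]] <- empty_terms()
    ipr <- get(f, 12)
    go <- get(f, 14)
    if (nzchar(ipr) && ipr != "-") {
      out[[id]]$ipr_ids <- union(out[[id]]$ipr_ids, ipr)
    }
    if (nzchar(go) && go != "-") {
      out[[id]]$go_ids <- union(out[[id]]$go_ids, strsplit(go, "|", fixed = TRUE)[[1]])
    }
    if (identical(f[[4]], "SUPERFAMILY")) {
      out[[id]]$superfamily <- f[[5]]
    }
  }
  lapply(out, function(t) {
    t$ipr_ids <- sort(t$ipr_ids)
    t$go_ids <- sort(t$go_ids)
    t
  })
}

#' Parse a profile-HMM scan table (hmmscan tblout layout)
#'
#' Whitespace-delimited table with 18 fixed fields followed by a free-text
#' target description; field 1 is the profile (target) name, field 2 its
#' accession, field 3 the protein (query) name, field 5 the full-sequence
#' e-value and field 8 the best-domain e-value. A row is retained only when
#' both e-values pass their cutoffs.
#'
#' @param path tblout-style file location.
#' @param seq_evalue_cutoff maximum full-sequence e-value.
#' @param dom_evalue_cutoff maximum best-domain e-value.
#' @return Named list mapping protein id to a data frame of domain hits
#'   (`source = "hmm"`, `accession`, `description`, `evalue`).
#' @export
parse_hmm_table <- function(path, seq_evalue_cutoff = 1e-5,
                            dom_evalue_cutoff = 1e-5) {
  if (!file.exists(path)) {
    stop(sprintf("hmm table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 18) {
      stop(sprintf("%s: expected at least 18 whitespace-separated fields but found %d on line %d",
                   basename(path), length(f), lineno[i]), call. = FALSE)
    }
    seq_e <- as_numeric_checked(f[[5]], "sequence e-value", lineno[i], path)
    dom_e <- as_numeric_checked(f[[8]], "domain e-value", lineno[i], path)
    if (seq_e > seq_evalue_cutoff || dom_e > dom_evalue_cutoff) next
    id <- f[[3]]
    acc <- if (f[[2]] != "-") f[[2]] else f[[1]]
    desc <- if (length(f) > 18) paste(f[19:length(f)], collapse = " ") else ""
    row <- data.frame(source = "hmm", accession = acc, description = desc,
                      evalue = seq_e, stringsAsFactors = FALSE)
    out[[id]] <- if (is.null(out[[id]])) row else rbind(out[[id]], row)
  }
  out
}

#' Parse a reverse PSI-BLAST domain-hit table
#'
#' Tab-separated, 4 columns: query id, subject accession, e-value, subject
#' title. Rows above the e-value cutoff are dropped; duplicate accessions for
#' one protein are kept as separate hits (deduplication happens only when id
#' sets are serialized).
#'
#' @param path hit-table location.
#' @param evalue_cutoff maximum e-value.
#' @return Named list mapping protein id to a data frame of domain hits
#'   (`source = "rps"`).
#' @export
parse_rps_table <- function(path, evalue_cutoff = 1e-5) {
  if (!file.exists(path)) {
    stop(sprintf("rps table not found: %s", path), call. = FALSE)
  }
  tab <- read_tab_lines(path)
  nf <- lengths(tab$fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop(sprintf("%s: expected 4 tab-separated fields but found %d on line %d",
                 basename(path), nf[bad], tab$lineno[bad]), call. = FALSE)
  }
  out <- list()
  for (i in seq_along(tab$fields)) {
    f <- tab$fields[[i]]
    e <- as_numeric_checked(f[[3]], "e-value", tab$lineno[i], path)
    if (e > evalue_cutoff) next
    row <- data.frame(source = "rps", accession = f[[2]], description = f[[4]],
                      evalue = e, stringsAsFactors = FALSE)
    id <- f[[1]]
    out[[id]] <- if (is.null(out[[id]])) row else rbind(out[[id]], row)
  }
  out
}

#' Attach functional terms to classified proteins
#'
#' Routing rule: annotated proteins receive their GO/IPR terms from the
#' whole-proteome scan only; hypothetical and no-hit proteins additionally
#' receive the deeper profile-HMM and reverse PSI-BLAST domain hits. Domain
#' hits present in the input files for annotated proteins are ignored (the
#' routing lives here, not in the file producer). Proteins absent from every
#' scan get empty terms. Attachment is idempotent.
#'
#' @param decisions classification data frame from [classify_proteome()].
#' @param interpro result of [parse_interproscan_tsv()].
#' @param hmm result of [parse_hmm_table()] (optional).
#' @param rps result of [parse_rps_table()] (optional).
#' @return Named list mapping every `decisions$protein_id` to a
#'   `functional_terms` object.
#' @export
attach_functional_terms <- function(decisions, interpro, hmm = list(),
                                    rps = list()) {
  out <- stats::setNames(vector("list", nrow(decisions)), decisions$protein_id)
  for (i in seq_len(nrow(decisions))) {
    id <- decisions$protein_id[i]
    t <- if (!is.null(interpro[[id]])) interpro[[id]] else empty_terms()
    if (decisions$status[i] != "annotated") {
      dh <- rbind(t$domain_hits, hmm[[id]], rps[[id]])
      if (!is.null(dh)) t$domain_hits <- dh
    }
    out[[id]] <- t
  }
  out
}
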