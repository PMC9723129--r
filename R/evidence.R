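# Experimental-evidence integration: transcript evidence from a TPM
# quantification table (threshold = dataset mean), peptide evidence from
# peptide-spectrum matches filtered at a q-value cutoff, the eight-way
# evidence categories, and the true-negative flag for unsupported no-hit
# proteins (candidate gene-prediction artifacts).

#' Parse a transcript-abundance table
#'
#' Tab-separated with a header line naming at least `target_id` and `tpm`
#' columns (the layout written by pseudo-alignment quantifiers). Other
#' columns are ignored.
#'
#' @param path abundance TSV location.
#' @return Named numeric vector of TPM values, one per target id.
#' @export
parse_abundance <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("abundance table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    stop(sprintf("%s: missing header line", basename(path)), call. = FALSE)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  id_col <- match("target_id", header)
  tpm_col <- match("tpm", header)
  if (is.na(id_col) || is.na(tpm_col)) {
    stop(sprintf("%s: header must contain 'target_id' and 'tpm' columns",
                 basename(path)), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(stats::setNames(numeric(0), character(0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", id_col)
  tpm <- as_numeric_checked(vapply(fields, `[[`, "", tpm_col), "tpm",
                            seq_along(body) + 1L, path)
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate target id '%s'", basename(path),
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  if (any(tpm < 0)) {
    stop(sprintf("%s: negative tpm for target '%s'", basename(path),
                 ids[tpm < 0][1]), call. = FALSE)
  }
  stats::setNames(tpm, ids)
}

#' Transcript-evidence TPM threshold
#'
#' The threshold separating transcribed from untranscribed targets is derived
#' from the quantification itself; in `mean` mode it is the arithmetic mean
#' over all quantified targets, zeros included.
#'
#' @param tpms numeric vector of TPM values (non-empty).
#' @param mode threshold mode; only `"mean"` is defined.
#' @return The threshold, a single number.
#' @export
transcript_threshold <- function(tpms, mode = "mean") {
  mode <- match.arg(mode, "mean")
  if (length(tpms) == 0) {
    stop("cannot derive a TPM threshold from an empty quantification", call. = FALSE)
  }
  mean(tpms)
}

#' Flag transcript evidence
#'
#' A target has transcript evidence when its abundance reaches the threshold
#' (inclusive) *and* is strictly positive; the positivity guard keeps the
#' degenerate all-zero quantification (threshold 0) from flagging everything.
#'
#' @param tpms named numeric vector from [parse_abundance()].
#' @param threshold from [transcript_threshold()].
#' @return Named logical vector parallel to `tpms`.
#' @export
flag_transcript_evidence <- function(tpms, threshold) {
  tpms >= threshold & tpms > 0
}

#' Parse a peptide-spectrum-match table
#'
#' Tab-separated with a header naming `PSMId`, `q-value`, `peptide` and
#' `proteinIds`; protein ids run from the `proteinIds` column to the end of
#' the line (the tab-separated trailing-column convention), so one PSM may
#' map to several proteins.
#'
#' @param path PSM TSV location.
#' @return A `data.frame` with columns `psm_id`, `qvalue`, `peptide` and a
#'   list-column `protein_ids`.
#' @export
parse_psms <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("PSM table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  empty <- data.frame(psm_id = character(0), qvalue = numeric(0),
                      peptide = character(0), stringsAsFactors = FALSE)
  empty$protein_ids <- list()
  if (length(lines) == 0) return(empty)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("PSMId", "q-value", "peptide", "proteinIds")
  idx <- match(need, header)
  if (anyNA(idx)) {
    stop(sprintf("%s: header must contain columns %s", basename(path),
                 paste(need[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  qv <- as_numeric_checked(vapply(fields, `[[`, "", idx[2]), "q-value",
                           seq_along(body) + 1L, path)
  if (any(qv < 0 | qv > 1)) {
    stop(sprintf("%s: q-value outside [0,1] on line %d", basename(path),
                 which(qv < 0 | qv > 1)[1] + 1L), call. = FALSE)
  }
  out <- data.frame(
    psm_id = vapply(fields, `[[`, "", idx[1]),
    qvalue = qv,
    peptide = vapply(fields, `[[`, "", idx[3]),
    stringsAsFactors = FALSE
  )
  out$protein_ids <- lapply(fields, function(f) f[idx[4]:length(f)])
  out
}

#' Flag peptide evidence per protein
#'
#' Over the PSMs passing the q-value cutoff, each mapped protein accumulates
#' its PSM count and minimum q-value; evidence requires at least one passing
#' PSM. Shared peptides credit every protein they map to.
#'
#' @param psms data frame from [parse_psms()].
#' @param q_cutoff maximum accepted q-value (in `(0, 1]`).
#' @return A `data.frame` with one row per protein seen in any PSM:
#'   `protein_id`, `psm_count` (passing PSMs), `min_qvalue` (over passing
#'   PSMs; `NA` if none) and logical `peptide_evidence`.
#' @export
flag_peptide_evidence <- function(psms, q_cutoff = 0.05) {
  stopifnot(q_cutoff > 0, q_cutoff <= 1)
  all_ids <- unique(unlist(psms$protein_ids))
  if (length(all_ids) == 0) {
    return(data.frame(protein_id = character(0), psm_count = integer(0),
                      min_qvalue = numeric(0), peptide_evidence = logical(0),
                      stringsAsFactors = FALSE))
  }
  pass <- psms$qvalue <= q_cutoff
  long_ids <- unlist(psms$protein_ids[pass])
  long_q <- rep(psms$qvalue[pass], lengths(psms$protein_ids[pass]))
  counts <- table(factor(long_ids, levels = all_ids))
  minq <- rep(NA_real_, length(all_ids))
  if (length(long_ids) > 0) {
    mins <- tapply(long_q, factor(long_ids, levels = all_ids), min)
    minq <- as.numeric(mins)
  }
  data.frame(protein_id = all_ids,
             psm_count = as.integer(counts),
             min_qvalue = minq,
             peptide_evidence = as.integer(counts) >= 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign the eight-way evidence category
#'
#' Every classified protein falls in one of eight categories from the cross
#' of three flags: hypothetic annotation (hypothetical or no-hit status),
#' transcript evidence, and peptide evidence. The category codes are:
#'
#' | category | hypothetic | transcript | peptide |
#' |---------:|:----------:|:----------:|:-------:|
#' | 1 | yes | no  | no  |
#' | 2 | no  | no  | no  |
#' | 3 | yes | yes | no  |
#' | 4 | yes | no  | yes |
#' | 5 | no  | yes | no  |
#' | 6 | no  | no  | yes |
#' | 7 | yes | yes | yes |
#' | 8 | no  | yes | yes |
#'
#' @param hypothetic,transcript,peptide logical vectors (recycled to a
#'   common length).
#' @return Integer vector of categories in `1..8`.
#' @examples
#' assign_category(FALSE, FALSE, FALSE) # 2
#' assign_category(TRUE, TRUE, TRUE)    # 7
#' @export
assign_category <- function(hypothetic, transcript, peptide) {
  n <- max(length(hypothetic), length(transcript), length(peptide))
  h <- rep_len(as.logical(hypothetic), n)
  t <- rep_len(as.logical(transcript), n)
  p <- rep_len(as.logical(peptide), n)
  # index by (h, t, p) bits; order matches the table above
  lut <- array(NA_integer_, dim = c(2, 2, 2))
  lut[2, 1, 1] <- 1L; lut[1, 1, 1] <- 2L
  lut[2, 2, 1] <- 3L; lut[2, 1, 2] <- 4L
  lut[1, 2, 1] <- 5L; lut[1, 1, 2] <- 6L
  lut[2, 2, 2] <- 7L; lut[1, 2, 2] <- 8L
  lut[cbind(h + 1L, t + 1L, p + 1L)]
}

#' Identify true-negative proteins
#'
#' A true negative has no similarity support in either database and no
#' experimental evidence of transcription or expression — the profile of a
#' gene-prediction artifact.
#'
#' @param status character vector of annotation statuses.
#' @param transcript_evidence,peptide_evidence logical vectors.
#' @return Logical vector: `TRUE` where status is `no_hit` and both evidence
#'   flags are `FALSE`.
#' @export
flag_true_negatives <- function(status, transcript_evidence, peptide_evidence) {
  status == "no_hit" & !transcript_evidence & !peptide_evidence
}

#' Integrate evidence for a classified proteome
#'
#' Convenience wrapper joining the similarity classification with the two
#' evidence sources: derives the TPM threshold, flags transcript and peptide
#' evidence per protein (proteins absent from a source get `FALSE`), assigns
#' categories (hypothetical and no-hit proteins share the hypothetic flag)
#' and marks true negatives. A disabled evidence channel contributes
#' all-`FALSE` flags.
#'
#' @param decisions data frame from [classify_proteome()].
#' @param tpms named numeric vector from [parse_abundance()], or `NULL`.
#' @param psms data frame from [parse_psms()], or `NULL`.
#' @param config a [pipeline_config()].
#' @return `decisions` extended with columns `tpm`, `transcript_evidence`,
#'   `psm_count`, `min_qvalue`, `peptide_evidence`, `category`,
#'   `true_negative`.
#' @export
integrate_evidence <- function(decisions, tpms = NULL, psms = NULL, config) {
  n <- nrow(decisions)
  out <- decisions
  out$tpm <- rep(NA_real_, n)
  out$transcript_evidence <- rep(FALSE, n)
  if (config$enable_transcript_evidence && !is.null(tpms) && length(tpms) > 0) {
    thr <- transcript_threshold(tpms, config$tpm_threshold_mode)
    flags <- flag_transcript_evidence(tpms, thr)
    idx <- match(out$protein_id, names(tpms))
    out$tpm <- unname(tpms[idx])
    out$transcript_evidence <- !is.na(idx) & unname(flags[idx]) %in% TRUE
  }
  out$psm_count <- rep(0L, n)
  out$min_qvalue <- rep(NA_real_, n)
  out$peptide_evidence <- rep(FALSE, n)
  if (config$enable_peptide_evidence && !is.null(psms) && nrow(psms) > 0) {
    pep <- flag_peptide_evidence(psms, config$psm_qvalue_cutoff)
    idx <- match(out$protein_id, pep$protein_id)
    got <- !is.na(idx)
    out$psm_count[got] <- pep$psm_count[idx[got]]
    out$min_qvalue[got] <- pep$min_qvalue[idx[got]]
    out$peptide_evidence[got] <- pep$peptide_evidence[idx[got]]
  }
  out$category <- assign_category(out$status %in% c("hypothetical", "no_hit"),
                                  out$transcript_evidence,
                                  out$peptide_evidence)
  out$true_negative <- flag_true_negatives(out$status,
                                           out$transcript_evidence,
                                           out$peptide_evidence)
  out
}
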