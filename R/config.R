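# Run configuration: every cutoff, keyword list, basename and input-file path
# used by the engine, loaded from a YAML file with documented defaults.

#' Default keyword list for hypothetical-protein classification
#'
#' Database descriptions that contain any of these words (case-insensitive
#' substring match) carry no transferable functional information; hits with
#' such descriptions are disregarded during annotation transfer.
#'
#' @return Character vector of the six default keywords, lowercase.
#' @examples
#' default_keywords()
#' @export
default_keywords <- function() {
  c("fragment", "hypothetical", "partial",
    "uncharacterized", "unknown", "unspecified")
}

#' Build a pipeline configuration
#'
#' Central container for all tunable parameters. Defaults follow common
#' practice for conservative annotation transfer: e-value at most 1e-5 and at
#' least 30% query coverage, 40% identity and 60% positivity before a hit may
#' donate its description.
#'
#' @param basename run basename used as the prefix of every output file; must
#'   contain no whitespace or path separators.
#' @param organism_name organism label written into FASTA headers.
#' @param threads worker count hint for external tools (default 4).
#' @param evalue_cutoff maximum e-value for a similarity hit (default 1e-5).
#' @param max_target_seqs maximum hits per query requested from the search
#'   tool (default 10); recorded for adapter command lines, the engine itself
#'   accepts any number of hits.
#' @param min_coverage_pct minimum query coverage percentage (default 30).
#' @param min_identity_pct minimum identity percentage (default 40).
#' @param min_positivity_pct minimum positivity percentage (default 60).
#' @param keywords keywords marking uninformative descriptions; stored
#'   lowercase (default [default_keywords()]).
#' @param hmm_evalue e-value cutoff for profile-HMM scan hits, applied to both
#'   the full-sequence and best-domain e-values (default 1e-5).
#' @param rps_evalue e-value cutoff for reverse PSI-BLAST domain hits
#'   (default 1e-5).
#' @param tpm_threshold_mode how the transcript-evidence TPM threshold is
#'   derived from the abundance table; only `"mean"` is currently defined.
#' @param psm_qvalue_cutoff maximum PSM q-value counted as peptide evidence
#'   (default 0.05).
#' @param enable_transcript_evidence,enable_peptide_evidence logical switches
#'   for the two experimental-evidence stages.
#' @param paths named list mapping input-file roles (`proteins`, `cds`, `gff`,
#'   `blast_curated`, `blast_specific`, `interpro`, `hmm`, `rps`, `abundance`,
#'   `psms`) to file locations. Stored as opaque strings.
#' @return An object of class `pipeline_config`.
#' @seealso [load_config()], [write_config()]
#' @export
pipeline_config <- function(basename = "run",
                            organism_name = "unknown organism",
                            threads = 4L,
                            evalue_cutoff = 1e-5,
                            max_target_seqs = 10L,
                            min_coverage_pct = 30,
                            min_identity_pct = 40,
                            min_positivity_pct = 60,
                            keywords = default_keywords(),
                            hmm_evalue = 1e-5,
                            rps_evalue = 1e-5,
                            tpm_threshold_mode = "mean",
                            psm_qvalue_cutoff = 0.05,
                            enable_transcript_evidence = TRUE,
                            enable_peptide_evidence = TRUE,
                            paths = list()) {
  cfg <- structure(list(
    basename = basename,
    organism_name = organism_name,
    threads = as.integer(threads),
    evalue_cutoff = evalue_cutoff,
    max_target_seqs = as.integer(max_target_seqs),
    min_coverage_pct = min_coverage_pct,
    min_identity_pct = min_identity_pct,
    min_positivity_pct = min_positivity_pct,
    keywords = tolower(keywords),
    hmm_evalue = hmm_evalue,
    rps_evalue = rps_evalue,
    tpm_threshold_mode = tpm_threshold_mode,
    psm_qvalue_cutoff = psm_qvalue_cutoff,
    enable_transcript_evidence = isTRUE(enable_transcript_evidence),
    enable_peptide_evidence = isTRUE(enable_peptide_evidence),
    paths = paths
  ), class = "pipeline_config")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks every bound stated for the configuration fields and fails with a
#' message naming the offending key.
#'
#' @param config a `pipeline_config`.
#' @return `config`, invisibly valid, for chaining.
#' @export
validate_config <- function(config) {
  fail <- function(key, why) {
    stop(sprintf("invalid configuration value for '%s': %s", key, why),
         call. = FALSE)
  }
  chk_num <- function(key, lo, hi, lo_open = FALSE) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      fail(key, "must be a single number")
    }
    if (lo_open && v <= lo) fail(key, sprintf("must be > %g", lo))
    if (!lo_open && v < lo) fail(key, sprintf("must be >= %g", lo))
    if (v > hi) fail(key, sprintf("must be <= %g", hi))
  }
  if (!is.character(config$basename) || length(config$basename) != 1 ||
      grepl("[/\\\\[:space:]]", config$basename) || !nzchar(config$basename)) {
    fail("basename", "must be a non-empty string without whitespace or path separators")
  }
  if (config$threads < 1) fail("threads", "must be a positive integer")
  if (config$max_target_seqs < 1) fail("max_target_seqs", "must be a positive integer")
  chk_num("evalue_cutoff", 0, Inf, lo_open = TRUE)
  chk_num("hmm_evalue", 0, Inf, lo_open = TRUE)
  chk_num("rps_evalue", 0, Inf, lo_open = TRUE)
  chk_num("min_coverage_pct", 0, 100)
  chk_num("min_identity_pct", 0, 100)
  chk_num("min_positivity_pct", 0, 100)
  chk_num("psm_qvalue_cutoff", 0, 1, lo_open = TRUE)
  if (!identical(config$tpm_threshold_mode, "mean")) {
    fail("tpm_threshold_mode", "only 'mean' is supported")
  }
  if (length(config$keywords) == 0) {
    fail("keywords", "keyword list must be non-empty")
  }
  if (!identical(config$keywords, tolower(config$keywords))) {
    fail("keywords", "keywords must be lowercase")
  }
  invisible(config)
}

#' Load a pipeline configuration from YAML
#'
#' Keys absent from the file take the documented defaults; unknown keys
#' produce a warning (not an error) so forward-compatible configs still load.
#'
#' @param path location of the YAML configuration file.
#' @return A validated `pipeline_config`.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeLines("basename: demo", p)
#' load_config(p)$threads  # 4
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown configuration keys: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, p))` recovers
#' `cfg` exactly.
#'
#' @param config a `pipeline_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration '", x$basename, "' (", x$organism_name, ")\n", sep = "")
  cat(sprintf("  similarity: e-value <= %g, coverage >= %g%%, identity >= %g%%, positivity >= %g%%\n",
              x$evalue_cutoff, x$min_coverage_pct, x$min_identity_pct, x$min_positivity_pct))
  cat(sprintf("  keywords: %s\n", paste(x$keywords, collapse = ", ")))
  cat(sprintf("  domains: hmm e <= %g, rps e <= %g\n", x$hmm_evalue, x$rps_evalue))
  cat(sprintf("  evidence: TPM threshold = %s%s, PSM q <= %g%s\n",
              x$tpm_threshold_mode,
              if (x$enable_transcript_evidence) "" else " (disabled)",
              x$psm_qvalue_cutoff,
              if (x$enable_peptide_evidence) "" else " (disabled)"))
  if (length(x$paths) > 0) {
    cat("  paths:", paste(names(x$paths), collapse = ", "), "\n")
  }
  invisible(x)
}
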