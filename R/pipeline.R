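# Orchestration: run the full engine (similarity -> functional -> evidence ->
# reporting) from a configuration, and render the external-tool command lines
# for users who run the upstream searches themselves.

#' Run the annotation engine end to end
#'
#' Executes the stages in order on the files named in `config$paths`:
#' similarity classification from the two hit tables, functional-term
#' attachment, experimental-evidence integration (each channel only when
#' enabled and its input is present), and report writing. A log file
#' (`<basename>_pgannotate.log`) in the output directory records per-stage
#' record counts and warnings.
#'
#' Run modes mirror the supported input combinations: `protein_only` (no
#' structural annotation; simplified FASTA headers, no GFF output) and
#' `protein_plus_gff` (full headers, rewritten GFF3). A precomputed gene
#' prediction (protein FASTA + GFF3) from a genome run enters as
#' `protein_plus_gff`; running the gene predictor itself is out of scope.
#'
#' @param config a [pipeline_config()] whose `paths` name at least
#'   `proteins`, `blast_curated` and `blast_specific`; optionally `cds`,
#'   `gff`, `interpro`, `hmm`, `rps`, `abundance`, `psms`.
#' @param mode `"protein_plus_gff"` or `"protein_only"`.
#' @param outdir output directory (created).
#' @return An object of class `annotation_run`: list with `records` (the
#'   integrated per-protein table), `terms`, `stats` ([summary_stats()]),
#'   `classification` ([classification_table()]), `outputs` (named file
#'   paths) and `config`.
#' @export
run_pipeline <- function(config, mode = c("protein_plus_gff", "protein_only"),
                         outdir) {
  mode <- match.arg(mode)
  validate_config(config)
  p <- config$paths
  need <- c("proteins", "blast_curated", "blast_specific")
  if (mode == "protein_plus_gff") need <- c(need, "gff")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    stop(sprintf("similarity stage: missing required input(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, sprintf("%s_pgannotate.log", config$basename))
  if (file.exists(log)) unlink(log)
  log_line(log, "run '%s' started (mode %s)", config$basename, mode)

  proteins <- Biostrings::readAAStringSet(p$proteins)
  names(proteins) <- sub("\\s.*$", "", names(proteins))
  if (length(proteins) == 0) {
    stop("similarity stage: empty proteome", call. = FALSE)
  }
  log_line(log, "input: %d proteins", length(proteins))

  cur <- parse_blast_table(p$blast_curated, "curated")
  spe <- parse_blast_table(p$blast_specific, "specific")
  log_line(log, "similarity: %d curated hits, %d specific hits", nrow(cur), nrow(spe))
  records <- classify_proteome(cur, spe, names(proteins), config)
  log_line(log, "similarity: %d annotated, %d hypothetical, %d no-hit",
           sum(records$status == "annotated"),
           sum(records$status == "hypothetical"),
           sum(records$status == "no_hit"))

  interpro <- if (!is.null(p$interpro)) parse_interproscan_tsv(p$interpro) else list()
  hmm <- if (!is.null(p$hmm)) parse_hmm_table(p$hmm, config$hmm_evalue, config$hmm_evalue) else list()
  rps <- if (!is.null(p$rps)) parse_rps_table(p$rps, config$rps_evalue) else list()
  terms <- attach_functional_terms(records, interpro, hmm, rps)
  log_line(log, "functional: %d proteins with terms from %d scan rows",
           sum(vapply(terms, function(t) length(t$ipr_ids) + length(t$go_ids) +
                        nrow(t$domain_hits) > 0, TRUE)),
           length(interpro) + length(hmm) + length(rps))

  tpms <- if (config$enable_transcript_evidence && !is.null(p$abundance)) {
    parse_abundance(p$abundance)
  } else NULL
  psms <- if (config$enable_peptide_evidence && !is.null(p$psms)) {
    parse_psms(p$psms)
  } else NULL
  records <- integrate_evidence(records, tpms, psms, config)
  log_line(log, "evidence: %d transcript-supported, %d peptide-supported, %d true negatives",
           sum(records$transcript_evidence), sum(records$peptide_evidence),
           sum(records$true_negative))

  cds <- if (!is.null(p$cds)) {
    x <- Biostrings::readDNAStringSet(p$cds)
    names(x) <- sub("\\s.*$", "", names(x))
    x
  } else NULL
  gff <- if (mode == "protein_plus_gff") p$gff else NULL
  outputs <- write_outputs(records, terms, proteins, config, outdir,
                           cds = cds, gff = gff)
  log_line(log, "reporting: wrote %s", paste(basename(outputs), collapse = ", "))

  structure(list(records = records, terms = terms,
                 stats = summary_stats(records, terms),
                 classification = classification_table(records$category),
                 outputs = c(outputs, log = log), config = config),
            class = "annotation_run")
}

#' @export
print.annotation_run <- function(x, ...) {
  cat("Annotation run '", x$config$basename, "'\n\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Render external-tool command lines
#'
#' The engine consumes tool outputs; users run the searches themselves. This
#' renders (without executing) the command lines with the configured
#' parameters, one entry per tool: the two protein similarity searches, the
#' whole-proteome domain scan, the two deep scans for the
#' hypothetical/no-hit group, transcript pseudo-alignment/quantification
#' (1,000 bootstraps) and the spectral search (scan range 200-4,000)
#' followed by PSM rescoring.
#'
#' @param config a [pipeline_config()].
#' @return Named character vector of command lines.
#' @export
adapter_commands <- function(config) {
  p <- function(role, default) {
    v <- config$paths[[role]]
    if (is.null(v)) default else v
  }
  prot <- p("proteins", "proteins.fasta")
  c(
    blast_curated = sprintf(
      "blastp -query %s -db curated_db -evalue %g -max_target_seqs %d -num_threads %d -outfmt '6 qseqid sseqid pident ppos length qlen evalue bitscore stitle' -out %s",
      prot, config$evalue_cutoff, config$max_target_seqs, config$threads,
      p("blast_curated", "blast_curated.tsv")),
    blast_specific = sprintf(
      "blastp -query %s -db specific_db -evalue %g -max_target_seqs %d -num_threads %d -outfmt '6 qseqid sseqid pident ppos length qlen evalue bitscore stitle' -out %s",
      prot, config$evalue_cutoff, config$max_target_seqs, config$threads,
      p("blast_specific", "blast_specific.tsv")),
    interproscan = sprintf(
      "interproscan.sh -i %s --goterms -f TSV -o %s",
      prot, p("interpro", "interpro.tsv")),
    hmmscan = sprintf(
      "hmmscan --tblout %s -E %g --domE %g --cpu %d Pfam-A.hmm hypothetical_proteins.fasta",
      p("hmm", "hmmscan.txt"), config$hmm_evalue, config$hmm_evalue,
      config$threads),
    rpsblast = sprintf(
      "rpsblast -query hypothetical_proteins.fasta -db Cdd -evalue %g -outfmt '6 qseqid sacc evalue stitle' -out %s",
      config$rps_evalue, p("rps", "rps.tsv")),
    kallisto = sprintf(
      "kallisto quant -i transcripts.idx -b 1000 -t %d -o quant reads_R1.fastq reads_R2.fastq",
      config$threads),
    comet = "comet -Pcomet.params -DscanRange=200-4000 spectra.mzXML",
    percolator = sprintf(
      "percolator --results-psms %s comet.pin", p("psms", "psms.tsv"))
  )
}
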