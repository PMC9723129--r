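# Synthetic input generation with planted ground truth. The generator writes
# the complete file set the engine consumes (protein/CDS FASTA, structural
# GFF3, two similarity-hit tables, three scan tables, abundance and PSM
# tables) so that running the engine on the files recovers a known intended
# status, source database, evidence pair and category for every protein.
# Hit metrics are written directly into the tables rather than computed from
# alignments: the engine never re-aligns, so sequence/metric consistency is
# not required.

CLEAN_DESCRIPTIONS <- c(
  "Protein kinase", "ATP-dependent RNA helicase", "Cytochrome P450",
  "ABC transporter", "Serine/threonine-protein phosphatase",
  "Ubiquitin-conjugating enzyme", "Heat shock protein", "DNA topoisomerase",
  "Glyceraldehyde-3-phosphate dehydrogenase", "Ribosomal protein L7",
  "Aquaporin", "Histone acetyltransferase", "Zinc finger protein",
  "Calmodulin-binding protein", "Sucrose synthase"
)

KEYWORDED_DESCRIPTIONS <- c(
  "hypothetical protein", "Uncharacterized protein", "unknown function protein",
  "predicted protein fragment", "partial coding sequence",
  "unspecified product", "conserved hypothetical protein"
)

rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# One similarity-hit line for the 9-column table dialect.
hit_line <- function(qid, sid, pident, ppos, len, qlen, evalue, bitscore, title) {
  sprintf("%s\t%s\t%.1f\t%.1f\t%d\t%d\t%.2e\t%.1f\t%s",
          qid, sid, pident, ppos, len, qlen, evalue, bitscore, title)
}

#' Generate a synthetic annotation cohort with planted ground truth
#'
#' Writes a complete, mutually consistent input set for `n` proteins under
#' `outdir` and returns the planted truth. Status proportions are realized
#' exactly (largest-remainder apportionment): annotated proteins get at least
#' one clean hit passing all thresholds in their intended source database
#' (specific-source proteins get only keyworded or sub-threshold curated
#' hits, so the curated stage cannot claim them); hypothetical proteins get
#' only keyworded passing hits; no-hit proteins get nothing or only
#' sub-threshold hits. Evidence proportions are likewise exact: transcript
#' evidence is planted through the abundance table such that flagged
#' proteins sit above and unflagged below the dataset-mean TPM threshold,
#' and peptide evidence through PSMs below/above the q-value cutoff.
#' Annotated and hypothetical proteins receive GO/IPR rows in the
#' whole-proteome scan TSV; hypothetical/no-hit proteins receive domain rows
#' in the profile-HMM and reverse PSI-BLAST tables. Generation is a pure
#' function of its arguments: the same seed yields byte-identical files.
#'
#' @param n cohort size (>= 1).
#' @param status_mix named proportions over `annotated`, `hypothetical`,
#'   `no_hit` (summing to 1).
#' @param evidence_mix named proportions over `none`, `transcript`,
#'   `peptide`, `both`.
#' @param curated_share fraction of annotated proteins credited to the
#'   curated database.
#' @param outdir directory to write the files into (created).
#' @param seed RNG seed (default 42).
#' @param with_gff also write CDS FASTA and structural GFF3 (default TRUE).
#' @return A list with `truth` (data frame: `protein_id`, `status`,
#'   `source_db`, `description`, `transcript_evidence`, `peptide_evidence`,
#'   `category`, `true_negative`, `go_ids`, `ipr_ids`), `files` (named paths)
#'   and `config` (a ready [pipeline_config()] pointing at the files).
#' @export
generate_cohort <- function(n,
                            status_mix = c(annotated = 0.7, hypothetical = 0.2,
                                           no_hit = 0.1),
                            evidence_mix = c(none = 0.55, transcript = 0.2,
                                             peptide = 0.1, both = 0.15),
                            curated_share = 0.7,
                            outdir = tempfile("cohort"),
                            seed = 42,
                            with_gff = TRUE) {
  stopifnot(n >= 1)
  status_mix <- status_mix[c("annotated", "hypothetical", "no_hit")]
  evidence_mix <- evidence_mix[c("none", "transcript", "peptide", "both")]
  if (anyNA(status_mix) || anyNA(evidence_mix)) {
    stop("status_mix and evidence_mix must name all their components", call. = FALSE)
  }
  if (abs(sum(status_mix) - 1) > 1e-8 || abs(sum(evidence_mix) - 1) > 1e-8) {
    stop("mix proportions must sum to 1", call. = FALSE)
  }
  with_seed(seed, generate_cohort_impl(n, status_mix, evidence_mix,
                                       curated_share, outdir, with_gff))
}

generate_cohort_impl <- function(n, status_mix, evidence_mix, curated_share,
                                 outdir, with_gff) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("g%d.t1", seq_len(n))

  status_counts <- apportion(n, status_mix)
  status <- sample(rep(names(status_counts), status_counts))
  n_ann <- sum(status == "annotated")
  src_counts <- apportion(n_ann, c(curated = curated_share,
                                   specific = 1 - curated_share))
  source_db <- rep("none", n)
  source_db[status == "annotated"] <- sample(rep(names(src_counts), src_counts))

  ev_counts <- apportion(n, evidence_mix)
  ev_kind <- sample(rep(names(ev_counts), ev_counts))
  transcript <- ev_kind %in% c("transcript", "both")
  peptide <- ev_kind %in% c("peptide", "both")

  description <- ifelse(
    status == "annotated",
    sprintf("%s %d", sample(CLEAN_DESCRIPTIONS, n, replace = TRUE), seq_len(n)),
    ifelse(status == "hypothetical", "hypothetical protein", "")
  )

  # --- sequences -----------------------------------------------------------
  aa_len <- sample(80:400, n, replace = TRUE)
  aa <- vapply(aa_len, rand_seq, "", alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  proteins <- Biostrings::AAStringSet(stats::setNames(aa, ids))
  f_proteins <- file.path(outdir, "proteins.fasta")
  Biostrings::writeXStringSet(proteins, f_proteins, width = 60)
  files <- c(proteins = f_proteins)

  if (with_gff) {
    nt <- vapply(3 * aa_len, rand_seq, "", alphabet = c("A", "C", "G", "T"))
    cds <- Biostrings::DNAStringSet(stats::setNames(nt, ids))
    f_cds <- file.path(outdir, "cds.fasta")
    Biostrings::writeXStringSet(cds, f_cds, width = 60)
    files["cds"] <- f_cds

    scaffold <- sprintf("scaffold_%d", sample(1:20, n, replace = TRUE))
    start <- sample(1000:500000, n, replace = TRUE)
    end <- start + 3 * aa_len - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_ids <- normalize_feature_id(ids)
    gff <- c("##gff-version 3", unlist(lapply(seq_len(n), function(i) c(
      sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              scaffold[i], start[i], end[i], strand[i], gene_ids[i]),
      sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              scaffold[i], start[i], end[i], strand[i], ids[i], gene_ids[i]),
      sprintf("%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              scaffold[i], start[i], end[i], strand[i], ids[i], ids[i])
    ))))
    f_gff <- file.path(outdir, "structure.gff3")
    writeLines(gff, f_gff)
    files["gff"] <- f_gff
  }

  # --- similarity hit tables ----------------------------------------------
  # Passing hits: e-value well below 1e-5, coverage/identity/positivity above
  # the defaults. Sub-threshold hits fail identity. The intended clean hit
  # always carries the highest bitscore of its query's clean hits; keyworded
  # decoys may outscore it (the disregard rule must still pick it).
  passing_metrics <- function() {
    list(pident = stats::runif(1, 55, 95), ppos = stats::runif(1, 70, 99),
         frac = stats::runif(1, 0.6, 1), evalue = 10^stats::runif(1, -80, -10))
  }
  failing_metrics <- function() {
    list(pident = stats::runif(1, 5, 35), ppos = stats::runif(1, 20, 55),
         frac = stats::runif(1, 0.6, 1), evalue = 10^stats::runif(1, -80, -10))
  }
  curated_lines <- character(0)
  specific_lines <- character(0)
  for (i in seq_len(n)) {
    qlen <- aa_len[i]
    mk <- function(m, bitscore, title, db_prefix) {
      hit_line(ids[i], sprintf("%s|%05d", db_prefix, sample.int(99999, 1)),
               m$pident, m$ppos, max(1L, as.integer(round(m$frac * qlen))),
               qlen, m$evalue, bitscore, title)
    }
    if (status[i] == "annotated") {
      win <- mk(passing_metrics(), stats::runif(1, 300, 500), description[i],
                if (source_db[i] == "curated") "sp" else "db")
      extras <- character(0)
      if (stats::runif(1) < 0.5) {  # lower-scoring clean competitor
        extras <- c(extras, mk(passing_metrics(), stats::runif(1, 100, 290),
                               sprintf("%s-like protein", sample(CLEAN_DESCRIPTIONS, 1)),
                               "xx"))
      }
      if (stats::runif(1) < 0.5) {  # keyworded decoy, possibly outscoring
        extras <- c(extras, mk(passing_metrics(), stats::runif(1, 100, 600),
                               sample(KEYWORDED_DESCRIPTIONS, 1), "xx"))
      }
      own <- sample(c(win, extras))
      if (source_db[i] == "curated") {
        curated_lines <- c(curated_lines, own)
        # the specific db may also hit; merge priority must still credit curated
        if (stats::runif(1) < 0.3) {
          specific_lines <- c(specific_lines,
                              mk(passing_metrics(), stats::runif(1, 100, 400),
                                 sprintf("%s homolog", sample(CLEAN_DESCRIPTIONS, 1)),
                                 "db"))
        }
      } else {
        specific_lines <- c(specific_lines, own)
        # curated stage must not annotate: keyworded or failing hits only
        if (stats::runif(1) < 0.5) {
          curated_lines <- c(curated_lines,
                             mk(passing_metrics(), stats::runif(1, 100, 400),
                                sample(KEYWORDED_DESCRIPTIONS, 1), "sp"))
        } else if (stats::runif(1) < 0.5) {
          curated_lines <- c(curated_lines,
                             mk(failing_metrics(), stats::runif(1, 50, 200),
                                sample(CLEAN_DESCRIPTIONS, 1), "sp"))
        }
      }
    } else if (status[i] == "hypothetical") {
      k <- sample(1:3, 1)
      tgt <- sample(c("curated", "specific"), k, replace = TRUE)
      for (j in seq_len(k)) {
        ln <- mk(passing_metrics(), stats::runif(1, 100, 400),
                 sample(KEYWORDED_DESCRIPTIONS, 1),
                 if (tgt[j] == "curated") "sp" else "db")
        if (tgt[j] == "curated") curated_lines <- c(curated_lines, ln)
        else specific_lines <- c(specific_lines, ln)
      }
    } else if (stats::runif(1) < 0.4) {  # no_hit with sub-threshold noise
      ln <- mk(failing_metrics(), stats::runif(1, 30, 100),
               sample(CLEAN_DESCRIPTIONS, 1), "xx")
      if (stats::runif(1) < 0.5) curated_lines <- c(curated_lines, ln)
      else specific_lines <- c(specific_lines, ln)
    }
  }
  f_cur <- file.path(outdir, "blast_curated.tsv")
  f_spe <- file.path(outdir, "blast_specific.tsv")
  writeLines(curated_lines, f_cur)
  writeLines(specific_lines, f_spe)
  files["blast_curated"] <- f_cur
  files["blast_specific"] <- f_spe

  # --- functional scans ----------------------------------------------------
  go_pool <- sprintf("GO:%07d", sample.int(9999999, 40))
  ipr_pool <- sprintf("IPR%06d", sample.int(999999, 30))
  scanned <- which(status != "no_hit")
  ipr_of <- stats::setNames(vector("list", n), ids)
  go_of <- stats::setNames(vector("list", n), ids)
  ips_lines <- character(0)
  for (i in scanned) {
    k <- sample(1:3, 1)
    for (j in seq_len(k)) {
      ipr <- sample(ipr_pool, 1)
      gos <- sample(go_pool, sample(0:2, 1))
      ipr_of[[i]] <- union(ipr_of[[i]], ipr)
      go_of[[i]] <- union(go_of[[i]], gos)
      ips_lines <- c(ips_lines, paste(
        ids[i], "md5", aa_len[i], "Pfam", sprintf("PF%05d", sample.int(99999, 1)),
        "domain", 1, aa_len[i], "1e-10", "T", "15-03-2022", ipr,
        "domain description",
        if (length(gos) > 0) paste(gos, collapse = "|") else "-",
        sep = "\t"))
    }
  }
  f_ips <- file.path(outdir, "interpro.tsv")
  writeLines(ips_lines, f_ips)
  files["interpro"] <- f_ips

  deep <- which(status != "annotated")
  hmm_lines <- character(0)
  rps_lines <- character(0)
  for (i in deep) {
    if (stats::runif(1) < 0.6) {
      hmm_lines <- c(hmm_lines, paste(
        sprintf("Domain_%d", sample.int(999, 1)),
        sprintf("PF%05d.1", sample.int(99999, 1)), ids[i], "-",
        format(10^stats::runif(1, -40, -6), scientific = TRUE),
        "120.0", "0.1", format(10^stats::runif(1, -40, -6), scientific = TRUE),
        "118.0", "0.1", "1", "1", "1", "1", "1", "1", "1", "1",
        "synthetic domain model"))
    }
    if (stats::runif(1) < 0.6) {
      rps_lines <- c(rps_lines, sprintf(
        "%s\tCDD:%d\t%.2e\t%s", ids[i], sample.int(99999, 1),
        10^stats::runif(1, -40, -6), "synthetic conserved domain"))
    }
  }
  f_hmm <- file.path(outdir, "hmmscan.txt")
  f_rps <- file.path(outdir, "rps.tsv")
  writeLines(hmm_lines, f_hmm)
  writeLines(rps_lines, f_rps)
  files["hmm"] <- f_hmm
  files["rps"] <- f_rps

  # --- transcript abundance ------------------------------------------------
  # Flagged proteins share TPM 150; unflagged get 0 or a value strictly below
  # 50 * n_flagged / n, which is below the dataset mean (>= 150 * n_f / n)
  # while 150 stays above it, so flags recover exactly for any feasible mix.
  n_f <- sum(transcript)
  tpm <- numeric(n)
  tpm[transcript] <- 150
  if (n_f > 0) {
    off <- which(!transcript)
    zero <- off[stats::runif(length(off)) < 0.5]
    low <- setdiff(off, zero)
    tpm[low] <- stats::runif(length(low), 0, 50 * n_f / n)
  }
  f_abund <- file.path(outdir, "abundance.tsv")
  writeLines(c("target_id\tlength\teff_length\test_counts\ttpm",
               sprintf("%s\t%d\t%.1f\t%.1f\t%s", ids, 3 * aa_len,
                       3 * aa_len - 100.5, tpm * 10,
                       format(tpm, scientific = FALSE, trim = TRUE))),
             f_abund)
  files["abundance"] <- f_abund

  # --- peptide-spectrum matches -------------------------------------------
  psm_lines <- character(0)
  psm_no <- 0
  aa_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in which(peptide)) {
    for (j in seq_len(sample(1:3, 1))) {
      psm_no <- psm_no + 1
      psm_lines <- c(psm_lines, sprintf(
        "psm_%d\t%.1f\t%.4f\t%.4f\t%s\t%s", psm_no, stats::runif(1, 2, 8),
        stats::runif(1, 0.0005, 0.04), stats::runif(1, 0.001, 0.1),
        sprintf("K.%s.R", rand_seq(sample(8:15, 1), aa_alpha)), ids[i]))
    }
  }
  # decoy PSMs above the cutoff for some unflagged proteins
  for (i in which(!peptide)) {
    if (stats::runif(1) < 0.1) {
      psm_no <- psm_no + 1
      psm_lines <- c(psm_lines, sprintf(
        "psm_%d\t%.1f\t%.4f\t%.4f\t%s\t%s", psm_no, stats::runif(1, 0.1, 2),
        stats::runif(1, 0.06, 0.9), stats::runif(1, 0.1, 0.9),
        sprintf("K.%s.R", rand_seq(sample(8:15, 1), aa_alpha)), ids[i]))
    }
  }
  f_psm <- file.path(outdir, "psms.tsv")
  writeLines(c("PSMId\tscore\tq-value\tposterior_error_prob\tpeptide\tproteinIds",
               psm_lines), f_psm)
  files["psms"] <- f_psm

  config <- pipeline_config(basename = "cohort",
                            organism_name = "Synthetica exempli",
                            paths = as.list(files))
  truth <- data.frame(
    protein_id = ids, status = status, source_db = source_db,
    description = description,
    transcript_evidence = transcript, peptide_evidence = peptide,
    category = assign_category(status != "annotated", transcript, peptide),
    true_negative = status == "no_hit" & !transcript & !peptide,
    go_ids = vapply(go_of, serialize_ids, ""),
    ipr_ids = vapply(ipr_of, serialize_ids, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(truth = truth, files = files, config = config)
}

#' Printed-scale reference cohort of evidence flags
#'
#' Builds the flags-only cohort (no sequences) whose category histogram is
#' `(203, 15417, 5, 7, 2480, 796, 2, 741)` over 19,651 proteins — the
#' published evidence-category distribution for the reannotated *Arabidopsis
#' thaliana* proteome — for exercising [classification_table()] and
#' [summary_stats()] at full printed scale. Statuses and sources are planted
#' consistently with the published marginals: 19,434 annotated (13,444
#' curated / 5,990 specific), 169 hypothetical, 48 no-hit of which 45 lack
#' all experimental evidence (true negatives).
#'
#' @return A data frame with columns `protein_id`, `status`, `source_db`,
#'   `hypothetic`, `transcript_evidence`, `peptide_evidence`, `category`,
#'   `true_negative`.
#' @export
table2_cohort <- function() {
  counts <- c(203L, 15417L, 5L, 7L, 2480L, 796L, 2L, 741L)
  hyp_flag <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  tr_flag <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  pe_flag <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  category <- rep(1:8, counts)
  df <- data.frame(
    protein_id = sprintf("at%05d.t1", seq_along(category)),
    hypothetic = rep(hyp_flag, counts),
    transcript_evidence = rep(tr_flag, counts),
    peptide_evidence = rep(pe_flag, counts),
    category = category,
    stringsAsFactors = FALSE
  )
  df$status <- ifelse(df$hypothetic, "hypothetical", "annotated")
  # 48 of the 217 hypothetic-flag proteins are no-hit: 45 without evidence
  # (true negatives, drawn from category 1) and 3 with evidence (category 3).
  no_ev_hyp <- which(df$category == 1)
  df$status[no_ev_hyp[seq_len(45)]] <- "no_hit"
  ev_hyp <- which(df$category == 3)
  df$status[ev_hyp[seq_len(3)]] <- "no_hit"
  df$source_db <- "none"
  ann <- which(df$status == "annotated")
  df$source_db[ann[seq_len(13444)]] <- "curated"
  df$source_db[ann[13445:length(ann)]] <- "specific"
  df$true_negative <- df$status == "no_hit" & !df$transcript_evidence &
    !df$peptide_evidence
  df[, c("protein_id", "status", "source_db", "hypothetic",
         "transcript_evidence", "peptide_evidence", "category",
         "true_negative")]
}
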