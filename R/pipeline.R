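#' Assemble and validate a pipeline configuration
#'
#' @param cp_genome,nuclear_genome,mito_genome FASTA paths (each may contain
#'   several sequences).
#' @param cds_fasta,trna_fasta FASTA paths of feature extracts, named by gene
#'   (optional; derived from the annotation when absent).
#' @param annotation Feature annotation path (TSV or GFF3).
#' @param reads Reads path (FASTQ/FASTA).
#' @param predicted_sites Optional predicted-editing-site TSV.
#' @param out_dir Output directory (created if needed).
#' @param min_len,max_len Read length window (18--24 nt for small RNA).
#' @param mrna_mode Disable the length filter for mRNA libraries.
#' @param max_mm Mismatch allowance of the final chloroplast pass.
#' @param min_coverage,max_p,stringent_p,terminal_window,err_rate Caller
#'   thresholds; \code{stringent_p} governs novel-site discovery.
#' @param score_cutoff Prediction-score cutoff for confirmation.
#' @param confirm_mode \code{"lenient"} or \code{"strict"}.
#' @param multiread Pileup multiread policy.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(cp_genome, nuclear_genome, mito_genome, annotation,
                            reads, cds_fasta = NULL, trna_fasta = NULL,
                            predicted_sites = NULL, out_dir = "srnaedit_out",
                            min_len = 18L, max_len = 24L, mrna_mode = FALSE,
                            max_mm = 2L, min_coverage = 5L, max_p = 1e-2,
                            stringent_p = 1e-10, terminal_window = 1L,
                            err_rate = 0.001, score_cutoff = 0.5,
                            confirm_mode = "lenient",
                            multiread = "count") {
  cfg <- as.list(environment())
  files <- c(cp_genome, nuclear_genome, mito_genome, annotation, reads,
             cds_fasta, trna_fasta, predicted_sites)
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("configuration error: input file(s) not found: ",
                            paste(missing, collapse = ", "))
  if (min_len > max_len) stop("configuration error: min_len > max_len")
  if (!max_mm %in% 0:2) stop("configuration error: max_mm must be 0, 1 or 2")
  stopifnot(min_coverage >= 1, max_p > 0, max_p <= 1, stringent_p > 0,
            terminal_window >= 0, err_rate > 0, err_rate < 1,
            score_cutoff >= 0, score_cutoff <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Load the reference set named by a pipeline configuration
#' @param cfg A [pipeline_config()].
#' @return A \code{ReferenceSet}.
#' @export
load_references <- function(cfg) {
  feats <- read_annotation(cfg$annotation)
  cp <- read_fasta(cfg$cp_genome)
  nuc <- read_fasta(cfg$nuclear_genome)
  mt <- read_fasta(cfg$mito_genome)
  seqs <- c(cp, nuc, mt)
  cats <- c(rep("chloroplast", length(cp)), rep("nuclear", length(nuc)),
            rep("mitochondrial", length(mt)))
  extras <- list(cds = cfg$cds_fasta, trna = cfg$trna_fasta)
  for (cat in names(extras)) {
    want_ft <- if (cat == "cds") "CDS" else "tRNA"
    if (!is.null(extras[[cat]])) {
      x <- read_fasta(extras[[cat]])
    } else {
      sub <- feats[feats$ftype == want_ft, , drop = FALSE]
      x <- stats::setNames(vapply(seq_len(nrow(sub)), function(i) {
        extract_feature_sequence(seqs[[sub$genome_ref[i]]], sub[i, ])
      }, character(1)), sub$gene)
    }
    seqs <- c(seqs, x)
    cats <- c(cats, rep(cat, length(x)))
  }
  reference_set(seqs, cats, feats)
}

#' Run the full editing-detection pipeline
#'
#' Executes length filtering, hierarchical partition, pileup construction,
#' C-to-T calling on CDS (standard and stringent p-value tracks), A-to-G
#' calling on tRNAs, confirmation of predicted sites and the
#' prediction-vs-SNP comparison, writing one TSV per report into
#' \code{cfg$out_dir} along with a run log (parameters, input checksums,
#' stage tallies). Identical configuration and inputs give byte-identical
#' outputs; no stage uses randomness.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with every intermediate and report.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- load_references(cfg)
  reads <- read_reads(cfg$reads)
  reads <- filter_by_length(reads, cfg$min_len, cfg$max_len, mrna_mode = cfg$mrna_mode)

  part <- hierarchical_partition(reads, refs, max_mm_final = cfg$max_mm)
  pile <- build_pileup(part$alignments, reads, refs, w = cfg$terminal_window,
                       multiread = cfg$multiread)
  calls <- call_sites(pile, "C2T", cfg$min_coverage, cfg$max_p, cfg$err_rate, refs)
  calls_stringent <- call_sites(pile, "C2T", cfg$min_coverage, cfg$stringent_p,
                                cfg$err_rate, refs)
  trna <- scan_trna_editing(pile, cfg$min_coverage, cfg$max_p, cfg$err_rate, refs)

  confirmation <- overlap <- NULL
  if (!is.null(cfg$predicted_sites)) {
    predicted <- read_predicted_sites(cfg$predicted_sites)
    confirmation <- confirm_predicted(predicted, calls, pile, refs,
                                      cfg$score_cutoff, cfg$confirm_mode)
    confirmed <- confirmation$records[confirmation$records$status == "confirmed", ]
    overlap <- compare_predictions_vs_snp(confirmed, calls_stringent)
  }
  covsum <- coverage_summary(genome_depth(part$alignments, reads, refs))

  hdr <- .param_header(cfg)
  .write_report(partition_summary(part$counts), file.path(cfg$out_dir, "partition_summary.tsv"), hdr)
  .write_report(calls, file.path(cfg$out_dir, "calls.tsv"), hdr)
  .write_report(calls_stringent, file.path(cfg$out_dir, "calls_stringent.tsv"), hdr)
  .write_report(trna, file.path(cfg$out_dir, "trna_calls.tsv"), hdr)
  if (!is.null(confirmation)) {
    .write_report(confirmation$records, file.path(cfg$out_dir, "confirmation.tsv"), hdr)
    venn <- data.frame(set = c("both", "prep_only", "snp_only"),
                       n_sites = c(overlap$n_both, overlap$n_prep_only, overlap$n_snp_only))
    .write_report(venn, file.path(cfg$out_dir, "prediction_vs_snp.tsv"), hdr)
  }
  .write_run_log(cfg, part, covsum, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(refs = refs, reads = reads, partition = part, pileups = pile,
                 calls = calls, calls_stringent = calls_stringent,
                 trna_calls = trna, confirmation = confirmation,
                 overlap = overlap, coverage = covsum))
}

.param_header <- function(cfg) {
  keep <- !vapply(cfg, is.null, logical(1))
  paste0("# ", names(cfg)[keep], " = ",
         vapply(cfg[keep], function(x) paste(format(x), collapse = ","), character(1)))
}

.write_report <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_run_log <- function(cfg, part, covsum, path) {
  inputs <- c(cfg$cp_genome, cfg$nuclear_genome, cfg$mito_genome,
              cfg$annotation, cfg$reads, cfg$predicted_sites)
  sums <- vapply(inputs, function(f) as.character(tools::md5sum(f)), character(1))
  lines <- c(paste0("srnaedit ", as.character(utils::packageVersion("srnaedit"))),
             .param_header(cfg),
             paste0("# input md5 ", inputs, " ", sums),
             paste0("reads_discarded_N\t", part$discarded_n),
             paste0("class_", names(part$counts), "\t", part$counts),
             paste0("genome_mean_coverage\t", format(covsum$mean)),
             paste0("genome_max_coverage\t", covsum$max),
             paste0("genome_zero_positions\t", covsum$zero_positions),
             paste0("genome_zero_fraction_pct\t", format(covsum$zero_fraction_pct)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the simulated fixture of a configuration to disk
#'
#' Convenience wrapper producing every file [pipeline_config()] expects:
#' genome FASTAs, annotation TSV, reads FASTQ, plus the truth tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a named list of the written paths plus the simulation
#'   result.
#' @export
write_sim_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- simulate_references(cfg)
  sim <- simulate_reads(refs, cfg)
  p <- function(f) file.path(dir, f)
  write_fasta(refs$sequences[refs$categories == "chloroplast"], p("cp_genome.fasta"))
  write_fasta(refs$sequences[refs$categories == "nuclear"], p("nuc_genome.fasta"))
  write_fasta(refs$sequences[refs$categories == "mitochondrial"], p("mt_genome.fasta"))
  write_fasta(refs$sequences[refs$categories == "cds"], p("cds.fasta"))
  write_fasta(refs$sequences[refs$categories == "trna"], p("trna.fasta"))
  write_annotation(refs$features, p("annotation.tsv"))
  write_reads(sim$reads, p("reads.fastq"))
  utils::write.table(sim$truth, p("read_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$site_truth)) {
    utils::write.table(sim$site_truth, p("site_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(paths = list(cp_genome = p("cp_genome.fasta"),
                              nuclear_genome = p("nuc_genome.fasta"),
                              mito_genome = p("mt_genome.fasta"),
                              cds_fasta = p("cds.fasta"),
                              trna_fasta = p("trna.fasta"),
                              annotation = p("annotation.tsv"),
                              reads = p("reads.fastq")),
                 refs = refs, sim = sim))
}
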