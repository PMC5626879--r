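#' Annotate the codon effect of a single-base change in a CDS
#'
#' @param cds_sequence Spliced sense CDS (character scalar).
#' @param cds_pos 1-based position of the change within the CDS.
#' @param alt_base The substituted base.
#' @param code Genetic code: \code{"standard"} (default) or \code{"table11"}
#'   (bacterial/plastid; identical codon assignments, alternative starts only).
#' @return List with \code{codon_index} (1-based amino-acid position),
#'   \code{position_in_codon} (1, 2 or 3), \code{ref_codon}, \code{alt_codon},
#'   \code{ref_aa}, \code{alt_aa} and \code{synonymous}.
#' @export
translate_effect <- function(cds_sequence, cds_pos, alt_base,
                             code = c("standard", "table11")) {
  code <- match.arg(code)
  L <- nchar(cds_sequence)
  if (cds_pos < 1 || cds_pos > L) stop("cds_pos outside the CDS (length ", L, ")")
  if (L %% 3L != 0L) {
    warning("CDS length ", L, " not divisible by 3; effect computed on the available frame")
  }
  ref_base <- substring(cds_sequence, cds_pos, cds_pos)
  if (ref_base == alt_base) stop("alt_base equals the reference base at cds_pos ", cds_pos)
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
  cstart <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substring(cds_sequence, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_base
  gc <- Biostrings::GENETIC_CODE # codon assignments shared by code 11
  tr <- function(cod) {
    if (nchar(cod) < 3L || grepl("N", cod)) NA_character_ else unname(gc[cod])
  }
  ref_aa <- tr(ref_codon); alt_aa <- tr(alt_codon)
  list(codon_index = codon_index, position_in_codon = pos_in_codon,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa,
       synonymous = isTRUE(ref_aa == alt_aa))
}

#' Map a spliced feature position to its genome coordinate
#'
#' Strand-aware and splice-aware inverse of [extract_feature_sequence()]:
#' the base at feature position \code{cds_pos} equals the (complemented, on
#' the minus strand) genome base at the returned coordinate.
#'
#' @param feature_row One-row slice of a feature table.
#' @param cds_pos 1-based position within the spliced feature (vectorized).
#' @return 1-based genome coordinate(s).
#' @export
cds_to_genome <- function(feature_row, cds_pos) {
  m <- feature_row$segments[[1]]
  lens <- m[, 2] - m[, 1] + 1L
  total <- sum(lens)
  if (any(cds_pos < 1 | cds_pos > total)) {
    stop("cds_pos outside the spliced feature (length ", total, ")")
  }
  ends <- cumsum(lens)
  starts0 <- c(0L, ends[-length(ends)])
  seg <- findInterval(cds_pos - 1L, ends) + 1L
  within <- cds_pos - starts0[seg] # 1-based offset within segment
  out <- if (feature_row$strand == "+") m[seg, 1] + within - 1L else m[seg, 2] - within + 1L
  unname(out)
}

#' Map a genome coordinate into spliced feature coordinates
#'
#' @param feature_row One-row slice of a feature table.
#' @param genome_pos 1-based genome coordinate(s).
#' @return 1-based spliced feature position(s); \code{NA} where the coordinate
#'   falls outside every segment.
#' @export
genome_to_cds <- function(feature_row, genome_pos) {
  m <- feature_row$segments[[1]]
  lens <- m[, 2] - m[, 1] + 1L
  starts0 <- c(0L, cumsum(lens)[-nrow(m)])
  out <- rep(NA_integer_, length(genome_pos))
  for (s in seq_len(nrow(m))) {
    inside <- genome_pos >= m[s, 1] & genome_pos <= m[s, 2]
    within <- if (feature_row$strand == "+") genome_pos - m[s, 1] + 1L
              else m[s, 2] - genome_pos + 1L
    out[inside] <- starts0[s] + within[inside]
  }
  out
}

CONFIRM_STATUSES <- c("confirmed", "covered_not_edited", "no_coverage", "genomic_T")
STATUS_GLYPHS <- c(confirmed = "*", covered_not_edited = "-",
                   no_coverage = "0", genomic_T = "T")

#' Confirm predicted editing sites against observed read evidence
#'
#' Classifies each predicted C-to-U site (after dropping sites below the
#' prediction-score cutoff) into exactly one status:
#' \describe{
#'   \item{genomic_T}{the reference CDS already carries T at the position, so
#'     no editing can occur (depends only on the reference, never on reads);}
#'   \item{no_coverage}{no surviving observation covers the position;}
#'   \item{confirmed}{editing evidence present --- in \code{"lenient"} mode at
#'     least one C-to-T observation surviving the terminal filter (matching
#'     manual-inspection confirmation, which accepts edited coverage of 1--2);
#'     in \code{"strict"} mode a call passing the caller's coverage and
#'     p-value thresholds;}
#'   \item{covered_not_edited}{reads cover the position but none shows the
#'     edit (or, in strict mode, the evidence fails the thresholds).}
#' }
#' Predicted sites naming genes absent from the annotation are excluded from
#' the denominators and returned separately.
#'
#' @param predicted Predicted-site table ([read_predicted_sites()]).
#' @param calls C2T call table from [call_sites()] (used in strict mode).
#' @param pileups Pileup table from [build_pileup()].
#' @param refs \code{ReferenceSet} with features.
#' @param score_cutoff Minimum prediction score retained (0.5 relaxed, 0.8
#'   stringent).
#' @param mode \code{"lenient"} (default, confirmation track) or
#'   \code{"strict"} (novel-site discovery thresholds).
#' @return List with \code{records} (one row per evaluated site: status,
#'   glyph, coverage, edited coverage, percent), \code{unmatched} (side table)
#'   and \code{summary} (status counts and percent confirmed).
#' @export
confirm_predicted <- function(predicted, calls, pileups, refs,
                              score_cutoff = 0.5, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  feats <- refs$features
  pred <- predicted[!is.na(predicted$score) & predicted$score >= score_cutoff, , drop = FALSE]
  # one record per (gene, cds_pos): duplicated-copy predictions collapse
  pred <- pred[!duplicated(pred[, c("gene", "cds_pos")]), , drop = FALSE]
  unmatched <- pred[!pred$gene %in% feats$gene, , drop = FALSE]
  pred <- pred[pred$gene %in% feats$gene, , drop = FALSE]

  feat_seq <- .feature_sequences(refs)
  n <- nrow(pred)
  status <- character(n); total_cov <- numeric(n); edited_cov <- numeric(n)
  for (i in seq_len(n)) {
    g <- pred$gene[i]; p <- pred$cds_pos[i]
    ref_base <- substring(feat_seq[[g]], p, p)
    col <- pileups[pileups$gene == g & pileups$cds_pos == p, , drop = FALSE]
    total_cov[i] <- if (nrow(col)) col$depth[1] else 0
    edited_cov[i] <- if (nrow(col)) col$T[1] else 0
    if (ref_base == "T") {
      status[i] <- "genomic_T"
    } else if (total_cov[i] == 0) {
      status[i] <- "no_coverage"
    } else if (mode == "lenient") {
      status[i] <- if (ref_base == "C" && edited_cov[i] >= 1) "confirmed" else "covered_not_edited"
    } else {
      hit <- nrow(calls[calls$gene == g & calls$cds_pos == p, , drop = FALSE]) > 0
      status[i] <- if (hit) "confirmed" else "covered_not_edited"
    }
  }
  records <- data.frame(gene = pred$gene, cds_pos = pred$cds_pos,
                        score = pred$score, status = status,
                        glyph = unname(STATUS_GLYPHS[status]),
                        total_cov = total_cov, edited_cov = edited_cov,
                        percent = ifelse(total_cov > 0,
                                         round_half_up(100 * edited_cov / pmax(total_cov, 1)),
                                         NA_real_),
                        stringsAsFactors = FALSE)
  counts <- vapply(CONFIRM_STATUSES, function(k) sum(status == k), integer(1))
  denom <- sum(counts)
  list(records = records, unmatched = unmatched,
       summary = list(counts = counts, evaluated = denom,
                      percent_confirmed = if (denom) round_half_up(100 * counts[["confirmed"]] / denom, 2) else NA_real_))
}

#' Overlap of predicted sites with SNP-derived calls
#'
#' Set algebra on site keys \code{(gene, cds_pos)}: sites found by both
#' routes, by prediction only, and by the SNP caller only (novel sites), plus
#' per-gene tallies of the union.
#'
#' @param predicted data.frame with \code{gene}, \code{cds_pos} (typically the
#'   confirmed predicted sites).
#' @param snp_calls data.frame with \code{gene}, \code{cds_pos} from
#'   [call_sites()].
#' @return List with data.frames \code{both}, \code{prep_only},
#'   \code{snp_only}, counts \code{n_both}/\code{n_prep_only}/\code{n_snp_only}
#'   and \code{per_gene} tallies.
#' @export
compare_predictions_vs_snp <- function(predicted, snp_calls) {
  keyp <- unique(paste(predicted$gene, predicted$cds_pos, sep = "\r"))
  keys <- unique(paste(snp_calls$gene, snp_calls$cds_pos, sep = "\r"))
  split_keys <- function(k) {
    if (!length(k)) return(data.frame(gene = character(), cds_pos = integer(),
                                      stringsAsFactors = FALSE))
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(gene = vapply(parts, `[`, "", 1L),
               cds_pos = as.integer(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  both <- split_keys(intersect(keyp, keys))
  prep_only <- split_keys(setdiff(keyp, keys))
  snp_only <- split_keys(setdiff(keys, keyp))
  all_genes <- c(both$gene, prep_only$gene, snp_only$gene)
  per_gene <- as.data.frame(table(gene = all_genes), stringsAsFactors = FALSE)
  names(per_gene) <- c("gene", "n_sites")
  list(both = both, prep_only = prep_only, snp_only = snp_only,
       n_both = nrow(both), n_prep_only = nrow(prep_only),
       n_snp_only = nrow(snp_only), per_gene = per_gene)
}

#' Scan tRNA pileups for A-to-I editing
#'
#' A-to-I editing is observed as an A-to-G change in reads, because inosine
#' base-pairs (and is reverse transcribed) like guanosine. Calls at sequence
#' positions 34 or 35 are flagged as the potential anticodon wobble site
#' (positions are 1-based from the annotated tRNA 5' end, not Sprinzl
#' numbering, and both coordinates are flagged rather than asserting a
#' convention).
#'
#' @inheritParams call_sites
#' @return Call data.frame with an added logical \code{wobble34_35} column.
#' @export
scan_trna_editing <- function(pileups, min_coverage = 5L, max_p = 1e-2,
                              err_rate = 0.001, refs = NULL) {
  calls <- call_sites(pileups, change = "A2G", min_coverage = min_coverage,
                      max_p = max_p, err_rate = err_rate, refs = refs)
  calls$wobble34_35 <- calls$cds_pos %in% c(34L, 35L)
  calls
}

#' Genome-coordinate read depth of the retained alignments
#'
#' Depth per chloroplast genome position, counting each read once per genome
#' position (cds/trna-copy alignments are projected back to the genome, and a
#' read seen at a position through both routes is deduplicated).
#'
#' @param alignments Retained alignments.
#' @param reads Read data.frame.
#' @param refs \code{ReferenceSet}.
#' @return Integer depth vector along the chloroplast genome.
#' @export
genome_depth <- function(alignments, reads, refs) {
  cp_id <- names(refs$categories)[refs$categories == "chloroplast"][1]
  glen <- nchar(refs$sequences[[cp_id]])
  if (nrow(alignments) == 0L) return(integer(glen))
  len_of <- stats::setNames(nchar(reads$seq), reads$id)
  obs <- list()
  g_aln <- alignments[alignments$ref_id == cp_id, , drop = FALSE]
  if (nrow(g_aln)) {
    n <- len_of[g_aln$read_id]
    obs[["genome"]] <- data.table::data.table(
      read_id = rep(g_aln$read_id, n),
      gpos = rep(g_aln$start, n) + sequence(n) - 1L)
  }
  feats <- refs$features
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    if (f$genome_ref != cp_id || !f$gene %in% names(refs$sequences)) next
    fa <- alignments[alignments$ref_id == f$gene, , drop = FALSE]
    if (!nrow(fa)) next
    n <- len_of[fa$read_id]
    fpos <- rep(fa$start, n) + sequence(n) - 1L
    obs[[paste0("f", i)]] <- data.table::data.table(
      read_id = rep(fa$read_id, n),
      gpos = cds_to_genome(f, fpos))
  }
  o <- unique(data.table::rbindlist(obs), by = c("read_id", "gpos"))
  depth <- integer(glen)
  tab <- o[, .N, by = gpos]
  depth[tab$gpos] <- tab$N
  depth
}

#' Summary statistics of genome coverage
#'
#' @param depth Integer depth vector over the genome ([genome_depth()]).
#' @return List with \code{mean}, \code{max}, \code{zero_positions} and
#'   \code{zero_fraction_pct} (percent of the genome uncovered, 2 decimals).
#' @export
coverage_summary <- function(depth) {
  list(mean = mean(depth), max = max(depth),
       zero_positions = sum(depth == 0),
       zero_fraction_pct = round_half_up(100 * sum(depth == 0) / length(depth), 2))
}
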