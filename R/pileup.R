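.empty_pileup <- function() {
  data.frame(gene = character(), ftype = character(), cds_pos = integer(),
             ref_base = character(), A = integer(), C = integer(),
             G = integer(), T = integer(), depth = numeric(),
             terminal_excluded = integer(), stringsAsFactors = FALSE)
}

#' Build per-position pileups over chloroplast features
#'
#' Tallies per-base observations of the retained (m0 + m2) alignments in
#' spliced feature coordinates. Alignments to a cds/trna extract contribute
#' directly; alignments to the chloroplast genome are projected, splice-aware,
#' into plus-strand features (a genome forward-strand alignment over a
#' minus-strand feature is antisense to the transcript and is not counted as
#' feature evidence). A read observed at the same feature position through
#' both its genome hit and its cds-copy hit is counted once.
#'
#' Mismatch observations within \code{w} bases of either read end are excluded
#' from the tallies (alignment artifacts at read termini mimic editing) and
#' counted in \code{terminal_excluded}; the read's matching bases still count
#' toward depth.
#'
#' @param alignments Retained alignments from [hierarchical_partition()] (or
#'   [map_read()]).
#' @param reads Read data.frame supplying the read sequences.
#' @param refs \code{ReferenceSet} with a feature table; cds/trna sequences
#'   must be named by gene.
#' @param w Terminal exclusion window (bases from each read end).
#' @param multiread \code{"count"} tallies every equal-best placement once;
#'   \code{"fractional"} weights each by \code{1/n_best_loci}.
#' @return data.frame with one row per covered feature position: \code{gene,
#'   ftype, cds_pos, ref_base, A, C, G, T, depth, terminal_excluded}.
#' @export
build_pileup <- function(alignments, reads, refs, w = 1L,
                         multiread = c("count", "fractional")) {
  multiread <- match.arg(multiread)
  if (!inherits(refs, "ReferenceSet") || is.null(refs$features)) {
    stop("build_pileup needs a ReferenceSet with a feature table")
  }
  if (nrow(alignments) == 0L) return(.empty_pileup())
  feats <- refs$features
  known <- c(names(refs$sequences))
  if (!all(alignments$ref_id %in% known)) {
    stop("alignment references unknown sequence: ",
         paste(unique(setdiff(alignments$ref_id, known)), collapse = ", "))
  }

  aln <- data.table::as.data.table(alignments)
  rd <- data.table::as.data.table(reads[, c("id", "seq")])
  aln <- merge(aln, rd, by.x = "read_id", by.y = "id", sort = FALSE)
  aln[, len := nchar(seq)]
  aln[, aid := .I]
  cat_of <- refs$categories

  obs_list <- list()

  direct <- aln[cat_of[ref_id] %in% c("cds", "trna")]
  if (nrow(direct)) {
    n <- direct$len
    obs_list[["direct"]] <- data.table::data.table(
      read_id = rep(direct$read_id, n),
      gene = rep(direct$ref_id, n),
      roff = sequence(n),
      fpos = rep(direct$start, n) + sequence(n) - 1L,
      seq = rep(direct$seq, n),
      weight = rep(1 / direct$n_best_loci, n)
    )
  }

  genome_aln <- aln[cat_of[ref_id] == "chloroplast"]
  if (nrow(genome_aln)) {
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      if (f$strand != "+") next
      segs <- f$segments[[1]]
      off0 <- 0L
      for (s in seq_len(nrow(segs))) {
        ss <- segs[s, 1]; se <- segs[s, 2]
        ov <- genome_aln[ref_id == f$genome_ref & start <= se & start + len - 1L >= ss]
        if (nrow(ov)) {
          a <- pmax(ov$start, ss); b <- pmin(ov$start + ov$len - 1L, se)
          n <- b - a + 1L
          g <- rep(a, n) + sequence(n) - 1L
          obs_list[[paste0("g", i, "_", s)]] <- data.table::data.table(
            read_id = rep(ov$read_id, n),
            gene = f$gene,
            roff = g - rep(ov$start, n) + 1L,
            fpos = off0 + (g - ss + 1L),
            seq = rep(ov$seq, n),
            weight = rep(1 / ov$n_best_loci, n)
          )
        }
        off0 <- off0 + (se - ss + 1L)
      }
    }
  }
  if (!length(obs_list)) return(.empty_pileup())
  obs <- data.table::rbindlist(obs_list)

  # one observation per read per feature position (genome/cds-copy dedup)
  obs <- unique(obs, by = c("read_id", "gene", "fpos"))
  obs[, base := substring(seq, roff, roff)]
  obs[, read_len := nchar(seq)]
  if (multiread == "count") obs[, weight := 1]

  feat_seq <- .feature_sequences(refs)
  obs[, ref_base := substring(feat_seq[gene], fpos, fpos)]
  obs[, mismatch := base != ref_base]
  obs[, terminal := mismatch & (roff <= w | roff > read_len - w)]

  ftype_of <- stats::setNames(feats$ftype, feats$gene)
  kept <- obs[terminal == FALSE]
  tallies <- kept[, .(n = sum(weight)), by = .(gene, fpos, ref_base, base)]
  wide <- data.table::dcast(tallies, gene + fpos + ref_base ~ base,
                            value.var = "n", fill = 0)
  for (b in c("A", "C", "G", "T")) if (is.null(wide[[b]])) wide[, (b) := 0]
  term <- obs[terminal == TRUE, .(terminal_excluded = .N), by = .(gene, fpos)]
  wide <- merge(wide, term, by = c("gene", "fpos"), all.x = TRUE)
  wide[is.na(terminal_excluded), terminal_excluded := 0L]
  wide[, depth := A + C + G + T]
  wide[, ftype := ftype_of[gene]]
  data.table::setnames(wide, "fpos", "cds_pos")
  data.table::setcolorder(wide, c("gene", "ftype", "cds_pos", "ref_base",
                                  "A", "C", "G", "T", "depth", "terminal_excluded"))
  data.table::setorder(wide, gene, cds_pos)
  as.data.frame(wide)
}

.feature_sequences <- function(refs) {
  feats <- refs$features
  out <- character(nrow(feats))
  names(out) <- feats$gene
  for (i in seq_len(nrow(feats))) {
    g <- feats$gene[i]
    if (g %in% names(refs$sequences)) {
      out[i] <- refs$sequences[[g]]
    } else {
      out[i] <- extract_feature_sequence(refs$sequences[[feats$genome_ref[i]]], feats[i, ])
    }
  }
  out
}

#' Classify alignment mismatches by the terminal-edit filter
#'
#' Splits each alignment's mismatch list into mismatches retained as editing
#' evidence and mismatches within \code{w} bases of either read end, which are
#' excluded (terminal mismatches are enriched for alignment artifacts that
#' mimic editing).
#'
#' @param alignments Alignment data.frame with \code{mismatches} strings.
#' @param reads Read data.frame supplying read lengths.
#' @param w Exclusion window width in bases from each end.
#' @return \code{alignments} with added columns \code{kept_mismatches} and
#'   \code{terminal_excluded}.
#' @export
terminal_edit_filter <- function(alignments, reads, w = 1L) {
  stopifnot(w >= 0)
  len_of <- stats::setNames(nchar(reads$seq), reads$id)
  kept <- character(nrow(alignments))
  excl <- integer(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    mm <- parse_mismatches(alignments$mismatches[i])
    if (nrow(mm) == 0L) { kept[i] <- ""; next }
    L <- len_of[[alignments$read_id[i]]]
    terminal <- mm$offset <= w | mm$offset > L - w
    kept[i] <- paste(mm$spec[!terminal], collapse = ",")
    excl[i] <- sum(terminal)
  }
  alignments$kept_mismatches <- kept
  alignments$terminal_excluded <- excl
  alignments
}

#' Parse a mismatch descriptor string
#' @param x Single \code{"off:ref>read"} comma-joined string (may be empty).
#' @return data.frame with \code{offset, ref_base, read_base, spec}.
#' @export
parse_mismatches <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(offset = integer(), ref_base = character(),
                      read_base = character(), spec = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):([ACGTN])>([ACGTN])$", parts))
  data.frame(offset = as.integer(vapply(m, `[`, "", 2L)),
             ref_base = vapply(m, `[`, "", 3L),
             read_base = vapply(m, `[`, "", 4L),
             spec = parts, stringsAsFactors = FALSE)
}

#' One-sided binomial variant test in log10 space
#'
#' Tests whether \code{edited_cov} alternative-base observations out of
#' \code{total_cov} exceed what the per-base sequencing error rate explains:
#' returns \eqn{\log_{10} P[X \ge k]} for \eqn{X \sim Binomial(n, err)}.
#' Computed in the log domain, so tail probabilities far below the smallest
#' normal double (e.g. 1e-300) keep finite, accurate logs.
#'
#' @param edited_cov Alternative-base observation count (vectorized).
#' @param total_cov Total observation count.
#' @param err_rate Per-base error probability; the default 0.001 corresponds
#'   to Q30 base quality.
#' @return log10 of the tail p-value; 0 when \code{edited_cov} is 0 (p = 1);
#'   \code{NA} when \code{total_cov} is 0 (no coverage).
#' @export
variant_test <- function(edited_cov, total_cov, err_rate = 0.001) {
  if (any(err_rate <= 0 | err_rate >= 1)) stop("err_rate must be in (0, 1)")
  if (any(edited_cov < 0 | edited_cov > total_cov, na.rm = TRUE)) {
    stop("edited_cov must lie in [0, total_cov]")
  }
  out <- rep(NA_real_, length(edited_cov))
  nocov <- total_cov == 0
  zero <- !nocov & edited_cov == 0
  out[zero] <- 0
  ix <- !nocov & !zero
  out[ix] <- stats::pbinom(edited_cov[ix] - 1, total_cov[ix], err_rate,
                           lower.tail = FALSE, log.p = TRUE) / log(10)
  out
}

#' Edited-read percentage of a site
#'
#' @param edited_cov,total_cov Edited and total coverage (vectorized).
#' @param digits Reporting precision (decimal places, rounded half-up; full
#'   precision is retained internally wherever this feeds computation).
#' @return \code{100 * edited_cov / total_cov}, rounded half-up.
#' @export
editing_percentage <- function(edited_cov, total_cov, digits = 1L) {
  if (any(total_cov < 1)) stop("no coverage: total_cov must be >= 1")
  round_half_up(100 * edited_cov / total_cov, digits)
}

#' Round half away from zero
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector (ties like 0.05 go up, unlike [round()]).
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Call editing sites from feature pileups
#'
#' Emits C-to-T calls on CDS positions (C-to-U editing observed in DNA space)
#' or A-to-G calls on tRNA positions (A-to-I editing; inosine is read as G).
#' A site is called when the reference base matches the change type, at least
#' one alternative-base observation survived the terminal filter, coverage
#' meets \code{min_coverage}, and the binomial variant test is at most
#' \code{max_p}.
#'
#' @param pileups Pileup data.frame from [build_pileup()].
#' @param change \code{"C2T"} (CDS) or \code{"A2G"} (tRNA).
#' @param min_coverage Minimum total coverage (default 5).
#' @param max_p Maximum variant p-value (default 1e-2; stringent discovery
#'   uses 1e-10).
#' @param err_rate Per-base error rate for [variant_test()].
#' @param refs Optional \code{ReferenceSet}; when supplied, CDS calls are
#'   annotated with codon change, amino-acid change/position and genome
#'   coordinate.
#' @return data.frame of calls: \code{gene, cds_pos, change, ref_base,
#'   total_cov, edited_cov, percent, log10_p} plus annotation columns when
#'   \code{refs} is given.
#' @export
call_sites <- function(pileups, change = c("C2T", "A2G"), min_coverage = 5L,
                       max_p = 1e-2, err_rate = 0.001, refs = NULL) {
  change <- match.arg(change)
  ref_b <- if (change == "C2T") "C" else "A"
  alt_b <- if (change == "C2T") "T" else "G"
  ft <- if (change == "C2T") "CDS" else "tRNA"
  p <- pileups[pileups$ftype == ft & pileups$ref_base == ref_b, , drop = FALSE]
  if (nrow(p) == 0L) return(.empty_calls(change, !is.null(refs)))
  edited <- p[[alt_b]]
  log10_p <- variant_test(edited, p$depth, err_rate)
  keep <- p$depth >= min_coverage & edited >= 1 & log10_p <= log10(max_p)
  p <- p[keep, , drop = FALSE]
  edited <- edited[keep]
  if (nrow(p) == 0L) return(.empty_calls(change, !is.null(refs)))
  out <- data.frame(gene = p$gene, cds_pos = p$cds_pos, change = change,
                    ref_base = p$ref_base, total_cov = p$depth,
                    edited_cov = edited,
                    percent = if (nrow(p)) editing_percentage(edited, p$depth) else numeric(0),
                    log10_p = log10_p[keep], stringsAsFactors = FALSE)
  if (!is.null(refs)) out <- .annotate_calls(out, refs, alt_b)
  rownames(out) <- NULL
  out
}

.empty_calls <- function(change, annotated) {
  out <- data.frame(gene = character(), cds_pos = integer(), change = character(),
                    ref_base = character(), total_cov = numeric(),
                    edited_cov = numeric(), percent = numeric(),
                    log10_p = numeric(), stringsAsFactors = FALSE)
  if (annotated) {
    out$genome_pos <- integer()
    if (change == "C2T") {
      out$codon_change <- character(); out$aa_change <- character()
      out$aa_pos <- integer(); out$synonymous <- logical()
    }
  }
  out
}

.annotate_calls <- function(calls, refs, alt_b) {
  feats <- refs$features
  feat_seq <- .feature_sequences(refs)
  gpos <- integer(nrow(calls))
  codon_change <- aa_change <- rep(NA_character_, nrow(calls))
  aa_pos <- rep(NA_integer_, nrow(calls))
  syn <- rep(NA, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    f <- feats[feats$gene == calls$gene[i], ][1, ]
    gpos[i] <- cds_to_genome(f, calls$cds_pos[i])
    if (f$ftype == "CDS") {
      eff <- translate_effect(feat_seq[[calls$gene[i]]], calls$cds_pos[i], alt_b)
      codon_change[i] <- paste0(eff$ref_codon, "-", eff$alt_codon)
      aa_change[i] <- paste0(eff$ref_aa, "-", eff$alt_aa)
      aa_pos[i] <- eff$codon_index
      syn[i] <- eff$synonymous
    }
  }
  calls$genome_pos <- gpos
  if (alt_b == "T") {
    calls$codon_change <- codon_change
    calls$aa_change <- aa_change
    calls$aa_pos <- aa_pos
    calls$synonymous <- syn
  }
  calls
}
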