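#' Configuration for the tri-genome editing simulation
#'
#' Defines the study conditions emulated by the generator: a chloroplast
#' genome carrying CDS and tRNA features, a nuclear genome containing exact
#' plastid-derived insertions (NUPT decoys), a mitochondrial genome sharing no
#' 18-mer with the chloroplast, and a small-RNA library drawn from transcript
#' sense strands plus genomic background in fixed proportions. Per-genome read
#' proportions default to 45\% nuclear, 0.1\% mitochondrial, 23\% chloroplast
#' and the remainder unalignable background, the composition observed for a
#' total (non-enriched) Arabidopsis small-RNA library.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines every output.
#' @param cp_length,nuc_length,mt_length Genome lengths (bp).
#' @param n_genes,n_trnas Feature counts on the chloroplast genome.
#' @param insertion_count Number of exact chloroplast insertions (>= 50 bp)
#'   planted in the nuclear genome.
#' @param insertion_length Length of each planted insertion (bp).
#' @param edit_sites data.frame with \code{gene, cds_pos, rate, type}
#'   (\code{type} in \code{"C2U"}, \code{"A2I"}), or \code{NULL} for none.
#' @param read_count Total reads in the simulated library.
#' @param length_dist Integer read lengths sampled uniformly (default 18:24;
#'   50:150 in mRNA mode).
#' @param error_rate Per-base substitution error probability.
#' @param mrna_mode Simulate mRNA-length fragments instead of small RNAs.
#' @param proportions Named numeric: \code{cp}, \code{nuclear}, \code{mito};
#'   the remainder of the library is unalignable background.
#' @param cp_feature_frac Fraction of chloroplast reads drawn from feature
#'   (transcript sense) sequence; the rest comes from intergenic genome.
#' @param antisense_frac Fraction of feature reads emitted antisense
#'   (contamination knob; default 0).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, cp_length = 20000L, nuc_length = 50000L,
                       mt_length = 20000L, n_genes = 6L, n_trnas = 2L,
                       insertion_count = 2L, insertion_length = 200L,
                       edit_sites = NULL, read_count = 20000L,
                       length_dist = NULL, error_rate = 0.001,
                       mrna_mode = FALSE,
                       proportions = c(cp = 0.23, nuclear = 0.45, mito = 0.001),
                       cp_feature_frac = 0.7, antisense_frac = 0) {
  if (is.null(length_dist)) length_dist <- if (mrna_mode) 50:150 else 18:24
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (!all(c("cp", "nuclear", "mito") %in% names(proportions)) ||
      sum(proportions) > 1) {
    stop("proportions must name cp/nuclear/mito and sum to at most 1")
  }
  if (!is.null(edit_sites)) {
    if (!all(c("gene", "cds_pos", "rate", "type") %in% names(edit_sites))) {
      stop("edit_sites needs columns gene, cds_pos, rate, type")
    }
    if (any(edit_sites$rate < 0 | edit_sites$rate > 1)) stop("edit rates must lie in [0, 1]")
    if (!all(edit_sites$type %in% c("C2U", "A2I"))) stop("edit type must be C2U or A2I")
  }
  structure(list(seed = as.integer(seed), cp_length = cp_length,
                 nuc_length = nuc_length, mt_length = mt_length,
                 n_genes = n_genes, n_trnas = n_trnas,
                 insertion_count = insertion_count,
                 insertion_length = insertion_length,
                 edit_sites = edit_sites, read_count = read_count,
                 length_dist = length_dist, error_rate = error_rate,
                 mrna_mode = mrna_mode, proportions = proportions,
                 cp_feature_frac = cp_feature_frac,
                 antisense_frac = antisense_frac),
            class = "sim_config")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

.stop_codons <- c("TAA", "TAG", "TGA")

.random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, .stop_codons)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""), "TAA")
}

#' Simulate the tri-genome reference set
#'
#' Builds the chloroplast genome with \code{n_genes} CDS (ATG start, TAA
#' stop, no internal stop codons, length divisible by 3) and \code{n_trnas}
#' 74-nt tRNA genes on alternating strands, a nuclear genome with
#' \code{insertion_count} exact chloroplast sub-sequence insertions, and a
#' mitochondrial genome verified (by brute-force k-mer scan, with redraws) to
#' share no 18-mer with the chloroplast genome. The nuclear backbone is
#' likewise redrawn until it shares no 18-mer with the chloroplast outside
#' the planted insertions, so a nuclear-origin small RNA can exact-match the
#' chloroplast only from inside an insertion.
#'
#' @param cfg A [sim_config()].
#' @return A \code{ReferenceSet} whose sequences carry categories
#'   \code{chloroplast}/\code{nuclear}/\code{mitochondrial}/\code{cds}/\code{trna},
#'   with attribute \code{"insertions"} (data.frame of cp/nuclear insertion
#'   coordinates).
#' @export
simulate_references <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)

  gene_codons <- sample(100:200, cfg$n_genes, replace = TRUE)
  gene_len <- gene_codons * 3L
  trna_len <- rep(74L, cfg$n_trnas)
  feat_len <- c(gene_len, trna_len)
  gap <- 30L
  span <- sum(feat_len) + gap * (length(feat_len) + 1L)
  if (span > cfg$cp_length) {
    stop("configuration error: cp_length ", cfg$cp_length,
         " cannot hold ", cfg$n_genes, " genes + ", cfg$n_trnas,
         " tRNAs (need >= ", span, ")")
  }

  # sense sequences, then placement left to right with random extra gaps
  sense <- c(vapply(gene_codons, .random_cds, character(1)),
             vapply(trna_len, .random_dna, character(1)))
  gene <- c(sprintf("gene%02d", seq_len(cfg$n_genes)),
            sprintf("trna%02d", seq_len(cfg$n_trnas)))
  ftype <- c(rep("CDS", cfg$n_genes), rep("tRNA", cfg$n_trnas))
  strand <- rep(c("+", "-"), length.out = length(feat_len))
  slack <- cfg$cp_length - span
  extra <- if (length(feat_len) > 1) {
    tabulate(sample.int(length(feat_len), slack, replace = TRUE), nbins = length(feat_len))
  } else slack
  cp <- character(0)
  starts <- integer(length(feat_len))
  pos <- 0L
  for (i in seq_along(feat_len)) {
    pre <- gap + extra[i]
    cp <- c(cp, .random_dna(pre))
    pos <- pos + pre
    starts[i] <- pos + 1L
    placed <- if (strand[i] == "-") revcomp(sense[i]) else sense[i]
    cp <- c(cp, placed)
    pos <- pos + feat_len[i]
  }
  cp <- paste(c(cp, .random_dna(cfg$cp_length - pos)), collapse = "")

  feats <- feature_table(gene, ftype, "cp_genome",
                         lapply(seq_along(feat_len), function(i) {
                           cbind(starts[i], starts[i] + feat_len[i] - 1L)
                         }),
                         strand,
                         ifelse(ftype == "tRNA", "ACG", NA_character_))

  kmer_set <- function(s, k = 18L) {
    unique(substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s)))
  }
  cp_kmers <- kmer_set(cp)

  draw_clean <- function(n, what) {
    for (attempt in 1:50) {
      s <- .random_dna(n)
      if (!any(kmer_set(s) %in% cp_kmers)) return(s)
    }
    stop("could not draw a ", what, " genome free of shared chloroplast 18-mers")
  }
  nuc <- draw_clean(cfg$nuc_length, "nuclear")
  mt <- draw_clean(cfg$mt_length, "mitochondrial")

  ins <- data.frame(cp_start = integer(), cp_end = integer(),
                    nuc_start = integer(), nuc_end = integer())
  if (cfg$insertion_count > 0) {
    ilen <- cfg$insertion_length
    if (ilen < 50L) stop("insertion_length must be >= 50")
    nuc_starts <- sort(sample.int(cfg$nuc_length - ilen + 1L, cfg$insertion_count))
    if (cfg$insertion_count > 1 && any(diff(nuc_starts) < ilen + 20L)) {
      nuc_starts <- seq(1L, by = ilen + 500L, length.out = cfg$insertion_count)
    }
    cp_starts <- sample.int(cfg$cp_length - ilen + 1L, cfg$insertion_count)
    for (i in seq_len(cfg$insertion_count)) {
      block <- substring(cp, cp_starts[i], cp_starts[i] + ilen - 1L)
      substr(nuc, nuc_starts[i], nuc_starts[i] + ilen - 1L) <- block
      ins[i, ] <- c(cp_starts[i], cp_starts[i] + ilen - 1L,
                    nuc_starts[i], nuc_starts[i] + ilen - 1L)
    }
  }

  seqs <- c(cp_genome = cp, nuc_genome = nuc, mt_genome = mt,
            stats::setNames(sense, gene))
  cats <- c("chloroplast", "nuclear", "mitochondrial",
            ifelse(ftype == "CDS", "cds", "trna"))
  refs <- reference_set(seqs, cats, feats)
  attr(refs, "insertions") <- ins
  refs
}

#' Pick plantable editing sites in the simulated references
#'
#' Chooses positions carrying the editable base (C for C2U in CDS, A for A2I
#' in tRNA) away from read termini bias at feature edges.
#'
#' @param refs Simulated \code{ReferenceSet}.
#' @param rates Numeric vector of per-site true editing rates; one site is
#'   planted per rate.
#' @param type \code{"C2U"} or \code{"A2I"}.
#' @param seed Seed for the choice.
#' @return data.frame suitable as \code{edit_sites} in [sim_config()].
#' @export
plant_edit_sites <- function(refs, rates, type = c("C2U", "A2I"), seed = 1L) {
  type <- match.arg(type)
  withr::local_seed(seed)
  base <- if (type == "C2U") "C" else "A"
  want_ft <- if (type == "C2U") "CDS" else "tRNA"
  feats <- refs$features[refs$features$ftype == want_ft, , drop = FALSE]
  pool <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    g <- feats$gene[i]
    s <- refs$sequences[[g]]
    pos <- which(strsplit(s, "", fixed = TRUE)[[1]] == base)
    pos <- pos[pos > 25 & pos < nchar(s) - 25] # keep sites coverable by full reads
    if (!length(pos)) return(NULL)
    data.frame(gene = g, cds_pos = pos, stringsAsFactors = FALSE)
  }))
  if (nrow(pool) < length(rates)) stop("not enough ", base, " positions to plant sites")
  pick <- pool[sample.int(nrow(pool), length(rates)), , drop = FALSE]
  data.frame(gene = pick$gene, cds_pos = pick$cds_pos, rate = rates,
             type = type, stringsAsFactors = FALSE)
}

#' Simulate a small-RNA library with planted editing and a truth table
#'
#' Reads are drawn from feature sense sequences and intergenic chloroplast
#' windows, from the nuclear and mitochondrial genomes, and as unalignable
#' random background (rejection-sampled against all references at up to 2
#' mismatches). A read overlapping a planted site carries the edited base
#' independently with probability \code{rate}; sequencing errors are added
#' i.i.d. per base at \code{error_rate}.
#'
#' The truth table records, per read, its origin, coordinates, applied edits
#' and errors, and the partition class the read must fall into
#' (\code{expected_class}): exact substrings of a chloroplast target are
#' \code{cp_m0} (this includes nuclear reads drawn wholly inside a planted
#' insertion --- the decoy the chloroplast-first filtration exists for);
#' chloroplast-origin reads within 1--2 changes are \code{cp_m2}.
#'
#' @param refs Simulated \code{ReferenceSet} from [simulate_references()].
#' @param cfg The same [sim_config()].
#' @return List with \code{reads} (data.frame id/seq/qual), \code{truth}
#'   (per-read data.frame) and \code{site_truth} (per planted site:
#'   \code{n_reads_overlapping}, \code{n_reads_edited}).
#' @export
simulate_reads <- function(refs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed + 1L)
  feats <- refs$features
  nr <- cfg$read_count
  pr <- cfg$proportions
  n_cp <- round(nr * pr[["cp"]])
  n_nuc <- round(nr * pr[["nuclear"]])
  n_mt <- round(nr * pr[["mito"]])
  n_bg <- nr - n_cp - n_nuc - n_mt
  n_feat <- round(n_cp * cfg$cp_feature_frac)
  n_inter <- n_cp - n_feat

  lens_all <- cfg$length_dist
  sites <- cfg$edit_sites
  edit_base <- c(C2U = "T", A2I = "G")

  # --- feature (transcript sense) reads ---
  flen <- vapply(seq_len(nrow(feats)), function(i) feature_length(feats[i, ]), integer(1))
  usable <- flen >= max(min(lens_all), 18L)
  wt <- ifelse(usable, flen, 0L)
  fidx <- sample.int(nrow(feats), n_feat, replace = TRUE, prob = wt)
  rlen <- sample(lens_all, n_feat, replace = TRUE)
  rlen <- pmin(rlen, flen[fidx])
  rstart <- 1L + floor(stats::runif(n_feat) * (flen[fidx] - rlen + 1L))
  fseq <- refs$sequences[feats$gene]
  seq_feat <- substring(fseq[fidx], rstart, rstart + rlen - 1L)
  feat_gene <- feats$gene[fidx]

  n_edits <- integer(n_feat)
  edited_at <- character(n_feat)
  if (!is.null(sites) && nrow(sites) && n_feat) {
    for (s in seq_len(nrow(sites))) {
      gi <- sites$gene[s]; sp <- sites$cds_pos[s]
      cover <- which(feat_gene == gi & rstart <= sp & rstart + rlen - 1L >= sp)
      if (!length(cover)) next
      do_edit <- cover[stats::runif(length(cover)) < sites$rate[s]]
      if (length(do_edit)) {
        off <- sp - rstart[do_edit] + 1L
        seq_feat[do_edit] <- .set_bases(seq_feat[do_edit], off, edit_base[[sites$type[s]]])
        n_edits[do_edit] <- n_edits[do_edit] + 1L
        edited_at[do_edit] <- ifelse(nzchar(edited_at[do_edit]),
                                     paste0(edited_at[do_edit], ",", gi, ":", sp),
                                     paste0(gi, ":", sp))
      }
    }
  }
  antisense <- stats::runif(n_feat) < cfg$antisense_frac
  if (any(antisense)) seq_feat[antisense] <- vapply(seq_feat[antisense], revcomp, character(1))

  # --- intergenic chloroplast reads (forward strand, outside features) ---
  cp <- refs$sequences[["cp_genome"]]
  occupied <- rep(FALSE, nchar(cp))
  for (i in seq_len(nrow(feats))) {
    m <- feats$segments[[i]]
    for (s in seq_len(nrow(m))) occupied[m[s, 1]:m[s, 2]] <- TRUE
  }
  maxlen <- max(lens_all)
  ok_start <- which(!vapply(seq_len(nchar(cp) - maxlen + 1L), function(p) {
    any(occupied[p:(p + maxlen - 1L)])
  }, logical(1)))
  rlen_i <- sample(lens_all, n_inter, replace = TRUE)
  rstart_i <- sample(ok_start, n_inter, replace = TRUE)
  seq_inter <- substring(cp, rstart_i, rstart_i + rlen_i - 1L)

  # --- nuclear / mitochondrial background ---
  draw_genomic <- function(genome, n) {
    if (n == 0L) return(list(seq = character(0), start = integer(0), len = integer(0)))
    L <- sample(lens_all, n, replace = TRUE)
    st <- 1L + floor(stats::runif(n) * (nchar(genome) - L + 1L))
    list(seq = substring(genome, st, st + L - 1L), start = st, len = L)
  }
  nucr <- draw_genomic(refs$sequences[["nuc_genome"]], n_nuc)
  mtr <- draw_genomic(refs$sequences[["mt_genome"]], n_mt)

  # --- unalignable background: rejection-sampled random reads ---
  all_refs <- unname(refs$sequences)
  bg <- character(0)
  while (length(bg) < n_bg) {
    need <- n_bg - length(bg)
    cand <- vapply(sample(lens_all, need + 10L, replace = TRUE), .random_dna, character(1))
    hit <- has_hit_cpp(cand, all_refs, 2L)
    bg <- c(bg, cand[!hit])
  }
  bg <- bg[seq_len(n_bg)]

  origin <- c(rep("cp_feature", n_feat), rep("cp_intergenic", n_inter),
              rep("nuclear", n_nuc), rep("mito", n_mt), rep("background", n_bg))
  seqs <- c(seq_feat, seq_inter, nucr$seq, mtr$seq, bg)
  src <- c(feat_gene, rep("cp_genome", n_inter), rep("nuc_genome", n_nuc),
           rep("mt_genome", n_mt), rep(NA_character_, n_bg))
  start <- c(rstart, rstart_i, nucr$start, mtr$start, rep(NA_integer_, n_bg))
  n_edits <- c(n_edits, integer(n_inter + n_nuc + n_mt + n_bg))
  edited_at <- c(edited_at, character(n_inter + n_nuc + n_mt + n_bg))

  # --- sequencing errors ---
  n_err <- integer(length(seqs))
  if (cfg$error_rate > 0) {
    lens <- nchar(seqs)
    k <- stats::rbinom(length(seqs), lens, cfg$error_rate)
    for (i in which(k > 0)) {
      pos <- sample.int(lens[i], k[i])
      for (p in pos) {
        cur <- substring(seqs[i], p, p)
        sub <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        substr(seqs[i], p, p) <- sub
      }
      n_err[i] <- k[i]
    }
  }

  ids <- sprintf("read%06d", seq_along(seqs))
  reads <- data.frame(id = ids, seq = seqs,
                      qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)

  anti <- c(antisense, rep(FALSE, n_inter + n_nuc + n_mt + n_bg))
  expected <- .expected_class(seqs, origin, n_edits + n_err, anti, refs)
  truth <- data.frame(id = ids, origin = origin, src = src, start = start,
                      length = nchar(seqs), n_edits = n_edits, n_errors = n_err,
                      antisense = anti, edited_sites = edited_at,
                      expected_class = expected, stringsAsFactors = FALSE)

  site_truth <- NULL
  if (!is.null(sites) && nrow(sites)) {
    ov <- integer(nrow(sites)); ed <- integer(nrow(sites))
    for (s in seq_len(nrow(sites))) {
      key <- paste0(sites$gene[s], ":", sites$cds_pos[s])
      cover <- origin == "cp_feature" & src == sites$gene[s] &
        start <= sites$cds_pos[s] & start + nchar(seqs) - 1L >= sites$cds_pos[s]
      ov[s] <- sum(cover)
      ed[s] <- sum(cover & grepl(key, edited_at, fixed = TRUE))
    }
    site_truth <- cbind(sites, n_reads_overlapping = ov, n_reads_edited = ed)
  }
  list(reads = reads, truth = truth, site_truth = site_truth)
}

.set_bases <- function(x, offset, base) {
  for (i in seq_along(x)) substr(x[i], offset[i], offset[i]) <- base
  x
}

# Expected partition class of each simulated read, derived independently of
# the mapper: exact-match membership is decided by hashing every window of the
# target sequences at the read lengths present, so it mirrors the stage order
# (chloroplast m0, then nuclear, then mitochondrial, then chloroplast <= 2
# changes from origin). Exact when error_rate = 0; with sequencing errors the
# cp_m2 label is approximate for the rare read whose errors collide.
.expected_class <- function(seqs, origin, n_changes, antisense, refs) {
  lens <- sort(unique(nchar(seqs)))
  window_set <- function(targets) {
    unlist(lapply(targets, function(t) {
      n <- nchar(t)
      unlist(lapply(lens[lens <= n], function(L) {
        substring(t, seq_len(n - L + 1L), L:n)
      }))
    }), use.names = FALSE)
  }
  cp_set <- window_set(refs$sequences[refs$categories %in% c("chloroplast", "cds", "trna")])
  nuc_set <- window_set(refs$sequences[refs$categories == "nuclear"])
  mt_set <- window_set(refs$sequences[refs$categories == "mitochondrial"])

  out <- rep("unaligned", length(seqs))
  m0 <- seqs %in% cp_set
  out[m0] <- "cp_m0"
  rest <- !m0
  nuc_hit <- rest & seqs %in% nuc_set
  out[nuc_hit] <- "nuclear"
  rest <- rest & !nuc_hit
  mt_hit <- rest & seqs %in% mt_set
  out[mt_hit] <- "mito"
  rest <- rest & !mt_hit
  cp_origin <- origin %in% c("cp_feature", "cp_intergenic")
  out[rest & cp_origin & !antisense & n_changes >= 1 & n_changes <= 2] <- "cp_m2"
  out
}
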