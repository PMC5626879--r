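# Hand-built tiny reference fixtures and independent oracles shared by the
# unit tests. Oracles here are deliberately naive (full scans, direct sums) so
# they stay independent of the package's seeded/log-domain implementations.

# A small ReferenceSet with a plus-strand CDS, a spliced minus-strand CDS, a
# tRNA, a nuclear genome carrying one exact chloroplast insertion (NUPT
# decoy), and a mitochondrial genome.
tiny_refs <- function() {
  cds1 <- "ATGCCTCATTCACTATAA"                  # + strand, 18 nt
  cds2 <- "ATGTCATCGGGACATTAA"                  # - strand, spliced 9 + 9
  trna1 <- withr::with_seed(4242, random_dna(74)) # non-repetitive 74 nt
  substr(trna1, 34, 35) <- "AA"                 # anticodon wobble candidates
  spacer <- function(n, b = "G") strrep(b, n)

  seg2b_g <- revcomp(substr(cds2, 10, 18))      # transcript 2nd half, earlier on genome? see below
  seg2a_g <- revcomp(substr(cds2, 1, 9))
  # genome layout: [10] cds1 [8 intron-ish] seg2b_g [6] seg2a_g [10] trna1 [10]
  genome <- paste0(spacer(10, "A"), cds1, spacer(8, "C"), seg2b_g,
                   spacer(6, "T"), seg2a_g, spacer(10, "A"), trna1, spacer(10, "C"))
  s_cds1 <- 11L
  s_seg2b <- s_cds1 + 18L + 8L
  s_seg2a <- s_seg2b + 9L + 6L
  s_trna <- s_seg2a + 9L + 10L
  feats <- feature_table(
    gene = c("cdsA", "cdsB", "trnX"),
    ftype = c("CDS", "CDS", "tRNA"),
    genome_ref = "cp",
    segments = list(cbind(s_cds1, s_cds1 + 17L),
                    # transcript order for minus strand: seg2a (later on genome) first
                    rbind(c(s_seg2a, s_seg2a + 8L), c(s_seg2b, s_seg2b + 8L)),
                    cbind(s_trna, s_trna + 73L)),
    strand = c("+", "-", "+"),
    anticodon = c(NA, NA, "ACG"))
  nupt <- substr(genome, s_cds1, s_cds1 + 17L)  # exact cds1 copy in the nuclear genome
  nuclear <- paste0(strrep("TTAGGCAT", 6), nupt, strrep("CCGATA", 6))
  mito <- strrep("TTGACA", 12)
  reference_set(
    c(cp = genome, nuc = nuclear, mt = mito,
      cdsA = cds1, cdsB = cds2, trnX = trna1),
    c("chloroplast", "nuclear", "mitochondrial", "cds", "cds", "trna"),
    feats)
}

read_df <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(seqs))
  data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

# Brute-force forward-strand Hamming scan over every window of every
# reference: the alignment oracle. Returns all loci at distance <= max_mm.
brute_scan <- function(read, refs, max_mm) {
  rchars <- strsplit(read, "")[[1]]
  L <- length(rchars)
  out <- list()
  for (rid in names(refs)) {
    schars <- strsplit(refs[[rid]], "")[[1]]
    n <- length(schars)
    if (n < L) next
    for (p in seq_len(n - L + 1L)) {
      w <- schars[p:(p + L - 1L)]
      d <- sum(w != rchars | !rchars %in% c("A", "C", "G", "T"))
      if (d <= max_mm) out[[length(out) + 1L]] <- data.frame(
        ref_id = rid, start = p, nm = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(ref_id = character(), start = integer(), nm = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# best-stratum subset of the brute scan, for direct comparison with map_read
brute_best <- function(read, refs, max_mm) {
  hits <- brute_scan(read, refs, max_mm)
  if (!nrow(hits)) return(hits)
  hits[hits$nm == min(hits$nm), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# mutate a string at k random positions (guaranteed substitutions)
mutate_string <- function(x, k) {
  pos <- sample.int(nchar(x), k)
  for (p in pos) {
    cur <- substr(x, p, p)
    substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  x
}

# direct log10 binomial tail by summation in log space (independent of pbinom)
direct_log10_tail <- function(k, n, p) {
  if (k == 0) return(0)
  terms <- vapply(k:n, function(x) {
    lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)
  }, numeric(1))
  m <- max(terms)
  (m + log(sum(exp(terms - m)))) / log(10)
}
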