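#' Pigeonhole seed segmentation of a read
#'
#' Splits a read into \code{max_mm + 1} contiguous near-equal segments. Any
#' ungapped alignment of the read with at most \code{max_mm} substitutions
#' must contain at least one segment that matches the reference exactly
#' (pigeonhole principle), so exact hits of these segments enumerate every
#' candidate locus; candidates are then verified by full Hamming comparison.
#'
#' @param read Read sequence (character scalar).
#' @param max_mm Maximum number of substitutions (0, 1 or 2 in this pipeline).
#' @return data.frame with \code{offset} (1-based start in the read),
#'   \code{length} and \code{segment}.
#' @export
pigeonhole_seeds <- function(read, max_mm) {
  stopifnot(max_mm >= 0)
  L <- nchar(read)
  nseg <- as.integer(max_mm) + 1L
  base <- L %/% nseg
  rem <- L %% nseg
  lens <- rep(base, nseg) + c(rep(1L, rem), rep(0L, nseg - rem))
  offs <- cumsum(c(1L, lens[-nseg]))
  data.frame(offset = offs, length = lens,
             segment = substring(read, offs, offs + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Align reads to the forward strand of references at bounded mismatch count
#'
#' Substitution-only, ungapped, strand-specific alignment: a read is compared
#' against every same-length window of the forward strand of each reference,
#' and all loci within \code{max_mm} mismatches are found. Only the
#' minimal-mismatch stratum is reported (all of it), with
#' \code{n_best_loci} set to the stratum size on each record. Reverse
#' complements are never searched: plastid small RNAs are treated as sense
#' transcript fragments and antisense hits must not be mistaken for editing.
#'
#' @param reads Read data.frame ([read_reads()]) or character vector.
#' @param refs \code{ReferenceSet}, or named character vector of sequences.
#' @param max_mm Maximum Hamming distance (0 or 2 in the standard pipeline).
#' @return data.frame with columns \code{read_id, ref_id, start} (1-based),
#'   \code{nm}, \code{mismatches} (\code{"off:ref>read"} comma-joined, offsets
#'   1-based in the alignment) and \code{n_best_loci}. Zero rows when nothing
#'   aligns (a read longer than every reference is simply unaligned).
#' @export
map_read <- function(reads, refs, max_mm = 0L) {
  if (is.character(reads)) {
    ids <- if (is.null(names(reads))) paste0("read", seq_along(reads)) else names(reads)
    reads <- data.frame(id = ids, seq = unname(reads), stringsAsFactors = FALSE)
  }
  seqs <- .ref_seqs(refs)
  if (!all(max_mm %in% 0:2)) stop("max_mm must be 0, 1 or 2")
  map_reads_cpp(reads$seq, reads$id, unname(seqs), names(seqs), as.integer(max_mm))
}

.ref_seqs <- function(refs, categories = NULL) {
  if (inherits(refs, "ReferenceSet")) {
    seqs <- refs$sequences
    if (!is.null(categories)) seqs <- seqs[refs$categories %in% categories]
    return(seqs)
  }
  if (is.null(names(refs))) stop("reference sequences must be named")
  refs
}

PARTITION_CLASSES <- c("cp_m0", "nuclear", "mito", "cp_m2", "unaligned")

#' Hierarchical read partition against chloroplast, nuclear and mitochondrial references
#'
#' The four-step filtration at the core of the pipeline:
#' \enumerate{
#'   \item reads are mapped at 0 mismatches against the chloroplast targets
#'     (genome + coding sequences + tRNAs); hits are class \code{cp_m0}
#'     (unedited chloroplast evidence). Mapping chloroplast-first prevents
#'     unedited reads from being absorbed by plastid DNA insertions in the
#'     nuclear genome (NUPTs);
#'   \item survivors are mapped at 0 mismatches against the nuclear genome and
#'     then the mitochondrial genome; hits are discarded (classes
#'     \code{nuclear}, \code{mito}; a read matching both counts as nuclear);
#'   \item survivors are remapped against the chloroplast targets at up to 2
#'     mismatches; hits are class \code{cp_m2} (editing-informative);
#'   \item the rest is \code{unaligned}.
#' }
#' Retained alignments are the union of the cp_m0 and cp_m2 hits.
#'
#' Reads containing N are never searched (mismatch semantics are undefined for
#' N); they are classed \code{unaligned} and additionally tallied in
#' \code{discarded_n}.
#'
#' @param reads Read data.frame.
#' @param refs \code{ReferenceSet} containing at least one sequence of each of
#'   the categories \code{chloroplast}, \code{nuclear}, \code{mitochondrial}.
#' @param max_mm_final Mismatch allowance of the final chloroplast pass.
#' @return List with \code{classes} (data.frame \code{read_id, class}),
#'   \code{counts} (named vector over the five classes), \code{alignments}
#'   (retained cp_m0 + cp_m2 records with a \code{stage} column) and
#'   \code{discarded_n}.
#' @export
hierarchical_partition <- function(reads, refs, max_mm_final = 2L) {
  if (!inherits(refs, "ReferenceSet")) stop("refs must be a ReferenceSet")
  for (cat in c("chloroplast", "nuclear", "mitochondrial")) {
    if (!any(refs$categories == cat)) {
      stop("configuration error: reference set has no '", cat, "' sequence")
    }
  }
  cp_targets <- .ref_seqs(refs, c("chloroplast", "cds", "trna"))
  nuc <- .ref_seqs(refs, "nuclear")
  mito <- .ref_seqs(refs, "mitochondrial")

  dn <- drop_n_reads(reads)
  clean <- dn$reads
  class <- stats::setNames(rep("unaligned", nrow(reads)), reads$id)

  aln_m0 <- map_read(clean, cp_targets, max_mm = 0L)
  hit1 <- unique(aln_m0$read_id)
  class[hit1] <- "cp_m0"
  rest <- clean[!clean$id %in% hit1, , drop = FALSE]

  aln_nuc <- map_read(rest, nuc, max_mm = 0L)
  class[unique(aln_nuc$read_id)] <- "nuclear"
  rest <- rest[!rest$id %in% aln_nuc$read_id, , drop = FALSE]
  aln_mito <- map_read(rest, mito, max_mm = 0L)
  class[unique(aln_mito$read_id)] <- "mito"
  rest <- rest[!rest$id %in% aln_mito$read_id, , drop = FALSE]

  aln_m2 <- map_read(rest, cp_targets, max_mm = as.integer(max_mm_final))
  class[unique(aln_m2$read_id)] <- "cp_m2"

  if (nrow(aln_m0)) aln_m0$stage <- "m0"
  if (nrow(aln_m2)) aln_m2$stage <- "m2"
  retained <- rbind(
    if (nrow(aln_m0)) aln_m0 else NULL,
    if (nrow(aln_m2)) aln_m2 else NULL
  )
  if (is.null(retained)) {
    retained <- data.frame(read_id = character(), ref_id = character(),
                           start = integer(), nm = integer(),
                           mismatches = character(), n_best_loci = integer(),
                           stage = character(), stringsAsFactors = FALSE)
  }
  counts <- vapply(PARTITION_CLASSES, function(k) sum(class == k), integer(1))
  list(classes = data.frame(read_id = reads$id, class = unname(class[reads$id]),
                            stringsAsFactors = FALSE),
       counts = counts, alignments = retained, discarded_n = dn$discarded_n)
}

#' Partition summary table (library composition report)
#'
#' One-row summary of a hierarchical partition in the shape used for
#' library-composition reporting: total reads, nuclear, mitochondrial,
#' chloroplast at 0 mismatches (m0), chloroplast rescued at up to 2 mismatches
#' (m2), chloroplast total and unaligned, each with its percentage of the
#' library to 2 decimals.
#'
#' @param counts Named class-count vector from [hierarchical_partition()].
#' @return data.frame with \code{class}, \code{reads} and \code{percent}.
#' @export
partition_summary <- function(counts) {
  total <- sum(counts)
  rows <- c(total = total,
            nuclear = counts[["nuclear"]],
            mtDNA = counts[["mito"]],
            cpDNA_m0 = counts[["cp_m0"]],
            cpDNA_m2 = counts[["cp_m2"]],
            cpDNA_total = counts[["cp_m0"]] + counts[["cp_m2"]],
            not_aligned = counts[["unaligned"]])
  data.frame(class = names(rows), reads = unname(rows),
             percent = round(100 * unname(rows) / total, 2),
             stringsAsFactors = FALSE)
}
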