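#' @useDynLib srnaedit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

REF_CATEGORIES <- c("chloroplast", "nuclear", "mitochondrial", "cds", "trna")

#' Read a FASTA file of reference sequences
#'
#' Sequences are uppercased and U is converted to T, so RNA-space FASTA is
#' accepted; editing changes are described in the DNA alphabet (C-to-T)
#' throughout the package. Only \code{A,C,G,T,N} are allowed after
#' normalization.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    stop("FASTA parse error in '", path, "': empty sequence for record ", bad,
         " ('", names(seqs)[bad], "') near line ", .fasta_record_line(path, bad))
  }
  bad_alpha <- grepl("[^ACGTN]", seqs)
  if (any(bad_alpha)) {
    stop("FASTA record '", names(seqs)[which(bad_alpha)[1]],
         "' contains characters outside {A,C,G,T,N,U}")
  }
  seqs
}

.fasta_record_line <- function(path, record) {
  hdr <- grep("^>", readLines(path, warn = FALSE))
  if (record <= length(hdr)) hdr[record] else NA_integer_
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read small-RNA (or mRNA) reads from FASTQ or FASTA
#'
#' @param path Input file.
#' @param format \code{"auto"} (by extension / first byte), \code{"fastq"} or
#'   \code{"fasta"}.
#' @return A data.frame with columns \code{id}, \code{seq} and \code{qual}
#'   (Sanger Phred+33 string, \code{NA} for FASTA input), in file order.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq"
      else if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) "fasta"
      else {
        first <- substr(readLines(path, n = 1L, warn = FALSE)[1], 1, 1)
        if (identical(first, "@")) "fastq" else "fasta"
      }
  }
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  if (format == "fasta") {
    seqs <- read_fasta(path)
    return(data.frame(id = names(seqs), seq = unname(seqs), qual = NA_character_,
                      stringsAsFactors = FALSE))
  }
  .validate_fastq(path)
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(seq = toupper(chartr("U", "T", as.character(x))),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         ids = names(x))
  }, error = function(e) {
    stop("FASTQ parse error in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  seq <- parsed$seq
  qual <- parsed$qual
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("FASTQ parse error in '", path, "': record ", bad[1], " ('",
         parsed$ids[bad[1]], "') has ", nchar(seq[bad[1]]), " bases but ",
         nchar(qual[bad[1]]), " quality characters")
  }
  data.frame(id = sub("\\s.*$", "", parsed$ids), seq = unname(seq),
             qual = unname(qual), stringsAsFactors = FALSE)
}

# structural check of 4-line FASTQ records; catches sequence/quality length
# disagreements before the binary parser sees them
.validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error in '", path, "': ", length(lines),
         " lines is not a multiple of 4")
  }
  seq_len_b <- nchar(lines[seq(2L, length(lines), by = 4L)], type = "bytes")
  qual_len_b <- nchar(lines[seq(4L, length(lines), by = 4L)], type = "bytes")
  bad <- which(seq_len_b != qual_len_b)
  if (length(bad)) {
    stop("FASTQ parse error in '", path, "': record ", bad[1], " (line ",
         4L * (bad[1] - 1L) + 1L, ") has ", seq_len_b[bad[1]], " bases but ",
         qual_len_b[bad[1]], " quality characters")
  }
  invisible(TRUE)
}

#' Write reads to FASTQ (or FASTA when no qualities are present)
#'
#' @param reads Read data.frame as returned by [read_reads()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  if (!is.null(reads$qual) && all(!is.na(reads$qual))) {
    q <- Biostrings::PhredQuality(reads$qual)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = Biostrings::BStringSet(q))
  } else {
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Select reads by length
#'
#' Small-RNA analysis keeps 18--24 nt reads; set \code{mrna_mode = TRUE} to
#' disable the filter for mRNA libraries.
#'
#' @param reads Read data.frame.
#' @param min_len,max_len Inclusive length bounds.
#' @param mrna_mode If \code{TRUE}, keep every read regardless of length.
#' @return The filtered data.frame, input order preserved.
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 24L, mrna_mode = FALSE) {
  if (mrna_mode) return(reads)
  if (min_len > max_len) stop("configuration error: min_len (", min_len,
                              ") > max_len (", max_len, ")")
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Build a feature table row set
#'
#' Features are stored one row per gene with a list-column \code{segments} of
#' two-column (start, end) integer matrices in 1-based inclusive genome
#' coordinates, ordered 5'--3' in transcript orientation (descending genome
#' coordinates on the minus strand).
#'
#' @param gene,ftype,genome_ref,strand,anticodon Per-feature scalars;
#'   \code{ftype} is \code{"CDS"} or \code{"tRNA"}.
#' @param segments A list of two-column matrices, one per feature.
#' @return A data.frame feature table.
#' @export
feature_table <- function(gene, ftype, genome_ref, segments, strand,
                          anticodon = NA_character_) {
  stopifnot(all(ftype %in% c("CDS", "tRNA")), all(strand %in% c("+", "-")))
  df <- data.frame(gene = gene, ftype = ftype, genome_ref = genome_ref,
                   strand = strand,
                   anticodon = rep_len(anticodon, length(gene)),
                   stringsAsFactors = FALSE)
  df$segments <- lapply(segments, function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    colnames(m) <- c("start", "end")
    if (any(m[, 1] > m[, 2])) stop("feature segment with start > end")
    m
  })
  df
}

feature_length <- function(feature_row) {
  m <- feature_row$segments[[1]]
  sum(m[, 2] - m[, 1] + 1L)
}

#' Extract the spliced, strand-corrected sequence of a feature
#'
#' Concatenates the feature's segments in transcript order and reverse
#' complements minus-strand segments, yielding the sense (transcript
#' orientation) sequence.
#'
#' @param genome_seq Genome sequence (character scalar).
#' @param feature_row One-row slice of a feature table.
#' @return Character scalar sense sequence.
#' @export
extract_feature_sequence <- function(genome_seq, feature_row) {
  m <- feature_row$segments[[1]]
  glen <- nchar(genome_seq)
  if (any(m < 1L) || any(m > glen)) {
    stop("coordinate error: feature '", feature_row$gene,
         "' has a segment outside the genome (length ", glen, ")")
  }
  parts <- substring(genome_seq, m[, 1], m[, 2])
  if (feature_row$strand == "-") parts <- vapply(parts, revcomp, character(1))
  paste(parts, collapse = "")
}

#' Reverse complement of a DNA string
#' @param x Character scalar over \code{A,C,G,T,N}.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Assemble a validated reference set
#'
#' Bundles genome/feature-extract sequences with their categories and the
#' feature annotation, checking the cross-consistency the downstream stages
#' rely on: every cds/trna sequence must equal the spliced, strand-corrected
#' extraction of its feature from the stored genome.
#'
#' @param sequences Named character vector of sequences.
#' @param categories Character vector (parallel to \code{sequences}) over
#'   \code{chloroplast, nuclear, mitochondrial, cds, trna}.
#' @param features Feature table ([feature_table()]); cds/trna sequence names
#'   must match \code{features$gene}.
#' @return An object of class \code{ReferenceSet}.
#' @export
reference_set <- function(sequences, categories, features = NULL) {
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence ids in reference set: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  }
  if (length(categories) != length(sequences)) stop("one category per sequence required")
  if (!all(categories %in% REF_CATEGORIES)) {
    stop("unknown reference category: ",
         paste(setdiff(categories, REF_CATEGORIES), collapse = ", "))
  }
  if (any(grepl("[^ACGTN]", sequences)) || any(!nzchar(sequences))) {
    stop("reference sequences must be non-empty over {A,C,G,T,N}")
  }
  names(categories) <- names(sequences)
  obj <- structure(list(sequences = sequences, categories = categories,
                        features = features), class = "ReferenceSet")
  if (!is.null(features)) {
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      gen <- sequences[f$genome_ref]
      if (is.na(gen)) stop("feature '", f$gene, "' refers to unknown genome '", f$genome_ref, "'")
      if (f$ftype == "CDS" && feature_length(f) %% 3L != 0L) {
        stop("CDS feature '", f$gene, "' has spliced length not divisible by 3")
      }
      if (f$gene %in% names(sequences)) {
        expected <- extract_feature_sequence(gen, f)
        if (!identical(unname(sequences[f$gene]), expected)) {
          stop("sequence '", f$gene, "' does not match its feature extraction from '",
               f$genome_ref, "'")
        }
      }
    }
  }
  obj
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", length(x$sequences), "sequences (",
      paste(names(table(x$categories)), table(x$categories), collapse = ", "), ")\n")
  if (!is.null(x$features)) cat("  features:", nrow(x$features), "(",
                                sum(x$features$ftype == "CDS"), "CDS,",
                                sum(x$features$ftype == "tRNA"), "tRNA )\n")
  invisible(x)
}

#' Read feature annotation from TSV or GFF3
#'
#' The native format is a 6-column TSV: \code{gene, type, ref, segments,
#' strand, anticodon}, where \code{segments} is \code{"start-end[,start-end]"}
#' (1-based inclusive, transcript order) and \code{anticodon} may be
#' \code{"."}. Files ending in \code{.gff}/\code{.gff3} are imported as GFF3
#' (CDS and tRNA features, grouped by their \code{gene} attribute).
#'
#' @param path Annotation file.
#' @return A feature table.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) return(.read_annotation_gff3(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "type", "ref", "segments", "strand", "anticodon")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  segs <- lapply(strsplit(df$segments, ",", fixed = TRUE), function(parts) {
    m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
    colnames(m) <- c("start", "end"); m
  })
  anticodon <- ifelse(df$anticodon %in% c(".", ""), NA_character_, df$anticodon)
  feature_table(df$gene, df$type, df$ref, segs, df$strand, anticodon)
}

.read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package; use the TSV format otherwise")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "tRNA")]
  if (!length(gr)) stop("no CDS/tRNA features found in ", path)
  gene <- as.character(gr$gene)
  if (anyNA(gene)) stop("GFF3 CDS/tRNA features must carry a 'gene' attribute")
  key <- paste(gene, as.character(gr$type))
  rows <- lapply(split(seq_along(gr), key), function(ix) {
    g <- gr[ix]
    strand <- as.character(BiocGenerics::strand(g))[1]
    m <- cbind(start = BiocGenerics::start(g), end = BiocGenerics::end(g))
    m <- m[order(m[, 1], decreasing = (strand == "-")), , drop = FALSE]
    ac <- if ("anticodon" %in% names(S4Vectors::mcols(g))) as.character(g$anticodon)[1] else NA_character_
    list(gene = as.character(g$gene)[1], ftype = as.character(g$type)[1],
         ref = as.character(GenomeInfoDb::seqnames(g))[1], segments = m,
         strand = strand, anticodon = ac)
  })
  feature_table(vapply(rows, `[[`, "", "gene"),
                vapply(rows, `[[`, "", "ftype"),
                vapply(rows, `[[`, "", "ref"),
                lapply(rows, `[[`, "segments"),
                vapply(rows, `[[`, "", "strand"),
                vapply(rows, `[[`, "", "anticodon"))
}

#' Write feature annotation to the 6-column TSV format
#' @param features Feature table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(features, path) {
  segs <- vapply(features$segments, function(m) {
    paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
  }, character(1))
  df <- data.frame(gene = features$gene, type = features$ftype,
                   ref = features$genome_ref, segments = segs,
                   strand = features$strand,
                   anticodon = ifelse(is.na(features$anticodon), ".", features$anticodon),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predicted-editing-site table
#'
#' Expects a TSV with header \code{gene, cds_pos, codon_change, aa_change,
#' score}; \code{codon_change} is of the form \code{"TCA-TTA"}. Such tables
#' come from conservation-based plastid editing-site predictors, which score
#' candidate C-to-U sites in coding sequences between 0 and 1.
#'
#' @param path TSV path.
#' @return A data.frame with the five columns plus split \code{ref_codon} /
#'   \code{edit_codon}.
#' @export
read_predicted_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "cds_pos", "codon_change", "aa_change", "score")
  if (!all(need %in% names(df))) {
    stop("predicted-site TSV must have columns: ", paste(need, collapse = ", "))
  }
  df$cds_pos <- as.integer(df$cds_pos)
  df$score <- as.numeric(df$score)
  if (any(!is.na(df$score) & (df$score < 0 | df$score > 1))) {
    stop("predicted-site scores must lie in [0, 1]")
  }
  cc <- strsplit(df$codon_change, "-", fixed = TRUE)
  df$ref_codon <- vapply(cc, `[`, "", 1L)
  df$edit_codon <- vapply(cc, `[`, "", 2L)
  df
}

#' Drop reads containing ambiguous bases
#'
#' Mismatch-bounded alignment is undefined for N, so reads containing N are
#' removed before mapping and tallied.
#'
#' @param reads Read data.frame.
#' @return List with \code{reads} (clean subset) and \code{discarded_n} count.
#' @export
drop_n_reads <- function(reads) {
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  list(reads = reads[!has_n, , drop = FALSE], discarded_n = sum(has_n))
}
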