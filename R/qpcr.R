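#' RNA-editing percentage from allele-specific qPCR Ct values
#'
#' Converts cycle-threshold measurements of the edited (T) and unedited (C)
#' variant-specific primers into a percent editing, using the logistic form
#' in base 2 of the Ct difference:
#' \deqn{\%\,editing = 100 \cdot \frac{2^{d}}{2^{d} + 1}, \quad
#'       d = \overline{Ct}_T - \overline{Ct}_C}
#' As written, a higher mean Ct of the T variant yields a higher percentage;
#' \code{flip_sign = TRUE} computes with \eqn{d' = -d} for users who read
#' lower Ct as higher template abundance (see the methods vignette for the
#' discussion of this sign convention). Amplification efficiency is fixed at
#' the base 2; no efficiency correction is applied.
#'
#' @param ct_t,ct_c Numeric Ct replicate vectors for the T (edited) and C
#'   (unedited) variant primers; at least one finite positive value each.
#' @param flip_sign Negate the Ct difference before the logistic transform.
#' @return Percent editing in (0, 100).
#' @export
editing_rate_from_ct <- function(ct_t, ct_c, flip_sign = FALSE) {
  for (v in list(ct_t, ct_c)) {
    if (!length(v)) stop("data error: empty Ct replicate list")
    if (any(!is.finite(v)) || any(v <= 0)) stop("data error: Ct values must be finite and > 0")
  }
  d <- mean(ct_t) - mean(ct_c)
  if (flip_sign) d <- -d
  100 * stats::plogis(d * log(2))
}

#' Read an allele-specific qPCR Ct table
#'
#' TSV with columns \code{sample, tissue, gene, cds_pos, variant, ct};
#' \code{variant} is \code{"T"} (edited primer) or \code{"C"} (unedited
#' primer), \code{sample} identifies the biological replicate.
#'
#' @param path TSV path.
#' @return data.frame of measurements.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "tissue", "gene", "cds_pos", "variant", "ct")
  if (!all(need %in% names(df))) {
    stop("qPCR TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$variant %in% c("T", "C"))) stop("qPCR variant must be 'T' or 'C'")
  df$ct <- as.numeric(df$ct)
  df$cds_pos <- as.integer(df$cds_pos)
  df
}

#' Per-replicate editing rates from a qPCR measurement table
#'
#' Technical replicates (rows sharing sample/tissue/site/variant) are averaged
#' into the Ct mean entering [editing_rate_from_ct()].
#'
#' @param measurements data.frame from [read_qpcr_table()].
#' @param flip_sign Passed to [editing_rate_from_ct()].
#' @return data.frame with one row per (gene, cds_pos, tissue, sample) and a
#'   \code{percent} column.
#' @export
qpcr_editing_rates <- function(measurements, flip_sign = FALSE) {
  key <- interaction(measurements$gene, measurements$cds_pos,
                     measurements$tissue, measurements$sample, drop = TRUE)
  rows <- lapply(split(measurements, key), function(m) {
    ct_t <- m$ct[m$variant == "T"]
    ct_c <- m$ct[m$variant == "C"]
    if (!length(ct_t) || !length(ct_c)) {
      stop("data error: sample '", m$sample[1], "' site ", m$gene[1], ":",
           m$cds_pos[1], " lacks a T or C variant measurement")
    }
    data.frame(gene = m$gene[1], cds_pos = m$cds_pos[1], tissue = m$tissue[1],
               sample = m$sample[1],
               percent = editing_rate_from_ct(ct_t, ct_c, flip_sign),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize editing rates per tissue over biological replicates
#'
#' Boxplot-style summary: the median over replicates, with the lowest and
#' highest observed editing value as whiskers.
#'
#' @param rates Per-replicate rates from [qpcr_editing_rates()].
#' @return data.frame with one row per (gene, cds_pos, tissue): \code{median},
#'   \code{min}, \code{max}, \code{n_replicates}.
#' @export
summarize_tissues <- function(rates) {
  key <- interaction(rates$gene, rates$cds_pos, rates$tissue, drop = TRUE)
  rows <- lapply(split(rates, key), function(r) {
    data.frame(gene = r$gene[1], cds_pos = r$cds_pos[1], tissue = r$tissue[1],
               median = stats::median(r$percent), min = min(r$percent),
               max = max(r$percent), n_replicates = nrow(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene, out$cds_pos, out$tissue), , drop = FALSE]
}
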