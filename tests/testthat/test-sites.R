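test_that("codon-effect annotation reproduces the serine-to-leucine change at 149", {
  # codon 50 = TCA; position 149 is its second base
  cds <- paste0(strrep("GCT", 49), "TCA", strrep("GCT", 463))
  eff <- translate_effect(cds, 149, "T")
  expect_equal(eff$codon_index, 50L)
  expect_equal(eff$position_in_codon, 2L)
  expect_identical(eff$ref_codon, "TCA")
  expect_identical(eff$alt_codon, "TTA")
  expect_identical(eff$ref_aa, "S")
  expect_identical(eff$alt_aa, "L")
  expect_false(eff$synonymous)
})

test_that("codon arithmetic and synonymous detection are correct", {
  eff3 <- translate_effect("TCAGGG", 3, "G")
  expect_equal(eff3$position_in_codon, 3L)
  expect_identical(eff3$alt_codon, "TCG")
  expect_true(eff3$synonymous) # TCA and TCG both serine

  # AGC -> AGT at a third codon position: S-S
  cds <- paste0(strrep("AAA", 85), "AGC", "TAA")
  eff <- translate_effect(cds, 258, "T")
  expect_equal(eff$codon_index, 86L)
  expect_identical(eff$ref_aa, "S")
  expect_identical(eff$alt_aa, "S")
  expect_true(eff$synonymous)

  expect_error(translate_effect("TCAGGG", 2, "C"), "equals the reference")
  expect_error(translate_effect("TCAGGG", 9, "C"), "outside")
  expect_warning(translate_effect("TCAGG", 2, "G"), "divisible")
})

test_that("feature-to-genome coordinates are strand-aware and invertible", {
  fplus <- feature_table("f", "tRNA", "g", list(cbind(4L, 6L)), "+")
  expect_equal(cds_to_genome(fplus[1, ], 1), 4L)
  fminus <- feature_table("f", "tRNA", "g", list(cbind(4L, 6L)), "-")
  expect_equal(cds_to_genome(fminus[1, ], 1), 6L)

  set.seed(37)
  for (i in 1:25) {
    nseg <- sample(1:3, 1)
    bounds <- sort(sample(1000, nseg * 2))
    m <- matrix(bounds, ncol = 2, byrow = TRUE)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") m <- m[rev(seq_len(nseg)), , drop = FALSE]
    f <- feature_table("f", "tRNA", "g", list(m), strand)
    total <- sum(m[, 2] - m[, 1] + 1L)
    p <- sample(total, min(total, 20))
    g <- cds_to_genome(f[1, ], p)
    expect_equal(genome_to_cds(f[1, ], g), p)
  }
})

make_confirm_fixture <- function() {
  refs <- tiny_refs()
  # cdsA = ATGCCTCATTCACTATAA: C at 4,5,8,10,11; T at 2,7,9,...
  predicted <- data.frame(
    gene = c("cdsA", "cdsA", "cdsA", "cdsA", "ghost", "cdsA"),
    cds_pos = c(4L, 5L, 8L, 2L, 10L, 11L),
    codon_change = "NNN-NNN", aa_change = "X-X",
    score = c(1, 1, 0.9, 1, 1, 0.3),
    stringsAsFactors = FALSE)
  pileups <- data.frame(
    gene = "cdsA", ftype = "CDS", cds_pos = c(4L, 5L),
    ref_base = "C", A = 0, C = c(8, 12), G = 0, T = c(32, 0),
    depth = c(40, 12), terminal_excluded = 0L, stringsAsFactors = FALSE)
  calls <- call_sites(pileups, "C2T")
  list(refs = refs, predicted = predicted, pileups = pileups, calls = calls)
}

test_that("predicted sites are classified into the four confirmation statuses", {
  fx <- make_confirm_fixture()
  res <- confirm_predicted(fx$predicted, fx$calls, fx$pileups, fx$refs,
                           score_cutoff = 0.5)
  rec <- res$records
  get <- function(pos) rec$status[rec$cds_pos == pos]
  expect_identical(get(4), "confirmed")           # 32/40 C-to-T reads
  expect_identical(get(5), "covered_not_edited")  # coverage, no editing
  expect_identical(get(8), "no_coverage")         # nothing mapped there
  expect_identical(get(2), "genomic_T")           # reference already T
  expect_identical(rec$glyph[rec$cds_pos == 4], "*")
  # the ghost gene is reported aside, the low-score site is dropped
  expect_identical(res$unmatched$gene, "ghost")
  expect_false(11 %in% rec$cds_pos)
  # statuses partition the evaluated set
  expect_equal(res$summary$evaluated, nrow(rec))
  expect_equal(sum(res$summary$counts), nrow(rec))
  expect_equal(res$summary$percent_confirmed, 25)
})

test_that("strict confirmation defers to the caller's thresholds", {
  fx <- make_confirm_fixture()
  weak <- fx$pileups
  weak$T[1] <- 1; weak$depth[1] <- 9; weak$C[1] <- 8
  weak_calls <- call_sites(weak, "C2T") # 1/9 at err 0.001 still passes p<=1e-2
  lenient <- confirm_predicted(fx$predicted, weak_calls, weak, fx$refs)
  strict <- confirm_predicted(fx$predicted, weak_calls, weak, fx$refs,
                              mode = "strict")
  expect_identical(lenient$records$status[lenient$records$cds_pos == 4], "confirmed")
  expect_identical(strict$records$status[strict$records$cds_pos == 4],
                   if (nrow(weak_calls)) "confirmed" else "covered_not_edited")
  # with an empty call table nothing is strictly confirmed
  none <- confirm_predicted(fx$predicted, fx$calls[0, ], weak, fx$refs, mode = "strict")
  expect_false(any(none$records$status == "confirmed"))
})

test_that("raising the score cutoff never increases the evaluated site count", {
  fx <- make_confirm_fixture()
  n05 <- confirm_predicted(fx$predicted, fx$calls, fx$pileups, fx$refs, 0.5)$summary$evaluated
  n08 <- confirm_predicted(fx$predicted, fx$calls, fx$pileups, fx$refs, 0.8)$summary$evaluated
  expect_lte(n08, n05)
})

test_that("genomic_T classification ignores read evidence entirely", {
  fx <- make_confirm_fixture()
  # pile a strong fake signal onto the genomic-T position: status must not move
  pos2 <- data.frame(gene = "cdsA", ftype = "CDS", cds_pos = 2L, ref_base = "T",
                     A = 0, C = 0, G = 0, T = 100, depth = 100,
                     terminal_excluded = 0L, stringsAsFactors = FALSE)
  res <- confirm_predicted(fx$predicted, fx$calls, rbind(fx$pileups, pos2), fx$refs)
  expect_identical(res$records$status[res$records$cds_pos == 2], "genomic_T")
})

test_that("prediction/SNP overlap is a disjoint three-way split", {
  pred <- data.frame(gene = c("g1", "g2"), cds_pos = c(10L, 20L))
  snp <- data.frame(gene = c("g2", "g3"), cds_pos = c(20L, 30L))
  ov <- compare_predictions_vs_snp(pred, snp)
  expect_equal(ov$n_both, 1L)
  expect_equal(ov$n_prep_only, 1L)
  expect_equal(ov$n_snp_only, 1L)
  expect_identical(ov$both$gene, "g2")

  empty <- compare_predictions_vs_snp(pred, snp[0, ])
  expect_equal(empty$n_both, 0L)
  expect_equal(empty$n_snp_only, 0L)

  set.seed(43)
  for (i in 1:20) {
    pl <- data.frame(gene = sample(letters[1:5], 12, TRUE),
                     cds_pos = sample(1:6, 12, TRUE))
    sl <- data.frame(gene = sample(letters[1:5], 12, TRUE),
                     cds_pos = sample(1:6, 12, TRUE))
    ov <- compare_predictions_vs_snp(pl, sl)
    npred <- nrow(unique(pl))
    expect_equal(ov$n_both + ov$n_prep_only, npred)
    expect_equal(nrow(ov$per_gene), length(unique(c(
      paste(pl$gene), paste(sl$gene)))))
  }
})

test_that("tRNA scanning calls A-to-G sites and flags the wobble window", {
  pile <- data.frame(gene = "trnX", ftype = "tRNA", cds_pos = c(35L, 50L),
                     ref_base = "A", A = c(69, 80), C = 0, G = c(145, 0), T = 0,
                     depth = c(214, 80), terminal_excluded = 0L,
                     stringsAsFactors = FALSE)
  calls <- scan_trna_editing(pile)
  expect_equal(nrow(calls), 1L) # the all-reference column is not a call
  expect_equal(calls$cds_pos, 35L)
  expect_equal(calls$percent, 67.8)
  expect_true(calls$wobble34_35)

  pile2 <- pile; pile2$cds_pos <- c(12L, 50L)
  calls2 <- scan_trna_editing(pile2)
  expect_false(calls2$wobble34_35)
})

test_that("a simulated A-to-I site is recovered near its planted rate", {
  refs0 <- simulate_references(sim_config(seed = 47))
  site <- plant_edit_sites(refs0, rates = 0.5, type = "A2I", seed = 47)
  cfg <- sim_config(seed = 47, read_count = 30000, error_rate = 0,
                    edit_sites = site)
  refs <- simulate_references(cfg)
  sim <- simulate_reads(refs, cfg)
  part <- hierarchical_partition(sim$reads, refs)
  pile <- build_pileup(part$alignments, sim$reads, refs)
  calls <- scan_trna_editing(pile, refs = refs)
  hit <- calls[calls$gene == site$gene & calls$cds_pos == site$cds_pos, ]
  expect_equal(nrow(hit), 1L)
  n <- hit$total_cov
  ci <- stats::qbinom(c(0.005, 0.995), n, site$rate) / n * 100
  expect_gte(hit$percent, ci[1])
  expect_lte(hit$percent, ci[2])
})

test_that("genome coverage summary counts uncovered positions exactly", {
  expect_equal(coverage_summary(rep(1L, 100)),
               list(mean = 1, max = 1, zero_positions = 0L, zero_fraction_pct = 0))
  half <- c(rep(2L, 50), rep(0L, 50))
  s <- coverage_summary(half)
  expect_equal(s$zero_fraction_pct, 50)
  expect_equal(s$mean, 1)

  refs <- tiny_refs()
  reads <- read_df(c(substr(refs$sequences[["cp"]], 1, 20),
                     substr(refs$sequences[["cp"]], 11, 30),
                     refs$sequences[["cdsB"]]))
  aln <- map_read(reads, refs, max_mm = 0)
  depth <- genome_depth(aln, reads, refs)
  # independent tally: genome reads cover 1-30 with overlap 11-20 doubled,
  # and the spliced cdsB read covers both its segments through projection
  m <- refs$features$segments[[2]]
  expected <- integer(nchar(refs$sequences[["cp"]]))
  expected[1:30] <- 1L; expected[11:20] <- 2L
  expected[m[1, 1]:m[1, 2]] <- expected[m[1, 1]:m[1, 2]] + 1L
  expected[m[2, 1]:m[2, 2]] <- expected[m[2, 1]:m[2, 2]] + 1L
  expect_equal(depth, expected)
})
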