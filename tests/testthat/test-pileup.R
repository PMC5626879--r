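aln_for <- function(reads, refs, max_mm = 2) {
  a <- map_read(reads, refs, max_mm = max_mm)
  a$stage <- ifelse(a$nm == 0, "m0", "m2")
  a
}

test_that("a single perfect read produces one depth-1 column per base", {
  refs <- tiny_refs()
  read <- read_df(substr(refs$sequences[["trnX"]], 10, 27))
  pile <- build_pileup(aln_for(read, refs), read, refs)
  pile <- pile[pile$gene == "trnX", ]
  expect_equal(nrow(pile), 18L)
  expect_equal(pile$cds_pos, 10:27)
  expect_true(all(pile$depth == 1))
  # every observation sits on the reference base
  ref_counts <- mapply(function(i) pile[i, pile$ref_base[i]], seq_len(nrow(pile)))
  expect_true(all(ref_counts == 1))
})

test_that("disagreeing reads stack into one column with two base counts", {
  refs <- tiny_refs()
  base <- substr(refs$sequences[["trnX"]], 10, 27)
  ref18 <- substr(base, 9, 9)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref18)[1]
  alt <- base
  substr(alt, 9, 9) <- alt_base
  reads <- read_df(c(base, alt))
  pile <- build_pileup(aln_for(reads, refs), reads, refs)
  col <- pile[pile$gene == "trnX" & pile$cds_pos == 18, ]
  expect_equal(col$depth, 2)
  expect_equal(col[[ref18]], 1)
  expect_equal(col[[alt_base]], 1)
})

test_that("a plus-strand read seen via genome and cds copy is counted once", {
  refs <- tiny_refs()
  read <- read_df(refs$sequences[["cdsA"]]) # maps cp genome, cdsA and the NUPT
  aln <- aln_for(read, refs)
  expect_true(all(c("cp", "cdsA") %in% aln$ref_id))
  pile <- build_pileup(aln, read, refs)
  expect_true(all(pile[pile$gene == "cdsA", "depth"] == 1))
})

test_that("minus-strand feature evidence comes only from the sense cds copy", {
  refs <- tiny_refs()
  sense <- read_df(refs$sequences[["cdsB"]])
  aln <- aln_for(sense, refs)
  expect_identical(unique(aln$ref_id), "cdsB") # spliced read: genome copy can't host it
  pile <- build_pileup(aln, sense, refs)
  expect_equal(sum(pile$gene == "cdsB"), 18L)

  # an antisense read (genome forward strand over the minus feature) adds no
  # cdsB columns
  m <- refs$features$segments[[2]]
  anti <- read_df(substr(refs$sequences[["cp"]], min(m), min(m) + 17L))
  aln_anti <- aln_for(anti, refs, max_mm = 0)
  expect_identical(unique(aln_anti$ref_id), "cp")
  pile2 <- build_pileup(aln_anti, anti, refs)
  expect_equal(sum(pile2$gene == "cdsB"), 0L)
})

test_that("terminal mismatches are excluded from tallies but tallied separately", {
  refs <- tiny_refs()
  base <- substr(refs$sequences[["trnX"]], 10, 27)
  alt1 <- setdiff(c("A", "C", "G", "T"), substr(base, 1, 1))[1]
  alt9 <- setdiff(c("A", "C", "G", "T"), substr(base, 9, 9))[1]
  edge <- base; substr(edge, 1, 1) <- alt1 # mismatch at read position 1
  mid <- base; substr(mid, 9, 9) <- alt9
  reads <- read_df(c(edge, mid), c("edge", "mid"))
  aln <- aln_for(reads, refs)
  pile <- build_pileup(aln, reads, refs, w = 1)
  col_edge <- pile[pile$gene == "trnX" & pile$cds_pos == 10, ]
  expect_equal(col_edge$terminal_excluded, 1)
  expect_equal(col_edge[[alt1]], 0) # the edge mismatch never becomes edited evidence
  expect_equal(col_edge$depth, 1)  # only the internal-mismatch read's matching base
  col_mid <- pile[pile$gene == "trnX" & pile$cds_pos == 18, ]
  expect_equal(col_mid[[alt9]], 1) # internal mismatch retained
  expect_equal(col_mid$terminal_excluded, 0)
  expect_equal(col_mid$depth, 2)
})

test_that("terminal filter conserves mismatches and widens with w", {
  refs <- tiny_refs()
  set.seed(31)
  trna <- refs$sequences[["trnX"]]
  reads <- read_df(vapply(1:30, function(i) {
    p <- sample(55, 1)
    mutate_string(substr(trna, p, p + 19L), sample(0:2, 1))
  }, character(1)))
  aln <- map_read(reads, refs, max_mm = 2)
  for (w in 0:3) {
    f <- terminal_edit_filter(aln, reads, w = w)
    kept_n <- vapply(f$kept_mismatches, function(x) nrow(parse_mismatches(x)), integer(1))
    expect_equal(unname(kept_n) + f$terminal_excluded, f$nm)
    if (w == 0) expect_equal(sum(f$terminal_excluded), 0L)
  }
})

test_that("column depth equals the summed base counts and read overlap", {
  cfg <- sim_config(seed = 17, read_count = 3000, error_rate = 0, insertion_count = 0)
  refs <- simulate_references(cfg)
  sim <- simulate_reads(refs, cfg)
  part <- hierarchical_partition(sim$reads, refs)
  pile <- build_pileup(part$alignments, sim$reads, refs)
  expect_true(all(pile$depth == pile$A + pile$C + pile$G + pile$T))
  # total feature observations = total length of feature-derived reads
  feat_reads <- sim$truth$origin == "cp_feature"
  expect_equal(sum(pile$depth) + sum(pile$terminal_excluded),
               sum(sim$truth$length[feat_reads]))
})

test_that("pileup depths match the truth table at planted sites", {
  refs0 <- simulate_references(sim_config(seed = 19))
  sites <- plant_edit_sites(refs0, rates = 0.5, seed = 19)
  cfg <- sim_config(seed = 19, read_count = 6000, error_rate = 0,
                    insertion_count = 0, edit_sites = sites)
  refs <- simulate_references(cfg)
  sim <- simulate_reads(refs, cfg)
  part <- hierarchical_partition(sim$reads, refs)
  pile <- build_pileup(part$alignments, sim$reads, refs, w = 0)
  col <- pile[pile$gene == sites$gene & pile$cds_pos == sites$cds_pos, ]
  expect_equal(col$depth, sim$site_truth$n_reads_overlapping)
  expect_equal(col$T, sim$site_truth$n_reads_edited)
})

test_that("binomial variant test matches direct summation and resists underflow", {
  expect_equal(variant_test(0, 10), 0)
  expect_true(is.na(variant_test(0, 0)))
  got <- variant_test(2, 10, 0.001)
  expect_equal(got, direct_log10_tail(2, 10, 0.001), tolerance = 1e-6)
  deep <- variant_test(500, 1000, 0.001)
  expect_true(is.finite(deep))
  expect_lt(deep, -300)
  expect_equal(deep, direct_log10_tail(500, 1000, 0.001), tolerance = 1e-6)
  expect_error(variant_test(5, 3), "edited_cov")
  expect_error(variant_test(1, 2, err_rate = 0), "err_rate")
})

test_that("editing percentage reproduces tabulated ratios with half-up rounding", {
  expect_equal(editing_percentage(32, 40), 80.0)
  expect_equal(editing_percentage(47, 47), 100.0)
  expect_equal(editing_percentage(5, 12), 41.7)
  expect_equal(editing_percentage(0, 25), 0.0)
  expect_equal(round_half_up(0.25, 1), 0.3) # half goes up, not to even
  expect_error(editing_percentage(0, 0), "coverage")
})

test_that("site calling applies coverage, evidence and p-value gates", {
  pile <- data.frame(gene = "g", ftype = "CDS", cds_pos = c(10L, 20L, 30L),
                     ref_base = "C",
                     A = 0, C = c(8, 12, 1), G = 0, T = c(32, 0, 3),
                     depth = c(40, 12, 4), terminal_excluded = 0L,
                     stringsAsFactors = FALSE)
  calls <- call_sites(pile, "C2T")
  expect_equal(nrow(calls), 1L) # no edited evidence and sub-threshold coverage drop out
  expect_equal(calls$cds_pos, 10L)
  expect_equal(calls$percent, 80.0)
  expect_lt(calls$log10_p, -2)
})

test_that("calling is monotone in its thresholds", {
  set.seed(41)
  pile <- data.frame(gene = "g", ftype = "CDS", cds_pos = 1:40, ref_base = "C",
                     A = 0, C = sample(0:30, 40, TRUE), G = 0,
                     T = sample(0:10, 40, TRUE), terminal_excluded = 0L,
                     stringsAsFactors = FALSE)
  pile$depth <- pile$C + pile$T
  base <- call_sites(pile, "C2T", min_coverage = 5, max_p = 1e-2)
  stricter_cov <- call_sites(pile, "C2T", min_coverage = 10, max_p = 1e-2)
  stricter_p <- call_sites(pile, "C2T", min_coverage = 5, max_p = 1e-6)
  expect_true(all(stricter_cov$cds_pos %in% base$cds_pos))
  expect_true(all(stricter_p$cds_pos %in% base$cds_pos))

  # adding an edited observation never removes a call
  more <- pile
  ix <- which(pile$cds_pos %in% base$cds_pos)[1]
  more$T[ix] <- more$T[ix] + 1; more$depth[ix] <- more$depth[ix] + 1
  again <- call_sites(more, "C2T", min_coverage = 5, max_p = 1e-2)
  expect_true(all(base$cds_pos %in% again$cds_pos))
})
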