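---
title: "Detecting chloroplast RNA editing from small RNA libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chloroplast RNA editing from small RNA libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaedit)
```

## The problem

Plant chloroplast transcripts are post-transcriptionally edited: specific
cytidines in coding sequences are deaminated to uridine (C-to-U), typically
restoring evolutionarily conserved amino acids, and the wobble adenosine of
tRNA-Arg(ACG) is deaminated to inosine (A-to-I), which sequencers read as G.
Total small-RNA (sRNA) libraries — sequenced for microRNA work, with no
organelle enrichment — contain large numbers of plastid-derived fragments,
and because these fragments are sense-strand transcript pieces they carry the
edited bases. `srnaedit` turns such libraries into per-site editing evidence:
which positions are edited, in what fraction of transcripts, and with what
statistical support.

Two obstacles make this non-trivial at the mapping stage:

1. **Nuclear plastid insertions (NUPTs).** Nuclear genomes carry exact copies
   of chloroplast DNA. If reads were aligned to the nuclear genome first,
   *unedited* chloroplast reads would be absorbed by those copies and the
   denominator of every editing fraction would be biased.
2. **Edited reads do not match the reference.** A read spanning an edited
   site differs from the chloroplast genome at that site, so an exact-match
   pass alone discards precisely the informative reads.

## The hierarchical partition

`hierarchical_partition()` resolves both with a fixed stage order, all
mapping being ungapped, substitution-only and strand-specific (no reverse
complement — plastid sRNAs are treated as sense transcript fragments, and an
antisense alignment must never be mistaken for editing):

1. reads are mapped at **0 mismatches** against the chloroplast targets
   (genome + extracted coding sequences + tRNAs); hits are `cp_m0`, the
   unedited evidence. Chloroplast-first ordering shields these reads from
   NUPTs;
2. survivors are mapped at 0 mismatches against the nuclear, then the
   mitochondrial genome, and discarded on a hit (`nuclear`, `mito`). The
   nuclear-before-mitochondrial order is a deterministic tie-break for reads
   matching both;
3. survivors are remapped against the chloroplast targets at **≤ 2
   mismatches**; hits are `cp_m2`, the editing-informative reads;
4. the rest is `unaligned`.

The five classes are mutually exclusive and exhaustive, so their counts sum
to the library size — a conservation property asserted in the test suite.
Pileups and calls are built from `cp_m0 ∪ cp_m2`.

The aligner itself finds **all** loci of a read within the mismatch bound by
pigeonhole seeding (`pigeonhole_seeds()`): the read is split into `max_mm +
1` near-equal segments, any valid alignment must contain one exactly matching
segment, candidate loci are harvested from a k-mer index of the segment
starts and every candidate is verified by full Hamming comparison. The
verification step makes seeding a pure candidate generator; the test suite
checks equivalence against a brute-force scan of every reference window.
Only the minimal-mismatch stratum is reported, all of it, with
`n_best_loci` recorded on each alignment. Multi-mapping reads (inverted-repeat
duplicates in real plastid genomes) therefore contribute an observation at
every equal-best locus; `build_pileup(multiread = "fractional")` instead
weights each by `1/n_best_loci`. Ties are never sampled away, so runs are
deterministic without a seed.

## Pileups, the terminal filter, and calling

`build_pileup()` tallies per-base observations in spliced feature
coordinates. Alignments to a cds/tRNA extract contribute directly; genome
alignments are projected splice-aware into plus-strand features. A genome
forward-strand alignment over a minus-strand feature is antisense and is not
feature evidence. A read seen at the same feature position through both its
genome hit and its cds-copy hit is counted once.

Mismatches within `w` bases of either read end (default `w = 1`) are removed
from the tallies and counted per column in `terminal_excluded`: terminal
mismatches are enriched for ligation/alignment artifacts that mimic editing.
The read's matching bases still count toward depth. The exact width of the
end window is not standardized anywhere, so it is a flag; `w = 1` removes the
single most artifact-prone base at each end while costing only ~2/L of the
edited observations for reads of length L. Editing percentages are computed
*after* this filter, from the same counts the variant test sees, so the
reported fraction and its p-value always refer to the same evidence.

A site is called (`call_sites()`) when:

* the reference base and alternative base match the change type — C→T on
  CDS, A→G on tRNA (inosine reads as G);
* total coverage ≥ `min_coverage` (default 5);
* at least one alternative observation survived the terminal filter;
* the variant test passes `max_p` (default 1e-2 for confirmation-grade
  evidence; 1e-10 for stringent novel-site discovery).

**The variant test** is a one-sided binomial tail: with `edited_cov = k` out
of `total_cov = n` and per-base error rate `e` (default 0.001 ≈ Q30),
`variant_test()` returns log10 P[X ≥ k], X ~ Binomial(n, e), computed in the
log domain so that tails far beyond double-precision underflow (p < 1e-300,
routinely reached at deep coverage) keep finite, accurate logs. The choice of
a defined, documented test matters: per-site editing p-values printed by
interactive SNP tools are produced by undocumented "approximate" methods and
can exceed the representable floating-point range, so they cannot be
reproduced exactly; a binomial error model with the same decision thresholds
preserves the intent while being checkable against direct summation (the
suite verifies 1e-6 relative agreement). When base qualities are trusted, `e`
should be set to the library's empirical error rate; the default is flat and
global for determinism.

Percentages are reported to one decimal, rounded half away from zero
(`round_half_up()`), matching the convention of per-site coverage tables that
print "41.7" for 5/12; full precision is kept internally.

## Confirmation of predicted sites

Conservation-based predictors (PREP-style) emit candidate C-to-U sites with
scores in [0, 1]. `confirm_predicted()` drops sites below the score cutoff
(0.5 relaxed, 0.8 stringent — the filter is monotone: raising the cutoff
never adds sites) and classifies the remainder into exactly one status:

| status | glyph | meaning |
|---|---|---|
| `genomic_T` | `T` | the reference already carries T; editing cannot occur. Depends only on the reference sequence, never on reads. |
| `no_coverage` | `0` | no surviving observation covers the position |
| `confirmed` | `*` | editing evidence present |
| `covered_not_edited` | `-` | reads present, none edited |

Confirmation runs in two modes because the two uses of the pipeline pull in
different directions. `lenient` (default) confirms on ≥ 1 edited read
surviving the terminal filter — published confirmation tables accept sites
with edited coverage of 1–2, where any p-value gate would be vacuous.
`strict` requires a passing `call_sites()` call and is the right setting when
the same machinery is used for novel-site discovery. Predicted sites whose
gene is absent from the annotation are excluded from denominators and
reported in a side table rather than silently dropped. Site identity is
`(gene, cds_pos)`, so predictions duplicated across inverted-repeat gene
copies collapse to one record.

`compare_predictions_vs_snp()` intersects confirmed predictions with
stringent SNP-style calls into disjoint both / prediction-only / SNP-only
sets; `scan_trna_editing()` reports A→G calls in tRNA coordinates, flagging
positions 34 and 35 as the potential anticodon wobble site. Sequence position
numbering is used (1-based from the annotated 5' end), not Sprinzl numbering;
because the two conventions disagree about the wobble position by one, both
34 and 35 are flagged rather than asserting either.

## The qPCR transform

`editing_rate_from_ct()` converts allele-specific qPCR threshold cycles into
a percentage with the base-2 logistic form

$$\%\,editing = 100\cdot\frac{2^{d}}{2^{d}+1},\qquad d = \overline{Ct}_T - \overline{Ct}_C$$

implemented exactly in this printed orientation. Note the tension: as
written, a *higher* Ct for the edited-variant primer (i.e. less edited
template under the usual reading of Ct) yields a *higher* editing percentage,
which inverts standard qPCR abundance logic. The source describing the method
does not print the underlying Ct values, so the orientation cannot be
re-derived from data; the transform is therefore implemented verbatim and a
`flip_sign` option computes with −d for users who want abundance-consistent
orientation. Amplification efficiency is fixed at the printed base 2; no
efficiency-correction model is applied. The transform is strictly increasing
in d, bounded in (0, 100) and complement-symmetric (rate(d) + rate(−d) =
100). `summarize_tissues()` reduces biological replicates to median and
observed extremes, the whisker convention of per-tissue editing boxplots.

## The simulator: what it emulates, and what it does not

`simulate_references()` / `simulate_reads()` generate the study conditions
every downstream stage is tested under, fully determined by the seed:

* a chloroplast genome (default 20 kb) carrying `n_genes` CDS (ATG…stop, no
  internal stops, length divisible by 3) and `n_trnas` 74-nt tRNAs on
  alternating strands;
* a nuclear genome containing `insertion_count` exact chloroplast insertions
  (default 2 × 200 bp) — the NUPT decoys — and otherwise verified to share no
  18-mer with the chloroplast, so a nuclear read can exact-match the
  chloroplast only from inside an insertion;
* a mitochondrial genome verified 18-mer-free of the chloroplast by
  brute-force k-mer scan (with redraws);
* reads at the default composition 23% chloroplast / 45% nuclear / 0.1%
  mitochondrial / remainder unalignable background, the composition of a
  total Arabidopsis sRNA library; 70% of chloroplast reads come from feature
  sense sequence and 30% from intergenic genome (sRNA coverage concentrates
  on transcribed regions but plastid genomes are pervasively transcribed, so
  intergenic mass is substantial); read lengths uniform on 18–24 nt.
  Background reads are rejection-sampled so that nothing aligns to any
  reference within 2 mismatches, giving exact expected partition classes.

Each read overlapping a planted site carries the edited base independently
with probability `rate` — a per-read Bernoulli with no haplotype structure,
which is exactly the sampling model the binomial caller assumes. Sequencing
errors are i.i.d. uniform substitutions at `error_rate` (default 0.001); there
is no quality-dependent error model and no indel model (the aligner is
substitution-only). The truth table records per-read origin, coordinates,
applied edits and the expected partition class, exact when `error_rate = 0`.

Passing tests on this simulator therefore demonstrate correctness of the
mechanics — partition order, projection, filtering, calling, quantification —
under the caller's own statistical assumptions. They do not demonstrate
robustness to what real libraries add: position-dependent error profiles,
ligation bias at read ends (the motivation for the terminal filter), RNA
degradation hotspots, incomplete annotations, or inverted-repeat structure
(absent from the simulated genome, though multi-mapping handling is tested
directly).

## Problem sizes and numerical choices

The suite exercises the pipeline at library sizes of 3,000–100,000 reads on
20–50 kb genomes — small enough for a laptop, large enough that planted sites
reach coverages of 50–300 and that the zero-editing specificity run
(100,000 reads at error rate 0.001) would expose an inflated false-positive
rate. Parameter-recovery checks require the estimated editing fraction to
fall inside the exact binomial 99% interval of the planted rate at the
observed coverage; with the default terminal window this costs a small
downward bias (edited observations at read termini are excluded, unedited
ones kept) that stays well inside the interval at these coverages.

Other fixed choices: candidate seeds use a 6-mer index (the smallest segment
of an 18-nt read at 2 mismatches), with a full-scan fallback for reads whose
segments are shorter; reads containing N are never aligned (Hamming distance
to N is undefined under a 0/2-mismatch contract) and are tallied separately;
ties in every ranking are resolved by fixed stage order or reported in full,
never sampled. All coordinates are 1-based inclusive at every external
interface (annotation, reports, VCF-style genome positions), 0-based
half-open only inside the C++ kernel.

## Known limitations

* U-to-C editing and other change types are out of scope; the caller models
  C→T (CDS) and A→G (tRNA) only.
* Strand is taken from the annotation; no strand-flip inference is attempted.
* The editing fraction is estimated per site independently; linked editing
  across sites on the same transcript is not modeled.
* Genome-route evidence for minus-strand features relies entirely on the
  extracted cds/tRNA copies; a read overlapping a minus-strand feature but
  absent from the extract (e.g. spanning the feature boundary) contributes
  genome coverage but no feature evidence.
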