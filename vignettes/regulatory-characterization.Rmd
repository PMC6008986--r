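---
title: "Characterizing 5' and 3' regulatory features of a gene locus"
author: "regchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing 5' and 3' regulatory features of a gene locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regchar)
```

## The problem

A gene's expression is shaped on both of its flanks. At the 5′ side,
alternative promoters differ in their core elements — TATA-box, initiator
(INR), downstream elements — in their CpG-island status, and in the
physical stability of their DNA; which promoter the transcription machinery
engages can decide how strongly, and in which tissue, the gene is
expressed. At the 3′ side, a convergently transcribed non-coding RNA on
the opposite strand can overlap the mRNA's 3′UTR, hybridize with it, and
host microRNAs that target recognition elements (MREs) in that UTR. The
archetype this package was built around is a protein-coding locus with
eleven overlapping alternative promoters (TATA-containing and CGI-less)
convergently paired with a lncRNA whose transcript is complementary to a
short stretch of the mRNA 3′UTR — but every stage is generic and works on
any FASTA input.

`regchar` implements the full desk analysis as composable, seeded,
oracle-tested functions: motif scanning, CpG-island detection,
stacking-energy profiling, promoter classification, heteroduplex-segment
discovery, MRE calling, and the accompanying hypothesis tests, plus
synthetic-data generators that make every stage verifiable offline.

## Coordinates and alphabets

All user-visible coordinates are 1-based and fully closed, the convention
of printed genome-browser strings; `parse_interval()` accepts those
strings directly and `length_inclusive()` is `end − start + 1`. BED is
0-based half-open *on disk only*: `write_bed()` and `read_bed()` convert
at the boundary, so a closed interval `[s, e]` stores as `(s − 1, e)`.
Published coordinate spans are not always internally consistent across
sources; this package standardizes on closed intervals and leaves any
discrepancy in the input's own printing to the input.

RNA records (`alphabet = "RNA"`) are folded U→T internally so one scanning
and alignment engine serves both alphabets; the original alphabet is
restored on output. The ambiguity code `N` is conservative everywhere: in
a scanned sequence it matches only an `N` in the pattern, windows holding
`N` are never PWM hits, `N` never Watson–Crick pairs in MRE calling, and
energy steps touching `N` are missing values.

## Motif scanning

Consensus motifs use IUPAC degenerate codes; `scan_consensus()` reports a
hit at *every* offset and strand where the window is in the pattern's
expansion set, reverse-strand hits mapped back to forward coordinates.
Overlapping and self-overlapping occurrences are all counted — incidence
is meant to capture motif richness, and an overlap policy would silently
halve counts for periodic motifs like `GAGAG`; a greedy left-to-right
non-overlapping mode is available through
`motif_incidence_table(..., overlapping = FALSE)` for users who want site
counts instead. Both strands are scanned by default because core elements
are routinely annotated on either strand and the convergent-locus setting
makes single-strand defaults error-prone.

The shipped `motif_catalog()` carries 18 consensus motifs (TATA-box
`TATAWA`, INR `YYANWYY`, DTIE `GBBRDNHGG`, BRE `SSRCGCC`, DPE `RGWCGTG`,
M3 `SCGGAAGY`, M22 `TGCGCANK`, HIF `RCGTG`, EBF3 `CCCNNGGG`, Sox
`WWCAAWG`, P53 `RRRCWWGY`, Oct4 `TTTKSWTW`, PU.1 `GAGGAA`, Nanog
`SRSSATTANS`, c-myc `CACRTG`, MAD `CCGNCGCG`, GAF `GAGAG`, GATA `WGATAR`)
plus PFM slots for the bidirectional-promoter factors NRF1 and ZNF143
loaded from JASPAR-format files. The consensus strings are kept verbatim
as curated, including the locally unusual DPE form.

PFM scanning scores each window as
$\sum_j \log_2\frac{(n_{b_j,j} + c)/(N_j + 4c)}{p_{b_j}}$ with
pseudocount $c = 0.25$ and uniform background by default, calling a hit
when the score reaches `threshold_fraction` (default 0.8) of the maximum
attainable score. The fraction-of-maximum rule makes the threshold
portable across matrices of different information content; 0.8 is the
common JASPAR-style screening default, and the pseudocount mainly guards
zero counts. At `threshold_fraction = 1` scanning reduces to finding the
matrix's argmax word, which the tests exploit as a closed-form oracle.

## CpG islands

`find_cgi()` applies the classic criteria: windows of 200 nt slid 1 nt at
a time are marked when GC fraction exceeds 0.5 **and** observed/expected
CpG $= N_{CpG} \cdot L / (N_C \cdot N_G)$ exceeds 0.6 (both strict
inequalities, matching the criteria's "greater than" phrasing); marked
windows that overlap or touch are merged, and merged spans of at least
200 nt are reported with both statistics recomputed on the span. The 1-nt
step maximizes sensitivity and is cheap at desk scale; step and window
are parameters because published CGI tools differ in their shifts.
Detection runs on the forward strand only: GC content and CpG count are
invariant under reverse complementation (CpG is its own reverse
complement), a property the test suite checks rather than double-scans.

One behaviour worth knowing: because qualification is assessed on whole
windows, a sub-window CpG-rich core (say a 150-nt CG repeat) can qualify
windows that also cover its flanks, so the reported merged region extends
beyond the core. This is inherent to the window formulation — the
package reports exactly what the all-windows definition implies, verified
against a brute-force oracle.

## Stacking-energy profiles

Each adjacent base step contributes the stacking energy of its
dinucleotide; a raw profile of a length-$L$ sequence has $L-1$ values
indexed by the step's left base. The 16 energies live in an editable
packaged table (`inst/extdata/stacking_energies.tsv`), transcribed from
the classic B-DNA stacking calculations of Ornstein et al. (1978); the
table is configuration, not code, and all package logic is correct for
any complete finite table. The packaged values are
complementation-symmetric, so complement profiles mirror — a property the
tests check against the configured table and would skip for an asymmetric
substitute.

`smooth_profile()` is a plain sliding mean (default window 25 steps for
region calling — wide enough to suppress single-step noise, narrow enough
to keep ~50-step features visible; raw profiles are always available
since published profiles are plotted in both modes).
`low_energy_regions()` reports maximal runs inside a closed band, default
−7.0 to −6.5 kcal/mol — under the packaged table this brackets the
energies characteristic of TATA/INR-like AT-rich steps, and it is a flag
because it is table-dependent. `colocalize_energy()` compares the mean
energy at motif-hit steps with the remaining steps and attaches an
empirical permutation p-value from random repositionings of the hit set
(count and lengths preserved), computed as $(1 + k)/(n + 1)$ so it is
never zero and lies in $[1/(n+1), 1]$; permutations are seeded and
reproducible.

## Convergent transcripts, heteroduplex segment, MREs

`local_align()` is optimal Smith–Waterman local alignment with affine
gaps (Biostrings' exact implementation underneath, cross-checked in the
test suite against an independently written dynamic-programming oracle).
Default scoring is the common EMBOSS-style DNA set: match +5, mismatch
−4, and a gap of total length $L$ costing $16 + 4L$. All four values are
parameters. Percent identity is matches divided by alignment columns
(gaps included in the denominator), the pairwise-alignment-tool
convention; an empty alignment (no positive-scoring substring pair)
returns `NULL`. When several alignments tie optimally the traceback is
deterministic but library-defined; the synthetic generator is constructed
so the planted optimum is unique, making all reported quantities
tie-free.

`find_complementary_segment()` aligns transcript A against the reverse
complement of transcript B and reports the segment when it meets length
(default 20 nt) and identity (default 70%) thresholds, mapping B's
coordinates back to B's own 5′→3′ frame. MRE calling is a documented
seed-complementarity rule, not a reimplementation of pattern-statistics
tools: the seed is miR positions 2–8, a site is a UTR window equal to the
seed's reverse complement with at most `max_seed_mismatches` mismatches
(default 0), Watson–Crick pairing only, no G:U wobble. Hybridization
free energies and the full target-prediction statistics of dedicated
tools are deliberately out of scope. `mir_similarity_search()` ranks a
mature-miRNA set against a query segment by alignment score, then
identity.

## Promoter classification and statistics

`classify_promoter()` is a pure function of four boolean features:
TATA-box hit present, CpG island present, NRF1 hit, ZNF143 hit. Labels:
`TATA_containing` ⇔ TATA present (absence of a CGI in a promoter panel is
the classic indication that those promoters run TATA-dependent
initiation); `CGI_positive`/`CGI_negative`; `bidirectional_candidate` ⇔
CGI ∧ NRF1 ∧ ZNF143 ∧ ¬TATA, the canonical bidirectional-promoter
signature; promoters matching neither positive rule are additionally
`unclassified`. `has_tata` means at least one hit anywhere in the
supplied promoter sequence — the caller controls the window by what it
scans.

`one_way_anova()` is the classic fixed-effects F test
($F = MS_{between}/MS_{within}$, df $(k-1, N-k)$, via
`stats::oneway.test(var.equal = TRUE)`); it accepts $k \ge 2$ groups so
that the $F = t^2$ identity with the pooled t test is testable.
`incidence_significance()` applies it with motifs as groups and
per-promoter counts as observations — ANOVA on counts, reproduced as the
field's stated analysis; because count data strain the normality
assumption, a chi-square homogeneity alternative is one flag away
(`method = "chisq"`). `two_sample_t()` defaults to Welch. The
significance threshold used by the pipeline report is p ≤ 0.05.

## The synthetic-data generators

The generators define the study conditions under which the package is
validated; they are first-class, tested code.

* `gen_background(length, gc, seed)`: i.i.d. bases at a target GC. This
  is a zeroth-order model — it emulates composition, not repeats,
  k-mer autocorrelation, or isochore structure.
* `plant_motif()`: overwrites a region with a uniformly sampled concrete
  expansion of a consensus, recording position and name.
* `gen_cgi_sequence()`: an island drawn CpG-dense (re-drawn under a
  derived seed until GC > 0.5 and obs/exp > 0.6 hold, so the criteria are
  true by construction) between AT-rich flanks (GC 0.02) in which no
  fully-flanking window can qualify. Windows straddling the island edge
  may qualify, so detected regions can exceed the planted interval — the
  recovery tests therefore assert overlap, not equality.
* `gen_convergent_pair(len_a = 5266, len_b = 422, seg_len = 52,
  identity = 0.75, seed)`: the defaults mirror the documented convergent
  mRNA/lncRNA pair — a 5,266-nt transcript and a 422-nt transcript
  sharing a 52-nt complementary segment at 75% identity, i.e. exactly
  `52 − round(0.75 × 52) = 13` mismatches. The mismatches are internal
  (first and last 5 positions always match) and never adjacent, and the
  flanks are poly-A (A) versus poly-C (B): under the default scoring
  every alignment prefix/suffix of the planted segment has positive
  running score and no off-segment window can approach the planted score,
  so the optimal local alignment is exactly the planted segment, for any
  seed. This determinism is what makes the emulated 52-nt/75% recovery a
  sharp, reproducible target rather than a distributional one.
* `gen_expression_table(n_groups = 11, replicates = 2, ...)`: Gaussian
  noise around per-group means on an (already log-like)
  fluorescence-intensity scale, matching the ANOVA's assumptions; the
  defaults mirror a panel of 11 tissues with the minimum of two
  measurements each. Tissue identities and real expression values are
  deliberately not guessed — group means are configuration.

All generators are pure functions of their arguments: the seed is applied
via an isolated RNG scope, identical configurations are byte-identical,
and the global RNG state is never touched.

What passing the plant-then-find suites shows — and does not. Recovery of
planted features in i.i.d. backgrounds demonstrates the detectors'
correctness and the pipeline's wiring, under favourable composition. It
does not demonstrate specificity or sensitivity on real genomic sequence,
where repeats, CpG decay gradients, and motif clustering produce hit
densities these backgrounds do not emulate. Genome-dependent counts
(how many of a real panel's promoters carry a TATA-box, real incidence
tables, a real promoter's energy profile) require the genomic sequences
themselves as inputs.

## Numerical and testing choices

* Strict inequalities for both CGI thresholds; boundary cases are pinned
  in tests.
* Permutation p-values use the add-one estimator and are seeded.
* The test suite checks implementations against independent oracles
  written from scratch in the test helpers: enumerate-all-expansions
  consensus scanning, an explicit affine-gap Smith–Waterman recurrence,
  an all-windows CGI caller with string counting, and closed-form /
  hand-computed statistics (e.g. the 3×3 ANOVA with F = 3, df (2, 6)).
  Oracle scales: 1,000 random consensus cases (sequences ≤ 60 nt, motifs
  ≤ 9 nt, degeneracy-bounded), 500 random alignment pairs (≤ 30 nt), 500
  random CGI sequences built from GC-mixture chunks, 1,000 null ANOVA
  tables for the type-I-error calibration (accepted at 5% ± 1.5%), and
  100 seeded plant-then-find replicates per feature type. These sizes
  were chosen to give the properties real bite at desk scale.
* The end-to-end pipeline echoes its configuration, seeds all stochastic
  stages from one integer, skips optional stages with a notice instead of
  aborting, and writes a JSON report plus TSV/BED mirrors whose bytes are
  identical across reruns.

## Known limitations

* Consensus incidence is presence counting; no positional weighting or
  TSS-anchored windows beyond what the caller scans.
* The MRE rule is seed complementarity only — no free-energy model, no
  wobble pairing, no conservation filter; treat calls as candidates.
* CGI detection is the classic parameter set, not an HMM; borderline
  islands are parameter-sensitive by nature.
* ANOVA on motif counts inherits the count-data caveat noted above.
* The stacking-energy band −7.0..−6.5 kcal/mol is meaningful only
  relative to the configured table.
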