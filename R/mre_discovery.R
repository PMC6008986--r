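# Convergent-transcript analysis: Smith-Waterman local alignment of the two
# transcripts to find complementary heteroduplex segments, miR seed
# extraction, seed-complementarity MRE site finding in 3'UTRs, and
# similarity search against a mature-miRNA set.

#' Local alignment scoring parameters
#'
#' DNA scoring in the style of the common EMBOSS defaults: match +5,
#' mismatch -4, affine gaps where a gap of length `L` costs
#' `gap_open + gap_extend * L`.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch score (typically negative).
#' @param gap_open Gap opening penalty, charged as negative (>= 0).
#' @param gap_extend Per-base gap extension penalty, charged as negative (>= 0).
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 5, mismatch = -4, gap_open = 16,
                              gap_extend = 4) {
  stopifnot(match > 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

# Internal: wrap a Biostrings pairwise alignment into the package's result.
new_alignment_result <- function(a_start, a_end, b_start, b_end,
                                 aligned_a, aligned_b, score) {
  cols_a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cols_b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  matches <- sum(cols_a == cols_b & cols_a != "-")
  alen <- length(cols_a)
  structure(list(
    a_start = a_start, a_end = a_end, b_start = b_start, b_end = b_end,
    aligned_a = aligned_a, aligned_b = aligned_b,
    score = score, matches = matches, alignment_length = alen,
    identity_percent = if (alen > 0L) 100 * matches / alen else NA_real_
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> score %.1f, length %d, identity %.1f%% (%d/%d)\n  a: %d-%d\n  b: %d-%d\n",
    x$score, x$alignment_length, x$identity_percent, x$matches,
    x$alignment_length, x$a_start, x$a_end, x$b_start, x$b_end))
  cat("  ", x$aligned_a, "\n  ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Optimal Smith-Waterman local alignment of two sequences
#'
#' Affine-gap local alignment (via Biostrings); RNA is aligned over the DNA
#' alphabet (U folded to T) and coordinates refer to the original inputs.
#' When no positive-scoring pair of substrings exists, `NULL` is returned
#' (the empty alignment, score 0).
#'
#' @param a,b [seq_record]s.
#' @param scoring An [alignment_scoring] object.
#' @return An `alignment_result` with 1-based closed coordinates on each
#'   input, the gapped aligned strings, score, match count, alignment length
#'   and percent identity (matches / alignment columns x 100) — or `NULL`.
#' @export
local_align <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"),
            inherits(scoring, "alignment_scoring"))
  if (nchar(a$residues) == 0L || nchar(b$residues) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    as_dna_string(a), as_dna_string(b), type = "local",
    substitutionMatrix = submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  if (Biostrings::score(pa) <= 0 || Biostrings::nchar(pa) == 0L) return(NULL)
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  new_alignment_result(
    a_start = Biostrings::start(pat), a_end = Biostrings::end(pat),
    b_start = Biostrings::start(sub), b_end = Biostrings::end(sub),
    aligned_a = as.character(pat), aligned_b = as.character(sub),
    score = Biostrings::score(pa))
}

#' Find the complementary segment of a convergent transcript pair
#'
#' Aligns transcript A against the reverse complement of transcript B
#' (both given 5'->3') and reports the optimal local alignment — the
#' candidate heteroduplex segment — when it reaches the length and identity
#' thresholds. B's coordinates are mapped back to B's own 5'->3' frame.
#'
#' @param tx_a,tx_b [seq_record]s, 5'->3'.
#' @param scoring An [alignment_scoring] object.
#' @param min_length Minimum alignment length to report.
#' @param min_identity Minimum percent identity to report.
#' @return An `alignment_result` (with `b_start`/`b_end` in tx_b's frame and
#'   `aligned_b` as read on the reverse complement), or `NULL` when no
#'   segment qualifies.
#' @export
find_complementary_segment <- function(tx_a, tx_b,
                                       scoring = alignment_scoring(),
                                       min_length = 20L, min_identity = 70) {
  res <- local_align(tx_a, reverse_complement(tx_b), scoring)
  if (is.null(res)) return(NULL)
  if (res$alignment_length < min_length || res$identity_percent < min_identity) {
    return(NULL)
  }
  len_b <- nchar(tx_b$residues)
  b_start_fwd <- len_b - res$b_end + 1L
  b_end_fwd <- len_b - res$b_start + 1L
  res$b_start <- b_start_fwd
  res$b_end <- b_end_fwd
  res
}

#' Extract the seed of a mature miRNA
#'
#' The seed is the 5' region principally responsible for target recognition;
#' positions 2-8 by default.
#'
#' @param mir A [seq_record] (RNA or DNA).
#' @param first,last 1-based seed bounds, inclusive.
#' @return The seed as text, 5'->3', in the miR's own alphabet.
#' @export
extract_seed <- function(mir, first = 2L, last = 8L) {
  stopifnot(inherits(mir, "seq_record"))
  first <- as.integer(first); last <- as.integer(last)
  if (first < 1L || last < first) stop("invalid seed bounds", call. = FALSE)
  if (nchar(mir$residues) < last) {
    stop("miR (", nchar(mir$residues), " nt) shorter than seed end ", last,
         call. = FALSE)
  }
  substr(mir$residues, first, last)
}

#' Find miRNA recognition elements in a 3'UTR
#'
#' Reports every UTR window (read 5'->3' in mRNA sense) equal to the reverse
#' complement of the miR seed, Watson-Crick pairing only (no G:U wobble), with
#' up to `max_seed_mismatches` mismatches tolerated.
#'
#' @param utr A [seq_record], mRNA sense 5'->3'.
#' @param mir A [seq_record] mature miRNA.
#' @param max_seed_mismatches 0 (default) or more mismatches tolerated.
#' @param first,last Seed bounds passed to [extract_seed()].
#' @return A data frame with columns `mir_id`, `utr_position` (1-based start
#'   of the site), `site_length`, `mismatches`, `match_type`
#'   (`seed7_exact` / `seed7_1mm`), `seed`.
#' @export
find_mre <- function(utr, mir, max_seed_mismatches = 0L, first = 2L, last = 8L) {
  stopifnot(inherits(utr, "seq_record"), inherits(mir, "seq_record"))
  seed <- extract_seed(mir, first, last)
  site <- revcomp_string(chartr("U", "T", toupper(seed)))
  L <- nchar(site)
  s <- as_dna_string(utr)
  n <- nchar(s)
  empty <- data.frame(mir_id = character(), utr_position = integer(),
                      site_length = integer(), mismatches = integer(),
                      match_type = character(), seed = character())
  if (n < L) return(empty)
  code <- encode_dna(s)
  site_code <- encode_dna(site)
  mm <- rep(0L, n - L + 1L)
  for (j in seq_len(L)) {
    window_codes <- code[j:(j + n - L)]
    # N in the UTR (code 5) never Watson-Crick pairs
    mm <- mm + as.integer(window_codes != site_code[j] | window_codes == 5L)
  }
  pos <- which(mm <= max_seed_mismatches)
  if (length(pos) == 0L) return(empty)
  data.frame(
    mir_id = mir$id,
    utr_position = pos,
    site_length = L,
    mismatches = mm[pos],
    match_type = ifelse(mm[pos] == 0L, "seed7_exact", "seed7_1mm"),
    seed = seed
  )
}

#' Rank a mature-miRNA set by local-alignment similarity to a query
#'
#' Aligns the query against each mature sequence (U folded to T), ranks by
#' alignment score and then percent identity, and returns the top entries.
#'
#' @param query A [seq_record] (e.g. a candidate miR-hosting segment).
#' @param mature_set A list of [seq_record]s of mature miRNAs.
#' @param scoring An [alignment_scoring] object.
#' @param top_n Number of ranked entries to return.
#' @return A data frame with columns `mir_id`, `score`, `identity_percent`,
#'   `alignment_length`, `a_start`, `a_end`, `b_start`, `b_end`; the full
#'   `alignment_result`s are attached as the `"alignments"` attribute, in
#'   ranked order.
#' @export
mir_similarity_search <- function(query, mature_set,
                                  scoring = alignment_scoring(), top_n = 5L) {
  stopifnot(inherits(query, "seq_record"), length(mature_set) > 0L)
  results <- lapply(mature_set, function(m) local_align(query, m, scoring))
  ids <- vapply(mature_set, `[[`, character(1), "id")
  score <- vapply(results, function(r) if (is.null(r)) 0 else r$score, numeric(1))
  ident <- vapply(results, function(r) if (is.null(r)) 0 else r$identity_percent,
                  numeric(1))
  ord <- order(-score, -ident)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  out <- data.frame(
    mir_id = ids[ord],
    score = score[ord],
    identity_percent = ident[ord],
    alignment_length = vapply(results[ord], function(r) {
      if (is.null(r)) 0L else r$alignment_length
    }, integer(1)),
    a_start = vapply(results[ord], function(r) {
      if (is.null(r)) NA_integer_ else as.integer(r$a_start)
    }, integer(1)),
    a_end = vapply(results[ord], function(r) {
      if (is.null(r)) NA_integer_ else as.integer(r$a_end)
    }, integer(1)),
    b_start = vapply(results[ord], function(r) {
      if (is.null(r)) NA_integer_ else as.integer(r$b_start)
    }, integer(1)),
    b_end = vapply(results[ord], function(r) {
      if (is.null(r)) NA_integer_ else as.integer(r$b_end)
    }, integer(1))
  )
  attr(out, "alignments") <- results[ord]
  out
}
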