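# IUPAC consensus and PFM log-odds scanning of promoter sequences.

# IUPAC degenerate nucleotide codes and the concrete bases each denotes.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC degenerate pattern into its concrete strings
#'
#' @param pattern IUPAC string over the 15 standard codes.
#' @return Character vector of all concrete expansions; its length is the
#'   product of the per-position code sizes.
#' @examples
#' expand_iupac("TATAWA") # TATAAA, TATATA
#' @export
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("illegal IUPAC code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sets <- IUPAC_SETS[chars]
  grid <- do.call(expand.grid, c(rev(sets), list(stringsAsFactors = FALSE)))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

# Internal: encode residues as integer codes 1..5 over A,C,G,T,N (U folded to T).
encode_dna <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T", "N"))
}

# Internal: 5 x L logical membership matrix for a consensus pattern; row 5 is
# the sequence letter N, which matches only pattern positions that are N.
consensus_membership <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  vapply(chars, function(code) {
    allowed <- c("A", "C", "G", "T") %in% IUPAC_SETS[[code]]
    c(allowed, code == "N")
  }, logical(5))
}

# Internal: empty hit table with the canonical column layout.
empty_hits <- function() {
  data.frame(motif_name = character(), seq_id = character(),
             start = integer(), end = integer(), strand = character(),
             matched = character(), score = numeric())
}

# Internal: forward-strand consensus scan of an encoded sequence; returns
# 1-based start offsets.
consensus_scan_starts <- function(code, membership) {
  L <- ncol(membership)
  n <- length(code)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & membership[code[j:(j + n - L)], j]
  }
  which(ok)
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Every offset (and strand) where the window matches the pattern under IUPAC
#' semantics is reported; overlapping occurrences are all kept. Reverse-strand
#' hits are reported in forward coordinates with strand `"-"`, and `matched`
#' is the concrete string as read 5'->3' on the hit strand. An `N` in the
#' sequence matches only an `N` in the pattern.
#'
#' @param seq A [seq_record].
#' @param motif A [motif_def] of kind `"consensus"`.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return A data frame of hits with columns `motif_name`, `seq_id`, `start`,
#'   `end` (1-based closed, forward coordinates), `strand`, `matched`,
#'   `score` (1 for consensus hits), ordered by start then strand.
#' @export
scan_consensus <- function(seq, motif, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(seq, "seq_record"), inherits(motif, "motif_def"))
  if (motif$kind != "consensus") stop("motif must be of kind 'consensus'", call. = FALSE)
  s <- as_dna_string(seq)
  n <- nchar(s)
  L <- nchar(motif$consensus)
  if (n < L) return(empty_hits())
  membership <- consensus_membership(motif$consensus)
  out <- list()
  if (strands %in% c("both", "+")) {
    starts <- consensus_scan_starts(encode_dna(s), membership)
    if (length(starts) > 0L) {
      out[["+"]] <- data.frame(
        motif_name = motif$name, seq_id = seq$id,
        start = starts, end = starts + L - 1L, strand = "+",
        matched = substring(s, starts, starts + L - 1L), score = 1)
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp_string(s)
    starts_rc <- consensus_scan_starts(encode_dna(rc), membership)
    if (length(starts_rc) > 0L) {
      out[["-"]] <- data.frame(
        motif_name = motif$name, seq_id = seq$id,
        start = n - (starts_rc + L - 1L) + 1L, end = n - starts_rc + 1L,
        strand = "-",
        matched = substring(rc, starts_rc, starts_rc + L - 1L), score = 1)
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Internal: log2-odds weight matrix from a PFM.
pfm_log_odds <- function(matrix, pseudocount, background) {
  colsums <- colSums(matrix)
  probs <- sweep(matrix + pseudocount, 2L, colsums + 4 * pseudocount, "/")
  log2(probs / background)
}

# Internal: forward PWM scan; returns data.frame(start, score) of windows
# meeting the threshold. Windows containing N are skipped.
pwm_scan_forward <- function(code, W, threshold) {
  L <- ncol(W)
  n <- length(code)
  if (n < L) return(data.frame(start = integer(), score = numeric()))
  nstart <- n - L + 1L
  score <- rep(0, nstart)
  for (j in seq_len(L)) {
    col <- c(W[, j], NA_real_) # N -> NA knocks the window out
    score <- score + col[code[j:(j + n - L)]]
  }
  keep <- !is.na(score) & score >= threshold
  data.frame(start = which(keep), score = score[keep])
}

#' Scan a sequence with a position frequency matrix
#'
#' Each window is scored as the sum over positions of
#' `log2(((count + pseudocount) / (colsum + 4 * pseudocount)) / background)`,
#' and reported as a hit when the score reaches `threshold_fraction` of the
#' maximum attainable score. Both strands are scanned as in
#' [scan_consensus()]; windows containing `N` are never hits.
#'
#' @param seq A [seq_record].
#' @param motif A [motif_def] of kind `"pfm"`.
#' @param threshold_fraction Fraction of the maximum attainable log-odds score
#'   in `(0, 1]`; default 0.8.
#' @param pseudocount Added to every cell before normalization; default 0.25.
#' @param background Length-4 vector of background probabilities for A, C, G,
#'   T; default uniform.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return A data frame of hits as in [scan_consensus()], with `score` the
#'   window log-odds.
#' @export
scan_pwm <- function(seq, motif, threshold_fraction = 0.8, pseudocount = 0.25,
                     background = rep(0.25, 4), strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(seq, "seq_record"), inherits(motif, "motif_def"))
  if (motif$kind != "pfm") stop("motif must be of kind 'pfm'", call. = FALSE)
  stopifnot(length(background) == 4L)
  if (any(background <= 0)) stop("background probabilities must be positive", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  }
  W <- pfm_log_odds(motif$matrix, pseudocount, background)
  threshold <- threshold_fraction * sum(apply(W, 2L, max))
  s <- as_dna_string(seq)
  n <- nchar(s)
  L <- ncol(W)
  out <- list()
  if (strands %in% c("both", "+")) {
    fw <- pwm_scan_forward(encode_dna(s), W, threshold)
    if (nrow(fw) > 0L) {
      out[["+"]] <- data.frame(
        motif_name = motif$name, seq_id = seq$id,
        start = fw$start, end = fw$start + L - 1L, strand = "+",
        matched = substring(s, fw$start, fw$start + L - 1L), score = fw$score)
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp_string(s)
    rv <- pwm_scan_forward(encode_dna(rc), W, threshold)
    if (nrow(rv) > 0L) {
      out[["-"]] <- data.frame(
        motif_name = motif$name, seq_id = seq$id,
        start = n - (rv$start + L - 1L) + 1L, end = n - rv$start + 1L,
        strand = "-",
        matched = substring(rc, rv$start, rv$start + L - 1L), score = rv$score)
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' The package's core-promoter and TFBS consensus catalog
#'
#' Eighteen transcription-factor binding-site motifs given as IUPAC consensus
#' strings — the TATA-box, initiator (INR), DTIE, BRE, DPE, M3, M22, HIF,
#' EBF3, Sox, P53, Oct4, PU.1, Nanog, c-myc, MAD, GAF and GATA elements —
#' plus optional position-frequency-matrix slots for the bidirectional
#' promoter factors NRF1 and ZNF143 loaded from JASPAR-format files.
#'
#' @param nrf1_pfm,znf143_pfm Optional paths to JASPAR PFM files for the NRF1
#'   and ZNF143 matrices; when omitted those slots are absent from the catalog.
#' @return A named list of [motif_def]s.
#' @export
motif_catalog <- function(nrf1_pfm = NULL, znf143_pfm = NULL) {
  consensus <- c(
    "TATA-box" = "TATAWA", "INR" = "YYANWYY", "DTIE" = "GBBRDNHGG",
    "BRE" = "SSRCGCC", "DPE" = "RGWCGTG", "M3" = "SCGGAAGY",
    "M22" = "TGCGCANK", "HIF" = "RCGTG", "EBF3" = "CCCNNGGG",
    "Sox" = "WWCAAWG", "P53" = "RRRCWWGY", "Oct4" = "TTTKSWTW",
    "PU.1" = "GAGGAA", "Nanog" = "SRSSATTANS", "c-myc" = "CACRTG",
    "MAD" = "CCGNCGCG", "GAF" = "GAGAG", "GATA" = "WGATAR")
  catalog <- mapply(function(name, pat) {
    motif_def(name, consensus = pat, source = "core promoter/TFBS consensus")
  }, names(consensus), consensus, SIMPLIFY = FALSE)
  if (!is.null(nrf1_pfm)) catalog[["NRF1"]] <- read_jaspar_pfm(nrf1_pfm, name = "NRF1")
  if (!is.null(znf143_pfm)) catalog[["ZNF143"]] <- read_jaspar_pfm(znf143_pfm, name = "ZNF143")
  catalog
}

# Internal: greedy left-to-right selection of non-overlapping hits per strand.
greedy_non_overlapping <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(nrow(hits))
  for (str in unique(hits$strand)) {
    idx <- which(hits$strand == str)
    idx <- idx[order(hits$start[idx])]
    last_end <- -Inf
    for (i in idx) {
      if (hits$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- hits$end[i]
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Tabulate motif incidence across promoters
#'
#' Counts hits of every catalog motif (both strands) in every promoter,
#' delegating to [scan_consensus()] or [scan_pwm()] per motif kind.
#'
#' @param promoters A list of [seq_record]s with unique ids.
#' @param catalog A named list of [motif_def]s, e.g. from [motif_catalog()].
#' @param overlapping Count all (self-)overlapping occurrences (default), or
#'   greedy left-to-right non-overlapping occurrences when `FALSE`.
#' @param ... Passed to [scan_pwm()] for PFM motifs.
#' @return A data frame with one row per promoter (row names are promoter
#'   ids) and one integer column per motif, in catalog order.
#' @export
motif_incidence_table <- function(promoters, catalog, overlapping = TRUE, ...) {
  if (length(promoters) == 0L) stop("empty promoter set", call. = FALSE)
  if (length(catalog) == 0L) stop("empty motif catalog", call. = FALSE)
  ids <- vapply(promoters, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate promoter id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  motif_names <- vapply(catalog, `[[`, character(1), "name")
  counts <- vapply(catalog, function(m) {
    vapply(promoters, function(p) {
      hits <- if (m$kind == "consensus") scan_consensus(p, m) else scan_pwm(p, m, ...)
      if (!overlapping) hits <- greedy_non_overlapping(hits)
      nrow(hits)
    }, integer(1))
  }, integer(length(promoters)))
  counts <- matrix(counts, nrow = length(promoters),
                   dimnames = list(ids, motif_names))
  as.data.frame(counts)
}
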