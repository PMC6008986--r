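# Seeded generators of fixture sequences and expression tables with
# ground-truth records, emulating the documented structure of the study's
# inputs (transcripts of 5,266 and 422 nt sharing a planted 52-nt
# complementary segment at 75% identity, CGI-bearing and CGI-less promoters
# with planted motifs) so every downstream stage is testable offline.

# Internal: a planted-truth record.
planted_truth <- function(feature_type, seq_id, position, length,
                          identity_fraction = NA_real_, motif_name = NA_character_) {
  data.frame(feature_type = feature_type, seq_id = seq_id,
             position = as.integer(position), length = as.integer(length),
             identity_fraction = identity_fraction, motif_name = motif_name)
}

#' Generate an i.i.d. background sequence
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`; identical `(length, gc, seed)` give
#' byte-identical output.
#'
#' @param length Sequence length, at least 1.
#' @param gc GC fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @param id Record id.
#' @return A [seq_record].
#' @export
gen_background <- function(length, gc = 0.5, seed = 1L, id = "background") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("gc must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- withr::with_seed(seed, {
    sample(names(p), length, replace = TRUE, prob = p)
  })
  seq_record(id, paste(bases, collapse = ""))
}

#' Plant a concrete motif occurrence into a sequence
#'
#' A concrete expansion of the motif's IUPAC consensus is sampled uniformly
#' and overwrites the region starting at `position`.
#'
#' @param seq A [seq_record].
#' @param motif A [motif_def] of kind `"consensus"`.
#' @param position 1-based start; the motif must fit.
#' @param seed Integer seed for the expansion draw.
#' @return A list with `seq` (modified [seq_record]) and `truth` (one-row
#'   data frame recording the plant).
#' @export
plant_motif <- function(seq, motif, position, seed = 1L) {
  stopifnot(inherits(seq, "seq_record"), inherits(motif, "motif_def"))
  if (motif$kind != "consensus") stop("motif must be of kind 'consensus'", call. = FALSE)
  L <- nchar(motif$consensus)
  n <- nchar(seq$residues)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position + L - 1L > n) {
    stop("motif does not fit at position ", position, call. = FALSE)
  }
  codes <- strsplit(motif$consensus, "", fixed = TRUE)[[1]]
  concrete <- withr::with_seed(seed, {
    paste(vapply(codes, function(code) {
      set <- IUPAC_SETS[[code]]
      set[[sample.int(length(set), 1L)]]
    }, character(1)), collapse = "")
  })
  residues <- paste0(substr(seq$residues, 1L, position - 1L), concrete,
                     substr(seq$residues, position + L, n))
  list(seq = seq_record(seq$id, residues, seq$alphabet),
       truth = planted_truth("motif", seq$id, position, L,
                             motif_name = motif$name))
}

#' Generate a sequence carrying one CpG island
#'
#' The island region is drawn CpG-rich (and re-drawn under a derived seed
#' until it satisfies GC > 0.5 and observed/expected CpG > 0.6, so the
#' criteria hold by construction); the flanks are drawn AT-rich so that no
#' window fully outside the island qualifies.
#'
#' @param total_length Total sequence length.
#' @param island_start 1-based island start.
#' @param island_length Island length, at least 200 nt (the minimum
#'   reportable island).
#' @param seed Integer seed.
#' @param id Record id.
#' @param flank_gc GC fraction of the flanks; default 0.02.
#' @return A list with `seq` and `truth` as in [plant_motif()].
#' @export
gen_cgi_sequence <- function(total_length, island_start, island_length,
                             seed = 1L, id = "cgi_seq", flank_gc = 0.02) {
  total_length <- as.integer(total_length)
  island_start <- as.integer(island_start)
  island_length <- as.integer(island_length)
  if (island_length < 200L) {
    stop("island_length must be >= 200 (minimum reportable island)", call. = FALSE)
  }
  if (island_start < 1L || island_start + island_length - 1L > total_length) {
    stop("island does not fit inside total_length", call. = FALSE)
  }
  draw_island <- function(sub_seed) {
    withr::with_seed(sub_seed, {
      out <- character(0)
      while (sum(nchar(out)) < island_length) {
        # favour CG dinucleotides; remainder G/C-rich singles
        piece <- if (stats::runif(1) < 0.35) "CG" else {
          sample(c("G", "C", "A", "T"), 1L, prob = c(0.3, 0.3, 0.2, 0.2))
        }
        out <- c(out, piece)
      }
      substr(paste(out, collapse = ""), 1L, island_length)
    })
  }
  island <- draw_island(seed)
  tries <- 0L
  while ((gc_fraction(island) <= 0.5 || obs_exp_cpg(island) <= 0.6) && tries < 100L) {
    tries <- tries + 1L
    island <- draw_island(seed + 7919L * tries)
  }
  left_len <- island_start - 1L
  right_len <- total_length - (island_start + island_length - 1L)
  left <- if (left_len > 0L) {
    gen_background(left_len, flank_gc, seed + 1L)$residues
  } else ""
  right <- if (right_len > 0L) {
    gen_background(right_len, flank_gc, seed + 2L)$residues
  } else ""
  rec <- seq_record(id, paste0(left, island, right))
  list(seq = rec,
       truth = planted_truth("cgi", id, island_start, island_length))
}

# Internal: sample k non-adjacent positions from first..last (inclusive),
# uniformly over the valid configurations, under the current RNG.
sample_non_adjacent <- function(k, first, last) {
  span <- last - first + 1L
  if (k > (span + 1L) %/% 2L) stop("too many non-adjacent positions requested",
                                   call. = FALSE)
  base <- sort(sample.int(span - k + 1L, k))
  base + seq_len(k) - 1L + first - 1L
}

#' Generate a convergent transcript pair with a planted complementary segment
#'
#' Emulates a convergently transcribed mRNA/ncRNA pair whose transcripts can
#' form a heteroduplex: transcript A carries a segment `S` and transcript B
#' carries the reverse complement of a variant `S'` differing from `S` at
#' exactly `seg_len - round(identity * seg_len)` positions. Mismatch
#' positions are internal (the first and last 5 segment positions always
#' match) and never adjacent, and the flanks of A and B are poly-A and
#' poly-C respectively, so the optimal local alignment of A against the
#' reverse complement of B is exactly the planted segment. Defaults mirror a
#' 5,266-nt mRNA and a 422-nt ncRNA sharing a 52-nt segment at 75% identity.
#'
#' @param len_a,len_b Transcript lengths.
#' @param seg_len Planted segment length.
#' @param identity Target identity fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return A list with `tx_a`, `tx_b` ([seq_record]s) and `truth` (two rows,
#'   one per transcript, recording segment position, length and identity).
#' @export
gen_convergent_pair <- function(len_a = 5266L, len_b = 422L, seg_len = 52L,
                                identity = 0.75, seed = 1L) {
  len_a <- as.integer(len_a); len_b <- as.integer(len_b)
  seg_len <- as.integer(seg_len)
  if (identity <= 0 || identity > 1) {
    stop("identity must lie in (0, 1]", call. = FALSE)
  }
  if (seg_len > min(len_a, len_b)) {
    stop("seg_len exceeds a transcript length", call. = FALSE)
  }
  n_mismatch <- seg_len - as.integer(round(identity * seg_len))
  if (n_mismatch > 0L && seg_len < 11L) {
    stop("segment too short to host internal mismatches with matched 5-nt ends",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    seg <- paste(sample(c("A", "C", "G", "T"), seg_len, replace = TRUE),
                 collapse = "")
    seg_chars <- strsplit(seg, "", fixed = TRUE)[[1]]
    var_chars <- seg_chars
    if (n_mismatch > 0L) {
      pos <- sample_non_adjacent(n_mismatch, 6L, seg_len - 5L)
      for (p in pos) {
        var_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seg_chars[p]), 1L)
      }
    }
    variant <- paste(var_chars, collapse = "")
    a_start <- sample.int(len_a - seg_len + 1L, 1L)
    b_start <- sample.int(len_b - seg_len + 1L, 1L)
    a_res <- paste0(strrep("A", a_start - 1L), seg,
                    strrep("A", len_a - a_start - seg_len + 1L))
    rc_variant <- revcomp_string(variant)
    b_res <- paste0(strrep("C", b_start - 1L), rc_variant,
                    strrep("C", len_b - b_start - seg_len + 1L))
    truth <- rbind(
      planted_truth("complementary_segment", "tx_a", a_start, seg_len,
                    identity_fraction = (seg_len - n_mismatch) / seg_len),
      planted_truth("complementary_segment", "tx_b", b_start, seg_len,
                    identity_fraction = (seg_len - n_mismatch) / seg_len))
    list(tx_a = seq_record("tx_a", a_res),
         tx_b = seq_record("tx_b", b_res),
         truth = truth)
  })
}

#' Generate a tissue-by-replicate expression table
#'
#' Values are `group_means[g] + Normal(0, noise_sd)` on an expression scale
#' akin to normalized fluorescence intensity; the default emulates 11 tissues
#' with two replicate measurements each.
#'
#' @param n_groups Number of tissue groups (at least 2).
#' @param replicates Replicates per group, at least 2.
#' @param group_means Numeric vector of per-group means (recycled scalar
#'   allowed); default all equal (a null table).
#' @param noise_sd Positive noise standard deviation.
#' @param seed Integer seed.
#' @return A data frame with columns `group` (factor), `replicate`, `value`.
#' @export
gen_expression_table <- function(n_groups = 11L, replicates = 2L,
                                 group_means = rep(100, n_groups),
                                 noise_sd = 10, seed = 1L) {
  n_groups <- as.integer(n_groups)
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (n_groups < 2L) stop("n_groups must be >= 2", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive", call. = FALSE)
  }
  group_means <- rep_len(group_means, n_groups)
  groups <- paste0("tissue", seq_len(n_groups))
  values <- withr::with_seed(seed, {
    rep(group_means, each = replicates) +
      stats::rnorm(n_groups * replicates, 0, noise_sd)
  })
  data.frame(
    group = factor(rep(groups, each = replicates), levels = groups),
    replicate = rep(seq_len(replicates), times = n_groups),
    value = values
  )
}
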