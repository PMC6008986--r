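# Dinucleotide base-stacking energy profiles along regulatory sequences.
# Low (more negative) stacking energy marks easily unstacked DNA, a
# structural signature of TSS neighbourhoods and several core-promoter
# motifs; the profile relates sequence structure to located motif hits.

ALL_DINUCLEOTIDES <- as.vector(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0))

#' Load a dinucleotide stacking-energy table
#'
#' Reads a two-column TSV (`dinucleotide`, `energy_kcal_mol`) mapping each of
#' the 16 dinucleotide steps to a stacking energy in kcal/mol. The packaged
#' default transcribes the B-DNA stacking energies of Ornstein et al. (1978);
#' any complete, finite table may be substituted.
#'
#' @param path Path to an energy TSV; default is the packaged table.
#' @return Named numeric vector of length 16 (class `energy_table`).
#' @export
read_energy_table <- function(path = system.file("extdata",
                                                 "stacking_energies.tsv",
                                                 package = "regchar")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "energy_kcal_mol") %in% names(tab))) {
    stop("energy table needs columns 'dinucleotide' and 'energy_kcal_mol'",
         call. = FALSE)
  }
  values <- stats::setNames(tab$energy_kcal_mol, toupper(tab$dinucleotide))
  missing_keys <- setdiff(ALL_DINUCLEOTIDES, names(values))
  if (length(missing_keys) > 0L) {
    stop("energy table is missing dinucleotide(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  values <- values[ALL_DINUCLEOTIDES]
  if (any(!is.finite(values))) stop("energy values must be finite", call. = FALSE)
  structure(values, class = "energy_table")
}

# Internal: energy_profile constructor.
new_energy_profile <- function(seq_id, values, window = 1L) {
  structure(list(seq_id = seq_id, values = as.numeric(values),
                 window = as.integer(window)),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> %s: %d steps (window %d), mean %.2f kcal/mol\n",
              x$seq_id, length(x$values), x$window,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Per-step stacking-energy profile of a sequence
#'
#' Step `i` (indexed by its left base) carries the energy of the dinucleotide
#' `seq[i..i+1]`; a raw profile has `L - 1` values for a sequence of length
#' `L`. Steps touching `N` are emitted as `NA`.
#'
#' @param seq A [seq_record] of length at least 2.
#' @param table An `energy_table` from [read_energy_table()].
#' @return An `energy_profile` with fields `seq_id`, `values` (kcal/mol),
#'   `window = 1`.
#' @export
dinucleotide_profile <- function(seq, table = read_energy_table()) {
  stopifnot(inherits(seq, "seq_record"), inherits(table, "energy_table"))
  s <- as_dna_string(seq)
  n <- nchar(s)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  steps <- paste0(chars[-n], chars[-1L])
  values <- unclass(table)[steps] # unmatched (N-touching) steps become NA
  new_energy_profile(seq$id, unname(values), window = 1L)
}

#' Smooth an energy profile by a sliding arithmetic mean
#'
#' @param profile An `energy_profile`.
#' @param window Window width in steps; 1 returns the profile unchanged. A
#'   smoothed profile is shorter by `window - 1`. Windows touching `NA`
#'   steps yield `NA`.
#' @return An `energy_profile` with the window recorded.
#' @export
smooth_profile <- function(profile, window) {
  stopifnot(inherits(profile, "energy_profile"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > length(profile$values)) {
    stop("window (", window, ") exceeds profile length (",
         length(profile$values), ")", call. = FALSE)
  }
  if (window == 1L) return(profile)
  smoothed <- rowMeans(stats::embed(profile$values, window))
  new_energy_profile(profile$seq_id, smoothed, window = window)
}

#' Runs of steps inside an energy band
#'
#' Reports maximal runs of consecutive steps whose (possibly smoothed) value
#' lies in the closed band `[lo, hi]` kcal/mol. The default band,
#' -7.0 to -6.5 kcal/mol, brackets the stacking energies characteristic of
#' TATA, INR and DTIE motif neighbourhoods under the packaged table; it is a
#' parameter because it is table-dependent.
#'
#' @param profile An `energy_profile`.
#' @param lo,hi Band limits in kcal/mol, `lo <= hi`.
#' @return A data frame with columns `seq_id`, `start`, `end` (1-based closed
#'   step indices), `length`, `mean_energy`.
#' @export
low_energy_regions <- function(profile, lo = -7.0, hi = -6.5) {
  stopifnot(inherits(profile, "energy_profile"))
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  v <- profile$values
  inside <- !is.na(v) & v >= lo & v <= hi
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      length = integer(), mean_energy = numeric())
  if (!any(inside)) return(empty)
  r <- rle(inside)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  starts <- run_start[keep]
  ends <- run_end[keep]
  data.frame(
    seq_id = profile$seq_id,
    start = starts, end = ends, length = ends - starts + 1L,
    mean_energy = vapply(seq_along(starts),
                         function(i) mean(v[starts[i]:ends[i]]), numeric(1))
  )
}

# Internal: step indices covered by a hit over bases [start, end] — the steps
# whose both bases fall inside the hit.
hit_steps <- function(start, end, n_steps) {
  if (end <= start) return(integer(0))
  seq.int(max(1L, start), min(n_steps, end - 1L))
}

#' Stacking energy at motif hits versus background
#'
#' Compares the mean profile value over steps covered by a set of motif hits
#' with the mean over all remaining steps, and attaches an empirical
#' permutation p-value obtained by randomly repositioning the hit set
#' (preserving the number and lengths of hits) and asking how often the
#' permuted at-hit mean is at least as low as the observed one.
#'
#' @param profile A raw (`window = 1`) `energy_profile`.
#' @param hits A data frame with columns `start`, `end` (1-based closed base
#'   coordinates on the profiled sequence).
#' @param n_permutations Number of random repositionings; 0 skips the test.
#' @param seed Integer seed for the permutations.
#' @return A list with `mean_at_hits`, `mean_background` (`NA` when the hits
#'   cover every step), `empirical_p` (`NA` when `n_permutations = 0`),
#'   `n_steps_at_hits`, `n_permutations`.
#' @export
colocalize_energy <- function(profile, hits, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(profile, "energy_profile"), is.data.frame(hits))
  n_steps <- length(profile$values)
  n_bases <- n_steps + 1L
  if (nrow(hits) == 0L) stop("no hits supplied", call. = FALSE)
  if (any(hits$start < 1L) || any(hits$end > n_bases)) {
    stop("hit(s) outside the profiled sequence", call. = FALSE)
  }
  cover <- function(starts, ends) {
    idx <- unlist(mapply(hit_steps, starts, ends,
                         MoreArgs = list(n_steps = n_steps), SIMPLIFY = FALSE))
    unique(idx)
  }
  obs_idx <- cover(hits$start, hits$end)
  if (length(obs_idx) == 0L) stop("hits cover no complete step", call. = FALSE)
  mean_at_hits <- mean(profile$values[obs_idx], na.rm = TRUE)
  bg_idx <- setdiff(seq_len(n_steps), obs_idx)
  mean_background <- if (length(bg_idx) == 0L) NA_real_ else {
    mean(profile$values[bg_idx], na.rm = TRUE)
  }
  empirical_p <- NA_real_
  if (n_permutations > 0L) {
    lens <- hits$end - hits$start + 1L
    perm_means <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(k) {
        s <- vapply(lens, function(l) sample.int(n_bases - l + 1L, 1L), integer(1))
        mean(profile$values[cover(s, s + lens - 1L)], na.rm = TRUE)
      }, numeric(1))
    })
    empirical_p <- (1 + sum(perm_means <= mean_at_hits)) / (n_permutations + 1)
  }
  list(mean_at_hits = mean_at_hits, mean_background = mean_background,
       empirical_p = empirical_p, n_steps_at_hits = length(obs_idx),
       n_permutations = as.integer(n_permutations))
}
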