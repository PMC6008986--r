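# CpG-island detection by the classic GC-content and observed/expected
# CpG criteria (window 200, GC > 0.5, obs/exp > 0.6, minimum length 200).

#' CpG-island detection parameters
#'
#' Defaults are the classic criteria: a region of at least 200 nt with GC
#' fraction above 0.5 and observed/expected CpG ratio above 0.6, assessed in
#' a 200-nt window slid 1 nt at a time. Both thresholds are strict
#' inequalities.
#'
#' @param min_length Minimum reported region length in nt.
#' @param gc_min GC-fraction threshold (exclusive).
#' @param oe_min Observed/expected CpG threshold (exclusive).
#' @param window Sliding-window width in nt.
#' @param step Window step in nt.
#' @return A list of class `cgi_params`.
#' @export
cgi_params <- function(min_length = 200L, gc_min = 0.5, oe_min = 0.6,
                       window = 200L, step = 1L) {
  stopifnot(min_length >= 1L, window >= 1L, step >= 1L,
            gc_min >= 0, gc_min <= 1, oe_min >= 0)
  structure(list(min_length = as.integer(min_length), gc_min = gc_min,
                 oe_min = oe_min, window = as.integer(window),
                 step = as.integer(step)),
            class = "cgi_params")
}

#' GC fraction of a window
#'
#' @param window Non-empty nucleotide string.
#' @return `(#C + #G) / length`.
#' @export
gc_fraction <- function(window) {
  stopifnot(is.character(window), length(window) == 1L)
  if (!nzchar(window)) stop("empty window", call. = FALSE)
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  sum(chars == "C" | chars == "G") / length(chars)
}

#' Observed/expected CpG ratio of a window
#'
#' Computed as `N_CpG * L / (N_C * N_G)`; defined as 0 when the window lacks
#' C or G. CpG dinucleotides cannot self-overlap, so counting is unambiguous.
#'
#' @param window Non-empty nucleotide string.
#' @return Nonnegative real.
#' @examples
#' obs_exp_cpg("CGCGCGCG") # 4 * 8 / (4 * 4) = 2
#' @export
obs_exp_cpg <- function(window) {
  stopifnot(is.character(window), length(window) == 1L)
  if (!nzchar(window)) stop("empty window", call. = FALSE)
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  n <- length(chars)
  n_c <- sum(chars == "C")
  n_g <- sum(chars == "G")
  if (n_c == 0L || n_g == 0L) return(0)
  n_cg <- if (n >= 2L) sum(chars[-n] == "C" & chars[-1L] == "G") else 0L
  n_cg * n / (n_c * n_g)
}

#' Find CpG islands in a sequence
#'
#' Slides a window along the forward strand, marks windows satisfying both
#' criteria (strict inequalities), merges overlapping or adjacent marked
#' windows, and reports merged regions of at least `min_length` nt with GC
#' fraction and observed/expected CpG recomputed on the merged span. `N`
#' counts as neither C nor G.
#'
#' @param seq A [seq_record].
#' @param params A [cgi_params] object.
#' @return A data frame with columns `seq_id`, `start`, `end` (1-based
#'   closed, sequence-local), `length`, `gc_fraction`, `obs_exp_cpg`;
#'   zero rows when nothing qualifies.
#' @export
find_cgi <- function(seq, params = cgi_params()) {
  stopifnot(inherits(seq, "seq_record"), inherits(params, "cgi_params"))
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      length = integer(), gc_fraction = numeric(),
                      obs_exp_cpg = numeric())
  s <- as_dna_string(seq)
  n <- nchar(s)
  w <- params$window
  if (n < w) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_cg <- c(is_c[-n] & is_g[-1L], FALSE) # CG step starting at each position
  cum_c <- cumsum(is_c)
  cum_g <- cumsum(is_g)
  cum_cg <- cumsum(is_cg)
  starts <- seq.int(1L, n - w + 1L, by = params$step)
  ends <- starts + w - 1L
  range_sum <- function(cum, a, b) cum[b] - c(0, cum)[a] # c(0,cum)[a] = cum[a-1]
  n_c <- range_sum(cum_c, starts, ends)
  n_g <- range_sum(cum_g, starts, ends)
  n_cg <- if (w >= 2L) range_sum(cum_cg, starts, ends - 1L) else rep(0, length(starts))
  gc <- (n_c + n_g) / w
  oe <- ifelse(n_c > 0 & n_g > 0, n_cg * w / (n_c * n_g), 0)
  marked <- gc > params$gc_min & oe > params$oe_min
  if (!any(marked)) return(empty)
  # merge overlapping/adjacent marked windows
  ms <- starts[marked]
  me <- ends[marked]
  brk <- which(ms[-1L] > me[-length(me)] + 1L)
  reg_start <- ms[c(1L, brk + 1L)]
  reg_end <- me[c(brk, length(me))]
  keep <- (reg_end - reg_start + 1L) >= params$min_length
  if (!any(keep)) return(empty)
  reg_start <- reg_start[keep]
  reg_end <- reg_end[keep]
  spans <- substring(s, reg_start, reg_end)
  data.frame(
    seq_id = seq$id,
    start = reg_start, end = reg_end,
    length = reg_end - reg_start + 1L,
    gc_fraction = vapply(spans, gc_fraction, numeric(1), USE.NAMES = FALSE),
    obs_exp_cpg = vapply(spans, obs_exp_cpg, numeric(1), USE.NAMES = FALSE)
  )
}
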