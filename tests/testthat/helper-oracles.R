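# Independent brute-force oracles. These deliberately share no code with the
# package: the IUPAC map is re-declared, scanning enumerates concrete
# expansions and compares substrings, the aligner is a plain dynamic program
# with explicit affine recurrences, and CGI calling loops over every window
# with string counting.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Recursive enumeration of all concrete strings of an IUPAC pattern.
oracle_expand <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  out <- ""
  for (ch in chars) {
    out <- as.vector(outer(out, ORACLE_IUPAC[[ch]], paste0))
  }
  out
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Enumerate-and-compare consensus scan over both strands: returns a data
# frame of (start, end, strand) in forward coordinates, sorted.
oracle_scan <- function(seq_string, pattern) {
  words <- oracle_expand(pattern)
  L <- nchar(pattern)
  n <- nchar(seq_string)
  rows <- list()
  if (n >= L) {
    for (off in 1:(n - L + 1)) {
      win <- substr(seq_string, off, off + L - 1)
      if (win %in% words) {
        rows[[length(rows) + 1]] <- data.frame(start = off, end = off + L - 1,
                                               strand = "+")
      }
      win_rc <- oracle_revcomp(win)
      if (win_rc %in% words) {
        rows[[length(rows) + 1]] <- data.frame(start = off, end = off + L - 1,
                                               strand = "-")
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Smith-Waterman score with explicit affine-gap recurrences; a gap of total
# length L costs gap_open + gap_extend * L (first gapped base pays both).
oracle_sw_score <- function(a, b, match = 5, mismatch = -4,
                            gap_open = 16, gap_extend = 4) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  neg <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(neg, n + 1, m + 1) # gap in b (consumes a)
  Iy <- matrix(neg, n + 1, m + 1) # gap in a (consumes b)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# All-windows CpG-island oracle: per-window counting with gregexpr, loop
# merge, minimum-length filter; returns (start, end) rows.
oracle_cgi <- function(seq_string, min_length = 200, gc_min = 0.5,
                       oe_min = 0.6, window = 200, step = 1) {
  n <- nchar(seq_string)
  if (n < window) return(data.frame(start = integer(), end = integer()))
  count_pat <- function(s, pat) {
    hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0 else length(hits)
  }
  starts <- seq(1, n - window + 1, by = step)
  marked <- logical(length(starts))
  for (k in seq_along(starts)) {
    win <- substr(seq_string, starts[k], starts[k] + window - 1)
    nc <- count_pat(win, "C"); ng <- count_pat(win, "G")
    ncg <- count_pat(win, "CG")
    gc <- (nc + ng) / window
    oe <- if (nc > 0 && ng > 0) ncg * window / (nc * ng) else 0
    marked[k] <- gc > gc_min && oe > oe_min
  }
  regions <- list()
  cur <- NULL
  for (k in seq_along(starts)) {
    if (!marked[k]) next
    s0 <- starts[k]; e0 <- starts[k] + window - 1
    if (!is.null(cur) && s0 <= cur[2] + 1) {
      cur[2] <- max(cur[2], e0)
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
      cur <- c(s0, e0)
    }
  }
  if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
  out <- do.call(rbind, lapply(regions, function(r) {
    data.frame(start = r[1], end = r[2])
  }))
  if (is.null(out)) out <- data.frame(start = integer(), end = integer())
  out[out$end - out$start + 1 >= min_length, , drop = FALSE]
}

# Random ACGT string under the current RNG.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random IUPAC pattern with bounded degeneracy (keeps expansion sets small).
random_pattern <- function(len, max_degenerate = 3) {
  plain <- c("A", "C", "G", "T")
  codes <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  chars <- sample(plain, len, replace = TRUE)
  k <- sample(0:min(max_degenerate, len), 1)
  if (k > 0) {
    idx <- sample(len, k)
    chars[idx] <- sample(codes, k, replace = TRUE)
  }
  paste(chars, collapse = "")
}
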