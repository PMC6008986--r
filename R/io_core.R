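# Sequence records, genomic intervals, and the I/O shared by every stage.

DNA_LETTERS <- c("A", "C", "G", "T", "N")
RNA_LETTERS <- c("A", "C", "G", "U", "N")

#' Create a sequence record
#'
#' The basic container used throughout the package: an identified DNA or RNA
#' string. Residues are uppercased on construction and validated against the
#' declared alphabet (the ambiguity code `N` is always allowed).
#'
#' @param id Character scalar, unique identifier of the sequence.
#' @param residues Character scalar over `A,C,G,T` (DNA) or `A,C,G,U` (RNA),
#'   plus `N`. Case-insensitive.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return An object of class `seq_record` with fields `id`, `alphabet`,
#'   `residues`.
#' @examples
#' seq_record("p1", "acgtACGT")
#' @export
seq_record <- function(id, residues, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  allowed <- if (alphabet == "DNA") DNA_LETTERS else RNA_LETTERS
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), allowed)
  if (length(bad) > 0L) {
    stop("illegal character(s) for ", alphabet, " alphabet in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, alphabet = alphabet, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat(sprintf("<seq_record> %s [%s, %d nt]\n  %s\n", x$id, x$alphabet, n, shown))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

# Internal: residues as DNA (U -> T), so one scanning/alignment engine serves
# both alphabets. The original alphabet is restored on output by the callers.
as_dna_string <- function(rec) {
  if (rec$alphabet == "RNA") chartr("U", "T", rec$residues) else rec$residues
}

# Internal: reverse-complement a plain DNA character scalar.
revcomp_string <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Reverse complement of a sequence record
#'
#' Length-preserving involution; `N` maps to `N`. RNA records are complemented
#' over the RNA alphabet (A-U pairing) and keep their alphabet.
#'
#' @param seq A [seq_record].
#' @return A `seq_record` with the same id and alphabet.
#' @examples
#' reverse_complement(seq_record("x", "AAACCC"))$residues # "GGGTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "seq_record"))
  rc <- revcomp_string(as_dna_string(seq))
  if (seq$alphabet == "RNA") rc <- chartr("T", "U", rc)
  seq_record(seq$id, rc, seq$alphabet)
}

#' Create a genomic interval (1-based, fully closed)
#'
#' All externally visible coordinates in this package are 1-based and
#' inclusive at both ends, the convention of GenBank and of printed genome
#' browser coordinates; conversion to BED's 0-based half-open convention
#' happens only at (de)serialization.
#'
#' @param chrom Chromosome / sequence name.
#' @param start,end Integers, `1 <= start <= end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1) {
    stop("interval start must be >= 1", call. = FALSE)
  }
  if (end < start) {
    stop("interval end (", end, ") < start (", start, ")", call. = FALSE)
  }
  if (!strand %in% c("+", "-", ".")) stop("strand must be +, - or .", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Inclusive length of a genomic interval
#'
#' @param iv A [genomic_interval].
#' @return `end - start + 1`.
#' @examples
#' length_inclusive(parse_interval("chr1:241,531,883-241,595,647")) # 63765
#' @export
length_inclusive <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1
}

#' Parse a printed coordinate string
#'
#' Accepts the `"chr1:241,531,883-241,595,647"` style used in genome browsers
#' and papers; thousands separators are ignored and an optional trailing
#' `:+` / `:-` sets the strand.
#'
#' @param x Character scalar.
#' @return A [genomic_interval].
#' @export
parse_interval <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub(",", "", gsub("\\s", "", x))
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)(:([+.-]))?$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse interval string: ", x, call. = FALSE)
  strand <- if (nzchar(m[6])) m[6] else "."
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]), strand)
}

#' Read sequences from a FASTA file
#'
#' Records are returned in file order with residues uppercased. The declared
#' alphabet controls validation: `U` is only legal under `"RNA"`, `T` only
#' under `"DNA"`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return A named list of [seq_record]s (names are record ids).
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # Pre-scan for line-accurate error reporting before handing off to Biostrings.
  lines <- readLines(path)
  allowed <- if (alphabet == "DNA") DNA_LETTERS else RNA_LETTERS
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      if (!nzchar(trimws(sub("^>", "", ln)))) {
        stop("malformed FASTA header at line ", i, " of ", path, call. = FALSE)
      }
      seen_header <- TRUE
    } else {
      if (!seen_header) {
        stop("sequence data before any FASTA header at line ", i, " of ", path,
             call. = FALSE)
      }
      chars <- unique(strsplit(toupper(trimws(ln)), "", fixed = TRUE)[[1]])
      bad <- setdiff(chars, allowed)
      if (length(bad) > 0L) {
        stop("illegal ", alphabet, " character(s) '",
             paste(bad, collapse = ""), "' at line ", i, " of ", path,
             call. = FALSE)
      }
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  recs <- lapply(seq_along(set), function(i) {
    seq_record(ids[[i]], as.character(set[[i]]), alphabet)
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to a FASTA file
#'
#' @param records A list of [seq_record]s.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(vapply(records, inherits, logical(1), "seq_record")))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write located features as BED6
#'
#' Features are held in memory as 1-based closed intervals; BED is 0-based
#' half-open on disk, so an interval `[s, e]` serializes as `start = s - 1`,
#' `end = e`.
#'
#' @param hits A data frame with columns `chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand` (defaulted to `"."`, `0`, `"."`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(hits))
  if (length(missing_cols) > 0L) {
    stop("hits lack required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(hits$end < hits$start)) {
    stop("interval(s) with end < start cannot be serialized", call. = FALSE)
  }
  name <- if ("name" %in% names(hits)) hits$name else rep(".", nrow(hits))
  score <- if ("score" %in% names(hits)) hits$score else rep(0, nrow(hits))
  strand <- if ("strand" %in% names(hits)) hits$strand else rep(".", nrow(hits))
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand values must be +, - or .", call. = FALSE)
  }
  out <- data.frame(chrom = hits$chrom, start = hits$start - 1L, end = hits$end,
                    name = name, score = score, strand = strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into 1-based closed intervals
#'
#' @param path Path to a BED file (3 to 6 columns).
#' @return A data frame with columns `chrom`, `start`, `end` (1-based closed),
#'   `name`, `score`, `strand`; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character())
  if (file.size(path) == 0L) return(empty)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file must have >= 3 columns: ", path, call. = FALSE)
  data.frame(
    chrom = as.character(raw[[1]]),
    start = raw[[2]] + 1,
    end = raw[[3]],
    name = if (ncol(raw) >= 4L) as.character(raw[[4]]) else ".",
    score = if (ncol(raw) >= 5L) raw[[5]] else 0,
    strand = if (ncol(raw) >= 6L) as.character(raw[[6]]) else "."
  )
}

#' Define a motif
#'
#' A motif is either an IUPAC degenerate consensus string or a 4 x L position
#' frequency matrix (rows A, C, G, T); exactly one of the two must be given.
#'
#' @param name Motif name, unique within a catalog.
#' @param consensus IUPAC consensus string (kind `"consensus"`).
#' @param matrix 4 x L nonnegative count matrix with rows A, C, G, T
#'   (kind `"pfm"`).
#' @param source Free-text provenance.
#' @return An object of class `motif_def` with fields `name`, `kind`,
#'   `consensus` or `matrix`, `source`.
#' @export
motif_def <- function(name, consensus = NULL, matrix = NULL, source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(consensus) == is.null(matrix)) {
    stop("exactly one of 'consensus' or 'matrix' must be given", call. = FALSE)
  }
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    bad <- setdiff(unique(strsplit(consensus, "", fixed = TRUE)[[1]]),
                   names(IUPAC_SETS))
    if (length(bad) > 0L) {
      stop("illegal IUPAC code(s) in consensus: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    def <- list(name = name, kind = "consensus", consensus = consensus,
                matrix = NULL, source = source)
  } else {
    stopifnot(is.matrix(matrix), nrow(matrix) == 4L)
    if (any(matrix < 0)) stop("PFM counts must be nonnegative", call. = FALSE)
    if (any(colSums(matrix) <= 0)) {
      stop("every PFM column must have positive total count", call. = FALSE)
    }
    rownames(matrix) <- c("A", "C", "G", "T")
    def <- list(name = name, kind = "pfm", consensus = NULL, matrix = matrix,
                source = source)
  }
  structure(def, class = "motif_def")
}

#' @export
print.motif_def <- function(x, ...) {
  if (x$kind == "consensus") {
    cat(sprintf("<motif_def> %s (consensus): %s\n", x$name, x$consensus))
  } else {
    cat(sprintf("<motif_def> %s (PFM, %d columns)\n", x$name, ncol(x$matrix)))
  }
  invisible(x)
}

# Internal: motif length in bases.
motif_length <- function(motif) {
  if (motif$kind == "consensus") nchar(motif$consensus) else ncol(motif$matrix)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Understands both the plain four-row dialect (`A 10 0 ...`) and the
#' bracketed dialect (`A [10 0 ...]`), with or without a `>` header line.
#'
#' @param path Path to a JASPAR PFM text file containing one matrix.
#' @param name Optional motif name; defaults to the header (or file base name
#'   when there is no header).
#' @return A [motif_def] of kind `"pfm"` with rows ordered A, C, G, T.
#' @export
read_jaspar_pfm <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  header <- NULL
  if (length(lines) > 0L && startsWith(lines[[1]], ">")) {
    header <- trimws(sub("^>", "", lines[[1]]))
    lines <- lines[-1L]
  }
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    m <- regmatches(ln, regexec("^([ACGTacgt])\\s*\\[?([-0-9. \t]*)\\]?\\s*$", ln))[[1]]
    if (length(m) == 0L) {
      stop("cannot parse PFM row at line ", i, " of ", path, ": ", ln,
           call. = FALSE)
    }
    base <- toupper(m[2])
    vals <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
    if (length(vals) == 0L || anyNA(vals)) {
      stop("cannot parse counts in PFM row for base ", base, " in ", path,
           call. = FALSE)
    }
    if (base %in% names(rows)) stop("duplicate PFM row for base ", base, call. = FALSE)
    rows[[base]] <- vals
  }
  missing_rows <- setdiff(c("A", "C", "G", "T"), names(rows))
  if (length(missing_rows) > 0L) {
    stop("PFM in ", path, " is missing row(s): ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("PFM rows have unequal lengths in ", path, call. = FALSE)
  }
  mat <- rbind(A = rows[["A"]], C = rows[["C"]], G = rows[["G"]], T = rows[["T"]])
  if (is.null(name)) {
    name <- if (!is.null(header) && nzchar(header)) {
      strsplit(header, "\\s+")[[1]][1]
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  motif_def(name, matrix = mat, source = paste0("JASPAR PFM: ", basename(path)))
}
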