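# Promoter classification rules and the hypothesis tests applied to
# motif-incidence and tissue-expression tables.

#' Classify a promoter from its motif hits and CpG islands
#'
#' Boolean features are derived from presence/absence and the labels follow
#' the classification rules for alternative and bidirectional promoters: a
#' promoter with a TATA-box hit is `TATA_containing`; one that carries a CpG
#' island together with NRF1 and ZNF143 sites but no TATA-box is a
#' `bidirectional_candidate` (the canonical bidirectional-promoter
#' signature: CGI-positive, TATA-less, NRF1/ZNF143-bearing); a promoter
#' matching neither rule is additionally `unclassified`.
#'
#' @param promoter_id Promoter sequence id.
#' @param hits Data frame of motif hits (as from [scan_consensus()] /
#'   [scan_pwm()]) for this promoter; may have zero rows.
#' @param cgi_regions Data frame of islands (as from [find_cgi()]) for this
#'   promoter; may have zero rows.
#' @param tata_motif,nrf1_motif,znf143_motif Motif names carrying the
#'   respective signals in `hits`.
#' @return A list of class `promoter_annotation` with fields `promoter_id`,
#'   `motif_counts` (named integer vector), `has_tata`, `has_cgi`,
#'   `has_nrf1`, `has_znf143`, `class_labels`.
#' @export
classify_promoter <- function(promoter_id, hits, cgi_regions,
                              tata_motif = "TATA-box", nrf1_motif = "NRF1",
                              znf143_motif = "ZNF143") {
  stopifnot(is.data.frame(hits), is.data.frame(cgi_regions))
  if (nrow(hits) > 0L && !all(hits$seq_id == promoter_id)) {
    stop("hits refer to a different sequence than ", promoter_id, call. = FALSE)
  }
  if (nrow(cgi_regions) > 0L && !all(cgi_regions$seq_id == promoter_id)) {
    stop("CGI regions refer to a different sequence than ", promoter_id,
         call. = FALSE)
  }
  motif_counts <- if (nrow(hits) > 0L) {
    tab <- table(hits$motif_name)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  n_of <- function(name) if (name %in% names(motif_counts)) motif_counts[[name]] else 0L
  has_tata <- n_of(tata_motif) > 0L
  has_cgi <- nrow(cgi_regions) > 0L
  has_nrf1 <- n_of(nrf1_motif) > 0L
  has_znf143 <- n_of(znf143_motif) > 0L
  labels <- c(
    if (has_tata) "TATA_containing" else "TATA_less",
    if (has_cgi) "CGI_positive" else "CGI_negative")
  bidirectional <- has_cgi && has_nrf1 && has_znf143 && !has_tata
  if (bidirectional) labels <- c(labels, "bidirectional_candidate")
  if (!has_tata && !bidirectional) labels <- c(labels, "unclassified")
  structure(list(promoter_id = promoter_id, motif_counts = motif_counts,
                 has_tata = has_tata, has_cgi = has_cgi, has_nrf1 = has_nrf1,
                 has_znf143 = has_znf143, class_labels = labels),
            class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat(sprintf("<promoter_annotation> %s: %s\n", x$promoter_id,
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

# Internal: test_result constructor.
test_result <- function(statistic, df, p_value, test_name) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_name = test_name),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, df (%s), p = %.4g\n",
              x$test_name, x$statistic, paste(x$df, collapse = ", "),
              x$p_value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects ANOVA: `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom, computed via [stats::oneway.test()]
#' with equal variances assumed.
#'
#' @param groups A list of at least 2 numeric vectors, each with at least 2
#'   values (more than two groups in typical use).
#' @return A `test_result` with fields `statistic` (F), `df` (length-2),
#'   `p_value`, `test_name`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), times = sizes))
  ht <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  test_result(ht$statistic, ht$parameter, ht$p.value, "one-way ANOVA")
}

#' Two-sample t test
#'
#' Two-sided; Student's pooled-variance form when `equal_variance = TRUE`,
#' Welch's otherwise.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param equal_variance Assume equal variances (pooled)? Default `FALSE`
#'   (Welch).
#' @return A `test_result`.
#' @export
two_sample_t <- function(a, b, equal_variance = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = equal_variance)
  test_result(ht$statistic, ht$parameter, ht$p.value,
              if (equal_variance) "two-sample t (pooled)" else "Welch t")
}

#' Test whether motif incidence varies across a promoter panel
#'
#' Applies [one_way_anova()] with each motif of interest as a group and its
#' per-promoter counts as observations — the stated analysis for incidence
#' tables, reproduced as such. (ANOVA on counts is an approximation; a
#' chi-square test of homogeneity is available via `method = "chisq"`.)
#'
#' @param table Promoter-by-motif count table from [motif_incidence_table()].
#' @param motifs_of_interest Character vector of at least 2 column names.
#' @param method `"anova"` (default) or `"chisq"`.
#' @return A `test_result`.
#' @export
incidence_significance <- function(table, motifs_of_interest,
                                   method = c("anova", "chisq")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table))
  if (nrow(table) < 2L) stop("need at least 2 promoters", call. = FALSE)
  if (length(motifs_of_interest) < 2L) {
    stop("need at least 2 motifs of interest", call. = FALSE)
  }
  missing_cols <- setdiff(motifs_of_interest, names(table))
  if (length(missing_cols) > 0L) {
    stop("motif(s) absent from table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  counts <- table[, motifs_of_interest, drop = FALSE]
  if (method == "anova") {
    one_way_anova(as.list(counts))
  } else {
    ht <- suppressWarnings(stats::chisq.test(as.matrix(counts)))
    test_result(ht$statistic, ht$parameter, ht$p.value,
                "chi-square homogeneity")
  }
}
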