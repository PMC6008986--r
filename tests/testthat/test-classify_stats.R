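# Promoter classification rules and the hypothesis tests.

make_hits <- function(id, motifs) {
  if (length(motifs) == 0) return(regchar:::empty_hits())
  data.frame(motif_name = motifs, seq_id = id, start = seq_along(motifs),
             end = seq_along(motifs) + 5L, strand = "+",
             matched = "NNNNNN", score = 1)
}

make_cgi <- function(id, n = 1) {
  if (n == 0) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      length = integer(), gc_fraction = numeric(),
                      obs_exp_cpg = numeric()))
  }
  data.frame(seq_id = id, start = 1L, end = 220L, length = 220L,
             gc_fraction = 0.6, obs_exp_cpg = 0.8)
}

test_that("classification follows the promoter rules", {
  # TATA hit, no CGI: a TATA-containing, CGI-negative promoter
  ann <- classify_promoter("p", make_hits("p", c("TATA-box", "INR")),
                           make_cgi("p", 0))
  expect_setequal(ann$class_labels, c("TATA_containing", "CGI_negative"))
  expect_true(ann$has_tata)

  # CGI + NRF1 + ZNF143, no TATA: the bidirectional signature
  ann <- classify_promoter("p", make_hits("p", c("NRF1", "ZNF143", "INR")),
                           make_cgi("p"))
  expect_true("bidirectional_candidate" %in% ann$class_labels)
  expect_setequal(ann$class_labels,
                  c("TATA_less", "CGI_positive", "bidirectional_candidate"))

  # nothing at all: TATA-less, CGI-negative, unclassified
  ann <- classify_promoter("p", make_hits("p", character(0)), make_cgi("p", 0))
  expect_setequal(ann$class_labels,
                  c("TATA_less", "CGI_negative", "unclassified"))

  # a TATA hit vetoes the bidirectional label
  ann <- classify_promoter("p",
                           make_hits("p", c("TATA-box", "NRF1", "ZNF143")),
                           make_cgi("p"))
  expect_false("bidirectional_candidate" %in% ann$class_labels)

  expect_error(classify_promoter("p", make_hits("q", "INR"), make_cgi("p", 0)),
               "different sequence")
})

test_that("label invariants hold on random boolean feature combinations", {
  withr::with_seed(111, {
    for (i in 1:100) {
      motifs <- c(if (runif(1) < 0.5) "TATA-box", if (runif(1) < 0.5) "NRF1",
                  if (runif(1) < 0.5) "ZNF143", if (runif(1) < 0.5) "INR")
      n_cgi <- rbinom(1, 1, 0.5)
      ann <- classify_promoter("p", make_hits("p", motifs), make_cgi("p", n_cgi))
      expect_equal("TATA_containing" %in% ann$class_labels, ann$has_tata)
      expect_equal("CGI_positive" %in% ann$class_labels, ann$has_cgi)
      if ("bidirectional_candidate" %in% ann$class_labels) {
        expect_true(ann$has_cgi && ann$has_nrf1 && ann$has_znf143 && !ann$has_tata)
      }
      expect_false(all(c("TATA_containing", "TATA_less") %in% ann$class_labels))
    }
  })
})

test_that("one-way ANOVA matches the hand-computed F and guards input", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$statistic, 3) # SSb = 6, SSw = 6, MSb = 3, MSw = 1
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, stats::pf(3, 2, 6, lower.tail = FALSE))

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)

  expect_error(one_way_anova(list(c(1, 2), c(3))), "at least 2 values")
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("ANOVA with two groups equals the squared pooled t statistic", {
  withr::with_seed(222, {
    for (i in 1:20) {
      a <- rnorm(sample(3:8, 1))
      b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
      f <- one_way_anova(list(a, b))$statistic
      t <- two_sample_t(a, b, equal_variance = TRUE)$statistic
      expect_equal(f, t^2, tolerance = 1e-10)
    }
  })
})

test_that("t tests behave at the extremes and the forms agree when they should", {
  a <- c(1, 2, 3, 4)
  res <- two_sample_t(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  eps <- c(0, 0, 0, 0) + rnorm(4, sd = 1e-3)
  far <- eps + 100 * stats::sd(eps)
  expect_lt(two_sample_t(eps, far)$p_value, 1e-3)

  # Welch and pooled agree for equal sizes and (empirical) variances
  b <- a + 10
  w <- two_sample_t(a, b, equal_variance = FALSE)
  p <- two_sample_t(a, b, equal_variance = TRUE)
  expect_equal(w$statistic, p$statistic)
  expect_equal(w$p_value, p$p_value, tolerance = 1e-12)

  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("null p-values are uniform (Kolmogorov-Smirnov at alpha 0.01)", {
  withr::with_seed(333, {
    pvals <- vapply(1:2000, function(i) {
      groups <- replicate(4, rnorm(3), simplify = FALSE)
      one_way_anova(groups)$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("incidence significance delegates to ANOVA over motif columns", {
  tab <- data.frame(`TATA-box` = c(1, 2, 3), INR = c(2, 3, 4),
                    DTIE = c(3, 4, 5), check.names = FALSE)
  rownames(tab) <- paste0("AP", 1:3)
  res <- incidence_significance(tab, c("TATA-box", "INR", "DTIE"))
  expect_equal(res$statistic, 3)
  direct <- one_way_anova(list(tab[["TATA-box"]], tab$INR, tab$DTIE))
  expect_equal(res$p_value, direct$p_value)

  # identical count vectors: F = 0
  flat <- data.frame(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  expect_equal(incidence_significance(flat, c("a", "b", "c"))$statistic, 0)

  # one motif far more frequent than the rest: significant
  skew <- data.frame(hot = rpois(8, 10) + 5, cold1 = rep(0L, 8),
                     cold2 = rep(0L, 8))
  expect_lt(incidence_significance(skew, c("hot", "cold1", "cold2"))$p_value,
            0.05)

  expect_error(incidence_significance(tab, "INR"), "at least 2 motifs")
  expect_error(incidence_significance(tab, c("INR", "nope")), "absent")
  # chi-square alternative runs
  expect_s3_class(incidence_significance(tab + 1, c("INR", "DTIE"),
                                         method = "chisq"), "test_result")
})
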