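# IUPAC expansion, consensus scanning, PFM log-odds scanning, incidence.

test_that("IUPAC expansion has the right cardinality and membership", {
  expect_setequal(expand_iupac("TATAWA"), c("TATAAA", "TATATA"))
  expect_length(expand_iupac("RCGTG"), 2L)
  # GBBRDNHGG: 1*3*3*2*3*4*3*1*1 = 648
  words <- expand_iupac("GBBRDNHGG")
  expect_length(words, 648L)
  expect_length(unique(words), 648L)
  expect_true(all(grepl("^G[CGT][CGT][AG][AGT][ACGT][ACT]GG$", words)))
  expect_error(expand_iupac("TAXA"), "illegal")
})

test_that("consensus scanning reports all hits on both strands", {
  tata <- motif_def("TATA-box", consensus = "TATAWA")
  hits <- scan_consensus(seq_record("x", "GGTATATAGG"), tata)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$start, 3L)
  expect_equal(fw$end, 8L)
  expect_equal(fw$matched, "TATATA")
  oracle <- oracle_scan("GGTATATAGG", "TATAWA")
  expect_equal(nrow(hits), nrow(oracle))

  expect_equal(nrow(scan_consensus(seq_record("x", "AAAAAA"), tata)), 0L)

  pu1 <- motif_def("PU.1", consensus = "GAGGAA")
  hits <- scan_consensus(seq_record("x", "GAGGAA"), pu1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(c(hits$start, hits$end), c(1L, 6L))

  # motif longer than sequence -> empty, not an error
  expect_equal(nrow(scan_consensus(seq_record("x", "TAT"), tata)), 0L)
})

test_that("sequence N matches only pattern N", {
  m <- motif_def("m", consensus = "TANA")
  hits <- scan_consensus(seq_record("x", "TANA"), m, strands = "+")
  expect_equal(nrow(hits), 1L) # N aligns with pattern N
  m2 <- motif_def("m2", consensus = "TACA")
  expect_equal(nrow(scan_consensus(seq_record("x", "TANA"), m2, strands = "+")),
               0L) # N never satisfies a non-N position
})

test_that("consensus scan equals the enumerate-expansions oracle", {
  withr::with_seed(101, {
    for (i in 1:300) {
      s <- random_dna(sample(10:60, 1))
      pat <- random_pattern(sample(3:9, 1))
      hits <- scan_consensus(seq_record("x", s), motif_def("m", consensus = pat))
      oracle <- oracle_scan(s, pat)
      expect_equal(hits$start, oracle$start)
      expect_equal(hits$end, oracle$end)
      expect_equal(hits$strand, oracle$strand)
    }
  })
})

test_that("strand decomposition is consistent with scanning the complement", {
  withr::with_seed(77, {
    for (i in 1:50) {
      rec <- seq_record("x", random_dna(40))
      pat <- motif_def("m", consensus = random_pattern(5))
      both <- scan_consensus(rec, pat, strands = "both")
      fw <- scan_consensus(rec, pat, strands = "+")
      rv_on_rc <- scan_consensus(reverse_complement(rec), pat, strands = "+")
      expect_equal(sum(both$strand == "+"), nrow(fw))
      expect_equal(sum(both$strand == "-"), nrow(rv_on_rc))
      # reverse-strand hits map to forward coordinates of complement hits
      n <- nchar(rec$residues)
      rv <- both[both$strand == "-", ]
      expect_setequal(rv$start, n - rv_on_rc$end + 1)
    }
  })
})

test_that("PWM scanning scores by the stated log-odds and thresholds", {
  pfm <- motif_def("toy", matrix = rbind(A = c(10, 0), C = c(0, 10),
                                         G = c(0, 0), T = c(0, 0)))
  hits <- scan_pwm(seq_record("y", "TACG"), pfm, threshold_fraction = 1.0)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(2L, 3L))
  expect_equal(hits$strand, "+")
  # hand-computed maximal score: 2 * log2((10.25/11)/0.25)
  expect_equal(hits$score, 2 * log2((10.25 / 11) / 0.25), tolerance = 1e-12)

  # at fraction 1.0 only the argmax word passes: verify over all dinucleotides
  all_dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0))
  passing <- vapply(all_dinucs, function(d) {
    nrow(scan_pwm(seq_record("y", d), pfm, threshold_fraction = 1.0,
                  strands = "+"))
  }, integer(1))
  expect_equal(names(passing[passing > 0]), "AC")

  expect_equal(nrow(scan_pwm(seq_record("y", "TTTT"), pfm,
                             threshold_fraction = 1.0)), 0L)
  expect_error(scan_pwm(seq_record("y", "TACG"), pfm, background = c(0, 1, 1, 1) / 3),
               "background")
})

test_that("lowering the PWM threshold never loses hits", {
  withr::with_seed(55, {
    for (i in 1:30) {
      mat <- matrix(sample(0:20, 4 * 5, replace = TRUE), nrow = 4)
      mat[, colSums(mat) == 0] <- 1
      pfm <- motif_def("m", matrix = mat)
      rec <- seq_record("x", random_dna(60))
      counts <- vapply(c(1.0, 0.9, 0.7, 0.5, 0.3),
                       function(f) nrow(scan_pwm(rec, pfm, threshold_fraction = f)),
                       integer(1))
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("the catalog carries the 18 consensus motifs verbatim", {
  cat18 <- motif_catalog()
  expect_length(cat18, 18L)
  expect_equal(cat18[["TATA-box"]]$consensus, "TATAWA")
  expect_equal(cat18[["INR"]]$consensus, "YYANWYY")
  expect_equal(cat18[["DTIE"]]$consensus, "GBBRDNHGG")
  expect_equal(cat18[["DPE"]]$consensus, "RGWCGTG")
  expect_equal(cat18[["GATA"]]$consensus, "WGATAR")
  # PFM slots appear when files are supplied
  pfm_path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0506.1 NRF1", "A [ 5 0 ]", "C [ 0 5 ]", "G [ 0 0 ]",
               "T [ 0 0 ]"), pfm_path)
  cat20 <- motif_catalog(nrf1_pfm = pfm_path, znf143_pfm = pfm_path)
  expect_length(cat20, 20L)
  expect_equal(cat20[["NRF1"]]$kind, "pfm")
})

test_that("incidence tables agree with per-motif scans", {
  tata <- motif_catalog()[["TATA-box"]]
  promo <- plant_motif(gen_background(120, 0.7, seed = 21), tata, 40,
                       seed = 22)$seq
  promoters <- list(promo, gen_background(120, 0.7, seed = 23, id = "bg"))
  tab <- motif_incidence_table(promoters, motif_catalog())
  expect_equal(rownames(tab), c("background", "bg"))
  expect_gte(tab["background", "TATA-box"], 1L)
  expect_equal(tab["background", "TATA-box"],
               nrow(scan_consensus(promo, tata)))
  for (m in names(tab)) {
    expect_equal(tab["bg", m],
                 nrow(scan_consensus(promoters[[2]], motif_catalog()[[m]])))
  }
  expect_error(motif_incidence_table(list(), motif_catalog()), "empty")
  expect_error(motif_incidence_table(list(promo, promo), motif_catalog()),
               "duplicate")
})

test_that("non-overlapping counting is greedy left-to-right", {
  gaf <- motif_def("GAF", consensus = "GAGAG")
  rec <- seq_record("x", "GAGAGAGAG") # overlapping occurrences at 1, 3, 5
  all_hits <- motif_incidence_table(list(rec), list(gaf))
  greedy <- motif_incidence_table(list(rec), list(gaf), overlapping = FALSE)
  expect_equal(all_hits[1, 1], 3L) # forward occurrences at 1, 3, 5
  expect_equal(greedy[1, 1], 1L) # greedy keeps 1-5, the rest overlap
})
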