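# Local alignment, complementary-segment discovery, seeds, MREs, similarity
# ranking.

test_that("local alignment reproduces hand-checked cases", {
  a <- seq_record("a", "ACGT")
  res <- local_align(a, seq_record("b", "ACGT"))
  expect_equal(res$score, 20)
  expect_equal(res$identity_percent, 100)
  expect_equal(res$alignment_length, 4L)

  res <- local_align(seq_record("a", "ACGTACGT"), seq_record("b", "ACGAACGT"))
  expect_equal(res$score, 31)
  expect_equal(res$matches, 7L)
  expect_equal(res$alignment_length, 8L)
  expect_equal(res$identity_percent, 87.5)

  expect_null(local_align(seq_record("a", "AAAA"), seq_record("b", "CCCC")))
  expect_error(local_align(seq_record("a", "ACGT"), seq_record("b", "")),
               "non-empty")
})

test_that("alignment scores equal an explicit affine-gap dynamic program", {
  withr::with_seed(606, {
    for (i in 1:250) {
      a <- random_dna(sample(5:30, 1))
      b <- random_dna(sample(5:30, 1))
      res <- local_align(seq_record("a", a), seq_record("b", b))
      got <- if (is.null(res)) 0 else res$score
      expect_equal(got, oracle_sw_score(a, b))
    }
  })
})

test_that("alignment is symmetric and identity is recomputable", {
  withr::with_seed(707, {
    for (i in 1:50) {
      a <- random_dna(sample(10:30, 1))
      b <- random_dna(sample(10:30, 1))
      r_ab <- local_align(seq_record("a", a), seq_record("b", b))
      r_ba <- local_align(seq_record("b", b), seq_record("a", a))
      expect_equal(is.null(r_ab), is.null(r_ba))
      if (!is.null(r_ab)) {
        expect_equal(r_ab$score, r_ba$score)
        # identity recomputable from the gapped strings
        ca <- strsplit(r_ab$aligned_a, "")[[1]]
        cb <- strsplit(r_ab$aligned_b, "")[[1]]
        expect_equal(r_ab$identity_percent,
                     100 * sum(ca == cb & ca != "-") / length(ca))
        # ungapped aligned strings reproduce the claimed substrings
        expect_equal(gsub("-", "", r_ab$aligned_a),
                     substr(a, r_ab$a_start, r_ab$a_end))
        expect_equal(gsub("-", "", r_ab$aligned_b),
                     substr(b, r_ab$b_start, r_ab$b_end))
      }
    }
  })
})

test_that("complementary segments are found and mapped to each frame", {
  # tx_b is the exact reverse complement of tx_a
  res <- find_complementary_segment(seq_record("a", "AAACCC"),
                                    seq_record("b", "GGGTTT"),
                                    min_length = 6, min_identity = 100)
  expect_equal(res$alignment_length, 6L)
  expect_equal(res$identity_percent, 100)
  expect_equal(c(res$a_start, res$a_end), c(1L, 6L))
  expect_equal(c(res$b_start, res$b_end), c(1L, 6L))

  expect_null(find_complementary_segment(seq_record("a", strrep("A", 50)),
                                         seq_record("b", strrep("C", 50))))

  pair <- gen_convergent_pair(seed = 11)
  res <- find_complementary_segment(pair$tx_a, pair$tx_b)
  expect_equal(res$alignment_length, 52L)
  expect_equal(res$identity_percent, 75)
  truth_a <- pair$truth[pair$truth$seq_id == "tx_a", ]
  truth_b <- pair$truth[pair$truth$seq_id == "tx_b", ]
  expect_equal(res$a_start, truth_a$position)
  expect_equal(res$b_start, truth_b$position)

  # mirrored call reports the same segment in mirrored coordinates
  mirrored <- find_complementary_segment(pair$tx_b, pair$tx_a)
  expect_equal(mirrored$alignment_length, res$alignment_length)
  expect_equal(mirrored$identity_percent, res$identity_percent)
  expect_equal(c(mirrored$a_start, mirrored$a_end), c(res$b_start, res$b_end))
  expect_equal(c(mirrored$b_start, mirrored$b_end), c(res$a_start, res$a_end))
})

test_that("seed extraction slices miR positions first..last", {
  mir <- seq_record("m", "ACGUACGUACGUACGUACGUAC", alphabet = "RNA")
  expect_equal(extract_seed(mir), "CGUACGU")
  expect_equal(nchar(extract_seed(mir, first = 1, last = 8)), 8L)
  expect_error(extract_seed(seq_record("m", "ACGUAC", alphabet = "RNA")),
               "shorter")
})

test_that("MRE calling finds seed complements with the declared tolerance", {
  mir <- seq_record("mir", "UAGGUAGUAGGUUGUAUAGUU", alphabet = "RNA")
  seed <- extract_seed(mir) # AGGUAGU
  site <- regchar:::revcomp_string(chartr("U", "T", seed)) # ACTACCT
  utr <- seq_record("utr", paste0(strrep("G", 30), site, strrep("G", 20)))
  hits <- find_mre(utr, mir)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$utr_position, 31L)
  expect_equal(hits$match_type, "seed7_exact")
  expect_equal(hits$seed, seed)

  # one mutation in the site: invisible at 0 mismatches, found at 1
  mut <- utr$residues
  substr(mut, 33, 33) <- "A" # site position 3 was T
  utr_mut <- seq_record("utr", mut)
  expect_equal(nrow(find_mre(utr_mut, mir)), 0L)
  hits1 <- find_mre(utr_mut, mir, max_seed_mismatches = 1)
  expect_equal(nrow(hits1), 1L)
  expect_equal(hits1$match_type, "seed7_1mm")

  # k planted sites give k hits
  withr::with_seed(808, {
    for (k in 1:4) {
      spacer <- strrep("G", 15)
      utr_k <- seq_record("utr",
                          paste0(spacer, paste(rep(paste0(site, spacer), k),
                                               collapse = "")))
      expect_equal(nrow(find_mre(utr_k, mir)), k)
    }
  })
})

test_that("similarity search ranks an embedded miR first", {
  query <- seq_record("segment", paste0("GGGG", "TAGGTAGTAGGTTGTATAGTTA", "GGGG"))
  mature <- list(
    seq_record("hit", "UAGGUAGUAGGUUGUAUAGUUA", alphabet = "RNA"),
    seq_record("decoy1", strrep("C", 22), alphabet = "RNA"),
    seq_record("decoy2", "CCCCCCCCCCUAGGCCCCCCCC", alphabet = "RNA"))
  ranked <- mir_similarity_search(query, mature, top_n = 3)
  expect_equal(ranked$mir_id[1], "hit")
  expect_equal(ranked$identity_percent[1], 100)
  expect_equal(ranked$alignment_length[1], 22L)
  # poly-C decoy scores 0 against the query
  expect_equal(ranked$score[ranked$mir_id == "decoy1"], 0)

  # ranking equals independently aligning and sorting
  scores <- vapply(mature, function(m) {
    r <- local_align(query, m)
    if (is.null(r)) 0 else r$score
  }, numeric(1))
  expect_equal(ranked$mir_id,
               vapply(mature, `[[`, character(1), "id")[order(-scores)])
})
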