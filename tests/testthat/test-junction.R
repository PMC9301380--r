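test_that("cdr3_length excludes the two anchors and rejects bad input", {
  expect_equal(cdr3_length("CACDTLGDTDKLIF"), 12L)
  expect_equal(cdr3_length("CACDTAGGSSWDTRQMFF"), 16L)
  expect_equal(cdr3_length("CAF"), 1L)
  expect_error(cdr3_length("ACDTF"), "nonproductive")
  expect_error(cdr3_length("CA"), "nonproductive")
})

test_that("position-5 extraction and hydrophobicity follow the junction index", {
  expect_equal(extract_aa5("CACDTLGDTDKLIF"),
               tibble::tibble(aa5 = "L", is_haa5 = TRUE))
  expect_equal(extract_aa5("CACDTEGTPTLLIF"),
               tibble::tibble(aa5 = "E", is_haa5 = FALSE))
  expect_equal(extract_aa5("CACDTAGGSSWDTRQMFF"),
               tibble::tibble(aa5 = "A", is_haa5 = TRUE))
  # junctions shorter than 7 residues have no defined position 5
  short <- extract_aa5("CACDTF")
  expect_true(is.na(short$aa5) && is.na(short$is_haa5))
})

test_that("invariant-T detection reads the second nucleotide of codon 6", {
  base <- "TGTGCCTGTGACACC"  # CACDT
  tail_j1 <- "GGAGATACGGATAAACTCATCTTT"
  aa_of <- function(codon6) translate_dna(paste0(base, codon6, tail_j1))
  mk <- function(codon6) paste0(base, codon6, tail_j1)
  expect_true(detect_inv_t(mk("CTG"), aa_of("CTG")))    # Leu
  expect_false(detect_inv_t(mk("GCC"), aa_of("GCC")))   # Ala, second nt C
  expect_false(detect_inv_t(mk("GGA"), aa_of("GGA")))   # Gly
  expect_error(detect_inv_t(mk("CTG"), sub("L", "V", aa_of("CTG"))),
               "inconsistent")
})

test_that("invariant-T implies a hydrophobic position 5 on simulated draws", {
  sim <- simulate_rearrangements(400, small_cohort_config(seed = 5L))
  ok <- nchar(sim$junction_aa) >= 7L
  inv <- detect_inv_t(sim$junction[ok], sim$junction_aa[ok])
  h <- extract_aa5(sim$junction_aa[ok])$is_haa5
  expect_true(all(h[inv]))
  expect_true(all(extract_aa5(sim$junction_aa[ok])$aa5[inv] %in%
                    c("F", "L", "I", "M", "V")))
})

test_that("J-region suffix classification works and j_call takes precedence", {
  expect_equal(classify_j_region("CACDTLGDTDKLIF"), "J1")
  expect_equal(classify_j_region("CACDTAGGSSWDTRQMFF"), "J3")
  # explicit call wins over the suffix
  expect_equal(classify_j_region("CACDTAGGSSWDTRQMFF", j_call = "TRDJ1*01"),
               "J1")
  # no overlap >= 4 residues -> unknown
  expect_true(is.na(classify_j_region("CACDGGGGGW")))
})

test_that("germline concatenations decompose with zero N insertions", {
  d <- decompose_junction(GERMLINE_JUNCTION_NT)
  expect_equal(d$total_n, 0L)
  expect_equal(d$score, nchar(GERMLINE_JUNCTION_NT))
  expect_equal(d$d_segment, "TRDD3*01")
  expect_equal(d$j_segment, "TRDJ1*01")

  # insertion of GGC between the V and D blocks is recovered as N1
  with_ins <- paste0("TGTGCCTGTGACACC", "GGC", "CTGGGGGATACGGATAAACTCATCTTT")
  d2 <- decompose_junction(with_ins)
  expect_equal(d2$n1_len, 3L)
  expect_equal(d2$total_n, 3L)
  expect_equal(d2$score, oracle_decompose_score(with_ins))
})

test_that("junctions matching no segment decompose to all-N", {
  # no V prefix, no J suffix, no D substring of >= 3 nt
  junction <- paste0(strrep("AC", 10L), "A")
  d <- decompose_junction(junction)
  expect_equal(d$v_match_len, 0L)
  expect_equal(d$j_match_len, 0L)
  expect_equal(d$total_n, 21L)
})

test_that("block lengths always sum to the junction length", {
  set.seed(42)
  lens <- sample(9:48, 60, replace = TRUE)
  junctions <- vapply(lens, random_nt_string, character(1))
  d <- decompose_junction(junctions)
  expect_equal(d$v_match_len + d$n1_len + d$d_match_len + d$n2_len +
                 d$j_match_len, nchar(junctions))
  expect_equal(d$score, nchar(junctions) - d$total_n)
  expect_true(all(d$n1_len >= 0 & d$n2_len >= 0))
  # merged N block when no D is called
  expect_true(all(d$n2_len[is.na(d$d_segment)] == 0L))
})

test_that("annotate_repertoire derives all features consistently", {
  sim <- simulate_cohort(small_cohort_config(seed = 9L, n_donors = 2L))
  ann <- annotate_repertoire(suppressWarnings(filter_singletons(sim$samples)))
  expect_true(all(c("frequency", "frequency_class", "cdr3_length", "aa5",
                    "is_haa5", "inv_t", "j_region", "n_insertions",
                    "germline_encoded") %in% names(ann)))
  # frequencies are percentages over post-filter sample totals
  sums <- tapply(ann$frequency, ann$sample_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_equal(ann$germline_encoded, ann$n_insertions == 0L)
  expect_equal(ann$cdr3_length, nchar(ann$junction_aa) - 2L)
  # inv_t implies hydrophobic position 5 everywhere
  both <- !is.na(ann$inv_t) & ann$inv_t
  expect_true(all(ann$is_haa5[both]))
})
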