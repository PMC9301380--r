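test_that("frequency classes follow the half-open printed bounds", {
  f <- classify_frequency(c(0.05, 0.1, 0.999, 1, 50))
  expect_equal(as.character(f), c("non_expanded", "expanded", "expanded",
                                  "hyperexpanded", "hyperexpanded"))
  expect_error(classify_frequency(0), "positive")
  expect_error(classify_frequency(-1), "positive")
  expect_error(classify_frequency(101), "exceed 100")
})

test_that("replicate concordance keeps nucleotypes seen in >= 2 donor samples", {
  tbl <- tibble::tibble(
    donor_id = "d1",
    sample_id = c("s1", "s2", "s1", "s1", "s2", "s3"),
    junction = c("X", "X", "Y", "Z", "Z", "Z"),
    v_call = "TRDV2*01", j_call = "TRDJ1*01",
    junction_aa = c("CXF", "CXF", "CYF", "CZF", "CZF", "CZF"),
    duplicate_count = c(2L, 3L, 4L, 2L, 2L, 2L))
  conc <- replicate_concordant_nucleotypes(tbl)
  expect_setequal(conc$junction, c("X", "Z"))  # Y seen once -> dropped
  expect_equal(conc$read_count[conc$junction == "Z"], 6L)
  expect_equal(nrow(conc[conc$junction == "Z", ]), 1L)  # set semantics

  single <- tbl[tbl$sample_id == "s1", ]
  expect_error(replicate_concordant_nucleotypes(single), "single sample")
})

test_that("publicity collapse conserves reads and applies sharing thresholds", {
  conc <- tibble::tibble(
    donor_id = c("A", "A", "B", "C"),
    junction = c("nt1", "nt2", "nt3", "nt4"),
    v_call = "TRDV2*01", j_call = "TRDJ1*01",
    junction_aa = c("CAAF", "CAAF", "CAAF", "CBBF"),
    n_samples = 2L,
    read_count = c(5L, 3L, 7L, 2L))
  pub <- publicity_table(conc, n_cohort_donors = 4L)
  shared <- pub[pub$junction_aa == "CAAF", ]
  expect_equal(shared$collapsed_read_count, 15L)
  expect_equal(shared$n_nucleotypes, 3L)
  expect_equal(shared$n_donors_sharing, 2L)
  expect_true(shared$is_public)
  expect_false(pub$is_public[pub$junction_aa == "CBBF"])
  # conservation under collapse
  expect_equal(sum(pub$collapsed_read_count), sum(conc$read_count))
  # same two nucleotypes within one donor are not public
  one_donor <- conc[conc$donor_id == "A", ]
  pub1 <- publicity_table(one_donor, n_cohort_donors = 4L)
  expect_false(pub1$is_public)
  expect_equal(pub1$collapsed_read_count, 8L)
})

test_that("highly-common flag uses a strict majority of the cohort", {
  conc <- tibble::tibble(
    donor_id = sprintf("D%02d", 1:11), junction = sprintf("nt%d", 1:11),
    v_call = "v", j_call = "j", junction_aa = "CACDTLGDTDKLIF",
    n_samples = 2L, read_count = 2L)
  pub <- publicity_table(conc, n_cohort_donors = 20L)
  expect_true(pub$is_highly_common)  # 11 > 10
  pub10 <- publicity_table(conc[1:10, ], n_cohort_donors = 20L)
  expect_false(pub10$is_highly_common)  # 10 is not > 10
})

test_that("sharing counts are monotone under donor addition", {
  sim <- simulate_cohort(small_cohort_config(seed = 21L, n_donors = 4L))
  filt <- suppressWarnings(filter_singletons(sim$samples))
  conc <- replicate_concordant_nucleotypes(filt)
  sub <- publicity_table(conc[conc$donor_id %in% c("D01", "D02"), ],
                         n_cohort_donors = 4L)
  full <- publicity_table(conc, n_cohort_donors = 4L)
  joined <- merge(sub, full, by = "junction_aa", suffixes = c("_sub", "_full"))
  expect_true(all(joined$n_donors_sharing_full >= joined$n_donors_sharing_sub))
  expect_true(all(joined$is_public_full >= joined$is_public_sub))
})

test_that("diversity metrics match closed forms", {
  expect_equal(shannon_entropy(5), 0)
  expect_equal(shannon_entropy(rep(3, 4)), log(4))
  expect_equal(shannon_entropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(d75(rep(1, 100)), 75)
  expect_equal(d75(c(97, 1, 1, 1)), 25)
  expect_equal(d75(7), 100)
  expect_equal(richness(c(2, 5, 9)), 3L)
  expect_error(shannon_entropy(numeric()), "empty")
  expect_error(d75(numeric()), "empty")
})

test_that("diversity metrics are permutation- and scale-invariant", {
  set.seed(1)
  counts <- sample(1:50, 30, replace = TRUE)
  perm <- sample(counts)
  expect_equal(shannon_entropy(counts), shannon_entropy(perm))
  expect_equal(d75(sort(counts)), d75(sort(perm)))
  expect_equal(shannon_entropy(counts * 7), shannon_entropy(counts))
  expect_equal(d75(counts * 7), d75(counts))
  expect_equal(richness(counts * 7), richness(counts))
  # entropy bounded by log richness
  expect_lte(shannon_entropy(counts), log(richness(counts)))
})

test_that("subrepertoire splits partition the sample without renormalising", {
  tbl <- tibble::tibble(sample_id = "s", junction = letters[1:3],
                        junction_aa = c("CAF", "CBF", "CCF"),
                        duplicate_count = c(4L, 4L, 2L),
                        frequency = c(40, 40, 20),
                        germline_encoded = c(TRUE, TRUE, FALSE))
  sp <- split_subrepertoire(tbl, "germline_vs_inserted")
  expect_equal(nrow(sp$germline), 2L)
  expect_equal(nrow(sp$inserted), 1L)
  expect_equal(nrow(sp$germline) + nrow(sp$inserted), nrow(tbl))
  expect_equal(sp$inserted$frequency, 20)  # not renormalised
  expect_error(split_subrepertoire(tbl, "public_vs_private"), "is_public")
  tbl$is_public <- c(FALSE, FALSE, FALSE)
  sp2 <- split_subrepertoire(tbl, "public_vs_private")
  expect_equal(nrow(sp2$public), 0L)
})
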