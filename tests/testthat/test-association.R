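annotated_fixture <- function() {
  tibble::tibble(
    donor_id = rep(c("d1", "d1", "d2", "d2"), each = 4L),
    subset_label = "CD27pos",
    sample_id = rep(c("s1", "s2", "s3", "s4"), each = 4L),
    junction_aa = rep(sprintf("CAC%sTDKLIF", c("DTL", "DEL", "GGG", "PPP")),
                      4L),
    frequency_class = factor(rep(c("non_expanded", "non_expanded",
                                   "hyperexpanded", "hyperexpanded"), 4L),
                             levels = c("non_expanded", "expanded",
                                        "hyperexpanded")),
    j_region = rep(c("J1", "J1", "J1", "J3"), 4L),
    cdr3_length = rep(c(12L, 12L, 16L, 14L), 4L),
    is_haa5 = rep(c(TRUE, FALSE, TRUE, TRUE), 4L))
}

test_that("feature proportions per class are clonotype-weighted ratios", {
  ann <- annotated_fixture()
  enr <- enrichment_by_class(ann, feature = "j1")
  rep_rows <- enr[enr$level == "replicate" & enr$sample_id == "s1", ]
  expect_equal(rep_rows$proportion[rep_rows$frequency_class == "non_expanded"],
               1)
  expect_equal(
    rep_rows$proportion[rep_rows$frequency_class == "hyperexpanded"], 0.5)
  # donor rows average the replicates
  donor_rows <- enr[enr$level == "donor" & enr$donor_id == "d1", ]
  expect_equal(donor_rows$proportion[donor_rows$frequency_class ==
                                       "hyperexpanded"], 0.5)
  expect_true(all(enr$proportion >= 0 & enr$proportion <= 1))
})

test_that("replicate proportions average per donor", {
  ann <- annotated_fixture()
  # force differing replicate proportions for donor d1
  ann$is_haa5[ann$sample_id == "s1"] <- c(TRUE, TRUE, TRUE, FALSE)
  ann$is_haa5[ann$sample_id == "s2"] <- c(TRUE, FALSE, FALSE, FALSE)
  enr <- enrichment_by_class(ann, feature = "haa5")
  d1 <- enr[enr$level == "donor" & enr$donor_id == "d1" &
              enr$frequency_class == "non_expanded", ]
  expect_equal(d1$proportion, mean(c(1, 0.5)))
})

test_that("length distributions normalise within class and sample", {
  ann <- annotated_fixture()
  dist <- length_distribution_by_class(ann, restrict_to = NULL)
  sums <- tapply(dist$mean_proportion, dist$frequency_class, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  # restriction drops non-J1 clonotypes
  j1_only <- length_distribution_by_class(ann, restrict_to = "J1")
  expect_false(14L %in% j1_only$cdr3_length)
  # {12, 12, 16} -> {12: 2/3, 16: 1/3}
  one <- length_distribution_by_class(
    ann[ann$sample_id == "s1" & ann$j_region == "J1", ], restrict_to = "J1")
  expect_equal(one$mean_proportion[one$cdr3_length == 12L &
                                     one$frequency_class == "non_expanded"],
               1)
})

test_that("wilcoxon rank-sum matches hand-computable cases", {
  # identical groups carry no signal
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # degenerate constant data falls back to the p = 1 convention
  expect_warning(res <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(res$p_value, 1)
  r2 <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r2$p_value, 1 / 3)
  expect_true(r2$exact)
  # p symmetric under swap, median difference antisymmetric
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.3, 4.2, 6.6)
  fwd <- wilcoxon_rank_sum(a, b); rev <- wilcoxon_rank_sum(b, a)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$median_difference, -rev$median_difference)
})

test_that("exact mode agrees with the permutation oracle", {
  set.seed(7)
  for (i in 1:25) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na); b <- rnorm(nb)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("spearman matrix handles monotone, reversed and constant columns", {
  x <- 1:10
  m <- spearman_correlation_matrix(
    data.frame(a = x, b = x^3, c = rev(x), k = rep(1, 10)))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_true(is.na(m["a", "k"]) && is.na(m["k", "k"]))
  expect_equal(m, t(m))
  expect_error(spearman_correlation_matrix(data.frame(a = 1:2, b = 2:1)),
               "3 donors")
})

test_that("independent columns rarely show |rho| above 0.2 at n = 200", {
  set.seed(11)
  hits <- vapply(1:40, function(i) {
    m <- spearman_correlation_matrix(data.frame(a = rnorm(200),
                                                b = rnorm(200)))
    abs(m["a", "b"]) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("compare_subsets tests per-sample metrics and honours the cell contract", {
  sim <- simulate_cohort(small_cohort_config(seed = 13L, n_donors = 3L))
  ann <- annotate_repertoire(suppressWarnings(filter_singletons(sim$samples)),
                             decompose = FALSE)
  res <- compare_subsets(ann, "CD27pos", "CD27neg", metric = "shannon")
  expect_equal(res$n_a, 6L)  # 3 donors x 2 replicates
  expect_gt(res$p_value, 0)
  # label swap negates the median difference
  swap <- compare_subsets(ann, "CD27neg", "CD27pos", metric = "shannon")
  expect_equal(swap$median_difference, -res$median_difference)
  expect_equal(swap$p_value, res$p_value)
  # identical subsets -> p = 1, zero median difference
  same <- suppressWarnings(
    compare_subsets(ann, "CD27pos", "CD27pos", metric = "richness"))
  expect_equal(same$p_value, 1)
  expect_equal(same$median_difference, 0)
  # unequal sorted cell counts are refused for diversity metrics
  ann2 <- ann
  ann2$sorted_cell_count[ann2$subset_label == "CD27neg"] <- 12000L
  expect_error(compare_subsets(ann2, "CD27pos", "CD27neg", metric = "d75"),
               "equal numbers of sorted cells")
  ok <- compare_subsets(ann2, "CD27pos", "CD27neg", metric = "d75",
                        allow_unequal_cells = TRUE)
  expect_s3_class(ok, "tbl_df")
  expect_error(compare_subsets(ann, "CD27pos", "NKG2Dbright",
                               metric = "shannon"), "absent")
})
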