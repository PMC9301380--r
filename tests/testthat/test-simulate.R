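test_that("configuration validation rejects degenerate settings", {
  expect_error(simulation_config(replicates_per_subset = 1L), "replicate")
  expect_error(simulation_config(reads_per_sample = 50L), "degenerate")
  expect_error(simulation_config(
    subsets = list(S = list(n_clones = 10L, clone_size_exponent = 0.5)),
    n_naive_clones = 10L), "exceed 1")
  expect_error(simulation_config(j_usage = c(TRDJ1 = 1)), "probabilities")
})

test_that("rearrangements are productive, deterministic and carry truth", {
  cfg <- small_cohort_config(seed = 2L)
  sim <- simulate_rearrangements(300, cfg)
  expect_equal(nrow(sim), 300L)
  expect_true(all(is_productive(sim$junction, sim$junction_aa)))
  expect_equal(sim$true_v_len + sim$true_n1 + sim$true_d_len +
                 sim$true_n2 + sim$true_j_len, nchar(sim$junction))
  expect_identical(simulate_rearrangements(300, cfg)$junction, sim$junction)
})

test_that("zero trimming and zero insertion yield pure germline junctions", {
  cfg <- simulation_config(seed = 4L, trim_prob = 1, n_insertion_mean = 0,
                           public_seed_prob = 0)
  sim <- simulate_rearrangements(150, cfg)
  expect_true(all(sim$true_total_n == 0L))
  dec <- decompose_junction(sim$junction, j_call = sim$j_call)
  expect_true(all(dec$total_n == 0L))
})

test_that("ground-truth germline-only clones annotate as germline encoded", {
  cfg <- small_cohort_config(seed = 6L, n_insertion_mean = 0.5)
  sim <- simulate_rearrangements(400, cfg)
  germ <- sim[sim$true_total_n == 0L & !is.na(sim$true_total_n), ,
              drop = FALSE]
  expect_gt(nrow(germ), 5L)
  dec <- decompose_junction(germ$junction, j_call = germ$j_call)
  expect_true(all(dec$total_n == 0L))
})

test_that("recovered insertion counts track the true inserted counts", {
  cfg <- small_cohort_config(seed = 8L)
  sim <- simulate_rearrangements(800, cfg)
  dec <- decompose_junction(sim$junction, j_call = sim$j_call)
  # exact matching can only reabsorb chance matches, never invent N
  expect_true(all(dec$total_n <= sim$true_total_n))
  # chance reabsorption at the four block boundaries stays small
  expect_lt(mean(sim$true_total_n) - mean(dec$total_n), 1.5)
})

test_that("cohorts are seed-deterministic with conserved read counts", {
  cfg <- small_cohort_config(seed = 31L, n_donors = 2L)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1, sim2)
  totals <- tapply(sim1$samples$duplicate_count, sim1$samples$sample_id, sum)
  expect_true(all(totals == cfg$reads_per_sample))
  # every emitted read traces to a ground-truth clone
  expect_true(all(sim1$samples$clone_id %in% sim1$truth$clones$clone_id))
  # (donor, replicate, subset) unique per sample
  expect_false(anyDuplicated(sim1$metadata[, c("donor_id", "replicate_id",
                                               "subset_label")]) > 0L)
})

test_that("adding a donor does not perturb existing donors' repertoires", {
  cfg3 <- small_cohort_config(seed = 17L, n_donors = 3L)
  cfg4 <- small_cohort_config(seed = 17L, n_donors = 4L)
  s3 <- simulate_cohort(cfg3)$samples
  s4 <- simulate_cohort(cfg4)$samples
  s4_sub <- s4[s4$donor_id %in% unique(s3$donor_id), , drop = FALSE]
  expect_identical(as.data.frame(s3), as.data.frame(s4_sub))
})

test_that("public-pool sequences arise via multiple nucleotide routes", {
  cfg <- small_cohort_config(seed = 23L, n_donors = 6L,
                             public_seed_prob = 1)
  sim <- simulate_cohort(cfg)
  pub <- sim$truth$clones[sim$truth$clones$route == "public", , drop = FALSE]
  expect_setequal(unique(pub$junction_aa), public_cdr3delta)
  n_routes <- tapply(pub$junction, pub$junction_aa,
                     function(x) length(unique(x)))
  expect_gt(mean(n_routes > 1L), 0.5)
})
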