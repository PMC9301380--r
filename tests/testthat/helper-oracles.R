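# Independent oracles and shared fixtures for the test suite.

# Exhaustive decomposition-score oracle: enumerates every D placement
# (segment, start in junction, start in D, length >= min_d_match) by direct
# substring comparison, plus the no-D case, and returns the maximal
# germline-attributed score.  Independent of the package's diagonal-run
# search.
oracle_decompose_score <- function(junction, reference = trd_reference(),
                                   j_call = NA, min_d_match = 3L) {
  L <- nchar(junction)
  v_tail <- reference$nt_sequence[reference$segment_class == "V"]
  jseg <- reference[reference$segment_class == "J", , drop = FALSE]
  if (!is.na(j_call)) {
    jseg <- jseg[sub("\\*.*$", "", jseg$segment_id) ==
                   sub("\\*.*$", "", j_call), , drop = FALSE]
  }
  dseqs <- reference$nt_sequence[reference$segment_class == "D"]
  lcp_len <- function(a, b) {
    n <- min(nchar(a), nchar(b)); k <- 0L
    while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L))
      k <- k + 1L
    k
  }
  lcs_len <- function(a, b) {
    na <- nchar(a); nb <- nchar(b); n <- min(na, nb); k <- 0L
    while (k < n && substr(a, na - k, na - k) == substr(b, nb - k, nb - k))
      k <- k + 1L
    k
  }
  lcp <- lcp_len(junction, v_tail)
  best <- 0L
  for (r in seq_len(nrow(jseg))) {
    head_nt <- substr(jseg$nt_sequence[r], 1L,
                      jseg$junction_anchor_offset[r] + 3L)
    lcs <- lcs_len(junction, head_nt)
    best <- max(best, min(lcp + lcs, L))
    for (dseq in dseqs) {
      K <- nchar(dseq)
      if (K < min_d_match) next
      g <- expand.grid(len = min_d_match:min(K, L), s = seq_len(L),
                       i0 = seq_len(K))
      g <- g[g$s + g$len - 1L <= L & g$i0 + g$len - 1L <= K, , drop = FALSE]
      hit <- substring(junction, g$s, g$s + g$len - 1L) ==
        substring(dseq, g$i0, g$i0 + g$len - 1L)
      g <- g[hit, , drop = FALSE]
      if (nrow(g) > 0L) {
        sc <- pmin(lcp, g$s - 1L) + g$len +
          pmin(lcs, L - (g$s + g$len - 1L))
        best <- max(best, max(sc))
      }
    }
  }
  best
}

# Full-permutation two-sided Wilcoxon rank-sum oracle (midranks; doubled
# smaller tail capped at 1), by enumeration of all group assignments.
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

random_nt_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a fully germline junction: untrimmed V end ++ TRDD3 frame-2 block ++
# TRDJ1 head suffix; translates to CACDTLGDTDKLIF
GERMLINE_JUNCTION_NT <- "TGTGCCTGTGACACCCTGGGGGATACGGATAAACTCATCTTT"
GERMLINE_JUNCTION_AA <- "CACDTLGDTDKLIF"

# small cohort configuration used by several suites
small_cohort_config <- function(seed = 11L, n_donors = 3L, ...) {
  simulation_config(
    seed = seed, n_donors = n_donors,
    subsets = list(CD27pos = list(n_clones = 250L, clone_size_exponent = 2.5),
                   CD27neg = list(n_clones = 50L, clone_size_exponent = 1.8)),
    n_naive_clones = 250L, reads_per_sample = 3000L, ...)
}

# per-donor, replicate-averaged proportion of unique clonotypes with a
# hydrophobic position-5 residue (singleton-filtered, one subset assumed)
donor_haa5_proportion <- function(samples) {
  filt <- suppressWarnings(filter_singletons(samples))
  flag <- extract_aa5(filt$junction_aa)$is_haa5
  filt$flag <- flag
  filt <- filt[!is.na(filt$flag), , drop = FALSE]
  per_rep <- stats::aggregate(flag ~ donor_id + sample_id, data = filt,
                              FUN = mean)
  out <- stats::aggregate(flag ~ donor_id, data = per_rep, FUN = mean)
  out[order(out$donor_id), ]
}
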