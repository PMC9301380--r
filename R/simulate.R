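# Generative multi-donor TRD repertoire simulator with ground truth.
#
# The generative model is a stand-in with known statistical structure for
# pipeline validation, not a biophysically realistic recombination model:
# TRDV2 -> (D) -> TRDJ rearrangement with geometric end trimming and
# Poisson N blocks; convergent recombination emulated by seeding shared
# amino-acid sequences through donor-specific synonymous nucleotide routes;
# clone sizes follow a heavy-tailed power law reweighted by a logistic
# expansion propensity coupled to J1 usage, position-5 hydrophobicity and
# CDR3 length.

#' Build and validate a simulation configuration
#'
#' Defaults mirror a typical adult sorting study: 9 donors, duplicate
#' libraries per sorted subset, CD27pos/CD27neg subsets with 50,000 sorted
#' cells each, and a CD27neg compartment drawn from a 10x smaller clone set
#' with a steeper clone-size law (clonal focusing).
#'
#' @param seed Integer root seed; it fully determines the output.  Donor
#'   substreams are derived by fixed integer hashing, so adding a donor
#'   does not perturb the others.
#' @param n_donors Number of donors.
#' @param replicates_per_subset Independent replicate libraries per sorted
#'   subset (at least 2, as required by the replicate-concordance
#'   analysis).
#' @param subsets Named list of subset specs, each with `n_clones` (clones
#'   sampled from the donor pool into the subset) and
#'   `clone_size_exponent` (power-law exponent alpha > 1; steeper = more
#'   even, shallower = more clonal).
#' @param n_naive_clones Donor naive clone-pool size.
#' @param sorted_cell_count Sorted cells per sample (metadata contract for
#'   head-to-head comparisons).
#' @param reads_per_sample Reads emitted per replicate library (>= 100).
#' @param j_usage,d_usage Named usage probabilities over TRDJ1-4 and
#'   {none, TRDD1-3}; normalised internally.
#' @param trim_prob Geometric success probability per trimmed segment end
#'   (mean trim `(1-p)/p` nt).
#' @param n_insertion_mean Poisson mean of each N block (nt).
#' @param expansion_coupling Named numeric `c(haa5=, j1=, length=)`:
#'   log-linear coefficients of the clone expansion weight
#'   `w = exp(haa5*I(hAA5) + j1*I(J1) - length*(cdr3_len - 12))`.
#' @param public_pool Amino-acid sequences seeded across donors via
#'   distinct synonymous nucleotide routes (default [public_cdr3delta]).
#' @param public_seed_prob Per-donor probability that a public-pool
#'   sequence is present in the donor's clone pool.
#' @return A validated config (class `cdr3delta_sim_config`).
#' @export
simulation_config <- function(seed = 1L,
                              n_donors = 9L,
                              replicates_per_subset = 2L,
                              subsets = list(
                                CD27pos = list(n_clones = 3000L,
                                               clone_size_exponent = 2.5),
                                CD27neg = list(n_clones = 300L,
                                               clone_size_exponent = 1.8)),
                              n_naive_clones = 3000L,
                              sorted_cell_count = 50000L,
                              reads_per_sample = 20000L,
                              j_usage = c(TRDJ1 = 0.85, TRDJ2 = 0.02,
                                          TRDJ3 = 0.10, TRDJ4 = 0.03),
                              d_usage = c(none = 0.05, TRDD1 = 0.05,
                                          TRDD2 = 0.10, TRDD3 = 0.80),
                              trim_prob = 0.25,
                              n_insertion_mean = 4,
                              expansion_coupling = c(haa5 = 1.5, j1 = 1.5,
                                                     length = 0.25),
                              public_pool = public_cdr3delta,
                              public_seed_prob = 0.6) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (replicates_per_subset < 2L) {
    stop("replicates_per_subset must be >= 2 (replicate concordance)",
         call. = FALSE)
  }
  if (reads_per_sample < 100L) {
    stop("reads_per_sample < 100 is degenerate; refusing", call. = FALSE)
  }
  if (is.null(names(subsets)) || any(names(subsets) == "")) {
    stop("subsets must be a named list", call. = FALSE)
  }
  for (s in names(subsets)) {
    spec <- subsets[[s]]
    if (spec$n_clones > n_naive_clones) {
      stop(sprintf("subset '%s': n_clones exceeds n_naive_clones", s),
           call. = FALSE)
    }
    if (spec$clone_size_exponent <= 1) {
      stop(sprintf("subset '%s': clone_size_exponent must exceed 1", s),
           call. = FALSE)
    }
  }
  .check_probs <- function(p, nm, what) {
    if (!identical(sort(names(p)), sort(nm)) || any(p < 0) || sum(p) <= 0) {
      stop(sprintf("%s must be non-negative probabilities over {%s}", what,
                   paste(nm, collapse = ", ")), call. = FALSE)
    }
    p[nm] / sum(p)
  }
  j_usage <- .check_probs(j_usage, paste0("TRDJ", 1:4), "j_usage")
  d_usage <- .check_probs(d_usage, c("none", paste0("TRDD", 1:3)), "d_usage")
  stopifnot(trim_prob > 0, trim_prob <= 1, n_insertion_mean >= 0,
            all(c("haa5", "j1", "length") %in% names(expansion_coupling)),
            public_seed_prob >= 0, public_seed_prob <= 1)
  structure(list(
    seed = as.integer(seed), n_donors = as.integer(n_donors),
    replicates_per_subset = as.integer(replicates_per_subset),
    subsets = subsets, n_naive_clones = as.integer(n_naive_clones),
    sorted_cell_count = as.integer(sorted_cell_count),
    reads_per_sample = as.integer(reads_per_sample),
    j_usage = j_usage, d_usage = d_usage, trim_prob = trim_prob,
    n_insertion_mean = n_insertion_mean,
    expansion_coupling = expansion_coupling,
    public_pool = public_pool, public_seed_prob = public_seed_prob
  ), class = "cdr3delta_sim_config")
}

# fixed integer hash of (root seed, donor, stream) -> substream seed < 2^31
.derive_seed <- function(seed, donor, stream) {
  as.integer((as.double(seed) + 1103515245 * donor + 12345 * stream) %%
               2147483647)
}

.random_nt <- function(lens) {
  total <- sum(lens)
  if (total == 0L) return(rep("", length(lens)))
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  s <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- substring(s, starts, ends)
  out[lens == 0L] <- ""
  out
}

# draw m junction candidates (nucleotide level, with ground truth); no
# productivity filtering and no translation here
.draw_candidates <- function(m, config, reference = trd_reference()) {
  v_tail <- reference$nt_sequence[reference$segment_class == "V"]
  dseg <- reference[reference$segment_class == "D", , drop = FALSE]
  jseg <- reference[reference$segment_class == "J", , drop = FALSE]
  j_order <- match(paste0("TRDJ", 1:4), sub("\\*.*$", "", jseg$segment_id))
  jseg <- jseg[j_order, , drop = FALSE]
  d_order <- match(paste0("TRDD", 1:3), sub("\\*.*$", "", dseg$segment_id))
  dseg <- dseg[d_order, , drop = FALSE]

  p <- config$trim_prob
  j_idx <- sample.int(4L, m, replace = TRUE, prob = config$j_usage)
  d_idx <- sample.int(4L, m, replace = TRUE, prob = config$d_usage) - 1L

  t_v <- pmin(rgeom(m, p), nchar(v_tail) - 3L)
  v_part <- substr(rep(v_tail, m), 1L, nchar(v_tail) - t_v)

  d_len <- ifelse(d_idx == 0L, 0L, nchar(dseg$nt_sequence)[pmax(d_idx, 1L)])
  t_d5 <- pmin(rgeom(m, p), d_len)
  t_d3 <- pmin(rgeom(m, p), d_len)
  d_rem <- pmax(0L, d_len - t_d5 - t_d3)
  # micro-remnants (1-2 nt) are indistinguishable from N; treat as deleted
  d_rem[d_rem < 3L] <- 0L
  d_part <- ifelse(d_rem == 0L, "",
                   substr(dseg$nt_sequence[pmax(d_idx, 1L)], t_d5 + 1L,
                          t_d5 + d_rem))

  n1 <- rpois(m, config$n_insertion_mean)
  n2 <- rpois(m, config$n_insertion_mean)
  n1_part <- .random_nt(n1)
  n2_part <- .random_nt(n2)

  anchor_j <- jseg$junction_anchor_offset[j_idx]
  t_j <- pmin(rgeom(m, p), anchor_j)
  j_part <- substr(jseg$nt_sequence[j_idx], t_j + 1L, anchor_j + 3L)

  tibble::tibble(
    junction = paste0(v_part, n1_part, d_part, n2_part, j_part),
    v_call = reference$segment_id[reference$segment_class == "V"],
    d_call = ifelse(d_rem == 0L, NA_character_,
                    dseg$segment_id[pmax(d_idx, 1L)]),
    j_call = jseg$segment_id[j_idx],
    true_v_len = nchar(v_part), true_d_len = d_rem,
    true_j_len = nchar(j_part),
    true_n1 = n1, true_n2 = n2, true_total_n = n1 + n2,
    route = "vdj"
  )
}

#' Simulate productive TRD rearrangements
#'
#' Draws V(D)J rearrangements under the configured usage, trimming and
#' insertion model, rejecting nonproductive junctions (out of frame, stop
#' codon, lost anchors) and redrawing until `n` productive junctions are
#' obtained.
#'
#' @param n Number of productive rearrangements to return.
#' @param config A [simulation_config()].
#' @param seed Optional seed (defaults to `config$seed`); the caller's RNG
#'   state is preserved.
#' @return A tibble of `n` rearrangements with columns `junction`,
#'   `junction_aa`, `v_call`, `d_call`, `j_call` and the ground-truth block
#'   structure (`true_v_len`, `true_d_len`, `true_j_len`, `true_n1`,
#'   `true_n2`, `true_total_n`).  Attribute `n_rejected` counts redraws.
#' @export
simulate_rearrangements <- function(n, config = simulation_config(),
                                    seed = config$seed) {
  .with_preserved_rng(seed, .simulate_rearrangements_impl(n, config))
}

.simulate_rearrangements_impl <- function(n, config) {
  out <- list()
  got <- 0L
  rejected <- 0L
  while (got < n) {
    m <- max(200L, ceiling(3 * (n - got)))
    cand <- .draw_candidates(m, config)
    cand$junction_aa <- translate_dna(cand$junction)
    keep <- .productive_junction(cand$junction, cand$junction_aa)
    rejected <- rejected + sum(!keep)
    if (!any(keep) && rejected > 10000L) {
      stop("more than 10,000 consecutive nonproductive draws; degenerate simulation parameters",
           call. = FALSE)
    }
    cand <- cand[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- cand
    got <- got + nrow(cand)
  }
  res <- dplyr::bind_rows(out)[seq_len(n), , drop = FALSE]
  attr(res, "n_rejected") <- rejected
  res
}

.productive_junction <- function(junction, junction_aa) {
  n <- nchar(junction)
  n %% 3L == 0L & n >= 9L &
    !is.na(junction_aa) &
    !grepl("*", junction_aa, fixed = TRUE) &
    substr(junction_aa, 1L, 1L) == "C" &
    substr(junction_aa, nchar(junction_aa),
           nchar(junction_aa)) %in% c("F", "W")
}

# reverse genetic code for synonymous codon draws
.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

# a donor-specific nucleotide route for a given public amino-acid junction:
# germline codons where the sequence overlaps the V tail / J head
# translations, random synonymous codons in between
.public_route <- function(aa, reference = trd_reference()) {
  v_aa <- reference$aa_junction[reference$segment_class == "V"]
  v_nt <- reference$nt_sequence[reference$segment_class == "V"]
  jseg <- reference[reference$segment_class == "J", , drop = FALSE]
  ov_j <- vapply(jseg$aa_junction, function(h) .lcs(aa, h), integer(1))
  jbest <- which.max(ov_j)
  n_aa <- nchar(aa)
  l_v <- min(.lcp(aa, v_aa), n_aa)
  l_j <- min(ov_j[jbest], n_aa - l_v)
  middle <- substr(aa, l_v + 1L, n_aa - l_j)
  codons <- .codons_by_aa()
  mid_nt <- if (nchar(middle) == 0L) "" else {
    paste(vapply(.chars(middle), function(ch) {
      opts <- codons[[ch]]
      opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
  }
  anchor <- jseg$junction_anchor_offset[jbest]
  j_nt <- substr(jseg$nt_sequence[jbest], anchor + 3L - 3L * l_j + 1L,
                 anchor + 3L)
  tibble::tibble(
    junction = paste0(substr(v_nt, 1L, 3L * l_v), mid_nt, j_nt),
    v_call = reference$segment_id[reference$segment_class == "V"],
    d_call = NA_character_,
    j_call = jseg$segment_id[jbest],
    true_v_len = 3L * l_v, true_d_len = NA_integer_,
    true_j_len = 3L * l_j, true_n1 = NA_integer_, true_n2 = NA_integer_,
    true_total_n = NA_integer_,
    route = "public",
    junction_aa = aa
  )
}

#' Simulate a multi-donor, multi-subset, multi-replicate cohort
#'
#' Per donor, a naive clone pool is drawn (public-pool sequences seeded
#' through donor-specific synonymous routes), each clone receives an
#' expansion weight coupled to its features, and each sorted subset samples
#' its clones from the pool with probability proportional to the weight.
#' Subset clone fractions follow the subset's power-law size distribution
#' reweighted by the expansion weight; each replicate library is a
#' multinomial read sample of exactly `reads_per_sample` reads.  The root
#' seed fully determines the output; per-donor substreams are derived by
#' fixed hashing.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `samples` (AIRR-style clonotype tibble,
#'   one row per clonotype per replicate library, metadata columns
#'   included), `metadata` (one row per sample) and `truth` (list of
#'   `clones` - per-clone ground truth including generation route and
#'   expansion weight - and `fractions` - true per-subset clone
#'   fractions).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "cdr3delta_sim_config"))
  .with_preserved_rng(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  reference <- trd_reference()
  n_pool <- config$n_naive_clones

  # phase 1: per-donor candidate draws under the donor generation substream
  cands <- vector("list", config$n_donors)
  for (d in seq_len(config$n_donors)) {
    set.seed(.derive_seed(config$seed, d, 1L))
    cand <- .draw_candidates(max(200L, ceiling(6 * n_pool)), config)
    seeded <- runif(length(config$public_pool)) < config$public_seed_prob
    pub <- dplyr::bind_rows(lapply(config$public_pool[seeded],
                                   .public_route, reference = reference))
    cands[[d]] <- list(cand = cand, pub = pub)
  }

  # phase 2: one batched translation across the cohort (deterministic)
  all_nt <- unlist(lapply(cands, function(x) x$cand$junction),
                   use.names = FALSE)
  all_aa <- translate_dna(all_nt)
  offsets <- c(0L, cumsum(vapply(cands, function(x) nrow(x$cand),
                                 integer(1))))

  samples <- vector("list", config$n_donors)
  truth_clones <- vector("list", config$n_donors)
  truth_fracs <- vector("list", config$n_donors)
  beta <- config$expansion_coupling

  # phase 3: per-donor pool assembly and read sampling under the donor
  # sampling substream
  for (d in seq_len(config$n_donors)) {
    donor_id <- sprintf("D%02d", d)
    set.seed(.derive_seed(config$seed, d, 2L))
    cand <- cands[[d]]$cand
    cand$junction_aa <- all_aa[(offsets[d] + 1L):offsets[d + 1L]]
    keep <- .productive_junction(cand$junction, cand$junction_aa)
    cand <- cand[keep, , drop = FALSE]
    while (nrow(cand) < n_pool) {  # rare top-up
      extra <- .draw_candidates(max(200L, 6L * (n_pool - nrow(cand))), config)
      extra$junction_aa <- translate_dna(extra$junction)
      extra <- extra[.productive_junction(extra$junction,
                                          extra$junction_aa), , drop = FALSE]
      cand <- dplyr::bind_rows(cand, extra)
    }
    pool <- dplyr::bind_rows(cand[seq_len(n_pool), , drop = FALSE],
                             cands[[d]]$pub)
    pool <- pool[!duplicated(pool$junction), , drop = FALSE]
    pool$clone_id <- sprintf("%s_c%05d", donor_id, seq_len(nrow(pool)))
    pool$donor_id <- donor_id

    len <- nchar(pool$junction_aa) - 2L
    haa5 <- !is.na(pool$junction_aa) & nchar(pool$junction_aa) >= 7L &
      substr(pool$junction_aa, 6L, 6L) %in% HYDROPHOBIC_AA5
    j1 <- j_region_of(pool$j_call) == "J1"
    w <- exp(beta[["haa5"]] * haa5 + beta[["j1"]] * j1 -
               beta[["length"]] * (len - 12L))
    pool$expansion_weight <- as.numeric(w)

    for (s in names(config$subsets)) {
      spec <- config$subsets[[s]]
      n_sub <- min(spec$n_clones, nrow(pool))
      sel <- if (n_sub < nrow(pool)) {
        sample.int(nrow(pool), n_sub, prob = pool$expansion_weight)
      } else seq_len(nrow(pool))
      alpha <- spec$clone_size_exponent
      sizes <- (1 - runif(n_sub))^(-1 / (alpha - 1))
      p <- sizes * pool$expansion_weight[sel]
      p <- p / sum(p)
      truth_fracs[[length(truth_fracs) + 1L]] <- tibble::tibble(
        donor_id = donor_id, subset_label = s,
        clone_id = pool$clone_id[sel], true_fraction = p)
      for (r in seq_len(config$replicates_per_subset)) {
        counts <- rmultinom(1L, config$reads_per_sample, p)[, 1L]
        nz <- counts > 0L
        samp <- pool[sel[nz], c("clone_id", "junction", "junction_aa",
                                "v_call", "d_call", "j_call"), drop = FALSE]
        samp$duplicate_count <- counts[nz]
        samp$sample_id <- sprintf("%s_%s_r%d", donor_id, s, r)
        samp$donor_id <- donor_id
        samp$replicate_id <- sprintf("r%d", r)
        samp$subset_label <- s
        samp$sorted_cell_count <- config$sorted_cell_count
        samples[[length(samples) + 1L]] <- samp
      }
    }
    truth_clones[[d]] <- pool[, c("donor_id", "clone_id", "junction",
                                  "junction_aa", "v_call", "d_call",
                                  "j_call", "route", "true_total_n",
                                  "true_v_len", "true_d_len", "true_j_len",
                                  "expansion_weight"), drop = FALSE]
  }

  samples <- dplyr::bind_rows(samples)
  samples$sequence_id <- sprintf("%s|%s", samples$sample_id,
                                 samples$clone_id)
  samples$productive <- TRUE
  samples <- dplyr::select(samples, dplyr::all_of(c(
    "sequence_id", "sample_id", "donor_id", "replicate_id", "subset_label",
    "sorted_cell_count", "junction", "junction_aa", "v_call", "d_call",
    "j_call", "duplicate_count", "productive", "clone_id")))
  metadata <- dplyr::distinct(samples[, c("sample_id", "donor_id",
                                          "replicate_id", "subset_label",
                                          "sorted_cell_count")])
  list(samples = samples, metadata = metadata,
       truth = list(clones = dplyr::bind_rows(truth_clones),
                    fractions = dplyr::bind_rows(truth_fracs)))
}
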