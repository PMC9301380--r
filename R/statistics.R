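# Frequency classes, publicity / convergent recombination statistics, and
# diversity / evenness metrics.

#' Classify clonotype frequencies into expansion classes
#'
#' Clonotype frequency `f` (percent of sample reads) is binned into
#' non-expanded (`f < 0.1`), expanded (`0.1 <= f < 1`) and hyperexpanded
#' (`f >= 1`); boundaries are closed on the left, so 0.1 is expanded and
#' 1 is hyperexpanded.
#'
#' @param frequency Numeric vector of frequencies in percent, in
#'   `(0, 100]`.
#' @return Factor with levels `non_expanded`, `expanded`, `hyperexpanded`.
#' @examples
#' classify_frequency(c(0.05, 0.1, 1))
#' @export
classify_frequency <- function(frequency) {
  if (any(!is.na(frequency) & frequency <= 0)) {
    stop("frequencies must be positive (percent of sample reads)",
         call. = FALSE)
  }
  if (any(!is.na(frequency) & frequency > 100)) {
    stop("frequencies are percentages and cannot exceed 100", call. = FALSE)
  }
  cut(frequency, breaks = c(0, 0.1, 1, Inf), right = FALSE,
      labels = c("non_expanded", "expanded", "hyperexpanded"))
}

#' Nucleotypes detected in at least two samples of the same donor
#'
#' To reduce the uncertainty intrinsic to low-frequency detection, publicity
#' analyses use only the nucleotide clonotypes (junction, v_call, j_call)
#' observed - after singleton filtering - in two or more samples of a
#' donor.  Read counts are summed over the donor's samples.
#'
#' @param repertoire A singleton-filtered repertoire tibble covering one or
#'   more donors.
#' @return A tibble with one row per (donor, nucleotype): `donor_id`,
#'   `junction`, `v_call`, `j_call`, `junction_aa`, `n_samples` (samples of
#'   the donor containing the nucleotype) and `read_count` (summed over the
#'   donor's samples).  Only nucleotypes with `n_samples >= 2` are
#'   returned.
#' @export
replicate_concordant_nucleotypes <- function(repertoire) {
  .assert_columns(repertoire, c("donor_id", "sample_id", "junction",
                                "v_call", "j_call", "junction_aa",
                                "duplicate_count"), "repertoire")
  single <- repertoire |>
    dplyr::distinct(.data$donor_id, .data$sample_id) |>
    dplyr::count(.data$donor_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(single) > 0L) {
    stop(sprintf(paste("donor(s) with a single sample cannot enter the",
                       "replicate-concordance analysis: %s; skip publicity",
                       "for these donors"),
                 paste(single$donor_id, collapse = ", ")), call. = FALSE)
  }
  repertoire |>
    dplyr::group_by(.data$donor_id, .data$junction, .data$v_call,
                    .data$j_call, .data$junction_aa) |>
    dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                     read_count = sum(.data$duplicate_count),
                     .groups = "drop") |>
    dplyr::filter(.data$n_samples >= 2L)
}

#' Collapse nucleotypes to amino-acid clonotypes and score publicity
#'
#' Groups replicate-concordant nucleotypes by junction amino-acid sequence:
#' nucleotypes encoding the same amino-acid sequence are collapsed to a
#' single entry whose read count is the total over all constituent
#' nucleotypes.  An amino-acid clonotype is public when shared by at least
#' two donors, and highly common when shared by more than half of the
#' cohort.
#'
#' @param concordant Output of [replicate_concordant_nucleotypes()] pooled
#'   across the donors in scope.
#' @param n_cohort_donors Number of donors in the cohort (denominator of
#'   the highly-common threshold); defaults to the number of distinct
#'   donors present in `concordant`.
#' @return A tibble with one row per amino-acid clonotype: `junction_aa`,
#'   `n_donors_sharing`, `n_nucleotypes` (distinct junction nucleotide
#'   sequences pooled over donors), `collapsed_read_count`, `is_public`
#'   (`n_donors_sharing >= 2`) and `is_highly_common`
#'   (`n_donors_sharing > n_cohort_donors / 2`).
#' @export
publicity_table <- function(concordant, n_cohort_donors = NULL) {
  if (nrow(concordant) == 0L) {
    return(tibble::tibble(junction_aa = character(),
                          n_donors_sharing = integer(),
                          n_nucleotypes = integer(),
                          collapsed_read_count = integer(),
                          is_public = logical(), is_highly_common = logical()))
  }
  if (is.null(n_cohort_donors)) {
    n_cohort_donors <- dplyr::n_distinct(concordant$donor_id)
  }
  if (n_cohort_donors < 2L) {
    stop("publicity requires at least 2 donors in scope", call. = FALSE)
  }
  concordant |>
    dplyr::group_by(.data$junction_aa) |>
    dplyr::summarise(
      n_donors_sharing = dplyr::n_distinct(.data$donor_id),
      n_nucleotypes = dplyr::n_distinct(.data$junction),
      collapsed_read_count = sum(.data$read_count),
      .groups = "drop") |>
    dplyr::mutate(is_public = .data$n_donors_sharing >= 2L,
                  is_highly_common =
                    .data$n_donors_sharing > n_cohort_donors / 2) |>
    dplyr::arrange(dplyr::desc(.data$n_donors_sharing), .data$junction_aa)
}

#' Flag public amino-acid clonotypes in an annotated repertoire
#'
#' @param repertoire An annotated repertoire tibble.
#' @param publicity A publicity table ([publicity_table()]).
#' @return The repertoire with a logical `is_public` column (amino-acid
#'   level membership in the public set).
#' @export
flag_public <- function(repertoire, publicity) {
  public_aa <- publicity$junction_aa[publicity$is_public]
  repertoire$is_public <- repertoire$junction_aa %in% public_aa
  repertoire
}

#' Shannon entropy of a clonotype read-count distribution
#'
#' `H = -sum(p_i * log(p_i))` in nats (natural logarithm), with
#' `p_i = count_i / total`.
#'
#' @param counts Positive read counts (one per clonotype).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(1, 4))  # log(4)
#' @export
shannon_entropy <- function(counts) {
  counts <- .check_counts(counts)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Repertoire evenness D75
#'
#' The percentage of unique clonotypes that occupy 75% of the sample
#' library: counts are sorted in decreasing order (ties broken by a
#' deterministic key when supplied), `k` is the smallest number of top
#' clonotypes whose cumulative read share reaches at least 75%, and D75 is
#' `100 * k / richness`.  Lower values indicate a more clonal (less even)
#' repertoire.
#'
#' @param counts Positive read counts (one per clonotype).
#' @param tie_break Optional character vector (e.g. junction nucleotide
#'   sequences) used to order tied counts deterministically.
#' @param share Cumulative read share defining the metric (0.75 for D75).
#' @return Percentage in `(0, 100]`.
#' @examples
#' d75(rep(1, 100))       # 75
#' d75(c(97, 1, 1, 1))    # 25
#' @export
d75 <- function(counts, tie_break = NULL, share = 0.75) {
  counts <- .check_counts(counts)
  ord <- if (is.null(tie_break)) order(-counts) else order(-counts, tie_break)
  cum <- cumsum(counts[ord]) / sum(counts)
  k <- which(cum >= share)[1L]
  100 * k / length(counts)
}

#' Repertoire richness
#'
#' The number of distinct retained clonotypes (post-filter).
#'
#' @param counts Read counts, one per clonotype (or any per-clonotype
#'   vector).
#' @return Integer count.
#' @export
richness <- function(counts) length(counts)

.check_counts <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L) stop("empty read-count vector", call. = FALSE)
  if (any(counts <= 0)) stop("read counts must be positive", call. = FALSE)
  counts
}

#' Per-sample diversity metrics
#'
#' Shannon entropy (nats), richness and D75 per sample, computed on the
#' post-filter read counts.
#'
#' @param repertoire A singleton-filtered repertoire tibble.
#' @return Tibble with columns `sample_id`, `donor_id`, `replicate_id`,
#'   `subset_label`, `sorted_cell_count` (where present), `shannon`,
#'   `richness` and `d75`.
#' @export
diversity_metrics <- function(repertoire) {
  keys <- intersect(c("sample_id", "donor_id", "replicate_id", "subset_label",
                      "sorted_cell_count"), names(repertoire))
  repertoire |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      shannon = shannon_entropy(.data$duplicate_count),
      richness = richness(.data$duplicate_count),
      d75 = d75(.data$duplicate_count, tie_break = .data$junction),
      .groups = "drop")
}

#' Split an annotated repertoire into bias-segregated subrepertoires
#'
#' Partitions the clonotypes of a sample along one of the generation-bias
#' axes: germline-encoded (no N insertions) versus N-inserted, or public
#' versus private.  The partition is disjoint and exhaustive; frequencies
#' are not renormalised within splits (they remain fractions of the whole
#' sample).
#'
#' @param repertoire An annotated repertoire with the columns required by
#'   `axis` (`germline_encoded`, or `is_public` from [flag_public()]).
#' @param axis `"germline_vs_inserted"` or `"public_vs_private"`.
#' @return A named list of two tibbles (`germline`/`inserted` or
#'   `public`/`private`).
#' @export
split_subrepertoire <- function(repertoire,
                                axis = c("germline_vs_inserted",
                                         "public_vs_private")) {
  axis <- match.arg(axis)
  col <- if (axis == "germline_vs_inserted") "germline_encoded" else "is_public"
  if (!col %in% names(repertoire)) {
    stop(sprintf("axis '%s' requires annotation column '%s'", axis, col),
         call. = FALSE)
  }
  flag <- repertoire[[col]]
  if (anyNA(flag)) {
    stop(sprintf("annotation column '%s' contains NA; cannot partition", col),
         call. = FALSE)
  }
  if (axis == "germline_vs_inserted") {
    list(germline = repertoire[flag, , drop = FALSE],
         inserted = repertoire[!flag, , drop = FALSE])
  } else {
    list(public = repertoire[flag, , drop = FALSE],
         private = repertoire[!flag, , drop = FALSE])
  }
}

#' Downsample sample reads to a common depth
#'
#' Optional utility (an extension, not part of the core comparison
#' contract): draws `depth` reads per sample without replacement from the
#' observed read multiset, seeded for reproducibility.  The core pipeline
#' instead refuses head-to-head diversity comparisons across samples with
#' unequal sorted cell counts.
#'
#' @param repertoire A repertoire tibble.
#' @param depth Target read depth per sample.
#' @param seed Integer seed.
#' @return The repertoire with downsampled `duplicate_count` (clonotypes
#'   falling to zero are dropped).
#' @export
downsample_reads <- function(repertoire, depth, seed = 1L) {
  .with_preserved_rng(seed, {
    repertoire |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(function(df, key) {
        total <- sum(df$duplicate_count)
        if (total <= depth) return(df)
        take <- sample(rep.int(seq_len(nrow(df)), df$duplicate_count), depth)
        df$duplicate_count <- tabulate(take, nbins = nrow(df))
        df[df$duplicate_count > 0L, , drop = FALSE]
      }) |>
      dplyr::ungroup()
  })
}
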