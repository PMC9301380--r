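# Frequency-stratified feature enrichment, length distributions,
# rank-based two-group tests and subset contrasts.

.FEATURE_COLS <- c(j1 = "j_region", inv_t = "inv_t", haa5 = "is_haa5",
                   germline = "germline_encoded", public = "is_public")

.feature_flag <- function(repertoire, feature) {
  col <- .FEATURE_COLS[[feature]]
  if (!col %in% names(repertoire)) {
    stop(sprintf("feature '%s' requires annotation column '%s'", feature, col),
         call. = FALSE)
  }
  if (feature == "j1") repertoire[[col]] == "J1" else repertoire[[col]]
}

#' Feature enrichment by frequency class
#'
#' For each sample and frequency class, the proportion of unique clonotypes
#' bearing the feature (clonotype-weighted: every clonotype counts once
#' within its class).  Per donor, replicate proportions are additionally
#' averaged.  Clonotypes for which the feature is undefined (e.g. the
#' position-5 residue of junctions shorter than 7 amino acids) are excluded
#' and counted.
#'
#' @param repertoire An annotated repertoire ([annotate_repertoire()];
#'   `feature = "public"` additionally needs [flag_public()]).
#' @param feature One of `"j1"`, `"inv_t"`, `"haa5"`, `"germline"`,
#'   `"public"`.
#' @return A tibble with columns `level` (`"replicate"` rows carry
#'   `sample_id`; `"donor"` rows average the donor's replicates),
#'   `donor_id`, `subset_label`, `sample_id`, `frequency_class`, `feature`,
#'   `proportion` and `n_clonotypes`; attribute `n_excluded` counts
#'   feature-undefined clonotypes.
#' @export
enrichment_by_class <- function(repertoire,
                                feature = c("j1", "inv_t", "haa5",
                                            "germline", "public")) {
  feature <- match.arg(feature)
  flag <- .feature_flag(repertoire, feature)
  keep <- !is.na(flag)
  n_excluded <- sum(!keep)
  df <- repertoire[keep, , drop = FALSE]
  df$.flag <- flag[keep]

  by_rep <- df |>
    dplyr::group_by(.data$donor_id, .data$subset_label, .data$sample_id,
                    .data$frequency_class) |>
    dplyr::summarise(proportion = mean(.data$.flag),
                     n_clonotypes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(level = "replicate")
  by_donor <- by_rep |>
    dplyr::group_by(.data$donor_id, .data$subset_label,
                    .data$frequency_class) |>
    dplyr::summarise(proportion = mean(.data$proportion),
                     n_clonotypes = sum(.data$n_clonotypes),
                     .groups = "drop") |>
    dplyr::mutate(level = "donor", sample_id = NA_character_)
  out <- dplyr::bind_rows(by_rep, by_donor)
  out$feature <- feature
  out <- dplyr::select(out, dplyr::all_of(c(
    "level", "donor_id", "subset_label", "sample_id", "frequency_class",
    "feature", "proportion", "n_clonotypes")))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' CDR3 length distribution by frequency class
#'
#' For each sample and frequency class, the fraction of unique clonotypes
#' of each CDR3 length (per-sample distributions sum to 1 within a class);
#' the returned distribution is the mean across samples.  The analysis is
#' typically restricted to J1-rearranged clonotypes.
#'
#' @param repertoire An annotated repertoire.
#' @param restrict_to Optional J region label (e.g. `"J1"`); `NULL` keeps
#'   all clonotypes.
#' @return Tibble of `frequency_class`, `cdr3_length`, `mean_proportion`
#'   and `n_samples`.
#' @export
length_distribution_by_class <- function(repertoire, restrict_to = "J1") {
  df <- repertoire[!is.na(repertoire$cdr3_length), , drop = FALSE]
  if (!is.null(restrict_to)) {
    df <- df[!is.na(df$j_region) & df$j_region == restrict_to, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(tibble::tibble(frequency_class = factor(), cdr3_length = integer(),
                          mean_proportion = numeric(), n_samples = integer()))
  }
  df |>
    dplyr::group_by(.data$sample_id, .data$frequency_class) |>
    dplyr::count(.data$cdr3_length, name = "n_len") |>
    dplyr::mutate(proportion = .data$n_len / sum(.data$n_len)) |>
    dplyr::group_by(.data$frequency_class, .data$cdr3_length) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Two-sided Wilcoxon rank-sum test between two independent groups
#'
#' Midranks are used for ties.  The null distribution is exact (full
#' enumeration) when `n_a + n_b <= 16` and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.  The
#' reported effect is the plain difference of group medians
#' (`median(a) - median(b)`).
#'
#' @param values_a,values_b Numeric vectors (each non-empty).
#' @param label_a,label_b Group labels for the result row.
#' @return A one-row tibble: `group_a`, `group_b`, `statistic` (rank-sum W
#'   for group a), `p_value`, `median_difference`, `n_a`, `n_b`, `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
wilcoxon_rank_sum <- function(values_a, values_b, label_a = "a",
                              label_b = "b") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("both groups must contain at least one value", call. = FALSE)
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- !ties && (length(values_a) + length(values_b)) <= 16L
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values identical across both groups; p = 1 by convention",
            call. = FALSE)
    w <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                             exact = FALSE))
    stat <- unname(w$statistic)
    p <- 1
  } else {
    w <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                             alternative = "two.sided",
                                             exact = exact, correct = TRUE))
    stat <- unname(w$statistic)
    p <- w$p.value
  }
  tibble::tibble(group_a = label_a, group_b = label_b, statistic = stat,
                 p_value = p,
                 median_difference = median(values_a) - median(values_b),
                 n_a = length(values_a), n_b = length(values_b),
                 exact = exact)
}

#' Spearman rank-correlation matrix of per-donor phenotype fractions
#'
#' Symmetric matrix of Spearman correlation coefficients (midranks for
#' ties) across the supplied columns; entries involving a constant column
#' are `NA`.
#'
#' @param fractions A data frame or tibble of numeric columns (one row per
#'   donor, at least 3 rows).
#' @return Numeric matrix with unit diagonal and entries in `[-1, 1]`
#'   (or `NA`).
#' @export
spearman_correlation_matrix <- function(fractions) {
  m <- as.matrix(fractions)
  if (!is.numeric(m)) stop("all columns must be numeric", call. = FALSE)
  if (nrow(m) < 3L) stop("at least 3 donors are required", call. = FALSE)
  constant <- apply(m, 2L, function(x) length(unique(x[!is.na(x)])) <= 1L)
  out <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "pairwise.complete.obs"))
  out[constant, ] <- NA_real_
  out[, constant] <- NA_real_
  diag(out) <- ifelse(constant, NA_real_, 1)
  out
}

#' Compare two sorted subsets on a repertoire metric
#'
#' Computes the metric per sample within each subset and applies the
#' unpaired two-sided Wilcoxon rank-sum test to the per-sample values
#' (donor pairing is reflected only in replicate averaging upstream, not in
#' the test).  Head-to-head diversity comparisons require equal sorted cell
#' counts across the samples in scope unless `allow_unequal_cells`.
#'
#' @param repertoire An annotated repertoire containing both subsets.
#' @param subset_a,subset_b Subset labels (e.g. `"CD27pos"`, `"CD27neg"`).
#' @param metric One of `"shannon"`, `"richness"`, `"d75"`,
#'   `"mean_cdr3_length"`, `"mean_n_insertions"`, or a feature name
#'   (`"j1"`, `"inv_t"`, `"haa5"`, `"germline"`, `"public"`) combined with
#'   `frequency_class` to compare a per-class feature proportion.
#' @param frequency_class Optional class restriction for feature-proportion
#'   metrics.
#' @param allow_unequal_cells Permit diversity comparisons across unequal
#'   sorted cell counts.
#' @return A one-row [wilcoxon_rank_sum()] result tibble with a `metric`
#'   column.
#' @export
compare_subsets <- function(repertoire, subset_a, subset_b, metric,
                            frequency_class = NULL,
                            allow_unequal_cells = FALSE) {
  .assert_columns(repertoire, c("subset_label", "sample_id"), "repertoire")
  df <- repertoire[repertoire$subset_label %in% c(subset_a, subset_b), ,
                   drop = FALSE]
  for (s in c(subset_a, subset_b)) {
    if (!any(df$subset_label == s)) {
      stop(sprintf("subset '%s' absent from the repertoire", s),
           call. = FALSE)
    }
  }
  diversity_like <- metric %in% c("shannon", "richness", "d75")
  if (diversity_like && !allow_unequal_cells &&
      "sorted_cell_count" %in% names(df) &&
      dplyr::n_distinct(df$sorted_cell_count) > 1L) {
    stop(paste("sorted cell counts differ across samples; head-to-head",
               "diversity comparisons require equal numbers of sorted cells",
               "(use allow_unequal_cells = TRUE to override)"),
         call. = FALSE)
  }

  per_sample <- if (diversity_like) {
    dm <- diversity_metrics(df)
    dm$value <- dm[[metric]]
    dm[, c("sample_id", "subset_label", "value")]
  } else if (metric == "mean_cdr3_length") {
    df |>
      dplyr::group_by(.data$sample_id, .data$subset_label) |>
      dplyr::summarise(value = mean(.data$cdr3_length, na.rm = TRUE),
                       .groups = "drop")
  } else if (metric == "mean_n_insertions") {
    df |>
      dplyr::group_by(.data$sample_id, .data$subset_label) |>
      dplyr::summarise(value = mean(.data$n_insertions, na.rm = TRUE),
                       .groups = "drop")
  } else if (metric %in% names(.FEATURE_COLS)) {
    flag <- .feature_flag(df, metric)
    df$.flag <- flag
    if (!is.null(frequency_class)) {
      df <- df[!is.na(df$frequency_class) &
                 df$frequency_class == frequency_class, , drop = FALSE]
    }
    df |>
      dplyr::filter(!is.na(.data$.flag)) |>
      dplyr::group_by(.data$sample_id, .data$subset_label) |>
      dplyr::summarise(value = mean(.data$.flag), .groups = "drop")
  } else {
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  }

  res <- wilcoxon_rank_sum(
    per_sample$value[per_sample$subset_label == subset_a],
    per_sample$value[per_sample$subset_label == subset_b],
    label_a = subset_a, label_b = subset_b)
  res$metric <- metric
  res
}
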