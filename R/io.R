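# Reading, validating and writing clonotype tables.
#
# A repertoire is represented as one tidy tibble with one row per clonotype
# per sample; sample metadata (donor, replicate, sorted subset, sorted cell
# count) is joined onto every row.  Clonotype identity at the nucleotide
# level is the tuple (junction, v_call, j_call); d_call is informative only.

.metadata_cols <- c("sample_id", "donor_id", "replicate_id", "subset_label",
                    "sorted_cell_count")

.repertoire_out_cols <- c("sample_id", "donor_id", "replicate_id",
                          "subset_label", "sorted_cell_count", "junction",
                          "junction_aa", "v_call", "d_call", "j_call",
                          "duplicate_count", "productive")

#' Read and validate an AIRR-style clonotype table with sample metadata
#'
#' Reads a tab-separated clonotype table in the AIRR Rearrangement dialect
#' (columns `junction`, `junction_aa`, `v_call`, `j_call`, a read-count
#' column, and `sample_id`; `d_call` optional) together with a metadata
#' table mapping `sample_id` to donor, replicate, sorted subset and sorted
#' cell count.  Rows with an empty junction or a non-positive count are
#' rejected and reported; records whose in-frame translation does not match
#' `junction_aa`, contains a stop, or lacks the Cys104/Phe-Trp118 anchors
#' are flagged nonproductive (retained, but excluded from amino-acid-level
#' analyses downstream).
#'
#' @param table_path Path to the clonotype TSV.
#' @param metadata_path Path to the metadata TSV with columns `sample_id`,
#'   `donor_id`, `replicate_id`, `subset_label`, `sorted_cell_count`.
#' @param count_column Name of the read-count column (default the AIRR
#'   `"duplicate_count"`).
#' @param keep_nonproductive Keep nonproductive records (flagged) rather
#'   than dropping them.
#' @return A tibble with one row per clonotype per sample, standard AIRR
#'   column names, a logical `productive` column, and the metadata columns
#'   joined on.  Attributes `rejected` (tibble of rejected rows with a
#'   reason) and `n_nonproductive` report the validation outcome.
#' @export
read_repertoire <- function(table_path, metadata_path,
                            count_column = "duplicate_count",
                            keep_nonproductive = TRUE) {
  tbl <- readr::read_tsv(table_path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  meta <- readr::read_tsv(metadata_path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  .assert_columns(meta, .metadata_cols, "metadata table")
  if (!count_column %in% names(tbl) && "duplicate_count" %in% names(tbl)) {
    count_column <- "duplicate_count"
  }
  .assert_columns(tbl, c("junction", "junction_aa", "v_call", "j_call",
                         count_column, "sample_id"), "clonotype table")
  tbl$duplicate_count <- as.integer(tbl[[count_column]])
  if (!"d_call" %in% names(tbl)) tbl$d_call <- NA_character_

  unknown <- setdiff(unique(tbl$sample_id), meta$sample_id)
  if (length(unknown) > 0L) {
    stop(sprintf("sample(s) present in clonotype table but absent from metadata: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(meta[, c("donor_id", "replicate_id", "subset_label")])) {
    stop("metadata: (donor_id, replicate_id, subset_label) must be unique per sample",
         call. = FALSE)
  }

  bad_junction <- is.na(tbl$junction) | tbl$junction == ""
  bad_count <- is.na(tbl$duplicate_count) | tbl$duplicate_count < 1L
  rejected <- tbl[bad_junction | bad_count, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    rejected$reason <- ifelse(bad_junction[bad_junction | bad_count],
                              "empty junction", "non-positive count")
    warning(sprintf("rejected %d invalid row(s) (empty junction or non-positive count)",
                    nrow(rejected)), call. = FALSE)
  }
  tbl <- tbl[!(bad_junction | bad_count), , drop = FALSE]

  tbl$productive <- is_productive(tbl$junction, tbl$junction_aa)
  n_nonprod <- sum(!tbl$productive)
  if (!keep_nonproductive) tbl <- tbl[tbl$productive, , drop = FALSE]

  out <- dplyr::inner_join(tbl, meta, by = "sample_id")
  out <- dplyr::select(out, dplyr::all_of(.repertoire_out_cols))
  out <- dplyr::arrange(out, .data$sample_id, dplyr::desc(.data$duplicate_count),
                        .data$junction)
  attr(out, "rejected") <- tibble::as_tibble(rejected)
  attr(out, "n_nonproductive") <- n_nonprod
  out
}

#' Productivity check for junction records
#'
#' A record is productive when the junction nucleotide length is a multiple
#' of three, its translation equals `junction_aa` without a stop codon, and
#' the amino-acid junction carries the anchors (leading `C`, trailing `F`
#' or `W`).
#'
#' @param junction Character vector of junction nucleotide sequences.
#' @param junction_aa Character vector of junction amino-acid sequences.
#' @return Logical vector.
#' @export
is_productive <- function(junction, junction_aa) {
  n <- nchar(junction)
  inframe <- !is.na(junction) & n >= 9L & n %% 3L == 0L
  aa <- rep(NA_character_, length(junction))
  aa[inframe] <- translate_dna(junction[inframe])
  inframe &
    !is.na(junction_aa) &
    !is.na(aa) &
    aa == junction_aa &
    !grepl("*", junction_aa, fixed = TRUE) &
    substr(junction_aa, 1L, 1L) == "C" &
    substr(junction_aa, nchar(junction_aa), nchar(junction_aa)) %in% c("F", "W")
}

#' Remove singleton clonotypes from a repertoire
#'
#' Retains exactly the clonotypes supported by more than one read
#' (`duplicate_count >= 2`), per sample.  The filter is applied before any
#' frequency computation; totals are always recomputed downstream, never
#' trusted from input.  Idempotent; the input is not modified.
#'
#' @param repertoire A repertoire tibble as returned by [read_repertoire()].
#' @return The filtered tibble (possibly empty, with a warning).
#' @examples
#' tbl <- tibble::tibble(sample_id = "s", duplicate_count = c(5L, 1L, 2L),
#'                       junction = c("a", "b", "c"))
#' filter_singletons(tbl)$duplicate_count
#' @export
filter_singletons <- function(repertoire) {
  .assert_columns(repertoire, "duplicate_count", "repertoire")
  out <- repertoire[repertoire$duplicate_count >= 2L, , drop = FALSE]
  if (nrow(out) == 0L && nrow(repertoire) > 0L) {
    warning("all clonotypes are singletons; filtered repertoire is empty",
            call. = FALSE)
  }
  out
}

#' Total reads per sample
#'
#' @param repertoire A repertoire tibble.
#' @return Tibble with columns `sample_id` and `total_reads` (sum of
#'   `duplicate_count`, recomputed from the rows).
#' @export
sample_totals <- function(repertoire) {
  repertoire |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total_reads = sum(.data$duplicate_count), .groups = "drop")
}

#' Write a tidy table deterministically
#'
#' Writes any record tibble as a UTF-8 TSV with `.` as the decimal
#' separator, stable column order, and deterministic row order (rows are
#' sorted by all character/integer key columns unless `sort` is `FALSE`).
#' An optional comment header carries provenance.  Two runs on the same
#' input produce byte-identical files.
#'
#' @param records A tibble.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written as
#'   `# ...`).
#' @param sort Sort rows lexicographically by all columns for determinism.
#' @return `path`, invisibly.
#' @export
write_tidy_table <- function(records, path, header = NULL, sort = TRUE) {
  if (sort && nrow(records) > 0L) {
    records <- records[do.call(order, lapply(records, as.character)), ,
                       drop = FALSE]
  }
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(records, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(records, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a repertoire and its metadata as AIRR-style TSVs
#'
#' Emits AIRR-standard column names; `read_repertoire()` on the two files
#' restores the repertoire losslessly (round-trip property).
#'
#' @param repertoire A repertoire tibble (clonotypes plus metadata columns).
#' @param table_path,metadata_path Output paths.
#' @param header Optional comment header lines.
#' @return `table_path`, invisibly.
#' @export
write_repertoire <- function(repertoire, table_path, metadata_path,
                             header = NULL) {
  clono_cols <- setdiff(names(repertoire),
                        setdiff(.metadata_cols, "sample_id"))
  write_tidy_table(repertoire[, clono_cols, drop = FALSE], table_path,
                   header = header)
  meta <- dplyr::distinct(repertoire[, .metadata_cols, drop = FALSE])
  write_tidy_table(meta, metadata_path, header = header)
  invisible(table_path)
}
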