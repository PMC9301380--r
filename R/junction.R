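# CDR3delta feature annotation: length, position-5 residue, invariant-T,
# J region, and V(D)J junction decomposition with N-insertion counting.

#' Hydrophobic amino acids at CDR3delta position 5
#'
#' The residues counted as hydrophobic at CDR3 position 5 (IMGT 109), a
#' determinant of phosphoantigen-induced reactivity of the gamma9delta2 TCR.
#' @format Character vector of one-letter amino-acid codes.
#' @export
HYDROPHOBIC_AA5 <- c("A", "V", "L", "I", "P", "W", "F", "M")

# residues whose codons carry T at the second position
.INVT_AA <- c("F", "L", "I", "M", "V")

#' CDR3 length from a junction amino-acid sequence
#'
#' The CDR3 excludes the two conserved anchors (Cys104 and Phe/Trp118), so
#' its length is the junction length minus two.
#'
#' @param junction_aa Character vector of productive junction amino-acid
#'   sequences (leading `C`, trailing `F`/`W`, length >= 3).
#' @return Integer vector of CDR3 lengths in amino acids.
#' @examples
#' cdr3_length("CACDTLGDTDKLIF")  # 12
#' @export
cdr3_length <- function(junction_aa) {
  n <- nchar(junction_aa)
  bad <- !is.na(junction_aa) &
    (n < 3L |
       substr(junction_aa, 1L, 1L) != "C" |
       !substr(junction_aa, n, n) %in% c("F", "W"))
  if (any(bad)) {
    stop(sprintf("nonproductive or under-length junction(s): %s",
                 paste(head(unique(junction_aa[bad]), 3L), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(n - 2L)
}

#' Residue at CDR3 position 5 and its hydrophobicity
#'
#' CDR3 position 5 (IMGT 109) is the sixth junction residue, counting the
#' residue after Cys104 as position 1.  It is defined only for junctions of
#' at least 7 amino acids; shorter junctions yield `NA` (excluded from
#' position-5 analyses, counted by callers).
#'
#' @param junction_aa Character vector of junction amino-acid sequences.
#' @return A tibble with columns `aa5` (character, `NA` when undefined) and
#'   `is_haa5` (logical: `aa5` in [HYDROPHOBIC_AA5]).
#' @examples
#' extract_aa5(c("CACDTLGDTDKLIF", "CACDTEGTPTLLIF"))
#' @export
extract_aa5 <- function(junction_aa) {
  aa5 <- ifelse(!is.na(junction_aa) & nchar(junction_aa) >= 7L,
                substr(junction_aa, 6L, 6L), NA_character_)
  tibble::tibble(aa5 = aa5,
                 is_haa5 = ifelse(is.na(aa5), NA, aa5 %in% HYDROPHOBIC_AA5))
}

#' Detect the invariant-T nucleotide
#'
#' True when the second nucleotide of the codon encoding CDR3 position 5
#' (codon 6 of the junction, nucleotides 16-18) is `T`.  A template `T` at
#' that position forces a hydrophobic residue (F/L/I/M/V), so `inv_t`
#' implies `is_haa5`.  Any `T` qualifies; its germline-versus-inserted
#' origin is not tested.
#'
#' @param junction Character vector of junction nucleotide sequences.
#' @param junction_aa Matching amino-acid sequences (frame check).
#' @return Logical vector (`NA` when the junction is shorter than 7
#'   residues).
#' @export
detect_inv_t <- function(junction, junction_aa) {
  ok <- !is.na(junction) & !is.na(junction_aa) & nchar(junction_aa) >= 7L
  frame_ok <- ok & nchar(junction) >= 18L &
    translate_dna(substr(junction, 16L, 18L)) == substr(junction_aa, 6L, 6L)
  if (any(ok & !frame_ok)) {
    stop("junction nucleotide sequence inconsistent with junction_aa at codon 6",
         call. = FALSE)
  }
  ifelse(ok, substr(junction, 17L, 17L) == "T", NA)
}

#' Classify the J region of a junction by amino-acid suffix
#'
#' Returns the J segment whose translated junction-proximal head shares the
#' longest amino-acid suffix (at least `min_overlap` residues) with the
#' junction.  Used only when `j_call` is absent; a supplied `j_call` always
#' takes precedence.
#'
#' @param junction_aa Character vector of productive junction amino-acid
#'   sequences.
#' @param reference Germline reference tibble ([trd_reference()]).
#' @param j_call Optional character vector of TRDJ calls; where non-`NA`
#'   the call decides the label.
#' @param min_overlap Minimum suffix overlap in residues (default 4).
#' @return Character vector over `{"J1","J2","J3","J4"}`, `NA` when no head
#'   overlaps sufficiently.
#' @examples
#' classify_j_region("CACDTLGDTDKLIF")      # "J1"
#' classify_j_region("CACDTAGGSSWDTRQMFF")  # "J3"
#' @export
classify_j_region <- function(junction_aa, reference = trd_reference(),
                              j_call = NULL, min_overlap = 4L) {
  jseg <- reference[reference$segment_class == "J", , drop = FALSE]
  heads <- setNames(jseg$aa_junction, j_region_of(jseg$segment_id))
  by_suffix <- vapply(junction_aa, function(aa) {
    if (is.na(aa)) return(NA_character_)
    ov <- vapply(heads, function(h) .lcs(aa, h), integer(1))
    if (max(ov) < min_overlap) NA_character_ else names(heads)[which.max(ov)]
  }, character(1), USE.NAMES = FALSE)
  if (is.null(j_call)) return(by_suffix)
  called <- !is.na(j_call)
  out <- by_suffix
  out[called] <- j_region_of(j_call[called])
  out
}

# ---------------------------------------------------------------------------
# Junction decomposition

# diagonal-run dynamic programme: all exact contiguous matches (length >=
# min_len) between the junction and one D segment; returns end position and
# maximal run length per cell with run >= min_len
.d_matches <- function(jc, dc, min_len) {
  L <- length(jc); K <- length(dc)
  runs <- matrix(0L, nrow = L, ncol = K)
  prev <- integer(K)
  for (i in seq_len(L)) {
    eq <- jc[i] == dc
    cur <- integer(K)
    cur[eq] <- 1L
    if (K > 1L) cur[-1L][eq[-1L]] <- prev[-K][eq[-1L]] + 1L
    runs[i, ] <- cur
    prev <- cur
  }
  idx <- which(runs >= min_len, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(end = as.integer(idx[, 1L]), run = as.integer(runs[idx]))
}

#' Decompose a junction into germline-attributable and inserted nucleotides
#'
#' Attributes junction nucleotides to contiguous, ordered blocks V, N1, D,
#' N2, J: an exact prefix match against the 3' end of TRDV2 (anchored at
#' Cys104), an optional exact contiguous match of at least `min_d_match`
#' nucleotides against a D segment, an exact suffix match against the 5'
#' head of a J segment, and unattributed (N) nucleotides in between.  Among
#' all decompositions the one maximising the germline-attributed score
#' (junction length minus total N) is returned; ties are broken by larger
#' V match, then larger J match, then presence of a D segment, then
#' lexicographically smallest D identifier.  Palindromic (P) additions are
#' not modelled separately and count as N, so `total_n == 0` means
#' "decomposable with zero unattributed nucleotides under exact matching".
#'
#' @param junction Character vector of junction nucleotide sequences.
#' @param reference Germline reference tibble ([trd_reference()]).
#' @param j_call Optional TRDJ call(s) restricting the J segment (recycled
#'   to the length of `junction`); when `NULL` all four J heads compete.
#' @param min_d_match Minimum D match length in nucleotides (default 3;
#'   shorter matches are indistinguishable from chance).
#' @return A tibble, one row per junction, with columns `v_match_len`,
#'   `n1_len`, `d_segment` (`NA` when no D is called; the N block is then
#'   merged into `n1_len`), `d_start` (1-based start of the D block in the
#'   junction), `d_match_len`, `n2_len`, `j_match_len`, `j_segment`,
#'   `total_n` and `score`.  Block lengths always sum to the junction
#'   length.
#' @examples
#' decompose_junction("TGTGCCTGTGACACCCTGGGGGATACGGATAAACTCATCTTT")$total_n  # 0
#' @export
decompose_junction <- function(junction, reference = trd_reference(),
                               j_call = NULL, min_d_match = 3L) {
  if (length(junction) == 0L) stop("empty junction input", call. = FALSE)
  if (!is.null(j_call)) j_call <- rep_len(j_call, length(junction))
  v_tail <- reference$nt_sequence[reference$segment_class == "V"]
  dseg <- reference[reference$segment_class == "D", , drop = FALSE]
  dseg <- dseg[order(dseg$segment_id), , drop = FALSE]
  d_chars <- lapply(dseg$nt_sequence, .chars)
  jseg <- reference[reference$segment_class == "J", , drop = FALSE]
  j_heads <- setNames(
    substr(jseg$nt_sequence, 1L, jseg$junction_anchor_offset + 3L),
    jseg$segment_id)

  rows <- lapply(seq_along(junction), function(i) {
    jc_call <- if (is.null(j_call)) NA_character_ else j_call[i]
    .decompose_one(junction[i], v_tail, dseg$segment_id, d_chars,
                   j_heads, jc_call, min_d_match)
  })
  dplyr::bind_rows(rows)
}

.decompose_one <- function(junction, v_tail, d_ids, d_chars, j_heads,
                           jc_call, min_d_match) {
  L <- nchar(junction)
  jc <- .chars(junction)
  lcp <- .lcp(junction, v_tail)
  if (!is.na(jc_call)) {
    gene <- sub("\\*.*$", "", jc_call)
    j_heads <- j_heads[sub("\\*.*$", "", names(j_heads)) == gene]
    if (length(j_heads) == 0L) {
      stop(sprintf("unknown TRDJ segment identifier: %s", jc_call),
           call. = FALSE)
    }
  }

  best <- NULL
  for (jn in names(j_heads)) {
    lcs <- .lcs(junction, j_heads[[jn]])
    # no-D candidate: maximal anchored prefix and suffix (v first on ties)
    v0 <- min(lcp, L)
    j0 <- min(lcs, L - v0)
    cand <- list(score = v0 + j0, v = v0, j = j0, has_d = FALSE,
                 d_id = NA_character_, d_start = NA_integer_, d_len = 0L,
                 j_id = jn)
    best <- .better_decomp(best, cand)
    for (k in seq_along(d_ids)) {
      m <- .d_matches(jc, d_chars[[k]], min_d_match)
      if (is.null(m)) next
      for (h in seq_along(m$end)) {
        e <- m$end[h]; maxrun <- m$run[h]
        for (len in min_d_match:maxrun) {
          s <- e - len + 1L
          v <- min(lcp, s - 1L)
          j <- min(lcs, L - e)
          cand <- list(score = v + len + j, v = v, j = j, has_d = TRUE,
                       d_id = d_ids[k], d_start = s, d_len = len, j_id = jn)
          best <- .better_decomp(best, cand)
        }
      }
    }
  }

  if (best$has_d) {
    n1 <- best$d_start - 1L - best$v
    n2 <- L - (best$d_start + best$d_len - 1L) - best$j
  } else {
    n1 <- L - best$v - best$j
    n2 <- 0L
  }
  tibble::tibble(
    v_match_len = best$v, n1_len = n1, d_segment = best$d_id,
    d_start = best$d_start, d_match_len = best$d_len, n2_len = n2,
    j_match_len = best$j, j_segment = best$j_id,
    total_n = n1 + n2, score = best$score
  )
}

# tie-breaking order: score, v_match_len, j_match_len, D over no-D,
# lexicographically smallest d id, then earliest/longest D block for
# determinism
.better_decomp <- function(best, cand) {
  if (is.null(best)) return(cand)
  keys <- function(x) c(x$score, x$v, x$j, as.integer(x$has_d))
  a <- keys(cand); b <- keys(best)
  d <- a - b
  nz <- which(d != 0)
  if (length(nz) > 0L) return(if (d[nz[1L]] > 0) cand else best)
  if (cand$has_d) {
    if (!identical(cand$d_id, best$d_id)) {
      return(if (cand$d_id < best$d_id) cand else best)
    }
    if (cand$d_start != best$d_start) {
      return(if (cand$d_start < best$d_start) cand else best)
    }
    if (cand$d_len != best$d_len) {
      return(if (cand$d_len > best$d_len) cand else best)
    }
  }
  best
}

# ---------------------------------------------------------------------------

#' Annotate a repertoire with CDR3delta features
#'
#' Adds the derived feature columns to a validated repertoire: per-sample
#' clonotype frequency (percent of post-filter sample reads) and frequency
#' class, CDR3 length, position-5 residue and hydrophobicity, invariant-T
#' status, J region, N-insertion count and germline-encoded flag.
#' Decomposition results are memoised over unique junctions.  Nonproductive
#' records receive `NA` for the amino-acid-level features.
#'
#' @param repertoire A repertoire tibble ([read_repertoire()]), normally
#'   already singleton-filtered ([filter_singletons()]).
#' @param reference Germline reference tibble.
#' @param min_d_match Minimum D match length for the decomposition.
#' @param decompose Compute the junction decomposition (set `FALSE` to skip
#'   the N-insertion columns when only amino-acid features are needed).
#' @return The repertoire tibble with the added columns `frequency`
#'   (percent), `frequency_class`, `cdr3_length`, `aa5`, `is_haa5`,
#'   `inv_t`, `j_region`, and (when `decompose`) `n_insertions` and
#'   `germline_encoded`.
#' @export
annotate_repertoire <- function(repertoire, reference = trd_reference(),
                                min_d_match = 3L, decompose = TRUE) {
  .assert_columns(repertoire, c("sample_id", "junction", "junction_aa",
                                "j_call", "duplicate_count"), "repertoire")
  if (!"productive" %in% names(repertoire)) {
    repertoire$productive <- is_productive(repertoire$junction,
                                           repertoire$junction_aa)
  }
  out <- repertoire |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(frequency = 100 * .data$duplicate_count /
                    sum(.data$duplicate_count)) |>
    dplyr::ungroup()
  out$frequency_class <- classify_frequency(out$frequency)

  prod <- out$productive
  out$cdr3_length <- NA_integer_
  out$cdr3_length[prod] <- cdr3_length(out$junction_aa[prod])
  a5 <- extract_aa5(ifelse(prod, out$junction_aa, NA_character_))
  out$aa5 <- a5$aa5
  out$is_haa5 <- a5$is_haa5
  out$inv_t <- NA
  out$inv_t[prod] <- detect_inv_t(out$junction[prod], out$junction_aa[prod])
  out$j_region <- classify_j_region(ifelse(prod, out$junction_aa,
                                           NA_character_),
                                    reference, j_call = out$j_call)

  if (decompose) {
    key <- paste(out$junction, out$j_call, sep = "|")
    uniq <- !duplicated(key)
    dec <- decompose_junction(out$junction[uniq], reference,
                              j_call = out$j_call[uniq],
                              min_d_match = min_d_match)
    idx <- match(key, key[uniq])
    out$n_insertions <- dec$total_n[idx]
    out$germline_encoded <- out$n_insertions == 0L
  }
  out
}
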