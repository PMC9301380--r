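# Human TRD junction-proximal germline reference.
#
# Sequences are packaged as in-repo constants (curated *01 alleles,
# junction-proximal regions only; no network access, ever).  Coordinates are
# 0-based half-open; `junction_anchor_offset` points at the first nucleotide
# of the conserved anchor codon (Cys104 for V, Phe118 for J).
#
# For V segments the stored sequence starts at the Cys104 codon and runs to
# the 3' end of the V region, i.e. exactly the part of V that can appear in
# a junction.  For J segments it starts at the 5' end of the J region; the
# junction-relevant head ends at anchor + 3 (the full Phe118 codon), the
# remainder is FR4 context kept for FASTA audit output.

.trd_segment_table <- function() {
  tibble::tribble(
    ~segment_id, ~segment_class, ~nt_sequence,                                                  ~junction_anchor_offset,
    "TRDV2*01",  "V",            "TGTGCCTGTGACACC",                                             0L,
    "TRDD1*01",  "D",            "GAAATAGT",                                                    NA_integer_,
    "TRDD2*01",  "D",            "CCTTCCTAC",                                                   NA_integer_,
    "TRDD3*01",  "D",            "ACTGGGGGATACG",                                               NA_integer_,
    "TRDJ1*01",  "J",            "ACACCGATAAACTCATCTTTGGAAAAGGAACCCGTGTGACTGTGGAACCAA",         17L,
    "TRDJ2*01",  "J",            "TTGACTGCCCAGCTCTTCTTTGGAAAAGGGACCCAACTCATCGTGGAACCT",         18L,
    "TRDJ3*01",  "J",            "AGCTGGGACACCCGACAGATGTTCTTCGGAACAGGGATTGAATTGTTTGTGGAGCCT",   24L,
    "TRDJ4*01",  "J",            "CGCCCATCTTCTGACTTCTTTAAGAAAGGCACCCGAGTCACTGTGGAGCCC",         18L
  )
}

# translated junction-proximal region, in the junction reading frame:
# for V, from the anchor codon to the segment 3' end; for J, the codons that
# end flush with the anchor codon (frame (anchor + 3) mod 3).
.segment_junction_aa <- function(segment_class, nt_sequence, anchor) {
  if (segment_class == "V") {
    translate_dna(substr(nt_sequence, anchor + 1L, nchar(nt_sequence)))
  } else if (segment_class == "J") {
    frame <- (anchor + 3L) %% 3L
    translate_dna(substr(nt_sequence, frame + 1L, anchor + 3L))
  } else {
    NA_character_
  }
}

.reference_cache <- new.env(parent = emptyenv())

#' Load the packaged human TRD germline reference
#'
#' Returns the junction-proximal germline segments of the human TRD locus
#' used throughout the package: the 3' end of TRDV2 (from the conserved
#' Cys104 codon), the three diversity segments TRDD1-TRDD3, and the 5'
#' regions of TRDJ1-TRDJ4 (through the conserved Phe118 codon, plus FR4
#' context).  The reference ships as an in-repo constant; it is validated on
#' first load (alphabet, anchor codons, segment counts) and cached.
#'
#' @return A tibble with one row per segment and columns `segment_id`,
#'   `segment_class` (`"V"`, `"D"` or `"J"`), `nt_sequence`,
#'   `junction_anchor_offset` (0-based offset of the anchor codon; `NA` for
#'   D segments) and `aa_junction` (translated junction-proximal region in
#'   the junction reading frame; `NA` for D segments).
#' @examples
#' trd_reference()
#' @export
trd_reference <- function() {
  if (!is.null(.reference_cache$ref)) return(.reference_cache$ref)
  ref <- .trd_segment_table()
  ref$aa_junction <- vapply(
    seq_len(nrow(ref)),
    function(i) .segment_junction_aa(ref$segment_class[i], ref$nt_sequence[i],
                                     ref$junction_anchor_offset[i]),
    character(1)
  )
  .validate_reference(ref)
  .reference_cache$ref <- ref
  ref
}

.validate_reference <- function(ref) {
  for (i in seq_len(nrow(ref))) {
    id <- ref$segment_id[i]
    nt <- ref$nt_sequence[i]
    if (is.na(nt) || nchar(nt) == 0L || grepl("[^ACGT]", nt)) {
      stop(sprintf("corrupt germline reference: segment %s has an invalid nucleotide sequence", id),
           call. = FALSE)
    }
    cls <- ref$segment_class[i]
    anchor <- ref$junction_anchor_offset[i]
    if (cls %in% c("V", "J")) {
      codon <- substr(nt, anchor + 1L, anchor + 3L)
      aa <- translate_dna(codon)
      ok <- if (cls == "V") identical(aa, "C") else aa %in% c("F", "W")
      if (!ok) {
        stop(sprintf("corrupt germline reference: segment %s anchor codon translates to %s",
                     id, aa), call. = FALSE)
      }
    }
  }
  if (anyDuplicated(ref$segment_id)) {
    stop("corrupt germline reference: duplicated segment_id", call. = FALSE)
  }
  counts <- table(ref$segment_class)
  if (!identical(as.integer(counts[c("V", "D", "J")]), c(1L, 3L, 4L))) {
    stop("corrupt germline reference: expected 1 V, 3 D and 4 J segments", call. = FALSE)
  }
  invisible(ref)
}

#' Map a TRDJ segment call to its J region label
#'
#' Accepts IMGT-style identifiers with or without an allele suffix
#' (`"TRDJ1*01"` or `"TRDJ1"`).
#'
#' @param j_call Character vector of TRDJ identifiers.
#' @return Character vector over `{"J1","J2","J3","J4"}`.
#' @examples
#' j_region_of(c("TRDJ1*01", "TRDJ3"))
#' @export
j_region_of <- function(j_call) {
  gene <- sub("\\*.*$", "", j_call)
  known <- paste0("TRDJ", 1:4)
  bad <- !is.na(gene) & !(gene %in% known)
  if (any(bad)) {
    stop(sprintf("unknown TRDJ segment identifier(s): %s",
                 paste(unique(j_call[bad]), collapse = ", ")), call. = FALSE)
  }
  ifelse(is.na(gene), NA_character_, sub("TRD", "", gene))
}

#' Export or import the germline reference as FASTA
#'
#' FASTA round-tripping is provided for audit: the packaged canonical form
#' is the internal constant table, and `read_reference_fasta()` restores the
#' nucleotide sequences written by `write_reference_fasta()`.
#'
#' @param path File path.
#' @param reference A reference tibble as returned by [trd_reference()].
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` returns a tibble with columns `segment_id`
#'   and `nt_sequence`.
#' @export
write_reference_fasta <- function(path, reference = trd_reference()) {
  seqs <- Biostrings::DNAStringSet(setNames(reference$nt_sequence,
                                            reference$segment_id))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(segment_id = names(seqs),
                 nt_sequence = unname(as.character(seqs)))
}

#' Widely shared public CDR3delta amino-acid sequences
#'
#' Fourteen public Vdelta2 CDR3 junction amino-acid sequences recurrently
#' reported in healthy-donor TRD repertoire studies, shared by more than
#' half of typical adult cohorts.  They serve as the default public pool of
#' the repertoire simulator (seeded across donors through distinct
#' nucleotide routes, emulating convergent recombination) and as a worked
#' example for the feature annotation: all fourteen are short and carry a
#' hydrophobic residue at CDR3 position 5.
#'
#' @format Character vector of junction amino-acid sequences (anchors
#'   included: leading Cys104, trailing Phe/Trp118).
#' @examples
#' cdr3_length(public_cdr3delta)
#' @export
public_cdr3delta <- c(
  "CACDTLGDTDKLIF", "CACDTLLGDTDKLIF", "CACDVLGDTDKLIF", "CACDTLGVYTDKLIF",
  "CACDTVGDTDKLIF", "CACDTVGEYTDKLIF", "CACDTVGGYTDKLIF", "CACDILGDTDKLIF",
  "CACDPLGDTDKLIF", "CACDTAGGSSWDTRQMFF", "CACDTVGGTDKLIF", "CACDTVGTYTDKLIF",
  "CACDTWGTDKLIF", "CACDTWGYTDKLIF"
)
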