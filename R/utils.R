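#' Translate DNA strings in the junction reading frame
#'
#' Vectorised translation of in-frame DNA strings with the standard genetic
#' code. Trailing nucleotides that do not complete a codon are ignored; stop
#' codons translate to `"*"`. The first codon is never treated as an
#' initiation codon (a junction starts mid-protein, at Cys104).
#'
#' @param x Character vector of DNA strings over `{A,C,G,T}`.
#' @return Character vector of amino-acid strings (`NA` where input is `NA`
#'   or shorter than one codon).
#' @examples
#' translate_dna("TGTGCCTGTGACACC")
#' @export
translate_dna <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nchar(x) >= 3L
  if (any(ok)) {
    trimmed <- substr(x[ok], 1L, 3L * (nchar(x[ok]) %/% 3L))
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                            no.init.codon = TRUE)
    ))
    out[ok] <- aa
  }
  out
}

# split one string into a character vector
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# longest common prefix length of two strings
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- .chars(substr(a, 1L, n))
  cb <- .chars(substr(b, 1L, n))
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# longest common suffix length of two strings
.lcs <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- rev(.chars(substr(a, nchar(a) - n + 1L, nchar(a))))
  cb <- rev(.chars(substr(b, nchar(b) - n + 1L, nchar(b))))
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

.assert_columns <- function(x, cols, what = "table") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# run code under a seed without disturbing the caller's RNG stream
.with_preserved_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
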