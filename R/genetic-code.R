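# Genetic code: codons, synonymous families, translation.

#' Genetic code with synonymous codon families
#'
#' Wraps an NCBI translation table as a codon -> amino-acid map together
#' with the synonymous families it induces (stop codons, rendered `"*"`,
#' form a family of their own).  All amino-acid assignments used by the
#' other functions in this package flow through this object, so the code
#' is configurable even though the standard code (table 1) is the default
#' and the one relevant for bacterial, archaeal and fungal hosts alike.
#'
#' Alternative start codons are deliberately counted as their standard
#' amino acid, not as Met: codon counting concerns codon occurrences, not
#' translational starts.
#'
#' @param table_id NCBI genetic-code table identifier (default 1, the
#'   standard code).
#' @return An object of class `genetic_code` with components `table_id`,
#'   `codon_to_aa` (named character vector over the 64 DNA codons) and
#'   `families` (list mapping each amino-acid symbol, and `"*"`, to its
#'   sorted synonymous codon set).
#' @examples
#' code <- genetic_code()
#' code$families[["G"]]   # the four glycine codons
#' @export
genetic_code <- function(table_id = 1L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L)
  fams <- split(names(map), map)
  fams <- lapply(fams, sort)
  structure(
    list(table_id = as.integer(table_id), codon_to_aa = map, families = fams),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code (NCBI table %d): 64 codons, %d synonymous families\n",
              x$table_id, length(x$families)))
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

#' Normalize a DNA string
#'
#' Upper-cases and maps U to T; no other transformation.
#' @param dna character scalar.
#' @return normalized character scalar.
#' @keywords internal
normalize_dna <- function(dna) {
  chartr("U", "T", toupper(as.character(dna)))
}

# Split an in-frame DNA string into consecutive codons.
split_codons <- function(dna) {
  n <- nchar(dna)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(dna, starts, starts + 2L)
}

#' Translate an in-frame coding sequence
#'
#' @param seq a [coding_sequence()] or a DNA string (length divisible by
#'   3; upper/lower case and U accepted, normalized before validation).
#' @param code a [genetic_code()].
#' @return Amino-acid string, one symbol per codon, stop rendered `"*"`.
#' @examples
#' translate_cds("ATGGGTGGC")  # "MGG"
#' @export
translate_cds <- function(seq, code = genetic_code()) {
  dna <- if (inherits(seq, "coding_sequence")) seq$dna else normalize_dna(seq)
  if (nchar(dna) %% 3L != 0L)
    stop("sequence length ", nchar(dna), " is not divisible by 3", call. = FALSE)
  codons <- split_codons(dna)
  aa <- unname(code$codon_to_aa[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop(sprintf("invalid codon '%s' at codon %d (non-ACGT character)",
                 codons[bad], bad), call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Synonymous codons of a codon
#'
#' @param codon a single DNA codon.
#' @param code a [genetic_code()].
#' @return Character vector of all codons encoding the same amino acid
#'   (or stop), sorted; always contains the input codon.
#' @examples
#' synonymous_codons("GGA")  # the glycine family
#' @export
synonymous_codons <- function(codon, code = genetic_code()) {
  codon <- normalize_dna(codon)
  aa <- unname(code$codon_to_aa[codon])
  if (is.na(aa)) stop("invalid codon '", codon, "'", call. = FALSE)
  code$families[[aa]]
}
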