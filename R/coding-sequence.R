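# Validated in-frame coding sequences.

#' Construct a validated coding sequence
#'
#' Normalizes the DNA (upper case, U -> T), then requires a length
#' divisible by 3 and an A/C/G/T alphabet.  This is the unit handled by
#' the scoring and recoding functions; CDS collections used for table
#' building are read leniently instead (see [build_codon_counts()]).
#'
#' @param dna DNA string, in frame (start through stop).
#' @param label free-text identifier (FASTA header text).
#' @param source_file provenance, e.g. the file the record came from.
#' @return Object of class `coding_sequence` with fields `label`, `dna`,
#'   `source_file`.
#' @examples
#' g <- coding_sequence("atgggtTGA", label = "toy")
#' g$dna
#' @export
coding_sequence <- function(dna, label = "", source_file = NA_character_) {
  dna <- normalize_dna(dna)
  if (nchar(dna) == 0L)
    stop("empty sequence", if (nzchar(label)) paste0(" for '", label, "'"),
         call. = FALSE)
  if (nchar(dna) %% 3L != 0L)
    stop(sprintf("sequence '%s': length %d not divisible by 3",
                 label, nchar(dna)), call. = FALSE)
  bad <- regexpr("[^ACGT]", dna)
  if (bad > 0L)
    stop(sprintf("sequence '%s': non-ACGT character '%s' at codon %d",
                 label, substr(dna, bad, bad), (bad - 1L) %/% 3L + 1L),
         call. = FALSE)
  structure(list(label = as.character(label), dna = dna,
                 source_file = source_file),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  n <- nchar(x$dna)
  head <- if (n > 30L) paste0(substr(x$dna, 1L, 30L), "...") else x$dna
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons) %s\n",
              if (nzchar(x$label)) x$label else "(unnamed)", n, n %/% 3L, head))
  invisible(x)
}

as_coding_sequence <- function(x, label = "") {
  if (inherits(x, "coding_sequence")) x else coding_sequence(x, label = label)
}

# Codons of a coding sequence, in order.
codons_of <- function(seq) split_codons(as_coding_sequence(seq)$dna)
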