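# Restriction-motif avoidance on recoded sequences.

#' Forbidden-motif constraint
#'
#' A set of DNA motifs (typically restriction-enzyme recognition sites)
#' that must not occur in a designed sequence.  Restriction enzymes act
#' on double-stranded DNA, so by default the reverse complement of each
#' motif is forbidden too.
#'
#' @param motifs character vector of non-empty ACGT strings, e.g.
#'   `c("GAATTC", "CTCGAG")`.
#' @param scan_both_strands also forbid reverse complements (default
#'   `TRUE`).
#' @return Object of class `motif_constraint`.
#' @export
motif_constraint <- function(motifs, scan_both_strands = TRUE) {
  motifs <- normalize_dna(motifs)
  if (length(motifs) == 0L || any(!nzchar(motifs)))
    stop("motifs must be non-empty DNA strings", call. = FALSE)
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must contain only A/C/G/T: ",
         paste(grep("[^ACGT]", motifs, value = TRUE), collapse = ", "),
         call. = FALSE)
  structure(list(motifs = unique(motifs),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "motif_constraint")
}

# All motif patterns to scan on the given strand, reverse complements
# included when the constraint is double-stranded.
effective_motifs <- function(constraints) {
  pats <- constraints$motifs
  if (constraints$scan_both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(pats)))
    pats <- unique(c(pats, rc))
  }
  pats
}

# Occurrences of any forbidden motif in `dna`, including overlapping
# ones; data frame sorted by start position.
find_motif_hits <- function(dna, constraints) {
  subject <- Biostrings::DNAString(dna)
  hits <- lapply(effective_motifs(constraints), function(m) {
    v <- Biostrings::matchPattern(m, subject)
    if (length(v) == 0L) return(NULL)
    data.frame(start = Biostrings::start(v), end = Biostrings::end(v),
               motif = m, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), stringsAsFactors = FALSE))
  hits[order(hits$start, hits$end, hits$motif), , drop = FALSE]
}

#' Remove forbidden motifs from a recoding result
#'
#' Scans the recoded sequence (and its reverse complement for
#' double-stranded constraints) left to right.  For each motif
#' occurrence, the leftmost overlapping codon that still has an untried
#' synonymous alternative is switched to its next-closest-RCA codon
#' (then third-closest, and so on); a substitution is only accepted if
#' it strictly reduces the total number of motif occurrences, and the
#' sequence is re-scanned until clean.  The "closeness" target is the
#' same one the recoder used: the native-host RCA of the original codon
#' for harmonized results, RCA 1 for most-frequent results.  The
#' translation is never altered.
#'
#' [harmonize()] and [recode_most_frequent()] call this automatically
#' when given a `constraints` argument.
#'
#' @param result a `recoding_result`.
#' @param constraints a [motif_constraint()].
#' @param native native-host table (optional; the per-position trace
#'   already carries the native RCA targets).
#' @param expr expression-host usage table the result was recoded for.
#' @return The updated `recoding_result`; codon positions where an
#'   alternative codon had to be used are listed in
#'   `substitutions_for_motifs`.
#' @section Errors:
#' If some motif occurrence survives every synonymous alternative at
#' every overlapping codon (e.g. a motif forced through Met/Trp codons),
#' an error names the motif and its position.
#' @export
avoid_motifs <- function(result, constraints, native = NULL, expr) {
  stopifnot(inherits(result, "recoding_result"),
            inherits(constraints, "motif_constraint"),
            is_codon_usage_table(expr))
  code <- expr$code
  out_codons <- result$per_position$output_codon
  targets <- if (identical(result$method, "harmonized"))
    result$per_position$rca_native else rep(1, length(out_codons))

  rankings <- vector("list", length(out_codons))
  ranking_at <- function(i) {
    if (is.null(rankings[[i]])) {
      fam <- code$families[[code$codon_to_aa[[out_codons[i]]]]]
      rankings[[i]] <<- rank_candidates(fam, expr$rca, targets[i],
                                        prefer = out_codons[i])
    }
    rankings[[i]]
  }
  rank_used <- rep(NA_integer_, length(out_codons))

  n_hits <- function(codons) nrow(find_motif_hits(paste(codons,
                                                        collapse = ""),
                                                  constraints))
  substituted <- integer(0)
  repeat {
    hits <- find_motif_hits(paste(out_codons, collapse = ""), constraints)
    if (nrow(hits) == 0L) break
    hit <- hits[1L, ]
    codon_idx <- ((hit$start - 1L) %/% 3L + 1L):((hit$end - 1L) %/% 3L + 1L)
    current_total <- nrow(hits)
    fixed <- FALSE
    for (ci in codon_idx) {
      rk <- ranking_at(ci)
      if (is.na(rank_used[ci]))
        rank_used[ci] <- match(out_codons[ci], rk)
      ranks_left <- seq_along(rk)[-seq_len(rank_used[ci])]
      for (r in ranks_left) {
        trial <- out_codons
        trial[ci] <- rk[r]
        if (n_hits(trial) < current_total) {
          out_codons <- trial
          rank_used[ci] <- r
          substituted <- c(substituted, ci)
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed)
      stop(sprintf(paste0("motif '%s' at nucleotide %d cannot be removed: ",
                          "all synonymous alternatives at codons %s are ",
                          "exhausted"),
                   hit$motif, hit$start,
                   paste(codon_idx, collapse = "-")), call. = FALSE)
  }

  per_position <- result$per_position
  per_position$output_codon <- out_codons
  per_position$rca_expr_chosen <- unname(expr$rca[out_codons])
  if (identical(result$method, "harmonized"))
    per_position$abs_delta <- abs(per_position$rca_expr_chosen -
                                  per_position$rca_native)
  native_tab <- if (!is.null(native)) native else attr(result, "native_table")
  res <- new_recoding_result(result$method, result$input_seq, out_codons,
                             per_position, native = native_tab, expr = expr,
                             substitutions = sort(unique(substituted)))
  if (identical(result$method, "harmonized") && is.null(native_tab)) {
    # native table not re-supplied: keep the original chi_before and
    # recompute chi_after from the stored native RCA targets
    res$chi_before <- result$chi_before
    res$chi_after <- mean(abs(res$per_position$rca_expr_chosen -
                              res$per_position$rca_native))
    res$native_label <- result$native_label
  }
  res
}
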