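# Synonymous recoding: harmonization, most-frequent baseline.

# Candidate ranking for one input codon: all synonymous codons of the
# expression host ordered by |RCA_expr - target|, exact-distance ties
# broken toward `prefer` (the codon already in place, so that
# self-harmonization is the identity), then toward higher
# expression-host RCA, then alphabetically.  `target` is the
# native-host RCA of the input codon for harmonization, or 1 for the
# most-frequent baseline.  Greedy per-position choice is globally
# optimal for CHI because the index is a mean of independent
# per-position terms.
rank_candidates <- function(fam, expr_rca, target, prefer = NULL) {
  d <- abs(expr_rca[fam] - target)
  keep <- if (is.null(prefer)) rep(1L, length(fam)) else as.integer(fam != prefer)
  fam[order(d, keep, -expr_rca[fam], fam)]
}

new_recoding_result <- function(method, input_seq, output_codons,
                                per_position, native, expr,
                                substitutions = integer(0)) {
  output_seq <- coding_sequence(paste(output_codons, collapse = ""),
                                label = if (nzchar(input_seq$label))
                                  paste0(input_seq$label, "_", method)
                                else method)
  p_out <- profile(output_seq, expr)
  p_in  <- profile(input_seq, expr)
  if (!is.null(native)) {
    p_nat <- profile(input_seq, native)
    chi_before <- chi(p_in, p_nat)
    chi_after <- chi(p_out, p_nat)
  } else {
    chi_before <- chi_after <- NA_real_
  }
  cai_before <- suppressWarnings(cai(p_in))
  cai_after <- suppressWarnings(cai(p_out))
  structure(
    list(method = method,
         input_seq = input_seq, output_seq = output_seq,
         per_position = per_position,
         chi_before = chi_before, chi_after = chi_after,
         cai_before = cai_before, cai_after = cai_after,
         substitutions_for_motifs = substitutions,
         native_label = if (is.null(native)) NA_character_
                        else native$host_label,
         expr_label = expr$host_label),
    class = "recoding_result"
  )
}

#' @export
print.recoding_result <- function(x, ...) {
  cat(sprintf("<recoding_result> %s: %d codons\n", x$method,
              nrow(x$per_position)))
  cat(sprintf("  CHI %s -> %s | CAI %.3f -> %.3f\n",
              if (is.na(x$chi_before)) "NA" else sprintf("%.3f", x$chi_before),
              if (is.na(x$chi_after)) "NA" else sprintf("%.3f", x$chi_after),
              x$cai_before, x$cai_after))
  if (length(x$substitutions_for_motifs) > 0L)
    cat("  motif substitutions at codon(s): ",
        paste(x$substitutions_for_motifs, collapse = ", "), "\n", sep = "")
  n_sub <- sum(x$per_position$input_codon != x$per_position$output_codon)
  cat(sprintf("  %d/%d codons changed\n", n_sub, nrow(x$per_position)))
  invisible(x)
}

#' Harmonize a gene's codon usage for an expression host
#'
#' Recodes a wild-type gene so that its codon landscape in the
#' expression host mimics the wild-type landscape in the native host:
#' at every position the synonymous codon whose expression-host RCA is
#' closest to the native-host RCA of the original codon is selected.
#' Frequent native codons stay frequent and rare native codons stay
#' rare, preserving putative translational pause sites — the opposite
#' philosophy to most-frequent-codon optimization
#' ([recode_most_frequent()]).
#'
#' Exact-distance ties are broken toward keeping the input codon (so
#' recoding a gene for its own host is the identity), then toward the
#' higher expression-host RCA, then alphabetically, so output is
#' deterministic.  Because CHI is a mean of
#' independent per-position terms, this per-position rule is the exact
#' CHI minimizer over all synonymous variants.  If `constraints` are
#' given, a motif-removal pass ([avoid_motifs()]) follows.
#'
#' @param seq wild-type gene, a [coding_sequence()] or DNA string.
#' @param native usage table of the native host (RCA filled).
#' @param expr usage table of the expression host (RCA filled).
#' @param constraints optional [motif_constraint()]; forbidden motifs
#'   are removed from the output by next-closest-RCA substitutions.
#' @return A `recoding_result`: `output_seq`, a `per_position` trace
#'   (position, input/output codon, native RCA, chosen expression RCA,
#'   absolute difference), `chi_before`/`chi_after` (input vs output
#'   against the native wild-type profile), `cai_before`/`cai_after`
#'   (in the expression host), and motif-substitution positions.
#' @examples
#' native <- codon_table_from_counts(
#'   c(ATG = 5, GGT = 10, GGC = 4, GGA = 2, GGG = 1, TAA = 5))
#' expr <- codon_table_from_counts(
#'   c(ATG = 5, GGT = 6, GGC = 20, GGA = 12, GGG = 1, TAA = 5))
#' harmonize("ATGGGCTAA", native, expr)
#' @export
harmonize <- function(seq, native, expr, constraints = NULL) {
  stopifnot(is_codon_usage_table(native), is_codon_usage_table(expr))
  if (native$code$table_id != expr$code$table_id)
    stop("native and expression tables use different genetic codes",
         call. = FALSE)
  if (is.null(native$rca) || is.null(expr$rca))
    stop("both tables need RCA scores; run counts_to_rca() first",
         call. = FALSE)
  seq <- as_coding_sequence(seq)
  code <- expr$code
  in_codons <- codons_of(seq)

  # the chosen output codon depends only on the input codon, so build
  # the 64-entry map once
  uniq <- unique(in_codons)
  choice <- vapply(uniq, function(cd) {
    fam <- code$families[[code$codon_to_aa[[cd]]]]
    rank_candidates(fam, expr$rca, native$rca[[cd]], prefer = cd)[1L]
  }, character(1))
  out_codons <- unname(choice[in_codons])

  per_position <- data.frame(
    position = seq_along(in_codons),
    input_codon = in_codons,
    output_codon = out_codons,
    rca_native = unname(native$rca[in_codons]),
    rca_expr_chosen = unname(expr$rca[out_codons]),
    abs_delta = abs(unname(expr$rca[out_codons]) -
                    unname(native$rca[in_codons])),
    stringsAsFactors = FALSE
  )
  res <- new_recoding_result("harmonized", seq, out_codons, per_position,
                             native, expr)
  if (!is.null(constraints)) res <- avoid_motifs(res, constraints,
                                                 native = native, expr = expr)
  res
}

#' Most-frequent-codon recoding (optimization baseline)
#'
#' Replaces every codon by its family's most frequent codon in the
#' expression host (RCA = 1; ties alphabetical), so the recoded gene
#' has CAI exactly 1.  This is a deliberately transparent stand-in for
#' commercial codon-optimization software: those are proprietary
#' multi-parameter algorithms (GC content, mRNA structure, motif rules,
#' ...) and this baseline is NOT equivalent to any of them — it isolates
#' the "use only frequent codons" principle that they share.
#'
#' @inheritParams harmonize
#' @return A `recoding_result`; `chi_before`/`chi_after` are `NA` (no
#'   native table is involved) and `rca_native`/`abs_delta` columns of
#'   the trace are `NA`.
#' @export
recode_most_frequent <- function(seq, expr, constraints = NULL) {
  stopifnot(is_codon_usage_table(expr))
  if (is.null(expr$rca))
    stop("table needs RCA scores; run counts_to_rca() first", call. = FALSE)
  seq <- as_coding_sequence(seq)
  code <- expr$code
  in_codons <- codons_of(seq)
  uniq <- unique(in_codons)
  choice <- vapply(uniq, function(cd) {
    fam <- code$families[[code$codon_to_aa[[cd]]]]
    rank_candidates(fam, expr$rca, 1)[1L]
  }, character(1))
  out_codons <- unname(choice[in_codons])
  per_position <- data.frame(
    position = seq_along(in_codons),
    input_codon = in_codons,
    output_codon = out_codons,
    rca_native = NA_real_,
    rca_expr_chosen = unname(expr$rca[out_codons]),
    abs_delta = NA_real_,
    stringsAsFactors = FALSE
  )
  res <- new_recoding_result("most_frequent", seq, out_codons, per_position,
                             native = NULL, expr = expr)
  if (!is.null(constraints)) res <- avoid_motifs(res, constraints,
                                                 native = NULL, expr = expr)
  res
}
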