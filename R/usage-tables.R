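# Codon usage tables: counts, family maxima, relative codon adaptiveness.

new_codon_usage_table <- function(counts, host_label, n_cds, code,
                                  pseudo_rule = NA_character_) {
  all_codons <- sort(names(code$codon_to_aa))
  full <- stats::setNames(numeric(64L), all_codons)
  full[names(counts)] <- as.numeric(counts)
  if (any(full < 0) || any(full != floor(full)))
    stop("codon counts must be non-negative integers", call. = FALSE)
  structure(
    list(host_label = as.character(host_label),
         counts = full,
         family_max = NULL,
         fraction = NULL,
         rca = NULL,
         n_cds = as.integer(n_cds),
         n_codons = sum(full),
         pseudo_rule = pseudo_rule,
         code = code),
    class = "codon_usage_table"
  )
}

is_codon_usage_table <- function(x) inherits(x, "codon_usage_table")

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> host '%s': %d CDS, %.0f codons%s\n",
              x$host_label, x$n_cds, x$n_codons,
              if (is.null(x$rca)) " (counts only)"
              else sprintf(", RCA filled (pseudo_rule=%s)", x$pseudo_rule)))
  invisible(x)
}

#' Count codons over a CDS collection
#'
#' Tallies every codon of reading frame 1 of every record, the convention
#' used to build whole-genome usage tables ("all codons of all
#' protein-coding genes").  CDS files are assumed pre-extracted; no ORF
#' re-detection is attempted, and internal stop codons are simply counted
#' as stops so that annotation artifacts cannot abort a genome-scale run.
#'
#' In lenient mode (default) a trailing partial codon is dropped and
#' codons containing non-ACGT characters are skipped, both with a
#' warning.  In strict mode either condition rejects the offending
#' record with an error naming it.
#'
#' @param cds_records character vector or list of DNA strings /
#'   `coding_sequence` objects; names (or labels) are used in messages.
#' @param code a [genetic_code()].
#' @param strict reject instead of repair malformed records.
#' @return A `codon_usage_table` with counts only (no RCA yet); see
#'   [counts_to_rca()].
#' @examples
#' tab <- build_codon_counts(c(gene1 = "ATGGGTGGTTAA", gene2 = "ATGGGCTAA"))
#' tab$counts[c("ATG", "GGT", "GGC", "TAA")]
#' @export
build_codon_counts <- function(cds_records, code = genetic_code(),
                               strict = FALSE) {
  if (length(cds_records) == 0L)
    stop("no CDS records supplied", call. = FALSE)
  labs <- names(cds_records)
  seqs <- vapply(seq_along(cds_records), function(i) {
    r <- cds_records[[i]]
    if (inherits(r, "coding_sequence")) r$dna else normalize_dna(r)
  }, character(1))
  if (is.null(labs))
    labs <- vapply(seq_along(cds_records), function(i) {
      r <- cds_records[[i]]
      if (inherits(r, "coding_sequence") && nzchar(r$label)) r$label
      else sprintf("record %d", i)
    }, character(1))

  partial <- nchar(seqs) %% 3L != 0L
  if (any(partial)) {
    if (strict)
      stop("strict mode: length of '", labs[which(partial)[1L]],
           "' is not divisible by 3", call. = FALSE)
    warning(sum(partial), " record(s) with a trailing partial codon; ",
            "partial codon dropped (e.g. '", labs[which(partial)[1L]], "')",
            call. = FALSE)
    seqs[partial] <- substr(seqs[partial], 1L,
                            (nchar(seqs[partial]) %/% 3L) * 3L)
  }

  all_codons <- unlist(lapply(seqs, split_codons), use.names = FALSE)
  valid <- all_codons %in% names(code$codon_to_aa)
  if (!all(valid)) {
    if (strict) {
      per_rec <- vapply(seqs, function(s)
        any(!split_codons(s) %in% names(code$codon_to_aa)), logical(1))
      stop("strict mode: non-ACGT codon in record '",
           labs[which(per_rec)[1L]], "'", call. = FALSE)
    }
    warning(sum(!valid), " codon(s) with non-ACGT characters skipped",
            call. = FALSE)
    all_codons <- all_codons[valid]
  }
  if (length(all_codons) == 0L)
    stop("no countable codons in input", call. = FALSE)

  counts <- table(factor(all_codons, levels = sort(names(code$codon_to_aa))))
  new_codon_usage_table(counts, host_label = "", n_cds = length(seqs),
                        code = code)
}

#' Fill relative codon adaptiveness (RCA) scores into a table
#'
#' For codon j of amino acid i with count \eqn{X_{ij}} and family maximum
#' \eqn{X_{i\max}}, \eqn{RCA = X_{ij} / X_{i\max}}.  Every family with at
#' least one observation therefore contains a codon with RCA exactly 1.
#'
#' Unobserved codons score 0 under `pseudo_rule = "zero"` (the plain
#' ratio) or \eqn{0.5 / X_{i\max}} under `"sharp_half"`, the classic
#' pseudo-count that keeps a geometric mean from collapsing to zero.  A
#' family never observed at all gets uniform RCA 1 with a warning.
#'
#' @param table a `codon_usage_table` with counts populated.
#' @param pseudo_rule `"zero"` (default) or `"sharp_half"`.
#' @return The table with `rca`, `fraction` (share within family) and
#'   `family_max` filled.
#' @examples
#' tab <- build_codon_counts(c("ATGGGTGGTGGATAA"))
#' tab <- counts_to_rca(tab)
#' tab$rca[c("GGT", "GGA", "GGG")]
#' @export
counts_to_rca <- function(table, pseudo_rule = c("zero", "sharp_half")) {
  stopifnot(is_codon_usage_table(table))
  pseudo_rule <- match.arg(pseudo_rule)
  code <- table$code
  counts <- table$counts
  rca <- fraction <- stats::setNames(numeric(length(counts)), names(counts))
  fam_max <- stats::setNames(numeric(length(code$families)),
                             names(code$families))
  empty_fams <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    cts <- counts[fam]
    m <- max(cts)
    fam_max[aa] <- m
    if (m == 0) {
      empty_fams <- c(empty_fams, aa)
      rca[fam] <- 1
      fraction[fam] <- 0
      next
    }
    r <- cts / m
    if (pseudo_rule == "sharp_half") r[cts == 0] <- 0.5 / m
    rca[fam] <- r
    fraction[fam] <- cts / sum(cts)
  }
  if (length(empty_fams) > 0L)
    warning("family/families never observed, RCA set uniform 1: ",
            paste(empty_fams, collapse = ", "), call. = FALSE)
  table$rca <- rca
  table$fraction <- fraction
  table$family_max <- fam_max
  table$pseudo_rule <- pseudo_rule
  table
}

#' Merge two codon usage tables
#'
#' Adds counts element-wise (e.g. a genome assembly split over several
#' CDS files) and recomputes RCA under the first table's pseudo rule.
#'
#' @param a,b `codon_usage_table` objects built over the same genetic
#'   code.  A `host_label` mismatch only warns.
#' @return Merged `codon_usage_table`.
#' @export
merge_tables <- function(a, b) {
  stopifnot(is_codon_usage_table(a), is_codon_usage_table(b))
  if (a$code$table_id != b$code$table_id)
    stop("tables use different genetic codes (", a$code$table_id, " vs ",
         b$code$table_id, ")", call. = FALSE)
  if (nzchar(a$host_label) && nzchar(b$host_label) &&
      !identical(a$host_label, b$host_label))
    warning("merging tables with different host labels: '", a$host_label,
            "' and '", b$host_label, "'", call. = FALSE)
  out <- new_codon_usage_table(a$counts + b$counts,
                               host_label = a$host_label,
                               n_cds = a$n_cds + b$n_cds,
                               code = a$code)
  rule <- if (!is.na(a$pseudo_rule)) a$pseudo_rule
          else if (!is.na(b$pseudo_rule)) b$pseudo_rule else NA_character_
  if (!is.na(rule)) out <- counts_to_rca(out, rule)
  out
}

#' Build a codon usage table directly from codon counts
#'
#' Convenience constructor for small worked examples and custom tables:
#' any codon not named gets count 0, then RCA is filled.
#'
#' @param counts named numeric vector, names are DNA codons.
#' @param host_label free-text host name recorded in the table.
#' @param code a [genetic_code()].
#' @param pseudo_rule passed to [counts_to_rca()].
#' @param n_cds number of CDS the counts came from, if known.
#' @return A `codon_usage_table` with RCA filled.
#' @examples
#' gly <- codon_table_from_counts(c(GGT = 10, GGC = 4, GGA = 2, GGG = 1))
#' gly$rca[c("GGT", "GGC", "GGA", "GGG")]
#' @export
codon_table_from_counts <- function(counts, host_label = "custom",
                                    code = genetic_code(),
                                    pseudo_rule = "zero", n_cds = 0L) {
  nm <- normalize_dna(names(counts))
  if (is.null(nm) || !all(nm %in% names(code$codon_to_aa)))
    stop("counts must be named by valid DNA codons", call. = FALSE)
  names(counts) <- nm
  tab <- new_codon_usage_table(counts, host_label = host_label,
                               n_cds = n_cds, code = code)
  suppressWarnings(counts_to_rca(tab, pseudo_rule))
}

#' Build a usage table from a CDS FASTA file
#'
#' Reads the multi-FASTA of all annotated CDS of a genome and produces
#' the host's codon usage table with RCA scores, i.e. the combination of
#' [read_cds_fasta()], [build_codon_counts()] and [counts_to_rca()].
#'
#' @param path FASTA file (gzip accepted).
#' @param host_label host name stored in the table (defaults to the file
#'   name).
#' @inheritParams build_codon_counts
#' @inheritParams counts_to_rca
#' @return A `codon_usage_table` with RCA filled.
#' @export
build_codon_table <- function(path, host_label = basename(path),
                              code = genetic_code(), strict = FALSE,
                              pseudo_rule = c("zero", "sharp_half")) {
  recs <- read_fasta(path)
  tab <- build_codon_counts(recs, code = code, strict = strict)
  tab$host_label <- host_label
  counts_to_rca(tab, match.arg(pseudo_rule))
}
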