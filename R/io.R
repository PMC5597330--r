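# FASTA and TSV readers/writers.

#' Read a (multi-)FASTA file
#'
#' Record order is preserved, multi-line sequences are joined, case is
#' normalized and U is mapped to T.  Duplicate headers give a warning.
#' Use this raw form for table building; [read_cds_fasta()] additionally
#' validates each record as an in-frame CDS.
#'
#' @param path FASTA file (gzip accepted).
#' @return Named character vector of DNA strings, names are the full
#'   header lines (without `>`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("no FASTA records in '", path, "'", call. = FALSE)
  seqs <- normalize_dna(as.character(set))
  names(seqs) <- names(set)
  dup <- duplicated(names(seqs))
  if (any(dup))
    warning("duplicate FASTA header(s) in '", path, "': ",
            paste(unique(names(seqs)[dup]), collapse = ", "), call. = FALSE)
  seqs
}

#' Read a FASTA file as validated coding sequences
#'
#' @inheritParams read_fasta
#' @return List of [coding_sequence()] objects, order preserved.
#' @export
read_cds_fasta <- function(path) {
  seqs <- read_fasta(path)
  lapply(seq_along(seqs), function(i)
    coding_sequence(seqs[[i]], label = names(seqs)[i], source_file = path))
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of DNA strings, or a list of
#'   [coding_sequence()] objects (a single one is accepted too).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "coding_sequence")) records <- list(records)
  if (is.list(records)) {
    nms <- vapply(records, function(r)
      if (inherits(r, "coding_sequence")) r$label else "", character(1))
    records <- stats::setNames(vapply(records, function(r)
      if (inherits(r, "coding_sequence")) r$dna else normalize_dna(r),
      character(1)), nms)
  }
  set <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

codon_table_columns <- c("codon", "amino_acid", "count",
                         "fraction_in_family", "rca")

#' Write a codon usage table as TSV
#'
#' One row per codon, `codon  amino_acid  count  fraction_in_family
#' rca`, preceded by `#` header lines carrying host label, record and
#' codon totals, pseudo rule and genetic-code id.  Numeric columns are
#' written with 17 significant digits so [read_codon_table()]
#' round-trips losslessly, and rows are codon-sorted so identical tables
#' serialize to identical bytes.
#'
#' @param table a `codon_usage_table` with RCA filled (see
#'   [counts_to_rca()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_table <- function(table, path) {
  stopifnot(is_codon_usage_table(table))
  if (is.null(table$rca))
    stop("table has no RCA scores yet; run counts_to_rca() first",
         call. = FALSE)
  codons <- sort(names(table$counts))
  aa <- unname(table$code$codon_to_aa[codons])
  header <- c(
    sprintf("# host_label=%s", table$host_label),
    sprintf("# n_cds=%d", table$n_cds),
    sprintf("# n_codons=%.0f", table$n_codons),
    sprintf("# pseudo_rule=%s", table$pseudo_rule),
    sprintf("# code_table_id=%d", table$code$table_id),
    paste0("# ", paste(codon_table_columns, collapse = "\t"))
  )
  rows <- sprintf("%s\t%s\t%.0f\t%.17g\t%.17g",
                  codons, aa, table$counts[codons],
                  table$fraction[codons], table$rca[codons])
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a codon usage table from TSV
#'
#' Inverse of [write_codon_table()]; the header metadata (host label,
#' totals, pseudo rule, genetic-code id) is restored.
#'
#' @param path TSV file in the dialect written by [write_codon_table()].
#' @return A `codon_usage_table` with RCA filled.
#' @export
read_codon_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)=(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L)
    stop("no data rows in codon table '", path, "'", call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_seen <- unique(lengths(fields))
  if (!identical(ncol_seen, 5L))
    stop("codon table '", path, "': expected 5 columns (",
         paste(codon_table_columns, collapse = ", "), "), found ",
         paste(ncol_seen, collapse = "/"), call. = FALSE)
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- codon_table_columns
  code <- genetic_code(as.integer(meta[["code_table_id"]] %||% 1L))
  if (anyDuplicated(df$codon))
    stop("codon table '", path, "': duplicate codon row '",
         df$codon[duplicated(df$codon)][1L], "'", call. = FALSE)
  missing <- setdiff(names(code$codon_to_aa), df$codon)
  if (length(missing) > 0L)
    stop("codon table '", path, "': missing codon row(s): ",
         paste(utils::head(missing, 3L), collapse = ", "),
         if (length(missing) > 3L) ", ...", call. = FALSE)
  counts <- stats::setNames(as.numeric(df$count), df$codon)
  if (anyNA(counts))
    stop("codon table '", path, "': non-numeric value in column 'count'",
         call. = FALSE)
  tab <- new_codon_usage_table(counts,
                               host_label = meta[["host_label"]] %||% "",
                               n_cds = as.integer(meta[["n_cds"]] %||% 0L),
                               code = code)
  rca <- stats::setNames(as.numeric(df$rca), df$codon)
  fraction <- stats::setNames(as.numeric(df$fraction_in_family), df$codon)
  if (anyNA(rca))
    stop("codon table '", path, "': non-numeric value in column 'rca'",
         call. = FALSE)
  ord <- names(tab$counts)
  tab$rca <- rca[ord]
  tab$fraction <- fraction[ord]
  tab$family_max <- vapply(code$families, function(fam)
    max(tab$counts[fam]), numeric(1))
  tab$pseudo_rule <- meta[["pseudo_rule"]] %||% NA_character_
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recoding or metrics report as TSV
#'
#' For a `recoding_result`, writes the per-position trace (position,
#' input codon, output codon, native RCA, chosen expression-host RCA,
#' absolute difference) with `#` summary lines for CHI and CAI before
#' and after recoding.  For a plain data frame (e.g. a metrics or
#' landscape table), writes it as TSV with a header row.
#'
#' @param result a `recoding_result` or a data frame.
#' @param path output file.
#' @param stamp add a timestamp comment line (off by default so reruns
#'   are byte-identical).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, stamp = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (stamp) writeLines(sprintf("# written %s", format(Sys.time())), con)
  if (inherits(result, "recoding_result")) {
    writeLines(c(
      sprintf("# method=%s", result$method),
      sprintf("# gene=%s", result$input_seq$label),
      sprintf("# chi_before=%s\tchi_after=%s",
              format(result$chi_before, digits = 10),
              format(result$chi_after, digits = 10)),
      sprintf("# cai_before=%s\tcai_after=%s",
              format(result$cai_before, digits = 10),
              format(result$cai_after, digits = 10)),
      sprintf("# motif_substitutions=%s",
              if (length(result$substitutions_for_motifs) == 0L) "none"
              else paste(result$substitutions_for_motifs, collapse = ","))
    ), con)
    utils::write.table(result$per_position, con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(result)) {
    utils::write.table(result, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    stop("don't know how to report an object of class ",
         paste(class(result), collapse = "/"), call. = FALSE)
  }
  invisible(path)
}
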