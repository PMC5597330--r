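# Gene-level codon usage metrics: RCA profiles, CAI, CHI, landscapes.

#' Per-codon RCA profile of a gene
#'
#' Looks up the relative codon adaptiveness of each codon of a gene in a
#' host's usage table, yielding the ordered RCA series that CAI and CHI
#' are computed from.
#'
#' By default every codon is scored, including the stop codon and
#' single-codon families (Met, Trp under the standard code), because
#' both indices run over "the number of codons in the gene" with no
#' stated exclusion.  Classic CAI practice drops Met/Trp, so both flags
#' are provided; CHI requires the two profiles being compared to use the
#' same flags.
#'
#' @param seq a [coding_sequence()] or DNA string.
#' @param table a `codon_usage_table` with RCA filled.
#' @param include_stop score the stop-family codons.
#' @param include_single_codon_aa score codons from single-codon
#'   families.
#' @return Object of class `gene_profile`: `gene_label`, `rca_series`,
#'   `n`, `positions` (1-based codon indices kept), `codons`, `aa`, and
#'   the two flags.
#' @examples
#' tab <- codon_table_from_counts(c(ATG = 5, GGT = 4, GGC = 1, TAA = 5))
#' profile("ATGGGT", tab)$rca_series
#' @export
profile <- function(seq, table, include_stop = TRUE,
                    include_single_codon_aa = TRUE) {
  stopifnot(is_codon_usage_table(table))
  if (is.null(table$rca))
    stop("table has no RCA scores; run counts_to_rca() first", call. = FALSE)
  seq <- as_coding_sequence(seq)
  codons <- codons_of(seq)
  aa <- unname(table$code$codon_to_aa[codons])
  keep <- rep(TRUE, length(codons))
  if (!include_stop) keep <- keep & aa != "*"
  if (!include_single_codon_aa) {
    fam_size <- lengths(table$code$families)[aa]
    keep <- keep & fam_size > 1L
  }
  if (!any(keep))
    stop("no codons left to score after applying the flags", call. = FALSE)
  structure(
    list(gene_label = seq$label,
         rca_series = unname(table$rca[codons[keep]]),
         n = sum(keep),
         positions = which(keep),
         codons = codons[keep],
         aa = aa[keep],
         include_stop = include_stop,
         include_single_codon_aa = include_single_codon_aa),
    class = "gene_profile"
  )
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("<gene_profile> %s: n=%d codons, mean RCA %.3f\n",
              if (nzchar(x$gene_label)) x$gene_label else "(unnamed)",
              x$n, mean(x$rca_series)))
  invisible(x)
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of a profile's RCA series,
#' \eqn{CAI = (\prod_i RCA_i)^{1/N}}, computed as the exponential of the
#' mean log for numerical stability.  A value near 1 means the gene uses
#' mostly the host's preferred codons.  Any zero entry (possible under
#' `pseudo_rule = "zero"` for a codon the host never uses) makes the
#' index exactly 0, with a warning suggesting the `sharp_half` rule.
#'
#' @param p a [profile()] (`gene_profile`).
#' @return CAI in \[0, 1\].
#' @examples
#' tab <- codon_table_from_counts(c(GGT = 4, GGC = 1))
#' cai(profile("GGTGGC", tab))  # sqrt(0.25) = 0.5
#' @export
cai <- function(p) {
  stopifnot(inherits(p, "gene_profile"))
  if (p$n < 1L) stop("empty profile", call. = FALSE)
  if (any(p$rca_series == 0)) {
    warning("profile contains RCA = 0 entries; CAI is 0 ",
            "(consider pseudo_rule = \"sharp_half\")", call. = FALSE)
    return(0)
  }
  exp(mean(log(p$rca_series)))
}

#' Codon harmonization index (CHI)
#'
#' Mean absolute per-position RCA difference between a gene variant
#' scored in the expression host and the wild-type gene scored in its
#' native host: \eqn{CHI = \frac{1}{N}\sum_i |RCA_i - RCA_{i,native}|}.
#' A value near 0 means the variant's codon landscape in the expression
#' host closely mimics the native landscape; the harmonization recoder
#' ([harmonize()]) minimizes this quantity.
#'
#' Both profiles must cover synonymous sequences of the same protein and
#' be built with identical flags, so their positions pair up.
#'
#' @param p_expr profile of the variant in the expression host.
#' @param p_native profile of the wild-type gene in the native host.
#' @return CHI in \[0, 1\].
#' @export
chi <- function(p_expr, p_native) {
  stopifnot(inherits(p_expr, "gene_profile"),
            inherits(p_native, "gene_profile"))
  if (p_expr$n != p_native$n)
    stop("profile lengths differ: n=", p_expr$n, " vs n=", p_native$n,
         call. = FALSE)
  if (!identical(p_expr$aa, p_native$aa)) {
    d <- which(p_expr$aa != p_native$aa)[1L]
    stop(sprintf(paste0("profiles are not synonymous: residue %d differs ",
                        "('%s' vs '%s')"),
                 d, p_expr$aa[d], p_native$aa[d]), call. = FALSE)
  }
  mean(abs(p_expr$rca_series - p_native$rca_series))
}

#' Codon landscape with sliding-window average
#'
#' The per-position RCA series of a gene in one host together with a
#' centered moving average (default window 5 codons), the standard way
#' to visualize where a gene places its frequent and rare codons.  Near
#' the gene ends the window truncates symmetrically to the available
#' codons, so the smoothed line spans the full gene.
#'
#' @inheritParams profile
#' @param window odd window length in codons.
#' @return Object of class `landscape_profile`: a data frame with
#'   columns `position` (1-based codon index), `codon`, `amino_acid`,
#'   `rca`, `moving_avg`, plus attributes `gene_label`, `host_label`,
#'   `window`.
#' @examples
#' tab <- codon_table_from_counts(c(ATG = 2, GGT = 4, GGC = 1, TAA = 1))
#' landscape("ATGGGTGGCTAA", tab, window = 3)
#' @export
landscape <- function(seq, table, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1, got ", window, call. = FALSE)
  p <- profile(seq, table, include_stop = TRUE,
               include_single_codon_aa = TRUE)
  n <- p$n
  half <- (window - 1L) %/% 2L
  mov <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    mean(p$rca_series[(i - k):(i + k)])
  }, numeric(1))
  out <- data.frame(position = seq_len(n),
                    codon = p$codons,
                    amino_acid = p$aa,
                    rca = p$rca_series,
                    moving_avg = mov,
                    stringsAsFactors = FALSE)
  structure(out, gene_label = p$gene_label, host_label = table$host_label,
            window = window,
            class = c("landscape_profile", "data.frame"))
}

#' Plot a codon landscape
#'
#' Per-codon RCA bars with the moving-average line, the conventional
#' codon-landscape figure.
#'
#' @param x a [landscape()] result.
#' @param main plot title; defaults to gene and host labels.
#' @param col bar color.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.landscape_profile <- function(x, main = NULL, col = "darkseagreen3",
                                   ...) {
  if (is.null(main))
    main <- sprintf("%s in %s", attr(x, "gene_label"), attr(x, "host_label"))
  mid <- graphics::barplot(x$rca, border = NA, col = col, ylim = c(0, 1),
                           xlab = "codon position", ylab = "RCA",
                           main = main, ...)
  graphics::lines(mid, x$moving_avg, lwd = 2)
  graphics::axis(1, at = mid[c(1L, nrow(x))],
                 labels = c(1L, nrow(x)))
  invisible(x)
}
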