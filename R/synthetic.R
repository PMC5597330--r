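# Seeded synthetic hosts and genes for testing without genome downloads.

# Run `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a host genome's CDS collection and usage table
#'
#' Generates a synthetic host with controllable codon-usage bias: each
#' synonymous family (stop family included, so stop-handling code paths
#' are exercised) gets codon probabilities proportional to
#' \eqn{\exp(skew \cdot u)} with \eqn{u \sim U(0,1)} drawn per codon.
#' `skew = 0` gives exactly uniform within-family usage (all RCA tend
#' to 1 as counts grow); large `skew` concentrates each family on one
#' dominant codon, emulating a strongly biased genome.  Amino-acid
#' composition is uniform over the 20 amino acids.
#'
#' CDS records start with ATG, end with a stop drawn from the skewed
#' stop-family probabilities, and have Poisson-distributed interior
#' length.  The returned table is rebuilt from the emitted CDS, so its
#' counts are exactly self-consistent with the FASTA the simulator can
#' write.
#'
#' @param seed integer seed; the only source of randomness.
#' @param skew non-negative usage-bias concentration (default 2).
#' @param n_cds number of CDS records (default 200).
#' @param mean_len_codons mean CDS length in codons, start and stop
#'   included (default 300).
#' @param code a [genetic_code()].
#' @param host_label host name stored in the table.
#' @param pseudo_rule passed to [counts_to_rca()].
#' @return Object of class `synthetic_host`: `table` (a
#'   `codon_usage_table`), `cds` (named character vector of CDS), and
#'   `probs` (the generating per-family codon probabilities, for
#'   parameter-recovery checks).
#' @examples
#' host <- simulate_host(seed = 7, skew = 2, n_cds = 20,
#'                       mean_len_codons = 60)
#' host$table
#' @export
simulate_host <- function(seed, skew = 2, n_cds = 200L,
                          mean_len_codons = 300L, code = genetic_code(),
                          host_label = sprintf("synthetic_host_%d", seed),
                          pseudo_rule = c("zero", "sharp_half")) {
  stopifnot(skew >= 0, n_cds >= 1L, mean_len_codons >= 3L)
  pseudo_rule <- match.arg(pseudo_rule)
  with_seed(seed, {
    probs <- lapply(code$families, function(fam) {
      w <- exp(skew * stats::runif(length(fam)))
      stats::setNames(w / sum(w), fam)
    })
    aa_pool <- setdiff(names(code$families), "*")
    n_interior <- pmax(1L, stats::rpois(n_cds, mean_len_codons - 2L))
    aas <- sample(aa_pool, sum(n_interior), replace = TRUE)
    codons <- character(length(aas))
    for (aa in aa_pool) {
      idx <- which(aas == aa)
      if (length(idx) == 0L) next
      fam <- code$families[[aa]]
      codons[idx] <- sample(fam, length(idx), replace = TRUE,
                            prob = probs[[aa]])
    }
    stop_fam <- code$families[["*"]]
    stops <- sample(stop_fam, n_cds, replace = TRUE, prob = probs[["*"]])
    grp <- rep.int(seq_len(n_cds), n_interior)
    interiors <- vapply(split(codons, grp), paste, character(1),
                        collapse = "")
    cds <- stats::setNames(paste0("ATG", interiors, stops),
                           sprintf("cds_%04d", seq_len(n_cds)))
    tab <- suppressWarnings(build_codon_counts(cds, code = code))
    tab$host_label <- host_label
    tab <- suppressWarnings(counts_to_rca(tab, pseudo_rule))
    structure(list(table = tab, cds = cds, probs = probs,
                   spec = list(seed = as.integer(seed), skew = skew,
                               n_cds = as.integer(n_cds),
                               mean_len_codons = as.integer(mean_len_codons))),
              class = "synthetic_host")
  })
}

#' @export
print.synthetic_host <- function(x, ...) {
  cat(sprintf("<synthetic_host> seed=%d skew=%g: %d CDS, %.0f codons\n",
              x$spec$seed, x$spec$skew, x$spec$n_cds, x$table$n_codons))
  invisible(x)
}

#' Simulate a gene with a host's codon usage
#'
#' Samples a coding sequence whose codons follow the host's overall
#' usage: interior codons are drawn proportional to the table's counts
#' over the non-stop codons, the first codon is ATG and the last is a
#' stop drawn proportional to the stop-family counts.  Such a gene is a
#' "wild-type" gene of the host: its RCA landscape fluctuates around the
#' host's typical codon adaptiveness.
#'
#' @param native_table `codon_usage_table` with RCA filled.
#' @param length_codons total gene length in codons (start and stop
#'   included), at least 3.
#' @param seed integer seed.
#' @param gene_label label for the resulting sequence.
#' @return A [coding_sequence()] of `length_codons` codons.
#' @export
simulate_gene <- function(native_table, length_codons, seed,
                          gene_label = sprintf("synthetic_gene_%d", seed)) {
  stopifnot(is_codon_usage_table(native_table), length_codons >= 3L)
  code <- native_table$code
  counts <- native_table$counts
  stop_fam <- code$families[["*"]]
  body_codons <- setdiff(names(counts), stop_fam)
  body_w <- counts[body_codons]
  if (sum(body_w) == 0) body_w[] <- 1
  stop_w <- counts[stop_fam]
  if (sum(stop_w) == 0) stop_w[] <- 1
  with_seed(seed, {
    interior <- sample(body_codons, length_codons - 2L, replace = TRUE,
                       prob = body_w)
    stop_codon <- sample(stop_fam, 1L, prob = stop_w)
    coding_sequence(paste(c("ATG", interior, stop_codon), collapse = ""),
                    label = gene_label)
  })
}
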