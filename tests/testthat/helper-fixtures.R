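# Shared fixtures: toy tables with hand-set RCA values, random synthetic
# host pairs, and a brute-force CHI minimizer used as the independent
# oracle for the harmonization recoder.

std_code <- genetic_code()

# Toy glycine tables: native RCA {GGT 1.0, GGC 0.4, GGA 0.2, GGG 0.1},
# expression RCA {GGT 0.3, GGC 1.0, GGA 0.6, GGG 0.05}; ATG/TAA rows so
# whole toy genes validate.
toy_native_table <- function() {
  codon_table_from_counts(
    c(ATG = 5, GGT = 10, GGC = 4, GGA = 2, GGG = 1, TAA = 5))
}
toy_expr_table <- function() {
  codon_table_from_counts(
    c(ATG = 5, GGT = 6, GGC = 20, GGA = 12, GGG = 1, TAA = 5))
}

# Small random host via the package's own generator (cheap: ~800 codons).
small_host <- function(seed, skew = NULL) {
  if (is.null(skew)) skew <- withr::with_seed(seed, stats::runif(1, 0.5, 3))
  simulate_host(seed, skew = skew, n_cds = 20L, mean_len_codons = 40L)
}

# Random valid CDS of `len` codons (start + random non-stop + stop),
# capped so full synonymous enumeration stays tractable.
random_small_cds <- function(seed, len, max_variants = 3e4) {
  code <- std_code
  non_stop <- setdiff(names(code$codon_to_aa),
                      code$families[["*"]])
  withr::with_seed(seed, {
    repeat {
      body <- sample(non_stop, len - 2L, replace = TRUE)
      stop_codon <- sample(code$families[["*"]], 1L)
      codons <- c("ATG", body, stop_codon)
      fam_sizes <- lengths(code$families)[
        unname(code$codon_to_aa[codons])]
      if (prod(fam_sizes) <= max_variants) break
    }
    coding_sequence(paste(codons, collapse = ""),
                    label = sprintf("rand_%d", seed))
  })
}

# Independent oracle: enumerate EVERY synonymous variant of `seq` and
# return the minimum achievable CHI against the native profile of the
# input.  Pure enumeration; shares no code with harmonize().
brute_force_min_chi <- function(seq, native, expr, code = std_code) {
  codons <- strsplit(seq$dna, "")[[1]]
  codons <- apply(matrix(codons, nrow = 3L), 2L, paste, collapse = "")
  fams <- lapply(codons, function(cd)
    code$families[[code$codon_to_aa[[cd]]]])
  grid <- expand.grid(fams, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  targets <- unname(native$rca[codons])
  diffs <- vapply(seq_along(codons), function(i)
    abs(unname(expr$rca[grid[[i]]]) - targets[i]),
    numeric(nrow(grid)))
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1L)
  min(rowMeans(diffs))
}
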