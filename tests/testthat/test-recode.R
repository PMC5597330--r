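test_that("harmonization picks the closest expression-host RCA per position", {
  native <- toy_native_table()
  expr <- toy_expr_table()
  # input GGC: native RCA 0.4; candidate |deltas| in E-host:
  # GGT 0.1, GGA 0.2, GGC 0.6, GGG 0.35 -> GGT wins
  res <- harmonize("ATGGGCTAA", native, expr)
  row <- res$per_position[2, ]
  expect_identical(row$output_codon, "GGT")
  expect_equal(row$rca_native, 0.4)
  expect_equal(row$rca_expr_chosen, 0.3)
  expect_equal(row$abs_delta, 0.1)
})

test_that("self-harmonization is the identity and has CHI 0", {
  for (seed in 1:5) {
    host <- small_host(seed + 200)
    g <- simulate_gene(host$table, 50L, seed = seed)
    res <- harmonize(g, host$table, host$table)
    expect_identical(res$output_seq$dna, g$dna)
    expect_identical(res$chi_after, 0)
  }
})

test_that("greedy harmonization attains the brute-force minimum CHI", {
  # desk-scale slice of the exhaustive oracle (the full 200-gene sweep
  # runs in the acceptance suite)
  n_checked <- 0L
  for (pair in 1:5) {
    a <- small_host(pair + 300)
    b <- small_host(pair + 400)
    for (k in 1:4) {
      len <- 3L + ((pair + k) %% 6L)  # 3..8 codons
      g <- random_small_cds(seed = pair * 100 + k, len = len)
      res <- harmonize(g, a$table, b$table)
      expect_equal(res$chi_after,
                   brute_force_min_chi(g, a$table, b$table),
                   tolerance = 1e-12)
      expect_lte(res$chi_after, res$chi_before)
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(n_checked, 20L)
})

test_that("harmonized choices are idempotent fixed points of the selection rule", {
  for (seed in 1:3) {
    a <- small_host(seed + 500)
    b <- small_host(seed + 600)
    g <- simulate_gene(a$table, 40L, seed = seed)
    res <- harmonize(g, a$table, b$table)
    # re-apply the per-position rule to the output, against the same
    # native wild-type targets: nothing may move
    code <- b$table$code
    again <- vapply(seq_len(nrow(res$per_position)), function(i) {
      out <- res$per_position$output_codon[i]
      fam <- code$families[[code$codon_to_aa[[out]]]]
      codonharmony:::rank_candidates(fam, b$table$rca,
                                     res$per_position$rca_native[i],
                                     prefer = out)[1L]
    }, character(1))
    expect_identical(again, res$per_position$output_codon)
    # and rerunning the whole recoder is deterministic
    expect_identical(harmonize(g, a$table, b$table)$output_seq$dna,
                     res$output_seq$dna)
  }
})

test_that("most-frequent recoding yields CAI exactly 1 and beats no variant on CHI", {
  expr <- toy_expr_table()
  expr_gly_max <- codon_table_from_counts(
    c(ATG = 1, GGT = 9, GGC = 3, TAA = 1))
  expect_identical(
    recode_most_frequent("ATGGGCTAA", expr_gly_max)$per_position$output_codon[2],
    "GGT")
  for (seed in 1:5) {
    a <- small_host(seed + 700)
    b <- small_host(seed + 800)
    g <- simulate_gene(a$table, 40L, seed = seed)
    opt <- recode_most_frequent(g, b$table)
    expect_identical(opt$cai_after, 1)
    harm <- harmonize(g, a$table, b$table)
    p_nat <- profile(g, a$table)
    expect_lte(harm$chi_after,
               chi(profile(opt$output_seq, b$table), p_nat) + 1e-12)
    expect_lte(harm$chi_after, chi(profile(g, b$table), p_nat) + 1e-12)
  }
})

test_that("motif avoidance removes sites via next-closest codons only", {
  tab <- codon_table_from_counts(
    c(ATG = 1, GAA = 2, GAG = 1, TTC = 2, TTT = 1, TAA = 1))
  g <- coding_sequence("ATGGAATTCTAA", "ecoRI_toy")
  clean <- harmonize(g, tab, tab, constraints = motif_constraint("GAATTC"))
  expect_false(grepl("GAATTC", clean$output_seq$dna, fixed = TRUE))
  expect_identical(translate_cds(clean$output_seq), "MEF*")
  expect_length(clean$substitutions_for_motifs, 1L)
  expect_gt(clean$chi_after, 0)  # the price of the constraint

  # no motif present: result untouched
  same <- harmonize(g, tab, tab, constraints = motif_constraint("CCCGGG"))
  expect_identical(same$output_seq$dna, g$dna)
  expect_length(same$substitutions_for_motifs, 0L)

  # motif forced through single-codon families is unavoidable
  tab2 <- codon_table_from_counts(c(ATG = 1, TGG = 1, TAA = 1))
  expect_error(
    harmonize("ATGTGGTAA", tab2, tab2,
              constraints = motif_constraint("ATGTGG",
                                             scan_both_strands = FALSE)),
    "cannot be removed")
})

test_that("double-stranded scanning catches reverse-complement sites", {
  tab <- codon_table_from_counts(
    c(ATG = 1, CAC = 2, CAT = 1, GTC = 2, GTT = 1, TAA = 1))
  g <- coding_sequence("ATGCACGTCTAA", "rc_toy")  # contains CACGTC
  # AflIII-like site GACGTG only present as reverse complement
  both <- harmonize(g, tab, tab,
                    constraints = motif_constraint("GACGTG"))
  expect_false(grepl("CACGTC", both$output_seq$dna, fixed = TRUE))
  expect_identical(translate_cds(both$output_seq), translate_cds(g))
  given <- harmonize(g, tab, tab,
                     constraints = motif_constraint(
                       "GACGTG", scan_both_strands = FALSE))
  expect_identical(given$output_seq$dna, g$dna)
})

test_that("the motif pass preserves translation and clears sites on random genes", {
  constraints <- motif_constraint(c("GAATTC", "GGATCC", "CTCGAG"))
  n_ok <- 0L
  for (seed in 1:10) {
    a <- small_host(seed + 900)
    b <- small_host(seed + 950)
    g <- simulate_gene(a$table, 120L, seed = seed)
    res <- tryCatch(harmonize(g, a$table, b$table, constraints = constraints),
                    error = function(e) NULL)
    if (is.null(res)) next  # genuinely unavoidable layout
    for (m in codonharmony:::effective_motifs(constraints))
      expect_false(grepl(m, res$output_seq$dna, fixed = TRUE))
    expect_identical(translate_cds(res$output_seq), translate_cds(g))
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 8L)
})
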