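test_that("profiles look up per-codon RCA and honor the exclusion flags", {
  tab <- codon_table_from_counts(c(ATG = 5, GGT = 5, TAA = 1))
  p <- profile("ATGGGT", tab)
  expect_equal(p$rca_series, c(1.0, 1.0))
  expect_identical(p$n, 2L)
  p2 <- profile("ATGGGT", tab, include_single_codon_aa = FALSE)
  expect_equal(p2$rca_series, 1.0)
  expect_identical(p2$n, 1L)
  expect_identical(p2$codons, "GGT")
  p3 <- profile("ATGGGTTAA", tab, include_stop = FALSE)
  expect_identical(p3$codons, c("ATG", "GGT"))

  # 9-codon toy gene vs independent per-codon lookup
  host <- small_host(11)
  g <- simulate_gene(host$table, 9L, seed = 2)
  codons <- substring(g$dna, seq(1, 25, 3), seq(3, 27, 3))
  expect_equal(profile(g, host$table)$rca_series,
               unname(host$table$rca[codons]))
  expect_identical(profile(g, host$table)$n, 9L)
})

test_that("CAI is the geometric mean of the RCA series", {
  tab <- codon_table_from_counts(c(GGT = 4, GGC = 4, GGA = 4))
  expect_equal(cai(profile("GGTGGCGGA", tab)), 1.0)
  tab2 <- codon_table_from_counts(c(GGT = 4, GGC = 1))
  expect_equal(cai(profile("GGTGGC", tab2)), 0.5)  # sqrt(0.25)
  # a zero entry collapses the index to exactly 0, with advice
  tab3 <- codon_table_from_counts(c(GGT = 4, GGC = 0))
  expect_warning(v <- cai(profile("GGTGGC", tab3)), "sharp_half")
  expect_identical(v, 0)
})

test_that("CHI is the mean absolute per-position RCA difference", {
  native <- codon_table_from_counts(c(GGT = 10, GGC = 10, GGA = 10))
  expr <- codon_table_from_counts(c(GGT = 8, GGC = 10, GGA = 6))
  g <- "GGTGGCGGA"  # per-position |diffs| 0.2, 0.0, 0.4
  expect_equal(chi(profile(g, expr), profile(g, native)), 0.2)
  p <- profile(g, native)
  expect_identical(chi(p, p), 0)

  expect_error(chi(profile("GGTGGC", expr), p), "n=2 vs n=3")
  expect_error(chi(profile("GGTAAA", codon_table_from_counts(
    c(GGT = 1, AAA = 1, GGC = 1))), profile("GGTGGC", expr)),
    "residue 2")
})

test_that("CHI behaves as a scaled L1 metric on random profiles", {
  hosts <- lapply(c(21, 22, 23), small_host)
  for (seed in 1:10) {
    g <- simulate_gene(hosts[[1]]$table, 50L, seed = seed)
    ps <- lapply(hosts, function(h) profile(g, h$table))
    expect_identical(chi(ps[[1]], ps[[1]]), 0)
    expect_equal(chi(ps[[1]], ps[[2]]), chi(ps[[2]], ps[[1]]))
    expect_lte(chi(ps[[1]], ps[[3]]),
               chi(ps[[1]], ps[[2]]) + chi(ps[[2]], ps[[3]]) + 1e-12)
  }
})

test_that("CAI hits 1 exactly iff every scored codon is the family maximum", {
  for (seed in 1:5) {
    host <- small_host(seed + 40)
    g <- simulate_gene(host$table, 40L, seed = seed)
    p <- profile(g, host$table)
    v <- suppressWarnings(cai(p))
    if (all(p$rca_series == 1)) expect_identical(v, 1) else expect_lt(v, 1)
    opt <- recode_most_frequent(g, host$table)
    expect_equal(cai(profile(opt$output_seq, host$table)), 1.0)
  }
})

test_that("landscape smoothing is a centered, symmetrically truncated mean", {
  tab <- codon_table_from_counts(c(GGT = 7, GGC = 10))
  const <- landscape(strrep("GGT", 10), tab, window = 5)
  expect_equal(const$moving_avg, rep(0.7, 10))
  expect_equal(const$position, 1:10)

  zig_tab <- codon_table_from_counts(c(GGT = 10, GGC = 0))
  zig <- landscape("GGTGGCGGTGGCGGT", zig_tab, window = 5)
  expect_equal(zig$rca, c(1, 0, 1, 0, 1))
  expect_equal(zig$moving_avg[3], 0.6)      # mean of all 5 values
  expect_equal(zig$moving_avg, c(1, 2 / 3, 0.6, 2 / 3, 1))

  short <- landscape("GGTGGCGGT", zig_tab, window = 5)  # 3 codons, w = 5
  expect_equal(short$moving_avg, c(1, 2 / 3, 1))
  expect_error(landscape("GGTGGC", zig_tab, window = 4), "odd")
  # every smoothed value stays within its window's range
  host <- small_host(31)
  g <- simulate_gene(host$table, 80L, seed = 5)
  lsc <- landscape(g, host$table)
  for (i in seq_len(nrow(lsc))) {
    k <- min(2L, i - 1L, nrow(lsc) - i)
    win <- lsc$rca[(i - k):(i + k)]
    expect_gte(lsc$moving_avg[i], min(win))
    expect_lte(lsc$moving_avg[i], max(win))
  }
})

test_that("a small CHI bounds how far mean landscape height can drift", {
  for (seed in 1:8) {
    a <- small_host(seed + 60)
    b <- small_host(seed + 80)
    g <- simulate_gene(a$table, 60L, seed = seed)
    pa <- profile(g, a$table)
    pb <- profile(g, b$table)
    expect_lte(abs(mean(pa$rca_series) - mean(pb$rca_series)),
               chi(pa, pb) + 1e-12)
  }
})
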