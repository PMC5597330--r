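---
title: "Codon harmonization: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon harmonization: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonharmony)
```

## The model

Every host genome induces a codon usage table: the count $X_{ij}$ of
codon $j$ of amino acid $i$ over all codons of all annotated
protein-coding genes. Within each synonymous family the counts are
rescaled by the family maximum into the *relative codon adaptiveness*

$$RCA_{ij} = X_{ij} / X_{i\max},$$

so the host's preferred codon of each family scores exactly 1 and rarer
codons score proportionally lower. Note the reference set: the whole
genome, not a curated list of highly expressed genes as in the classic
codon-adaptation literature. This makes tables reproducible from a
single CDS FASTA and needs no expression data, at the price of a
flatter notion of "preferred".

A gene read against a table yields an RCA series, one value per codon —
its *codon landscape*. Two scalar summaries are used:

* $CAI = (\prod_{i=1}^{N} RCA_i)^{1/N}$, the geometric mean; near 1
  when the gene uses mostly preferred codons of the scoring host.
* $CHI = \frac{1}{N}\sum_{i=1}^{N} |RCA_i - RCA_{i,native}|$, the mean
  absolute per-position difference between a variant's series in the
  expression host and the wild-type gene's series in the native host;
  near 0 when the landscape is faithfully mimicked. In practice a
  variant below 0.1 is well harmonized.

Harmonization is positional: for input codon $c_i$ with native RCA
$r_i$, the recoder picks, within the synonymous family, the codon whose
expression-host RCA is closest to $r_i$. Because CHI is a mean of
independent per-position terms, this greedy choice is the *exact*
global CHI minimizer over all synonymous variants — the test suite
verifies this against full enumeration of every synonymous variant of
hundreds of short random genes. The assumption doing the work is
biological, not numerical: that the native frequency of a codon (as a
proxy for local translation speed) is the feature worth transplanting.

## Tie-breaking

When two synonymous codons are equally close to the native target, the
recoder keeps the input codon if it is among the tied set, then prefers
the higher expression-host RCA, then alphabetical order. The first rule
is what makes recoding a gene *for its own host* the identity (families
with tied counts are common in real tables, so without it
self-harmonization would permute tied codons); the others make output
deterministic. Among equally close codons the less rare one is the
safer default.

## Parameters that matter

* **`pseudo_rule`** (`counts_to_rca()`): what an unobserved codon
  scores. `"zero"` (default) is the plain ratio; it can zero out CAI
  for any gene using that codon. `"sharp_half"` assigns
  $0.5/X_{i\max}$, the classic pseudo-count that keeps geometric means
  finite. The rule is recorded in the table TSV header, so a table file
  is self-describing.
* **`include_stop`, `include_single_codon_aa`** (`profile()`): both
  default `TRUE` — the printed formulas run over "the number of codons
  in the gene" with no stated exclusion, and stop codons are counted as
  a three-member family in the tables. Classic CAI drops Met/Trp
  (their RCA is identically 1 and only dilutes the index), so both
  conventions are one flag away; CHI requires the two profiles being
  compared to use identical flags.
* **`window`** (`landscape()`): moving-average window in codons,
  default 5, odd. Near the ends the window truncates symmetrically to
  the available codons rather than padding, so the smoothed line spans
  the full gene.
* **`skew`** (`simulate_host()`): per-family usage-bias concentration;
  0 is exactly uniform usage, values of 2–3 give tables that look like
  moderately biased microbial genomes, large values collapse each
  family onto one dominant codon.

## Motif avoidance

Restriction sites needed for cloning must not appear in the designed
sequence. The pass scans the recoded gene (both strands by default —
restriction enzymes cut double-stranded DNA; disable with
`scan_both_strands = FALSE`) and, at each surviving occurrence,
substitutes at the *leftmost* overlapping codon that still has an
untried synonymous alternative its next-closest-RCA codon, then the
third-closest, and so on; a substitution is accepted only if it
strictly reduces the total occurrence count, and the sequence is
re-scanned until clean. Leftmost-first is a documented convention of
this package, not a claim about any other tool; since each accepted
substitution strictly decreases the occurrence count, the pass always
terminates, and it errors — naming the motif and position — when a site
is unavoidable (e.g. forced through Met/Trp codons). Translation is
never altered; the CHI cost of the detour is visible in
`chi_after` and the affected positions in `substitutions_for_motifs`.

## The most-frequent baseline

`recode_most_frequent()` replaces every codon by its family's RCA-1
codon, giving CAI exactly 1. It stands in for commercial
codon-optimization only in the one respect all such algorithms share —
preferring frequent host codons. Real optimizers are proprietary
multi-parameter procedures (GC targets, mRNA structure, repeat and
motif rules); this baseline is **not** equivalent to any of them and is
labelled accordingly wherever it appears.

## What the synthetic generator does and does not establish

`simulate_host()` draws, per synonymous family (stop family included,
so stop-handling paths are exercised), codon probabilities proportional
to $e^{s\,u}$ with $u \sim U(0,1)$ and $s$ the skew; CDS records start
with ATG, end with a sampled stop, have Poisson-distributed length
(default mean 300 codons, a typical microbial CDS; default 200 CDS
keeps tables in the $10^4$–$10^5$-codon range where sampling error is
visible but small), and uniform amino-acid composition. The returned
table is rebuilt from the emitted CDS, so counts are self-consistent by
construction.

This emulates exactly the statistical structure the algorithms consume:
per-family codon frequencies and genes drawn from them. It does *not*
emulate amino-acid composition bias, GC gradients along genes,
expression-level-dependent codon bias, introns/UTRs, or correlated
codon pairs. A green test therefore establishes algorithmic
correctness (counting, RCA algebra, optimality, synonymity,
round-trips) — not that harmonization improves expression of any real
protein, which is an experimental question.

Reproducing published per-gene CHI/CAI values for real proteins
requires the original hosts' genome CDS sets; those are genome-scale
downloads whose assembly/annotation versions were never pinned, so
third-decimal agreement is assembly-dependent. The machinery (table
builder, flag sweep over the stop/Met/Trp conventions) is in place and
the corresponding acceptance test runs whenever the files are supplied
under `tests/testthat/ref_data/`; offline it fails visibly rather than
passing vacuously.

## Numerical choices and degenerate inputs

* CAI is computed as $\exp(\text{mean}(\log RCA_i))$; a zero entry
  short-circuits to exactly 0 with a warning pointing at
  `sharp_half`.
* A family never observed in a genome gets uniform RCA 1 with a
  warning (it carries no preference information).
* Table building counts reading frame 1 of each record as given — CDS
  files are assumed pre-extracted, no ORF re-detection; internal stops
  are counted as stops rather than aborting a genome-scale run. In
  lenient mode trailing partial codons are dropped and ambiguous codons
  skipped (warned); `strict = TRUE` rejects the record by name.
* Sequences are upper-cased and U-mapped to T before validation;
  positions are reported 1-based in codons.
* Table TSVs are written codon-sorted with 17 significant digits:
  reruns are byte-identical and read–write round-trips are lossless.

## Limitations

Single-objective design: no GC-content targeting, no 5'UTR mRNA
structure minimization, no repeat/Shine-Dalgarno avoidance — the
harmonized sequence optimizes landscape mimicry only, subject to the
motif constraints. CHI weighs all positions equally; it has no notion
of *where* along the gene a mismatch matters. And the whole-genome RCA
reference treats every annotated CDS equally, so hosts with strong
expression-level codon bias are summarized more coarsely than a
highly-expressed-gene reference would.
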