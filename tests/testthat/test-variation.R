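pile_row <- function(A = 0, C = 0, G = 0, T = 0, genome = "g", pos = 1L) {
  data.frame(genome_id = genome, pos = pos, A = A, C = C, G = G, T = T,
             stringsAsFactors = FALSE)
}

test_that("the six SNP criteria follow the stated inequalities", {
  out <- call_snps(pile_row(A = 8, C = 2))
  expect_true(out$crit_i); expect_true(out$crit_ii)
  expect_true(out$crit_iii)            # 20% > 10%
  expect_false(out$crit_iv)            # 20% is not > 20%
  expect_true(out$crit_v); expect_true(out$crit_vi)

  out <- call_snps(pile_row(A = 9, C = 1))
  expect_true(out$crit_i)
  expect_false(out$crit_ii)
  expect_false(out$crit_iii)           # 10% is not > 10%
  expect_false(out$crit_iv); expect_false(out$crit_v); expect_false(out$crit_vi)

  out <- call_snps(pile_row(A = 4))
  expect_false(out$evaluable)          # below the 5x floor
  expect_true(is.na(out$crit_i))
})

test_that("second allele ties break in fixed base order", {
  out <- call_snps(pile_row(A = 5, C = 2, G = 2, T = 1))
  expect_equal(out$second_allele, "C")  # A < C < G < T
})

test_that("criterion implication lattice holds on random columns", {
  set.seed(71)
  n <- 2000
  cols <- data.frame(genome_id = "g", pos = seq_len(n),
                     A = rpois(n, 8), C = rpois(n, 1),
                     G = rpois(n, 0.3), T = rpois(n, 0.1))
  calls <- call_snps(cols)
  ev <- calls[calls$evaluable, ]
  expect_true(all(!ev$crit_vi | (ev$crit_ii & ev$crit_iii)))
  expect_true(all(!ev$crit_ii | ev$crit_i))
  expect_true(all(!ev$crit_iii | ev$crit_i))
  expect_true(all(!ev$crit_iv | ev$crit_iii))
  expect_equal(ev$crit_v, ev$crit_ii | ev$crit_iii)
  r <- snp_rate(calls)
  expect_true(r$rate_i >= r$rate_ii)
  expect_true(r$rate_i >= r$rate_iii)
  expect_true(r$rate_iii >= r$rate_iv)
  expect_true(r$rate_v >= r$rate_vi)
})

test_that("nucleotide diversity matches its closed form and oracle", {
  # monomorphic column
  expect_equal(nucleotide_diversity(pile_row(A = 10))$pi_percent, 0)
  # balanced biallelic column: (10/9) * (1 - 0.5) = 50/90 pairwise
  pi1 <- nucleotide_diversity(pile_row(A = 5, C = 5))$pi_percent
  expect_equal(pi1, 100 * (10 / 9) * 0.5)
  # genome value is the mean over evaluable sites, in percent
  two <- rbind(pile_row(A = 5, C = 5, pos = 1L), pile_row(A = 10, pos = 2L))
  expect_equal(nucleotide_diversity(two)$pi_percent,
               100 * ((10 / 9) * 0.5) / 2)

  # brute-force all-pairs mismatch oracle on random columns
  set.seed(72)
  for (i in 1:50) {
    counts <- c(A = sample(0:12, 1), C = sample(0:12, 1),
                G = sample(0:4, 1), T = sample(0:4, 1))
    if (sum(counts) < 5 || sum(counts) > 30) next
    reads <- rep(names(counts), counts)
    pairs <- combn(length(reads), 2)
    oracle <- mean(reads[pairs[1, ]] != reads[pairs[2, ]])
    got <- nucleotide_diversity(pile_row(A = counts["A"], C = counts["C"],
                                         G = counts["G"], T = counts["T"]))
    expect_equal(got$pi_percent, 100 * oracle, tolerance = 1e-12)
  }
})

test_that("snp_rate reports percent of evaluable sites", {
  calls <- call_snps(rbind(
    pile_row(A = 8, C = 2, pos = 1L),    # positive under i,ii,iii
    pile_row(A = 10, pos = 2L),
    pile_row(A = 9, C = 1, pos = 3L),
    pile_row(A = 3, pos = 4L)))          # not evaluable
  r <- snp_rate(calls)
  expect_equal(r$evaluable_sites, 3)
  expect_equal(r$rate_i, 100 * 2 / 3)
  expect_equal(r$rate_iii, 100 * 1 / 3)
})

test_that("pileups keep only high-quality bases", {
  aln <- data.frame(
    id = c("r1", "r2"), genome_id = "g",
    qstart = 1L, qend = 4L, sstart = 11L, send = 14L, strand = "+",
    identity = 1,
    seq = c("ACGT", "ACGT"),
    qual = c(qual_of(rep(40L, 4)), qual_of(c(40L, 10L, 40L, 30L))),
    stringsAsFactors = FALSE)
  p <- build_pileup(aln, q_threshold = 30L)
  expect_equal(p$pos, 11:14)
  expect_equal(p$A, c(2L, 0L, 0L, 0L))
  expect_equal(p$C, c(0L, 1L, 0L, 0L))   # r2 base at pos 12 is Q10
  expect_equal(p$T[4], 1L)               # r2 base at pos 14 is Q30, excluded
})

test_that("minus-strand alignments are complemented into the pileup", {
  aln <- data.frame(
    id = "r1", genome_id = "g", qstart = 1L, qend = 4L,
    sstart = 14L, send = 11L, strand = "-", identity = 1,
    seq = "ACGT", qual = qual_of(rep(40L, 4)), stringsAsFactors = FALSE)
  p <- build_pileup(aln)
  # read ACGT maps to positions 14,13,12,11 with complements TGCA
  expect_equal(p$pos, 11:14)
  expect_equal(p$A[p$pos == 11], 1L)
  expect_equal(p$T[p$pos == 14], 1L)
})

test_that("planted polymorphism is recovered through mapping and pileup", {
  g <- random_coding_genome(4000, seed = 73)
  pos <- 2000L
  ref <- substr(g[[1]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snps <- data.frame(genome_id = "g1", pos = pos, alt = alt, freq = 0.2,
                     stringsAsFactors = FALSE)
  sim <- read_sim_spec(read_length = 100, insert_mean = 250, insert_sd = 20,
                       coverage = 100, per_base_error = 0, seed = 74,
                       quality_mean = 40, quality_decay = 0, quality_sd = 0)
  rd <- simulate_reads(g, sim, snps = snps)
  aln <- map_reads(rd$pairs, g)
  pile <- build_pileup(aln)
  col <- pile[pile$pos == pos, ]
  cov <- col$A + col$C + col$G + col$T
  minor <- col[[alt]]
  expect_gt(cov, 30)
  ci <- qbinom(c(0.005, 0.995), cov, 0.2)
  expect_gte(minor, ci[1])
  expect_lte(minor, ci[2])
  # diversity at the planted site is positive, elsewhere mostly zero
  div <- nucleotide_diversity(pile)
  expect_gt(div$pi_percent, 0)
})
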