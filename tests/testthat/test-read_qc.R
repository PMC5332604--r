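test_that("deduplication keeps one representative of identical pairs", {
  p <- make_pairs(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC", "TTTTACGTAC"),
                  c("GGGGACGTAC", "GGGGACGTAC", "GGGGACGTAC", "GGGGACGTAC"))
  out <- deduplicate(p)
  expect_equal(nrow(out), 2)
  expect_equal(out$id, c("p1", "p4"))  # order-stable, first kept

  # duplicate in the forward mate only: both retained
  p2 <- make_pairs(c("ACGTACGTAC", "ACGTACGTAC"),
                   c("GGGGACGTAC", "CCCCACGTAC"))
  expect_equal(nrow(deduplicate(p2)), 2)

  empty <- make_pairs(character(0), character(0))
  expect_equal(nrow(deduplicate(empty)), 0)
})

test_that("pairs merge at the best overlap with the arithmetic length", {
  set.seed(31)
  frag <- random_dna(270)
  f <- substr(frag, 1, 150)
  r <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag, 121, 270))))
  out <- merge_pairs(make_pairs(f, r), min_overlap = 10)
  expect_equal(nrow(out$merged), 1)
  expect_equal(nchar(out$merged$seq), 270)  # 150 + 150 - 30
  expect_equal(out$merged$seq, frag)
  expect_equal(nrow(out$pairs), 0)
})

test_that("non-overlapping pairs are returned unmerged", {
  set.seed(32)
  out <- merge_pairs(make_pairs(random_dna(80), random_dna(80)),
                     min_overlap = 20)
  expect_equal(nrow(out$merged), 0)
  expect_equal(nrow(out$pairs), 1)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  set.seed(33)
  frag <- random_dna(100)
  f <- substr(frag, 1, 60)
  r_fwd <- substr(frag, 41, 100)  # 20 bp overlap
  # disagreeing base at overlap position 5 (frag position 45)
  truthbase <- substr(f, 45, 45)
  wrong <- setdiff(c("A", "C", "G", "T"), truthbase)[1]
  substr(r_fwd, 5, 5) <- wrong
  r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r_fwd)))
  p <- make_pairs(f, r, q = 40)
  # reverse mate quality low at the disagreeing position (position 5 of
  # the oriented mate = position 56 of the stored reverse read)
  q2 <- rep(10L, 60)
  p$qual2 <- qual_of(q2)
  out <- merge_pairs(p, min_overlap = 10, max_mismatch_density = 0.25)
  expect_equal(nrow(out$merged), 1)
  expect_equal(substr(out$merged$seq, 45, 45), truthbase)
})

test_that("quality filter applies the strict 80% boundary and demotes mates", {
  q79 <- qual_of(c(rep(40L, 79), rep(30L, 21)))  # 79% strictly above Q30
  q80 <- qual_of(c(rep(40L, 80), rep(30L, 20)))
  reads <- data.frame(id = c("a", "b"),
                      seq = c(random_dna(100), random_dna(100)),
                      qual = c(q79, q80), stringsAsFactors = FALSE)
  out <- filter_quality(reads)
  expect_equal(out$kept$id, "b")
  expect_equal(out$removed$id, "a")

  p <- make_pairs(random_dna(100), random_dna(100), q = 40)
  p$qual2 <- q79
  out2 <- filter_quality(p)
  expect_equal(nrow(out2$pairs), 0)
  expect_equal(nrow(out2$singletons), 1)  # forward mate survives alone
  expect_equal(out2$singletons$seq, p$seq1)
})

test_that("complexity filter unions DUST mask with ambiguous bases", {
  # homopolymer: fully masked, removed
  polyA <- paste(rep("A", 100), collapse = "")
  set.seed(34)
  normal <- random_dna(100)
  n41 <- paste0(paste(rep("N", 41), collapse = ""), substr(normal, 42, 100))
  n40 <- paste0(paste(rep("N", 40), collapse = ""), substr(normal, 41, 100))
  reads <- data.frame(id = c("poly", "ok", "n41", "n40"),
                      seq = c(polyA, normal, n41, n40),
                      qual = rep(qual_of(rep(40L, 100)), 4),
                      stringsAsFactors = FALSE)
  out <- filter_complexity(reads)
  expect_true("poly" %in% out$removed$id)
  expect_true("ok" %in% out$kept$id)
  expect_true("n41" %in% out$removed$id)  # 41% > 40%
  expect_true("n40" %in% out$kept$id)     # exactly 40% passes
})

test_that("the QC pipeline conserves reads and is idempotent", {
  g <- random_coding_genome(4000, seed = 55)
  sim <- read_sim_spec(read_length = 120, insert_mean = 200, insert_sd = 20,
                       coverage = 6, per_base_error = 0.01,
                       duplicate_fraction = 0.2, seed = 56)
  rd <- simulate_reads(g, sim)
  res <- qc_reads(rd$pairs)
  rep <- res$report

  # conservation: each input read is kept or removed exactly once
  # (a kept merged unit accounts for its two input reads)
  expect_equal(2L * rep$input_pairs,
               2L * rep$duplicate_pairs_removed +
                 rep$quality_failed_reads + rep$complexity_failed_reads +
                 2L * rep$kept_merged + 2L * rep$kept_pairs +
                 rep$kept_singletons)

  # idempotence on the paired survivors
  res2 <- qc_reads(res$pairs)
  expect_equal(nrow(res2$pairs) + nrow(res2$merged), nrow(res$pairs))
  expect_equal(res2$report$quality_failed_reads, 0)
  expect_equal(res2$report$complexity_failed_reads, 0)
  # merged and singleton survivors pass their own filters again
  fq <- filter_quality(res$merged)
  fc <- filter_complexity(fq$kept)
  expect_equal(nrow(fq$removed) + nrow(fc$removed), 0)
})
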