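test_that("terminal repeats call circularity with strict thresholds", {
  g <- random_coding_genome(20000, seed = 61)
  art <- make_circular_artifact(g, 60)
  call <- detect_circular(art)
  expect_true(call$is_circular)
  expect_equal(call$overlap_length, 60)
  expect_equal(call$trimmed_length, 20000)

  # repeat one base below the 50-bp floor is rejected
  art49 <- make_circular_artifact(g, 49)
  expect_false(detect_circular(art49)$is_circular)

  # 94 matches in a 100-bp overlap: identity must strictly exceed 94%
  art100 <- make_circular_artifact(g, 100)
  len <- nchar(art100)
  mm_pos <- len - 100 + c(20, 30, 40, 50, 60, 70)
  for (p in mm_pos) {
    old <- substr(art100, p, p)
    substr(art100, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  call94 <- detect_circular(art100)
  expect_equal(call94$overlap_identity, 0.94)
  expect_false(call94$is_circular)
  # one mismatch fewer (95%) is accepted
  art95 <- make_circular_artifact(g, 100)
  for (p in mm_pos[1:5]) {
    old <- substr(art95, p, p)
    substr(art95, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_true(detect_circular(art95)$is_circular)
})

test_that("circularity detection is rotation and reverse-complement invariant", {
  g <- random_coding_genome(3000, seed = 62)
  set.seed(63)
  for (rot in c(0L, sample.int(2999, 5))) {
    art <- make_circular_artifact(g, 80, rotate = rot)
    expect_true(detect_circular(art)$is_circular)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(art)))
    expect_true(detect_circular(rc)$is_circular)
  }
})

test_that("short contigs are flagged not evaluable", {
  call <- detect_circular(random_dna(80), min_overlap = 50)
  expect_false(call$evaluable)
  expect_true(is.na(call$is_circular))
})

test_that("length filter is strictly greater-than", {
  set.seed(64)
  contigs <- setNames(c(random_dna(9999), random_dna(10000), random_dna(10001)),
                      c("a", "b", "c"))
  expect_equal(names(filter_by_length(contigs)), "c")
  expect_length(filter_by_length(character(0)), 0)
  expect_equal(names(filter_by_length(contigs, min_bp = 100)),
               c("a", "b", "c"))
})

test_that("G+C statistics exclude ambiguous bases", {
  st <- genome_stats(setNames(c("GGCC", "ATGC", "ATGCN"), c("a", "b", "c")))
  expect_equal(st$gc_fraction, c(1, 0.5, 0.5))
  expect_equal(st$length, c(4, 4, 5))
})

test_that("redundancy merges HSP coverage on the shorter genome", {
  genomes <- setNames(c(random_dna(1000), random_dna(2000)), c("s", "l"))
  hsp <- function(qs, qe, ss, se, ident) {
    data.frame(query = "s", subject = "l", qstart = qs, qend = qe,
               sstart = ss, send = se, length = qe - qs + 1,
               identity = ident, stringsAsFactors = FALSE)
  }
  # one HSP covering 90% of the shorter at 96%: redundant
  p <- find_redundant_pairs(genomes, hsp(1, 900, 1, 900, 0.96))
  expect_true(p$redundant)
  # 99% identity but only 79% coverage: not redundant
  p <- find_redundant_pairs(genomes, hsp(1, 790, 1, 790, 0.99))
  expect_false(p$redundant)
  expect_equal(p$coverage, 0.79)
  # overlapping HSPs: union coverage 85%, weighted mean identity 95%
  h2 <- rbind(hsp(1, 500, 1, 500, 0.95), hsp(401, 850, 401, 850, 0.95))
  p <- find_redundant_pairs(genomes, h2)
  # brute-force base-marking oracle for the union
  marked <- rep(FALSE, 1000)
  marked[1:500] <- TRUE; marked[401:850] <- TRUE
  expect_equal(p$coverage, mean(marked))
  expect_true(p$redundant)
})

test_that("dereplication collapses single-linkage components", {
  set.seed(65)
  genomes <- setNames(lapply(c(1200, 1000, 1100, 900), random_dna),
                      c("A", "B", "C", "D"))
  genomes <- unlist(genomes)
  pairs <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                      coverage = 0.9, mean_identity = 0.99, redundant = TRUE)
  out <- dereplicate(genomes, pairs)
  expect_setequal(out$representatives, c("A", "D"))  # A longest in {A,B,C}
  expect_equal(out$members$representative[out$members$genome_id == "C"], "A")

  none <- pairs; none$redundant <- FALSE
  expect_length(dereplicate(genomes, none)$representatives, 4)
})

test_that("planted redundant pairs are recovered from the internal search", {
  cm <- generate_community(community_spec(
    2, 2, c(3000, 4000), n_redundant_pairs = 2, seed = 66))
  planted <- cm$truth$redundant_pairs
  expect_equal(nrow(planted), 2)
  pairs <- find_redundant_pairs(cm$genomes)
  red <- pairs[pairs$redundant, ]
  found <- paste(red$id_a, red$id_b)
  for (i in seq_len(nrow(planted))) {
    key <- paste(min(planted$id_a[i], planted$id_b[i]),
                 max(planted$id_a[i], planted$id_b[i]))
    expect_true(key %in% found)
  }
  # dereplicated set has no redundant pair left
  derep <- dereplicate(cm$genomes, pairs)
  seqs <- as.character(cm$genomes)[derep$representatives]
  pairs2 <- find_redundant_pairs(seqs)
  expect_false(any(pairs2$redundant))
})
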