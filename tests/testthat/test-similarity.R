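test_that("six-frame translation follows the genetic code", {
  tr <- six_frame_translate("ATGAAA")
  expect_equal(unname(tr["+1"]), "MK")
  # frame -1 of S equals frame +1 of revcomp(S)
  set.seed(81)
  s <- random_dna(99)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(unname(six_frame_translate(s)["-1"]),
               unname(six_frame_translate(rc)["+1"]))
  # trailing bases that do not fill a codon are dropped per frame
  tr2 <- six_frame_translate("ATGAAAC")
  expect_equal(nchar(unname(tr2["+1"])), 2)
  expect_equal(nchar(unname(tr2["+2"])), 2)
})

test_that("identical ORFs align at full identity with closed-form bits", {
  set.seed(82)
  orf <- random_coding_genome(900, seed = 82)
  h <- find_hsps(orf, orf, mode = "translated")
  expect_gt(nrow(h), 0)
  expect_true(all(h$identity == 1))
  # bit score closed form from the ungapped BLOSUM62 constants
  expect_equal(h$bitscore, (0.3176 * h$raw - log(0.134)) / log(2),
               tolerance = 1e-12)
})

test_that("unrelated random sequences yield no HSPs at the expect threshold", {
  set.seed(83)
  empty <- 0L
  for (i in 1:40) {
    a <- random_dna(1000)
    b <- random_dna(1000)
    h <- find_hsps(a, b, mode = "translated", evalue_max = 1e-3)
    if (nrow(h) == 0) empty <- empty + 1L
  }
  expect_gte(empty, 38L)  # empty with high probability
})

test_that("greedy HSP tiling follows the 50% overlap rule", {
  hsp <- function(qs, qe, bit) data.frame(qstart = qs, qend = qe,
                                          bitscore = bit)
  # two disjoint HSPs plus a duplicate fully overlapping the first
  hsps <- rbind(hsp(1, 100, 80), hsp(200, 260, 40), hsp(1, 100, 70))
  expect_equal(raw_similarity(hsps, hsps), 120)
  # no HSPs at all
  expect_equal(raw_similarity(hsps[0, ], hsps[0, ]), 0)
  # single symmetric HSP
  expect_equal(raw_similarity(hsp(1, 50, 120), hsp(1, 50, 120)), 120)
  # an HSP overlapping a selected one by exactly half its length is kept
  hsps2 <- rbind(hsp(1, 100, 80), hsp(51, 150, 60))
  expect_equal(raw_similarity(hsps2, hsps2), 140)
})

test_that("S_G normalization reproduces the endpoint properties", {
  expect_equal(compute_sg(30, 100, 200), 0.30)
  expect_equal(compute_sg(0, 50, 80), 0)
  expect_equal(compute_sg(100, 100, 150), 1)
  expect_error(compute_sg(10, 0, 50), "self-score")
  # geometric-mean variant
  expect_equal(compute_sg(30, 100, 400, method = "geomean"), 30 / 200)
})

test_that("identical genomes score exactly one, unrelated exactly zero", {
  g <- random_coding_genome(5000, seed = 84)
  two <- setNames(c(g[[1]], g[[1]]), c("a", "b"))
  sg <- sg_matrix(two)
  expect_identical(sg["a", "b"], 1)
  # three identical genomes: all-ones matrix
  three <- setNames(rep(g[[1]], 3), c("a", "b", "c"))
  expect_true(all(sg_matrix(three) == 1))
})

test_that("the S_G matrix is symmetric, bounded, and genus-structured", {
  sg <- fix_sg
  expect_true(all(sg >= 0 & sg <= 1))
  expect_identical(sg, t(sg))
  expect_true(all(diag(sg) == 1))
  genus <- fix_truth_genus[rownames(sg)]
  same <- outer(genus, genus, "==") & upper.tri(sg)
  diff <- outer(genus, genus, "!=") & upper.tri(sg)
  expect_gt(mean(sg[same]), mean(sg[diff]))
})

test_that("external HSP tables round-trip to the same S_G", {
  cm <- generate_community(community_spec(2, 2, c(3000, 3000), seed = 85))
  seqs <- as.character(cm$genomes)
  sg_direct <- sg_matrix(seqs)
  hsps <- blast_search(seqs, seqs, mode = "tblastx")
  # through the tabular format on disk
  tab <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(hsps, tab)
  back <- read_blast_tab(tab)
  sg_imported <- sg_from_hsps(back, ids = names(seqs))
  expect_equal(sg_imported, sg_direct, tolerance = 1e-6)
})

test_that("S_G tolerates circular permutation and reverse complement", {
  g <- random_coding_genome(8000, seed = 86)
  rot <- paste0(substr(g[[1]], 4001, 8000), substr(g[[1]], 1, 4000))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g[[1]])))
  sg <- sg_matrix(setNames(c(g[[1]], rot, rc), c("g", "rot", "rc")))
  expect_gte(sg["g", "rot"], 0.95)
  expect_gte(sg["g", "rc"], 0.95)
})

test_that("S_G decreases with planted divergence", {
  base <- random_coding_genome(6000, seed = 87)
  set.seed(88)
  mut <- function(seq, d) {
    b <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(b)) < d)
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }
  divs <- c(0, 0.05, 0.1, 0.2, 0.4)
  seqs <- c(base[[1]], vapply(divs[-1], function(d) mut(base[[1]], d),
                              character(1)))
  names(seqs) <- paste0("d", divs)
  sg <- sg_matrix(seqs)
  series <- sg["d0", ]
  expect_equal(unname(series["d0"]), 1)
  expect_true(all(diff(unname(series[paste0("d", divs)])) <= 0))
})
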