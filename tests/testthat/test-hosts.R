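mk_sg <- function(n, ids = NULL) {
  ids <- ids %||% paste0("v", seq_len(n))
  m <- matrix(runif(n * n, 0, 0.4), n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

test_that("best-score recording follows the eligibility rule", {
  set.seed(111)
  # two genomes share a group, one is alone: the singleton-group genome
  # has no same-group partner and is excluded -> 2 records, 4 scores
  sg <- mk_sg(3)
  labs <- setNames(c("H1", "H1", "H2"), rownames(sg))
  expect_message(rec <- record_best_scores(sg, labs), "excluded")
  expect_equal(nrow(rec), 2)

  # all genomes in one group: nobody has an out-group partner
  labs1 <- setNames(rep("H1", 3), rownames(sg))
  expect_message(rec1 <- record_best_scores(sg, labs1), "excluded")
  expect_equal(nrow(rec1), 0)

  # fully eligible set: exactly two scores per genome
  sg4 <- mk_sg(4)
  labs4 <- setNames(c("H1", "H1", "H2", "H2"), rownames(sg4))
  rec4 <- record_best_scores(sg4, labs4)
  expect_equal(nrow(rec4), 4)
  expect_equal(rec4$best_same_group_sg[1], sg4[1, 2])
  expect_equal(rec4$best_diff_group_sg[1], max(sg4[1, 3:4]))
})

test_that("precision counts hits strictly above the cutoff", {
  rec <- data.frame(genome_id = c("a", "b"), host_group = "H1",
                    best_same_group_sg = c(0.5, 0.3),
                    best_diff_group_sg = c(0.2, 0.1))
  curve <- precision_curve(rec, grid = c(0.15, 0.25, 0.6))
  expect_equal(curve$precision[curve$cutoff == 0.25], 1.0)   # 2 TP, 0 FP
  expect_equal(curve$precision[curve$cutoff == 0.15], 2 / 3) # 2 TP, 1 FP
  expect_true(is.na(curve$precision[curve$cutoff == 0.6]))   # undefined
})

test_that("cutoff choice takes the first sustained crossing", {
  rec <- data.frame(genome_id = letters[1:4], host_group = "H1",
                    best_same_group_sg = c(0.5, 0.45, 0.3, 0.28),
                    best_diff_group_sg = c(0.2, 0.15, 0.1, 0.33))
  curve <- precision_curve(rec)
  cut <- choose_cutoff(curve, 0.90)
  # brute-force scan oracle: smallest cutoff from which precision stays
  # above target wherever defined
  def <- which(!is.na(curve$precision))
  ok <- curve$precision[def] > 0.90
  oracle <- curve$cutoff[def[which(rev(cumprod(rev(ok))) == 1)[1]]]
  expect_equal(cut, oracle)
  # precision at the chosen cutoff and everywhere above it exceeds target
  above <- curve$cutoff >= cut & !is.na(curve$precision)
  expect_true(all(curve$precision[above] > 0.90))
  expect_warning(expect_true(is.na(choose_cutoff(curve, 1.01))), "target")
})

test_that("host prediction applies the strict S_G cutoff", {
  sg <- matrix(c(1, 0.35, 0.29,
                 0.35, 1, 0.1,
                 0.29, 0.1, 1), 3, 3,
               dimnames = list(c("u1", "ref1", "ref2"),
                               c("u1", "ref1", "ref2")))
  labs <- setNames(c("HostA", "HostB"), c("ref1", "ref2"))
  pred <- predict_hosts(sg, labs, cutoff = 0.2937)
  expect_true(pred$predicted)
  expect_equal(pred$predicted_host_group, "HostA")  # best partner 0.35
  pred2 <- predict_hosts(sg, labs, cutoff = 0.35)   # 0.35 is not > 0.35
  expect_false(pred2$predicted)
  expect_true(is.na(pred2$predicted_host_group))
})

test_that("planted host groups are recovered at high precision", {
  cm <- generate_community(community_spec(
    6, 3, c(3000, 4000), genera_per_host_group = 2, seed = 112))
  sg <- sg_matrix(cm$genomes)
  hosts <- setNames(cm$truth$genomes$host_group,
                    cm$truth$genomes$genome_id)
  genus <- setNames(cm$truth$genomes$genus, cm$truth$genomes$genome_id)
  unlabeled <- unname(vapply(split(names(hosts), genus[names(hosts)]),
                             function(m) m[1], character(1)))
  labeled <- setdiff(names(hosts), unlabeled)
  rec <- record_best_scores(sg[labeled, labeled], hosts[labeled])
  curve <- precision_curve(rec)
  cut <- choose_cutoff(curve, 0.90)
  expect_false(is.na(cut))
  pred <- predict_hosts(sg, hosts[labeled], cut, unlabeled = unlabeled)
  hit <- pred[pred$predicted, ]
  expect_gt(nrow(hit), 0)
  correct <- hosts[hit$genome_id] == hit$predicted_host_group
  expect_gte(mean(correct), 0.85)
})

test_that("bidirectional best hits quantify colinearity", {
  set.seed(114)
  aas <- function(n) paste(sample(setdiff(strsplit(
    "ARNDCQEGHILKMFPSTWYV", "")[[1]], ""), n, replace = TRUE), collapse = "")
  genes <- setNames(vapply(rep(160, 5), aas, character(1)), paste0("a", 1:5))
  # identical gene sets: full colinearity
  out <- bidirectional_best_hits(genes, setNames(genes, paste0("b", 1:5)))
  expect_equal(out$bg, 100)
  expect_true(out$colinear)
  # involution: the reverse map inverts the forward map
  back <- bidirectional_best_hits(setNames(genes, paste0("b", 1:5)), genes)
  expect_equal(nrow(back$map), nrow(out$map))

  # 3 of 5 orthologs: B_g = 60, still "nearly complete colinearity"
  other <- setNames(vapply(rep(160, 2), aas, character(1)), c("b4", "b5"))
  bset <- c(setNames(genes[1:3], paste0("b", 1:3)), other)
  out35 <- bidirectional_best_hits(genes, bset)
  expect_equal(out35$bg, 60)
  expect_true(out35$colinear)

  # unrelated gene sets: nothing crosses the BBH E-value bar
  unrelated <- setNames(vapply(rep(160, 4), aas, character(1)),
                        paste0("u", 1:4))
  out0 <- bidirectional_best_hits(genes, unrelated)
  expect_equal(out0$bg, 0)
  expect_false(out0$colinear)
  expect_error(bidirectional_best_hits(genes, character(0)), "zero genes")
})

test_that("gene translation matches hand-built annotations", {
  set.seed(116)
  filler <- random_dna(30)
  plus_orf <- "ATGAAATTTGGGTAA"              # MKFG + stop
  minus_orf <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGCCCGTTTAA")))  # MPV + stop on minus strand
  genome <- paste0(filler, plus_orf, filler, minus_orf, filler)
  genes <- data.frame(
    gene_id = c("fw", "rv"),
    start = c(31L, 31L + 15L + 30L),
    end = c(45L, 31L + 15L + 30L + 11L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  prot <- gene_proteins(genome, genes)
  expect_equal(as.character(prot), c(fw = "MKFG", rv = "MPV"))
})

test_that("naive ORF calling finds planted genes", {
  g <- random_coding_genome(4000, seed = 115)
  orfs <- call_orfs(g, min_codons = 100)
  expect_gt(nrow(orfs), 0)
  prot <- gene_proteins(g, orfs)
  expect_true(all(substr(as.character(prot), 1, 1) == "M"))
  expect_false(any(grepl("\\*", as.character(prot))))
})
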