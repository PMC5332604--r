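#' Map reads onto genomes with the internal nucleotide aligner
#'
#' Each read is assigned to its single best-scoring ungapped hit (highest
#' bit score) that covers at least `min_qcov` of the read at identity
#' `min_identity` or better. Mapping here feeds pileup construction; any
#' external mapper can substitute by supplying an equivalent hit table.
#'
#' @param reads data.frame with `id, seq, qual` (single reads) or
#'   `id, seq1, qual1, seq2, qual2` (pairs; mates are mapped independently
#'   with `/1` and `/2` id suffixes).
#' @param genomes named nucleotide sequences.
#' @param min_identity minimum alignment identity.
#' @param min_qcov minimum fraction of the read covered by the alignment.
#' @param evalue_max E-value threshold of the underlying search.
#' @return data.frame of best hits: `id, genome_id, qstart, qend, sstart,
#'   send, strand, identity`, joined with the read sequence and quality.
#' @export
map_reads <- function(reads, genomes, min_identity = 0.80, min_qcov = 0.90,
                      evalue_max = 1e-3) {
  if ("seq1" %in% names(reads)) {
    reads <- rbind(
      data.frame(id = paste0(reads$id, "/1"), seq = reads$seq1,
                 qual = reads$qual1, stringsAsFactors = FALSE),
      data.frame(id = paste0(reads$id, "/2"), seq = reads$seq2,
                 qual = reads$qual2, stringsAsFactors = FALSE))
  }
  hits <- blast_search(setNames(reads$seq, reads$id), genomes,
                       mode = "blastn", evalue_max = evalue_max)
  hits <- hits[hits$identity >= min_identity &
                 hits$length / hits$qlen >= min_qcov, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(id = character(0), genome_id = character(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), identity = numeric(0),
                      seq = character(0), qual = character(0)))
  }
  hits <- hits[order(hits$query, -hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(hits$query), , drop = FALSE]
  out <- data.frame(id = hits$query, genome_id = hits$subject,
                    qstart = hits$qstart, qend = hits$qend,
                    sstart = hits$sstart, send = hits$send,
                    strand = ifelse(hits$sframe < 0, "-", "+"),
                    identity = hits$identity, stringsAsFactors = FALSE)
  m <- match(out$id, reads$id)
  out$seq <- reads$seq[m]
  out$qual <- reads$qual[m]
  rownames(out) <- NULL
  out
}

#' Build high-quality pileups from read alignments
#'
#' Counts aligned bases per genome position, keeping only bases whose
#' Phred quality is strictly above `q_threshold` (to keep sequencing
#' errors out of the SNP and diversity statistics). Alignments are
#' ungapped: read offset maps linearly to genome position, complemented on
#' the minus strand.
#'
#' @param alignments hit table from [map_reads()] (needs `genome_id,
#'   qstart, qend, sstart, send, strand, seq, qual`).
#' @param q_threshold quality a base must exceed to be counted.
#' @return data.frame `genome_id, pos, A, C, G, T` with one row per
#'   covered position.
#' @export
build_pileup <- function(alignments, q_threshold = 30L) {
  empty <- data.frame(genome_id = character(0), pos = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0))
  if (!nrow(alignments)) return(empty)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nrow(alignments)
  gacc <- vector("list", n); pacc <- vector("list", n); bacc <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- alignments$qstart[i]:alignments$qend[i]
    bases <- strsplit(alignments$seq[i], "", fixed = TRUE)[[1]][idx]
    quals <- phred_ints(alignments$qual[i])[idx]
    minus <- alignments$strand[i] == "-"
    pos <- if (minus) alignments$sstart[i] - (idx - alignments$qstart[i]) else
      alignments$sstart[i] + (idx - alignments$qstart[i])
    if (minus) bases <- unname(comp[bases])
    keep <- quals > q_threshold & bases %in% c("A", "C", "G", "T")
    if (!any(keep)) next
    gacc[[i]] <- rep(alignments$genome_id[i], sum(keep))
    pacc[[i]] <- pos[keep]
    bacc[[i]] <- bases[keep]
  }
  gl <- unlist(gacc); pl <- unlist(pacc); bl <- unlist(bacc)
  if (!length(pl)) return(empty)
  out <- lapply(split(seq_along(pl), gl), function(ii) {
    pos <- pl[ii]
    base <- factor(bl[ii], levels = c("A", "C", "G", "T"))
    upos <- sort(unique(pos))
    counts <- vapply(levels(base), function(b) {
      tabulate(match(pos[base == b], upos), nbins = length(upos))
    }, integer(length(upos)))
    if (length(upos) == 1L) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, levels(base)))
    data.frame(genome_id = gl[ii[1]], pos = upos,
               A = counts[, "A"], C = counts[, "C"],
               G = counts[, "G"], T = counts[, "T"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Apply the six SNP criteria to pileup columns
#'
#' A position is evaluable at `min_coverage`-fold high-quality coverage or
#' more. The criteria are applied to the count `n2` of the
#' second-most-frequent nucleotide (ties broken in the fixed base order
#' A < C < G < T): (i) `n2 >= 1` read, (ii) `n2 >= 2` reads, (iii)
#' `n2 > 10%` of coverage, (iv) `n2 > 20%` of coverage ("more than" is
#' strict), (v) criterion iii or ii, (vi) criterion iii and ii.
#'
#' @param pileup data.frame from [build_pileup()].
#' @param min_coverage evaluability floor.
#' @return the pileup with added columns `coverage, second_allele,
#'   second_allele_count, second_allele_fraction, evaluable,
#'   crit_i..crit_vi` (criteria are NA for non-evaluable positions).
#' @export
call_snps <- function(pileup, min_coverage = 5L) {
  counts <- as.matrix(pileup[, c("A", "C", "G", "T")])
  cov <- rowSums(counts)
  bases <- c("A", "C", "G", "T")
  second_idx <- apply(counts, 1, function(r) order(-r, seq_along(r))[2])
  n2 <- counts[cbind(seq_len(nrow(counts)), second_idx)]
  out <- pileup
  out$coverage <- cov
  out$second_allele <- bases[second_idx]
  out$second_allele_count <- n2
  out$second_allele_fraction <- ifelse(cov > 0, n2 / cov, NA_real_)
  out$evaluable <- cov >= min_coverage
  ci <- n2 >= 1
  cii <- n2 >= 2
  ciii <- n2 > 0.10 * cov
  civ <- n2 > 0.20 * cov
  out$crit_i <- ifelse(out$evaluable, ci, NA)
  out$crit_ii <- ifelse(out$evaluable, cii, NA)
  out$crit_iii <- ifelse(out$evaluable, ciii, NA)
  out$crit_iv <- ifelse(out$evaluable, civ, NA)
  out$crit_v <- ifelse(out$evaluable, ciii | cii, NA)
  out$crit_vi <- ifelse(out$evaluable, ciii & cii, NA)
  out
}

# unbiased per-site heterozygosity of one column of base counts
pi_site <- function(counts) {
  C <- sum(counts)
  if (C < 2) return(0)
  (C / (C - 1)) * (1 - sum((counts / C)^2))
}

#' Nucleotide diversity from pileups
#'
#' Per-site heterozygosity with small-sample correction,
#' `pi_site = C/(C-1) * (1 - sum_b (c_b/C)^2)` at coverage `C`, averaged
#' over evaluable sites (coverage >= `min_coverage`) and reported in
#' percent. Equals the mean pairwise mismatch fraction of the aligned
#' reads at each site.
#'
#' @param pileup data.frame from [build_pileup()].
#' @param min_coverage evaluability floor (shared with [call_snps()] so
#'   SNP rates and diversity use the same denominator).
#' @return data.frame `genome_id, pi_percent, evaluable_sites`; genomes
#'   with no evaluable site get NA with a warning.
#' @export
nucleotide_diversity <- function(pileup, min_coverage = 5L) {
  counts <- as.matrix(pileup[, c("A", "C", "G", "T")])
  cov <- rowSums(counts)
  out <- lapply(split(seq_len(nrow(pileup)), pileup$genome_id), function(ii) {
    ok <- ii[cov[ii] >= min_coverage]
    if (!length(ok)) {
      warning("no evaluable site for genome ", pileup$genome_id[ii[1]])
      return(data.frame(genome_id = pileup$genome_id[ii[1]],
                        pi_percent = NA_real_, evaluable_sites = 0L))
    }
    pis <- apply(counts[ok, , drop = FALSE], 1, pi_site)
    data.frame(genome_id = pileup$genome_id[ii[1]],
               pi_percent = 100 * mean(pis),
               evaluable_sites = length(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-criterion SNP rates
#'
#' For each genome and each of the six criteria, the percentage of
#' evaluable sites called as SNPs.
#'
#' @param calls output of [call_snps()].
#' @return data.frame with `genome_id, evaluable_sites` and
#'   `rate_i..rate_vi` (percent of evaluable sites).
#' @export
snp_rate <- function(calls) {
  crit_cols <- paste0("crit_", c("i", "ii", "iii", "iv", "v", "vi"))
  out <- lapply(split(seq_len(nrow(calls)), calls$genome_id), function(ii) {
    ev <- ii[which(calls$evaluable[ii])]
    n <- length(ev)
    if (!n) stop("zero evaluable sites for genome ", calls$genome_id[ii[1]])
    rates <- vapply(crit_cols, function(cc) {
      100 * sum(calls[[cc]][ev]) / n
    }, numeric(1))
    cbind(data.frame(genome_id = calls$genome_id[ii[1]],
                     evaluable_sites = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(rates, sub("crit", "rate",
                                                    crit_cols)))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
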