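## File formats: FASTA/FASTQ via Biostrings, 12-column tabular alignments,
## square matrices, pileup and truth tables as TSV, minimal GFF3 output.

#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param path file path.
#' @param x named sequences.
#' @return `read_fasta` returns a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_seq_chars(x)), path)
}

#' Read and write FASTQ read pairs
#'
#' Pairs are stored as two Phred+33 FASTQ files (`_1`/`_2`).
#'
#' @param pairs data.frame `id, seq1, qual1, seq2, qual2`.
#' @param path1,path2 mate file paths.
#' @return `read_fastq_pairs` returns the pairs data.frame.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(ids, seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$id, pairs$seq1, pairs$qual1, path1)
  write_one(pairs$id, pairs$seq2, pairs$qual2, path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  stopifnot(length(r1) == length(r2))
  data.frame(id = names(r1),
             seq1 = as.character(r1),
             qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             seq2 = as.character(r2),
             qual2 = as.character(S4Vectors::mcols(r2)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read and write the 12-column tabular alignment format
#'
#' The classic tab-separated format (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore), so
#' external search tools can substitute for the internal aligner.
#'
#' @param hits HSP data.frame (as from [blast_search()]).
#' @param path file path.
#' @return `read_blast_tab` returns a data.frame with `query, subject,
#'   identity` (fraction), `length, qstart, qend, sstart, send, evalue,
#'   bitscore` columns compatible with the package's consumers.
#' @export
write_blast_tab <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query, sseqid = hits$subject,
    pident = round(100 * hits$identity, 3),
    length = hits$length,
    mismatch = hits$length - hits$matches,
    gapopen = 0L,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = hits$evalue, bitscore = hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_blast_tab
#' @export
read_blast_tab <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.delim(path, header = FALSE, col.names = cols,
                  stringsAsFactors = FALSE)
  x$identity <- x$pident / 100
  x$matches <- x$length - x$mismatch
  x
}

#' Read and write square matrices (S_G or distances) as TSV
#'
#' @param m symmetric matrix with dimnames.
#' @param path file path.
#' @return `read_square_matrix` returns the matrix.
#' @export
write_square_matrix <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  x <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(x)
}

#' Write a tree in Newick format
#'
#' Stored branch lengths are untransformed; `log_branches = TRUE` applies
#' the display transform `log10(1 + d / epsilon)` for plotting exports
#' only.
#'
#' @param tree an [ape::phylo].
#' @param path file path.
#' @param log_branches apply the display transform.
#' @param epsilon scale of the log transform.
#' @return `read_tree` returns the [ape::phylo].
#' @export
write_tree <- function(tree, path, log_branches = FALSE, epsilon = 0.01) {
  if (log_branches) {
    tree$edge.length <- log10(1 + tree$edge.length / epsilon)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) ape::read.tree(path)

#' Write and read pileup tables
#'
#' @param pileup data.frame `genome_id, pos, A, C, G, T`.
#' @param path file path.
#' @return `read_pileup_tsv` returns the pileup data.frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write gene annotations as GFF3
#'
#' @param genes data.frame `genome_id, gene_id, start, end, strand`.
#' @param path file path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf("%s\tevgtools\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$genome_id, genes$start, genes$end, genes$strand,
                     genes$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' @param path file path.
#' @return data.frame `genome_id, gene_id, start, end, strand`.
#' @export
read_gff3_genes <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  data.frame(genome_id = x$V1,
             gene_id = sub("^ID=", "", sub(";.*$", "", x$V9)),
             start = x$V4, end = x$V5, strand = x$V7,
             stringsAsFactors = FALSE)
}
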