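#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1..+3 read the forward strand, -1..-3 the reverse complement,
#' using the standard genetic code. Stop codons are rendered as `*`, which
#' the alignment engine treats as chain-breaking; trailing bases that do
#' not fill a codon are ignored.
#'
#' @param seq a single nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @return named character vector of six peptide strings
#'   (`+1,+2,+3,-1,-2,-3`).
#' @export
six_frame_translate <- function(seq) {
  s <- Biostrings::DNAString(unname(as_seq_chars(seq)[1]))
  rc <- Biostrings::reverseComplement(s)
  one <- function(x, f) {
    n <- length(x) - f + 1L
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(x, f, f + n - 1L),
                                       if.fuzzy.codon = "X"))
  }
  out <- c(one(s, 1L), one(s, 2L), one(s, 3L),
           one(rc, 1L), one(rc, 2L), one(rc, 3L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Search sequence sets for local alignments (HSPs)
#'
#' Ungapped seed-and-extend search in one of four classic flavours:
#' `tblastx` (six-frame translated vs six-frame translated, BLOSUM62),
#' `blastn` (nucleotide, both strands, +1/-2), `blastp` (protein vs
#' protein) and `tblastn` (protein vs six-frame translated). Bit scores use
#' ungapped Karlin-Altschul statistics (BLOSUM62: lambda 0.3176, K 0.134;
#' nucleotide: lambda 1.3327, K 0.621); HSPs with E-value above
#' `evalue_max` are discarded. This is a desk-scale aligner: seeds are
#' exact words (4-mer peptide with a two-hit diagonal rule, 11-mer
#' nucleotide), so it is not output-identical to any external search tool,
#' which can substitute through [read_blast_tab()].
#'
#' @param queries,subjects named sequence sets (character or
#'   [Biostrings::XStringSet]). Nucleotide or protein according to `mode`.
#' @param mode one of `"tblastx"`, `"blastn"`, `"blastp"`, `"tblastn"`.
#' @param evalue_max maximum reported E-value.
#' @return data.frame with columns `query, subject` (names), 1-based
#'   coordinates `qstart, qend, sstart, send` (start > end on the minus
#'   strand/frame), `qframe, sframe`, alignment `length` (residues),
#'   `matches`, `identity` (fraction), `raw`, `bitscore`, `evalue`,
#'   `qlen, slen`.
#' @export
blast_search <- function(queries, subjects, mode = "tblastx",
                         evalue_max = 1e-3) {
  mode <- match.arg(mode, c("tblastx", "blastn", "blastp", "tblastn"))
  q <- as_seq_chars(queries)
  s <- as_seq_chars(subjects)
  if (anyDuplicated(names(q)) || anyDuplicated(names(s))) {
    stop("duplicate sequence ids")
  }
  hits <- .cpp_search(unname(q), unname(s), mode, evalue_max)
  hits$query <- names(q)[hits$query]
  hits$subject <- names(s)[hits$subject]
  hits
}

#' Find HSPs between two sequences
#'
#' Convenience wrapper around [blast_search()] for a single pair, using
#' the module's mode vocabulary: `"translated"` (tblastx-like),
#' `"nucleotide"` (blastn-like) or `"protein"` (blastp-like).
#'
#' @param query,subject single sequences.
#' @param mode alignment mode.
#' @param evalue_max maximum reported E-value.
#' @return HSP data.frame as in [blast_search()]; zero rows when nothing
#'   aligns.
#' @export
find_hsps <- function(query, subject,
                      mode = c("translated", "nucleotide", "protein"),
                      evalue_max = 1e-3) {
  mode <- match.arg(mode)
  blast_mode <- c(translated = "tblastx", nucleotide = "blastn",
                  protein = "blastp")[[mode]]
  q <- as_seq_chars(query)[1]
  s <- as_seq_chars(subject)[1]
  names(q) <- names(q) %||% "query"
  names(s) <- names(s) %||% "subject"
  blast_search(q, s, blast_mode, evalue_max)
}

# greedy HSP tiling on the query: select by descending bit score, discard
# any HSP overlapping an already selected one by more than half its own
# length; return the summed bit scores.
tile_bits <- function(hsps) {
  if (!nrow(hsps)) return(0)
  lo <- pmin(hsps$qstart, hsps$qend)
  hi <- pmax(hsps$qstart, hsps$qend)
  bit <- hsps$bitscore
  ord <- order(-bit, lo, hi)
  lo <- lo[ord]; hi <- hi[ord]; bit <- bit[ord]
  sel <- integer(0)
  total <- 0
  for (i in seq_along(bit)) {
    len <- hi[i] - lo[i] + 1
    ov <- pmin(hi[i], hi[sel]) - pmax(lo[i], lo[sel]) + 1
    if (!length(sel) || all(2 * ov <= len)) {
      sel <- c(sel, i)
      total <- total + bit[i]
    }
  }
  total
}

#' Genome-wide raw similarity from HSP sets
#'
#' Reduces the HSPs between genomes A and B to a single raw score: per
#' search ordering, HSPs are greedily tiled on the query (descending bit
#' score, discarding HSPs overlapping a selected one by more than 50% of
#' their length) and their bit scores summed; the raw similarity is the
#' mean of the two orderings. Zero when no HSPs exist.
#'
#' @param hsps_ab HSPs with A as query (data.frame with `qstart, qend,
#'   bitscore`).
#' @param hsps_ba HSPs with B as query.
#' @return a single nonnegative raw score.
#' @export
raw_similarity <- function(hsps_ab, hsps_ba) {
  (tile_bits(hsps_ab) + tile_bits(hsps_ba)) / 2
}

#' Normalize a raw similarity to the genome-wide score S_G
#'
#' `S_G = raw_AB / min(raw_AA, raw_BB)` (or the geometric-mean denominator),
#' clipped to \[0, 1\]. By construction S_G is 1 when the two genomes are
#' identical and 0 when the translated search finds no similarity.
#'
#' @param raw_ab raw similarity between A and B.
#' @param raw_aa,raw_bb self raw similarities; must be positive.
#' @param method denominator: `"min"` (default) or `"geomean"`.
#' @return S_G in \[0, 1\].
#' @export
compute_sg <- function(raw_ab, raw_aa, raw_bb, method = c("min", "geomean")) {
  method <- match.arg(method)
  if (raw_aa <= 0 || raw_bb <= 0) {
    stop("undefined similarity: a genome has zero self-score")
  }
  denom <- if (method == "min") min(raw_aa, raw_bb) else sqrt(raw_aa * raw_bb)
  min(1, max(0, raw_ab / denom))
}

#' All-against-all S_G matrix
#'
#' Runs the translated search over every ordered genome pair (including
#' self comparisons), tiles and sums bit scores per ordering, and
#' normalizes with [compute_sg()]. The result is symmetric with unit
#' diagonal.
#'
#' @param genomes named nucleotide sequences (>= 2).
#' @param evalue_max HSP E-value threshold.
#' @param method S_G denominator, see [compute_sg()].
#' @return symmetric numeric matrix with genome ids as dimnames.
#' @export
sg_matrix <- function(genomes, evalue_max = 1e-3, method = c("min", "geomean")) {
  method <- match.arg(method)
  seqs <- as_seq_chars(genomes)
  if (length(seqs) < 2) stop("need at least two genomes")
  if (anyDuplicated(names(seqs))) stop("duplicate genome ids")
  raw <- .cpp_sg_raw(unname(seqs), evalue_max)
  sg_from_raw(raw, names(seqs), method)
}

# assemble the S_G matrix from an ordered raw score matrix (query rows)
sg_from_raw <- function(raw, ids, method = "min") {
  self <- diag(raw)
  if (any(self <= 0)) {
    stop("undefined similarity: zero self-score for ",
         paste(ids[self <= 0], collapse = ", "))
  }
  sym <- (raw + t(raw)) / 2
  denom <- if (method == "min") outer(self, self, pmin) else
    sqrt(outer(self, self))
  sg <- sym / denom
  sg[sg < 0] <- 0
  sg[sg > 1] <- 1
  diag(sg) <- 1
  dimnames(sg) <- list(ids, ids)
  sg
}

#' S_G matrix from an imported HSP table
#'
#' Builds the raw score matrix by tiling a precomputed HSP table (e.g. read
#' from the 12-column tabular format of an external translated search) and
#' normalizes it exactly like [sg_matrix()]. Self comparisons must be
#' present for every genome.
#'
#' @param hsps HSP data.frame with `query, subject, qstart, qend, bitscore`.
#' @param ids genome ids defining the matrix order (default: ids seen in
#'   `hsps`).
#' @param method S_G denominator, see [compute_sg()].
#' @return symmetric S_G matrix.
#' @export
sg_from_hsps <- function(hsps, ids = NULL, method = c("min", "geomean")) {
  method <- match.arg(method)
  ids <- ids %||% sort(unique(c(hsps$query, hsps$subject)))
  n <- length(ids)
  raw <- matrix(0, n, n)
  key <- split(seq_len(nrow(hsps)),
               list(factor(hsps$query, ids), factor(hsps$subject, ids)),
               drop = TRUE)
  for (nm in names(key)) {
    idx <- key[[nm]]
    qs <- match(hsps$query[idx[1]], ids)
    ss <- match(hsps$subject[idx[1]], ids)
    raw[qs, ss] <- tile_bits(hsps[idx, , drop = FALSE])
  }
  sg_from_raw(raw, ids, method)
}
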