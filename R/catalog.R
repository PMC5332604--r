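#' Detect circular (complete) contigs from terminal repeats
#'
#' A contig assembled from a circular genome carries a duplicated stretch:
#' its 5' and 3' terminal regions are nearly identical. The contig is
#' called circular when the best suffix-prefix alignment is at least
#' `min_overlap` bases long with identity strictly above `min_identity`.
#' The search seeds exact prefix k-mers within a bounded window of each
#' terminus and evaluates the implied ungapped overlap without end gaps.
#'
#' @param contig a single nucleotide sequence.
#' @param min_overlap minimum terminal repeat length (bp).
#' @param min_identity identity that the repeat must exceed (strict).
#' @param k seed length for locating the repeat.
#' @param window terminal search window; default `min(5000, 20%% of the
#'   contig)` at each end.
#' @return list (class `circularity_call`) with `contig_id, length,
#'   overlap_length, overlap_identity, is_circular, trimmed_length,
#'   evaluable`. `trimmed_length` drops the duplicated terminus when
#'   circular. Contigs shorter than `2 * min_overlap` are flagged not
#'   evaluable.
#' @export
detect_circular <- function(contig, min_overlap = 50L, min_identity = 0.94,
                            k = 15L, window = NULL) {
  seqs <- as_seq_chars(contig)
  seq <- unname(seqs[1])
  id <- names(seqs)[1]
  len <- nchar(seq)
  out <- list(contig_id = id, length = len, overlap_length = 0L,
              overlap_identity = NA_real_, is_circular = FALSE,
              trimmed_length = len, evaluable = TRUE)
  class(out) <- "circularity_call"
  if (len <= 2L * min_overlap) {
    out$evaluable <- FALSE
    out$is_circular <- NA
    return(out)
  }
  W <- window %||% min(5000L, floor(0.2 * len))
  W <- max(W, min_overlap + k)
  tail_start <- len - W + 1L
  tail_seq <- substr(seq, tail_start, len)

  cand <- integer(0)
  for (off in seq(0L, min(50L, W - k), by = 5L)) {
    seed <- substr(seq, 1L + off, off + k)
    m <- gregexpr(seed, tail_seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    cand <- c(cand, tail_start + as.integer(m) - 1L - off)
  }
  cand <- unique(cand[cand > 1L & cand <= len])
  best <- NULL
  for (q0 in cand) {
    ov <- len - q0 + 1L
    a <- strsplit(substr(seq, 1L, ov), "", fixed = TRUE)[[1]]
    b <- strsplit(substr(seq, q0, len), "", fixed = TRUE)[[1]]
    ident <- mean(a == b)
    hit <- list(ov = ov, ident = ident,
                ok = ov >= min_overlap && ident > min_identity)
    if (is.null(best) || (hit$ok && !best$ok) ||
        (hit$ok == best$ok && ov > best$ov)) {
      best <- hit
    }
  }
  if (!is.null(best)) {
    out$overlap_length <- best$ov
    out$overlap_identity <- best$ident
    if (best$ok) {
      out$is_circular <- TRUE
      out$trimmed_length <- len - best$ov
    }
  }
  out
}

#' Keep contigs larger than a size floor
#'
#' The genome catalog keeps only contigs strictly larger than `min_bp`
#' (default 10 kb, the size floor for complete dsDNA viral genomes).
#'
#' @param contigs named sequences.
#' @param min_bp exclusive length threshold.
#' @return the subset of `contigs`, same class as the input.
#' @export
filter_by_length <- function(contigs, min_bp = 10000L) {
  if (methods::is(contigs, "XStringSet")) {
    contigs[Biostrings::width(contigs) > min_bp]
  } else {
    contigs[nchar(contigs) > min_bp]
  }
}

#' Per-genome length and G+C statistics
#'
#' @param genomes named sequences.
#' @return data.frame with `genome_id, length, gc_fraction`; G+C is
#'   computed over unambiguous bases only (NA when a sequence has none).
#' @export
genome_stats <- function(genomes) {
  x <- Biostrings::DNAStringSet(as_seq_chars(genomes))
  freq <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
  data.frame(genome_id = names(x), length = Biostrings::width(x),
             gc_fraction = unname(gc), stringsAsFactors = FALSE)
}

#' Find redundant genome pairs from merged HSP coverage
#'
#' For every genome pair with nucleotide HSPs, the HSPs are projected onto
#' the shorter genome and merged into an interval union; the pair is
#' redundant when the union covers at least `min_coverage` of the shorter
#' genome and the alignment-length-weighted mean identity of the
#' (unmerged) HSPs is at least `min_identity`.
#'
#' @param genomes named sequences (used for lengths, and for the internal
#'   all-against-all nucleotide search when `hsps` is missing).
#' @param hsps optional precomputed nucleotide HSP table (columns `query,
#'   subject, qstart, qend, sstart, send, length, identity`); self hits
#'   are ignored.
#' @param min_coverage coverage of the shorter genome required.
#' @param min_identity weighted mean identity required.
#' @param evalue_max E-value threshold for the internal search.
#' @return data.frame `id_a, id_b, coverage, mean_identity, redundant`
#'   with one row per unordered pair having at least one HSP.
#' @export
find_redundant_pairs <- function(genomes, hsps = NULL, min_coverage = 0.80,
                                 min_identity = 0.95, evalue_max = 1e-3) {
  seqs <- as_seq_chars(genomes)
  lens <- setNames(nchar(seqs), names(seqs))
  if (is.null(hsps)) {
    hsps <- blast_search(seqs, seqs, mode = "blastn", evalue_max = evalue_max)
  }
  hsps <- hsps[hsps$query != hsps$subject, , drop = FALSE]
  if (!nrow(hsps)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      coverage = numeric(0), mean_identity = numeric(0),
                      redundant = logical(0)))
  }
  a <- pmin(hsps$query, hsps$subject)
  b <- pmax(hsps$query, hsps$subject)
  out <- lapply(split(seq_len(nrow(hsps)), paste(a, b, sep = "\r")),
    function(idx) {
      h <- hsps[idx, , drop = FALSE]
      id_a <- min(h$query[1], h$subject[1])
      id_b <- max(h$query[1], h$subject[1])
      shorter <- if (lens[[id_a]] <= lens[[id_b]]) id_a else id_b
      lo <- ifelse(h$query == shorter, pmin(h$qstart, h$qend),
                   pmin(h$sstart, h$send))
      hi <- ifelse(h$query == shorter, pmax(h$qstart, h$qend),
                   pmax(h$sstart, h$send))
      covered <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = lo, end = hi))))
      coverage <- covered / lens[[shorter]]
      mid <- sum(h$identity * h$length) / sum(h$length)
      data.frame(id_a = id_a, id_b = id_b, coverage = coverage,
                 mean_identity = mid,
                 redundant = coverage >= min_coverage && mid >= min_identity,
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Collapse redundant genomes to a nonredundant set
#'
#' Single-linkage clustering of redundant pairs: connected components of
#' the redundancy graph are collapsed to one representative each (the
#' longest genome; ties broken by lexicographic id).
#'
#' @param genomes named sequences (lengths pick representatives).
#' @param pairs output of [find_redundant_pairs()].
#' @return list with `representatives` (character ids) and `members`
#'   (data.frame `genome_id, representative`).
#' @export
dereplicate <- function(genomes, pairs) {
  seqs <- as_seq_chars(genomes)
  ids <- names(seqs)
  lens <- setNames(nchar(seqs), ids)
  red <- pairs[pairs$redundant, c("id_a", "id_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(red, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  rep_of <- vapply(split(ids, comp), function(m) {
    m[order(-lens[m], m)][1]
  }, character(1))
  members <- data.frame(genome_id = ids,
                        representative = unname(rep_of[as.character(comp)]),
                        stringsAsFactors = FALSE)
  list(representatives = sort(unique(members$representative)),
       members = members)
}
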