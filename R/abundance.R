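#' Count fragments per genome from a hit table
#'
#' Each query fragment (merged read or read pair) is assigned to its
#' single best-scoring target genome; ties are split equally among the
#' tied targets.
#'
#' @param hits hit table (`query, subject, bitscore`).
#' @param targets target genome ids defining the output order (default:
#'   targets seen in `hits`).
#' @return named numeric vector of fragment counts per target.
#' @export
count_fragments <- function(hits, targets = NULL) {
  targets <- targets %||% sort(unique(hits$subject))
  counts <- setNames(numeric(length(targets)), targets)
  if (!nrow(hits)) return(counts)
  for (idx in split(seq_len(nrow(hits)), hits$query)) {
    h <- hits[idx, , drop = FALSE]
    best <- h$subject[h$bitscore == max(h$bitscore)]
    best <- unique(best)
    counts[best] <- counts[best] + 1 / length(best)
  }
  counts
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / ((length / 1000) * (library_size / 1e6))`, per genome
#' and sample.
#'
#' @param fragment_counts genome x sample matrix (or vector for one
#'   sample) of fragment counts.
#' @param genome_lengths named lengths (bp) covering all genomes.
#' @param library_sizes total mapped fragments per sample.
#' @return genome x sample FPKM matrix.
#' @export
fpkm <- function(fragment_counts, genome_lengths, library_sizes) {
  counts <- as.matrix(fragment_counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(genome_lengths <= 0)) stop("genome lengths must be positive")
  lens <- genome_lengths[rownames(counts) %||% names(genome_lengths)]
  sweep(sweep(counts, 1, lens / 1e3, "/"), 2, library_sizes / 1e6, "/")
}

#' Aggregate genome FPKMs to gOTU FPKMs
#'
#' Per sample, member-genome FPKMs are summed within each gOTU. Samples
#' belonging to a declared group are first averaged into one
#' pseudo-sample (so a locally replicated site does not bias the
#' average), and the gOTU value is the mean over the resulting samples.
#'
#' @param fpkm_table genome x sample FPKM matrix.
#' @param partition named gOTU assignment per genome.
#' @param sample_groups optional named list mapping a group name to the
#'   sample (column) names it collapses.
#' @return named numeric vector of gOTU FPKMs.
#' @export
gotu_fpkm <- function(fpkm_table, partition, sample_groups = NULL) {
  x <- as.matrix(fpkm_table)
  if (!all(rownames(x) %in% names(partition))) {
    stop("every genome needs a gOTU assignment")
  }
  sums <- rowsum(x, group = partition[rownames(x)])
  if (!is.null(sample_groups)) {
    grouped <- lapply(sample_groups, function(cols) {
      rowMeans(sums[, cols, drop = FALSE])
    })
    rest <- setdiff(colnames(sums), unlist(sample_groups))
    sums <- cbind(do.call(cbind, grouped), sums[, rest, drop = FALSE])
  }
  rowMeans(sums)
}

#' Normalize abundances to percentages
#'
#' Scales values so that they sum to 100.
#'
#' @param x nonnegative abundances with at least one nonzero value.
#' @return `x * 100 / sum(x)`.
#' @export
normalize_abundance <- function(x) {
  total <- sum(x)
  if (total <= 0) stop("undefined abundance: all values are zero")
  x * 100 / total
}

#' Sequence recruitment under identity/coverage filters
#'
#' A query is recruited by a target set when it has at least one hit to a
#' member of the set passing the E-value filter, with identity at least
#' `min_identity` and alignment covering at least `min_query_cov` of the
#' query. Reports the recruited fraction per target set; fractions are
#' monotone non-decreasing in the target set.
#'
#' @param hits hit table (`query, subject, identity, length, qlen,
#'   evalue`).
#' @param n_queries total number of query sequences searched (recruited
#'   fractions are relative to this).
#' @param target_sets named list of target id vectors (default: one set
#'   with every target in `hits`).
#' @param min_identity minimum alignment identity (fraction).
#' @param min_query_cov minimum fraction of the query covered.
#' @param evalue_max E-value filter applied before identity/coverage.
#' @return data.frame `target_set, recruited, fraction`.
#' @export
recruit <- function(hits, n_queries, target_sets = NULL,
                    min_identity = 0.60, min_query_cov = 0.80,
                    evalue_max = 1e-3) {
  stopifnot(n_queries >= 1)
  target_sets <- target_sets %||% list(all = sort(unique(hits$subject)))
  pass <- hits[hits$evalue <= evalue_max &
                 hits$identity >= min_identity &
                 hits$length / hits$qlen >= min_query_cov, , drop = FALSE]
  out <- lapply(names(target_sets), function(nm) {
    rec <- length(unique(pass$query[pass$subject %in% target_sets[[nm]]]))
    data.frame(target_set = nm, recruited = rec,
               fraction = rec / n_queries, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
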