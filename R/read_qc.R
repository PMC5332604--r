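#' Remove exact duplicate read pairs
#'
#' A pair is a duplicate of an earlier pair when both mates are identical
#' full-length sequences (qualities are ignored). The first occurrence is
#' kept; order is preserved.
#'
#' @param pairs data.frame with columns `id, seq1, qual1, seq2, qual2`.
#' @return the deduplicated pairs data.frame.
#' @export
deduplicate <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$seq1, pairs$seq2, sep = "\r")
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# orient mate 2 onto the forward strand: revcomp sequence, reverse quality
orient_mate2 <- function(seq2, qual2) {
  list(seq = revcomp_chr(seq2),
       qual = vapply(qual2, function(q) {
         paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = "")
       }, character(1), USE.NAMES = FALSE))
}

merge_one <- function(s1, q1, s2r, q2r, min_overlap, max_mismatch_density) {
  b1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(s2r, "", fixed = TRUE)[[1]]
  l1 <- length(b1); l2 <- length(b2)
  if (min(l1, l2) < min_overlap) return(NULL)
  best_o <- 0L; best_d <- Inf
  for (o in seq(min(l1, l2), min_overlap)) {
    mism <- sum(b1[(l1 - o + 1):l1] != b2[1:o])
    d <- mism / o
    if (d < best_d) { best_d <- d; best_o <- o }  # ties keep larger overlap
  }
  if (best_o < min_overlap || best_d > max_mismatch_density) return(NULL)
  o <- best_o
  p1 <- phred_ints(q1); p2 <- phred_ints(q2r)
  ov1 <- (l1 - o + 1):l1; ov2 <- 1:o
  take1 <- p1[ov1] >= p2[ov2]       # disagreements: higher quality wins,
  cons <- ifelse(take1, b1[ov1], b2[ov2])  # forward mate on quality ties
  consq <- pmax(p1[ov1], p2[ov2])
  list(seq = paste0(substr(s1, 1, l1 - o), paste(cons, collapse = ""),
                    substr(s2r, o + 1, l2)),
       qual = paste0(substr(q1, 1, l1 - o), ints_phred(consq),
                     substr(q2r, o + 1, l2)))
}

#' Merge overlapping paired-end reads
#'
#' A pair merges when its best 3' overlap is at least `min_overlap` bases
#' with mismatch density at most `max_mismatch_density`; the merged length
#' is `len(F) + len(R) - overlap`. Disagreeing overlap bases are resolved
#' in favour of the higher-quality mate. Pairs that do not merge are
#' returned unchanged.
#'
#' @param pairs data.frame with `id, seq1, qual1, seq2, qual2`.
#' @param min_overlap minimum overlap in bp.
#' @param max_mismatch_density maximum fraction of mismatching overlap
#'   positions.
#' @return list with `merged` (data.frame `id, seq, qual`) and `pairs`
#'   (the unmerged pairs).
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_density = 0.25) {
  stopifnot(min_overlap >= 1)
  merged <- list()
  keep <- logical(nrow(pairs))
  if (nrow(pairs)) {
    m2 <- orient_mate2(pairs$seq2, pairs$qual2)
    for (i in seq_len(nrow(pairs))) {
      m <- merge_one(pairs$seq1[i], pairs$qual1[i], m2$seq[i], m2$qual[i],
                     min_overlap, max_mismatch_density)
      if (is.null(m)) {
        keep[i] <- TRUE
      } else {
        merged[[length(merged) + 1L]] <-
          data.frame(id = pairs$id[i], seq = m$seq, qual = m$qual,
                     stringsAsFactors = FALSE)
      }
    }
  }
  merged <- if (length(merged)) do.call(rbind, merged) else
    data.frame(id = character(0), seq = character(0), qual = character(0))
  rownames(merged) <- NULL
  unmerged <- pairs[keep, , drop = FALSE]
  rownames(unmerged) <- NULL
  list(merged = merged, pairs = unmerged)
}

#' Quality-filter reads
#'
#' A read is removed when the fraction of its positions with Phred quality
#' strictly above `q_threshold` is below `min_hq_fraction` (exactly the
#' boundary fraction passes). For read pairs, a pair where only one mate
#' fails demotes the surviving mate to a single read.
#'
#' @param x single reads (`id, seq, qual`) or pairs
#'   (`id, seq1, qual1, seq2, qual2`).
#' @param q_threshold quality score that a position must exceed to count as
#'   high quality.
#' @param min_hq_fraction minimum fraction of high-quality positions.
#' @return for single reads, list(`kept`, `removed`); for pairs,
#'   list(`pairs`, `singletons`, `removed`) where `singletons` holds mates
#'   retained as single reads.
#' @export
filter_quality <- function(x, q_threshold = 30L, min_hq_fraction = 0.80) {
  pass <- function(qual) {
    vapply(qual, hq_fraction, numeric(1), q_threshold = q_threshold,
           USE.NAMES = FALSE) >= min_hq_fraction
  }
  if ("seq" %in% names(x)) {
    ok <- if (nrow(x)) pass(x$qual) else logical(0)
    list(kept = x[ok, , drop = FALSE], removed = x[!ok, , drop = FALSE])
  } else {
    ok1 <- if (nrow(x)) pass(x$qual1) else logical(0)
    ok2 <- if (nrow(x)) pass(x$qual2) else logical(0)
    singles1 <- x[ok1 & !ok2, c("id", "seq1", "qual1")]
    singles2 <- x[!ok1 & ok2, c("id", "seq2", "qual2")]
    names(singles1) <- names(singles2) <- c("id", "seq", "qual")
    singletons <- rbind(singles1, singles2)
    rownames(singletons) <- NULL
    list(pairs = x[ok1 & ok2, , drop = FALSE],
         singletons = singletons,
         removed = x[!ok1 & !ok2, , drop = FALSE])
  }
}

# DUST-style low-complexity mask: sliding windows of triplet counts,
# window score 10 * sum c*(c-1)/2 / (k-1); windows scoring above the
# threshold are masked wholesale. Returns a logical mask over positions.
dust_mask <- function(seq, window = 64L, threshold = 20) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(b)
  mask <- rep(FALSE, L)
  if (L < 3) return(mask)
  code <- match(b, c("A", "C", "G", "T")) - 1L
  tri <- code[1:(L - 2)] * 16L + code[2:(L - 1)] * 4L + code[3:L]  # NA if ambig
  w <- min(window, L)
  k <- w - 2L
  counts <- integer(64)
  pairs2 <- 0  # running sum of c*(c-1)/2
  add <- function(t) {
    if (is.na(t)) return(invisible())
    counts[t + 1L] <<- counts[t + 1L] + 1L
    pairs2 <<- pairs2 + counts[t + 1L] - 1L
  }
  drop1 <- function(t) {
    if (is.na(t)) return(invisible())
    pairs2 <<- pairs2 - (counts[t + 1L] - 1L)
    counts[t + 1L] <<- counts[t + 1L] - 1L
  }
  for (t in tri[1:k]) add(t)
  for (start in 1:(L - w + 1L)) {
    score <- 10 * pairs2 / max(k - 1L, 1L)
    if (score > threshold) mask[start:(start + w - 1L)] <- TRUE
    if (start + w <= L) {
      drop1(tri[start])
      add(tri[start + k])
    }
  }
  mask
}

#' Filter low-complexity and ambiguous reads
#'
#' A read is removed when the union of its ambiguous (non-ACGT) positions
#' and the intervals masked by a DUST-style low-complexity scan covers more
#' than `max_masked_fraction` of its length (exactly the boundary passes).
#'
#' @inheritParams filter_quality
#' @param max_masked_fraction maximum tolerated masked+ambiguous fraction.
#' @param dust_window,dust_threshold DUST scan parameters: window size and
#'   score threshold (score is 10 x triplet-pair count / (k-1) per window).
#' @return same shape as [filter_quality()].
#' @export
filter_complexity <- function(x, max_masked_fraction = 0.40,
                              dust_window = 64L, dust_threshold = 20) {
  frac_masked <- function(seq) {
    b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    ambig <- !(b %in% c("A", "C", "G", "T"))
    mask <- dust_mask(seq, dust_window, dust_threshold)
    mean(ambig | mask)
  }
  pass <- function(seqs) {
    vapply(seqs, frac_masked, numeric(1), USE.NAMES = FALSE) <=
      max_masked_fraction
  }
  if ("seq" %in% names(x)) {
    ok <- if (nrow(x)) pass(x$seq) else logical(0)
    list(kept = x[ok, , drop = FALSE], removed = x[!ok, , drop = FALSE])
  } else {
    ok1 <- if (nrow(x)) pass(x$seq1) else logical(0)
    ok2 <- if (nrow(x)) pass(x$seq2) else logical(0)
    singles1 <- x[ok1 & !ok2, c("id", "seq1", "qual1")]
    singles2 <- x[!ok1 & ok2, c("id", "seq2", "qual2")]
    names(singles1) <- names(singles2) <- c("id", "seq", "qual")
    singletons <- rbind(singles1, singles2)
    rownames(singletons) <- NULL
    list(pairs = x[ok1 & ok2, , drop = FALSE],
         singletons = singletons,
         removed = x[!ok1 & !ok2, , drop = FALSE])
  }
}

#' Run the four-step read quality-control pipeline
#'
#' Fixed order: (i) exact-duplicate pair removal, (ii) pair merging with
#' merged and unmerged reads kept, (iii) quality filtering, (iv)
#' low-complexity filtering. Merged reads pass through steps (iii) and (iv)
#' like any other kept read. A pair losing one mate in (iii) or (iv)
#' retains the other mate as a single read.
#'
#' @param pairs data.frame with `id, seq1, qual1, seq2, qual2`.
#' @param min_overlap,max_mismatch_density see [merge_pairs()].
#' @param q_threshold,min_hq_fraction see [filter_quality()].
#' @param max_masked_fraction see [filter_complexity()].
#' @return list with `pairs`, `merged`, `singletons` (kept reads) and
#'   `report`, a one-row data.frame of per-step counts whose removals and
#'   survivors account for every input read.
#' @export
qc_reads <- function(pairs, min_overlap = 10L, max_mismatch_density = 0.25,
                     q_threshold = 30L, min_hq_fraction = 0.80,
                     max_masked_fraction = 0.40) {
  n_in <- nrow(pairs)
  dd <- deduplicate(pairs)
  n_dup <- n_in - nrow(dd)

  mg <- merge_pairs(dd, min_overlap, max_mismatch_density)

  fq_m <- filter_quality(mg$merged, q_threshold, min_hq_fraction)
  fq_p <- filter_quality(mg$pairs, q_threshold, min_hq_fraction)

  fc_m <- filter_complexity(fq_m$kept, max_masked_fraction)
  fc_s <- filter_complexity(fq_p$singletons, max_masked_fraction)
  fc_p <- filter_complexity(fq_p$pairs, max_masked_fraction)

  singletons <- rbind(fc_s$kept, fc_p$singletons)
  rownames(singletons) <- NULL

  # counts are in reads: a merged unit stands for its two input reads
  report <- data.frame(
    input_pairs = n_in,
    duplicate_pairs_removed = n_dup,
    pairs_merged = nrow(mg$merged),
    quality_failed_reads = 2L * nrow(fq_m$removed) + nrow(fq_p$singletons) +
      2L * nrow(fq_p$removed),
    complexity_failed_reads = 2L * nrow(fc_m$removed) + nrow(fc_s$removed) +
      nrow(fc_p$singletons) + 2L * nrow(fc_p$removed),
    kept_merged = nrow(fc_m$kept),
    kept_pairs = nrow(fc_p$pairs),
    kept_singletons = nrow(singletons))

  list(pairs = fc_p$pairs, merged = fc_m$kept, singletons = singletons,
       report = report)
}
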