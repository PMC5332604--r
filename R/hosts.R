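#' Record best same-group and different-group S_G scores
#'
#' For every labeled genome with at least one same-host-group partner and
#' one different-group partner, records the best S_G against each partner
#' class — two scores per eligible genome. Genomes without both partner
#' classes are excluded with a message.
#'
#' @param sg symmetric S_G matrix.
#' @param host_labels named host-group labels for (a subset of) the
#'   genomes.
#' @return data.frame `genome_id, host_group, best_same_group_sg,
#'   best_diff_group_sg`.
#' @export
record_best_scores <- function(sg, host_labels) {
  ids <- intersect(rownames(sg), names(host_labels))
  labs <- host_labels[ids]
  out <- lapply(ids, function(g) {
    same <- ids[labs == labs[[g]] & ids != g]
    diff <- ids[labs != labs[[g]]]
    if (!length(same) || !length(diff)) return(NULL)
    data.frame(genome_id = g, host_group = labs[[g]],
               best_same_group_sg = max(sg[g, same]),
               best_diff_group_sg = max(sg[g, diff]),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped) {
    message(dropped, " genome(s) without both partner classes excluded")
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(0), host_group = character(0),
                      best_same_group_sg = numeric(0),
                      best_diff_group_sg = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Precision curve over sliding S_G cutoffs
#'
#' At each cutoff `t`, TP counts the recorded same-group scores above `t`,
#' FP the different-group scores above `t`, and precision is
#' `TP / (TP + FP)` (NA, not zero, when no score exceeds `t`).
#'
#' @param records output of [record_best_scores()].
#' @param grid cutoff grid; default 0.0001 steps from 0 to the largest
#'   recorded score.
#' @return data.frame `cutoff, tp, fp, precision`.
#' @export
precision_curve <- function(records, grid = NULL) {
  stopifnot(nrow(records) > 0)
  same <- records$best_same_group_sg
  diff <- records$best_diff_group_sg
  grid <- grid %||% seq(0, max(c(same, diff)), by = 1e-4)
  ssame <- sort(same)
  sdiff <- sort(diff)
  tp <- length(same) - findInterval(grid, ssame)   # strictly greater than t
  fp <- length(diff) - findInterval(grid, sdiff)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  data.frame(cutoff = grid, tp = tp, fp = fp, precision = prec)
}

#' Choose an operating cutoff from a precision curve
#'
#' The smallest grid cutoff whose precision strictly exceeds the target
#' and stays above it at every larger cutoff with defined precision.
#'
#' @param curve output of [precision_curve()].
#' @param target_precision required precision (e.g. 0.90 or 0.95).
#' @return the chosen cutoff, or NA (with a warning) when the target is
#'   never sustainably exceeded.
#' @export
choose_cutoff <- function(curve, target_precision) {
  def <- which(!is.na(curve$precision))
  if (!length(def)) {
    warning("no cutoff reaches the target precision")
    return(NA_real_)
  }
  ok <- curve$precision[def] > target_precision
  sustained <- rev(cumprod(rev(ok))) == 1
  if (!any(sustained)) {
    warning("no cutoff reaches the target precision")
    return(NA_real_)
  }
  curve$cutoff[def[which(sustained)[1]]]
}

#' Predict host groups for unlabeled genomes
#'
#' Each unlabeled genome inherits the host group of its best-scoring
#' labeled partner if and only if that S_G strictly exceeds the cutoff;
#' otherwise it stays unpredicted.
#'
#' @param sg symmetric S_G matrix.
#' @param host_labels named host-group labels of the reference genomes.
#' @param cutoff operating S_G cutoff (see [choose_cutoff()]).
#' @param unlabeled genomes to predict (default: all genomes in `sg`
#'   without a label).
#' @return data.frame `genome_id, best_partner, best_sg,
#'   predicted_host_group, predicted`.
#' @export
predict_hosts <- function(sg, host_labels, cutoff, unlabeled = NULL) {
  labeled <- intersect(rownames(sg), names(host_labels))
  unlabeled <- unlabeled %||% setdiff(rownames(sg), labeled)
  out <- lapply(unlabeled, function(g) {
    scores <- sg[g, labeled]
    j <- which.max(scores)
    hit <- scores[[j]] > cutoff
    data.frame(genome_id = g, best_partner = labeled[j],
               best_sg = scores[[j]],
               predicted_host_group = if (hit)
                 unname(host_labels[[labeled[j]]]) else NA_character_,
               predicted = hit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Translate annotated genes to proteins
#'
#' Extracts gene intervals from a genome (reverse-complementing minus
#' strand genes), translates them, and strips the trailing stop.
#'
#' @param genome a single nucleotide sequence.
#' @param genes data.frame with `gene_id, start, end, strand`.
#' @return named [Biostrings::AAStringSet].
#' @export
gene_proteins <- function(genome, genes) {
  seq <- unname(as_seq_chars(genome)[1])
  aa <- vapply(seq_len(nrow(genes)), function(i) {
    g <- substr(seq, genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") g <- revcomp_chr(g)
    n <- nchar(g) - nchar(g) %% 3
    p <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(g, 1, n)), if.fuzzy.codon = "X"))
    sub("\\*$", "", p)
  }, character(1))
  Biostrings::AAStringSet(setNames(aa, genes$gene_id))
}

#' Naive ORF calling
#'
#' Finds open reading frames (ATG to stop, minimum length) on both
#' strands; a stand-in gene caller for genomes without annotations.
#' Overlapping calls in the same frame keep the longest.
#'
#' @param genome a single nucleotide sequence.
#' @param min_codons minimum ORF length in codons (excluding the stop).
#' @return data.frame `gene_id, start, end, strand` in genome coordinates.
#' @export
call_orfs <- function(genome, min_codons = 100L) {
  seq <- toupper(unname(as_seq_chars(genome)[1]))
  L <- nchar(seq)
  find_in <- function(s) {
    # returns ORFs as (start, end) 1-based on s
    out <- list()
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(b)
    cod <- function(i) paste0(b[i], b[i + 1], b[i + 2])
    for (f in 0:2) {
      starts <- integer(0)
      i <- 1 + f
      while (i + 2 <= n) {
        cc <- cod(i)
        if (cc == "ATG" && !length(starts)) starts <- i
        if (cc %in% c("TAA", "TAG", "TGA")) {
          if (length(starts) && (i - starts) / 3 >= min_codons) {
            out[[length(out) + 1L]] <- c(starts, i + 2)
          }
          starts <- integer(0)
        }
        i <- i + 3
      }
    }
    out
  }
  fw <- find_in(seq)
  rv <- find_in(revcomp_chr(seq))
  rows <- c(
    lapply(fw, function(x) data.frame(start = x[1], end = x[2], strand = "+")),
    lapply(rv, function(x) data.frame(start = L - x[2] + 1, end = L - x[1] + 1,
                                      strand = "-")))
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out <- cbind(gene_id = sprintf("orf%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Bidirectional best hits and gene-level colinearity
#'
#' Protein-level orthology between two gene sets: gene pairs that are
#' mutually each other's best-scoring hit with E-value below `evalue_max`
#' (ties broken by longer alignment, then lexicographic id). `B_g` is the
#' percentage of query-genome genes with such an ortholog; 60% or more is
#' interpreted as nearly complete genomic colinearity.
#'
#' @param genes_a,genes_b named protein sets ([Biostrings::AAStringSet] or
#'   character).
#' @param evalue_max BBH E-value threshold.
#' @return list with `map` (data.frame `gene_a, gene_b, bitscore`), `bg`
#'   (percent of `genes_a` with an ortholog) and `colinear`
#'   (`bg >= 60`).
#' @export
bidirectional_best_hits <- function(genes_a, genes_b, evalue_max = 1e-5) {
  a <- as_seq_chars(genes_a)
  b <- as_seq_chars(genes_b)
  if (!length(a) || !length(b)) {
    stop("undefined colinearity: a genome has zero genes")
  }
  best_of <- function(hits) {
    if (!nrow(hits)) return(character(0))
    hits <- hits[order(hits$query, -hits$bitscore, -hits$length,
                       hits$subject), , drop = FALSE]
    hits <- hits[!duplicated(hits$query), , drop = FALSE]
    setNames(hits$subject, hits$query)
  }
  ab <- best_of(blast_search(a, b, mode = "blastp", evalue_max = evalue_max))
  ba <- best_of(blast_search(b, a, mode = "blastp", evalue_max = evalue_max))
  mutual <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  map <- data.frame(gene_a = mutual, gene_b = unname(ab[mutual]),
                    stringsAsFactors = FALSE)
  bg <- 100 * nrow(map) / length(a)
  list(map = map, bg = bg, colinear = bg >= 60)
}
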