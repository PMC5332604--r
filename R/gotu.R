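#' Delineate genomic OTUs at an S_G cutoff
#'
#' Average-linkage (UPGMA-style) agglomeration on the distance `1 - S_G`,
#' cut at height `1 - cutoff`: members of a cluster are linked at average
#' S_G of at least the cutoff. Cutoff 0.15 approximates viral genera.
#'
#' @param sg symmetric S_G matrix.
#' @param cutoff S_G cutoff in (0, 1).
#' @return named integer vector of cluster ids (a partition).
#' @export
average_linkage_cluster <- function(sg, cutoff) {
  stopifnot(cutoff > 0, cutoff < 1)
  hc <- stats::hclust(stats::as.dist(to_distance(sg)), method = "average")
  stats::cutree(hc, h = 1 - cutoff)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 0 in expectation for independent random
#' partitions, 1 for identical ones.
#'
#' @param p1,p2 named cluster-assignment vectors over the same items.
#' @return the adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (is.null(names(p1)) || is.null(names(p2)) ||
      !setequal(names(p1), names(p2))) {
    stop("partitions must be named over the same item set")
  }
  p2 <- p2[names(p1)]
  tab <- table(p1, p2)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expct <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expct
  if (denom == 0) return(1)  # both partitions trivial and identical
  (sij - expct) / denom
}

#' Scan S_G cutoffs against a reference classification
#'
#' Clusters the genomes at every cutoff on a grid (default 0.01 steps) and
#' scores the induced partition of the labeled subset against the
#' reference partition with the adjusted Rand index. The cutoff with the
#' highest ARI (ties: smallest cutoff) is the operating genus-level
#' cutoff.
#'
#' @param sg symmetric S_G matrix.
#' @param truth_partition named reference labels (e.g. genus names) for a
#'   subset of the genomes; needs at least two distinct labels.
#' @param grid cutoff grid.
#' @return list of class `cutoff_evaluation`: `evaluation` (data.frame
#'   cutoff, ari), `best_cutoff`, `best_ari`, `best_partition` (labeled
#'   subset at the best cutoff).
#' @export
scan_cutoffs <- function(sg, truth_partition, grid = seq(0.01, 0.99, by = 0.01)) {
  labeled <- intersect(rownames(sg), names(truth_partition))
  if (length(unique(truth_partition[labeled])) < 2) {
    stop("need at least two labeled reference classes")
  }
  hc <- stats::hclust(stats::as.dist(to_distance(sg)), method = "average")
  cuts <- stats::cutree(hc, h = 1 - grid)  # one column per cutoff
  ari <- vapply(seq_along(grid), function(k) {
    adjusted_rand_index(cuts[labeled, k], truth_partition[labeled])
  }, numeric(1))
  best <- which.max(ari)  # first maximum = smallest cutoff on ties
  structure(list(
    evaluation = data.frame(cutoff = grid, ari = ari),
    best_cutoff = grid[best],
    best_ari = ari[best],
    best_partition = cuts[labeled, best]
  ), class = "cutoff_evaluation")
}

#' Chao1 richness estimate
#'
#' Bias-corrected Chao1, `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, from the
#' singleton (`f1`) and doubleton (`f2`) cluster counts; the classical
#' form `S_obs + f1^2 / (2 f2)` is available when `f2 > 0`.
#'
#' @param cluster_sizes nonnegative cluster sizes (genomes per gOTU).
#' @param bias_corrected use the bias-corrected form (default).
#' @return list `S_obs, f1, f2, chao1`.
#' @export
chao1 <- function(cluster_sizes, bias_corrected = TRUE) {
  stopifnot(all(cluster_sizes >= 0))
  sizes <- cluster_sizes[cluster_sizes > 0]
  s_obs <- length(sizes)
  f1 <- sum(sizes == 1)
  f2 <- sum(sizes == 2)
  est <- if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
  list(S_obs = s_obs, f1 = f1, f2 = f2, chao1 = est)
}

# analytic expected richness at subsample size m (hypergeometric)
rarefy_expected <- function(sizes, m) {
  n <- sum(sizes)
  vapply(m, function(mm) {
    miss <- exp(lchoose(n - sizes, mm) - lchoose(n, mm))
    sum(1 - miss)
  }, numeric(1))
}

#' Rarefaction curve with bootstrap confidence band
#'
#' Expected number of distinct clusters in a random subsample of `m`
#' genomes, `E[S_m] = sum_k (1 - C(n - n_k, m) / C(n, m))`, with a
#' percentile confidence band from bootstrap resampling of genomes
#' (default 100 replicates, 95%).
#'
#' @param assignments cluster id per genome (vector; names optional).
#' @param sizes subsample sizes (default every size up to n).
#' @param n_boot bootstrap replicates.
#' @param ci confidence level.
#' @return data.frame `m, expected, lower, upper`.
#' @export
rarefaction <- function(assignments, sizes = NULL, n_boot = 100, ci = 0.95) {
  stopifnot(length(assignments) >= 1)
  counts <- as.numeric(table(assignments))
  n <- sum(counts)
  sizes <- sizes %||% seq_len(n)
  expected <- rarefy_expected(counts, sizes)
  boot <- replicate(n_boot, {
    res <- sample(assignments, n, replace = TRUE)
    rarefy_expected(as.numeric(table(res)), sizes)
  })
  if (is.null(dim(boot))) boot <- matrix(boot, nrow = 1)
  alpha <- (1 - ci) / 2
  data.frame(m = sizes, expected = expected,
             lower = apply(boot, 1, quantile, probs = alpha),
             upper = apply(boot, 1, quantile, probs = 1 - alpha))
}

#' Cluster composition by source label
#'
#' Categorizes each cluster by the set of source labels of its members
#' (e.g. environmental vs reference genomes): single-label clusters are
#' `<label>-only`, mixed clusters are `shared`. Shares are reported both
#' by cluster count and by genome count.
#'
#' @param partition named cluster ids.
#' @param source_labels named source label per genome.
#' @return data.frame `category, clusters, genomes, share_by_cluster,
#'   share_by_genome`.
#' @export
composition <- function(partition, source_labels) {
  if (!all(names(partition) %in% names(source_labels))) {
    stop("every genome must have a source label")
  }
  labs <- source_labels[names(partition)]
  cat_of <- vapply(split(labs, partition), function(x) {
    u <- sort(unique(x))
    if (length(u) == 1) paste0(u, "-only") else "shared"
  }, character(1))
  genome_cat <- cat_of[as.character(partition)]
  cats <- sort(unique(cat_of))
  out <- data.frame(
    category = cats,
    clusters = as.integer(table(factor(cat_of, cats))),
    genomes = as.integer(table(factor(genome_cat, cats))))
  out$share_by_cluster <- out$clusters / sum(out$clusters)
  out$share_by_genome <- out$genomes / sum(out$genomes)
  out
}
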