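#' Specify a synthetic viral community
#'
#' A community is a set of genus-structured dsDNA viral genomes: one
#' ancestral genome per genus, descendants derived by point substitution.
#' Genera descend from a common community root so that between-genus
#' divergence is controlled rather than saturated. All planted structure
#' (genus labels, host groups, gene coordinates, redundant near-copies) is
#' recorded in a truth table, so downstream stages can be scored against
#' known labels.
#'
#' @param n_genera number of viral genera.
#' @param genomes_per_genus genomes generated per genus.
#' @param genome_length_bp length-2 numeric range (bp); each genus draws its
#'   genome length uniformly from this range. Defaults to 15--60 kb, the
#'   size regime of complete dsDNA virus genomes passing a 10-kb catalog
#'   filter.
#' @param gc_fraction target G+C fraction of the root genome.
#' @param within_genus_divergence expected substitutions/site separating a
#'   genome from its genus ancestor.
#' @param between_genus_divergence expected substitutions/site separating
#'   two genus ancestors (each ancestor receives half this divergence from
#'   the community root).
#' @param gene_density genes per kb placed on the root as non-overlapping
#'   ORFs (start codon, stop-free body, stop codon) on either strand.
#' @param genera_per_host_group consecutive genera sharing one host-group
#'   label (1 = one host group per genus).
#' @param n_redundant_pairs number of genomes additionally emitted as a
#'   near-identical copy (a planted redundant pair).
#' @param redundant_divergence substitutions/site separating a planted
#'   redundant copy from its original (default 0.02, i.e. ~98% identity,
#'   inside the >=95% redundancy rule).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(n_genera,
                           genomes_per_genus,
                           genome_length_bp = c(15000, 60000),
                           gc_fraction = 0.45,
                           within_genus_divergence = 0.05,
                           between_genus_divergence = 0.5,
                           gene_density = 0.7,
                           genera_per_host_group = 1,
                           n_redundant_pairs = 0,
                           redundant_divergence = 0.02,
                           seed = 1) {
  stopifnot(n_genera >= 1, genomes_per_genus >= 1,
            length(genome_length_bp) == 2,
            genome_length_bp[1] >= 300,
            genome_length_bp[1] <= genome_length_bp[2],
            gc_fraction > 0, gc_fraction < 1,
            within_genus_divergence >= 0,
            gene_density >= 0, genera_per_host_group >= 1,
            n_redundant_pairs >= 0)
  if (within_genus_divergence >= between_genus_divergence) {
    stop("within_genus_divergence must be smaller than between_genus_divergence")
  }
  structure(list(
    n_genera = as.integer(n_genera),
    genomes_per_genus = as.integer(genomes_per_genus),
    genome_length_bp = as.integer(genome_length_bp),
    gc_fraction = gc_fraction,
    within_genus_divergence = within_genus_divergence,
    between_genus_divergence = between_genus_divergence,
    gene_density = gene_density,
    genera_per_host_group = as.integer(genera_per_host_group),
    n_redundant_pairs = as.integer(n_redundant_pairs),
    redundant_divergence = redundant_divergence,
    seed = as.integer(seed)
  ), class = "community_spec")
}

# random sequence with a target GC fraction
random_genome <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# point substitutions: each site mutates to a different base with prob d
mutate_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < d)
  if (length(hit)) {
    alt <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

# sample a codon sequence (no stop codons) of n codons
random_orf <- function(n_codons) {
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(codons, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

# place non-overlapping ORFs on seq; returns list(seq, genes data.frame)
place_genes <- function(seq, density) {
  len <- nchar(seq)
  n_target <- max(1L, round(density * len / 1000))
  placed <- IRanges::IRanges()
  genes <- list()
  attempts <- 0L
  while (length(genes) < n_target && attempts < n_target * 20L) {
    attempts <- attempts + 1L
    n_codons <- sample(150:400, 1)
    glen <- 3L * (n_codons + 2L)
    if (glen + 2 > len) next
    start <- sample.int(len - glen + 1L, 1)
    cand <- IRanges::IRanges(start = start, width = glen)
    if (length(placed) && any(IRanges::overlapsAny(cand, placed))) next
    placed <- c(placed, cand)
    strand <- sample(c("+", "-"), 1)
    orf <- random_orf(n_codons)
    ins <- if (strand == "+") orf else revcomp_chr(orf)
    substr(seq, start, start + glen - 1L) <- ins
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = sprintf("gene%03d", length(genes) + 1L),
      start = start, end = start + glen - 1L, strand = strand,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes <- genes[order(genes$start), , drop = FALSE]
  genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  list(seq = seq, genes = genes)
}

#' Generate a genus-structured synthetic viral community
#'
#' Builds a community root genome carrying non-overlapping ORFs, derives one
#' ancestor per genus at half the between-genus divergence, and emits
#' `genomes_per_genus` descendants per genus at the within-genus divergence.
#' Optionally appends near-identical copies of chosen genomes as planted
#' redundant pairs.
#'
#' @param spec a [community_spec()].
#' @return a list of class `evg_community` with elements:
#'   * `genomes`: named [Biostrings::DNAStringSet] of generated genomes;
#'   * `truth`: list with `genomes` (genome_id, genus, host_group, length),
#'     `genes` (per-genome gene coordinates inherited by descent), and
#'     `redundant_pairs` (id_a, id_b) for planted near-copies.
#' @examples
#' cm <- generate_community(community_spec(3, 4, c(5000, 8000), seed = 7))
#' length(cm$genomes)   # 12
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)

  lens <- spec$genome_length_bp[1] +
    sample.int(spec$genome_length_bp[2] - spec$genome_length_bp[1] + 1L,
               spec$n_genera, replace = TRUE) - 1L
  root_len <- max(lens)
  root <- random_genome(root_len, spec$gc_fraction)
  rooted <- place_genes(root, spec$gene_density)
  root <- rooted$seq
  root_genes <- rooted$genes

  genomes <- character(0)
  info <- list()
  genes <- list()
  for (g in seq_len(spec$n_genera)) {
    anc <- substr(mutate_seq(root, spec$between_genus_divergence / 2),
                  1, lens[g])
    ggenes <- root_genes[root_genes$end <= lens[g], , drop = FALSE]
    host <- sprintf("H%03d", (g - 1L) %/% spec$genera_per_host_group + 1L)
    for (k in seq_len(spec$genomes_per_genus)) {
      id <- sprintf("G%03d_v%02d", g, k)
      genomes[[id]] <- mutate_seq(anc, spec$within_genus_divergence)
      info[[id]] <- data.frame(genome_id = id,
                               genus = sprintf("genus%03d", g),
                               host_group = host,
                               length = lens[g],
                               stringsAsFactors = FALSE)
      if (nrow(ggenes)) {
        genes[[id]] <- cbind(data.frame(genome_id = id,
                                        stringsAsFactors = FALSE), ggenes)
      }
    }
  }

  redundant <- data.frame(id_a = character(0), id_b = character(0),
                          stringsAsFactors = FALSE)
  if (spec$n_redundant_pairs > 0) {
    origin <- sample(names(genomes),
                     min(spec$n_redundant_pairs, length(genomes)))
    for (id in origin) {
      dup_id <- paste0(id, "_dup")
      genomes[[dup_id]] <- mutate_seq(genomes[[id]],
                                      spec$redundant_divergence)
      row <- info[[id]]
      row$genome_id <- dup_id
      info[[dup_id]] <- row
      if (!is.null(genes[[id]])) {
        gd <- genes[[id]]
        gd$genome_id <- dup_id
        genes[[dup_id]] <- gd
      }
      redundant <- rbind(redundant,
                         data.frame(id_a = id, id_b = dup_id,
                                    stringsAsFactors = FALSE))
    }
  }

  truth_genomes <- do.call(rbind, info)
  rownames(truth_genomes) <- NULL
  truth_genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(genome_id = character(0), gene_id = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  rownames(truth_genes) <- NULL

  structure(list(
    genomes = Biostrings::DNAStringSet(unlist(genomes)),
    truth = list(genomes = truth_genomes,
                 genes = truth_genes,
                 redundant_pairs = redundant)
  ), class = "evg_community")
}

#' Turn a genome into a circular-assembly artifact
#'
#' Assemblers emit circular genomes as linear contigs whose 3' end repeats
#' the 5' start. This helper rotates the genome (circular genomes have no
#' defined origin) and appends the first `repeat_bp` bases to the 3' end,
#' creating the terminal repeat that [detect_circular()] looks for.
#'
#' @param genome a single sequence (character or [Biostrings::DNAString]).
#' @param repeat_bp terminal repeat length; must be smaller than the genome.
#' @param rotate rotation offset in bp applied before appending the repeat
#'   (0 = none).
#' @return the artifact contig as a character string.
#' @export
make_circular_artifact <- function(genome, repeat_bp, rotate = 0L) {
  seq <- unname(as_seq_chars(genome)[1])
  len <- nchar(seq)
  if (repeat_bp >= len) stop("repeat_bp must be smaller than the genome length")
  if (repeat_bp < 1) stop("repeat_bp must be positive")
  rotate <- as.integer(rotate) %% len
  if (rotate > 0) {
    seq <- paste0(substr(seq, rotate + 1L, len), substr(seq, 1L, rotate))
  }
  paste0(seq, substr(seq, 1L, repeat_bp))
}

#' Specify paired-end read simulation
#'
#' Emulates shotgun sequencing of a viral community on a short-read
#' instrument: uniform fragment sampling (wrapping the origin for circular
#' genomes), per-base substitution errors, position-dependent Phred
#' qualities, and exact duplicate pairs.
#'
#' @param read_length read length in bp (default 150, a common paired-end
#'   instrument configuration).
#' @param insert_mean,insert_sd fragment (insert) size distribution in bp.
#' @param coverage target fold coverage per genome.
#' @param per_base_error substitution error probability per base.
#' @param duplicate_fraction fraction of unique pairs re-emitted as exact
#'   duplicates.
#' @param quality_mean,quality_decay,quality_sd Phred quality model: mean
#'   quality at the first cycle, linear decay over the read, and Gaussian
#'   spread. Qualities are clipped to \[2, 41\].
#' @param seed integer seed.
#' @return an object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_length = 150L,
                          insert_mean = 400,
                          insert_sd = 40,
                          coverage = 50,
                          per_base_error = 0.005,
                          duplicate_fraction = 0,
                          quality_mean = 38,
                          quality_decay = 5,
                          quality_sd = 3,
                          seed = 1L) {
  stopifnot(read_length >= 20, coverage > 0,
            per_base_error >= 0, per_base_error <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            insert_mean >= read_length)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, per_base_error = per_base_error,
                 duplicate_fraction = duplicate_fraction,
                 quality_mean = quality_mean, quality_decay = quality_decay,
                 quality_sd = quality_sd, seed = as.integer(seed)),
            class = "read_sim_spec")
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(b)) < rate)
    if (length(hit)) {
      b[hit] <- vapply(b[hit], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1)
      }, character(1), USE.NAMES = FALSE)
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sim_quals <- function(n, rl, sim) {
  mu <- sim$quality_mean - sim$quality_decay * (seq_len(rl) - 1) / (rl - 1)
  q <- matrix(round(rnorm(n * rl, mean = rep(mu, each = n),
                          sd = sim$quality_sd)), nrow = n)
  q <- pmin(pmax(q, 2L), 41L)
  vapply(seq_len(n), function(i) ints_phred(q[i, ]), character(1))
}

#' Simulate paired-end reads from a genome set
#'
#' @param genomes named sequences ([Biostrings::DNAStringSet] or character).
#' @param sim a [read_sim_spec()].
#' @param snps optional planted polymorphism: data.frame with columns
#'   `genome_id`, `pos`, `alt` (base), `freq` (allele frequency); each
#'   fragment covering `pos` carries `alt` with probability `freq`.
#' @param circular character vector of genome ids whose fragments may wrap
#'   the origin.
#' @return list with `pairs` (data.frame: id, seq1, qual1, seq2, qual2) and
#'   `truth` (list: `origins` with genome/start/insert per unique pair,
#'   `snps` as supplied, `n_unique`, `n_duplicated`).
#' @export
simulate_reads <- function(genomes, sim, snps = NULL, circular = character()) {
  stopifnot(inherits(sim, "read_sim_spec"))
  set.seed(sim$seed)
  seqs <- as_seq_chars(genomes)
  rl <- sim$read_length

  all_pairs <- list()
  origins <- list()
  for (id in names(seqs)) {
    len <- nchar(seqs[[id]])
    n_pairs <- round(sim$coverage * len / (2 * rl))
    if (n_pairs < 1) {
      warning("coverage implies zero read pairs for genome ", id)
      next
    }
    ins <- pmax(rl, pmin(round(rnorm(n_pairs, sim$insert_mean, sim$insert_sd)),
                         len))
    is_circ <- id %in% circular
    src <- if (is_circ) paste0(seqs[[id]], substr(seqs[[id]], 1, max(ins)))
           else seqs[[id]]
    start_max <- if (is_circ) len else pmax(1L, len - ins + 1L)
    starts <- if (is_circ) sample.int(len, n_pairs, replace = TRUE) else
      vapply(start_max, function(m) sample.int(m, 1), integer(1))
    frags <- substring(src, starts, starts + ins - 1L)

    # planted polymorphism, applied per fragment before errors
    if (!is.null(snps) && nrow(snps)) {
      gs <- snps[snps$genome_id == id, , drop = FALSE]
      for (r in seq_len(nrow(gs))) {
        pos <- gs$pos[r]
        cover <- which(starts <= pos & starts + ins - 1L >= pos)
        if (is_circ) {
          wrapped <- which(starts + ins - 1L >= pos + len)
          cover <- union(cover, wrapped)
        }
        if (!length(cover)) next
        carry <- cover[runif(length(cover)) < gs$freq[r]]
        for (i in carry) {
          off <- pos - starts[i] + 1L
          if (off < 1L) off <- off + len
          if (off >= 1L && off <= ins[i]) substr(frags[i], off, off) <- gs$alt[r]
        }
      }
    }

    fwd <- substr(frags, 1L, rl)
    rev <- revcomp_chr(substring(frags, ins - rl + 1L, ins))
    all_pairs[[id]] <- data.frame(
      id = sprintf("%s_p%06d", id, seq_len(n_pairs)),
      seq1 = fwd, seq2 = rev, stringsAsFactors = FALSE)
    origins[[id]] <- data.frame(
      id = all_pairs[[id]]$id, genome_id = id, start = starts,
      insert = ins, stringsAsFactors = FALSE)
  }
  if (!length(all_pairs)) {
    pairs <- data.frame(id = character(0), seq1 = character(0),
                        qual1 = character(0), seq2 = character(0),
                        qual2 = character(0))
    return(list(pairs = pairs,
                truth = list(origins = NULL, snps = snps,
                             n_unique = 0L, n_duplicated = 0L)))
  }
  pairs <- do.call(rbind, all_pairs)
  rownames(pairs) <- NULL
  n_unique <- nrow(pairs)

  pairs$seq1 <- inject_errors(pairs$seq1, sim$per_base_error)
  pairs$seq2 <- inject_errors(pairs$seq2, sim$per_base_error)
  pairs$qual1 <- sim_quals(n_unique, rl, sim)
  pairs$qual2 <- sim_quals(n_unique, rl, sim)

  n_dup <- round(sim$duplicate_fraction * n_unique)
  if (n_dup > 0) {
    dup <- pairs[sample.int(n_unique, n_dup, replace = TRUE), , drop = FALSE]
    dup$id <- paste0(dup$id, "_dup", seq_len(n_dup))
    pairs <- rbind(pairs, dup)
    rownames(pairs) <- NULL
  }
  pairs <- pairs[, c("id", "seq1", "qual1", "seq2", "qual2")]

  list(pairs = pairs,
       truth = list(origins = do.call(rbind, origins),
                    snps = snps,
                    n_unique = n_unique, n_duplicated = n_dup))
}
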