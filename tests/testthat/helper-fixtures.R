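# Small shared fixtures, built in code at load time.

# compact genus-structured community reused across files
fix_community <- generate_community(
  community_spec(n_genera = 3, genomes_per_genus = 3,
                 genome_length_bp = c(4000, 6000),
                 within_genus_divergence = 0.05,
                 between_genus_divergence = 0.5,
                 seed = 101))

fix_sg <- sg_matrix(fix_community$genomes)

fix_truth_genus <- setNames(fix_community$truth$genomes$genus,
                            fix_community$truth$genomes$genome_id)

# a random coding genome (single sequence, character)
random_coding_genome <- function(len, seed) {
  cm <- generate_community(community_spec(1, 1, c(len, len), seed = seed))
  setNames(as.character(cm$genomes), "g1")
}

# read pair table from explicit sequences, constant quality
make_pairs <- function(seq1, seq2, q = 40L, ids = NULL) {
  qual <- function(s) vapply(nchar(s), function(n) {
    paste(rep(intToUtf8(q + 33L), n), collapse = "")
  }, character(1))
  data.frame(id = ids %||% sprintf("p%d", seq_along(seq1)),
             seq1 = seq1, qual1 = qual(seq1),
             seq2 = seq2, qual2 = qual(seq2),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# quality string helper
qstr <- function(q) intToUtf8(q + 33L, multiple = FALSE)
qual_of <- function(qs) paste(vapply(qs, function(q) intToUtf8(q + 33L),
                                     character(1)), collapse = "")
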