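## shared internal helpers

# accept DNAStringSet / DNAString / character, return named character vector
as_seq_chars <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (methods::is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq1"
  } else {
    nm <- names(x)
    out <- as.character(x)
    names(out) <- nm
  }
  if (!length(out)) return(out)
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 string -> integer vector
phred_ints <- function(qual) {
  utf8ToInt(qual) - 33L
}

ints_phred <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
}

# fraction of positions with quality strictly above threshold
hq_fraction <- function(qual, q_threshold = 30L) {
  q <- phred_ints(qual)
  mean(q > q_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
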