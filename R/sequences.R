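# Low-level sequence helpers shared across modules. Sequences are stored as
# single upper-case strings over {A,C,G,T,N}; coordinate arithmetic is 1-based
# and closed, matching the IRanges/GenomicRanges convention used throughout R.

DNA_BASES <- c("A", "C", "G", "T")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character strings (N allowed).
#'
#' @param x A DNA string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement of a character vector of bases (no reversal)
comp_chars <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[x])
}

check_dna <- function(x, what = "sequence") {
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N}: '%s'. Ambiguity codes other than N are rejected.",
      what, substr(bad, 1, 10)
    ))
  }
  invisible(x)
}

random_dna <- function(n, base_freqs = rep(0.25, 4)) {
  chars_seq(sample(DNA_BASES, n, replace = TRUE, prob = base_freqs))
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}
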