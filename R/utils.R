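# Internal sequence helpers shared across modules.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the annotator; the
#' empty string maps to itself.
#'
#' @param x A character vector of DNA strings (A/C/G/T/N, uppercase).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(DNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Standard genetic code, DNA alphabet, stop = "*".
codon_table <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
}

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "X"
)

aa_three <- function(aa1) {
  unname(AA_THREE[strsplit(aa1, "", fixed = TRUE)[[1]]])
}

# Translate an in-frame DNA string with the standard code; stop codons are "*".
# Codons containing N translate to "X"-free "?" never occurs in fixtures; they
# become NA and are treated as unknown.
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n < 3L) return("")
  n <- n - n %% 3L
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Longest common prefix / suffix lengths of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  neq <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

common_suffix_len <- function(a, b) {
  common_prefix_len(stringi_rev(a), stringi_rev(b))
}

stringi_rev <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
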