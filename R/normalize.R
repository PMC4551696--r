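# Allele canonicalization: trimming, left/right alignment against the
# reference, and enumeration of equivalent indel representations.
#
# A variant is held as a trimmed ("minimal") allele pair:
#   substitution  ref/alt both length 1
#   deletion      alt == "", pos = first deleted base
#   insertion     ref == "", pos = base AFTER which the sequence is inserted
#   complex       both non-empty, length-changing or MNV; never shifted

#' Construct a genomic variant
#'
#' Alleles must already be trimmed (see [trim_alleles()]).
#'
#' @param chrom Contig. @param pos Position (see conventions above).
#' @param ref,alt Trimmed allele strings (one may be empty).
#' @param qual,filter Optional echo fields.
#' @return A `gvariant` list with derived `vtype`.
#' @export
gvariant <- function(chrom, pos, ref, alt, qual = NA, filter = NA) {
  if (!nzchar(ref) && !nzchar(alt)) stop("ref and alt both empty", call. = FALSE)
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 qual = qual, filter = filter,
                 vtype = variant_type(ref, alt)),
            class = "gvariant")
}

variant_type <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "substitution"
  else if (!nzchar(ref)) "insertion"
  else if (!nzchar(alt)) "deletion"
  else "complex"
}

variant_identical <- function(a, b) {
  a$chrom == b$chrom && a$pos == b$pos && a$ref == b$ref && a$alt == b$alt
}

#' Trim an allele pair to its minimal representation
#'
#' Removes the longest common suffix first, then the longest common prefix
#' (advancing `pos` for each prefix base). Suffix-first keeps the leftmost
#' breakpoint for VCF anchor-base alleles; normalization re-shifts afterwards,
#' so any fixed order would do — this one is fixed for determinism.
#'
#' @param ref,alt Allele strings. @param pos Position of the first ref base.
#' @return List `(ref, alt, pos)`; for pure insertions `pos` is the base
#'   after which the insertion occurs.
#' @export
trim_alleles <- function(ref, alt, pos) {
  if (ref == alt) stop("not a variant: ref == alt", call. = FALSE)
  # suffix removal keeps at least one character in the shorter allele, so the
  # anchor base is consumed by the prefix stage (advancing pos)
  ns <- max(0L, min(common_suffix_len(ref, alt), nchar(ref) - 1L, nchar(alt) - 1L))
  ref2 <- substr(ref, 1L, nchar(ref) - ns)
  alt2 <- substr(alt, 1L, nchar(alt) - ns)
  np <- min(common_prefix_len(ref2, alt2), max(nchar(ref2), nchar(alt2)))
  ref3 <- substr(ref2, np + 1L, nchar(ref2))
  alt3 <- substr(alt2, np + 1L, nchar(alt2))
  pos3 <- pos + np
  if (!nzchar(ref3)) pos3 <- pos3 - 1L  # pure insertion: anchor to base before
  list(ref = ref3, alt = alt3, pos = as.integer(pos3))
}

#' Apply a variant to a contig sequence
#'
#' String-edit oracle used by the equivalence machinery and by tests.
#'
#' @param seq Contig sequence. @param v A `gvariant` (trimmed conventions).
#' @return The edited sequence.
#' @export
apply_variant <- function(seq, v) {
  n <- nchar(seq)
  if (v$vtype == "insertion") {
    paste0(substr(seq, 1L, v$pos), v$alt, substr(seq, v$pos + 1L, n))
  } else {
    paste0(substr(seq, 1L, v$pos - 1L), v$alt,
           substr(seq, v$pos + nchar(v$ref), n))
  }
}

rotl <- function(s) paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L))
rotr <- function(s) paste0(substr(s, nchar(s), nchar(s)), substr(s, 1L, nchar(s) - 1L))

# Hard cap on how far an indel may be slid (degenerate repeat tracts must
# terminate); beyond this the extreme reached so far is returned.
MAX_SHIFT <- 10000L

#' Slide an indel to its extreme equivalent position
#'
#' Pure insertions and deletions are moved base-by-base through their repeat
#' context; substitutions and complex variants are immobile and returned
#' unchanged. Applying the result to the reference yields the same edited
#' sequence as the input.
#'
#' @param v A `gvariant`. @param reference A `ref_genome`.
#' @param direction `"left"` (most 5' on the forward strand) or `"right"`.
#' @return The shifted `gvariant`.
#' @export
shift_variant <- function(v, reference, direction = c("left", "right")) {
  direction <- match.arg(direction)
  if (!v$vtype %in% c("insertion", "deletion")) return(v)
  ctg <- resolve_contig(reference, v$chrom)
  seq <- reference$seqs[[ctg]]
  len <- nchar(seq)
  p <- v$pos
  if (v$vtype == "insertion") {
    s <- v$alt
    k <- nchar(s)
    steps <- 0L
    if (direction == "right") {
      while (p + 1L <= len && substr(seq, p + 1L, p + 1L) == substr(s, 1L, 1L) &&
             steps < MAX_SHIFT) {
        p <- p + 1L; s <- rotl(s); steps <- steps + 1L
      }
    } else {
      while (p >= 1L && substr(seq, p, p) == substr(s, k, k) && steps < MAX_SHIFT) {
        s <- rotr(s); p <- p - 1L; steps <- steps + 1L
      }
    }
    out <- v; out$pos <- p; out$alt <- s
    return(out)
  }
  # deletion of s at p..q
  s <- v$ref
  L <- nchar(s)
  q <- p + L - 1L
  steps <- 0L
  if (direction == "right") {
    while (q + 1L <= len && substr(seq, q + 1L, q + 1L) == substr(s, 1L, 1L) &&
           steps < MAX_SHIFT) {
      p <- p + 1L; q <- q + 1L; s <- rotl(s); steps <- steps + 1L
    }
  } else {
    while (p - 1L >= 1L && substr(seq, p - 1L, p - 1L) == substr(s, L, L) &&
           steps < MAX_SHIFT) {
      p <- p - 1L; q <- q - 1L; s <- rotr(s); steps <- steps + 1L
    }
  }
  out <- v; out$pos <- p; out$ref <- s
  out
}

#' Enumerate all equivalent representations of a variant
#'
#' Slides an indel between its left- and right-shifted extremes, collecting
#' every placement; all members applied to the reference give the identical
#' edited sequence (the defining equivalence). Substitutions and complex
#' variants have a single representation.
#'
#' @param v A `gvariant`. @param reference A `ref_genome`.
#' @return List with `members` (list of `gvariant`s ordered left to right),
#'   `most_5prime`, `most_3prime_forward` (the genomic-right extreme) and
#'   `has_alternatives`.
#' @export
enumerate_representations <- function(v, reference) {
  if (!v$vtype %in% c("insertion", "deletion")) {
    return(list(members = list(v), most_5prime = v, most_3prime_forward = v,
                has_alternatives = FALSE))
  }
  left <- shift_variant(v, reference, "left")
  right <- shift_variant(v, reference, "right")
  members <- list(left)
  cur <- left
  while (cur$pos < right$pos) {
    nxt <- cur
    nxt$pos <- cur$pos + 1L
    if (v$vtype == "insertion") nxt$alt <- rotl(cur$alt) else nxt$ref <- rotl(cur$ref)
    members[[length(members) + 1L]] <- nxt
    cur <- nxt
  }
  list(members = members, most_5prime = left, most_3prime_forward = right,
       has_alternatives = length(members) > 1L)
}

#' Normalize a variant for a specific transcript
#'
#' The canonical representation is the most 3' placement in the coding
#' transcript: genomic-right for "+" transcripts and genomic-left for "-"
#' ones. The opposite extreme (most 5' in the transcript) is returned as the
#' alternative when it differs.
#'
#' @param v A `gvariant`. @param tx A `transcript`.
#' @param reference A `ref_genome`.
#' @return List `(canonical, alt5)`; `alt5` is `NULL` when the variant has a
#'   single representation.
#' @export
normalize_for_transcript <- function(v, tx, reference) {
  if (!v$vtype %in% c("insertion", "deletion")) {
    return(list(canonical = v, alt5 = NULL))
  }
  canonical <- shift_variant(v, reference,
                             if (tx$strand == "+") "right" else "left")
  alt5 <- shift_variant(v, reference,
                        if (tx$strand == "+") "left" else "right")
  if (variant_identical(canonical, alt5)) alt5 <- NULL
  list(canonical = canonical, alt5 = alt5)
}
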