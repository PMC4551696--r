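# Single-class variant ontology, Sequence Ontology terms and impact levels.
#
# Classes in priority order (a variant gets the FIRST class whose predicate
# holds; exactly one class per variant x transcript):
#   SG   stop-gain caused by base substitution
#   ESS  alters an essential splice-site base (+1, +2, -1, -2)
#   SS5  alters the +5 splice-site base (not an ESS base)
#   SS   alters a splice-site base within the first 8 intronic bases
#        flanking an exon (+8 to -8), not ESS/SS5
#   EE   alters the first or last 3 bases of an exon without changing the
#        frame of the coding sequence
#   FS   frameshifting insertion/deletion (alters length AND frame of CDS)
#   IM   alters the initiating methionine codon
#   SL   the stop codon is altered (and no longer encodes a stop)
#   IF   inframe insertion/deletion (alters CDS length, frame preserved)
#   NSY  nonsynonymous (missense) substitution
#   SY   synonymous substitution
#   INT  intronic, no splice-site base altered
#   5PU  5' untranslated region
#   3PU  3' untranslated region

CLASS_ORDER <- c("SG", "ESS", "SS5", "SS", "EE", "FS", "IM", "SL", "IF",
                 "NSY", "SY", "INT", "5PU", "3PU")

IMPACT_MAP <- c(ESS = 1L, FS = 1L, SG = 1L,
                NSY = 2L, SS5 = 2L, IF = 2L, IM = 2L, SL = 2L, EE = 2L,
                SY = 3L, SS = 3L, INT = 3L, `5PU` = 3L, `3PU` = 3L)

# Positional context of a canonical variant within a transcript: which intron
# offsets and exon-end bases it alters, and where its bases fall.
#
# Overlap semantics ("alters"):
#   substitutions / deletions / complex: interval intersection with the set;
#   insertions: a plain insertion alters a set only when BOTH flanking bases
#   of its breakpoint are in the set; an insertion that duplicates the
#   immediately 5' reference copy uses that copy as its affected interval.
variant_context <- function(tx, v, reference) {
  fwd <- tx$strand == "+"
  cp_of <- function(g) tryCatch(genomic_to_coding(tx, g), error = function(e) NULL)

  if (v$vtype == "insertion") {
    ins_t <- if (fwd) v$alt else reverse_complement(v$alt)
    k <- nchar(ins_t)
    dup_lo <- if (fwd) v$pos - k + 1L else v$pos + 1L
    dup_hi <- if (fwd) v$pos else v$pos + k
    ctg <- resolve_contig(reference, tx$chrom)
    is_dup <- dup_lo >= 1L && dup_hi <= reference$lengths[[ctg]] &&
      identical(segment_tx(tx, reference, dup_lo, dup_hi), ins_t)
    if (is_dup) {
      g_affected <- dup_lo:dup_hi
      breakpoint_rule <- FALSE
    } else {
      g_affected <- c(v$pos, v$pos + 1L)
      breakpoint_rule <- TRUE
    }
  } else {
    g_affected <- v$pos:(v$pos + nchar(v$ref) - 1L)
    breakpoint_rule <- FALSE
  }
  g_affected <- g_affected[g_affected >= tx$exon_starts[1L] &
                           g_affected <= tx$exon_ends[tx$n_exons]]
  cps <- lapply(g_affected, cp_of)
  offs <- vapply(cps, function(cp)
    if (is.null(cp)) NA_integer_ else cp$offset, integer(1))
  kinds <- vapply(cps, function(cp)
    if (is.null(cp)) NA_character_ else cp$kind, character(1))
  intron_offs <- offs[kinds == "intron" & !is.na(offs)]

  alters_offsets <- function(set) {
    if (breakpoint_rule) {
      length(intron_offs) == length(g_affected) &&
        length(intron_offs) > 0L && all(intron_offs %in% set)
    } else {
      any(intron_offs %in% set)
    }
  }

  # exon-end bases: first/last 3 bases of each exon in transcript orientation,
  # excluding the transcript's outermost edges (no adjacent intron there)
  ee_pos <- integer(0)
  for (i in seq_len(tx$n_exons)) {
    lo <- tx$exon_starts[i]; hi <- tx$exon_ends[i]
    head3 <- lo:min(lo + 2L, hi)
    tail3 <- max(hi - 2L, lo):hi
    drop_head <- (fwd && i == 1L) || (!fwd && i == tx$n_exons)
    drop_tail <- (fwd && i == tx$n_exons) || (!fwd && i == 1L)
    if (fwd) {
      if (!drop_head) ee_pos <- c(ee_pos, head3)
      if (!drop_tail) ee_pos <- c(ee_pos, tail3)
    } else {
      if (!drop_head) ee_pos <- c(ee_pos, tail3)  # transcript-first bases
      if (!drop_tail) ee_pos <- c(ee_pos, head3)
    }
  }
  ee_hit <- if (breakpoint_rule) {
    all(g_affected %in% ee_pos) && length(g_affected) > 0L
  } else {
    any(g_affected %in% ee_pos)
  }

  exonic <- kinds[!is.na(kinds)]
  list(
    ess = alters_offsets(c(-2L, -1L, 1L, 2L)),
    ss5 = alters_offsets(5L),
    ss = alters_offsets(c(-8L:-1L, 1L:8L)),
    ee = ee_hit,
    donor_side = any(intron_offs > 0L),
    acceptor_side = any(intron_offs < 0L),
    all_intronic = length(exonic) > 0L && all(exonic == "intron"),
    any_utr5 = any(exonic == "utr5"),
    any_utr3 = any(exonic == "utr3"),
    any_cds = any(exonic == "cds"),
    kinds = exonic
  )
}

#' Classify a variant against a transcript
#'
#' Evaluates the 14 class predicates on the canonical (most 3' in the coding
#' transcript) representation and returns the first class in priority order.
#'
#' @param tx A `transcript`. @param canonical A normalized `gvariant`.
#' @param reference A `ref_genome`.
#' @param consequence Optional precomputed [protein_consequence()] result.
#' @return Single class code string.
#' @export
classify_variant <- function(tx, canonical, reference, consequence = NULL) {
  v <- canonical
  if (v$pos + max(nchar(v$ref) - 1L, 0L) < tx$exon_starts[1L] ||
      v$pos > tx$exon_ends[tx$n_exons]) {
    stop("variant does not overlap transcript ", tx$transcript_id, call. = FALSE)
  }
  pc <- consequence %||% protein_consequence(tx, v, reference)
  f <- pc$facts
  ctx <- variant_context(tx, v, reference)
  is_indel <- v$vtype %in% c("insertion", "deletion", "complex")
  frame_ok <- !f$frameshift

  if (v$vtype == "substitution" && f$stop_gained) return("SG")
  if (ctx$ess) return("ESS")
  if (ctx$ss5) return("SS5")
  if (ctx$ss) return("SS")
  if (ctx$ee && frame_ok) return("EE")
  if (is_indel && f$cds_overlap && f$frameshift) return("FS")
  if (f$start_lost) return("IM")
  if (f$stop_lost) return("SL")
  if (is_indel && f$cds_overlap && f$cds_len_change != 0L && frame_ok) return("IF")
  if (f$cds_overlap && f$cds_len_change == 0L && f$aa_changed) return("NSY")
  if (f$cds_overlap && f$cds_len_change == 0L && !f$aa_changed) return("SY")
  if (ctx$all_intronic) return("INT")
  if (ctx$any_utr5 && !ctx$any_utr3) return("5PU")
  if (ctx$any_utr3) return("3PU")
  if (length(ctx$kinds) == 0L) return("INT")  # breakpoint wholly intronic
  "INT"
}

#' Sequence Ontology term for a classified variant
#'
#' Terms are lowercase-with-underscores; compound classes join terms with
#' `"|"`. ESS picks donor vs acceptor from the side of the intron altered.
#'
#' @param class_code One of the 14 class codes.
#' @param tx,canonical,reference Used to resolve context-dependent terms.
#' @param consequence Optional precomputed [protein_consequence()] result.
#' @return SO term string.
#' @export
so_term <- function(class_code, tx = NULL, canonical = NULL, reference = NULL,
                    consequence = NULL) {
  ctx <- if (!is.null(tx)) variant_context(tx, canonical, reference) else NULL
  pc <- if (!is.null(tx))
    (consequence %||% protein_consequence(tx, canonical, reference)) else NULL
  switch(class_code,
    SG = "stop_gained",
    ESS = {
      if (!is.null(ctx) && ctx$acceptor_side && !ctx$donor_side)
        "splice_acceptor_variant" else "splice_donor_variant"
    },
    SS5 = "splice_donor_5th_base_variant",
    SS = "intron_variant|splice_region_variant",
    EE = {
      base <- if (is.null(pc)) "" else {
        f <- pc$facts
        if (f$cds_overlap && f$cds_len_change == 0L && !f$aa_changed &&
            canonical$vtype == "substitution") "synonymous_variant"
        else if (f$nonsynonymous && canonical$vtype == "substitution")
          "missense_variant"
        else if (f$cds_len_change > 0L) "inframe_insertion"
        else if (f$cds_len_change < 0L) "inframe_deletion"
        else ""
      }
      if (nzchar(base)) paste0("splice_region_variant|", base)
      else "splice_region_variant"
    },
    FS = "frameshift_variant",
    IM = "initiator_codon_variant",
    SL = "stop_lost",
    IF = {
      if (!is.null(pc) && pc$facts$cds_len_change < 0L) "inframe_deletion"
      else "inframe_insertion"
    },
    NSY = "missense_variant",
    SY = "synonymous_variant",
    INT = "intron_variant",
    `5PU` = "5_prime_utr_variant",
    `3PU` = "3_prime_utr_variant",
    stop("unknown class: ", class_code, call. = FALSE)
  )
}

#' Impact category of a class
#'
#' 1 = ESS, FS, SG; 2 = NSY, SS5, IF, IM, SL, EE; 3 = SY, SS, INT, 5PU, 3PU.
#'
#' @param class_code One of the 14 class codes.
#' @return Integer 1, 2 or 3.
#' @export
impact_category <- function(class_code) {
  out <- IMPACT_MAP[class_code]
  if (any(is.na(out))) stop("unknown class: ",
                            paste(class_code[is.na(out)], collapse = ","),
                            call. = FALSE)
  unname(out)
}
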