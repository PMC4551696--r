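# Transcript models and genomic <-> coding coordinate mapping.
#
# Coordinates are 1-based inclusive throughout. Exons are stored in genomic
# order (ascending); exon numbering for reporting follows transcription
# order, so the genomically last exon of a reverse-strand transcript is
# exon 1. coding_start/coding_end are genomically ordered: the translation
# start is coding_start on "+" transcripts and coding_end on "-" ones.

#' Construct a transcript model
#'
#' @param transcript_id Transcript identifier (e.g. Ensembl-style ENST...).
#' @param gene HGNC gene symbol.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 1-based inclusive exon
#'   bounds, ascending, non-overlapping.
#' @param coding_start,coding_end Genomic positions of the genomically first
#'   and last coding base (translation start + stop inclusive).
#' @return A `transcript` object.
#' @export
transcript <- function(transcript_id, gene, chrom, strand,
                       exon_starts, exon_ends, coding_start, coding_end) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_ends >= exon_starts))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o]); exon_ends <- as.integer(exon_ends[o])
  if (any(diff(exon_starts) <= 0) && length(exon_starts) > 1)
    stop("exons not strictly ordered", call. = FALSE)
  if (length(exon_starts) > 1 && any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stop("overlapping exons in ", transcript_id, call. = FALSE)
  lens <- exon_ends - exon_starts + 1L
  n <- length(lens)
  # transcript coordinate of the first base of each genomic exon
  t_first_fwd <- cumsum(c(0L, lens[-n])) + 1L
  t_first_rev <- rev(cumsum(c(0L, rev(lens)[-n])) + 1L)  # rev strand, per genomic exon
  tx <- structure(list(
    transcript_id = transcript_id, gene = gene, chrom = chrom, strand = strand,
    exon_starts = exon_starts, exon_ends = exon_ends,
    exon_lens = lens, n_exons = n,
    coding_start = as.integer(coding_start), coding_end = as.integer(coding_end),
    transcript_length = sum(lens),
    genomic_span = exon_ends[n] - exon_starts[1L] + 1L,
    t_first_fwd = t_first_fwd, t_first_rev = t_first_rev
  ), class = "transcript")
  ts <- tx_tpos(tx, if (strand == "+") coding_start else coding_end)
  te <- tx_tpos(tx, if (strand == "+") coding_end else coding_start)
  if (is.na(ts) || is.na(te) || te < ts)
    stop("coding bounds of ", transcript_id, " not inside exons", call. = FALSE)
  tx$cds_tstart <- ts
  tx$cds_tend <- te
  tx$cds_length <- te - ts + 1L
  tx
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript> ", x$transcript_id, " (", x$gene, ") ", x$chrom, x$strand,
      " exons=", x$n_exons, " len=", x$transcript_length,
      " cds=", x$cds_length, "\n", sep = "")
  invisible(x)
}

# Exon index (genomic order) containing g, or NA if intronic/outside.
exon_index_of <- function(tx, g) {
  i <- findInterval(g, tx$exon_starts)
  if (i >= 1L && g <= tx$exon_ends[i]) i else NA_integer_
}

# Transcript coordinate (1..transcript_length) of exonic genomic position g.
tx_tpos <- function(tx, g) {
  i <- exon_index_of(tx, g)
  if (is.na(i)) return(NA_integer_)
  if (tx$strand == "+") tx$t_first_fwd[i] + (g - tx$exon_starts[i])
  else tx$t_first_rev[i] + (tx$exon_ends[i] - g)
}

# Inverse of tx_tpos.
tx_gpos <- function(tx, t) {
  stopifnot(t >= 1L, t <= tx$transcript_length)
  first <- if (tx$strand == "+") tx$t_first_fwd else tx$t_first_rev
  last <- first + tx$exon_lens - 1L
  i <- which(t >= first & t <= last)
  if (tx$strand == "+") tx$exon_starts[i] + (t - first[i])
  else tx$exon_ends[i] - (t - first[i])
}

# Exon number in transcription order for genomic exon index i.
exon_number <- function(tx, i) {
  if (tx$strand == "+") i else tx$n_exons - i + 1L
}

#' Map a genomic position into coding-transcript coordinates
#'
#' Returns a `coding_pos`: a list with `kind` (`"cds"`, `"utr5"`, `"utr3"` or
#' `"intron"`), `base` (CDS coordinate, or distance into the UTR; for introns
#' the coordinate of the nearest exonic base), `offset` (0 for exonic, signed
#' intron offset in transcript orientation: +k is k bases 3' of an exon end)
#' and, for introns, `anchor_kind` (the kind of the anchoring exonic base).
#'
#' @param tx A `transcript`.
#' @param g Genomic position within the transcript span.
#' @return A `coding_pos` list.
#' @export
genomic_to_coding <- function(tx, g) {
  if (g < tx$exon_starts[1L] || g > tx$exon_ends[tx$n_exons])
    stop("position ", g, " is intergenic for ", tx$transcript_id, call. = FALSE)
  i <- exon_index_of(tx, g)
  if (!is.na(i)) {
    t <- tx_tpos(tx, g)
    if (t < tx$cds_tstart) {
      return(coding_pos("utr5", tx$cds_tstart - t, 0L))
    } else if (t > tx$cds_tend) {
      return(coding_pos("utr3", t - tx$cds_tend, 0L))
    }
    return(coding_pos("cds", t - tx$cds_tstart + 1L, 0L))
  }
  k <- findInterval(g, tx$exon_starts)  # g lies between exon k and k+1
  dL <- g - tx$exon_ends[k]
  dR <- tx$exon_starts[k + 1L] - g
  if (tx$strand == "+") {
    plus_anchor <- tx$exon_ends[k];        plus_off <- dL
    minus_anchor <- tx$exon_starts[k + 1L]; minus_off <- dR
  } else {
    plus_anchor <- tx$exon_starts[k + 1L]; plus_off <- dR
    minus_anchor <- tx$exon_ends[k];        minus_off <- dL
  }
  use_plus <- plus_off <= minus_off  # tie anchors to the upstream (+) exon
  anchor <- genomic_to_coding(tx, if (use_plus) plus_anchor else minus_anchor)
  coding_pos("intron", anchor$base,
             if (use_plus) plus_off else -minus_off,
             anchor_kind = anchor$kind)
}

coding_pos <- function(kind, base, offset, anchor_kind = NA_character_) {
  structure(list(kind = kind, base = as.integer(base), offset = as.integer(offset),
                 anchor_kind = anchor_kind), class = "coding_pos")
}

#' Map a coding position back to its genomic position
#'
#' Exact inverse of [genomic_to_coding()].
#'
#' @param tx A `transcript`.
#' @param cpos A `coding_pos`.
#' @return Genomic position (integer).
#' @export
coding_to_genomic <- function(tx, cpos) {
  kind <- if (cpos$kind == "intron") cpos$anchor_kind else cpos$kind
  t <- switch(kind,
    cds  = tx$cds_tstart + cpos$base - 1L,
    utr5 = tx$cds_tstart - cpos$base,
    utr3 = tx$cds_tend + cpos$base,
    stop("bad coding_pos kind", call. = FALSE))
  if (t < 1L || t > tx$transcript_length)
    stop("coding position out of transcript range", call. = FALSE)
  g0 <- tx_gpos(tx, t)
  if (cpos$offset == 0L) return(g0)
  if (tx$strand == "+") g0 + cpos$offset else g0 - cpos$offset
}

# CSN-style coordinate text: "246", "-45", "*12", "484+5", "2929-5", "-45+3".
format_coding_pos <- function(cpos) {
  kind <- if (cpos$kind == "intron") cpos$anchor_kind else cpos$kind
  core <- switch(kind,
    cds  = as.character(cpos$base),
    utr5 = paste0("-", cpos$base),
    utr3 = paste0("*", cpos$base))
  if (cpos$offset == 0L) core
  else paste0(core, if (cpos$offset > 0L) "+" else "-", abs(cpos$offset))
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the CDS segments of each exon in transcription order,
#' reverse-complementing for reverse-strand transcripts. Complete fixture
#' transcripts start with ATG and end with a stop codon.
#'
#' @param tx A `transcript`.
#' @param reference A `ref_genome`.
#' @return Uppercase DNA string whose length is a multiple of 3.
#' @export
coding_sequence <- function(tx, reference) {
  segs <- character(0)
  for (i in seq_len(tx$n_exons)) {
    s <- max(tx$exon_starts[i], tx$coding_start)
    e <- min(tx$exon_ends[i], tx$coding_end)
    if (s <= e) segs <- c(segs, ref_fetch(reference, tx$chrom, s, e))
  }
  cds <- paste(segs, collapse = "")
  if (tx$strand == "-") cds <- reverse_complement(cds)
  cds
}

# ---- transcript database ----------------------------------------------------

strip_chr <- function(x) sub("^chr", "", x)

new_transcript_db <- function(tx_list) {
  tx_list <- tx_list[order(vapply(tx_list, `[[`, character(1), "transcript_id"))]
  names(tx_list) <- vapply(tx_list, `[[`, character(1), "transcript_id")
  gr <- GenomicRanges::GRanges(
    seqnames = strip_chr(vapply(tx_list, `[[`, character(1), "chrom")),
    ranges = IRanges::IRanges(
      start = vapply(tx_list, function(t) t$exon_starts[1L], integer(1)),
      end = vapply(tx_list, function(t) t$exon_ends[t$n_exons], integer(1))
    )
  )
  structure(list(transcripts = tx_list, spans = gr), class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("<transcript_db> ", length(x$transcripts), " transcript(s)\n", sep = "")
  invisible(x)
}

#' Load a transcript database
#'
#' Accepts either a GTF/GFF file (exon and CDS features grouped by their
#' `transcript_id` attribute) or the package's native tab-separated format
#' (see [write_native_transcripts()]). Transcripts whose CDS length is not a
#' multiple of 3, or that fail structural validation, are excluded with a
#' warning rather than aborting the load.
#'
#' @param path GTF/GFF or native TSV file.
#' @param reference Optional `ref_genome` (used only for contig sanity checks).
#' @return A `transcript_db`.
#' @export
load_transcripts <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("transcript database not found: ", path, call. = FALSE)
  is_native <- grepl("\\.(tsv|txt)$", path, ignore.case = TRUE) ||
    !grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE)
  raw <- if (is_native) read_native_transcripts(path) else read_gtf_transcripts(path)
  keep <- list()
  for (spec in raw) {
    tx <- tryCatch(do.call(transcript, spec), error = function(e) e)
    if (inherits(tx, "error")) {
      warning("skipping transcript ", spec$transcript_id, ": ",
              conditionMessage(tx), call. = FALSE)
      next
    }
    if (tx$cds_length %% 3L != 0L) {
      warning("skipping transcript ", tx$transcript_id,
              ": incomplete CDS (length not a multiple of 3)", call. = FALSE)
      next
    }
    if (!is.null(reference) && is.na(resolve_contig(reference, tx$chrom))) {
      warning("skipping transcript ", tx$transcript_id,
              ": contig ", tx$chrom, " absent from reference", call. = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- tx
  }
  if (length(keep) == 0L) stop("no valid transcript in ", path, call. = FALSE)
  new_transcript_db(keep)
}

read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tid <- as.character(md$transcript_id)
  gene <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
          else as.character(md$gene_id)
  use <- type %in% c("exon", "CDS") & !is.na(tid)
  out <- list()
  for (id in unique(tid[use])) {
    sel_ex <- use & tid == id & type == "exon"
    sel_cds <- use & tid == id & type == "CDS"
    if (!any(sel_ex) || !any(sel_cds)) next
    out[[id]] <- list(
      transcript_id = id,
      gene = gene[which(sel_ex)[1L]],
      chrom = as.character(GenomicRanges::seqnames(gr))[which(sel_ex)[1L]],
      strand = as.character(GenomicRanges::strand(gr))[which(sel_ex)[1L]],
      exon_starts = GenomicRanges::start(gr)[sel_ex],
      exon_ends = GenomicRanges::end(gr)[sel_ex],
      coding_start = min(GenomicRanges::start(gr)[sel_cds]),
      coding_end = max(GenomicRanges::end(gr)[sel_cds])
    )
  }
  out
}

NATIVE_COLS <- c("transcript_id", "gene", "chrom", "strand",
                 "exon_starts", "exon_ends", "coding_start", "coding_end")

read_native_transcripts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(NATIVE_COLS %in% names(df)))
    stop("native transcript TSV must have columns: ",
         paste(NATIVE_COLS, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    list(
      transcript_id = df$transcript_id[i], gene = df$gene[i],
      chrom = df$chrom[i], strand = df$strand[i],
      exon_starts = as.integer(strsplit(df$exon_starts[i], ",", fixed = TRUE)[[1]]),
      exon_ends = as.integer(strsplit(df$exon_ends[i], ",", fixed = TRUE)[[1]]),
      coding_start = as.integer(df$coding_start[i]),
      coding_end = as.integer(df$coding_end[i])
    )
  })
}

#' Write a transcript database in the native TSV format
#'
#' One line per transcript: identifier, gene symbol, contig, strand,
#' comma-separated exon starts and ends, and genomic coding bounds.
#'
#' @param db A `transcript_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_native_transcripts <- function(db, path) {
  rows <- vapply(db$transcripts, function(tx) {
    paste(tx$transcript_id, tx$gene, tx$chrom, tx$strand,
          paste(tx$exon_starts, collapse = ","),
          paste(tx$exon_ends, collapse = ","),
          tx$coding_start, tx$coding_end, sep = "\t")
  }, character(1))
  writeLines(c(paste(NATIVE_COLS, collapse = "\t"), rows), path)
  invisible(path)
}

#' Find transcripts overlapping a genomic interval
#'
#' @param db A `transcript_db`.
#' @param chrom Contig name ("chr" prefix optional).
#' @param start,end 1-based inclusive interval.
#' @param flank Extra bases added to each transcript span (default 0).
#' @return List of `transcript` objects, sorted by transcript_id; empty for
#'   unknown contigs (such variants are intergenic).
#' @export
find_overlapping_transcripts <- function(db, chrom, start, end, flank = 0L) {
  q <- GenomicRanges::GRanges(strip_chr(chrom),
                              IRanges::IRanges(start = start, end = end))
  spans <- db$spans
  if (flank > 0L) {
    spans <- GenomicRanges::resize(spans,
      width = GenomicRanges::width(spans) + 2L * flank, fix = "center")
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, spans))
  idx <- sort(unique(S4Vectors::subjectHits(hits)))
  unname(db$transcripts[idx])
}
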