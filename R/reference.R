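#' Load a reference genome from FASTA
#'
#' Reads every contig into memory (uppercased) and records contig lengths.
#' Contig names are matched leniently against VCF/GTF names: a query with or
#' without a leading `"chr"` resolves to the same contig.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `ref_genome` with elements `seqs` (named
#'   character vector of uppercase sequences) and `lengths`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) {
    stop("duplicate contig name in reference: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nms
  structure(
    list(seqs = seqs, lengths = vapply(seqs, nchar, integer(1))),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x$seqs), " contig(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

# Resolve a contig name with "chr"-prefix tolerance; NA if absent.
resolve_contig <- function(reference, chrom) {
  nms <- names(reference$seqs)
  if (chrom %in% nms) return(chrom)
  alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom) else paste0("chr", chrom)
  if (alt %in% nms) return(alt)
  NA_character_
}

#' Fetch reference bases
#'
#' 1-based inclusive coordinates; pure (repeated calls return the same string).
#'
#' @param reference A `ref_genome`.
#' @param chrom Contig name ("chr" prefix optional).
#' @param start,end 1-based inclusive bounds.
#' @return Uppercase DNA string of length `end - start + 1`.
#' @export
ref_fetch <- function(reference, chrom, start, end) {
  ctg <- resolve_contig(reference, chrom)
  if (is.na(ctg)) stop("unknown contig: ", chrom, call. = FALSE)
  len <- reference$lengths[[ctg]]
  if (start < 1L || end > len || end < start) {
    stop("fetch out of range for contig ", ctg, ": ", start, "-", end, call. = FALSE)
  }
  substr(reference$seqs[[ctg]], start, end)
}
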