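# Shared fixtures (generated once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

get_manifest <- function() {
  if (is.null(.fixture_cache$manifest)) {
    .fixture_cache$manifest <- generate_fixture_genome(fixture_spec(1L))
  }
  .fixture_cache$manifest
}

get_db <- function() {
  if (is.null(.fixture_cache$db)) {
    m <- get_manifest()
    .fixture_cache$db <- load_transcripts(m$gtf, m$reference)
  }
  .fixture_cache$db
}

get_cases <- function() {
  if (is.null(.fixture_cache$cases)) {
    .fixture_cache$cases <- generate_fixture_vcf(get_manifest())
  }
  .fixture_cache$cases
}

get_records <- function() {
  if (is.null(.fixture_cache$records)) {
    m <- get_manifest()
    vars <- read_vcf(get_cases()$vcf, m$reference)
    .fixture_cache$records <- annotate_variants(vars, get_db(), m$reference)
  }
  .fixture_cache$records
}

# ---- oracle: brute-force coding-coordinate walker ---------------------------
# Steps base-by-base through the exons in transcription order accumulating
# CDS/UTR indices; returns a data.frame genomic position -> (kind, base).
# Memoized per transcript (the sweeps call it thousands of times).
walker_map <- function(tx) {
  key <- paste0("walker_", tx$transcript_id)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  .fixture_cache[[key]] <- walker_map_impl(tx)
  .fixture_cache[[key]]
}

walker_map_impl <- function(tx) {
  gpos <- integer(0)
  for (i in seq_len(tx$n_exons)) gpos <- c(gpos, tx$exon_starts[i]:tx$exon_ends[i])
  if (tx$strand == "-") gpos <- rev(gpos)
  tstart_g <- if (tx$strand == "+") tx$coding_start else tx$coding_end
  tend_g <- if (tx$strand == "+") tx$coding_end else tx$coding_start
  its <- match(tstart_g, gpos); ite <- match(tend_g, gpos)
  kind <- character(length(gpos)); base <- integer(length(gpos))
  for (j in seq_along(gpos)) {
    if (j < its) { kind[j] <- "utr5"; base[j] <- its - j }
    else if (j > ite) { kind[j] <- "utr3"; base[j] <- j - ite }
    else { kind[j] <- "cds"; base[j] <- j - its + 1L }
  }
  data.frame(gpos = gpos, kind = kind, base = base)
}

# ---- oracle: quadratic representation enumerator ----------------------------
# Applies every candidate placement of the same-length indel in a window and
# keeps those whose edited sequence matches.
brute_force_representations <- function(v, reference, window = 100L) {
  ctg <- names(reference$seqs)[1]
  seq <- reference$seqs[[ctg]]
  target <- apply_variant(seq, v)
  lo <- max(1L, v$pos - window); hi <- min(nchar(seq), v$pos + window)
  out <- list()
  if (v$vtype == "deletion") {
    L <- nchar(v$ref)
    for (p in lo:(hi - L + 1L)) {
      cand <- gvariant(v$chrom, p, substr(seq, p, p + L - 1L), "")
      if (identical(apply_variant(seq, cand), target)) out[[length(out) + 1L]] <- cand
    }
  } else if (v$vtype == "insertion") {
    L <- nchar(v$alt)
    # an insertion after p reproducing `target` must insert target[p+1..p+L]
    for (p in lo:hi) {
      s <- substr(target, p + 1L, p + L)
      if (nchar(s) < L) next
      cand <- gvariant(v$chrom, p, "", s)
      if (identical(apply_variant(seq, cand), target)) {
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  ps <- vapply(out, `[[`, integer(1), "pos")
  out[order(ps)]
}

# ---- oracle: full-retranslation protein facts -------------------------------
# Rebuilds the edited CDS from the genomic CDS position list and translates
# ref/edited with Biostrings; facts derived from naive string comparison.
oracle_cds_positions <- function(tx) {
  w <- walker_map(tx)
  w$gpos[w$kind == "cds"]
}

# reference CDS characters (transcript sense) per genomic CDS position, memoized
oracle_cds_chars <- function(tx, reference) {
  key <- paste0("cdschars_", tx$transcript_id)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cds_g <- oracle_cds_positions(tx)
  ch <- vapply(cds_g, function(g) ref_fetch(reference, tx$chrom, g, g), character(1))
  if (tx$strand == "-") ch <- unname(vapply(ch, reverse_complement, character(1)))
  .fixture_cache[[key]] <- ch
  ch
}

oracle_edited_cds <- function(tx, v, reference) {
  cds_g <- oracle_cds_positions(tx)
  chars <- oracle_cds_chars(tx, reference)
  if (v$vtype == "substitution") {
    i <- match(v$pos, cds_g)
    if (is.na(i)) return(NULL)
    chars[i] <- if (tx$strand == "-") reverse_complement(v$alt) else v$alt
    return(paste(chars, collapse = ""))
  }
  if (v$vtype %in% c("deletion", "complex")) {
    del <- v$pos:(v$pos + nchar(v$ref) - 1L)
    idx <- match(del, cds_g)
    if (all(is.na(idx))) return(NULL)
    if (any(is.na(idx))) return(NA)  # boundary-spanning: facts only
    alt_t <- if (tx$strand == "-") reverse_complement(v$alt) else v$alt
    keep <- setdiff(seq_along(chars), idx)
    at <- min(idx)
    return(paste0(paste(chars[seq_len(at - 1L)], collapse = ""), alt_t,
                  paste(chars[setdiff(keep, seq_len(at - 1L))], collapse = "")))
  }
  # insertion: joins the CDS only if both breakpoint flanks are CDS bases
  i1 <- match(v$pos, cds_g); i2 <- match(v$pos + 1L, cds_g)
  if (is.na(i1) || is.na(i2) || abs(i2 - i1) != 1L) return(NULL)
  ins_t <- if (tx$strand == "-") reverse_complement(v$alt) else v$alt
  at <- min(i1, i2)
  paste0(paste(chars[seq_len(at)], collapse = ""), ins_t,
         paste(chars[(at + 1L):length(chars)], collapse = ""))
}

bs_translate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                          no.init.codon = TRUE)))
}

oracle_protein_facts <- function(tx, v, reference) {
  ref_cds <- paste(oracle_cds_chars(tx, reference), collapse = "")
  ed <- oracle_edited_cds(tx, v, reference)
  if (is.null(ed)) {
    return(list(cds_overlap = FALSE, frameshift = FALSE, synonymous = FALSE,
                stop_gained = FALSE, stop_lost = FALSE, start_lost = FALSE))
  }
  if (length(ed) == 1L && is.na(ed)) return(NA)  # boundary span: skip
  net <- nchar(ed) - nchar(ref_cds)
  rp <- bs_translate(ref_cds)
  ep <- bs_translate(ed)
  L <- nchar(ref_cds)
  cds_g <- oracle_cds_positions(tx)
  last3 <- cds_g[(length(cds_g) - 2L):length(cds_g)]
  first3 <- cds_g[1:3]
  if (v$vtype == "insertion") {
    fl <- c(v$pos, v$pos + 1L)
    hits_start <- all(fl %in% first3)
    hits_stop <- all(fl %in% last3)
  } else {
    g <- v$pos:(v$pos + nchar(v$ref) - 1L)
    hits_start <- any(g %in% first3)
    hits_stop <- any(g %in% last3)
  }
  frameshift <- v$vtype != "substitution" && net %% 3L != 0L
  stop_gained <- v$vtype == "substitution" &&
    substr(ep, nchar(rp), nchar(rp)) != "" &&
    {
      i <- which(strsplit(rp, "")[[1]] != strsplit(ep, "")[[1]])
      length(i) == 1L && substr(ep, i, i) == "*" && substr(rp, i, i) != "*"
    }
  stop_lost <- if (v$vtype == "substitution") {
    i <- which(strsplit(rp, "")[[1]] != strsplit(ep, "")[[1]])
    length(i) == 1L && substr(rp, i, i) == "*"
  } else hits_stop && !frameshift
  list(cds_overlap = TRUE, frameshift = frameshift,
       synonymous = v$vtype == "substitution" && identical(rp, ep),
       stop_gained = isTRUE(stop_gained), stop_lost = isTRUE(stop_lost),
       start_lost = if (v$vtype == "insertion")
         all(c(v$pos, v$pos + 1L) %in% first3) else hits_start)
}

# ---- oracle: independent slow classifier ------------------------------------
# Evaluates the 14 predicates from explicitly enumerated genomic base sets
# and naive retranslation, taking the first satisfied class in list order.
oracle_classify <- function(tx, v, reference) {
  n_ex <- tx$n_exons
  donor <- function(k) {  # offset +k bases for every transcript-internal intron
    out <- integer(0)
    for (i in seq_len(n_ex)) {
      if (tx$strand == "+" && i < n_ex) out <- c(out, tx$exon_ends[i] + k)
      if (tx$strand == "-" && i > 1L) out <- c(out, tx$exon_starts[i] - k)
    }
    out
  }
  acceptor <- function(k) {
    out <- integer(0)
    for (i in seq_len(n_ex)) {
      if (tx$strand == "+" && i > 1L) out <- c(out, tx$exon_starts[i] - k)
      if (tx$strand == "-" && i < n_ex) out <- c(out, tx$exon_ends[i] + k)
    }
    out
  }
  ess_set <- c(donor(1), donor(2), acceptor(1), acceptor(2))
  ss5_set <- donor(5)
  ss_set <- unlist(lapply(1:8, function(k) c(donor(k), acceptor(k))))
  ee_set <- integer(0)
  for (i in seq_len(n_ex)) {
    first_tx <- (tx$strand == "+" && i == 1L) || (tx$strand == "-" && i == n_ex)
    last_tx <- (tx$strand == "+" && i == n_ex) || (tx$strand == "-" && i == 1L)
    lo <- tx$exon_starts[i]; hi <- tx$exon_ends[i]
    head3 <- lo:min(lo + 2L, hi); tail3 <- max(hi - 2L, lo):hi
    if (tx$strand == "+") {
      if (!first_tx) ee_set <- c(ee_set, head3)
      if (!last_tx) ee_set <- c(ee_set, tail3)
    } else {
      if (!first_tx) ee_set <- c(ee_set, tail3)
      if (!last_tx) ee_set <- c(ee_set, head3)
    }
  }
  exon_set <- unlist(lapply(seq_len(n_ex), function(i)
    tx$exon_starts[i]:tx$exon_ends[i]))
  w <- walker_map(tx)
  utr5_set <- w$gpos[w$kind == "utr5"]; utr3_set <- w$gpos[w$kind == "utr3"]

  if (v$vtype == "insertion") {
    ins_t <- if (tx$strand == "-") reverse_complement(v$alt) else v$alt
    k <- nchar(ins_t)
    dup_lo <- if (tx$strand == "+") v$pos - k + 1L else v$pos + 1L
    dup_hi <- if (tx$strand == "+") v$pos else v$pos + k
    seg <- if (dup_lo >= 1L) ref_fetch(reference, tx$chrom, dup_lo, dup_hi) else ""
    if (tx$strand == "-") seg <- reverse_complement(seg)
    if (identical(seg, ins_t)) {
      affected <- dup_lo:dup_hi; both <- FALSE
    } else {
      affected <- c(v$pos, v$pos + 1L); both <- TRUE
    }
  } else {
    affected <- v$pos:(v$pos + nchar(v$ref) - 1L); both <- FALSE
  }
  hits <- function(set) {
    if (both) all(affected %in% set) else any(affected %in% set)
  }
  pf <- oracle_protein_facts(tx, v, reference)
  if (length(pf) == 1L && is.na(pf)) pf <- NULL  # boundary span
  ed <- if (!is.null(pf)) oracle_edited_cds(tx, v, reference) else NULL
  net_cds <- if (!is.null(ed) && !is.na(ed)) {
    nchar(ed) - length(oracle_cds_positions(tx))
  } else 0L
  is_indel <- v$vtype %in% c("insertion", "deletion", "complex")

  if (v$vtype == "substitution" && !is.null(pf) && isTRUE(pf$stop_gained))
    return("SG")
  if (hits(ess_set)) return("ESS")
  if (hits(ss5_set)) return("SS5")
  if (hits(ss_set)) return("SS")
  fshift <- !is.null(pf) && isTRUE(pf$frameshift)
  # boundary-spanning deletions: frame from count of CDS bases removed
  if (is.null(pf) && v$vtype %in% c("deletion", "complex")) {
    cds_g <- oracle_cds_positions(tx)
    d <- sum(affected %in% cds_g)
    if (d > 0L) fshift <- (nchar(v$alt) - d) %% 3L != 0L
    pf <- list(cds_overlap = d > 0L, frameshift = fshift,
               start_lost = any(affected %in% cds_g[1:3]),
               stop_lost = any(affected %in% cds_g[(length(cds_g) - 2L):length(cds_g)]) && !fshift,
               synonymous = FALSE, stop_gained = FALSE)
    net_cds <- if (d > 0L) nchar(v$alt) - d else 0L
  }
  if (hits(ee_set) && !fshift) return("EE")
  if (is_indel && isTRUE(pf$cds_overlap) && fshift) return("FS")
  if (isTRUE(pf$start_lost)) return("IM")
  if (isTRUE(pf$stop_lost)) return("SL")
  if (is_indel && isTRUE(pf$cds_overlap) && net_cds != 0L && !fshift) return("IF")
  if (isTRUE(pf$cds_overlap) && net_cds == 0L && !isTRUE(pf$synonymous))
    return("NSY")
  if (isTRUE(pf$cds_overlap) && isTRUE(pf$synonymous)) return("SY")
  exonic <- intersect(affected, exon_set)
  if (length(exonic) == 0L) return("INT")
  if (any(exonic %in% utr5_set) && !any(exonic %in% utr3_set)) return("5PU")
  if (any(exonic %in% utr3_set)) return("3PU")
  "INT"
}

# deterministic base flip for sweep substitutions
flip_base <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
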