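# Deterministic synthetic fixtures: a reference contig carrying six genes
# (three per strand, one tail-to-tail overlapping pair), a transcript set,
# and variant calls with known truth annotations. Every engineered motif is
# recorded in the manifest so tests can look coordinates up instead of
# recomputing them.
#
# Engineered structures:
#   GENE1 (+) 10 kb CDS carrying the twelve exonic-substitution vectors
#        (c.1040A>G ... c.9976A>T), a frameshift T at c.246, a synonymous
#        exon-end base at c.600, a donor ladder intron (+1..+9), an acceptor
#        T-tract giving the c.2929-5dupT / c.2929-9_2929-8insT pair, a
#        deep-intronic AAAAAA tract, and UTR substitution sites.
#   GENE2 (+) ACT|CCT codons 702/703 so a left-aligned CTC insertion
#        right-normalizes to c.2107_2109dupCCT_p.Pro703dup.
#   GENE3 (+) acceptor G-tract + GGG GGG exon start: a GGG insertion is an
#        inframe Gly duplication when 3'-aligned but intronic when 5'-aligned.
#   GENE4 (-) overlaps GENE2 tail-to-tail; the shared 3'UTR carries an
#        AAAAAA tract whose canonical deletion placement differs by strand.
#   GENE5/GENE6 (-) plain multi-exon genes for randomized property tests.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  pool <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  sample(pool, n, replace = TRUE)
}

override_substr <- function(s, pos, repl) {
  stopifnot(pos >= 1L, pos + nchar(repl) - 1L <= nchar(s))
  paste0(substr(s, 1L, pos - 1L), repl, substr(s, pos + nchar(repl), nchar(s)))
}

#' Fixture specification
#'
#' The gene blueprints are fixed (they define the structures the worked
#' examples and property tests rely on); the seed controls the random fill
#' sequence. Same seed, same spec: byte-identical FASTA/GTF/VCF.
#'
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L) {
  structure(list(seed = as.integer(seed), contig = "1", contig_length = 25000L),
            class = "fixture_spec")
}

# Build one gene cassette in transcript orientation, then place it genomically.
# def: id, gene, strand, offset, utr5, utr3, n_codons, codon_overrides
#      (named list idx -> codon), exon_tlens, intron_lens, intron_overrides
#      (list of list(intron, pos|at_end, seq)), utr5_seq/utr3_seq overrides,
#      utr_overrides (list of list(which, pos, seq)).
build_gene <- function(def) {
  codons <- random_codons(def$n_codons)
  codons[1L] <- "ATG"
  codons[def$n_codons] <- "TAA"
  for (ix in names(def$codon_overrides %||% list())) {
    codons[as.integer(ix)] <- def$codon_overrides[[ix]]
  }
  cds <- paste(codons, collapse = "")
  utr5 <- def$utr5_seq %||% random_bases(def$utr5)
  utr3 <- def$utr3_seq %||% random_bases(def$utr3)
  for (ov in def$utr_overrides %||% list()) {
    if (ov$which == "utr5") utr5 <- override_substr(utr5, ov$pos, ov$seq)
    else utr3 <- override_substr(utr3, ov$pos, ov$seq)
  }
  tseq <- paste0(utr5, cds, utr3)
  stopifnot(sum(def$exon_tlens) == nchar(tseq))
  n_ex <- length(def$exon_tlens)
  introns <- lapply(def$intron_lens, random_bases)
  for (ov in def$intron_overrides %||% list()) {
    s <- introns[[ov$intron]]
    pos <- if (isTRUE(ov$at_end)) nchar(s) - nchar(ov$seq) + 1L else ov$pos
    introns[[ov$intron]] <- override_substr(s, pos, ov$seq)
  }
  t_end <- cumsum(def$exon_tlens)
  t_start <- t_end - def$exon_tlens + 1L
  # block-local exon coordinates (transcript order)
  bstart <- integer(n_ex); bend <- integer(n_ex)
  segs <- character(0)
  bpos <- 1L
  for (i in seq_len(n_ex)) {
    bstart[i] <- bpos
    bend[i] <- bpos + def$exon_tlens[i] - 1L
    segs <- c(segs, substr(tseq, t_start[i], t_end[i]))
    bpos <- bend[i] + 1L
    if (i < n_ex) {
      segs <- c(segs, introns[[i]])
      bpos <- bpos + def$intron_lens[i]
    }
  }
  block <- paste(segs, collapse = "")
  blen <- nchar(block)
  t2b <- function(t) {
    i <- which(t >= t_start & t <= t_end)
    bstart[i] + (t - t_start[i])
  }
  b2g <- function(b) {
    if (def$strand == "+") def$offset + b - 1L else def$offset + (blen - b)
  }
  t2g <- function(t) b2g(t2b(t))
  gblock <- if (def$strand == "+") block else reverse_complement(block)
  exon_g <- t(vapply(seq_len(n_ex), function(i) {
    sort(c(b2g(bstart[i]), b2g(bend[i])))
  }, integer(2)))
  o <- order(exon_g[, 1L])
  ct1 <- def$utr5 + 1L
  ct2 <- def$utr5 + 3L * def$n_codons
  cg <- sort(c(t2g(ct1), t2g(ct2)))
  list(def = def, gblock = gblock, blen = blen,
       gstart = def$offset, gend = def$offset + blen - 1L,
       exon_starts = exon_g[o, 1L], exon_ends = exon_g[o, 2L],
       coding_start = cg[1L], coding_end = cg[2L],
       cds = cds, codons = codons, tseq = tseq, t2g = t2g)
}

#' Generate the synthetic fixture genome
#'
#' Writes a FASTA reference and a GTF transcript set to `dir` and returns a
#' manifest recording every engineered site, the transcript objects, the
#' in-memory reference, and the generator's bookkeeping (per-gene CDS
#' strings, exon layouts) that tests use as an independent record of what
#' was built.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest (list; see components in source).
#' @export
generate_fixture_genome <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  defs <- list()
  defs$GENE1 <- list(
    id = "ENST00000000101", gene = "GENE1", strand = "+", offset = 1001L,
    utr5 = 50L, utr3 = 50L, n_codons = 3328L,
    exon_tlens = c(650L, 2328L, 3072L, 4034L),
    intron_lens = c(300L, 300L, 300L),
    codon_overrides = list(
      `82` = "CTT", `83` = "CAG", `200` = "CTG", `347` = "CAA", `637` = "GGT",
      `1088` = "CCT", `1172` = "TCG", `1894` = "TAC", `1952` = "TTA",
      `2044` = "GGT", `2225` = "ACA", `2520` = "CGA", `2728` = "GTT",
      `3326` = "AAA"),
    intron_overrides = list(
      list(intron = 1L, pos = 1L, seq = "GTAAGTATC"),
      list(intron = 2L, at_end = TRUE, seq = "ATTTTCCAG"),
      list(intron = 3L, pos = 49L, seq = "CAAAAAAG"))
  )
  defs$GENE2 <- list(
    id = "ENST00000000102", gene = "GENE2", strand = "+", offset = 13001L,
    utr5 = 20L, utr3 = 20L, n_codons = 704L,
    exon_tlens = c(1020L, 1132L), intron_lens = 200L,
    codon_overrides = list(`702` = "ACT", `703` = "CCT"),
    utr_overrides = list(list(which = "utr3", pos = 2L, seq = "CAAAAAAG"))
  )
  defs$GENE3 <- list(
    id = "ENST00000000103", gene = "GENE3", strand = "+", offset = 18001L,
    utr5 = 20L, utr3 = 20L, n_codons = 400L,
    exon_tlens = c(320L, 920L), intron_lens = 150L,
    codon_overrides = list(`101` = "GGG", `102` = "GGG", `103` = "CAT"),
    intron_overrides = list(list(intron = 1L, at_end = TRUE, seq = "TGGGGGGGG"))
  )
  defs$GENE5 <- list(
    id = "ENST00000000105", gene = "GENE5", strand = "-", offset = 21001L,
    utr5 = 20L, utr3 = 20L, n_codons = 300L,
    exon_tlens = c(300L, 300L, 340L), intron_lens = c(120L, 120L)
  )
  defs$GENE6 <- list(
    id = "ENST00000000106", gene = "GENE6", strand = "-", offset = 23001L,
    utr5 = 15L, utr3 = 15L, n_codons = 200L,
    exon_tlens = c(300L, 330L), intron_lens = 100L
  )

  genes <- list()
  for (nm in c("GENE1", "GENE2", "GENE3")) genes[[nm]] <- build_gene(defs[[nm]])

  # GENE4 (-) overlaps GENE2 tail-to-tail: its genomically first 30 bases are
  # GENE2's final 30 (3'UTR tail incl. the AAAAAA tract), i.e. a shared 3'UTR.
  overlap_len <- 30L
  shared <- substr(genes$GENE2$gblock, genes$GENE2$blen - overlap_len + 1L,
                   genes$GENE2$blen)
  defs$GENE4 <- list(
    id = "ENST00000000104", gene = "GENE4", strand = "-",
    offset = genes$GENE2$gend - overlap_len + 1L,
    utr5 = 30L, utr3 = 30L, n_codons = 600L,
    exon_tlens = c(600L, 600L, 660L), intron_lens = c(150L, 150L),
    utr3_seq = reverse_complement(shared)
  )
  for (nm in c("GENE4", "GENE5", "GENE6")) genes[[nm]] <- build_gene(defs[[nm]])
  genes <- genes[c("GENE1", "GENE2", "GENE3", "GENE4", "GENE5", "GENE6")]

  # assemble the contig; overlapping placements must agree byte-for-byte
  contig <- random_bases(spec$contig_length)
  for (g in genes) {
    contig <- override_substr(contig, g$gstart, g$gblock)
  }
  ov <- substr(contig, genes$GENE4$gstart, genes$GENE4$gstart + overlap_len - 1L)
  stopifnot(identical(ov, shared))

  fasta <- file.path(dir, "fixture.fa")
  writeLines(c(paste0(">", spec$contig), contig), fasta)
  tx_objects <- lapply(genes, function(g) {
    transcript(g$def$id, g$def$gene, spec$contig, g$def$strand,
               g$exon_starts, g$exon_ends, g$coding_start, g$coding_end)
  })
  gtf <- file.path(dir, "fixture.gtf")
  write_fixture_gtf(gtf, spec$contig, genes)

  manifest <- list(
    spec = spec, dir = dir, fasta = fasta, gtf = gtf,
    contig = spec$contig, contig_length = spec$contig_length,
    genes = lapply(genes, function(g) {
      list(id = g$def$id, gene = g$def$gene, strand = g$def$strand,
           gstart = g$gstart, gend = g$gend,
           exon_starts = g$exon_starts, exon_ends = g$exon_ends,
           coding_start = g$coding_start, coding_end = g$coding_end,
           cds = g$cds, tseq = g$tseq,
           utr5 = g$def$utr5, utr3 = g$def$utr3)
    }),
    tx = tx_objects,
    contig_seq = contig
  )
  manifest$reference <- load_reference(fasta)
  # engineered-site bookkeeping (genomic positions resolved through the maps)
  g1 <- tx_objects$GENE1
  cpos_g <- function(tx, kind, base, offset = 0L, anchor = NA_character_) {
    coding_to_genomic(tx, coding_pos(kind, base, offset, anchor_kind = anchor))
  }
  manifest$sites <- list(
    donor_ladder = list(tx = "GENE1",
      gpos = vapply(1:9, function(k) cpos_g(g1, "cds", 600L, k, "cds"), integer(1)),
      ref = strsplit("GTAAGTATC", "")[[1]],
      alt = strsplit("ACGGACGCT", "")[[1]],
      classes = c("ESS", "ESS", "SS", "SS", "SS5", "SS", "SS", "SS", "INT"),
      impacts = c(1L, 1L, 3L, 3L, 2L, 3L, 3L, 3L, 3L)),
    acceptor_ttract = list(tx = "GENE1",
      anchor_g = cpos_g(g1, "cds", 2929L, -9L, "cds")),
    intron3_polyA = list(tx = "GENE1",
      run_start = cpos_g(g1, "cds", 6000L, 50L, "cds"), run_len = 6L),
    utr5_site = list(tx = "GENE1", gpos = cpos_g(g1, "utr5", 21L)),
    utr3_site = list(tx = "GENE1", gpos = cpos_g(g1, "utr3", 20L)),
    shared_polyA = list(
      run_start = genes$GENE2$gend - 20L + 3L, run_len = 6L),
    fig1_anchor = list(tx = "GENE3",
      gpos = cpos_g(tx_objects$GENE3, "cds", 301L, -9L, "cds"))
  )
  manifest
}

write_fixture_gtf <- function(path, contig, genes) {
  lines <- character(0)
  for (g in genes) {
    d <- g$def
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     d$gene, d$id, d$gene)
    for (i in seq_along(g$exon_starts)) {
      lines <- c(lines, paste(contig, "fixture", "exon", g$exon_starts[i],
                              g$exon_ends[i], ".", d$strand, ".", attrs,
                              sep = "\t"))
      cs <- max(g$exon_starts[i], g$coding_start)
      ce <- min(g$exon_ends[i], g$coding_end)
      if (cs <= ce) {
        lines <- c(lines, paste(contig, "fixture", "CDS", cs, ce, ".",
                                d$strand, "0", attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

FIXTURE_CASES <- c("table2_substitutions", "frameshift_del", "start_codon_fs",
                   "cct_dup", "fig1_boundary", "splice_ladder", "ss_int_dup",
                   "synon_ee", "utr_cases", "homopolymer_del", "overlap_pair")

#' Generate a fixture VCF with truth annotations
#'
#' Emits anchor-base VCF records (indels LEFT-aligned, the adversarial input
#' for a 3'-normalizing annotator) for the requested engineered cases, plus a
#' truth table of the expected annotation per record. `NA` truth cells mean
#' "not asserted".
#'
#' @param manifest From [generate_fixture_genome()].
#' @param cases Subset of the case catalogue (default: all).
#' @param path Output VCF path (default: `cases.vcf` next to the FASTA).
#' @return List with `vcf` (path) and `truth` (tibble).
#' @export
generate_fixture_vcf <- function(manifest, cases = FIXTURE_CASES,
                                 path = file.path(manifest$dir, "cases.vcf")) {
  unknown <- setdiff(cases, FIXTURE_CASES)
  if (length(unknown)) stop("unknown fixture case(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  ref <- manifest$reference
  ctg <- manifest$contig
  g1 <- manifest$tx$GENE1
  base_at <- function(g) ref_fetch(ref, ctg, g, g)
  g_of <- function(tx, base, offset = 0L, kind = "cds") {
    coding_to_genomic(tx, coding_pos(kind, base, offset,
                                     anchor_kind = if (offset != 0L) kind else NA))
  }
  recs <- list()
  add <- function(id, pos, refa, alta, tx_id = NA, csn = NA, class = NA,
                  so = NA, impact = NA, alt_ann = NA, alt_class = NA,
                  alt_so = NA) {
    recs[[length(recs) + 1L]] <<- tibble::tibble(
      id = id, pos = as.integer(pos), ref = refa, alt = alta,
      transcript = tx_id, csn = csn, class = class, so = so,
      impact = as.integer(impact), alt_ann = alt_ann, alt_class = alt_class,
      alt_so = alt_so)
  }

  if ("table2_substitutions" %in% cases) {
    vec <- list(
      list(1040L, "G", "c.1040A>G_p.Gln347Arg", "NSY", "missense_variant", 2L),
      list(1911L, "C", "c.1911T>C_p.=", "SY", "synonymous_variant", 3L),
      list(3264L, "C", "c.3264T>C_p.=", "SY", "synonymous_variant", 3L),
      list(3515L, "T", "c.3515C>T_p.Ser1172Leu", "NSY", "missense_variant", 2L),
      list(3516L, "A", "c.3516G>A_p.=", "SY", "synonymous_variant", 3L),
      list(5682L, "G", "c.5682C>G_p.Tyr1894X", "SG", "stop_gained", 1L),
      list(5855L, "A", "c.5855T>A_p.Leu1952X", "SG", "stop_gained", 1L),
      list(6131L, "T", "c.6131G>T_p.Gly2044Val", "NSY", "missense_variant", 2L),
      list(6675L, "G", "c.6675A>G_p.=", "SY", "synonymous_variant", 3L),
      list(7558L, "T", "c.7558C>T_p.Arg2520X", "SG", "stop_gained", 1L),
      list(8182L, "A", "c.8182G>A_p.Val2728Ile", "NSY", "missense_variant", 2L),
      list(9976L, "T", "c.9976A>T_p.Lys3326X", "SG", "stop_gained", 1L))
    for (v in vec) {
      g <- g_of(g1, v[[1L]])
      add("table2", g, base_at(g), v[[2L]], g1$transcript_id, v[[3L]], v[[4L]],
          v[[5L]], v[[6L]])
    }
  }
  if ("frameshift_del" %in% cases) {
    # one-base deletion in the TT run at c.245-246, left-aligned anchor at c.244
    g <- g_of(g1, 244L)
    add("frameshift_del", g, paste0(base_at(g), base_at(g + 1L)), base_at(g),
        g1$transcript_id, csn = "c.246delT", class = "FS",
        so = "frameshift_variant", impact = 1L)
  }
  if ("start_codon_fs" %in% cases) {
    g <- g_of(g1, 1L)  # delete the T of ATG; anchor at c.1
    add("start_codon_fs", g, paste0(base_at(g), base_at(g + 1L)), base_at(g),
        g1$transcript_id, class = "FS", impact = 1L)
  }
  if ("cct_dup" %in% cases) {
    g2 <- manifest$tx$GENE2
    g <- g_of(g2, 2104L)
    add("cct_dup", g, base_at(g), paste0(base_at(g), "CTC"), g2$transcript_id,
        csn = "c.2107_2109dupCCT_p.Pro703dup", class = "IF",
        so = "inframe_insertion", impact = 2L,
        alt_ann = "c.2104_2105insCTC_p.Pro703dup", alt_class = "",
        alt_so = "")
  }
  if ("fig1_boundary" %in% cases) {
    g3 <- manifest$tx$GENE3
    g <- manifest$sites$fig1_anchor$gpos
    add("fig1_boundary", g, base_at(g), paste0(base_at(g), "GGG"),
        g3$transcript_id, csn = "c.304_306dupGGG_p.Gly102dup", class = "IF",
        so = "inframe_insertion", impact = 2L,
        alt_ann = "c.301-9_301-8insGGG", alt_class = "INT",
        alt_so = "intron_variant")
  }
  if ("splice_ladder" %in% cases) {
    lad <- manifest$sites$donor_ladder
    for (k in 1:9) {
      add(paste0("splice_ladder_", k), lad$gpos[k], lad$ref[k], lad$alt[k],
          g1$transcript_id, class = lad$classes[k], impact = lad$impacts[k])
    }
  }
  if ("ss_int_dup" %in% cases) {
    g <- manifest$sites$acceptor_ttract$anchor_g
    add("ss_int_dup", g, base_at(g), paste0(base_at(g), "T"),
        g1$transcript_id, csn = "c.2929-5dupT", class = "SS",
        so = "intron_variant|splice_region_variant", impact = 3L,
        alt_ann = "c.2929-9_2929-8insT", alt_class = "INT",
        alt_so = "intron_variant")
  }
  if ("synon_ee" %in% cases) {
    g <- g_of(g1, 600L)
    add("synon_ee", g, base_at(g), "A", g1$transcript_id,
        csn = "c.600G>A_p.=", class = "EE",
        so = "splice_region_variant|synonymous_variant", impact = 2L)
  }
  if ("utr_cases" %in% cases) {
    g5 <- manifest$sites$utr5_site$gpos
    b <- base_at(g5)
    add("utr5", g5, b, setdiff(c("A", "C", "G", "T"), b)[1L],
        g1$transcript_id, class = "5PU", impact = 3L)
    g3p <- manifest$sites$utr3_site$gpos
    b <- base_at(g3p)
    add("utr3", g3p, b, setdiff(c("A", "C", "G", "T"), b)[1L],
        g1$transcript_id, class = "3PU", impact = 3L)
  }
  if ("homopolymer_del" %in% cases) {
    rs <- manifest$sites$intron3_polyA$run_start
    add("homopolymer_del", rs - 1L,
        paste0(base_at(rs - 1L), base_at(rs)), base_at(rs - 1L),
        g1$transcript_id, class = "INT", so = "intron_variant", impact = 3L)
  }
  if ("overlap_pair" %in% cases) {
    rs <- manifest$sites$shared_polyA$run_start
    add("overlap_pair", rs - 1L,
        paste0(base_at(rs - 1L), base_at(rs)), base_at(rs - 1L),
        NA, class = "3PU", impact = 3L)
  }

  truth <- dplyr::bind_rows(recs)
  truth$chrom <- ctg
  o <- order(truth$pos)
  truth <- truth[o, ]
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", ctg, manifest$contig_length),
              paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                  "FILTER", "INFO"), collapse = "\t")))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t200\tPASS\t.",
                  truth$chrom, truth$pos, truth$id, truth$ref, truth$alt)
  writeLines(c(header, body), path)
  list(vcf = path, truth = truth)
}

#' Mirror a fixture: reverse-complement the genome and flip every strand
#'
#' Testing utility for the strand-symmetry property: a position g maps to
#' N - g + 1, exon bounds mirror, strands flip, and [mirror_variant()] maps
#' variants into the mirrored frame. CSN strings and classes computed in the
#' mirrored fixture must equal the originals.
#'
#' @param manifest From [generate_fixture_genome()].
#' @return List with `reference` (mirrored `ref_genome`), `tx` (mirrored
#'   transcript list) and `n` (contig length).
#' @export
mirror_fixture <- function(manifest) {
  n <- manifest$contig_length
  mseq <- reverse_complement(manifest$contig_seq)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", manifest$contig), mseq), fa)
  mref <- load_reference(fa)
  mtx <- lapply(manifest$tx, function(tx) {
    transcript(tx$transcript_id, tx$gene, tx$chrom,
               if (tx$strand == "+") "-" else "+",
               rev(n - tx$exon_ends + 1L), rev(n - tx$exon_starts + 1L),
               n - tx$coding_end + 1L, n - tx$coding_start + 1L)
  })
  list(reference = mref, tx = mtx, n = n)
}

#' Map a trimmed variant into the mirrored genome frame
#'
#' @param v A `gvariant`. @param n Contig length.
#' @return The equivalent `gvariant` on the mirrored contig.
#' @export
mirror_variant <- function(v, n) {
  if (v$vtype == "insertion") {
    gvariant(v$chrom, n - v$pos, "", reverse_complement(v$alt),
             qual = v$qual, filter = v$filter)
  } else {
    q <- v$pos + nchar(v$ref) - 1L
    gvariant(v$chrom, n - q + 1L, reverse_complement(v$ref),
             reverse_complement(v$alt), qual = v$qual, filter = v$filter)
  }
}
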