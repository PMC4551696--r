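# Nucleotide+protein CSN string generation.

test_that("exonic substitution CSN discriminates nonsynonymous/synonymous/stop-gain", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  at <- function(cbase) coding_to_genomic(tx, csnannot:::coding_pos("cds", cbase, 0L))
  csn <- function(cbase, alt) {
    csn_substitution(tx, gvariant("1", at(cbase),
                                  ref_fetch(m$reference, "1", at(cbase), at(cbase)),
                                  alt), m$reference)$full
  }
  expect_equal(csn(1040L, "G"), "c.1040A>G_p.Gln347Arg")
  expect_equal(csn(1911L, "C"), "c.1911T>C_p.=")
  expect_equal(csn(5682L, "G"), "c.5682C>G_p.Tyr1894X")
  expect_equal(csn(9976L, "T"), "c.9976A>T_p.Lys3326X")
})

test_that("intronic and UTR substitutions carry decorated coordinates, no protein part", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  lad <- m$sites$donor_ladder
  got <- csn_substitution(tx, gvariant("1", lad$gpos[5], lad$ref[5], lad$alt[5]),
                          m$reference)
  expect_equal(got$full, "c.600+5G>A")
  expect_equal(got$protein, "")
  u5 <- m$sites$utr5_site$gpos
  b <- ref_fetch(m$reference, "1", u5, u5)
  expect_match(csn_substitution(tx, gvariant("1", u5, b, flip_base(b)),
                                m$reference)$full, "^c\\.-21")
})

test_that("frameshifting deletions use nucleotide-only notation", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  g <- coding_to_genomic(tx, csnannot:::coding_pos("cds", 245L, 0L))
  v <- gvariant("1", g, "T", "")  # left member of the TT run at c.245-246
  canonical <- normalize_for_transcript(v, tx, m$reference)$canonical
  got <- csn_indel(tx, canonical, m$reference)
  expect_equal(got$full, "c.246delT")
  expect_equal(got$protein, "")
})

test_that("insertions equal to the preceding reference become duplications", {
  m <- get_manifest()
  tx2 <- m$tx$GENE2
  g <- coding_to_genomic(tx2, csnannot:::coding_pos("cds", 2104L, 0L))
  v <- gvariant("1", g, "", "CTC")  # left-aligned representation
  canonical <- normalize_for_transcript(v, tx2, m$reference)$canonical
  expect_equal(csn_indel(tx2, canonical, m$reference)$full,
               "c.2107_2109dupCCT_p.Pro703dup")
  # the most 5' alternative keeps ins notation with the same protein change
  alt5 <- normalize_for_transcript(v, tx2, m$reference)$alt5
  expect_equal(csn_indel(tx2, alt5, m$reference)$full,
               "c.2104_2105insCTC_p.Pro703dup")
})

test_that("intronic duplication near the acceptor uses offset coordinates", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  g <- m$sites$acceptor_ttract$anchor_g
  v <- gvariant("1", g, "", "T")  # insertion between offsets -9 and -8
  nrm <- normalize_for_transcript(v, tx, m$reference)
  expect_equal(csn_indel(tx, nrm$canonical, m$reference)$full, "c.2929-5dupT")
  expect_equal(csn_indel(tx, nrm$alt5, m$reference)$full, "c.2929-9_2929-8insT")
})

test_that("every member of a representation set yields the same canonical CSN", {
  m <- get_manifest()
  tx <- m$tx$GENE3
  v <- gvariant("1", m$sites$fig1_anchor$gpos, "", "GGG")
  reps <- enumerate_representations(v, m$reference)
  expect_gt(length(reps$members), 2L)
  strs <- vapply(reps$members, function(mm) {
    canonical <- normalize_for_transcript(mm, tx, m$reference)$canonical
    csn_indel(tx, canonical, m$reference)$full
  }, character(1))
  expect_equal(unique(strs), "c.304_306dupGGG_p.Gly102dup")
})

test_that("CSN protein parts never contain '*' or 'ter'; no whitespace anywhere", {
  rec <- get_records()
  csns <- c(rec$csn, rec$alt_ann)
  csns <- csns[nzchar(csns) & csns != "."]
  expect_false(any(grepl("[[:space:]]|ter", csns)))
  prot <- ifelse(grepl("_p\\.", csns), sub("^.*_p\\.", "", csns), "")
  expect_false(any(grepl("\\*", prot)))  # stop is written X, never *
  # exactly one joining underscore between nucleotide and protein parts
  expect_true(all(lengths(regmatches(csns, gregexpr("_p\\.", csns))) <= 1L))
})

test_that("toy single-exon gene: dup coordinates and codon arithmetic", {
  # CDS "ATG CCT GGG TAA" on its own contig; insertion of CCT after c.6
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy", paste0("AAAA", "ATGCCTGGGTAA", "AAAA")), fa)
  ref <- load_reference(fa)
  tx <- transcript("ENSTTOY", "TOY", "toy", "+", 1L, 20L, 5L, 16L)
  v_left <- gvariant("toy", 8L, "", "CTC")   # equivalent left placement
  v_can <- normalize_for_transcript(v_left, tx, ref)$canonical
  expect_equal(csn_indel(tx, v_can, ref)$full, "c.4_6dupCCT_p.Pro2dup")
})

test_that("protein facts agree with full-retranslation oracle on random variants", {
  m <- get_manifest()
  set.seed(101)
  n_checked <- 0L
  for (i in 1:400) {
    nm <- sample(c("GENE2", "GENE3", "GENE5", "GENE6"), 1L)
    tx <- m$tx[[nm]]
    span <- tx$exon_starts[1]:tx$exon_ends[tx$n_exons]
    p <- sample(span, 1L)
    kind <- sample(c("sub", "del1", "del3", "ins"), 1L)
    v <- switch(kind,
      sub = {
        b <- ref_fetch(m$reference, "1", p, p)
        gvariant("1", p, b, flip_base(b))
      },
      del1 = gvariant("1", p, ref_fetch(m$reference, "1", p, p), ""),
      del3 = gvariant("1", p, ref_fetch(m$reference, "1", p, p + 2L), ""),
      ins = gvariant("1", p, "",
                     paste(sample(c("A", "C", "G", "T"),
                                  sample(c(1L, 2L, 3L), 1L), TRUE), collapse = "")))
    can <- normalize_for_transcript(v, tx, m$reference)$canonical
    if (can$pos + max(nchar(can$ref) - 1L, 0L) > tx$exon_ends[tx$n_exons] ||
        can$pos < tx$exon_starts[1]) next
    ofacts <- oracle_protein_facts(tx, can, m$reference)
    if (length(ofacts) == 1L && is.na(ofacts)) next  # boundary span
    got <- protein_consequence(tx, can, m$reference)$facts
    expect_equal(got$cds_overlap && got$contained, ofacts$cds_overlap,
                 info = paste(nm, kind, can$pos))
    if (!ofacts$cds_overlap) next
    expect_equal(got$frameshift, ofacts$frameshift, info = paste(nm, kind, can$pos))
    expect_equal(got$synonymous, ofacts$synonymous, info = paste(nm, kind, can$pos))
    expect_equal(got$stop_gained, ofacts$stop_gained, info = paste(nm, kind, can$pos))
    expect_equal(got$stop_lost, ofacts$stop_lost, info = paste(nm, kind, can$pos))
    expect_equal(got$start_lost, ofacts$start_lost, info = paste(nm, kind, can$pos))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})
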