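# 14-class priority ontology, SO terms and impact categories.

test_that("splice ladder classifies ESS/ESS/SS/SS/SS5/SS/SS/SS/INT with matching impacts", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  lad <- m$sites$donor_ladder
  got <- vapply(1:9, function(k) {
    classify_variant(tx, gvariant("1", lad$gpos[k], lad$ref[k], lad$alt[k]),
                     m$reference)
  }, character(1))
  expect_equal(got, c("ESS", "ESS", "SS", "SS", "SS5", "SS", "SS", "SS", "INT"))
  expect_equal(impact_category(got), c(1L, 1L, 3L, 3L, 2L, 3L, 3L, 3L, 3L))
})

test_that("a frameshifting deletion across the start codon is FS, not IM", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  g <- coding_to_genomic(tx, csnannot:::coding_pos("cds", 2L, 0L))
  v <- normalize_for_transcript(gvariant("1", g, "T", ""), tx, m$reference)$canonical
  expect_equal(classify_variant(tx, v, m$reference), "FS")
  # the same codon hit by a substitution is IM
  b <- ref_fetch(m$reference, "1", g, g)
  expect_equal(classify_variant(tx, gvariant("1", g, b, flip_base(b)), m$reference),
               "IM")
})

test_that("synonymous change at an exon-end base is EE, not SY", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  g <- coding_to_genomic(tx, csnannot:::coding_pos("cds", 600L, 0L))
  v <- gvariant("1", g, "G", "A")
  expect_equal(classify_variant(tx, v, m$reference), "EE")
  expect_equal(so_term("EE", tx, v, m$reference),
               "splice_region_variant|synonymous_variant")
  expect_equal(impact_category("EE"), 2L)
})

test_that("canonical and most-5' representations may classify differently", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  v <- gvariant("1", m$sites$acceptor_ttract$anchor_g, "", "T")
  nrm <- normalize_for_transcript(v, tx, m$reference)
  expect_equal(classify_variant(tx, nrm$canonical, m$reference), "SS")
  expect_equal(classify_variant(tx, nrm$alt5, m$reference), "INT")
  expect_equal(so_term("SS"), "intron_variant|splice_region_variant")
  expect_equal(so_term("INT"), "intron_variant")
})

test_that("ESS SO term distinguishes donor and acceptor sites", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  lad <- m$sites$donor_ladder
  vd <- gvariant("1", lad$gpos[1], lad$ref[1], lad$alt[1])
  expect_equal(so_term("ESS", tx, vd, m$reference), "splice_donor_variant")
  ga <- coding_to_genomic(tx, csnannot:::coding_pos("cds", 601L, 0L)) - 1L
  b <- ref_fetch(m$reference, "1", ga, ga)
  va <- gvariant("1", ga, b, flip_base(b))
  expect_equal(classify_variant(tx, va, m$reference), "ESS")
  expect_equal(so_term("ESS", tx, va, m$reference), "splice_acceptor_variant")
})

test_that("impact categories partition all 14 classes", {
  cls <- c("SG", "ESS", "SS5", "SS", "EE", "FS", "IM", "SL", "IF", "NSY",
           "SY", "INT", "5PU", "3PU")
  imp <- impact_category(cls)
  expect_setequal(cls[imp == 1L], c("ESS", "FS", "SG"))
  expect_setequal(cls[imp == 2L], c("NSY", "SS5", "IF", "IM", "SL", "EE"))
  expect_setequal(cls[imp == 3L], c("SY", "SS", "INT", "5PU", "3PU"))
  expect_error(impact_category("XX"), "unknown class")
})

test_that("stop codon changes: loss is SL, stop-to-stop falls through to SY", {
  m <- get_manifest()
  tx <- m$tx$GENE6
  cds_len <- tx$cds_length
  # GENE6 stop codon is TAA; transcript-sense base swaps
  g3 <- coding_to_genomic(tx, csnannot:::coding_pos("cds", cds_len, 0L))
  b <- ref_fetch(m$reference, "1", g3, g3)    # genomic base under c.<last>
  # TAA -> TAG (third base A->G in transcript sense) remains a stop
  alt_t <- "G"
  alt_g <- if (tx$strand == "-") reverse_complement(alt_t) else alt_t
  expect_equal(classify_variant(tx, gvariant("1", g3, b, alt_g), m$reference), "SY")
  # TAA -> CAA loses the stop
  g1 <- coding_to_genomic(tx, csnannot:::coding_pos("cds", cds_len - 2L, 0L))
  b1 <- ref_fetch(m$reference, "1", g1, g1)
  alt_g1 <- if (tx$strand == "-") reverse_complement("C") else "C"
  expect_equal(classify_variant(tx, gvariant("1", g1, b1, alt_g1), m$reference), "SL")
  # inframe deletion of the stop codon is SL too (toy gene, unshiftable)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s", paste0("TTTT", "ATGCATTAA", "CCGG")), fa)
  toy_ref <- load_reference(fa)
  toy <- transcript("ENSTS", "S", "s", "+", 1L, 17L, 5L, 13L)
  vdel <- normalize_for_transcript(gvariant("s", 11L, "TAA", ""),
                                   toy, toy_ref)$canonical
  expect_equal(classify_variant(toy, vdel, toy_ref), "SL")
})

test_that("exhaustive sweep over a reverse-strand gene matches the slow predicate oracle", {
  m <- get_manifest()
  tx <- m$tx$GENE6
  span <- tx$exon_starts[1]:tx$exon_ends[tx$n_exons]
  mismatches <- character(0)
  for (p in span) {
    vs <- list()
    b <- ref_fetch(m$reference, "1", p, p)
    vs$sub <- gvariant("1", p, b, flip_base(b))
    vs$del1 <- gvariant("1", p, b, "")
    if (p + 2L <= tx$exon_ends[tx$n_exons]) {
      vs$del3 <- gvariant("1", p, ref_fetch(m$reference, "1", p, p + 2L), "")
    }
    vs$ins1 <- gvariant("1", p, "", "A")
    for (nm in names(vs)) {
      can <- normalize_for_transcript(vs[[nm]], tx, m$reference)$canonical
      if (can$pos < span[1] ||
          can$pos + max(nchar(can$ref) - 1L, 0L) > span[length(span)]) next
      got <- classify_variant(tx, can, m$reference)
      want <- oracle_classify(tx, can, m$reference)
      if (!identical(got, want)) {
        mismatches <- c(mismatches, paste0(nm, "@", p, ": ", got, " vs ", want))
      }
    }
  }
  expect_equal(mismatches, character(0))
})

test_that("sweep over a forward-strand gene with UTRs matches the oracle", {
  m <- get_manifest()
  tx <- m$tx$GENE3
  span <- tx$exon_starts[1]:tx$exon_ends[tx$n_exons]
  mismatches <- character(0)
  for (p in span) {
    b <- ref_fetch(m$reference, "1", p, p)
    for (v in list(gvariant("1", p, b, flip_base(b)),
                   gvariant("1", p, b, ""))) {
      can <- normalize_for_transcript(v, tx, m$reference)$canonical
      if (can$pos < span[1] ||
          can$pos + max(nchar(can$ref) - 1L, 0L) > span[length(span)]) next
      got <- classify_variant(tx, can, m$reference)
      want <- oracle_classify(tx, can, m$reference)
      if (!identical(got, want)) {
        mismatches <- c(mismatches, paste0(p, ": ", got, " vs ", want))
      }
    }
  }
  expect_equal(mismatches, character(0))
})
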