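# Output formatting, filters, identifiers, writers and the CLI driver.

test_that("TRINFO formats strand/span/exons/length with half-away rounding", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  expect_equal(format_trinfo(tx),
               sprintf("+/%.1fkb/4/%.1fkb", floor(tx$genomic_span / 100 + 0.5) / 10,
                       floor(tx$transcript_length / 100 + 0.5) / 10))
  mk <- function(span_len) {
    transcript("T", "G", "c", "+", 1L, span_len,
               4L, 4L + 3L * floor((span_len - 8L) / 3L) - 1L)
  }
  # rounding table: 949 -> 0.9kb, 950 -> 1.0kb, 1049 -> 1.0kb
  expect_equal(strsplit(format_trinfo(mk(949L)), "/")[[1]][2], "0.9kb")
  expect_equal(strsplit(format_trinfo(mk(950L)), "/")[[1]][2], "1.0kb")
  expect_equal(strsplit(format_trinfo(mk(1049L)), "/")[[1]][2], "1.0kb")
  rv <- m$tx$GENE6
  expect_match(format_trinfo(rv), "^-/")
})

test_that("Loc labels exons, introns and UTRs in transcription order", {
  m <- get_manifest()
  tx <- m$tx$GENE1
  at <- function(base, off = 0L, kind = "cds")
    coding_to_genomic(tx, csnannot:::coding_pos(kind, base, off, anchor_kind = kind))
  expect_equal(format_loc(tx, gvariant("1", at(1040L), "A", "G")), "Ex2")
  expect_equal(format_loc(tx, gvariant("1", at(600L, 5L), "G", "A")), "In1/2")
  expect_equal(format_loc(tx, gvariant("1", at(21L, kind = "utr5"), "A", "C")), "5UTR")
  expect_equal(format_loc(tx, gvariant("1", at(20L, kind = "utr3"), "A", "C")), "3UTR")
  # reverse strand: the genomically last intron is In1/2
  rv <- m$tx$GENE5
  g_in <- rv$exon_ends[2] + 10L   # genomic gap between exons 2 and 3
  b <- ref_fetch(m$reference, "1", g_in, g_in)
  expect_equal(format_loc(rv, gvariant("1", g_in, b, flip_base(b))), "In1/2")
  g_in1 <- rv$exon_ends[1] + 10L
  b <- ref_fetch(m$reference, "1", g_in1, g_in1)
  expect_equal(format_loc(rv, gvariant("1", g_in1, b, flip_base(b))), "In2/3")
})

test_that("SNP identifiers match across equivalent indel representations", {
  m <- get_manifest()
  rs <- m$sites$intron3_polyA$run_start
  tsv <- withr::local_tempfile(fileext = ".tsv")
  # catalogue stores the LEFT-aligned deletion with an anchor base
  writeLines(c("chrom\tpos\tref\talt\trsid",
               sprintf("1\t%d\t%s\t%s\trs12345",
                       rs - 1L,
                       ref_fetch(m$reference, "1", rs - 1L, rs),
                       ref_fetch(m$reference, "1", rs - 1L, rs - 1L)),
               sprintf("1\t%d\tA\tG\trs99999", rs)), tsv)
  snp <- load_snp_db(tsv, m$reference)
  # right-aligned equivalent query still matches
  vr <- shift_variant(gvariant("1", rs, "A", ""), m$reference, "right")
  expect_equal(assign_snp_id(vr, snp, m$reference), "rs12345")
  expect_equal(assign_snp_id(gvariant("1", rs, "A", "G"), snp, m$reference),
               "rs99999")
  expect_equal(assign_snp_id(gvariant("1", rs, "A", "C"), snp, m$reference), "")
})

test_that("TSV output has the 18 standard columns with '.' for empty cells", {
  rec <- get_records()
  out <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_tsv(rec, out)
  lines <- readLines(out)
  hdr <- strsplit(lines[1], "\t")[[1]]
  expect_equal(hdr, c("Chr", "Pos", "Ref", "Alt", "Qual", "Filter", "Type",
                      "ENST", "Gene", "TRINFO", "Loc", "CSN", "Class", "SO",
                      "Impact", "Alt ann", "Alt class", "Alt SO"))
  expect_equal(length(lines), nrow(rec) + 1L)
  cells <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(cells) == 18L))
  expect_true(all(vapply(cells, function(x) all(nzchar(x)), logical(1))))
  # variant type labels are capitalized words
  expect_true(all(vapply(cells, `[[`, character(1), 7) %in%
                    c("Substitution", "Insertion", "Deletion", "Complex")))
})

test_that("echo columns preserve the split input allele", {
  m <- get_manifest()
  rec <- get_records()
  truth <- get_cases()$truth
  for (i in seq_len(nrow(truth))) {
    sub <- rec[rec$pos == truth$pos[i] & rec$ref == truth$ref[i] &
               rec$alt == truth$alt[i], ]
    expect_gt(nrow(sub), 0L)
    expect_true(all(sub$qual == "200"))
    expect_true(all(sub$filter == "PASS"))
  }
})

test_that("VCF-append output restores the input byte-for-byte when stripped", {
  m <- get_manifest()
  cases <- get_cases()
  rec <- get_records()
  out <- withr::local_tempfile(fileext = ".vcf")
  write_annotated_vcf(rec, cases$vcf, out)
  orig <- readLines(cases$vcf)
  got <- readLines(out)
  # one header line added
  expect_equal(length(got), length(orig) + 1L)
  expect_true(any(grepl("^##INFO=<ID=CSNANN", got)))
  stripped <- got[!grepl("^##INFO=<ID=CSNANN", got)]
  body <- !startsWith(stripped, "#")
  strip_info <- function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[8] <- sub(";?CSNANN=[^\t;]*", "", f[8])
    if (f[8] == "") f[8] <- "."
    paste(f, collapse = "\t")
  }
  stripped[body] <- vapply(stripped[body], strip_info, character(1), USE.NAMES = FALSE)
  expect_identical(stripped, orig)
})

test_that("annotation is deterministic and identical for any worker count", {
  m <- get_manifest()
  vars <- read_vcf(get_cases()$vcf, m$reference)
  r1 <- annotate_variants(vars, get_db(), m$reference, workers = 1L)
  r4 <- annotate_variants(vars, get_db(), m$reference, workers = 4L)
  expect_identical(r1, r4)
  f1 <- withr::local_tempfile(); f4 <- withr::local_tempfile()
  write_annotated_tsv(r1, f1); write_annotated_tsv(r4, f4)
  expect_identical(readLines(f1), readLines(f4))
})

test_that("intergenic, gene and region filters behave as documented", {
  m <- get_manifest()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  g_inter <- 12500L  # gap between GENE1 and GENE2
  b <- ref_fetch(m$reference, "1", g_inter, g_inter)
  g_in1 <- coding_to_genomic(m$tx$GENE1, csnannot:::coding_pos("cds", 1040L, 0L))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("1\t%d\t.\tA\tG\t9\tPASS\t.", g_in1),
               sprintf("1\t%d\t.\t%s\t%s\t9\tPASS\t.", g_inter, b, flip_base(b))),
             vcf)
  vars <- read_vcf(vcf, m$reference)
  keep <- annotate_variants(vars, get_db(), m$reference, drop_intergenic = FALSE)
  drop <- annotate_variants(vars, get_db(), m$reference, drop_intergenic = TRUE)
  expect_equal(nrow(keep), 2L)   # one annotated + one pass-through row
  expect_equal(nrow(drop), 1L)
  expect_equal(sum(keep$transcript == "."), 1L)
  only_g2 <- annotate_variants(vars, get_db(), m$reference, genes = "GENE2")
  expect_equal(nrow(only_g2), 0L)
  only_g1 <- annotate_variants(vars, get_db(), m$reference,
                               drop_intergenic = TRUE, genes = "GENE1")
  expect_equal(unique(only_g1$gene), "GENE1")
  reg <- tibble::tibble(chrom = "1", start = g_in1 - 5L, end = g_in1 + 5L)
  in_reg <- annotate_variants(vars, get_db(), m$reference, regions = reg,
                              drop_intergenic = TRUE)
  expect_equal(nrow(in_reg), 1L)
  expect_equal(in_reg$csn, "c.1040A>G_p.Gln347Arg")
})

test_that("the CLI annotates end-to-end and signals usage errors", {
  m <- get_manifest()
  cases <- get_cases()
  out <- withr::local_tempfile(fileext = ".tsv")
  log <- withr::local_tempfile(fileext = ".log")
  code <- run_cli(c("--in", cases$vcf, "--ref", m$fasta, "--db", m$gtf,
                    "--out", out, "--format", "tsv", "--log", log))
  expect_equal(code, 0L)
  lines <- readLines(out)
  expect_equal(strsplit(lines[1], "\t")[[1]][1], "Chr")
  expect_gt(length(lines), nrow(cases$truth))
  expect_true(any(grepl("annotation records", readLines(log))))
  expect_equal(run_cli(c("--in", cases$vcf)), 2L)
  expect_equal(suppressMessages(
    run_cli(c("--in", "nope.vcf", "--ref", m$fasta, "--db", m$gtf))), 1L)
})

test_that("summaries and plots are produced from annotation records", {
  rec <- get_records()
  s <- summarize_annotation(rec)
  expect_true(all(c("class", "impact", "n") %in% names(s)))
  expect_gt(sum(s$n), 0L)
  p <- plot_class_distribution(rec)
  expect_s3_class(p, "ggplot")
})
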