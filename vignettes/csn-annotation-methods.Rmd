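---
title: "Strand-aware clinical variant annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware clinical variant annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csnannot)
```

## The problem

Clinical laboratories describe a variant relative to the *coding transcript*:
indels are placed at their most 3' equivalent position in transcript
orientation, and the nucleotide and protein consequences are reported
together. VCF-producing pipelines instead left-align indels on the forward
genomic strand. For the roughly half of genes transcribed from the forward
strand these two conventions place the same indel at *different* coordinates,
and in repetitive sequence the alternative placements can even belong to
different functional classes (an insertion at an intron–exon boundary may be
an intronic variant in one representation and an inframe duplication in the
other). `csnannot` resolves this by normalizing every indel per transcript,
emitting one fixed Clinical Sequencing Nomenclature (CSN) string per variant,
and flagging the most 5' alternative representation alongside.

## The annotation model

For each variant × overlapping-transcript pair the engine computes:

1. **Minimal alleles.** The VCF record is split per ALT allele and trimmed:
   longest common suffix first, then longest common prefix. Suffix-first is an
   arbitrary but fixed choice — normalization re-shifts indels afterwards, so
   any order yields the same canonical form; fixing one keeps intermediate
   results deterministic.
2. **Canonical placement.** Pure insertions and deletions are slid base by
   base through their repeat context. The canonical representation is the
   genomic-right extreme for `+` transcripts and the genomic-left extreme for
   `-` transcripts (i.e. most 3' in transcript orientation); the opposite
   extreme is the reported alternative. Substitutions and complex
   (length-changing, both-alleles-nonempty) variants are immobile.
   Sliding is capped at 10 kb to guarantee termination on degenerate inputs.
3. **CSN string.** `c.` coordinates count CDS bases, with `-k`/`*k` for UTRs
   and `+k`/`-k` intron offsets in transcript orientation. An insertion whose
   bases equal the immediately 5' reference copy (transcript sense) becomes a
   `dup` citing that copy. Protein parts use three-letter codes, `p.=` for
   synonymous changes and `X` for stops; frameshifting indels carry no
   protein part at all, because the hypothetical downstream stop is wrong for
   the majority of transcripts subject to nonsense-mediated decay. Inframe
   protein changes are localized by trimming the longest common prefix of the
   reference and edited proteins first, which places the change at its most
   3' (HGVS-style) protein position and makes duplication detection exact.
4. **One class from a 14-class priority ontology.** SG, ESS, SS5, SS, EE, FS,
   IM, SL, IF, NSY, SY, INT, 5PU, 3PU — the first class whose predicate holds
   is assigned, so e.g. a frameshifting deletion that also removes the start
   codon is FS, not IM. A Sequence Ontology term (lowercase, `|`-joined for
   compound cases) and an impact category (1 = ESS/FS/SG, 2 =
   NSY/SS5/IF/IM/SL/EE, 3 = SY/SS/INT/5PU/3PU) accompany the class.
5. **Alternative annotation.** The most 5' representation is annotated
   independently; its CSN is reported whenever it differs, and its class/SO
   only when those differ too. This is the clinically important flag:
   representations of one physical indel can differ in predicted effect.

## Overlap semantics for "alters"

The class definitions say a variant "alters" a splice-site or exon-end base.
For substitutions, deletions and complex variants this is interval
intersection with the named base set. For insertions the affected bases are
ambiguous, and the package uses two rules, stated here because they are a
design choice:

* an insertion that duplicates its 5' reference copy affects the bases of
  that copy (so a `dupT` at intron offset −5 alters the −5 base);
* any other insertion affects a base set only when **both** flanking bases of
  its breakpoint lie in the set (so an insertion between offsets −9 and −8
  does not alter the −8..−1 splice region and stays intronic).

This is the minimal reading that reproduces the intended dup/ins class pairs.
Exon-end (EE) bases are the first and last three bases of each exon in
transcript orientation, excluding the transcript's outermost edges, which
have no adjacent intron and no splice function. EE additionally requires the
frame to be preserved; frameshifting boundary indels fall through to FS.

Two further corner decisions: a stop-to-stop substitution (e.g. TAA>TAG)
alters a stop-codon base but does not lose the stop, and is classified SY;
and the intron midpoint of an even-length intron is anchored to the upstream
(`+`) exon, following the usual first-half-of-intron convention.

## The synthetic fixture genome

All tests run against a generated 25 kb contig carrying six genes, three per
strand, one pair overlapping tail-to-tail on opposite strands. The engineered
content makes the printed worked examples executable without any downloads:

* a 10 kb-CDS forward gene whose codons are fixed at twelve positions so the
  exonic substitution vectors (`c.1040A>G_p.Gln347Arg` … `c.9976A>T_p.Lys3326X`)
  come out exactly;
* an `ACT CCT` codon pair so a left-aligned `CTC` insertion right-normalizes
  to `c.2107_2109dupCCT_p.Pro703dup` with alternative
  `c.2104_2105insCTC_p.Pro703dup`;
* an acceptor G-tract plus `GGG GGG` exon start, so a `GGG` insertion is an
  inframe glycine duplication when 3'-aligned but intronic when 5'-aligned;
* a donor ladder (intron offsets +1…+9), an acceptor T-tract giving the
  `c.2929-5dupT` / `c.2929-9_2929-8insT` class-changing pair, deep-intronic
  and shared-UTR homopolymers, and UTR substitution sites.

Random fill is seeded (`fixture_spec(seed)`); the engineered structure is
identical for every seed, and the stopper bases flanking each engineered
repeat are fixed so representation-set sizes are exactly as designed. The
fixtures emulate coordinate geometry, strandedness and repeat context; they
do **not** emulate sequencing error, genotype likelihoods, real splice-site
composition or genome-scale transcript density, so passing tests demonstrate
the correctness of the annotation algebra, not calling performance on real
data.

## Verification strategy

Every nontrivial computation is checked against an independent oracle:

* coordinate mapping against a base-by-base exon walker, with full
  round-trip identity over every transcript base;
* representation enumeration against a quadratic brute force that applies
  every candidate placement and string-compares the edited contig
  (1,000 random indels ≤ 6 bp on random 200 bp references);
* protein consequence facts against full-CDS retranslation with
  Biostrings (10,000 random variants across four genes);
* the classifier against a slow reference that enumerates every splice/exon
  base set explicitly and evaluates all 14 predicates in list order
  (exhaustive sweep over every position of two genes × variant types);
* strand symmetry: reverse-complementing the genome and flipping every
  strand leaves all CSN strings and classes unchanged.

Problem sizes (200 bp oracle references, 1,000/10,000 randomized cases,
exhaustive sweeps over the two smallest genes) were chosen so the whole suite
completes in a few minutes while still exercising every code path; the
acceptance script reruns the same computations from scratch.

## Numerical and degenerate-input choices

* kilobase figures in TRINFO are rounded half away from zero to one decimal;
* transcripts whose CDS length is not a multiple of 3 are excluded at load
  with a warning (protein annotation would be undefined, and padding would
  silently misreport downstream codons);
* REF-mismatching and malformed VCF records are skipped with a warning, never
  fatal — a clinical pipeline must not abort a whole batch for one bad row;
  the skip count is reported in the run log;
* unknown contigs make a variant intergenic rather than raising an error;
* parallel annotation (`workers > 1`) splits by input line; lines are
  independent, so output order and bytes are identical for any worker count.

## Known limitations

* Complex variants are never shifted and get no alternative representation;
  placement of a complex variant is taken at face value from the caller.
* No CNV-scale nomenclature (larger exonic deletions/duplications), no
  haplotype-aware re-annotation of nearby variants, no genotype handling.
* SO terms for class/context combinations without a printed convention
  (acceptor-side ESS, IM, SL, UTRs, inframe deletions) follow standard SO
  names and are documented as inferred.
* The start-loss (IM) protein field is left empty and stop-loss uses the
  `p.X<pos><aa>` extension of the substitution grammar; classification
  carries the information in both cases.
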