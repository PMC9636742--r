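---
title: "Methods: epimutation-anchored lncRNA discovery"
author: "epilnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epimutation-anchored lncRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The discovery idea

Most long non-coding RNAs (lncRNAs) lie in intergenic regions, and their
expression is under strong epigenetic control. `epilnc` operationalises a
discovery strategy that inverts the usual RNA-Seq-first search: first find
single CpG dinucleotides whose methylation differs sharply between a disease
group and a control group (*epimutations*), then look at assembled RNA-Seq
transcript models that physically overlap those positions, and finally screen
the overlapping transcripts through a noncoding filter cascade. The survivors
are candidate lncRNAs whose expression is plausibly coupled to an epigenetic
lesion — the configuration in which the antisense lncRNA LINC02892 was
originally found.

The package implements the dry-lab pipeline end to end: methylation-count
ingestion, the differential test, anchoring, the cascade, RPKM expression,
and candidate MS-HRM primer regions for wet-lab validation of the methylation
call. Read alignment (Tophat-class), transcript assembly (Cufflinks-class),
protein-domain search and external noncoding classifiers are deliberately
*not* reimplemented; the pipeline consumes their standard outputs (GTF,
count tables, per-transcript score tables).

## The differential methylation statistic

Per CpG site, methylated/unmethylated read counts are pooled within each
group and laid out as a 2×2 table
\[ \begin{pmatrix} m_\mathrm{case} & u_\mathrm{case} \\
                   m_\mathrm{ctrl} & u_\mathrm{ctrl} \end{pmatrix}. \]
The p-value is the two-sided Fisher exact test (conditional hypergeometric
tail sum, the same definition `stats::fisher.test` uses), and the effect size
is the coverage-weighted pooled fraction difference
\(\delta = m_c/(m_c+u_c) - m_k/(m_k+u_k) \in [-1,1]\).

Why this statistic: targeted bisulfite capture yields small, uneven per-site
coverages where asymptotic tests misbehave; the exact test is valid at any
count, handles zero cells natively (missing data is represented as coverage
0, never imputed), and ranking by \(|\delta|\) directly mirrors "highest
differential methylation rate" site selection. Pooling across samples is the
simplest defensible choice and is declared as such; a per-sample
beta-binomial likelihood-ratio test would model inter-individual
overdispersion but is out of scope here. Multiple testing is handled with
Benjamini–Hochberg across all testable sites (the field default); calls
require both \(|\delta| \ge\) `min_abs_delta` (default 0.2) and
\(q \le\) `alpha` (default 0.05). Ties in \(|\delta|\) are broken by the
smaller p-value, then genomic position, so call sets are byte-reproducible.

The implementation computes the tail sum from `stats::dhyper` over the table
support; the test suite checks it against an independent `choose()`-based
enumeration of every 2×2 table with margins up to 30 and against
`stats::fisher.test`.

## What the null model is (and why it matters)

The generator's *global null* treats a CpG site as having one underlying
methylation level: a single \(p \sim \mathrm{Beta}(5,5)\) is drawn per site
and shared by all samples in both groups, with per-sample coverage
\(\sim\) Poisson(30) and methylated counts Binomial. Under this model the
pooled counts are genuinely binomial and the exact test is conservative —
the calibration test asserts the empirical fraction of \(p \le 0.05\) stays
below \(0.05 + 3\,\mathrm{SE}\).

The alternative reading — a fresh Beta draw per *sample* even under the null
— makes the pooled counts beta-binomially overdispersed (variance ratio
\(\approx 3.6\) at these settings) and any pooled test anti-conservative;
that is a statement about pooling under inter-individual heterogeneity, not
about this implementation. We therefore reserve per-sample Beta draws for
*planted epimutations* (case \(\sim \mathrm{Beta}(9,1)\), control
\(\sim \mathrm{Beta}(1,9)\), i.e. \(\delta \approx 0.8\)), where
inter-individual variability of the lesion is the realistic picture and the
signal is far above the detection threshold anyway.

## Anchoring and positional filters

A transcript is *anchored* at a call when the CpG position falls inside its
genomic span (relation `exonic` or `intronic`) or within a configurable
window of it (default 0 nt: reads were mapped directly onto the epimutation
position, so span overlap is the faithful default). Only the top `top_k`
calls (default 2) are used as anchors.

The flank criterion removes candidates overlapping any annotated gene span
extended symmetrically by 1000 nt, in half-open arithmetic (a candidate
starting exactly at `gene_end + 1000` survives). Read literally and
strand-blind, this criterion would also remove antisense lncRNAs that
overlap a gene body — yet the discovery this design is modelled on *is* an
antisense lncRNA. We resolve the contradiction with an antisense exemption,
on by default and configurable: a candidate whose only overlaps are with
opposite-strand genes is retained.

`classify_position` reports one of four mutually exclusive classes:
`sense_overlap` (a candidate exon overlaps a same-strand gene span — a
candidate inside an annotated intron on the same strand is sense),
`antisense_overlap`, `flank_proximal` (0 < distance ≤ flank), and
`intergenic`, plus the nearest gene and its distance.

## The coding-potential model

The built-in scorer follows the CPAT design: logistic regression on four
sequence features.

* **Longest ORF length and ORF coverage.** ORFs are ATG-initiated and
  stop-terminated in the three forward frames (transcripts are already
  strand-resolved); nested starts sharing a stop keep the most 5' ATG;
  codons containing `N` never match a start or stop. The ORF length counts
  the stop codon, so the "< 400 nt" criterion is inclusive of it. A
  stop-less trailing ORF is reported but flagged `open_ended`.
* **Fickett TESTCODE score**, computed from the published 1982 position and
  content lookup tables and weights (the same constants CPAT uses). Bases
  other than A/C/G/T are ignored; a sequence that is more than half
  non-ACGT has no defined score.
* **Hexamer usage bias**: log-ratio of add-one-smoothed 6-mer frequencies,
  coding counted in frame (step 3) over CDS/ORF training sequences,
  noncoding in all frames (step 1); a transcript is scored by the mean
  log-ratio over its longest ORF's in-frame hexamers (0 without an ORF).

The logistic model is trained on a seeded synthetic corpus
(`default_coding_model()`, 150 sequences per class, lengths 300–1500 nt), so
the pipeline is self-contained and deterministic. Coefficients serialize to
JSON as 17-significant-digit decimal strings, which round-trip doubles
exactly.

## The filter cascade

Six criteria, evaluated for every candidate with no short-circuiting
(`"pass"`/`"fail"`/`"skipped"` each, plus an overall verdict and the first
failed criterion): length strictly > 200 nt; longest ORF strictly < 400 nt
(no ORF passes); PFAM best E-value > 1e-5 or no hit (whole criterion skipped
without a table); external noncoding score > 0.5 (skipped without a table —
skipped is never treated as passed); coding probability against the 0.375
threshold; and the flank verdict from the anchoring module.

One printed threshold needs a direction decision: "coding probability
> 0.375" as a *keep* rule would select coding transcripts, the opposite of a
lncRNA screen under the standard convention that high CPAT probability means
coding. The default keeps candidates with probability **below** 0.375
(`cpat_direction = "noncoding_below"`); the literal reading is available as
`"literal_above"`. The cascade is evaluated after anchoring and together
with the flank verdict; since every criterion is always evaluated and
reported, the cascade order affects only the `first_failed` label, not the
verdicts.

## MS-HRM primer regions

For wet-lab validation of a called site, `find_primer_regions()` scans every
window containing the anchor CpG with length 80–150 nt and reports those
with 3–10 plus-strand CG dinucleotides, best (CpG-richest, then shortest)
first. The defaults reflect methylation-sensitive high-resolution melting
practice: short amplicons survive bisulfite-degraded DNA, and a handful of
CpGs gives a melting shift without saturating the curve. Melting
thermodynamics, primer Tm and dimer checks stay in dedicated primer-design
tools.

## The synthetic study and its limits

`generate_fixture()` writes a complete 60 kb study: a random genome; four
annotated genes; 1000 CpG sites (real CG positions) of which two are planted
epimutations — one in the intron of gene 1 underneath a planted antisense
lncRNA (3 exons, 600 nt, minus strand) and two anchored mRNA-like decoys,
one in an intergenic desert with no transcript (emulating a called site
without expression); six case and six control coverage files; a counts table
giving the lncRNA 250 uniquely mapped reads; and a FASTQ mix of clean,
low-quality and N-rich reads. mRNA-like sequences carry a planted
codon-biased ORF covering ~70% of the transcript (third-position G/C
preference, strength 0.5 — a coarse stand-in for mammalian codon usage);
lncRNA-like sequences are random with stops planted until no ORF reaches
300 nt. One anchored decoy has an ORF above 400 nt (caught by the ORF
criterion) and one below it (caught only by the coding-probability model),
so the fixture exercises both rejection routes.

What the generator does *not* emulate — and hence what green tests do not
show about real data: bisulfite conversion errors, sequencing error models,
mapping ambiguity, fragment-length effects, CpG-island spatial structure,
realistic codon usage and splice-site signals, and biological covariates
(age, tumour purity). Recovery results on the fixture demonstrate that the
machinery is correct, not that the thresholds are optimal for a given
tissue.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; bismark-coverage
  (1-based) and GTF (1-based inclusive) convert at the I/O boundary; BED
  output is native half-open.
* Opposite-strand CpGs are kept separate by default; `merge_strands`
  destrands onto the plus-strand cytosine by summing counts.
* The read QC rule takes the printed inequalities strictly: keep iff the
  `N` fraction is < 0.10 *and* the fraction of bases with Phred quality
  > 20 is > 0.85; an empty read is discarded. A per-read mean-quality
  reading of the rule is conceivable; the per-base reading is declared, and
  all three constants are arguments.
* RPKM is the closed form `1e9 * count / (library_size * exon_length)`,
  computed in double precision; counts are ingested, never computed from
  alignments.
* Seeds fan out from one global seed via fixed offsets, so components stay
  reproducible when other configuration parts change; derived seeds are
  reduced modulo 2^31 - 1.
* Problem sizes in the test suite (1000 sites × 12 samples; 500 null
  replicates; 200 recovery replicates; 500 random sequences for the ORF
  oracle; margins ≤ 30 for the exact-test enumeration) were chosen as the
  smallest designs that make the statistical assertions sharp; they are the
  package's own test design, and all are seeded.

## Known limitations

The pooled Fisher test ignores inter-individual overdispersion; with truly
heterogeneous methylation levels within a group it will overcall (see the
null-model section — a beta-binomial test is the natural extension). The
"regions" reported by the original discovery step are represented here as
single CpG sites plus a primer window; the package does not attempt to
reproduce counts from private capture data. The built-in coding model is
trained on synthetic sequences: for production use on a real genome, retrain
`train_coding_model()` on annotated CDS/lncRNA sets of the target species
and pass real PFAM and noncoding-score tables so criteria 3 and 4 are
evaluated rather than skipped.
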