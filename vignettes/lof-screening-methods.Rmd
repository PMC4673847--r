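---
title: "Methods: consequence annotation, concordance and LoF screening"
author: "lofscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consequence annotation, concordance and LoF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`lofscreen` implements the downstream half of a deep-resequencing study in a
livestock cohort: it consumes a multi-sample VCF, gene models (GFF3), the
reference FASTA, array genotypes, a large-cohort genotype table, a
known-sites set and a gene-to-term map, and produces (i) a functional
consequence class per variant allele, (ii) cohort summary statistics,
(iii) an array-vs-sequencing concordance report, (iv) a screened list of
candidate recessive-lethal loss-of-function (LoF) variants, and (v) a
gene-set over/under-representation analysis.  Everything upstream — read
QC, alignment, variant calling — is out of scope; the pipeline starts from
called genotypes.

# Coordinates, normalization and novelty

All coordinates are 1-based, fully closed intervals, matching both VCF and
GFF3; nothing is converted internally.  Indels are normalized by the
standard left-alignment recursion (trim a shared trailing base, extending
leftwards from the reference when an allele would empty; then trim a shared
leading base while both alleles keep two or more bases).  Every
representation of the same event in a repeat context maps to a single
canonical `(pos, ref, alt)`; the test suite verifies this against
brute-force enumeration of all equivalent representations in synthetic
repeat contexts.

*Novelty* is an exact match of the normalized `chrom:pos:ref:alt` key
against the supplied known-sites set.  The ID column of the input VCF is
deliberately ignored: it encodes a particular database build and is not
reproducible from the data.

Multiallelic records are kept as one *site* for counting (a triallelic SNP
is one site in the summary table) but split into one row per ALT allele
before normalization and annotation, since consequences are properties of
alleles, not sites.

# The consequence taxonomy

Each allele is classified against every transcript within reach (the
transcript span plus a 5 kb flank on each side, measured from the
transcript, not the gene).  The class set is fixed: intergenic, intronic,
upstream, downstream, 3'/5' UTR, splice region, splice donor, splice
acceptor, initiator codon, stop gained, frameshift, missense, synonymous,
coding sequence (indeterminate effect), inframe deletion/insertion, stop
lost, stop retained, non-coding exon, mature miRNA and nc transcript.

Positional rules, all strand-aware:

* **splice donor / acceptor** — the first two / last two intron bases in
  transcription direction;
* **splice region** — exon bases 1–3 adjacent to a junction, or intron
  bases 3–8 from either junction, excluding the donor/acceptor
  dinucleotides;
* **upstream / downstream** — within 5000 bp of the transcript span on the
  strand-appropriate side (5001 bp is outside);
* coding SNP effects are computed by splicing the CDS, reverse-complementing
  on the minus strand, and translating the affected codon with the standard
  genetic code; any change to codon 1 is *initiator codon*;
* coding indels: length not divisible by three is a *frameshift*; divisible
  is *inframe* by sign; equal-length (MNP) substitutions are translated;
* an indel spanning a CDS boundary, or any coding variant in a transcript
  whose annotated CDS length is not a multiple of three, is
  *coding sequence (indeterminate effect)* — this is the operational
  trigger for the indeterminate bucket.

**Precedence within a transcript** (the rules overlap; one class must win):
donor/acceptor > coding classes > splice region > UTR > intronic >
non-coding classes > upstream/downstream.  Donor and acceptor outrank
coding classes because a donor base is also an intron base and the
splice-site call is the biologically operative one.

One design point deserves a note: a literal reading of that precedence
would make the *nc transcript* class unreachable (every intronic base of a
non-coding transcript would be "intronic").  We therefore restrict
"intronic" to transcripts with a CDS; within a non-coding transcript,
exonic bases are *non-coding exon* (or *mature miRNA* for the miRNA
biotype) and intronic bases are *nc transcript*.

**Severity across transcripts.**  When several transcripts yield different
classes, the reported `most_severe` follows a fixed total order (stop
gained > frameshift > donor/acceptor > stop lost > initiator codon >
missense > inframe > indeterminate > splice region > stop
retained/synonymous > UTR > non-coding > intronic > flanks > intergenic);
ties across transcripts break on the transcript identifier so the result
is independent of input order.  `coding_sequence_indeterminate` does not
have a conventional rank; we place it between the inframe classes and
splice region — severe enough not to be masked by near-junction noise, but
below every determinate coding effect.

A variant is **LoF** when its most severe class is stop gained, splice
donor, splice acceptor or frameshift.  In the LoF report donor and
acceptor collapse into a single *splice site* class.

# Concordance

Array (chip) genotypes are the benchmark; sequencing calls are evaluated
against them.  Chip A/B alleles are mapped onto VCF ref/alt alleles by
direct base match, then by complement (opposite-strand manifest);
palindromic A/T and C/G assays cannot be strand-resolved and are excluded
by default.  Chip homozygous-reference calls are skipped — a
sequencing-derived call set lists variant sites only, so they carry no
information.  A chip site with no VCF record is oriented against the
reference base: homozygous-reference is skipped, anything else is an
*undetected* variant call.

The discordance taxonomy per comparable pair: *concordant* (same alleles),
*over-called* (chip homozygous, sequencing heterozygous), *under-called*
(chip heterozygous, sequencing homozygous for either allele),
*inconsistent* (both homozygous, different alleles — chip hom-alt vs
sequencing hom-ref counts here), *undetected* (no sequencing genotype).
All rates use the number of comparable chip calls in the class as
denominator; raw rates are kept alongside half-up one-decimal display
values.

# The LoF screen

The zygosity partition over the sequenced samples is dichotomous: a LoF
variant is *heterozygous in at least one sample* or *homozygous in all*
(no sample heterozygous; every carrier homozygous for the variant allele).
Records whose genotype columns carry no called variant allele — possible
in multi-sample call sets when every carrier genotype is missing or
reference — admit no partition and are dropped with a logged count.

The **homozygote-absence filter** retains a LoF variant iff the large
reference cohort contains zero variant-allele homozygotes: the classic
screen for candidate recessive lethals, since a truly lethal recessive can
segregate at appreciable frequency yet never be observed homozygous in
live animals.  Records without a cohort entry (matched on the normalized
key) are dropped and logged: absence of evidence of homozygotes is not
evidence of absence.  Missing cohort genotypes are ignored (complete-case),
as is standard when missingness is sparse and uninformative.

**Cross-dataset consistency** matches retained variants against a second
call set on `(chrom, pos)`: *consistent* requires the same variant type
and the same normalized alleles; a position-level match with any
representation difference (notably indel-called-as-SNP between different
callers) is *inconsistent*; otherwise *absent*.  Cohort genotype counts
and the second dataset's variant representations are supplied as separate
inputs, because an indel genotyped correctly in the cohort may still be
*represented* as a SNP by the cohort's caller.

**MAF** is computed from cohort genotype counts,
`p = (2·hom_alt + het) / (2·called)`, `maf = min(p, 1 − p)`; the spectrum
reports, per LoF class, the fraction with MAF strictly above 0.05.

**Hotspots**: records are binned into fixed windows (1 Mb by default; the
per-kb density generalizes to `count/(bin_bp/1000)` for other widths) and
a window is flagged when its count exceeds the mean plus `k` SD (default
3) over the non-empty bins of the genome; contiguous flagged windows merge
into regions.  The threshold is a conventional outlier flag, not a
calibrated test: with many bins of small Poisson counts the family-wise
false-flag probability of a 3 SD rule is not small (about 12% over 100
bins), which is why the uniformity property in the test suite uses 30
dense bins, where the normal approximation holds and false flags are rare.

# Enrichment

Gene-set over/under-representation uses a two-sided Fisher exact
(hypergeometric) test per term against the background of every gene in the
annotation map, with Bonferroni correction over the number of terms
tested.  Study genes absent from the map are dropped and logged.  The
exact test is chosen as the reproducible standard; the original analysis
tool's internal statistic is not published, so this is an explicit
substitution.  The test suite verifies the p-values against brute-force
enumeration of all 2×2 tables with fixed margins up to 30.

# The synthetic-data generator

`simulate_study()` emits a complete toy study — reference, gene models,
multi-sample VCF, per-sample chip files, cohort counts, known sites, a
second call set, and a truth table — under one root seed (per-stage child
seeds derive from it by fixed offsets, so the same seed reproduces every
file byte for byte).

**Construction, not annotation.**  Every truth variant is placed so that
its class holds by construction: splice-donor truths on intron bases 1–2,
stop-gain truths at codon positions where a single substitution yields a
stop (verified by translating the designed codon at generation time),
boundary-spanning deletions across a CDS/UTR edge inside one exon, and so
on.  Designed coding sequences start ATG, end with a stop, and contain no
internal stop; CDS lengths are multiples of three; genes are laid out with
12 kb spacing so 5 kb flanks never overlap.  Degenerate placements (a
variant matching two classes) are excluded by margins and an
occupied-position mask, and indels are re-checked after left-alignment so
the normalized representation still satisfies its class constraints.  The
generator therefore serves as a ground-truth oracle for the annotator
without ever calling it.

**Default conditions.**  The defaults emulate the study design the package
targets: 4 sequenced samples; a 288-animal cohort under Hardy–Weinberg
proportions; ~560 truth variants covering every class, dominated by
intergenic and intronic ones; 95.5% of SNPs and 82.1% of indels in the
known set; transitions drawn at 2.11/3.11 so the simulated Ts/Tv is ~2.11;
a U-shaped allele-frequency spectrum (Beta(0.4, 0.4) clipped to
[0.02, 0.98]) so high-frequency, often all-homozygous sites exist;
frameshift frequencies capped at 0.5 and designated-lethal frequencies at
0.2, mirroring purifying selection; 12% of intergenic variants emitted as
short indels with a ±1-dominated length spectrum, providing the
genome-wide background against which coding-indel 3n enrichment is
measured; 16% of LoF variants designated "lethal" (their cohort
homozygote draws are redrawn as heterozygotes, so they have zero
variant-allele homozygotes by construction); 97% coverage in the second
call set with 30% of covered indels represented there as SNPs.

**Error model.**  The chip carries the truth genotypes of every SNP site.
Sequencing genotypes are corrupted per chip class: a truth homozygous-
alternative genotype becomes heterozygous with probability 0.002
(over-call) or homozygous-reference with 10⁻⁴ (inconsistent); a truth
heterozygote becomes homozygous (either side, equal odds) with 0.003
(under-call); genotypes go missing at class-specific rates (0.04 for
heterozygotes, driving the detection rate into the mid-90s; 0.002 for
hom-alt).  Because corruption is per chip class, the recovered rates are
exactly binomial in the number of comparable chip calls, which is what the
parameter-recovery checks assert.  Sites whose corrupted genotypes retain
no carrier are still emitted (as real multi-sample callers do); downstream
functions drop them with a logged count.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium and pedigree structure;
read-level error processes (mapping ambiguity in repeated gene families,
reference errors) that make real LoF calls cluster and false-positive;
structural variants; a realistic discovery-conditioned site-frequency
spectrum (the toy reaches ~25% all-homozygous sites where deep cattle
call sets show ~47%, because fixed breed-vs-reference differences are
under-represented); and any dependence between functional class and
mutation spectrum beyond the configured transition fraction.  The toy
study's indel set is also CDS-heavy by construction, so its 3n contrast is
weak; the 3n test's calibration (type-I error) and sensitivity are
established separately in the test suite.

# Numerical conventions and problem sizes

Displayed percentages round half away from zero to one decimal (matching
the arithmetic of published variant tables; base R's `round()` rounds half
to even).  Ts/Tv with zero transversions is reported missing, not
infinite.  The MAF cutoff is strictly greater-than.  Empty chip classes
report missing rates rather than zeros.

Test and acceptance problem sizes were chosen to keep the full suite
around one minute on one CPU while leaving the statistical checks
well-powered: the exhaustive substitution scan uses a 45-codon CDS on both
strands (810 substitutions); closure runs on the ~560-variant default
study; concordance recovery uses 10⁵ chip sites with exact binomial 99%
intervals; the absence-filter exactness check runs 10 seeds at cohort size
288; the 3n type-I simulation uses 1000 replicates of 120 indels, compared
against the exact attainable size of the discrete test; enrichment is
checked against full enumeration for margins up to 30.

# Known limitations

The annotator classifies against supplied transcript models only — no
phasing, no combined effect of nearby variants, no protein-domain or
conservation annotation.  The A/T and C/G chip assays are excluded rather
than strand-resolved via manifest metadata.  The absence filter treats the
cohort as a simple genotype-count table; relatedness within the cohort is
not modelled.  Hotspot flagging is descriptive, not a calibrated scan
statistic.
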