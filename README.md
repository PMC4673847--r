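# lofscreen

Post-variant-calling analysis for deep-resequencing studies in livestock
cohorts. Given a multi-sample VCF, gene models (GFF3), the reference
FASTA, array genotypes, a large-cohort genotype table, a known-sites set
and a gene-to-term map, the package produces the downstream analyses such
a study reports:

* **functional consequence annotation** of every variant allele against
  transcript models, over a fixed 22-class taxonomy (intergenic ... stop
  gained / frameshift / splice donor / splice acceptor), with a
  most-severe class per variant and a loss-of-function (LoF) flag;
* **call-set summary statistics**: homozygous/heterozygous, novel/known,
  biallelic/triallelic partitions, deletion/insertion counts, the
  transition:transversion ratio Ts/Tv, per-Mb density tracks, and a
  binomial test for 3n enrichment of coding-indel lengths (the signature
  of purifying selection against frameshifts);
* **array-vs-sequencing genotype concordance** per sample, with the
  standard discordance taxonomy — over-called (chip homozygous seen
  heterozygous), under-called (chip heterozygous seen homozygous),
  inconsistent (both homozygous, different alleles), undetected;
* the **LoF screen**: extraction, zygosity partition (heterozygous in ≥1
  sample vs homozygous in all), the *homozygote-absence filter* — retain a
  LoF variant iff no animal in a large cohort is homozygous for the
  variant allele, the classic screen for candidate recessive lethals —
  cross-dataset call-type consistency (SNP-vs-indel flips between
  callers), minor-allele-frequency spectra
  (`maf = min(p, 1-p)`, `p = (2·hom_alt + het) / (2·called)`), and
  per-Mb hotspot detection at mean + 3 SD;
* **gene-set over/under-representation** of LoF-affected genes by
  two-sided Fisher exact test with Bonferroni correction.

A seeded synthetic-data generator (`simulate_study()`) emits a complete
toy study — reference, gene models, variants of every functional class
placed so the class holds by construction, genotypes, corrupted chip
calls, cohort counts and a truth table — and backs the whole test suite.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_annotate.R
Rscript analysis/03_summarize.R
Rscript analysis/04_concordance.R
Rscript analysis/05_lof_screen.R
Rscript analysis/06_enrichment.R
```

Output of a run (seed 1):

```
simulated 562 truth variants (75 LoF) over 20 genes; outputs in results/sim
annotated 562 alleles; 75 LoF; truth-class recovery 100.0%
           class count    pct
      total_snps   480 100.00
        hom_snps   120  25.00
        het_snps   360  75.00
      novel_snps    21   4.40
           ts_tv    NA   2.18
      ...
S1: hom-alt concordance 99.3% (n=152), het detection 96.8%, het concordance 96.8%
LoF variants: 73 in 16 genes (16 genes with >1)
zygosity: 7 hom in all samples, 66 het in >=1 sample
homozygote-absence filter retained 31 of 73 (24 consistent, 7 inconsistent across datasets)
    lof_class  n fraction_above
1  frameshift 19      0.2105263
2 splice_site  7      0.4285714
3 stop_gained  5      1.0000000
```

Reading this: the annotator recovered the intended functional class of all
562 truth variants; 4.4% of SNP sites were absent from the known set;
the simulated Ts/Tv is 2.18 (transitions are drawn at the genome-wide
ratio); chip concordance sits at 99–100% for homozygous-alternative calls
and 94–97% for heterozygous ones, exactly the pattern injected by the
configured error rates; 31 of 73 LoF variants have zero variant-allele
homozygotes among the 288 cohort animals and survive the absence filter
(every designated "lethal" truth variant among them); and the retained
stop-gain/splice variants sit at higher minor allele frequencies than the
frameshifts.

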