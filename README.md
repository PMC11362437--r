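# greyCNV

Greying with age in horses is caused by a tandem copy number variant (CNV)
of a 4.6 kb enhancer-bearing unit in intron 6 of *STX17*. The locus forms an
allelic series defined by the per-chromosome copy count of the unit: **G1**
(one copy, wild type), **G2** (two copies, slow greying), **G3** (three
copies, fast greying). Standard diploid assays — read depth, droplet digital
PCR (ddPCR) — measure only the *total* copy number (2–6), so resolving the
series requires a chain of inferences: pedigree-constrained deduction of
per-chromosome alleles, long-read typing of individual haplotypes, and
population-level deduction from copy-number histograms.

greyCNV implements that whole inference chain as a tested R package, for
geneticists working on this locus or on structurally similar tandem CNVs:

- **Copy-number estimation** — from windowed coverage tracks
  (`2 * mean depth in CNV / mean baseline depth`) and from ddPCR droplet
  counts via Poisson correction
  (`λ = −ln(1 − positives/total)`, estimate `= 2 λ_target / λ_reference`),
  both with delta-method confidence intervals.
- **Pedigree allele deduction** — fixed-point constraint propagation over
  all genotype configurations `(m, p)` with `m + p = total`, constrained by
  phenotype (fast ⇒ an allele ≥ 3 copies; slow ⇒ largest allele = 2;
  non-grey ⇒ 1 + 1) and by what each parent can transmit; Mendelian
  inconsistencies are explained as minimal single-gamete copy-number
  mutations (de novo contraction/expansion events) with the implicated
  parent named when identifiable.
- **Association statistics** — exact two-sided Fisher tests, χ²
  goodness-of-fit without continuity correction, a carrier/non-carrier
  (dominance-model) per-SNP scan, and Bonferroni thresholds.
- **IBD and ROH scans** — sliding-window fractions of opposite-homozygote
  calls between samples (windows of 100 SNPs), heterozygous-comparator
  tracks, and run-of-homozygosity calling from pileup-based nucleotide
  diversity with a minor-read support filter.
- **Long-read allele typing** — spanning-read length classification
  (`flank + k × unit`; 7.7/12.3/16.9 kb for k = 1/2/3 at full scale),
  per-allele binning with majority-vote consensus, k-mer dotplot detection
  of head-to-tail tandem structure, and junction microhomology as the
  longest shared flank across the two breakpoints.
- **CpG methylation** — per-site profiles from per-read 5mC/5hmC calls,
  5-CpG sliding-window smoothing, and enhancer hypomethylation contrasts.
- **Breed population genetics** — genotype counts and G2/G3 allele
  frequencies deduced from per-breed total-copy-number histograms under
  the no-G2/G2 assumption, with Hardy–Weinberg expectations for
  round-trip simulation.
- **Synthetic data** — generators for every input above (pedigrees,
  coverage tracks, droplet assays, SNP matrices with planted IBD segments,
  spanning reads with methylation calls, pileups with planted ROHs), so
  the full pipeline runs and is tested without any external data.

## Worked example

A fast-greying sire measures 5 total copies; his mates are non-grey
(wild-type), one foal measures 4 copies and greys fast, another measures 3
and greys slowly:

```r
library(greyCNV)

fam <- data.frame(id = c("sire", "dam1", "dam2", "k4", "k3"),
                  sire = c(NA, NA, NA, "sire", "sire"),
                  dam = c(NA, NA, NA, "dam1", "dam2"),
                  phenotype = c("fast", "non_grey", "non_grey", "fast", "slow"),
                  total_copies = c(5L, 2L, 2L, 4L, 3L))
deduce_alleles(fam)
#> Allele deduction over 5 individuals; 5 unique, 0 Mendelian-inconsistent
#>     id n_configurations unique genotype consistent
#> 1 sire                1   TRUE    G3/G2       TRUE
#> 2 dam1                1   TRUE    G1/G1       TRUE
#> 3 dam2                1   TRUE    G1/G1       TRUE
#> 4   k4                1   TRUE    G3/G1       TRUE
#> 5   k3                1   TRUE    G2/G1       TRUE
```

The sire is heterozygous G3/G2 — the only way to reach 5 copies when no
germ-line allele exceeds three copies — and each foal's genotype is forced
because a wild-type dam can only transmit a single-copy allele. A simulated
ddPCR assay of such a sire Poisson-corrects back to his total:

```r
ddpcr_copy_number(simulate_droplet_assay(total_copies = 5, seed = 11))
#> Copy-number call (ddPCR): 4.885 -> 5 copies  [95% CI 4.749-5.025]
```

Breed-level histograms of total copy number resolve into allele
frequencies under the assumption that G2/G2 homozygotes are absent
(justified where G1/G2 and G2/G3 heterozygotes are rare):

```r
head(breed_frequency_report(grey_breed_survey()), 3)
#>             breed  n  fG2  fG3
#> 1      Andalusian 83 0.05 0.36
#> 2  Connemara Pony 90 0.05 0.39
#> 3 Miniature Horse 41 0.01 0.18
```

The G2 allele is consistently much rarer than G3, reflecting historical
selection for the fully white phenotype.

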