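---
title: "Resolving a tandem CNV into an allelic series: models and methods"
author: "greyCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a tandem CNV into an allelic series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyCNV)
```

# The genetic model

The Grey locus is a tandem repeat of a 4.6 kb unit inside an intron of
*STX17*. Each chromosome carries `k >= 1` head-to-tail copies of the unit,
and the allele is named by that count: G1 (wild type), G2, G3. The package
models phenotype as a deterministic function of the diploid genotype
through the *largest* allele:

- any allele with ≥ 3 copies → fast greying,
- largest allele exactly 2 copies → slow greying,
- both alleles single-copy → non-grey.

This max-allele rule encodes the observed dosage behaviour: one
triplicated chromosome activates the enhancer more strongly than two
duplicated ones. It is deliberately discrete. A single known G2/G2
individual was described as intermediate between slow (G1/G2) and fast
(G1/G3); a discrete classifier cannot express "intermediate", so G2/G2 is
classified slow and this is a documented limitation rather than a claim
about biology (`phenotype_from_genotype()`).

Diploid assays measure only the total `m + p`. Three inference routes
recover the per-chromosome structure, and the package implements all
three: pedigree constraint propagation, long-read haplotype typing, and
population-level deduction.

# Copy-number estimation

**Coverage.** `estimate = 2 * mean(depth in CNV windows) / mean(depth in
baseline windows)`. The baseline is a user-supplied CNV-free interval set
(the analogue of a control assay targeting a neighbouring region) rather
than a genome-wide mean, because the package operates on locus-scale
tracks. Integer calls round half away from zero, so estimates are
symmetric around true integers. The 95% CI is a delta-method interval on
the log ratio of the two window means; published analyses of this locus
report no uncertainty treatment, so this is the package's own addition.

**ddPCR.** Droplet partitioning makes the per-droplet molecule count
Poisson, so the positive fraction `p` inverts to a concentration
`λ = −ln(1 − p)` and the diploid copy number is `2 λ_target / λ_ref`.
This Poisson inversion is the standard ddPCR model; how the original
assays rounded concentration ratios to integers is not documented, so the
same half-away-from-zero rule is used. Saturated (all-positive) and empty
channels are hard errors naming the channel, since `λ` is then undefined.

At the simulator's default assay settings (20,000 droplets, reference
`λ = 0.5`, depth 30 with 20 CNV windows of 1 kb) both estimators call
totals 2–6 correctly in ≥ 99% of replicates, and this is asserted in the
test suite at 1,000 replicates per genotype.

# Pedigree deduction and de novo events

`deduce_alleles()` enumerates, per individual, every ordered configuration
`(dam-side m, sire-side p)` with `m + p` equal to the measured total and
the phenotype rule satisfied, then iterates two constraints to a fixed
point: a child's `m` (`p`) must be transmissible by its dam (sire), and a
parent must be able to supply the gamete of each of its children. Genotype
reports are unordered unless parental data force an ordering. The default
`max_allele = 3` reflects that no germ-line allele beyond three copies has
been observed at this locus; it is a parameter, not a constant.

Two asymmetries are deliberate:

- **Conflict attribution.** Parent-to-child filters may empty a child's
  configuration set (flagging a Mendelian inconsistency), but
  child-to-parent filters are skipped when they would empty the parent.
  A de novo mutation happens in the meiosis that produced the child, so
  the child, not the parent, is the right place to localise the conflict;
  without this rule the outcome would depend on iteration order.
- **Repair bounds.** `detect_cnv_mutation_events()` explains an
  inconsistency by the smallest single-gamete copy change (ties:
  contraction first), drawn from the parent's transmissible alleles. The
  repaired allele may exceed `max_allele` by one unit — de novo expansion
  is precisely how larger alleles first arise — but not by more; an
  inconsistency needing a larger jump, or more than one event, is flagged
  complex. Single-copy alleles may expand (the ancestral duplication had
  to arise once) but cannot contract below one copy. When both parents
  admit an equivalent minimal repair the parent is reported as not
  identifiable (NA), as in a slow-greying foal of two wild-type parents.

# Association statistics

`fisher_exact_two_sided()` and `chi2_goodness_of_fit()` delegate to R's
exact hypergeometric and Pearson machinery; the package's contribution is
the fixed conventions. Two-sidedness is by the point-probability method
(sum over tables at most as probable as the observed one), the common
convention among implementations, and the suite verifies it against a full
enumeration oracle for all table sizes up to n = 30. No continuity
correction is applied anywhere; with the correction neither of the two
printed goodness-of-fit statistics (1.0 for a 10:6 segregation against
1:1; 25.0 for 0 affected of 25 against an expected proportion of one
half) would be reproduced. The dominance scan encodes carrier status as
genotype ≥ 1 and runs the exact test per site; sites monomorphic in
carrier status return p = 1, and samples with missing genotypes are
dropped per site. The melanoma contrast is computed exactly as a
one-sample test of 0/25 against 0.5 — the arithmetic that yields the
printed χ² = 25.0 — although prose descriptions of that comparison cite
an 80% vs 0% incidence difference; the package reproduces the computation
without asserting which framing was intended.

# IBD scan, diversity and ROH

Two samples sharing both haplotypes identical-by-descent cannot be
homozygous for different alleles, so `opposite_homozygote_fractions()`
slides a window of 100 SNPs (step 1 SNP; both configurable — the source
analysis specifies "sliding" without a step) and reports the fraction of
opposite-homozygote calls. Missing genotypes are excluded from numerator
and denominator, and windows are defined over non-missing sites.
`call_ibd_intervals()` merges maximal runs of windows at or below a
threshold (default 0: a single opposite homozygote breaks IBD).
Coordinates are 0-based half-open internally and in BED output; VCF
positions are 1-based.

`pileup_diversity()` computes the per-site fraction of reads supporting a
non-major allele and zeroes sites where *no single* non-major allele
reaches `min_minor_reads` (default 3). The per-allele reading of the
support filter matters: basecalling errors scatter across the three
alternative bases and essentially never concentrate three reads on one of
them, while a true heterozygous site always does, so the filter separates
an error floor of about 1×10⁻⁴ from a heterozygosity signal of about
`het_density / 2` per site. Windowed means (default 500 kb) feed
`call_roh_intervals()`.

# Long-read typing

A spanning read's length is `flank + k * unit` plus noise, so
`classify_read_copy_number()` assigns the nearest `k` and rejects reads
whose residual is at least half a unit. Consensus is per-column majority
vote after anchoring reads at the fragment start and trimming/padding to
the bin's modal length — adequate because the simulated reads have
substitution-only errors; with real indel-rich long reads one would use a
partial-order aligner instead, and the consensus method behind the
original figures is unspecified. Fifty reads at 3% substitution error
reconstruct a template at ≥ 99.9% identity (verified in the suite, and
expected: a column errs only when ≥ half its reads do).

`detect_tandem_structure()` builds a dotplot from exact k-mers sampled
every `kmer_size = 15` bases along the unit (both orientations).
Substitutions delete k-mers but never shift alignment offsets, so
collinear matches collapse onto identical offsets; offsets supported by
≥ `min_chain = 5` k-mers become unit placements. Classification: one
placement → single; mixed orientations → inverted; same-orientation
placements all adjacent within 10% of a unit length → head-to-tail
tandem; otherwise complex. Reverse-complementing the consensus flips all
orientations and preserves the classification. Ambiguous bases break
k-mer matches; there is no wildcard matching.

**Junction microhomology** is the longest sequence that is simultaneously
the suffix of the consensus ending at a copy–copy junction and the prefix
of the reference sequence that follows the corresponding breakpoint on
the other side — the longest exact shared flank across the two
breakpoints, the standard structural-variant convention (exact breakpoint
conventions for this locus are not published, so this definition is a
design decision). The junction coordinate is the end of the preceding
unit placement. The simulator plants the motif (default `TCTCAG`, 6 bp)
as both prefix and suffix of the unit and keeps the rest of the sequence
motif-free, so the planted microhomology is exactly the motif.

# Methylation profiles

`build_methylation_profile()` merges 5mC and 5hmC calls into a total
methylation fraction per CpG (merging is optional); sites with zero call
depth are omitted rather than imputed. `smooth_profile()` averages
sliding windows of 5 adjacent CpGs moving one site at a time, reporting
the mean member position as the window position (needed for interval
overlap; unspecified upstream). Note that sliding-window smoothing does
not exactly preserve any fixed trimmed mean of the raw profile — edge
sites enter fewer windows — so the suite asserts the correct invariants
instead: windows average exactly, constants are fixed points, and output
is bounded by the input extrema. `hypomethylation_contrast()` reports
mean flank minus mean target methylation, positive when the target (the
enhancer inside each unit copy) is hypomethylated.

# Breed histograms

Totals map to genotypes as 2 → G1/G1, 3 → G1/G2, 4 → G1/G3, 5 → G2/G3,
6 → G3/G3, with all 4-copy horses counted as G1/G3 under the assumption
that G2/G2 homozygotes are absent — defensible exactly in breeds where
G1/G2 and G2/G3 heterozygotes are rare, and the package demonstrates the
resulting downward bias of the G2 frequency by simulation when that
assumption is violated. Frequencies are
`fG2 = (n3 + n5)/2n`, `fG3 = (n4 + n5 + 2 n6)/2n`, reported at two
decimals rounding half away from zero (the presentation convention of the
published survey). Counts implying totals above 6 are rejected — no
germ-line allele beyond three copies is supported — unless `max_allele`
is raised. These are frequency estimates for the genotyped samples, which
were not randomly ascertained; the package reproduces the computation,
not population truth.

# The synthetic-data generator

Every pipeline input can be generated in-package; the defaults are the
study conditions the analyses assume:

- **Pedigrees** (`simulate_pedigree()`): founder allele frequencies
  default to a breed segregating all three alleles (G1 0.56, G2 0.05,
  G3 0.39, the Connemara-like configuration); contraction and expansion
  rates default to 10⁻³ per meiosis — germ-line copy-number change is
  observable but rare (one contraction among the genotyped meioses that
  motivated the event detector), and only alleles with ≥ 2 copies mutate,
  since change requires misalignment between existing copies.
- **Coverage** (`simulate_coverage_track()`): Poisson window sums at
  `mean_depth × total/2` inside the CNV; depth 30, 1 kb windows, 200
  windows with 20 in the CNV.
- **ddPCR** (`simulate_droplet_assay()`): binomial positives at
  `1 − exp(−λ)`; 20,000 droplets, reference λ = 0.5.
- **SNP matrices** (`simulate_snp_genotypes()`): two haplotypes per
  sample, independent across sites (no linkage disequilibrium except the
  planted IBD segment — only the segment structure matters to the scan);
  background alternate-allele frequencies uniform on 0.2–0.5.
- **Spanning reads** (`simulate_allele_reads()`): a 1:10 scaled locus
  (460 bp unit, 310 bp flank) by default so consensus and dotplot tests
  run in milliseconds; the full-scale 4600/3100 model is available and
  used wherever length arithmetic itself is under test. Gaussian length
  noise, substitution-only errors, per-read CpG calls with an enhancer
  dip (`p_enhancer = 0.1` vs `p_background = 0.9` by default).
- **Pileups** (`simulate_pileup()`): per-site Poisson depth 45 (the
  coverage of the long-read ROH analysis), heterozygous site density
  2×10⁻³ (a realistic genome-wide heterozygosity for horses), 1% error
  spread over the three alternative bases.

What the generator does *not* emulate, and hence what passing tests do
not show: alignment and mapping artefacts, GC or mappability bias in
coverage, linkage disequilibrium and allele-frequency spectra of real
populations, indel errors and quality scores in long reads, and
genotyping error in pedigree totals. Results on real data additionally
depend on those upstream steps (mapping-quality filtering is assumed to
have happened before the pileup abstraction).

All randomness flows from one integer seed per generator call
(documented default 17), so every simulated object is reproducible.

# Problem sizes and runtime

The test suite runs the estimator-accuracy properties at 1,000 replicates
per genotype, the Fisher-vs-enumeration property at 200 random tables
plus all worked tables, the microhomology oracle at 200 random junctions,
IBD recovery on 800-SNP matrices, and ROH recovery on a 300 kb synthetic
chromosome at 10 kb windows — sizes chosen so the whole suite completes
in about a minute on one CPU while keeping Monte-Carlo margins (binomial
3–4 SE) well away from the asserted thresholds. The acceptance script
(`scripts/acceptance.R`) re-derives its reported quantities at 200
replicates per genotype in a few seconds.

# Known limitations

- The discrete phenotype model cannot represent the intermediate G2/G2
  phenotype, and G2/G3 phenotype expectations rest on few observations.
- Deduction is combinatorial, not probabilistic: it reports the set of
  consistent configurations and never weighs them by likelihood, matching
  how the original deductions were argued; measurement error in totals is
  out of scope.
- Whether a detected contraction arose intra- or inter-chromosomally is
  not inferable from copy numbers (the one directly observed event
  occurred in a dam homozygous across the surrounding megabases) and the
  package does not attempt it.
- The ddPCR integer-rounding and long-read consensus procedures of the
  original analyses are unspecified; the package's choices are standard
  but not certified identical.
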