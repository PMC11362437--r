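test_that("phenotype follows the max-allele dosage rule", {
  expect_equal(phenotype_from_genotype(1, 1), "non_grey")
  expect_equal(phenotype_from_genotype(1, 2), "slow")
  expect_equal(phenotype_from_genotype(1, 3), "fast")
  expect_equal(phenotype_from_genotype(3, 2), "fast")
  expect_equal(phenotype_from_genotype(2, 2), "slow")
  # vectorised over genotype pairs
  expect_equal(phenotype_from_genotype(c(1, 2, 3), c(1, 1, 3)),
               c("non_grey", "slow", "fast"))
  expect_equal(allele_label(1:3), c("G1", "G2", "G3"))
  expect_equal(genotype_label(2, 3), "G3/G2")
})

test_that("without mutation every offspring allele is a parental allele and totals add up", {
  cfg <- grey_sim_config(contraction_rate = 0, expansion_rate = 0)
  for (s in 1:10) {
    ped <- simulate_pedigree(cfg, n_founders = 8, n_generations = 3, seed = s)
    expect_equal(ped$total_copies, ped$dam_allele + ped$sire_allele)
    expect_equal(nrow(pedigree_events(ped)), 0)
    kids <- ped[!is.na(ped$dam), ]
    for (i in seq_len(nrow(kids))) {
      dam <- ped[ped$id == kids$dam[i], ]
      sire <- ped[ped$id == kids$sire[i], ]
      expect_true(kids$dam_allele[i] %in% c(dam$dam_allele, dam$sire_allele))
      expect_true(kids$sire_allele[i] %in% c(sire$dam_allele, sire$sire_allele))
    }
    expect_equal(ped$phenotype,
                 phenotype_from_genotype(ped$dam_allele, ped$sire_allele))
  }
})

test_that("recorded mutation events match parent-offspring allele mismatches exactly", {
  # all-G3 founders, one generation: every transmitted allele that is not
  # 3 copies must be a recorded event, and vice versa
  cfg <- grey_sim_config(allele_frequencies = c(G3 = 1),
                         contraction_rate = 0.2, expansion_rate = 0)
  ped <- simulate_pedigree(cfg, n_founders = 40, n_generations = 1,
                           offspring_per_mating = 4, seed = 11)
  kids <- ped[!is.na(ped$dam), ]
  mismatches <- sum(kids$dam_allele != 3) + sum(kids$sire_allele != 3)
  ev <- pedigree_events(ped)
  expect_gt(nrow(ev), 0)
  expect_equal(nrow(ev), mismatches)
  expect_true(all(ev$direction == "contraction"))
  expect_true(all(ev$from_copies == 3 & ev$to_copies == 2))
})

test_that("forced contraction on a G3/G3 x G1/G1 mating births a G2 allele", {
  set.seed(1)
  g <- transmit_allele(3, contraction_rate = 1)
  expect_true(g$mutated)
  expect_equal(g$direction, "contraction")
  expect_equal(g$copies, 2L)
  # offspring of (3,3) dam and (1,1) sire with the contracted gamete
  expect_equal(phenotype_from_genotype(g$copies, 1), "slow")
  # wild-type alleles never mutate
  set.seed(1)
  expect_false(transmit_allele(1, contraction_rate = 1, expansion_rate = 1)$mutated)
})

test_that("a heterozygous parent transmits each allele with probability one half", {
  cfg <- grey_sim_config(allele_frequencies = c(G2 = 0.5, G3 = 0.5),
                         contraction_rate = 0, expansion_rate = 0)
  ped <- simulate_pedigree(cfg, n_founders = 250, n_generations = 1,
                           offspring_per_mating = 80, seed = 23)
  kids <- ped[!is.na(ped$dam), ]
  dam_geno <- ped[match(kids$dam, ped$id), ]
  het_dam <- (pmin(dam_geno$dam_allele, dam_geno$sire_allele) == 2) &
    (pmax(dam_geno$dam_allele, dam_geno$sire_allele) == 3)
  transmitted <- kids$dam_allele[het_dam]
  expect_gt(length(transmitted), 3000)
  expect_lt(abs(mean(transmitted == 3) - 0.5), 0.015)
})

test_that("coverage tracks obey the copy-ratio law", {
  for (geno in list(c(1, 1), c(3, 2), c(1, 3))) {
    tr <- simulate_coverage_track(geno, mean_depth = 1000, seed = sum(geno))
    cnv <- attr(tr, "cnv_interval")
    in_cnv <- tr$start >= cnv$start & tr$end <= cnv$end
    ratio <- mean(tr$mean_depth[in_cnv]) / mean(tr$mean_depth[!in_cnv])
    expect_lt(abs(ratio - sum(geno) / 2), 0.02 * sum(geno) / 2)
  }
})

test_that("droplet positive fractions follow the Poisson partition law", {
  # total 6 at base_lambda 0.5: target lambda 1.5, positive fraction 1-e^-1.5
  a <- simulate_droplet_assay(6, n_droplets = 20000, base_lambda = 0.5, seed = 3)
  p_exp <- 1 - exp(-1.5)
  se <- sqrt(p_exp * (1 - p_exp) / 20000)
  expect_lt(abs(a$target_positive / a$target_total - p_exp), 4 * se)
  p_ref <- 1 - exp(-0.5)
  se_r <- sqrt(p_ref * (1 - p_ref) / 20000)
  expect_lt(abs(a$reference_positive / a$reference_total - p_ref), 4 * se_r)
  # 2-copy sample: equal fractions in expectation
  reps <- vapply(1:200, function(s) {
    b <- simulate_droplet_assay(2, n_droplets = 5000, seed = s)
    b$target_positive / b$target_total - b$reference_positive / b$reference_total
  }, numeric(1))
  expect_lt(abs(mean(reps)), 4 * stats::sd(reps) / sqrt(200))
})

test_that("spanning-read lengths equal flank + k x unit and carry the junction motif", {
  # paper-scale: a triplication produces a ~16.9 kb fragment
  rs3 <- simulate_allele_reads(3, locus_model = cnv_locus_model(),
                               n_reads = 5, seed = 2)
  expect_true(all(nchar(rs3$reads) == 16900))
  # scaled model, zero noise: all reads are flank + 2 x unit
  rs2 <- simulate_allele_reads(2, n_reads = 10, seed = 4)
  expect_true(all(nchar(rs2$reads) == 310 + 2 * 460))
  expect_equal(rs2$reads[[1]], rs2$fragment)
  # the unit starts and ends with the microhomology motif
  expect_equal(substr(rs2$unit_seq, 1, 6), "TCTCAG")
  expect_equal(substr(rs2$unit_seq, 455, 460), "TCTCAG")
  # motif longer than the unit is rejected
  expect_error(simulate_allele_reads(2, microhomology_motif = random_dna(461)),
               "longer than")
})

test_that("pileup base counts are consistent and heterozygous sites are balanced", {
  pu <- simulate_pileup(5000, het_density = 0, error_rate = 0, depth = 40, seed = 5)
  counts <- as.matrix(pu[, c("A", "C", "G", "T")])
  expect_equal(unname(rowSums(counts)), pu$depth)
  # no het sites, no errors: every site is monoallelic
  expect_equal(apply(counts, 1, max), pu$depth)

  pu2 <- simulate_pileup(20000, het_density = 0.05, error_rate = 0, depth = 40,
                         seed = 6)
  counts2 <- as.matrix(pu2[, c("A", "C", "G", "T")])
  minor <- pu2$depth - apply(counts2, 1, max)
  het <- minor > 0
  expect_gt(sum(het), 500)
  # binomial(depth, 1/2) sharing: the observed minor fraction sits just
  # below one half (taking the max of the two alleles skims the mean)
  minor_frac <- (minor / pu2$depth)[het]
  expect_gt(mean(minor_frac), 0.42)
  expect_lte(max(minor_frac), 0.5)
})
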