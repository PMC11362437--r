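worked_family <- function() {
  # a fast-greying 5-copy sire mated to wild-type dams, with 4-copy fast
  # and 3-copy slow progeny
  data.frame(id = c("sire", "dam1", "dam2", "fast_kid", "slow_kid"),
             sire = c(NA, NA, NA, "sire", "sire"),
             dam = c(NA, NA, NA, "dam1", "dam2"),
             phenotype = c("fast", "non_grey", "non_grey", "fast", "slow"),
             total_copies = c(5L, 2L, 2L, 4L, 3L),
             stringsAsFactors = FALSE)
}

test_that("worked family deductions are unique and correct", {
  d <- deduce_alleles(worked_family())
  s <- d$summary
  expect_true(all(s$consistent))
  expect_true(all(s$unique))
  expect_equal(s$genotype[s$id == "sire"], "G3/G2")
  expect_equal(s$genotype[s$id == "fast_kid"], "G3/G1")
  expect_equal(s$genotype[s$id == "slow_kid"], "G2/G1")
  # progeny orderings are forced: the wild-type dam transmits the 1-copy allele
  expect_equal(unname(d$configurations[["fast_kid"]][1, ]), c(1, 3))
  expect_equal(unname(d$configurations[["slow_kid"]][1, ]), c(1, 2))
})

test_that("a 5-copy fast horse without pedigree needs the max-allele bound", {
  lone <- data.frame(id = "sire", sire = NA, dam = NA, phenotype = "fast",
                     total_copies = 5L, stringsAsFactors = FALSE)
  # allowing 4-copy alleles leaves two configurations: 3+2 and 4+1
  d4 <- deduce_alleles(lone, max_allele = 4)
  expect_equal(d4$summary$n_configurations, 2)
  expect_false(d4$summary$unique)
  u <- unique(t(apply(d4$configurations[["sire"]], 1, sort)))
  expect_setequal(paste(u[, 1], u[, 2]), c("2 3", "1 4"))
  # no germ-line allele beyond three copies: deduction becomes unique
  d3 <- deduce_alleles(lone, max_allele = 3)
  expect_true(d3$summary$unique)
  expect_equal(d3$summary$genotype, "G3/G2")
})

test_that("deduction always contains the simulator's true genotype", {
  cfg <- grey_sim_config(contraction_rate = 0, expansion_rate = 0)
  for (s in 1:15) {
    ped <- simulate_pedigree(cfg, n_founders = 6, n_generations = 2, seed = s)
    d <- deduce_alleles(ped)
    expect_true(all(d$summary$consistent))
    for (i in seq_len(nrow(ped))) {
      cand <- d$configurations[[ped$id[i]]]
      truth_hi <- max(ped$dam_allele[i], ped$sire_allele[i])
      truth_lo <- min(ped$dam_allele[i], ped$sire_allele[i])
      hit <- any(pmax(cand[, "m"], cand[, "p"]) == truth_hi &
                   pmin(cand[, "m"], cand[, "p"]) == truth_lo)
      expect_true(hit)
    }
  }
})

test_that("matings with a wild-type parent always resolve offspring uniquely", {
  # the mapping-family design: every informative mating uses a G1/G1 dam
  set.seed(42)
  for (r in 1:50) {
    sire_geno <- sort(c(sample(1:3, 1), sample(1:3, 1)), decreasing = TRUE)
    kid_m <- 1L
    kid_p <- sample(sire_geno, 1)
    ped <- data.frame(id = c("sire", "dam", "kid"),
                      sire = c(NA, NA, "sire"), dam = c(NA, NA, "dam"),
                      phenotype = c(phenotype_from_genotype(sire_geno[1], sire_geno[2]),
                                    "non_grey",
                                    phenotype_from_genotype(kid_m, kid_p)),
                      total_copies = c(sum(sire_geno), 2L, kid_m + kid_p),
                      stringsAsFactors = FALSE)
    d <- deduce_alleles(ped)
    kid_row <- d$summary[d$summary$id == "kid", ]
    expect_true(kid_row$unique)
    expect_equal(kid_row$genotype, genotype_label(kid_m, kid_p))
  }
})

test_that("a de novo contraction in a homozygous dam is detected and attributed", {
  ped <- data.frame(id = c("dam", "sire", "X"),
                    sire = c(NA, NA, "sire"), dam = c(NA, NA, "dam"),
                    phenotype = c("fast", "non_grey", "slow"),
                    total_copies = c(6L, 2L, 3L), stringsAsFactors = FALSE)
  ev <- detect_cnv_mutation_events(ped)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$child, "X")
  expect_equal(ev$parent, "dam")
  expect_equal(ev$from_copies, 3L)
  expect_equal(ev$to_copies, 2L)
  expect_equal(ev$direction, "contraction")
  expect_false(ev$complex)
  # the dam's own deduction must survive the conflicting child
  d <- deduce_alleles(ped)
  expect_true(d$summary$consistent[d$summary$id == "dam"])
  expect_equal(d$summary$genotype[d$summary$id == "dam"], "G3/G3")
})

test_that("an expansion between wild-type parents is found but not attributed", {
  ped <- data.frame(id = c("dam", "sire", "kid"),
                    sire = c(NA, NA, "sire"), dam = c(NA, NA, "dam"),
                    phenotype = c("non_grey", "non_grey", "slow"),
                    total_copies = c(2L, 2L, 3L), stringsAsFactors = FALSE)
  ev <- detect_cnv_mutation_events(ped)
  expect_equal(nrow(ev), 1)
  expect_true(is.na(ev$parent))
  expect_equal(ev$from_copies, 1L)
  expect_equal(ev$to_copies, 2L)
  expect_equal(ev$direction, "expansion")
})

test_that("consistent pedigrees yield no events and unrepairable ones are complex", {
  cfg <- grey_sim_config(contraction_rate = 0, expansion_rate = 0)
  for (s in 1:10) {
    ped <- simulate_pedigree(cfg, n_founders = 6, n_generations = 2, seed = s)
    expect_equal(nrow(detect_cnv_mutation_events(ped)), 0)
  }
  ped <- data.frame(id = c("dam", "sire", "kid"),
                    sire = c(NA, NA, "sire"), dam = c(NA, NA, "dam"),
                    phenotype = c("non_grey", "non_grey", "fast"),
                    total_copies = c(2L, 2L, 6L), stringsAsFactors = FALSE)
  ev <- detect_cnv_mutation_events(ped)
  expect_equal(nrow(ev), 1)
  expect_true(ev$complex)
})

test_that("simulated forced mutations are detected with the correct parent", {
  set.seed(7)
  n_detected <- 0
  for (r in 1:200) {
    # scenarios in which a single parent is implicated unambiguously:
    # a G3/G3 expansion with a wild-type mate is genuinely ambiguous
    # (either parent could have expanded), so it is excluded here
    k <- sample(2:3, 1)
    direction <- if (k == 3) "contraction" else sample(c("contraction", "expansion"), 1)
    gamete <- if (direction == "contraction")
      transmit_allele(k, contraction_rate = 1)
    else transmit_allele(k, expansion_rate = 1)
    kid_m <- gamete$copies; kid_p <- 1L
    ped <- data.frame(id = c("dam", "sire", "kid"),
                      sire = c(NA, NA, "sire"), dam = c(NA, NA, "dam"),
                      phenotype = c(phenotype_from_genotype(k, k), "non_grey",
                                    phenotype_from_genotype(kid_m, kid_p)),
                      total_copies = c(2L * k, 2L, kid_m + kid_p),
                      stringsAsFactors = FALSE)
    ev <- detect_cnv_mutation_events(ped)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$child, "kid")
    expect_equal(ev$parent, "dam")
    expect_equal(ev$from_copies, k)
    expect_equal(ev$to_copies, gamete$copies)
    expect_equal(ev$direction, direction)
    n_detected <- n_detected + 1
  }
  expect_equal(n_detected, 200)
})
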