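test_that("read length classification matches the fragment-length arithmetic", {
  full <- cnv_locus_model()
  expect_equal(expected_fragment_length(full, 1:3), c(7700, 12300, 16900))
  expect_equal(classify_read_copy_number(c(7700, 12300, 16900), full), 1:3)
  # observed dominant fragment sizes classify to the right alleles
  expect_equal(classify_read_copy_number(c(13000, 17000), full), c(2L, 3L))
  # off-scale reads are rejected
  expect_true(is.na(classify_read_copy_number(2000, full)))
  # boundaries: residual >= unit/2 rejects
  expect_true(is.na(classify_read_copy_number(7700 + 2300, full)))
  expect_equal(classify_read_copy_number(7700 + 2299, full), 1L)
})

test_that("classification is non-decreasing in read length", {
  model <- scaled_locus_model()
  lens <- seq(400, 3000, by = 7)
  k <- classify_read_copy_number(lens, model)
  kk <- k[!is.na(k)]
  expect_true(all(diff(kk) >= 0))
})

test_that("simulated reads with sub-half-unit noise classify to their allele", {
  model <- scaled_locus_model()
  for (copies in 1:3) {
    rs <- simulate_allele_reads(copies, model, n_reads = 40,
                                length_noise_sd = 40, seed = copies)
    noise <- abs(nchar(rs$reads) - expected_fragment_length(model, copies))
    stopifnot(all(noise < model$unit_length_bp / 2))  # construction guard
    k <- classify_read_copy_number(nchar(rs$reads), model)
    expect_true(all(k == copies))
  }
})

test_that("binning a heterozygous sample yields one bin per allele", {
  model <- scaled_locus_model()
  g2 <- simulate_allele_reads(2, model, n_reads = 15, length_noise_sd = 20,
                              per_base_error = 0.01, seed = 5)
  g3 <- simulate_allele_reads(3, model, unit_seq = g2$unit_seq,
                              flank_seqs = g2$flank_seqs, n_reads = 15,
                              length_noise_sd = 20, per_base_error = 0.01,
                              seed = 6)
  bins <- bin_and_consensus(c(g2$reads, setNames(g3$reads, paste0("b_", names(g3$reads)))),
                            model)
  expect_equal(names(bins), c("G2", "G3"))
  expect_equal(vapply(bins, `[[`, integer(1), "k"), c(G2 = 2L, G3 = 3L))
  expect_false(any(vapply(bins, `[[`, logical(1), "low_confidence")))
})

test_that("consensus of error-free identical reads is the read itself", {
  model <- scaled_locus_model()
  rs <- simulate_allele_reads(2, model, n_reads = 5, seed = 7)
  bins <- bin_and_consensus(rs$reads, model)
  expect_equal(bins$G2$consensus, rs$fragment)
})

test_that("majority-vote consensus corrects 3% substitution error", {
  model <- scaled_locus_model()
  rs <- simulate_allele_reads(2, model, n_reads = 50, per_base_error = 0.03,
                              seed = 9)
  bins <- bin_and_consensus(rs$reads, model)
  cons <- strsplit(bins$G2$consensus, "")[[1]]
  truth <- strsplit(rs$fragment, "")[[1]]
  expect_gte(mean(cons == truth), 0.999)
})

test_that("tandem copies are detected head-to-tail with correct placements", {
  model <- scaled_locus_model()
  rs <- simulate_allele_reads(3, model, n_reads = 5, seed = 12)
  st <- detect_tandem_structure(rs$fragment, rs$unit_seq)
  expect_equal(nrow(st$placements), 3)
  expect_true(all(st$placements$orientation == "+"))
  expect_equal(st$classification, "tandem_head_to_tail")
  up <- nchar(rs$flank_seqs$upstream)
  expect_equal(st$placements$start, up + (0:2) * model$unit_length_bp)

  # single copy
  rs1 <- simulate_allele_reads(1, model, unit_seq = rs$unit_seq,
                               flank_seqs = rs$flank_seqs, n_reads = 3, seed = 13)
  st1 <- detect_tandem_structure(rs1$fragment, rs$unit_seq)
  expect_equal(st1$classification, "single")

  # a reverse-complement copy makes the arrangement inverted
  inv <- paste0(rs$flank_seqs$upstream, rs$unit_seq, revcomp_chr(rs$unit_seq),
                rs$flank_seqs$downstream)
  stinv <- detect_tandem_structure(inv, rs$unit_seq)
  expect_equal(stinv$classification, "inverted")
  expect_setequal(stinv$placements$orientation, c("+", "-"))

  expect_error(detect_tandem_structure(paste0(rs$flank_seqs$upstream,
                                              rs$flank_seqs$downstream,
                                              random_dna(600)),
                                       rs$unit_seq), "not found")
})

test_that("structure detection is strand-consistent", {
  model <- scaled_locus_model()
  rs <- simulate_allele_reads(3, model, n_reads = 3, seed = 14)
  fwd <- detect_tandem_structure(rs$fragment, rs$unit_seq)
  rev <- detect_tandem_structure(revcomp_chr(rs$fragment), rs$unit_seq)
  expect_equal(rev$classification, fwd$classification)
  expect_true(all(rev$placements$orientation == "-"))
  expect_equal(nrow(rev$placements), nrow(fwd$placements))
})

test_that("junction microhomology recovers the planted motif", {
  model <- scaled_locus_model()
  rs <- simulate_allele_reads(3, model, n_reads = 3, seed = 15)
  st <- detect_tandem_structure(rs$fragment, rs$unit_seq)
  jr <- find_junction_microhomology(rs$fragment, st, rs$unit_seq)
  expect_equal(nrow(jr), 2)
  expect_true(all(jr$microhomology == "TCTCAG"))
  expect_true(all(jr$length == 6))

  # a junction with no shared bases
  unit0 <- paste0("A", substr(random_dna(100), 1, 98), "C")
  stopifnot(shared_flank_oracle(unit0, unit0, cap = 99) == 0)
  cons0 <- paste0(unit0, unit0)
  pl <- data.frame(start = c(0, 100), end = c(100, 200), orientation = "+")
  jr0 <- find_junction_microhomology(cons0, pl, unit0)
  expect_equal(jr0$length, 0)
  expect_equal(jr0$microhomology, "")

  # non-adjacent placements are an error
  plgap <- data.frame(start = c(0, 300), end = c(100, 400), orientation = "+")
  expect_error(find_junction_microhomology(paste0(cons0, cons0), plgap, unit0),
               "not adjacent")
})

test_that("microhomology equals the brute-force shared-flank oracle on random junctions", {
  set.seed(33)
  for (r in 1:200) {
    h <- sample(0:10, 1)
    motif <- if (h > 0) random_dna(h) else ""
    mid <- random_dna(sample(40:80, 1))
    unit <- paste0(motif, mid, motif)
    cons <- paste(rep(unit, 2), collapse = "")
    L <- nchar(unit)
    pl <- data.frame(start = c(0, L), end = c(L, 2 * L), orientation = "+")
    jr <- find_junction_microhomology(cons, pl, unit)
    want <- shared_flank_oracle(substr(cons, 1, L), unit, cap = L - 1)
    expect_equal(jr$length, want)
    expect_gte(jr$length, h)
  }
})
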