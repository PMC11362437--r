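#' Simulation configuration for pedigree generation
#'
#' Collects the population-genetic parameters of the pedigree simulator.
#' Default allele frequencies follow the deduced frequencies in a breed
#' (Connemara pony) segregating for all three alleles: G1 0.56, G2 0.05,
#' G3 0.39. Per-meiosis copy-number mutation rates default to 1e-3 in each
#' direction; germ-line copy-number change at this locus is observable but
#' rare (a single contraction among the genotyped meioses in the source
#' pedigrees), and only alleles with two or more copies can gain or lose a
#' unit by misalignment between existing copies.
#'
#' @param seed Integer seed; all randomness in [simulate_pedigree()] flows
#'   from it.
#' @param allele_frequencies Named numeric vector of founder allele
#'   frequencies; names are allele labels ("G1", "G2", ...), values must sum
#'   to 1.
#' @param contraction_rate,expansion_rate Per-meiosis probability that a
#'   transmitted allele with >= 2 copies loses (resp. gains) one copy.
#' @return An object of class `grey_sim_config`.
#' @export
grey_sim_config <- function(seed = 17,
                            allele_frequencies = c(G1 = 0.56, G2 = 0.05, G3 = 0.39),
                            contraction_rate = 0.001,
                            expansion_rate = 0.001) {
  if (abs(sum(allele_frequencies) - 1) > 1e-8)
    stop("allele_frequencies must sum to 1")
  if (any(allele_frequencies < 0))
    stop("allele_frequencies must be non-negative")
  if (is.null(names(allele_frequencies)) ||
      !all(grepl("^G[0-9]+$", names(allele_frequencies))))
    stop("allele_frequencies must be named G1, G2, ...")
  stopifnot(contraction_rate >= 0, contraction_rate <= 1,
            expansion_rate >= 0, expansion_rate <= 1)
  structure(list(seed = as.integer(seed),
                 allele_frequencies = allele_frequencies,
                 contraction_rate = contraction_rate,
                 expansion_rate = expansion_rate),
            class = "grey_sim_config")
}

#' Transmit one allele through meiosis, with possible copy-number mutation
#'
#' A transmitted allele with two or more unit copies loses one copy with
#' probability `contraction_rate`, otherwise gains one with probability
#' `expansion_rate`. Single-copy (wild-type) alleles are never mutated:
#' copy-number change requires misalignment between existing tandem copies.
#' Setting a rate to 1 forces the event, which is convenient for
#' constructing de novo mutation scenarios deterministically.
#'
#' @param copies Copy count of the transmitted allele (>= 1).
#' @param contraction_rate,expansion_rate Mutation probabilities in `[0, 1]`.
#' @return A list with elements `copies` (transmitted copy count after any
#'   mutation), `mutated` (logical) and `direction` (`"contraction"`,
#'   `"expansion"` or `NA`).
#' @export
transmit_allele <- function(copies, contraction_rate = 0, expansion_rate = 0) {
  stopifnot(copies >= 1)
  out <- list(copies = as.integer(copies), mutated = FALSE, direction = NA_character_)
  if (copies >= 2) {
    u <- stats::runif(1)
    if (u < contraction_rate) {
      out$copies <- as.integer(copies - 1L)
      out$mutated <- TRUE
      out$direction <- "contraction"
    } else if (u < contraction_rate + expansion_rate) {
      out$copies <- as.integer(copies + 1L)
      out$mutated <- TRUE
      out$direction <- "expansion"
    }
  }
  out
}

#' Simulate a multi-generation pedigree segregating CNV alleles
#'
#' Founders draw two alleles independently from the configured allele
#' frequencies. In each later generation, individuals of the previous
#' generation are paired at random (one acting as sire, one as dam) and each
#' mating produces `offspring_per_mating` children; every child receives one
#' allele from each parent through [transmit_allele()], so copy-number
#' mutation events can arise and are recorded. Phenotypes are assigned from
#' the true genotype by [phenotype_from_genotype()] and the measured total
#' copy number is the (error-free) sum of the two allele counts.
#'
#' @param config A [grey_sim_config()].
#' @param n_founders Number of founder individuals (generation 0).
#' @param n_generations Number of generations bred after the founders.
#' @param offspring_per_mating Children per mating.
#' @param seed Integer seed; defaults to the seed in `config`.
#' @return A data frame of class `grey_pedigree` with columns `id`, `sire`,
#'   `dam` (NA for founders), `generation`, `dam_allele`, `sire_allele`
#'   (true per-chromosome copy counts), `total_copies` and `phenotype`.
#'   Recorded mutation events are attached as attribute `"events"`: a data
#'   frame with columns `child`, `parent`, `from_copies`, `to_copies`,
#'   `direction`.
#' @export
simulate_pedigree <- function(config = grey_sim_config(), n_founders = 8,
                              n_generations = 3, offspring_per_mating = 2,
                              seed = config$seed) {
  stopifnot(inherits(config, "grey_sim_config"), n_founders >= 2,
            n_generations >= 0, offspring_per_mating >= 1)
  set.seed(seed)
  freqs <- config$allele_frequencies
  allele_copies <- as.integer(sub("^G", "", names(freqs)))

  draw_allele <- function(n)
    allele_copies[sample.int(length(allele_copies), n, replace = TRUE, prob = freqs)]

  # preallocate: generation sizes are deterministic
  sizes <- integer(n_generations + 1)
  sizes[1] <- n_founders
  for (g in seq_len(n_generations))
    sizes[g + 1] <- (sizes[g] %/% 2L) * offspring_per_mating
  total_n <- sum(sizes)

  ids <- character(total_n); sires <- rep(NA_character_, total_n)
  dams <- rep(NA_character_, total_n); gens <- integer(total_n)
  dam_al <- integer(total_n); sire_al <- integer(total_n)
  events <- list()

  ids[seq_len(n_founders)] <- sprintf("F%03d", seq_len(n_founders))
  dam_al[seq_len(n_founders)] <- draw_allele(n_founders)
  sire_al[seq_len(n_founders)] <- draw_allele(n_founders)

  prev <- seq_len(n_founders)
  counter <- n_founders
  for (g in seq_len(n_generations)) {
    if (length(prev) < 2) break
    shuffled <- sample(prev)
    n_matings <- length(shuffled) %/% 2L
    children <- integer(0)
    for (m in seq_len(n_matings)) {
      si <- shuffled[2 * m - 1]
      di <- shuffled[2 * m]
      for (o in seq_len(offspring_per_mating)) {
        counter <- counter + 1L
        child <- sprintf("I%04d", counter - n_founders)
        # one gamete per parent: pick one of the parent's two alleles
        from_dam <- if (stats::runif(1) < 0.5) dam_al[di] else sire_al[di]
        from_sire <- if (stats::runif(1) < 0.5) dam_al[si] else sire_al[si]
        gd <- transmit_allele(from_dam, config$contraction_rate, config$expansion_rate)
        gs <- transmit_allele(from_sire, config$contraction_rate, config$expansion_rate)
        if (gd$mutated)
          events[[length(events) + 1L]] <- data.frame(
            child = child, parent = ids[di], from_copies = from_dam,
            to_copies = gd$copies, direction = gd$direction,
            stringsAsFactors = FALSE)
        if (gs$mutated)
          events[[length(events) + 1L]] <- data.frame(
            child = child, parent = ids[si], from_copies = from_sire,
            to_copies = gs$copies, direction = gs$direction,
            stringsAsFactors = FALSE)
        ids[counter] <- child; sires[counter] <- ids[si]; dams[counter] <- ids[di]
        gens[counter] <- g
        dam_al[counter] <- gd$copies; sire_al[counter] <- gs$copies
        children <- c(children, counter)
      }
    }
    prev <- children
  }

  keep <- seq_len(counter)
  ids <- ids[keep]; sires <- sires[keep]; dams <- dams[keep]
  gens <- gens[keep]; dam_al <- dam_al[keep]; sire_al <- sire_al[keep]
  ped <- data.frame(id = ids, sire = sires, dam = dams, generation = gens,
                    dam_allele = dam_al, sire_allele = sire_al,
                    total_copies = dam_al + sire_al,
                    phenotype = phenotype_from_genotype(dam_al, sire_al),
                    stringsAsFactors = FALSE)
  attr(ped, "events") <- if (length(events)) do.call(rbind, events) else
    data.frame(child = character(0), parent = character(0),
               from_copies = integer(0), to_copies = integer(0),
               direction = character(0), stringsAsFactors = FALSE)
  class(ped) <- c("grey_pedigree", "data.frame")
  ped
}

#' Recorded de novo mutation events of a simulated pedigree
#' @param pedigree A pedigree from [simulate_pedigree()].
#' @return The events data frame attached by the simulator.
#' @export
pedigree_events <- function(pedigree) {
  ev <- attr(pedigree, "events")
  if (is.null(ev)) stop("pedigree carries no recorded events")
  ev
}

#' Simulate a read-depth coverage track over the CNV locus
#'
#' Windows tile `[0, n_windows * window_bp)` on one chromosome. The summed
#' per-window read depth is Poisson with mean `mean_depth * window_bp`
#' outside the CNV interval and `mean_depth * window_bp * total/2` inside
#' it, where `total` is the diploid copy number of the simulated genotype;
#' the reported value is the per-base mean (sum / window size). The CNV
#' interval is placed mid-track and aligned to window boundaries.
#'
#' @param genotype Integer vector of length 2: per-chromosome copy counts.
#' @param locus_model A [cnv_locus_model()] (carried through to the track
#'   metadata; window placement does not depend on it).
#' @param mean_depth Haploid-genome average per-base depth (for a 2-copy
#'   diploid locus).
#' @param window_bp Window size in bp.
#' @param n_windows Number of windows in the track.
#' @param cnv_windows Integer indices (1-based) of the windows inside the
#'   CNV interval; defaults to 20 windows in the middle of the track.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A data frame of class `coverage_track` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `mean_depth`, with attributes
#'   `cnv_interval` and `baseline_intervals` (data frames in the same
#'   coordinate convention) and `true_total_copies`.
#' @export
simulate_coverage_track <- function(genotype, locus_model = cnv_locus_model(),
                                    mean_depth = 30, window_bp = 1000,
                                    n_windows = 200, cnv_windows = NULL,
                                    chrom = "chr25", seed = 17) {
  stopifnot(length(genotype) == 2, all(genotype >= 1), mean_depth > 0,
            window_bp >= 1, n_windows >= 2)
  if (is.null(cnv_windows)) {
    k <- min(20L, max(1L, n_windows %/% 10L))
    first <- (n_windows - k) %/% 2L + 1L
    cnv_windows <- seq(first, first + k - 1L)
  }
  stopifnot(all(cnv_windows >= 1), all(cnv_windows <= n_windows))
  set.seed(seed)
  total <- sum(genotype)
  mult <- rep(1, n_windows)
  mult[cnv_windows] <- total / 2
  depth_sum <- stats::rpois(n_windows, mean_depth * window_bp * mult)
  starts <- (seq_len(n_windows) - 1L) * window_bp
  track <- data.frame(chrom = chrom, start = starts, end = starts + window_bp,
                      mean_depth = depth_sum / window_bp,
                      stringsAsFactors = FALSE)
  cnv_iv <- data.frame(chrom = chrom,
                       start = (min(cnv_windows) - 1L) * window_bp,
                       end = max(cnv_windows) * window_bp,
                       stringsAsFactors = FALSE)
  base_w <- setdiff(seq_len(n_windows), cnv_windows)
  base_iv <- data.frame(chrom = chrom, start = (min(base_w) - 1L) * window_bp,
                        end = cnv_iv$start, stringsAsFactors = FALSE)
  tail_iv <- data.frame(chrom = chrom, start = cnv_iv$end,
                        end = n_windows * window_bp, stringsAsFactors = FALSE)
  attr(track, "cnv_interval") <- cnv_iv
  attr(track, "baseline_intervals") <- rbind(base_iv, tail_iv)
  attr(track, "true_total_copies") <- total
  attr(track, "locus_model") <- locus_model
  class(track) <- c("coverage_track", "data.frame")
  track
}

#' Simulate a droplet digital PCR assay
#'
#' Target molecules partition into droplets so that the per-droplet molecule
#' count is Poisson; a droplet is positive when it received at least one
#' molecule, hence the positive fraction is `1 - exp(-lambda)`. The target
#' assay amplifies the duplicated unit (`lambda = base_lambda * total/2`)
#' and the reference assay a neighbouring CNV-free region
#' (`lambda = base_lambda`).
#'
#' @param total_copies True diploid copy number of the unit.
#' @param n_droplets Droplets generated per channel.
#' @param base_lambda Per-droplet mean molecule count of the 2-copy
#'   reference assay.
#' @param seed Integer seed.
#' @return An object of class `droplet_assay`: a list with
#'   `target_positive`, `target_total`, `reference_positive`,
#'   `reference_total`, plus attribute `saturated` flagging a fully
#'   positive channel.
#' @export
simulate_droplet_assay <- function(total_copies, n_droplets = 20000,
                                   base_lambda = 0.5, seed = 17) {
  stopifnot(total_copies >= 1, n_droplets > 0, base_lambda > 0)
  set.seed(seed)
  lam_t <- base_lambda * total_copies / 2
  tp <- stats::rbinom(1, n_droplets, 1 - exp(-lam_t))
  rp <- stats::rbinom(1, n_droplets, 1 - exp(-base_lambda))
  out <- structure(list(target_positive = tp, target_total = n_droplets,
                        reference_positive = rp, reference_total = n_droplets),
                   class = "droplet_assay")
  attr(out, "saturated") <- (tp == n_droplets) || (rp == n_droplets)
  out
}

#' Construct a droplet assay from explicit counts
#' @param target_positive,target_total,reference_positive,reference_total
#'   Droplet counts; positives must lie in `[0, total]`.
#' @return A `droplet_assay`.
#' @export
droplet_assay <- function(target_positive, target_total,
                          reference_positive, reference_total) {
  stopifnot(target_total > 0, reference_total > 0,
            target_positive >= 0, target_positive <= target_total,
            reference_positive >= 0, reference_positive <= reference_total)
  structure(list(target_positive = as.integer(round(target_positive)),
                 target_total = as.integer(target_total),
                 reference_positive = as.integer(round(reference_positive)),
                 reference_total = as.integer(reference_total)),
            class = "droplet_assay")
}

#' Simulate diploid SNP genotypes with a planted IBD segment
#'
#' Two haplotypes per sample are drawn independently per site from
#' background alternate-allele frequencies (no linkage disequilibrium:
#' only the planted segment structure matters to the downstream scan).
#' Designated sample pairs then share one or both haplotypes identically
#' inside `ibd_interval` by copying from the first member of the pair.
#'
#' @param n_snps Number of ordered biallelic sites.
#' @param n_samples Number of samples (named S01, S02, ...).
#' @param chrom Chromosome name.
#' @param chrom_length Coordinate range; positions are sorted draws from
#'   `1..chrom_length`.
#' @param ibd_pairs List of `list(pair = c(i, j), haplotypes = 1 or 2)`
#'   entries: sample `j` copies that many haplotypes from sample `i` inside
#'   the interval.
#' @param ibd_interval Length-2 numeric `c(start, end)` (bp, 0-based
#'   half-open) or NULL for no sharing.
#' @param maf_range Background alternate-allele frequencies are uniform
#'   draws from this range.
#' @param seed Integer seed.
#' @return An object of class `snp_matrix`: a list with `chrom`,
#'   `positions` (1-based bp) and `genotypes` (samples x sites integer
#'   matrix of 0/1/2 alternate-allele dosages, rownames = sample ids).
#' @export
simulate_snp_genotypes <- function(n_snps, n_samples, chrom = "chr25",
                                   chrom_length = 1e6, ibd_pairs = NULL,
                                   ibd_interval = NULL,
                                   maf_range = c(0.2, 0.5), seed = 17) {
  stopifnot(n_snps >= 1, n_samples >= 1)
  set.seed(seed)
  positions <- sort(sample.int(chrom_length, n_snps))
  p_alt <- stats::runif(n_snps, maf_range[1], maf_range[2])
  hap <- function() matrix(stats::rbinom(n_samples * n_snps, 1, rep(p_alt, each = n_samples)),
                           nrow = n_samples)
  h1 <- hap(); h2 <- hap()
  if (!is.null(ibd_interval) && !is.null(ibd_pairs)) {
    inside <- positions - 1 >= ibd_interval[1] & positions - 1 < ibd_interval[2]
    for (ip in ibd_pairs) {
      i <- ip$pair[1]; j <- ip$pair[2]
      nh <- if (is.null(ip$haplotypes)) 2L else ip$haplotypes
      h1[j, inside] <- h1[i, inside]
      if (nh >= 2) h2[j, inside] <- h2[i, inside]
    }
  }
  geno <- h1 + h2
  rownames(geno) <- sprintf("S%02d", seq_len(n_samples))
  structure(list(chrom = chrom, positions = positions, genotypes = geno),
            class = "snp_matrix")
}

#' Construct a SNP matrix from explicit genotypes
#' @param genotypes Samples x sites integer matrix of 0/1/2 dosages (NA for
#'   missing); must have rownames.
#' @param positions 1-based bp positions, strictly increasing.
#' @param chrom Chromosome name.
#' @return A `snp_matrix`.
#' @export
snp_matrix <- function(genotypes, positions, chrom = "chr25") {
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == length(positions),
            !is.unsorted(positions, strictly = TRUE),
            all(genotypes %in% c(0L, 1L, 2L, NA)))
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("S%02d", seq_len(nrow(genotypes)))
  structure(list(chrom = chrom, positions = as.integer(positions),
                 genotypes = genotypes),
            class = "snp_matrix")
}

#' Plant a perfectly phenotype-associated SNP in a simulated matrix
#'
#' Replaces the genotypes at one site so that exactly the `carrier_samples`
#' are heterozygous carriers and everyone else is homozygous reference —
#' the configuration a fully penetrant dominant variant produces.
#'
#' @param snps A [snp_matrix()].
#' @param carrier_samples Character vector of sample ids to make carriers.
#' @param at Site index (default: middle site).
#' @return The modified `snp_matrix`.
#' @export
plant_associated_snp <- function(snps, carrier_samples,
                                 at = ceiling(length(snps$positions) / 2)) {
  stopifnot(inherits(snps, "snp_matrix"),
            all(carrier_samples %in% rownames(snps$genotypes)))
  snps$genotypes[, at] <- 0L
  snps$genotypes[carrier_samples, at] <- 1L
  snps
}

# rejection-sample random DNA that avoids a motif (so planted junction
# microhomology stays exactly the motif)
random_dna_avoiding <- function(n, motif) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
}

#' Simulate long spanning reads over a CNV allele
#'
#' Builds a captured fragment `upstream flank + k x unit + downstream
#' flank` and emits reads covering the whole fragment, with Gaussian length
#' noise (truncation / random-tail padding), substitution errors, and
#' per-read CpG methylation calls. The unit sequence carries the
#' microhomology motif as both its prefix and suffix, so every head-to-tail
#' copy junction in a multi-copy allele presents the motif as shared flank
#' on both sides of the breakpoint; the remainder of the unit and the
#' flanks are motif-free random sequence.
#'
#' Methylation calls emulate an enhancer that is hypomethylated relative to
#' its surroundings: CpG sites whose position within the unit falls inside
#' `enhancer_interval` are methylated with probability `p_enhancer`, all
#' other CpGs with probability `p_background`; a methylated call is
#' reported as 5hmC with probability `hydroxy_frac`, otherwise 5mC.
#'
#' @param allele_copies Copy count k of the simulated allele (>= 1).
#' @param locus_model A [cnv_locus_model()]; [scaled_locus_model()] by
#'   default for desk-scale sequence lengths.
#' @param unit_seq,flank_seqs Optional explicit sequences: `unit_seq` a
#'   string of length `unit_length_bp`; `flank_seqs` a list with elements
#'   `upstream` and `downstream` whose lengths sum to `flank_length_bp`.
#'   Generated randomly when NULL.
#' @param microhomology_motif Motif placed at both unit junction sides.
#' @param n_reads Number of spanning reads.
#' @param length_noise_sd SD in bp of Gaussian read-length noise.
#' @param per_base_error Substitution error probability per base.
#' @param meth_pattern List with `enhancer_interval` (`c(start, end)`,
#'   0-based half-open within the unit), `p_enhancer`, `p_background`,
#'   `hydroxy_frac`; NULL disables methylation simulation.
#' @param seed Integer seed.
#' @return A list of class `spanning_read_set`: `reads` (named character
#'   vector), `meth_calls` (data frame `read_id`, `cpg_pos` (1-based
#'   fragment coordinate), `call` in 5mC/5hmC/unmethylated; NULL if no
#'   pattern), `fragment` (error-free template), `unit_seq`, `flank_seqs`,
#'   `cpg_positions`, `allele_copies`, `locus_model`.
#' @export
simulate_allele_reads <- function(allele_copies,
                                  locus_model = scaled_locus_model(),
                                  unit_seq = NULL, flank_seqs = NULL,
                                  microhomology_motif = "TCTCAG",
                                  n_reads = 30, length_noise_sd = 0,
                                  per_base_error = 0, meth_pattern = NULL,
                                  seed = 17) {
  stopifnot(allele_copies >= 1, n_reads >= 1,
            per_base_error >= 0, per_base_error < 1)
  if (nchar(microhomology_motif) >= locus_model$unit_length_bp)
    stop("microhomology motif longer than the duplicated unit")
  set.seed(seed)
  mlen <- nchar(microhomology_motif)
  if (is.null(unit_seq)) {
    mid <- random_dna_avoiding(locus_model$unit_length_bp - 2 * mlen,
                               microhomology_motif)
    unit_seq <- paste0(microhomology_motif, mid, microhomology_motif)
  }
  stopifnot(nchar(unit_seq) == locus_model$unit_length_bp)
  if (is.null(flank_seqs)) {
    up_len <- locus_model$flank_length_bp %/% 2
    down_len <- locus_model$flank_length_bp - up_len
    flank_seqs <- list(
      upstream = random_dna_avoiding(up_len, microhomology_motif),
      downstream = random_dna_avoiding(down_len, microhomology_motif))
  }
  stopifnot(nchar(flank_seqs$upstream) + nchar(flank_seqs$downstream) ==
              locus_model$flank_length_bp)

  fragment <- paste0(flank_seqs$upstream,
                     paste(rep(unit_seq, allele_copies), collapse = ""),
                     flank_seqs$downstream)
  frag_len <- nchar(fragment)
  bases <- c("A", "C", "G", "T")
  frag_chars <- strsplit(fragment, "")[[1]]

  cpg_positions <- as.integer(gregexpr("CG", fragment, fixed = TRUE)[[1]])
  if (length(cpg_positions) == 1 && cpg_positions[1] == -1)
    cpg_positions <- integer(0)

  reads <- character(n_reads)
  meth_rows <- list()
  unit_start <- nchar(flank_seqs$upstream)  # 0-based start of first copy
  for (r in seq_len(n_reads)) {
    L <- max(1L, as.integer(round(stats::rnorm(1, frag_len, length_noise_sd))))
    ch <- frag_chars
    if (L < frag_len) ch <- ch[seq_len(L)]
    if (L > frag_len) ch <- c(ch, sample(bases, L - frag_len, replace = TRUE))
    if (per_base_error > 0) {
      err <- which(stats::runif(L) < per_base_error)
      if (length(err)) {
        for (i in err) ch[i] <- sample(setdiff(bases, ch[i]), 1)
      }
    }
    rid <- sprintf("read_%03d", r)
    reads[r] <- paste(ch, collapse = "")
    names(reads)[r] <- rid

    if (!is.null(meth_pattern) && length(cpg_positions)) {
      pos0 <- cpg_positions - 1L
      off <- (pos0 - unit_start) %% locus_model$unit_length_bp
      in_unit <- pos0 >= unit_start &
        pos0 < unit_start + allele_copies * locus_model$unit_length_bp
      in_enh <- in_unit & off >= meth_pattern$enhancer_interval[1] &
        off < meth_pattern$enhancer_interval[2]
      p <- ifelse(in_enh, meth_pattern$p_enhancer, meth_pattern$p_background)
      meth <- stats::runif(length(p)) < p
      hydro <- stats::runif(length(p)) < meth_pattern$hydroxy_frac
      call <- ifelse(meth, ifelse(hydro, "5hmC", "5mC"), "unmethylated")
      meth_rows[[r]] <- data.frame(read_id = rid, cpg_pos = cpg_positions,
                                   call = call, stringsAsFactors = FALSE)
    }
  }

  structure(list(reads = reads,
                 meth_calls = if (length(meth_rows)) do.call(rbind, meth_rows) else NULL,
                 fragment = fragment, unit_seq = unit_seq,
                 flank_seqs = flank_seqs, cpg_positions = cpg_positions,
                 allele_copies = as.integer(allele_copies),
                 locus_model = locus_model),
            class = "spanning_read_set")
}

#' Simulate a per-site pileup table with an optional run of homozygosity
#'
#' Every position on a synthetic chromosome gets a Poisson depth and base
#' counts. Outside `roh_interval`, heterozygous sites occur at density
#' `het_density` and draw roughly 50/50 major/minor counts; inside it (and
#' at all homozygous sites) the only minor counts are sequencing errors at
#' `error_rate` per read.
#'
#' @param chromosome_length Number of simulated positions.
#' @param het_density Per-site probability of a heterozygous site outside
#'   the ROH.
#' @param roh_interval `c(start, end)` in bp (0-based half-open) or NULL.
#' @param depth Mean per-site depth.
#' @param error_rate Per-read substitution error probability.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A data frame of class `pileup_table` with columns `chrom`,
#'   `pos` (1-based), `depth`, `A`, `C`, `G`, `T`.
#' @export
simulate_pileup <- function(chromosome_length = 2e5, het_density = 0.002,
                            roh_interval = NULL, depth = 45,
                            error_rate = 0.01, chrom = "chr25", seed = 17) {
  stopifnot(chromosome_length >= 1, depth > 0,
            het_density >= 0, het_density <= 1,
            error_rate >= 0, error_rate < 1)
  set.seed(seed)
  n <- chromosome_length
  pos <- seq_len(n)
  d <- stats::rpois(n, depth)
  ref_idx <- sample.int(4, n, replace = TRUE)
  alt_idx <- ((ref_idx - 1 + sample.int(3, n, replace = TRUE)) %% 4) + 1
  het <- stats::runif(n) < het_density
  if (!is.null(roh_interval))
    het[pos - 1 >= roh_interval[1] & pos - 1 < roh_interval[2]] <- FALSE

  counts <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  # heterozygous: alt reads Binomial(depth, 0.5) on the alternate allele;
  # homozygous: Binomial(depth, error_rate) errors spread uniformly over
  # the three other bases
  alt_n <- integer(n)
  alt_n[het] <- stats::rbinom(sum(het), d[het], 0.5)
  counts[cbind(seq_len(n), alt_idx)] <- alt_n
  err_n <- integer(n)
  if (error_rate > 0)
    err_n[!het] <- stats::rbinom(sum(!het), d[!het], error_rate)
  e1 <- stats::rbinom(n, err_n, 1 / 3)
  e2 <- stats::rbinom(n, err_n - e1, 1 / 2)
  e3 <- err_n - e1 - e2
  other <- cbind((ref_idx %% 4) + 1, ((ref_idx + 1) %% 4) + 1,
                 ((ref_idx + 2) %% 4) + 1)
  counts[cbind(seq_len(n), other[, 1])] <- counts[cbind(seq_len(n), other[, 1])] + e1
  counts[cbind(seq_len(n), other[, 2])] <- counts[cbind(seq_len(n), other[, 2])] + e2
  counts[cbind(seq_len(n), other[, 3])] <- counts[cbind(seq_len(n), other[, 3])] + e3
  ref_n <- d - alt_n - err_n
  counts[cbind(seq_len(n), ref_idx)] <- counts[cbind(seq_len(n), ref_idx)] + ref_n

  out <- data.frame(chrom = chrom, pos = pos, depth = d,
                    A = counts[, "A"], C = counts[, "C"],
                    G = counts[, "G"], T = counts[, "T"],
                    stringsAsFactors = FALSE)
  class(out) <- c("pileup_table", "data.frame")
  out
}
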