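#' @name ibd_scan
#' @title Opposite-homozygote IBD scan and pileup-based diversity
#' @description Two samples that share both haplotypes identical-by-descent
#'   over a segment can never be homozygous for different alleles there, so
#'   windows with a zero fraction of opposite-homozygote calls delimit IBD
#'   sharing. A heterozygous carrier of two haplotypes is compared to a
#'   homozygous reference through two complementary tracks (opposite
#'   homozygotes, and heterozygous differences), which resolve which of the
#'   two haplotypes is shared. Runs of homozygosity within one individual
#'   are detected from windowed per-site nucleotide diversity computed on a
#'   pileup, after zeroing minor-allele observations supported by too few
#'   reads to be trusted over sequencing error.
NULL

# genotype vectors of a pair, restricted to sites non-missing in both
pair_genotypes <- function(snps, a, b) {
  stopifnot(inherits(snps, "snp_matrix"))
  g <- snps$genotypes
  if (!all(c(a, b) %in% rownames(g))) stop("unknown sample id")
  ga <- g[a, ]; gb <- g[b, ]
  ok <- !is.na(ga) & !is.na(gb)
  list(ga = ga[ok], gb = gb[ok], positions = snps$positions[ok])
}

# sliding-window mean of an indicator over SNP index space
window_scan <- function(indicator, positions, chrom, window_snps, step_snps) {
  n <- length(indicator)
  if (n < window_snps)
    stop(sprintf("only %d usable sites but window is %d SNPs", n, window_snps))
  cs <- c(0, cumsum(indicator))
  starts <- seq(1L, n - window_snps + 1L, by = step_snps)
  frac <- (cs[starts + window_snps] - cs[starts]) / window_snps
  out <- data.frame(window = seq_along(starts),
                    start_pos = positions[starts],
                    end_pos = positions[starts + window_snps - 1L],
                    fraction = frac)
  attr(out, "chrom") <- chrom
  attr(out, "window_snps") <- window_snps
  attr(out, "step_snps") <- step_snps
  class(out) <- c("ibd_scan", "data.frame")
  out
}

#' Sliding-window fractions of opposite-homozygote calls between two samples
#'
#' A site counts as an opposite-homozygote call when one sample has
#' genotype 0 and the other genotype 2. Fractions are computed in sliding
#' windows of `window_snps` sites (over sites non-missing in both
#' samples), advancing `step_snps` sites at a time.
#'
#' @param snps A [snp_matrix()].
#' @param reference_sample,other_sample Sample ids (rownames of the
#'   genotype matrix).
#' @param window_snps Window size in SNPs.
#' @param step_snps Step between window starts in SNPs.
#' @return Data frame of class `ibd_scan` with columns `window`,
#'   `start_pos`, `end_pos` (1-based positions of the first/last SNP in
#'   the window) and `fraction`.
#' @export
opposite_homozygote_fractions <- function(snps, reference_sample, other_sample,
                                          window_snps = 100, step_snps = 1) {
  pg <- pair_genotypes(snps, reference_sample, other_sample)
  opp <- (pg$ga == 0 & pg$gb == 2) | (pg$ga == 2 & pg$gb == 0)
  window_scan(opp, pg$positions, snps$chrom, window_snps, step_snps)
}

#' Homozygous and heterozygous difference tracks against a heterozygous sample
#'
#' For a heterozygous carrier compared with a homozygous reference, the
#' opposite-homozygote track reflects differences to both carried
#' haplotypes while the heterozygous-difference track (sites where the
#' carrier is heterozygous and the reference homozygous) reflects
#' differences to exactly one of them; together they resolve which
#' haplotype is shared with the reference.
#'
#' @inheritParams opposite_homozygote_fractions
#' @param het_sample Sample id of the heterozygous carrier.
#' @return List with elements `homozygous` and `heterozygous`, each an
#'   `ibd_scan` data frame over the same windows.
#' @export
het_comparison_fractions <- function(snps, reference_sample, het_sample,
                                     window_snps = 100, step_snps = 1) {
  pg <- pair_genotypes(snps, reference_sample, het_sample)
  opp <- (pg$ga == 0 & pg$gb == 2) | (pg$ga == 2 & pg$gb == 0)
  hetdiff <- (pg$gb == 1) & (pg$ga %in% c(0, 2))
  list(homozygous = window_scan(opp, pg$positions, snps$chrom,
                                window_snps, step_snps),
       heterozygous = window_scan(hetdiff, pg$positions, snps$chrom,
                                  window_snps, step_snps))
}

# maximal runs of TRUE -> merged bp intervals (0-based half-open)
runs_to_intervals <- function(keep, start_pos, end_pos, chrom) {
  if (!any(keep))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  r <- rle(keep)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  sel <- which(r$values)
  iv <- data.frame(chrom = chrom,
                   start = start_pos[idx_start[sel]] - 1L,
                   end = end_pos[idx_end[sel]],
                   stringsAsFactors = FALSE)
  # windows overlap when step < window, so successive runs may touch
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], iv$end[i])
      } else merged <- rbind(merged, iv[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Call IBD intervals from an opposite-homozygote scan
#'
#' Maximal runs of consecutive windows whose fraction does not exceed
#' `max_fraction` are merged and reported as genomic intervals.
#'
#' @param scan An `ibd_scan` data frame.
#' @param max_fraction Largest window fraction still compatible with IBD
#'   sharing (0 by default: any opposite homozygote breaks IBD).
#' @return BED-style data frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
call_ibd_intervals <- function(scan, max_fraction = 0) {
  stopifnot(inherits(scan, "ibd_scan"))
  runs_to_intervals(scan$fraction <= max_fraction, scan$start_pos,
                    scan$end_pos, attr(scan, "chrom"))
}

#' Windowed nucleotide diversity from a pileup table
#'
#' Per-site diversity is the fraction of reads supporting a non-major
#' allele, `(depth - major count) / depth`, set to zero when no single
#' non-major allele is supported by at least `min_minor_reads` reads —
#' scattered low-support observations are indistinguishable from
#' sequencing error, whereas a true second allele concentrates its reads.
#' Sites are averaged in fixed, non-overlapping windows of `window_bp`.
#'
#' @param pileup A `pileup_table` data frame (`chrom`, `pos`, `depth`,
#'   `A`, `C`, `G`, `T`), e.g. from [simulate_pileup()] or
#'   [read_pileup_tsv()], sorted by position. Zero-depth sites are
#'   skipped.
#' @param min_minor_reads Minimum read support of a single non-major
#'   allele for a site to contribute diversity (default 3, i.e. sites
#'   where every non-major allele has <= 2 supporting reads are zeroed).
#' @param window_bp Window size in bp.
#' @return Data frame of class `diversity_track` with `chrom`, `start`,
#'   `end` (0-based half-open), `diversity`, `n_sites`.
#' @export
pileup_diversity <- function(pileup, min_minor_reads = 3, window_bp = 500000) {
  stopifnot(all(c("chrom", "pos", "depth", "A", "C", "G", "T") %in% names(pileup)),
            !is.unsorted(pileup$pos), min_minor_reads >= 1, window_bp >= 1)
  keep <- pileup$depth > 0
  p <- pileup[keep, , drop = FALSE]
  counts <- as.matrix(p[, c("A", "C", "G", "T")])
  nr <- nrow(counts)
  i1 <- cbind(seq_len(nr), max.col(counts, ties.method = "first"))
  major <- counts[i1]
  rest <- counts
  rest[i1] <- -1L
  second <- rest[cbind(seq_len(nr), max.col(rest, ties.method = "first"))]
  nonmajor <- p$depth - major
  frac <- ifelse(second <= min_minor_reads - 1, 0, nonmajor / p$depth)
  bin <- (p$pos - 1L) %/% as.integer(window_bp)
  agg <- tapply(frac, bin, mean)
  nsite <- tapply(frac, bin, length)
  b <- as.integer(names(agg))
  out <- data.frame(chrom = p$chrom[1], start = b * as.integer(window_bp),
                    end = (b + 1L) * as.integer(window_bp),
                    diversity = as.numeric(agg), n_sites = as.integer(nsite),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diversity_track", "data.frame")
  out
}

#' Call runs of homozygosity from a diversity track
#'
#' Maximal runs of consecutive windows whose mean diversity does not
#' exceed `max_diversity` are merged into intervals.
#'
#' @param track A `diversity_track` from [pileup_diversity()].
#' @param max_diversity Diversity threshold for a window to be called
#'   homozygous.
#' @return BED-style data frame `chrom`, `start`, `end`.
#' @export
call_roh_intervals <- function(track, max_diversity) {
  stopifnot(inherits(track, "diversity_track"))
  runs_to_intervals(track$diversity <= max_diversity,
                    track$start + 1L, track$end, track$chrom[1])
}
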