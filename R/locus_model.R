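#' CNV locus model
#'
#' Describes the physical layout of the tandem CNV locus: the length of the
#' duplicated unit, the total length of captured flanking sequence, and
#' (optionally) the genomic interval occupied by one reference copy of the
#' unit. A spanning fragment carrying `k` copies of the unit has expected
#' length `flank_length_bp + k * unit_length_bp`.
#'
#' The defaults describe the horse Grey locus at full scale: a 4.6 kb unit
#' with 3.1 kb of captured flank, so that 1/2/3-copy haplotypes yield
#' ~7.7/12.3/16.9 kb spanning fragments. For fast simulation a 1:10
#' scaled-down model is available via [scaled_locus_model()].
#'
#' @param unit_length_bp Length in bp of one copy of the duplicated unit.
#' @param flank_length_bp Total captured flanking sequence (both sides
#'   combined), so that a 1-copy fragment is `flank + unit` long.
#' @param cnv_interval Optional genomic interval (see [parse_region()])
#'   locating one reference copy of the unit.
#' @return An object of class `cnv_locus_model`.
#' @examples
#' m <- cnv_locus_model()
#' expected_fragment_length(m, 1:3)  # 7700 12300 16900
#' @export
cnv_locus_model <- function(unit_length_bp = 4600, flank_length_bp = 3100,
                            cnv_interval = NULL) {
  stopifnot(unit_length_bp > 0, flank_length_bp >= 0)
  structure(
    list(unit_length_bp = as.integer(unit_length_bp),
         flank_length_bp = as.integer(flank_length_bp),
         cnv_interval = cnv_interval),
    class = "cnv_locus_model"
  )
}

#' Scaled-down locus model for simulation
#'
#' A 1:10 miniature of the default locus (460 bp unit, 310 bp flank) used by
#' the read simulator and the test-suite so that consensus building and
#' dotplot chaining run in milliseconds. All length arithmetic is identical
#' to the full-scale model.
#'
#' @inheritParams cnv_locus_model
#' @return A `cnv_locus_model`.
#' @export
scaled_locus_model <- function(unit_length_bp = 460, flank_length_bp = 310,
                               cnv_interval = NULL) {
  cnv_locus_model(unit_length_bp, flank_length_bp, cnv_interval)
}

#' Expected spanning-fragment length for a k-copy allele
#'
#' @param model A [cnv_locus_model()].
#' @param k Integer vector of per-chromosome unit copy counts (>= 1).
#' @return Numeric vector of expected fragment lengths in bp.
#' @export
expected_fragment_length <- function(model, k) {
  stopifnot(inherits(model, "cnv_locus_model"), all(k >= 1))
  model$flank_length_bp + k * model$unit_length_bp
}

#' @exportS3Method base::print
print.cnv_locus_model <- function(x, ...) {
  cat("CNV locus model: unit", x$unit_length_bp, "bp, flank",
      x$flank_length_bp, "bp\n")
  cat("Expected spanning fragments (k = 1..3):",
      paste(expected_fragment_length(x, 1:3), collapse = " / "), "bp\n")
  invisible(x)
}

#' Allele label for a copy count
#'
#' Alleles are named "G" followed by the number of unit copies on that
#' chromosome: G1 is the single-copy wild type, G2 the duplication, G3 the
#' triplication.
#'
#' @param copies Integer vector of per-chromosome copy counts (>= 1).
#' @return Character vector of labels.
#' @examples
#' allele_label(1:3)  # "G1" "G2" "G3"
#' @export
allele_label <- function(copies) {
  stopifnot(all(copies >= 1))
  paste0("G", as.integer(copies))
}

#' Genotype label for a pair of alleles
#'
#' @param a,b Integer copy counts of the two alleles. Reported with the
#'   larger allele first (genotypes are unordered unless pedigree data
#'   forces an ordering).
#' @return Character vector like "G3/G2".
#' @export
genotype_label <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  paste0(allele_label(hi), "/", allele_label(lo))
}

#' Greying phenotype implied by a CNV genotype
#'
#' The allelic series is dosage sensitive on the larger allele: any allele
#' with three or more unit copies causes fast greying, a largest allele of
#' exactly two copies causes slow greying, and two single-copy (wild-type)
#' alleles give a non-grey horse.
#'
#' @param maternal,paternal Integer vectors of per-chromosome copy counts
#'   (>= 1); recycled against each other.
#' @return Character vector with values in
#'   `c("non_grey", "slow", "fast")`.
#' @examples
#' phenotype_from_genotype(1, 1)  # non_grey
#' phenotype_from_genotype(1, 2)  # slow
#' phenotype_from_genotype(3, 2)  # fast
#' @export
phenotype_from_genotype <- function(maternal, paternal) {
  stopifnot(all(maternal >= 1), all(paternal >= 1))
  mx <- pmax(maternal, paternal)
  ifelse(mx >= 3, "fast", ifelse(mx == 2, "slow", "non_grey"))
}

#' Phenotype classes used throughout the package
#' @return Character vector of the recognised phenotype codes.
#' @export
phenotype_classes <- function() c("non_grey", "slow", "fast", "unknown")

# rounding half away from zero; used for all integer copy-number calls so
# estimates are symmetric around true integers
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
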