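#' Breed copy-number histogram
#'
#' A per-breed histogram of diploid total copy number of the duplicated
#' unit, as produced by ddPCR screening. Only totals 2-6 are supported:
#' with no germ-line allele beyond three copies, seven or more total
#' copies cannot arise, and such counts are rejected unless
#' `max_allele` is raised.
#'
#' @param breed Breed or population name.
#' @param counts Numeric vector of horse counts for total copy numbers
#'   2, 3, ..., in order; length must be `2 * max_allele - 1`.
#' @param max_allele Largest per-chromosome copy count entertained
#'   (default 3, giving totals 2-6).
#' @return Data-frame row of class `breed_cnv_table` with columns `breed`
#'   and `n2`, `n3`, ... plus `n`.
#' @examples
#' breed_cnv_table("Andalusian", c(25, 8, 40, 1, 9))
#' @export
breed_cnv_table <- function(breed, counts, max_allele = 3) {
  expected <- 2 * max_allele - 1
  if (length(counts) > expected)
    stop(sprintf(paste("counts for total copy number above %d supplied;",
                       "alleles beyond %d copies are not supported",
                       "(raise max_allele to override)"),
                 2 * max_allele, max_allele))
  stopifnot(length(counts) == expected, all(counts >= 0), sum(counts) > 0,
            all(counts == round(counts)))
  out <- data.frame(breed = breed, stringsAsFactors = FALSE)
  for (i in seq_along(counts)) out[[paste0("n", i + 1)]] <- as.integer(counts[i])
  out$n <- as.integer(sum(counts))
  class(out) <- c("breed_cnv_table", "data.frame")
  out
}

#' Deduce genotype counts from a breed copy-number histogram
#'
#' Total copy numbers map to genotypes as 2 = G1/G1, 3 = G1/G2,
#' 5 = G2/G3 and 6 = G3/G3. Four copies is ambiguous (G1/G3 or G2/G2);
#' under the assumption that no G2/G2 homozygote is present — justified
#' when G1/G2 and G2/G3 heterozygotes are rare in the same sample — all
#' 4-copy horses are counted as G1/G3.
#'
#' @param table A [breed_cnv_table()] row (totals 2-6).
#' @return Named integer vector of genotype counts.
#' @examples
#' deduce_genotype_counts(breed_cnv_table("Andalusian", c(25, 8, 40, 1, 9)))
#' @export
deduce_genotype_counts <- function(table) {
  stopifnot(inherits(table, "breed_cnv_table"),
            all(c("n2", "n3", "n4", "n5", "n6") %in% names(table)))
  c("G1/G1" = table$n2, "G1/G2" = table$n3, "G1/G3" = table$n4,
    "G2/G3" = table$n5, "G3/G3" = table$n6)
}

#' Allele frequencies from a breed copy-number histogram
#'
#' Under the no-G2/G2 assumption of [deduce_genotype_counts()], each
#' genotype contributes its alleles to the frequency estimate:
#' `fG2 = (n3 + n5) / 2n`, `fG3 = (n4 + n5 + 2 n6) / 2n`,
#' `fG1 = 1 - fG2 - fG3`. When the sampled population does contain G2/G2
#' homozygotes these are biased estimates — fG2 is undercounted (its
#' homozygotes are attributed to G1/G3).
#'
#' @param table A [breed_cnv_table()] row.
#' @return Named numeric vector of class `allele_frequencies` with
#'   elements `G1`, `G2`, `G3` (summing to 1) and attribute `n`.
#' @examples
#' allele_frequencies(breed_cnv_table("Andalusian", c(25, 8, 40, 1, 9)))
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "breed_cnv_table"))
  n <- table$n
  if (n == 0) stop("empty breed table")
  fG2 <- (table$n3 + table$n5) / (2 * n)
  fG3 <- (table$n4 + table$n5 + 2 * table$n6) / (2 * n)
  structure(c(G1 = 1 - fG2 - fG3, G2 = fG2, G3 = fG3),
            n = n, class = "allele_frequencies")
}

#' Expected total-copy-number distribution under Hardy-Weinberg equilibrium
#'
#' Genotype probabilities are the usual Hardy-Weinberg products
#' (`f_i^2` on the diagonal, `2 f_i f_j` off it), mapped onto diploid
#' total copy number; note that four copies pools G1/G3 with G2/G2.
#'
#' @param freqs An [allele_frequencies()] vector (or any named numeric
#'   `c(G1 = ..., G2 = ..., G3 = ...)` summing to 1).
#' @param n Sample size to scale the distribution to.
#' @return Named numeric vector of expected counts for totals "2".."6".
#' @export
hwe_expected_cn_distribution <- function(freqs, n = 1) {
  stopifnot(all(c("G1", "G2", "G3") %in% names(freqs)),
            abs(sum(freqs[c("G1", "G2", "G3")]) - 1) < 1e-8)
  f1 <- freqs[["G1"]]; f2 <- freqs[["G2"]]; f3 <- freqs[["G3"]]
  probs <- c("2" = f1^2,
             "3" = 2 * f1 * f2,
             "4" = 2 * f1 * f3 + f2^2,
             "5" = 2 * f2 * f3,
             "6" = f3^2)
  probs * n
}

#' Two-decimal frequency report for a set of breed tables
#'
#' @param tables A `breed_cnv_table` (one or more rows, e.g. from
#'   `rbind`ing [breed_cnv_table()] rows or [grey_breed_survey()]).
#' @return Data frame `breed`, `n`, `fG2`, `fG3` with frequencies rounded
#'   half away from zero to two decimals, matching the presentation
#'   convention of published breed surveys.
#' @export
breed_frequency_report <- function(tables) {
  rows <- lapply(seq_len(nrow(tables)), function(i) {
    row <- tables[i, , drop = FALSE]
    class(row) <- class(tables)
    f <- allele_frequencies(row)
    data.frame(breed = row$breed, n = row$n,
               fG2 = round_half_away(f[["G2"]] * 100) / 100,
               fG3 = round_half_away(f[["G3"]] * 100) / 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published breed survey of the Grey CNV
#'
#' Copy-number histograms for the eight breeds/populations in which both
#' variant alleles (G2 and G3) were definitively detected in a ddPCR
#' genotyping survey of 1,400 horses from 78 breeds. Counts are horses
#' with diploid totals of 2-6 unit copies.
#'
#' @return A `breed_cnv_table` data frame with eight rows.
#' @examples
#' breed_frequency_report(grey_breed_survey())
#' @export
grey_breed_survey <- function() {
  rows <- list(
    breed_cnv_table("Andalusian",              c(25, 8, 40, 1, 9)),
    breed_cnv_table("Connemara Pony",          c(23, 6, 49, 3, 9)),
    breed_cnv_table("Miniature Horse",         c(25, 1, 15, 0, 0)),
    breed_cnv_table("Mangalarga Marchador",    c(0, 1, 8, 0, 0)),
    breed_cnv_table("Mustang",                 c(3, 2, 8, 0, 0)),
    breed_cnv_table("Quarter Horse",           c(141, 0, 284, 1, 13)),
    breed_cnv_table("Tennessee Walking Horse", c(16, 2, 23, 0, 4)),
    breed_cnv_table("Welsh Pony",              c(7, 1, 25, 0, 3)))
  out <- do.call(rbind, rows)
  class(out) <- c("breed_cnv_table", "data.frame")
  out
}
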