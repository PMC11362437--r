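#' Parse a genomic region string
#'
#' Accepts `"chrom:start-end"` with optional `kb`/`Mb` suffixes on the
#' numbers (a suffix on the second number alone applies to both, so
#' `"chr25:2-18Mb"` means 2 Mb to 18 Mb). Input coordinates are 1-based
#' inclusive, as in region strings used by samtools and genome browsers;
#' the returned interval is 0-based half-open.
#'
#' @param text Region string.
#' @return Data frame with one row: `chrom`, `start`, `end`.
#' @examples
#' parse_region("chr25:6450000-6800000")
#' parse_region("chr25:2-18Mb")
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec(
    "^(.+):([0-9.]+)\\s*(kb|Kb|KB|mb|Mb|MB)?\\s*-\\s*([0-9.]+)\\s*(kb|Kb|KB|mb|Mb|MB)?$",
    text))[[1]]
  if (length(m) == 0) stop("malformed region: ", text)
  chrom <- m[2]
  unit_of <- function(u) switch(tolower(u), kb = 1e3, mb = 1e6, 1)
  u1 <- m[4]; u2 <- m[6]
  if (u1 == "" && u2 != "") u1 <- u2  # trailing unit applies to both
  start1 <- as.numeric(m[3]) * unit_of(u1)
  end1 <- as.numeric(m[5]) * unit_of(u2)
  if (start1 != round(start1) || end1 != round(end1))
    stop("region coordinates do not resolve to whole base pairs: ", text)
  if (start1 >= end1) stop("region start must be before end: ", text)
  data.frame(chrom = chrom, start = as.integer(start1) - 1L,
             end = as.integer(end1), stringsAsFactors = FALSE)
}

#' @rdname pedigree_io
#' @name pedigree_io
#' @title Pedigree TSV input/output
#' @description Pedigrees travel as TSV with columns `id`, `sire`, `dam`,
#'   `phenotype`, `total_copies` (missing values as NA).
#' @param pedigree Data frame with the pedigree columns.
#' @param path File path.
#' @return `read_pedigree_tsv` returns the pedigree data frame;
#'   `write_pedigree_tsv` returns `path` invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  cols <- c("id", "sire", "dam", "phenotype", "total_copies")
  stopifnot(all(cols %in% names(pedigree)))
  utils::write.table(pedigree[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname pedigree_io
#' @export
read_pedigree_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "phenotype", "total_copies")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("id", "sire", "dam", "phenotype")) df[[col]] <- as.character(df[[col]])
  df$total_copies <- as.integer(df$total_copies)
  df
}

#' Write a SNP matrix as a minimal VCF
#'
#' GT-only dialect: one biallelic record per site (placeholder REF/ALT
#' `A`/`G`), genotypes `0/0`, `0/1`, `1/1` or `./.` from the 0/1/2 dosage
#' matrix. Positions are written 1-based per the VCF convention.
#'
#' @param snps A [snp_matrix()].
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "snp_matrix"))
  g <- snps$genotypes
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- vapply(seq_along(snps$positions), function(j) {
    paste(c(snps$chrom, snps$positions[j], ".", "A", "G", ".", ".", ".",
            "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a minimal (GT-only) VCF into a SNP matrix
#'
#' @param path VCF path.
#' @return A [snp_matrix()] with 0/1/2 alternate-allele dosages (NA for
#'   missing genotypes). Multi-chromosome files are rejected; sites are
#'   assumed biallelic.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  chroms <- unique(vcfR::getCHROM(v))
  if (length(chroms) != 1) stop("expected a single-chromosome VCF")
  dose <- function(x) {
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
  }
  g <- t(apply(gt, 2, dose))  # samples x sites
  colnames(g) <- NULL
  snp_matrix(g, positions = vcfR::getPOS(v), chrom = chroms)
}

#' @rdname bed_io
#' @name bed_io
#' @title BED interval input/output
#' @description Intervals are data frames `chrom`, `start`, `end` in the
#'   0-based half-open BED convention; files are read and written through
#'   rtracklayer.
#' @param intervals Data frame `chrom`, `start`, `end`.
#' @param path File path.
#' @return `read_bed` returns the intervals data frame; `write_bed`
#'   returns `path` invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname bed_io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' @rdname coverage_io
#' @name coverage_io
#' @title Coverage-track TSV input/output
#' @description Columns `chrom`, `start`, `end` (0-based half-open
#'   windows) and `mean_depth`.
#' @param track Coverage track data frame.
#' @param path File path.
#' @return `read_coverage_tsv` returns a `coverage_track`;
#'   `write_coverage_tsv` returns `path` invisibly.
#' @export
write_coverage_tsv <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "mean_depth") %in% names(track)))
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end", "mean_depth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coverage_io
#' @export
read_coverage_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mean_depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("coverage TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  class(df) <- c("coverage_track", "data.frame")
  df
}

#' @rdname pileup_io
#' @name pileup_io
#' @title Pileup TSV input/output
#' @description Columns `chrom`, `pos` (1-based), `depth`, `A`, `C`, `G`,
#'   `T`.
#' @param pileup Pileup data frame.
#' @param path File path.
#' @return `read_pileup_tsv` returns a `pileup_table`;
#'   `write_pileup_tsv` returns `path` invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  cols <- c("chrom", "pos", "depth", "A", "C", "G", "T")
  stopifnot(all(cols %in% names(pileup)))
  utils::write.table(as.data.frame(pileup)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pileup_io
#' @export
read_pileup_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("chrom", "pos", "depth", "A", "C", "G", "T")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pileup TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  class(df) <- c("pileup_table", "data.frame")
  df
}

#' @rdname methylation_io
#' @name methylation_io
#' @title Per-read methylation-call TSV input/output
#' @description Columns `read_id`, `cpg_pos` (1-based), `call` in
#'   5mC/5hmC/unmethylated.
#' @param calls Calls data frame.
#' @param path File path.
#' @return `read_methylation_tsv` returns the calls data frame;
#'   `write_methylation_tsv` returns `path` invisibly.
#' @export
write_methylation_tsv <- function(calls, path) {
  cols <- c("read_id", "cpg_pos", "call")
  stopifnot(all(cols %in% names(calls)))
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname methylation_io
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "cpg_pos", "call")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("methylation TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname fasta_io
#' @name fasta_io
#' @title FASTA input/output for reads and consensus sequences
#' @description Thin wrappers over Biostrings for named DNA sequence sets
#'   (spanning reads, unit/flank/consensus sequences).
#' @param sequences Named character vector of DNA sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
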