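#' Classify a spanning read's allele copy number from its length
#'
#' The expected captured-fragment length of a k-copy allele is
#' `flank + k * unit`; a read is assigned the positive integer k that
#' minimises the absolute residual, and rejected (NA) when the residual is
#' at least half a unit length — such a read cannot be attributed to any
#' copy class.
#'
#' @param read_length Numeric vector of read lengths in bp.
#' @param locus_model A [cnv_locus_model()].
#' @return Integer vector of copy counts, NA for off-scale reads.
#' @examples
#' classify_read_copy_number(c(7700, 12300, 16900), cnv_locus_model())
#' @export
classify_read_copy_number <- function(read_length, locus_model) {
  stopifnot(inherits(locus_model, "cnv_locus_model"), all(read_length > 0))
  unit <- locus_model$unit_length_bp
  k <- pmax(1, round_half_away((read_length - locus_model$flank_length_bp) / unit))
  resid <- abs(read_length - expected_fragment_length(locus_model, k))
  k[resid >= unit / 2] <- NA_integer_
  as.integer(k)
}

# per-column majority vote over a character matrix; NA cells (padding)
# do not vote; ties resolved to the alphabetically first base
majority_consensus <- function(chars) {
  apply(chars, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
}

#' Bin spanning reads by allele and build per-allele consensus sequences
#'
#' Reads are classified by length ([classify_read_copy_number()]) and
#' grouped by copy count. Within a bin, reads are anchored at the start of
#' the captured fragment, trimmed or NA-padded to the bin's modal length,
#' and a per-column majority vote yields the consensus. Bins with fewer
#' than `min_reads` members are flagged low-confidence.
#'
#' @param reads Named character vector of read sequences (or a
#'   `spanning_read_set` from [simulate_allele_reads()], whose reads are
#'   used).
#' @param locus_model A [cnv_locus_model()].
#' @param min_reads Minimum reads for a confident bin.
#' @return List of class `allele_bins`; each element is a list with `k`,
#'   `read_ids`, `n_reads`, `consensus` and `low_confidence`. Elements are
#'   named by allele label (G1, G2, ...).
#' @export
bin_and_consensus <- function(reads, locus_model, min_reads = 3) {
  if (inherits(reads, "spanning_read_set")) reads <- reads$reads
  stopifnot(is.character(reads), length(reads) >= 1)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%03d", seq_along(reads))
  k <- classify_read_copy_number(nchar(reads), locus_model)
  if (all(is.na(k))) stop("no classifiable spanning reads")
  bins <- lapply(sort(unique(stats::na.omit(k))), function(kk) {
    members <- reads[which(k == kk)]
    lens <- nchar(members)
    modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    chars <- t(vapply(members, function(s) {
      v <- strsplit(s, "")[[1]]
      length(v) <- modal  # trims or NA-pads
      v
    }, character(modal)))
    list(k = as.integer(kk), read_ids = names(members),
         n_reads = length(members),
         consensus = paste(majority_consensus(chars), collapse = ""),
         low_confidence = length(members) < min_reads)
  })
  names(bins) <- allele_label(vapply(bins, `[[`, integer(1), "k"))
  structure(bins, class = "allele_bins")
}

#' @exportS3Method base::print
print.allele_bins <- function(x, ...) {
  for (b in x)
    cat(sprintf("%s: %d reads, consensus %d bp%s\n", allele_label(b$k),
                b$n_reads, nchar(b$consensus),
                if (b$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exact matches of every k-th k-mer of `query` in `subject`; returns
# offsets (0-based start of the implied query placement in subject)
kmer_offsets <- function(subject, query, kmer_size) {
  subj <- Biostrings::DNAString(subject)
  starts <- seq(1L, nchar(query) - kmer_size + 1L, by = kmer_size)
  offs <- integer(0)
  for (s in starts) {
    km <- substr(query, s, s + kmer_size - 1L)
    if (grepl("[^ACGT]", km)) next  # ambiguous bases break k-mer matches
    hits <- Biostrings::start(Biostrings::matchPattern(km, subj))
    if (length(hits)) offs <- c(offs, (hits - 1L) - (s - 1L))
  }
  offs
}

#' Detect the tandem structure of a consensus sequence
#'
#' Exact k-mers sampled along the reference unit (and its reverse
#' complement) are matched in the consensus; matches sharing a common
#' offset chain into collinear dotplot segments, and each offset supported
#' by at least `min_chain` k-mers is reported as one placement of the unit
#' with its orientation. The arrangement is classified as `single` (one
#' placement), `tandem_head_to_tail` (two or more same-orientation
#' placements, each adjacent to the next within a gap tolerance),
#' `inverted` (mixed orientations) or `complex`.
#'
#' @param consensus Consensus sequence (character) longer than the unit.
#' @param unit_seq Reference sequence of one unit copy.
#' @param kmer_size K-mer length for the dotplot (sampled every
#'   `kmer_size` bases).
#' @param min_chain Minimum number of collinear k-mer matches supporting a
#'   placement.
#' @param gap_tol Maximum gap between adjacent placements, as a fraction
#'   of the unit length, for them to count as tandem.
#' @return List of class `structure_report` with `placements` (data frame
#'   `start`, `end` — 0-based half-open on the consensus — and
#'   `orientation` "+"/"-") and `classification`.
#' @export
detect_tandem_structure <- function(consensus, unit_seq, kmer_size = 15,
                                    min_chain = 5, gap_tol = 0.1) {
  if (inherits(consensus, "allele_bins")) stop("pass one consensus sequence")
  unit_len <- nchar(unit_seq)
  stopifnot(nchar(consensus) > unit_len, kmer_size >= 4,
            kmer_size <= unit_len)
  find_placements <- function(query, orientation) {
    offs <- kmer_offsets(consensus, query, kmer_size)
    if (!length(offs)) return(NULL)
    # substitution errors drop k-mers but never shift offsets, so collinear
    # chains collapse to identical offsets
    tab <- table(offs)
    good <- as.integer(names(tab)[tab >= min_chain])
    if (!length(good)) return(NULL)
    data.frame(start = good, end = good + unit_len,
               orientation = orientation, stringsAsFactors = FALSE)
  }
  pl <- rbind(find_placements(unit_seq, "+"),
              find_placements(revcomp(unit_seq), "-"))
  if (is.null(pl) || nrow(pl) == 0)
    stop("reference unit not found in the consensus")
  pl <- pl[order(pl$start), , drop = FALSE]
  rownames(pl) <- NULL

  classification <- if (nrow(pl) == 1) {
    "single"
  } else if (length(unique(pl$orientation)) > 1) {
    "inverted"
  } else {
    gaps <- pl$start[-1] - pl$end[-nrow(pl)]
    if (all(abs(gaps) <= gap_tol * unit_len)) "tandem_head_to_tail" else "complex"
  }
  structure(list(placements = pl, classification = classification,
                 unit_length = unit_len),
            class = "structure_report")
}

#' @exportS3Method base::print
print.structure_report <- function(x, ...) {
  cat("Structure:", x$classification, "with", nrow(x$placements),
      "unit placement(s)\n")
  print(x$placements)
  invisible(x)
}

# longest m with suffix(left, m) == prefix(right, m), m <= cap
longest_shared_flank <- function(left, right, cap) {
  cap <- min(cap, nchar(left), nchar(right))
  best <- 0L
  for (m in seq_len(cap)) {
    if (substr(left, nchar(left) - m + 1L, nchar(left)) ==
        substr(right, 1L, m)) best <- m
  }
  best
}

#' Microhomology at copy-copy junctions of a tandem consensus
#'
#' At each junction between adjacent unit placements, the microhomology is
#' the longest sequence that is simultaneously the suffix of the consensus
#' ending at the junction and the prefix of the reference sequence that
#' follows the corresponding breakpoint on the other side (for a
#' head-to-tail junction, the start of the unit) — the longest exact
#' shared flank across the two breakpoints.
#'
#' @param consensus Consensus sequence.
#' @param structure A `structure_report` from [detect_tandem_structure()],
#'   or a placements data frame.
#' @param unit_seq Reference sequence of one unit copy.
#' @param gap_tol Maximum junction gap (fraction of unit length) for
#'   placements to count as adjacent.
#' @return Data frame of class `junction_report`: `junction_pos` (0-based
#'   consensus coordinate of the breakpoint), `microhomology`, `length`.
#' @export
find_junction_microhomology <- function(consensus, structure, unit_seq,
                                        gap_tol = 0.1) {
  pl <- if (inherits(structure, "structure_report")) structure$placements
        else structure
  stopifnot(is.data.frame(pl), nrow(pl) >= 2)
  pl <- pl[order(pl$start), , drop = FALSE]
  unit_len <- nchar(unit_seq)
  rows <- list()
  for (i in seq_len(nrow(pl) - 1)) {
    gap <- pl$start[i + 1] - pl$end[i]
    if (abs(gap) > gap_tol * unit_len)
      stop(sprintf("placements %d and %d are not adjacent (gap %d bp)",
                   i, i + 1, gap))
    ref_next <- if (pl$orientation[i + 1] == "+") unit_seq else revcomp(unit_seq)
    j <- pl$end[i]  # 0-based breakpoint position on the consensus
    left <- substr(consensus, 1, j)
    mh <- longest_shared_flank(left, ref_next, cap = unit_len - 1L)
    rows[[i]] <- data.frame(
      junction_pos = j,
      microhomology = if (mh > 0) substr(left, j - mh + 1L, j) else "",
      length = mh, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("junction_report", "data.frame")
  out
}
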