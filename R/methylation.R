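#' Build a per-site CpG methylation profile from per-read calls
#'
#' Aggregates per-read calls into per-site methylated-call fractions. With
#' `merge_hydroxymethyl = TRUE` (the default) 5mC and 5hmC calls are
#' merged into a total methylation fraction, `(5mC + 5hmC) / calls`;
#' otherwise only 5mC counts as methylated. Sites with no calls are
#' omitted rather than imputed.
#'
#' @param per_read_calls Data frame with columns `read_id`, `cpg_pos`
#'   (1-based position of the CpG) and `call` in
#'   `c("5mC", "5hmC", "unmethylated")`, e.g. the `meth_calls` element of
#'   [simulate_allele_reads()] or [read_methylation_tsv()].
#' @param merge_hydroxymethyl Merge 5hmC with 5mC into total methylation.
#' @param cpg_positions Optional vector of the known CpG positions of the
#'   reference; a call at any other position is an error naming the
#'   position.
#' @return Data frame of class `methylation_profile` with columns `pos`
#'   (strictly increasing), `fraction` in `[0, 1]` and `depth` (number of
#'   calls).
#' @export
build_methylation_profile <- function(per_read_calls,
                                      merge_hydroxymethyl = TRUE,
                                      cpg_positions = NULL) {
  stopifnot(all(c("read_id", "cpg_pos", "call") %in% names(per_read_calls)))
  bad_call <- setdiff(unique(per_read_calls$call),
                      c("5mC", "5hmC", "unmethylated"))
  if (length(bad_call))
    stop("unrecognised methylation call(s): ", paste(bad_call, collapse = ", "))
  if (!is.null(cpg_positions)) {
    off <- setdiff(unique(per_read_calls$cpg_pos), cpg_positions)
    if (length(off))
      stop("methylation call at non-CpG position(s): ",
           paste(sort(off), collapse = ", "))
  }
  meth <- per_read_calls$call == "5mC" |
    (merge_hydroxymethyl & per_read_calls$call == "5hmC")
  depth <- tapply(meth, per_read_calls$cpg_pos, length)
  frac <- tapply(meth, per_read_calls$cpg_pos, mean)
  pos <- as.integer(names(depth))
  o <- order(pos)
  out <- data.frame(pos = pos[o], fraction = as.numeric(frac)[o],
                    depth = as.integer(depth)[o])
  class(out) <- c("methylation_profile", "data.frame")
  out
}

#' Smooth a methylation profile in sliding CpG windows
#'
#' Averages per-site fractions in sliding windows of `window_cpgs`
#' adjacent CpG sites, moving forward `step_cpgs` sites at a time. With
#' the defaults (5 CpGs, step 1) a profile of n sites yields n - 4
#' smoothed values. The reported window position is the mean position of
#' the member sites.
#'
#' @param profile A `methylation_profile`.
#' @param window_cpgs Number of adjacent CpGs per window.
#' @param step_cpgs Step between windows, in CpG sites.
#' @return A `methylation_profile` data frame with `pos` (mean member
#'   position), `fraction` (window mean) and `n_sites`.
#' @export
smooth_profile <- function(profile, window_cpgs = 5, step_cpgs = 1) {
  stopifnot(inherits(profile, "methylation_profile") || is.data.frame(profile),
            window_cpgs >= 1, step_cpgs >= 1)
  n <- nrow(profile)
  if (n < window_cpgs)
    stop(sprintf("profile has %d sites but the window needs %d", n, window_cpgs))
  starts <- seq(1L, n - window_cpgs + 1L, by = step_cpgs)
  csf <- c(0, cumsum(profile$fraction))
  csp <- c(0, cumsum(as.numeric(profile$pos)))
  out <- data.frame(
    pos = (csp[starts + window_cpgs] - csp[starts]) / window_cpgs,
    fraction = (csf[starts + window_cpgs] - csf[starts]) / window_cpgs,
    n_sites = window_cpgs)
  class(out) <- c("methylation_profile", "data.frame")
  out
}

# positions (1-based) falling in 0-based half-open intervals
pos_in_intervals <- function(pos, intervals) {
  if (is.numeric(intervals) && is.null(dim(intervals)))
    intervals <- matrix(intervals, ncol = 2, byrow = TRUE)
  if (is.data.frame(intervals))
    intervals <- as.matrix(intervals[, c("start", "end")])
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (pos - 1 >= intervals[i, 1] & pos - 1 < intervals[i, 2])
  hit
}

#' Quantify hypomethylation of a target region against its flanks
#'
#' Computes mean methylation over the CpGs inside the target intervals
#' (e.g. the enhancer within each unit copy) and inside the flank
#' intervals, and their difference `flank - target`; a positive difference
#' means the target is hypomethylated relative to its surroundings.
#'
#' @param profile A `methylation_profile` (raw or smoothed).
#' @param target_intervals,flank_intervals Intervals as numeric
#'   `c(start, end)`, a two-column matrix, or a data frame with
#'   `start`/`end` (0-based half-open); each set must contain at least one
#'   profiled CpG.
#' @return List of class `hypomethylation_contrast` with `mean_target`,
#'   `mean_flank`, `difference`, `n_target`, `n_flank`.
#' @export
hypomethylation_contrast <- function(profile, target_intervals, flank_intervals) {
  in_t <- pos_in_intervals(profile$pos, target_intervals)
  in_f <- pos_in_intervals(profile$pos, flank_intervals)
  if (!any(in_t)) stop("no profiled CpG inside the target intervals")
  if (!any(in_f)) stop("no profiled CpG inside the flank intervals")
  mt <- mean(profile$fraction[in_t])
  mf <- mean(profile$fraction[in_f])
  structure(list(mean_target = mt, mean_flank = mf, difference = mf - mt,
                 n_target = sum(in_t), n_flank = sum(in_f)),
            class = "hypomethylation_contrast")
}

#' @exportS3Method base::print
print.hypomethylation_contrast <- function(x, ...) {
  cat(sprintf("Methylation contrast: target %.3f (n=%d), flank %.3f (n=%d), difference %.3f\n",
              x$mean_target, x$n_target, x$mean_flank, x$n_flank, x$difference))
  invisible(x)
}
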