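#' @name pedigree_alleles
#' @title Pedigree-constrained deduction of per-chromosome CNV alleles
#' @description Measured diploid totals constrain, but do not by themselves
#'   determine, the two per-chromosome allele copy counts. Mendelian
#'   transmission through a pedigree often resolves the ambiguity: a
#'   4-copy horse with a wild-type (1+1) dam must be 3+1, because the dam
#'   can only transmit a single-copy allele. [deduce_alleles()] enumerates
#'   every genotype configuration consistent with the measured totals,
#'   phenotypes and parental transmissible alleles, propagating constraints
#'   through the pedigree to a fixed point; [detect_cnv_mutation_events()]
#'   explains the remaining Mendelian inconsistencies by minimal single
#'   allele copy-number changes during one meiosis.
NULL

# phenotype consistency of an ordered configuration
pheno_ok <- function(m, p, phenotype) {
  if (is.na(phenotype) || phenotype == "unknown") return(rep(TRUE, length(m)))
  phenotype_from_genotype(m, p) == phenotype
}

# initial candidate (dam_allele, sire_allele) matrix for one individual
initial_candidates <- function(total, phenotype, max_allele) {
  grid <- expand.grid(m = seq_len(max_allele), p = seq_len(max_allele))
  keep <- rep(TRUE, nrow(grid))
  if (!is.na(total)) keep <- keep & (grid$m + grid$p == total)
  keep <- keep & pheno_ok(grid$m, grid$p, phenotype)
  as.matrix(grid[keep, , drop = FALSE])
}

# alleles an individual could transmit, given its candidate set;
# unknown or unresolvable parents may transmit anything
transmissible <- function(cand, max_allele) {
  if (is.null(cand) || nrow(cand) == 0) return(seq_len(max_allele))
  sort(unique(c(cand[, "m"], cand[, "p"])))
}

# collapse ordered candidates to unique unordered configurations (hi, lo)
unordered_configs <- function(cand) {
  if (nrow(cand) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("hi", "lo"))))
  u <- unique(cbind(hi = pmax(cand[, "m"], cand[, "p"]),
                    lo = pmin(cand[, "m"], cand[, "p"])))
  u[order(u[, "hi"], u[, "lo"]), , drop = FALSE]
}

#' Deduce per-chromosome allele copy numbers through a pedigree
#'
#' For every individual, all ordered pairs `(dam_allele, sire_allele)`
#' compatible with the measured total copy number and phenotype are
#' enumerated, then filtered to a fixed point under two Mendelian
#' constraints: the dam-side (sire-side) allele must be transmissible by
#' the dam (sire), and a parent's configuration must be able to supply the
#' required gamete of every one of its children. Individuals whose
#' candidate set empties are reported as Mendelian inconsistencies — the
#' input to [detect_cnv_mutation_events()] — and are ignored when
#' filtering their relatives.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (ids or
#'   NA), `phenotype` (see [phenotype_classes()]; NA treated as unknown)
#'   and `total_copies` (NA allowed), e.g. from [simulate_pedigree()] or
#'   [read_pedigree_tsv()]. Parents must precede children.
#' @param max_allele Largest per-chromosome copy count considered. The
#'   default 3 reflects that surveys of this locus have found no germ-line
#'   allele beyond three copies; raise it to entertain larger alleles.
#' @return An object of class `allele_deduction`: a list with `summary`
#'   (data frame: `id`, `n_configurations` — unordered, `unique`,
#'   `genotype` label when unique, `consistent`) and `configurations`
#'   (named list of ordered candidate matrices with columns `m` =
#'   dam-side, `p` = sire-side).
#' @examples
#' ped <- data.frame(id = c("dam", "kid"), sire = c(NA, NA),
#'                   dam = c(NA, "dam"), phenotype = c("non_grey", "fast"),
#'                   total_copies = c(2, 4))
#' deduce_alleles(ped)$summary  # kid resolves uniquely to G3/G1
#' @export
deduce_alleles <- function(pedigree, max_allele = 3) {
  stopifnot(all(c("id", "sire", "dam", "total_copies") %in% names(pedigree)),
            max_allele >= 1)
  if (anyDuplicated(pedigree$id)) stop("duplicate individual ids")
  n <- nrow(pedigree)
  pheno <- if ("phenotype" %in% names(pedigree)) pedigree$phenotype else
    rep(NA_character_, n)
  cand <- vector("list", n)
  names(cand) <- pedigree$id
  for (i in seq_len(n))
    cand[[i]] <- initial_candidates(pedigree$total_copies[i], pheno[i], max_allele)

  dam_idx <- match(pedigree$dam, pedigree$id)
  sire_idx <- match(pedigree$sire, pedigree$id)
  kids_as_dam <- lapply(seq_len(n), function(i) which(dam_idx == i))
  kids_as_sire <- lapply(seq_len(n), function(i) which(sire_idx == i))

  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      C <- cand[[i]]
      if (nrow(C) == 0) next
      keep <- rep(TRUE, nrow(C))
      if (!is.na(dam_idx[i]))
        keep <- keep & C[, "m"] %in% transmissible(cand[[dam_idx[i]]], max_allele)
      if (!is.na(sire_idx[i]))
        keep <- keep & C[, "p"] %in% transmissible(cand[[sire_idx[i]]], max_allele)
      # a configuration must be able to supply every consistent child's
      # gamete. Unlike the parent-to-child filter above, a child filter is
      # skipped if it would empty the set: a conflict between a parent and
      # a child is attributed to the child, because a de novo mutation
      # happens in the meiosis that produced the child.
      for (k in c(kids_as_dam[[i]], kids_as_sire[[i]])) {
        ck <- cand[[k]]
        if (nrow(ck) == 0) next
        side <- if (k %in% kids_as_dam[[i]]) "m" else "p"
        need <- unique(ck[, side])
        keep2 <- keep & (C[, "m"] %in% need | C[, "p"] %in% need)
        if (any(keep2)) keep <- keep2
      }
      if (!all(keep)) {
        cand[[i]] <- C[keep, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  summ <- do.call(rbind, lapply(seq_len(n), function(i) {
    u <- unordered_configs(cand[[i]])
    data.frame(id = pedigree$id[i],
               n_configurations = nrow(u),
               unique = nrow(u) == 1,
               genotype = if (nrow(u) == 1) genotype_label(u[1, "hi"], u[1, "lo"])
                          else NA_character_,
               consistent = nrow(cand[[i]]) > 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, configurations = cand,
                 max_allele = max_allele),
            class = "allele_deduction")
}

#' @exportS3Method base::print
print.allele_deduction <- function(x, ...) {
  cat("Allele deduction over", nrow(x$summary), "individuals;",
      sum(x$summary$unique), "unique,",
      sum(!x$summary$consistent), "Mendelian-inconsistent\n")
  print(x$summary)
  invisible(x)
}

#' Detect de novo copy-number mutation events in a pedigree
#'
#' Each Mendelian inconsistency reported by [deduce_alleles()] is explained
#' by the smallest single-allele copy-number change in one parental gamete
#' that restores consistency with the child's total copy number and
#' phenotype. Candidate repairs are searched in order of increasing copy
#' change, contraction before expansion. When only one parent's gamete can
#' carry the event the parent is named; when either parent could, the
#' parent is reported as NA (not identifiable). Inconsistencies that no
#' single event can repair are flagged complex.
#'
#' @inheritParams deduce_alleles
#' @param deduction Optional precomputed [deduce_alleles()] result for the
#'   same pedigree and `max_allele`.
#' @return Data frame of class `cnv_mutation_events` with one row per
#'   inconsistent individual: `child`, `parent` (id or NA),
#'   `from_copies` (expected parental allele), `to_copies` (transmitted),
#'   `direction` (`"contraction"`/`"expansion"`), `complex` (logical).
#' @examples
#' ped <- data.frame(id = c("dam", "sire", "X"), sire = c(NA, NA, "sire"),
#'                   dam = c(NA, NA, "dam"),
#'                   phenotype = c("fast", "non_grey", "slow"),
#'                   total_copies = c(6, 2, 3))
#' detect_cnv_mutation_events(ped)  # G3 -> G2 contraction in the dam
#' @export
detect_cnv_mutation_events <- function(pedigree, max_allele = 3,
                                       deduction = NULL) {
  if (is.null(deduction)) deduction <- deduce_alleles(pedigree, max_allele)
  stopifnot(inherits(deduction, "allele_deduction"))
  bad <- deduction$summary$id[!deduction$summary$consistent]
  empty <- data.frame(child = character(0), parent = character(0),
                      from_copies = integer(0), to_copies = integer(0),
                      direction = character(0), complex = logical(0),
                      stringsAsFactors = FALSE)
  if (length(bad) == 0) {
    class(empty) <- c("cnv_mutation_events", "data.frame")
    return(empty)
  }

  rows <- list()
  for (id in bad) {
    i <- match(id, pedigree$id)
    total <- pedigree$total_copies[i]
    phenotype <- if ("phenotype" %in% names(pedigree)) pedigree$phenotype[i] else NA
    parent_trans <- function(pid) {
      if (is.na(pid) || !(pid %in% names(deduction$configurations)))
        return(seq_len(max_allele))
      transmissible(deduction$configurations[[pid]], max_allele)
    }
    parent_sets <- list(
      dam = list(id = pedigree$dam[i], alleles = parent_trans(pedigree$dam[i])),
      sire = list(id = pedigree$sire[i], alleles = parent_trans(pedigree$sire[i])))
    if (is.na(total)) {
      rows[[id]] <- data.frame(child = id, parent = NA_character_,
                               from_copies = NA_integer_, to_copies = NA_integer_,
                               direction = NA_character_, complex = TRUE,
                               stringsAsFactors = FALSE)
      next
    }

    repairs <- NULL
    for (d in seq_len(max_allele + total)) {
      found <- list()
      for (side in c("dam", "sire")) {
        mutated <- parent_sets[[side]]
        other <- parent_sets[[setdiff(c("dam", "sire"), side)]]
        for (a in mutated$alleles) {
          for (direction in c("contraction", "expansion")) {
            a2 <- if (direction == "contraction") a - d else a + d
            # a de novo event may create an allele one step beyond the
            # known series (that is how larger alleles first arise), but
            # not further
            if (a2 < 1 || a2 > max_allele + 1L) next
            for (b in other$alleles) {
              m <- if (side == "dam") a2 else b
              p <- if (side == "dam") b else a2
              if (m + p == total && pheno_ok(m, p, phenotype)) {
                found[[length(found) + 1L]] <- data.frame(
                  side = side, parent = mutated$id, from_copies = a,
                  to_copies = a2, direction = direction,
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
      if (length(found)) { repairs <- unique(do.call(rbind, found)); break }
    }

    if (is.null(repairs)) {
      rows[[id]] <- data.frame(child = id, parent = NA_character_,
                               from_copies = NA_integer_, to_copies = NA_integer_,
                               direction = NA_character_, complex = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    # tie-break: contraction before expansion
    if (any(repairs$direction == "contraction"))
      repairs <- repairs[repairs$direction == "contraction", , drop = FALSE]
    parent <- if (length(unique(repairs$side)) == 1) repairs$parent[1] else NA_character_
    rows[[id]] <- data.frame(child = id, parent = parent,
                             from_copies = repairs$from_copies[1],
                             to_copies = repairs$to_copies[1],
                             direction = repairs$direction[1], complex = FALSE,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("cnv_mutation_events", "data.frame")
  out
}
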