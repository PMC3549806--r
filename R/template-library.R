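# Template library curation: pair coverage of related dimers,
# representative selection, minimum pair identity.

#' Pair coverage of two related dimers
#'
#' Measures the overlap of the interface contact sets of two dimers A-B and
#' A'-B' under residue correspondences (e.g. from a structural alignment of
#' A with A' and of B with B'):
#' `PC = NCP_M^2 / (NCP_AB * NCP_A'B')`, where `NCP_M` is the number of
#' contact pairs of A-B whose mapped residues form a contact pair of A'-B',
#' and `NCP_AB`, `NCP_A'B'` are the two dimers' contact-pair counts.
#'
#' @param cpAB,cpApBp [ContactMap-class] objects of the two dimers.
#' @param mapA,mapB residue correspondences: two-column data.frames (residue
#'   number in X, residue number in X'), required injective.
#' @return A list of class `PairCoverageResult` with `ncpM`, `ncpAB`,
#'   `ncpApBp` and `pc`. When either contact map is empty `pc` is `NA` and a
#'   warning of class `undefinedPC` is raised.
#' @export
#' @examples
#' # worked case: 6 matching pairs, interfaces of 10 and 9 -> PC = 36/90
pairCoverage <- function(cpAB, cpApBp, mapA, mapB) {
  toMap <- function(m) {
    m <- as.data.frame(m)
    if (anyDuplicated(m[[1L]]) || anyDuplicated(m[[2L]]))
      ppStop("validationError", "correspondence map must be injective")
    stats::setNames(m[[2L]], m[[1L]])
  }
  ma <- toMap(mapA); mb <- toMap(mapB)
  pab <- contactPairs(cpAB); papbp <- contactPairs(cpApBp)
  if (nrow(pab) == 0L || nrow(papbp) == 0L) {
    ppWarn("undefinedPC", "pair coverage undefined for an empty interface")
    return(structure(list(ncpM = NA_integer_, ncpAB = nrow(pab),
                          ncpApBp = nrow(papbp), pc = NA_real_),
                     class = "PairCoverageResult"))
  }
  tgt <- paste(papbp$resno_a, papbp$resno_b)
  mappedA <- ma[as.character(pab$resno_a)]
  mappedB <- mb[as.character(pab$resno_b)]
  ncpM <- sum(!is.na(mappedA) & !is.na(mappedB) &
              paste(mappedA, mappedB) %in% tgt)
  structure(list(ncpM = ncpM, ncpAB = nrow(pab), ncpApBp = nrow(papbp),
                 pc = ncpM^2 / (nrow(pab) * nrow(papbp))),
            class = "PairCoverageResult")
}

#' @export
print.PairCoverageResult <- function(x, ...) {
  cat(sprintf("PairCoverage: NCP_M = %s, NCP_AB = %d, NCP_A'B' = %d, PC = %s\n",
              x$ncpM, x$ncpAB, x$ncpApBp,
              ifelse(is.na(x$pc), "NA", sprintf("%.4f", x$pc))))
  invisible(x)
}

#' Do two related dimers share the same interaction type?
#'
#' @param pc a `PairCoverageResult` from [pairCoverage()].
#' @param threshold PC threshold (default 0.4, inclusive).
#' @return logical(1); `NA` when PC is undefined.
#' @export
sameInteractionType <- function(pc, threshold = 0.4) {
  pc$pc >= threshold
}

#' Select the representative dimer of a cluster
#'
#' Among members whose contact-pair count strictly exceeds the cluster mean,
#' the one with the smallest resolution is chosen. When no member exceeds
#' the mean (e.g. all counts equal), the smallest-resolution member overall
#' is taken. Remaining ties break by lexicographic dimer id.
#'
#' @param members data.frame with columns `dimer_id`, `n_contact_pairs`,
#'   `resolution`.
#' @return The selected row of `members` (one-row data.frame).
#' @export
selectRepresentative <- function(members) {
  if (is.null(members) || nrow(members) == 0L)
    ppStop("emptyCluster", "cluster has no members")
  above <- members[members$n_contact_pairs > mean(members$n_contact_pairs), ,
                   drop = FALSE]
  pool <- if (nrow(above)) above else members
  pool <- pool[order(pool$resolution, pool$dimer_id), , drop = FALSE]
  out <- pool[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum sequence identity of a dimer pair
#'
#' The sequence identity between two related dimers A-B and A'-B' is the
#' minimum of the A/A' and B/B' identities: the less conserved partner
#' limits how confidently the interaction can be transferred.
#'
#' @param identityA,identityB percent identities in `[0, 100]`.
#' @return numeric(1).
#' @export
minPairIdentity <- function(identityA, identityB) {
  stopifnot(identityA >= 0, identityA <= 100, identityB >= 0, identityB <= 100)
  pmin(identityA, identityB)
}
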