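# pairPSSM core: pseudocount target frequencies, per-position log-ratio
# score tables, candidate energies and classification.

#' Data-dependent pseudocount blend
#'
#' Target frequency `Q = (alpha * f + beta * g) / (alpha + beta)`, mixing the
#' observed frequency `f` (weight `alpha`, the data-dependent weight: number
#' of distinct residue-pair symbols in the column minus one) with the prior
#' pseudocount frequency `g` (weight `beta`).
#'
#' @param f observed frequency, in `[0, 1]`.
#' @param g pseudocount frequency, positive.
#' @param alpha non-negative observed weight.
#' @param beta positive pseudocount weight.
#' @return The blended probability estimate (vectorized over `f` and `g`).
#' @export
#' @examples
#' pseudocountQ(0.5, 0.01, alpha = 3, beta = 5)   # 0.19375
pseudocountQ <- function(f, g, alpha, beta) {
  if (alpha + beta == 0) ppStop("degenerateWeights", "alpha + beta must be > 0")
  stopifnot(alpha >= 0, all(f >= 0), all(f <= 1), all(g > 0))
  (alpha * f + beta * g) / (alpha + beta)
}

#' Score table for one contact position
#'
#' For every ordered residue pair (x, y), chain-A residue first, computes
#' `score(x, y) = log(Q_xy / (P_x P_y))` with
#' `Q_xy = (alpha f_xy + beta g_xy) / (alpha + beta)`, where `f_xy` is the
#' observed frequency of the pair's symbol in the column (group-pair symbol
#' under `scheme`, raw pair when `scheme = "raw"`),
#' `g_xy = P_x P_y exp(S_xy)` is the potential-derived pseudocount frequency
#' and `alpha` is the number of distinct observed symbols minus one. With no
#' usable observations (`nEffective = 0`) alpha falls back to 0 with a
#' warning, and the score reduces to `S_xy` exactly (natural log).
#'
#' @param counts a `PairColumnCounts` from [columnPairCounts()].
#' @param pot an [EmpiricalPotential-class].
#' @param scheme the [GroupScheme-class] used for counting, or "raw"; must
#'   match the symbols in `counts`.
#' @param beta pseudocount weight (default 5).
#' @param logBase base of the logarithm (default `exp(1)`).
#' @return 20 x 20 numeric matrix of scores (rows chain-A residue).
#' @export
positionScores <- function(counts, pot, scheme = groupScheme("modified"),
                           beta = 5, logBase = exp(1)) {
  S <- potentialMatrix(pot)
  P <- backgroundComposition(pot)
  nEff <- counts$nEffective
  if (nEff == 0L) {
    ppWarn("noObservations",
           "no usable observations in column; using pure pseudocount (alpha = 0)")
    alpha <- 0
  } else {
    alpha <- counts$nDistinct - 1L
  }
  raw <- identical(scheme, "raw")
  ## symbol of each ordered residue pair
  sym <- if (raw) {
    outer(AA_CODES, AA_CODES, function(a, b) paste(a, b, sep = ":"))
  } else {
    g <- aaGroup(scheme, AA_CODES)
    outer(g, g, function(a, b) paste(a, b, sep = ":"))
  }
  f <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  if (nEff > 0L) {
    hit <- counts$counts[match(sym, names(counts$counts))]
    hit[is.na(hit)] <- 0L
    f[] <- hit / nEff
  }
  Pij <- outer(P, P)
  g0 <- Pij * exp(S)
  Q <- pseudocountQ(f, g0, alpha, beta)
  log(Q / Pij, base = logBase)
}

#' Build the pairPSSM of a dimer template
#'
#' Builds one 20 x 20 log-ratio score table per contact position of the
#' template's ContactMap (in ContactMap order) from the paired profile, and
#' computes the template self-energy: the sum over positions of the score of
#' the template's own residue pair, used to normalize candidate energies.
#'
#' @param dimer a [TemplateDimer-class].
#' @param profile a [PairedProfile-class] whose template rows are the two
#'   chains of `dimer`.
#' @param pot an [EmpiricalPotential-class].
#' @param scheme a [GroupScheme-class] or "raw" (default: modified scheme).
#' @param beta pseudocount weight (default 5).
#' @param logBase logarithm base (default natural log).
#' @return A [PairPSSM-class].
#' @export
buildPairPSSM <- function(dimer, profile, pot,
                          scheme = groupScheme("modified"), beta = 5,
                          logBase = exp(1)) {
  p <- contactPairs(dimer)
  if (nrow(p) == 0L) ppStop("buildError", "template has no contact pairs")
  if (max(p$pos_a) > length(profile@colmapA))
    ppStop("buildError",
           sprintf("contact position %d on chain A not covered by the profile",
                   max(p$pos_a)))
  if (max(p$pos_b) > length(profile@colmapB))
    ppStop("buildError",
           sprintf("contact position %d on chain B not covered by the profile",
                   max(p$pos_b)))
  scores <- lapply(seq_len(nrow(p)), function(r) {
    cnt <- columnPairCounts(profile, p$pos_a[r], p$pos_b[r], scheme)
    positionScores(cnt, pot, scheme, beta, logBase)
  })
  tp <- data.frame(pos_a = p$pos_a, pos_b = p$pos_b,
                   aa_a = p$aa_a, aa_b = p$aa_b, stringsAsFactors = FALSE)
  self <- sum(vapply(seq_along(scores), function(r)
    scores[[r]][tp$aa_a[r], tp$aa_b[r]], numeric(1)))
  schemeName <- if (identical(scheme, "raw")) "raw" else scheme@name
  new("PairPSSM", templateId = dimer@id, templatePairs = tp, scores = scores,
      beta = beta, scheme = schemeName, logBase = logBase, selfEnergy = self)
}

#' Construct a candidate alignment pair
#'
#' A candidate protein pair (A', B') with its alignments to the two template
#' chains. Each alignment maps ungapped template positions to the candidate
#' residue aligned there; template positions absent from the mapping are
#' unaligned.
#'
#' @param idA,idB candidate protein identifiers.
#' @param alnA,alnB data.frames with columns `tpos` (template position,
#'   1-based), `spos` (candidate position) and `aa` (candidate residue).
#' @param identityA,identityB percent identities of the two alignments.
#' @param evalueA,evalueB E-values of the two hits.
#' @return A list of class `CandidatePair`.
#' @export
candidatePair <- function(idA, idB, alnA, alnB,
                          identityA = NA_real_, identityB = NA_real_,
                          evalueA = NA_real_, evalueB = NA_real_) {
  for (aln in list(alnA, alnB)) {
    stopifnot(all(c("tpos", "aa") %in% names(aln)))
    if (anyDuplicated(aln$tpos))
      ppStop("validationError", "alignment maps a template position twice")
  }
  structure(list(idA = idA, idB = idB, alnA = alnA, alnB = alnB,
                 identityA = identityA, identityB = identityB,
                 evalueA = evalueA, evalueB = evalueB,
                 selfPair = identical(idA, idB)),
            class = "CandidatePair")
}

#' Interfacial energies of a candidate pair
#'
#' Sums, over the contact positions where both sides of the candidate are
#' aligned, the pairPSSM score of the aligned residue pair (specific
#' interfacial energy) and, when a potential is supplied, the empirical
#' matrix entry (general interfacial energy). Unaligned contact positions
#' contribute zero, so a candidate missing the interacting region scores
#' low after normalization. The normalized specific energy is the specific
#' energy divided by the template self-energy.
#'
#' @param pssm a [PairPSSM-class].
#' @param cand a `CandidatePair` from [candidatePair()].
#' @param pot optional [EmpiricalPotential-class] for the general energy.
#' @return A list of class `EnergyResult`: `specific`, `normalized`,
#'   `general` (NA without `pot`), `covered` (contact positions with both
#'   sides aligned), `idA`, `idB`.
#' @export
specificEnergy <- function(pssm, cand, pot = NULL) {
  if (selfEnergy(pssm) <= 0)
    ppStop("normalizationUndefined",
           sprintf("template self-energy %.4f is not positive; template unusable",
                   selfEnergy(pssm)))
  tp <- pssm@templatePairs
  xa <- cand$alnA$aa[match(tp$pos_a, cand$alnA$tpos)]
  xb <- cand$alnB$aa[match(tp$pos_b, cand$alnB$tpos)]
  ok <- !is.na(xa) & !is.na(xb) & isStandardAA(xa) & isStandardAA(xb)
  spec <- 0; gen <- if (is.null(pot)) NA_real_ else 0
  for (r in which(ok)) {
    spec <- spec + pssm@scores[[r]][xa[r], xb[r]]
    if (!is.null(pot)) gen <- gen + potentialMatrix(pot)[xa[r], xb[r]]
  }
  structure(list(specific = spec, normalized = spec / selfEnergy(pssm),
                 general = gen, covered = sum(ok),
                 idA = cand$idA, idB = cand$idB),
            class = "EnergyResult")
}

#' @export
print.EnergyResult <- function(x, ...) {
  cat(sprintf("EnergyResult %s-%s: specific %.4f (normalized %.4f), general %s, %d position(s) covered\n",
              x$idA, x$idB, x$specific, x$normalized,
              ifelse(is.na(x$general), "NA", sprintf("%.4f", x$general)),
              x$covered))
  invisible(x)
}

#' Classify a candidate as a homologous interaction
#'
#' @param result an `EnergyResult` from [specificEnergy()].
#' @param threshold normalized-energy threshold (default 0.4; 0.5 is the
#'   stricter setting for multi-organism screening). Inclusive: a candidate
#'   exactly at the threshold is accepted.
#' @return logical(1).
#' @export
classifyInteraction <- function(result, threshold = 0.4) {
  result$normalized >= threshold
}

#' Serialize / restore a PairPSSM
#'
#' JSON serialization preserving all scores at full precision. Contact
#' position indices are stored 0-based in the file.
#'
#' @param pssm a [PairPSSM-class].
#' @param file output (input) path.
#' @return `writePairPSSM`: `file` invisibly. `readPairPSSM`: the restored
#'   [PairPSSM-class], bit-identical to the written one.
#' @export
writePairPSSM <- function(pssm, file) {
  obj <- list(template_id = pssm@templateId,
              beta = pssm@beta, scheme = pssm@scheme, log_base = pssm@logBase,
              self_energy = pssm@selfEnergy,
              positions = lapply(seq_along(pssm@scores), function(r) {
                list(index = r - 1L,
                     pos_a = pssm@templatePairs$pos_a[r] - 1L,
                     pos_b = pssm@templatePairs$pos_b[r] - 1L,
                     aa_a = pssm@templatePairs$aa_a[r],
                     aa_b = pssm@templatePairs$aa_b[r],
                     scores = pssm@scores[[r]])
              }))
  ## I(17) significant digits guarantees doubles survive the round trip
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' @rdname writePairPSSM
#' @export
readPairPSSM <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  np <- nrow(obj$positions)
  scores <- lapply(seq_len(np), function(r) {
    m <- obj$positions$scores[[r]]
    dimnames(m) <- list(AA_CODES, AA_CODES)
    m
  })
  tp <- data.frame(pos_a = obj$positions$pos_a + 1L,
                   pos_b = obj$positions$pos_b + 1L,
                   aa_a = obj$positions$aa_a, aa_b = obj$positions$aa_b,
                   stringsAsFactors = FALSE)
  new("PairPSSM", templateId = obj$template_id, templatePairs = tp,
      scores = scores, beta = obj$beta, scheme = obj$scheme,
      logBase = obj$log_base, selfEnergy = obj$self_energy)
}

#' Flat TSV export of a PairPSSM
#'
#' One row per (position, chain-A residue, chain-B residue) score.
#'
#' @param pssm a [PairPSSM-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportPairPSSMTsv <- function(pssm, file) {
  rows <- do.call(rbind, lapply(seq_along(pssm@scores), function(r) {
    data.frame(position = r,
               aa_a = rep(AA_CODES, times = 20),
               aa_b = rep(AA_CODES, each = 20),
               score = as.vector(pssm@scores[[r]]))
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
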