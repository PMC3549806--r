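# Screening and evaluation: candidate generation from homology hits,
# ranking, average precision / false-positive statistics, error sweeps,
# expression-profile tests.

#' Construct a homology hit
#'
#' One subject found by a homology search with one of the two template
#' chains as query.
#'
#' @param chain "A" or "B": the template chain the query was.
#' @param subjectId subject protein identifier.
#' @param evalue hit E-value.
#' @param identity percent identity.
#' @param aln data.frame with columns `tpos` (template position, 1-based),
#'   `spos` (subject position) and `aa` (subject residue).
#' @return list of class `HomologyHit`.
#' @export
homologyHit <- function(chain, subjectId, evalue, identity, aln) {
  stopifnot(chain %in% c("A", "B"), evalue >= 0,
            identity >= 0, identity <= 100)
  structure(list(chain = chain, subjectId = subjectId, evalue = evalue,
                 identity = identity, aln = aln),
            class = "HomologyHit")
}

#' Read homology hits from a tabular file
#'
#' Native format: TSV with columns `chain`, `subject_id`, `evalue`,
#' `identity`, `aln` where `aln` is a `;`-separated list of
#' `tpos:spos:aa` triplets (template positions 1-based). BLAST 12-column
#' tabular (outfmt 6) is also accepted when `format = "blast6"`, with an
#' optional 13th column carrying the same `aln` string; rows without it
#' get an empty alignment (usable for candidate enumeration only).
#'
#' @param file path.
#' @param chain template chain to assign when the file has no `chain`
#'   column ("A" or "B").
#' @param format "native" (default) or "blast6".
#' @return list of `HomologyHit`.
#' @export
readHomologyHits <- function(file, chain = NULL,
                             format = c("native", "blast6")) {
  format <- match.arg(format)
  parseAln <- function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(tpos = integer(), spos = integer(),
                        aa = character()))
    tri <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    data.frame(tpos = as.integer(vapply(tri, `[[`, "", 1L)),
               spos = as.integer(vapply(tri, `[[`, "", 2L)),
               aa = vapply(tri, `[[`, "", 3L), stringsAsFactors = FALSE)
  }
  if (format == "native") {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    ch <- if ("chain" %in% names(tab)) tab$chain else rep(chain, nrow(tab))
    lapply(seq_len(nrow(tab)), function(i)
      homologyHit(ch[i], tab$subject_id[i], tab$evalue[i], tab$identity[i],
                  parseAln(tab$aln[i])))
  } else {
    tab <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(tab)), function(i)
      homologyHit(chain, tab[[2L]][i], as.numeric(tab[[11L]][i]),
                  as.numeric(tab[[3L]][i]),
                  parseAln(if (ncol(tab) >= 13L) tab[[13L]][i] else NA)))
  }
}

#' Enumerate candidate pairs from per-chain hits
#'
#' Every homologous protein of chain A crossed with every homologous protein
#' of chain B (after the E-value filter) is a candidate homologous
#' interaction. Candidates pairing a protein with itself are allowed and
#' flagged (`selfPair`).
#'
#' @param hitsA,hitsB lists of `HomologyHit` for the two chains.
#' @param evalueMax E-value cutoff (default 1e-3, inclusive).
#' @return list of `CandidatePair`.
#' @export
buildCandidates <- function(hitsA, hitsB, evalueMax = 1e-3) {
  hitsA <- Filter(function(h) h$evalue <= evalueMax, hitsA)
  hitsB <- Filter(function(h) h$evalue <= evalueMax, hitsB)
  out <- list()
  for (ha in hitsA) for (hb in hitsB) {
    out[[length(out) + 1L]] <- candidatePair(
      ha$subjectId, hb$subjectId, ha$aln, hb$aln,
      identityA = ha$identity, identityB = hb$identity,
      evalueA = ha$evalue, evalueB = hb$evalue)
  }
  out
}

#' Remove candidates above a sequence-identity limit
#'
#' A candidate is removed when either of its proteins aligns to its template
#' chain with identity strictly greater than `limit`; used to probe how
#' performance degrades for remote homologs.
#'
#' @param cands list of `CandidatePair`.
#' @param limit percent identity limit.
#' @return Filtered list.
#' @export
applyIdentityLimit <- function(cands, limit) {
  Filter(function(cd) !(cd$identityA > limit || cd$identityB > limit), cands)
}

#' Score a list of candidates against a pairPSSM
#'
#' @param pssm a [PairPSSM-class].
#' @param cands list of `CandidatePair`.
#' @param pot optional [EmpiricalPotential-class] for general energies.
#' @return data.frame: `id_a`, `id_b`, `specific`, `normalized`, `general`,
#'   `covered`, `self_pair`.
#' @export
scoreCandidates <- function(pssm, cands, pot = NULL) {
  rows <- lapply(cands, function(cd) {
    e <- specificEnergy(pssm, cd, pot)
    data.frame(id_a = cd$idA, id_b = cd$idB, specific = e$specific,
               normalized = e$normalized, general = e$general,
               covered = e$covered, self_pair = cd$selfPair,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank scored candidates against gold-standard labels
#'
#' Joins scores with labels and sorts by decreasing score. Ties are broken
#' pessimistically by default (negatives rank before positives at equal
#' score, so the reported average precision is a lower bound). Candidates
#' without a label are handled per `unannotated`: counted as negatives, or
#' dropped before ranking.
#'
#' @param scored data.frame from [scoreCandidates()] (or any data.frame with
#'   `id_a`, `id_b` and the score column).
#' @param labels data.frame with columns `id_a`, `id_b`, `label`
#'   ("positive"/"negative"); unordered pair matching.
#' @param scoreCol column of `scored` to rank by (default "normalized").
#' @param unannotated "negative" (default) or "drop".
#' @param tieRule "pessimistic" (default) or "optimistic".
#' @param decreasing rank high scores first (default TRUE; set FALSE for
#'   potentials whose favourable direction is negative).
#' @return A [RankedHitList-class].
#' @export
rankCandidates <- function(scored, labels, scoreCol = "normalized",
                           unannotated = c("negative", "drop"),
                           tieRule = c("pessimistic", "optimistic"),
                           decreasing = TRUE) {
  unannotated <- match.arg(unannotated)
  tieRule <- match.arg(tieRule)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lab <- labels$label[match(key(scored$id_a, scored$id_b),
                            key(labels$id_a, labels$id_b))]
  lab[is.na(lab)] <- "unannotated"
  entries <- data.frame(id_a = scored$id_a, id_b = scored$id_b,
                        score = scored[[scoreCol]], label = lab,
                        stringsAsFactors = FALSE)
  if (unannotated == "drop") {
    entries <- entries[entries$label != "unannotated", , drop = FALSE]
  } else {
    entries$label[entries$label == "unannotated"] <- "negative"
  }
  if (!decreasing) entries$score <- -entries$score
  posLast <- entries$label == "positive"   # pessimistic: positives after ties
  ord <- if (tieRule == "pessimistic") order(-entries$score, posLast)
         else order(-entries$score, !posLast)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  new("RankedHitList", entries = entries, K = nrow(entries),
      A = sum(entries$label == "positive"), tieRule = tieRule)
}

#' Average precision and false-positive rate of one ranked list
#'
#' With positives at ranks `T_1 < ... < T_A` in a list of `K` candidates:
#' `AP = (1/A) * sum_i i / T_i` and
#' `FP = (1/A) * sum_i (T_i - i) / (K - A)`.
#'
#' @param ranked a [RankedHitList-class] with at least one positive and one
#'   negative.
#' @return c(AP = ..., FP = ...).
#' @export
#' @examples
#' # K = 4, A = 2, positives at ranks 1 and 3: AP = 5/6, FP = 1/4
averagePrecision <- function(ranked) {
  e <- ranked@entries
  A <- ranked@A; K <- ranked@K
  if (A < 1L) ppStop("noPositives", "hit list has no positives")
  if (K == A) ppStop("fpUndefined", "hit list has no negatives (K = A)")
  Ti <- which(e$label == "positive")
  i <- seq_len(A)
  c(AP = mean(i / Ti), FP = sum((Ti - i) / (K - A)) / A)
}

#' Mean metrics over templates
#'
#' @param perTemplate list of `c(AP, FP)` vectors, or a two-column
#'   matrix/data.frame with one row per template.
#' @return c(MAP = ..., MFP = ..., M = number of templates).
#' @export
meanMetrics <- function(perTemplate) {
  if (is.list(perTemplate) && !is.data.frame(perTemplate))
    perTemplate <- do.call(rbind, perTemplate)
  if (is.null(perTemplate) || NROW(perTemplate) == 0L)
    ppStop("noEvaluableTemplates", "no templates to average over")
  perTemplate <- as.matrix(perTemplate)
  c(MAP = mean(perTemplate[, 1L]), MFP = mean(perTemplate[, 2L]),
    M = nrow(perTemplate))
}

#' Balanced error-rate sweep over score thresholds
#'
#' At each threshold t a candidate is predicted positive when its score is
#' `>= t`. The balanced error rate averages the false-negative fraction of
#' the positive set and the false-positive fraction of the negative set:
#' `error(t) = (FN(t)/|pos| + FP(t)/|neg|) / 2`. Setting
#' `literal = TRUE` swaps the denominators
#' (`(FP(t)/|pos| + FN(t)/|neg|) / 2`), a variant kept for comparison.
#'
#' @param posScores,negScores numeric score vectors of the two classes.
#' @param thresholds thresholds to sweep (default: midpoints of the sorted
#'   unique scores, plus the extremes).
#' @param literal use the transposed-denominator variant (default FALSE).
#' @return list of class `ErrorSweep`: `thresholds`, `errorRates`,
#'   `bestThreshold` (smallest threshold attaining the minimum),
#'   `minError`.
#' @export
errorSweep <- function(posScores, negScores, thresholds = NULL,
                       literal = FALSE) {
  if (length(posScores) == 0L || length(negScores) == 0L)
    ppStop("emptyClass", "both score sets must be nonempty")
  if (is.null(thresholds)) {
    s <- sort(unique(c(posScores, negScores)))
    thresholds <- c(s[1L] - 1e-9, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
                    s[length(s)] + 1e-9)
  }
  err <- vapply(thresholds, function(t) {
    fn <- sum(posScores < t); fp <- sum(negScores >= t)
    if (literal) (fp / length(posScores) + fn / length(negScores)) / 2
    else (fn / length(posScores) + fp / length(negScores)) / 2
  }, numeric(1))
  best <- min(thresholds[err == min(err)])
  structure(list(thresholds = thresholds, errorRates = err,
                 bestThreshold = best, minError = min(err)),
            class = "ErrorSweep")
}

#' @export
print.ErrorSweep <- function(x, ...) {
  cat(sprintf("ErrorSweep over %d threshold(s): min error %.4f at %.4g\n",
              length(x$thresholds), x$minError, x$bestThreshold))
  invisible(x)
}

#' Expression-profile test of predicted interactions
#'
#' Computes the Pearson correlation of the expression profiles of each
#' predicted pair and of each null (non-interacting) pair, then tests with a
#' one-sided Welch two-sample t-test whether the mean correlation of the
#' predictions exceeds that of the null set. Pairs composed of the same gene
#' twice are excluded (their correlation is 1 by construction); pairs with
#' fewer than 3 pairwise-complete observations or a constant profile are
#' dropped and counted.
#'
#' @param pairs,nullPairs data.frames with columns `id_a`, `id_b`.
#' @param profiles numeric matrix, genes x conditions, rownames = gene ids;
#'   `NA` for missing values.
#' @return list of class `ExpressionTestResult`: `correlations`,
#'   `nullCorrelations`, `tScore`, `pValue`, `dropped` (named counts).
#' @export
expressionTest <- function(pairs, nullPairs, profiles) {
  corSet <- function(df) {
    dropSelf <- sum(df$id_a == df$id_b)
    df <- df[df$id_a != df$id_b, , drop = FALSE]
    dropped <- 0L
    rs <- numeric(0)
    for (i in seq_len(nrow(df))) {
      x <- profiles[df$id_a[i], ]; y <- profiles[df$id_b[i], ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        dropped <- dropped + 1L
        next
      }
      rs <- c(rs, stats::cor(x[ok], y[ok]))
    }
    list(r = rs, dropped = dropped, self = dropSelf)
  }
  a <- corSet(pairs); b <- corSet(nullPairs)
  tt <- stats::t.test(a$r, b$r, alternative = "greater", var.equal = FALSE)
  structure(list(correlations = a$r, nullCorrelations = b$r,
                 tScore = unname(tt$statistic), pValue = tt$p.value,
                 dropped = c(pred_incomplete = a$dropped,
                             pred_self = a$self,
                             null_incomplete = b$dropped,
                             null_self = b$self)),
            class = "ExpressionTestResult")
}

#' @export
print.ExpressionTestResult <- function(x, ...) {
  cat(sprintf("ExpressionTest: mean r %.4f (n = %d) vs null %.4f (n = %d); T = %.3f, one-sided p = %.3g\n",
              mean(x$correlations), length(x$correlations),
              mean(x$nullCorrelations), length(x$nullCorrelations),
              x$tScore, x$pValue))
  invisible(x)
}
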