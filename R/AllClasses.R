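#' @import methods
NULL

## ---------------------------------------------------------------------------
## ContactMap
## ---------------------------------------------------------------------------

#' ContactMap: inter-chain contact residue pairs of a dimer
#'
#' Holds all residue pairs (one residue per chain) of a two-chain structure
#' whose minimum heavy-atom distance does not exceed the cutoff. The `pairs`
#' slot is a data.frame with one row per contact residue pair and columns
#' `chain_a, resno_a, icode_a, aa_a, pos_a, chain_b, resno_b, icode_b, aa_b,
#' pos_b, min_dist`, where `pos_*` is the 1-based position of the residue in
#' its chain's extracted sequence and `resno_*` the author residue number.
#'
#' @slot pairs data.frame of contact residue pairs (see Details).
#' @slot cutoff numeric(1), heavy-atom distance cutoff in Angstrom.
#' @export
setClass("ContactMap",
         representation(pairs = "data.frame", cutoff = "numeric"))

setValidity("ContactMap", function(object) {
  need <- c("chain_a", "resno_a", "icode_a", "aa_a", "pos_a",
            "chain_b", "resno_b", "icode_b", "aa_b", "pos_b", "min_dist")
  if (!all(need %in% names(object@pairs)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    return("cutoff must be a single positive number")
  key <- paste(object@pairs$chain_a, object@pairs$resno_a, object@pairs$icode_a,
               object@pairs$chain_b, object@pairs$resno_b, object@pairs$icode_b)
  if (anyDuplicated(key)) return("duplicate contact pairs")
  if (nrow(object@pairs) && any(object@pairs$min_dist > object@cutoff + 1e-9))
    return("min_dist exceeds cutoff")
  TRUE
})

## ---------------------------------------------------------------------------
## TemplateDimer
## ---------------------------------------------------------------------------

#' TemplateDimer: a two-chain structural template
#'
#' A dimer template: the two chain sequences (with author numbering), its
#' inter-chain ContactMap, the crystallographic resolution when known, and
#' optional domain annotations.
#'
#' @slot id character(1) template identifier.
#' @slot chainA,chainB character(1) chain identifiers.
#' @slot residuesA,residuesB data.frame per-chain residue tables with columns
#'   `resno`, `icode`, `aa` in sequence order.
#' @slot resolution numeric(1), Angstrom; `NA` when unknown.
#' @slot contactMap a [ContactMap-class].
#' @slot domains data.frame of domain annotations (`chain`, `domain`,
#'   `start`, `end`) or a 0-row data.frame when absent.
#' @export
setClass("TemplateDimer",
         representation(id = "character", chainA = "character",
                        chainB = "character",
                        residuesA = "data.frame", residuesB = "data.frame",
                        resolution = "numeric", contactMap = "ContactMap",
                        domains = "data.frame"))

setValidity("TemplateDimer", function(object) {
  p <- object@contactMap@pairs
  if (nrow(p)) {
    if (any(p$pos_a < 1L) || any(p$pos_a > nrow(object@residuesA)))
      return("contact pair references a residue outside chain A")
    if (any(p$pos_b < 1L) || any(p$pos_b > nrow(object@residuesB)))
      return("contact pair references a residue outside chain B")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## EmpiricalPotential
## ---------------------------------------------------------------------------

#' EmpiricalPotential: 20 x 20 interfacial pair potential with background
#' composition
#'
#' The general empirical matrix `S` gives the interaction energy `S[i, j]` of
#' residue types i and j across a protein-protein interface; `P` is the
#' background composition of interface residues. By convention stored
#' symmetric. `favorability` records the sign convention of favourable
#' contacts ("negative" in the usual statistical-potential convention).
#'
#' @slot S numeric 20 x 20 matrix, dimnames the standard amino acids.
#' @slot P named numeric(20), strictly positive, summing to 1.
#' @slot source character(1) free-text provenance note.
#' @slot favorability character(1), "negative" or "positive".
#' @export
setClass("EmpiricalPotential",
         representation(S = "matrix", P = "numeric", source = "character",
                        favorability = "character"))

setValidity("EmpiricalPotential", function(object) {
  if (!identical(dim(object@S), c(20L, 20L))) return("S must be 20 x 20")
  if (!identical(rownames(object@S), AA_CODES) ||
      !identical(colnames(object@S), AA_CODES))
    return("S dimnames must be the 20 standard amino acids in standard order")
  if (max(abs(object@S - t(object@S))) > 1e-9) return("S must be symmetric")
  if (!identical(names(object@P), AA_CODES))
    return("P names must be the 20 standard amino acids in standard order")
  if (any(object@P <= 0)) return("all composition entries must be positive")
  if (abs(sum(object@P) - 1) > 1e-6) return("composition must sum to 1")
  if (!object@favorability %in% c("negative", "positive"))
    return("favorability must be 'negative' or 'positive'")
  TRUE
})

## ---------------------------------------------------------------------------
## GroupScheme
## ---------------------------------------------------------------------------

#' GroupScheme: reduced amino-acid alphabet in nine groups
#'
#' A complete, disjoint partition of the 20 standard amino acids into nine
#' groups of physicochemically similar residues, used to pool conservative
#' substitutions when counting residue-pair symbols.
#'
#' @slot name character(1) scheme name.
#' @slot groups named list of character vectors partitioning the alphabet.
#' @slot aaToGroup named integer(20): group index of each amino acid.
#' @seealso [groupScheme()]
#' @export
setClass("GroupScheme",
         representation(name = "character", groups = "list",
                        aaToGroup = "integer"))

setValidity("GroupScheme", function(object) {
  all20 <- sort(unlist(object@groups, use.names = FALSE))
  if (!identical(all20, sort(AA_CODES)))
    return("groups must partition the 20 standard amino acids")
  if (length(object@groups) != 9L) return("exactly nine groups required")
  if (!identical(sort(names(object@aaToGroup)), sort(AA_CODES)))
    return("aaToGroup must cover the 20 standard amino acids")
  TRUE
})

## ---------------------------------------------------------------------------
## Msa / PairedProfile
## ---------------------------------------------------------------------------

#' Msa: a multiple sequence alignment with a designated template row
#'
#' @slot ids character row identifiers.
#' @slot keys character pairing keys (e.g. source organism), `NA` when absent.
#' @slot seqs character aligned sequences, all the same width.
#' @slot templateRow integer(1) index of the template (query) row.
#' @export
setClass("Msa",
         representation(ids = "character", keys = "character",
                        seqs = "character", templateRow = "integer"))

setValidity("Msa", function(object) {
  n <- length(object@seqs)
  if (length(object@ids) != n || length(object@keys) != n)
    return("ids, keys and seqs must have equal length")
  if (n == 0L) return("alignment has no rows")
  if (length(unique(nchar(object@seqs))) != 1L)
    return("all aligned sequences must have equal width")
  if (object@templateRow < 1L || object@templateRow > n)
    return("templateRow out of range")
  TRUE
})

#' PairedProfile: two column-mapped alignments with paired rows
#'
#' Rows of the two per-chain alignments are paired by a shared key so that a
#' row pair represents one observed homologous sequence pair. `colmapA` and
#' `colmapB` map ungapped template positions (1-based) to alignment columns.
#'
#' @slot msaA,msaB [Msa-class] objects.
#' @slot rowPairs integer matrix, two columns (row in A, row in B); the first
#'   row pairs the two template rows.
#' @slot colmapA,colmapB integer vectors, template position -> column.
#' @export
setClass("PairedProfile",
         representation(msaA = "Msa", msaB = "Msa", rowPairs = "matrix",
                        colmapA = "integer", colmapB = "integer"))

setValidity("PairedProfile", function(object) {
  rp <- object@rowPairs
  if (ncol(rp) != 2L) return("rowPairs must have two columns")
  if (nrow(rp) == 0L) return("rowPairs must contain at least the template pair")
  if (rp[1L, 1L] != object@msaA@templateRow ||
      rp[1L, 2L] != object@msaB@templateRow)
    return("first row pair must pair the two template rows")
  TRUE
})

## ---------------------------------------------------------------------------
## PairPSSM
## ---------------------------------------------------------------------------

#' PairPSSM: contact position-specific scoring matrix of a dimer template
#'
#' One log-ratio score table per interface contact position of a template
#' dimer. At position r the table gives, for every ordered residue pair
#' (x, y) with the chain-A residue first, the score
#' `log(Q_xy / (P_x * P_y))`, where Q blends the observed paired-profile
#' frequency with the empirical-potential pseudocount frequency
#' `g_xy = P_x * P_y * exp(S_xy)`.
#'
#' @slot templateId character(1).
#' @slot templatePairs data.frame with columns `pos_a`, `pos_b`, `aa_a`,
#'   `aa_b`: the template's own residue pair at each contact position, in
#'   ContactMap order.
#' @slot scores list of 20 x 20 numeric matrices, one per contact position
#'   (rows: chain-A residue; columns: chain-B residue).
#' @slot beta numeric(1) pseudocount weight.
#' @slot scheme character(1) name of the residue grouping used for observed
#'   frequencies ("modified", "saha" or "raw").
#' @slot logBase numeric(1) logarithm base of the scores.
#' @slot selfEnergy numeric(1) specific interfacial energy of the template
#'   scored against itself; the normalization constant.
#' @export
setClass("PairPSSM",
         representation(templateId = "character", templatePairs = "data.frame",
                        scores = "list", beta = "numeric", scheme = "character",
                        logBase = "numeric", selfEnergy = "numeric"))

setValidity("PairPSSM", function(object) {
  if (nrow(object@templatePairs) != length(object@scores))
    return("one score table per contact position required")
  ok <- vapply(object@scores, function(m)
    identical(dim(m), c(20L, 20L)) && all(is.finite(m)), logical(1))
  if (!all(ok)) return("every score table must be finite and 20 x 20")
  self <- sum(vapply(seq_along(object@scores), function(r)
    object@scores[[r]][object@templatePairs$aa_a[r],
                       object@templatePairs$aa_b[r]], numeric(1)))
  if (length(object@scores) && abs(self - object@selfEnergy) > 1e-8)
    return("selfEnergy inconsistent with score tables")
  TRUE
})

## ---------------------------------------------------------------------------
## RankedHitList
## ---------------------------------------------------------------------------

#' RankedHitList: scored, labelled candidate pairs sorted for evaluation
#'
#' @slot entries data.frame with columns `id_a`, `id_b`, `score`, `label`
#'   (one of "positive", "negative", "unannotated"), sorted by decreasing
#'   score under the tie rule recorded in `tieRule`.
#' @slot K integer(1) total candidates; `A` integer(1) positives.
#' @slot A integer(1) number of positives.
#' @slot tieRule character(1), "pessimistic" (ties rank negatives first) or
#'   "optimistic".
#' @export
setClass("RankedHitList",
         representation(entries = "data.frame", K = "integer", A = "integer",
                        tieRule = "character"))

setValidity("RankedHitList", function(object) {
  e <- object@entries
  if (!all(c("id_a", "id_b", "score", "label") %in% names(e)))
    return("entries must have id_a, id_b, score, label")
  if (!all(e$label %in% c("positive", "negative", "unannotated")))
    return("labels must be positive/negative/unannotated")
  if (object@K != nrow(e)) return("K must equal the number of entries")
  if (object@A != sum(e$label == "positive")) return("A inconsistent")
  if (is.unsorted(rev(e$score))) return("entries must be sorted by score desc")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap with %d contact residue pairs (cutoff %.2f A)\n",
              nrow(object@pairs), object@cutoff))
  if (nrow(object@pairs)) {
    cat(sprintf("  chain %s: %d contact residues; chain %s: %d contact residues\n",
                object@pairs$chain_a[1], length(unique(object@pairs$pos_a)),
                object@pairs$chain_b[1], length(unique(object@pairs$pos_b))))
  }
})

setMethod("show", "TemplateDimer", function(object) {
  cat(sprintf("TemplateDimer '%s': chains %s (%d aa) / %s (%d aa)\n",
              object@id, object@chainA, nrow(object@residuesA),
              object@chainB, nrow(object@residuesB)))
  cat(sprintf("  resolution: %s A; R = %d contact pairs\n",
              ifelse(is.na(object@resolution), "NA",
                     format(object@resolution)),
              nrow(object@contactMap@pairs)))
})

setMethod("show", "EmpiricalPotential", function(object) {
  cat(sprintf("EmpiricalPotential (favourable contacts %s): S in [%.3g, %.3g]\n",
              object@favorability, min(object@S), max(object@S)))
  cat("  source:", object@source, "\n")
})

setMethod("show", "GroupScheme", function(object) {
  cat(sprintf("GroupScheme '%s' with %d groups:\n", object@name,
              length(object@groups)))
  for (g in seq_along(object@groups))
    cat(sprintf("  (%s) %s\n", as.roman(g),
                paste(object@groups[[g]], collapse = ", ")))
})

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d rows x %d columns (template row %d: '%s')\n",
              length(object@seqs), nchar(object@seqs[1]),
              object@templateRow, object@ids[object@templateRow]))
})

setMethod("show", "PairedProfile", function(object) {
  cat(sprintf("PairedProfile: %d row pairs (incl. template pair)\n",
              nrow(object@rowPairs)))
})

setMethod("show", "PairPSSM", function(object) {
  cat(sprintf("PairPSSM '%s': R = %d contact positions, beta = %g, scheme = %s\n",
              object@templateId, length(object@scores), object@beta,
              object@scheme))
  cat(sprintf("  template self-energy: %.4f\n", object@selfEnergy))
})

setMethod("show", "RankedHitList", function(object) {
  cat(sprintf("RankedHitList: K = %d candidates, A = %d positives (%s ties)\n",
              object@K, object@A, object@tieRule))
})
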