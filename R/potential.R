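# Empirical interfacial pair potential, background composition, and
# reduced amino-acid alphabets.

#' Built-in nine-group amino-acid classifications
#'
#' Two reduced alphabets partitioning the 20 standard amino acids into nine
#' groups of residues with similar side-chain character. `"saha"` is the
#' structure-environment classification of Saha et al.; `"modified"` adjusts
#' three of its groups (splitting Ala/Val, merging His/Arg, isolating Lys and
#' moving Pro in with Ser/Thr) so that contact-potential values vary little
#' within each group. Counting residue-pair symbols at group level tolerates
#' conservative substitutions.
#'
#' @param name "modified" (default) or "saha"; or supply `groups` directly.
#' @param groups optional named list of character vectors giving a custom
#'   nine-group partition (overrides `name`).
#' @return A [GroupScheme-class].
#' @export
#' @examples
#' groupScheme("modified")
groupScheme <- function(name = c("modified", "saha"), groups = NULL) {
  if (is.null(groups)) {
    name <- match.arg(name)
    groups <- switch(name,
      saha = list(g1 = c("A", "V"), g2 = c("M", "L", "I"),
                  g3 = c("G", "S", "T"), g4 = c("P", "F", "Y", "W"),
                  g5 = "C", g6 = "H", g7 = c("R", "K"), g8 = c("D", "E"),
                  g9 = c("N", "Q")),
      modified = list(g1 = c("A", "G"), g2 = c("V", "M", "L", "I"),
                      g3 = c("P", "S", "T"), g4 = c("F", "Y", "W"),
                      g5 = "C", g6 = c("H", "R"), g7 = "K",
                      g8 = c("D", "E"), g9 = c("N", "Q")))
  } else {
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    name <- if (is.character(name) && length(name) == 1L) name else "custom"
  }
  a2g <- integer(20); names(a2g) <- AA_CODES
  for (g in seq_along(groups)) a2g[groups[[g]]] <- g
  new("GroupScheme", name = name, groups = groups, aaToGroup = a2g)
}

#' Load an empirical interfacial pair potential
#'
#' Reads a 20 x 20 pair-potential matrix and a 20-entry interface background
#' composition from TSV files. The matrix must carry one-letter amino-acid
#' codes as header row and first column; it is symmetrized by averaging when
#' the input is asymmetric (recorded in the `source` slot). The composition
#' file has two columns (code, fraction); fractions must be positive and sum
#' to 1 within 1e-6.
#'
#' A synthetic potential with realistic group-level structure is bundled
#' under `system.file("extdata", package = "pairPSSM")` for examples and
#' tests; for production work supply a published interfacial statistical
#' potential and the matching interface composition.
#'
#' @param matrixFile path to the 20 x 20 potential TSV.
#' @param compositionFile path to the composition TSV.
#' @param favorability sign convention of favourable contacts in the matrix;
#'   "negative" (default, the usual statistical-potential convention) or
#'   "positive".
#' @return An [EmpiricalPotential-class].
#' @export
#' @examples
#' pot <- loadPotential(
#'   system.file("extdata", "potential_synthetic.tsv", package = "pairPSSM"),
#'   system.file("extdata", "composition_synthetic.tsv", package = "pairPSSM"))
loadPotential <- function(matrixFile, compositionFile,
                          favorability = c("negative", "positive")) {
  favorability <- match.arg(favorability)
  m <- utils::read.delim(matrixFile, row.names = 1L, check.names = FALSE)
  m <- as.matrix(m)
  if (!all(AA_CODES %in% rownames(m)) || !all(AA_CODES %in% colnames(m)))
    ppStop("formatError",
           "potential matrix must have all 20 amino-acid rows and columns")
  m <- m[AA_CODES, AA_CODES]
  if (!is.numeric(m) || anyNA(m))
    ppStop("formatError", "potential matrix must be numeric and complete")
  src <- basename(matrixFile)
  if (max(abs(m - t(m))) > 1e-9) {
    m <- (m + t(m)) / 2
    src <- paste0(src, " (symmetrized by averaging)")
  }
  comp <- utils::read.delim(compositionFile, header = TRUE,
                            stringsAsFactors = FALSE)
  if (ncol(comp) < 2L)
    ppStop("formatError", "composition file needs columns: code, fraction")
  p <- comp[[2L]]; names(p) <- comp[[1L]]
  if (!all(AA_CODES %in% names(p)))
    ppStop("formatError", "composition must cover all 20 amino acids")
  p <- p[AA_CODES]
  if (any(p <= 0))
    ppStop("validationError", "composition fractions must be positive")
  if (abs(sum(p) - 1) > 1e-6)
    ppStop("validationError",
           sprintf("composition must sum to 1 (got %.8f)", sum(p)))
  new("EmpiricalPotential", S = m, P = p,
      source = paste0(src, " + ", basename(compositionFile)),
      favorability = favorability)
}

#' Within-group spread of contact potentials
#'
#' For each pair of groups (g, h) of the scheme, the population standard
#' deviation of the potential values `S[i, j]` over all unordered residue
#' combinations with i in g and j in h. A low cell value means all residue
#' pairs pooled into that group-pair symbol carry nearly the same contact
#' energy, i.e. the grouping is compatible with the potential.
#'
#' @param pot an [EmpiricalPotential-class].
#' @param scheme a [GroupScheme-class].
#' @return Symmetric 9 x 9 numeric matrix of standard deviations.
#' @export
groupSdTable <- function(pot, scheme) {
  S <- potentialMatrix(pot)
  gs <- scheme@groups
  n <- length(gs)
  out <- matrix(NA_real_, n, n, dimnames = list(names(gs), names(gs)))
  for (g in seq_len(n)) for (h in g:n) {
    if (g == h) {
      aa <- gs[[g]]
      vals <- S[aa, aa, drop = FALSE][upper.tri(S[aa, aa, drop = FALSE],
                                                diag = TRUE)]
    } else {
      vals <- as.vector(S[gs[[g]], gs[[h]], drop = FALSE])
    }
    out[g, h] <- out[h, g] <- popSd(vals)
  }
  out
}

#' Compare the spread of two group schemes
#'
#' Computes [groupSdTable()] under both built-in schemes and tallies cells in
#' the bands < 0.3, 0.3-0.5 and > 0.5 (the shading convention used when the
#' schemes are displayed as heat maps).
#'
#' @param pot an [EmpiricalPotential-class].
#' @return list with elements `saha`, `modified` (9 x 9 SD tables) and
#'   `bands` (data.frame of cell counts per band and scheme, counting the 45
#'   unique cells of each symmetric table).
#' @export
compareSchemes <- function(pot) {
  tabs <- list(saha = groupSdTable(pot, groupScheme("saha")),
               modified = groupSdTable(pot, groupScheme("modified")))
  bandCount <- function(tab) {
    v <- tab[upper.tri(tab, diag = TRUE)]
    c(`<0.3` = sum(v < 0.3), `0.3-0.5` = sum(v >= 0.3 & v <= 0.5),
      `>0.5` = sum(v > 0.5))
  }
  bands <- as.data.frame(rbind(saha = bandCount(tabs$saha),
                               modified = bandCount(tabs$modified)),
                         check.names = FALSE)
  c(tabs, list(bands = bands))
}
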