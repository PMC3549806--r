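# Interface geometry: structure parsing, contact extraction, template QC,
# domain mapping.

#' Read a dimer structure file
#'
#' Parses a PDB or mmCIF file (format chosen by extension, or forced with
#' `format`). Only the first model of multi-model files is used. The
#' crystallographic resolution is parsed from the `REMARK 2` record (PDB) or
#' the `_refine.ls_d_res_high` / `_reflns.d_resolution_high` item (mmCIF)
#' when present.
#'
#' @param file path to a `.pdb` or `.cif` file.
#' @param format "auto" (default), "pdb" or "cif".
#' @return A `bio3d` structure object with a `resolution` attribute
#'   (`NA` when the file carries none).
#' @export
readStructure <- function(file, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", file, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(file))
  } else {
    suppressWarnings(bio3d::read.pdb(file, rm.alt = FALSE, multi = FALSE))
  }
  txt <- readLines(file, warn = FALSE)
  res <- NA_real_
  if (format == "pdb") {
    ln <- grep("^REMARK   2 RESOLUTION\\.", txt, value = TRUE)
    if (length(ln)) {
      m <- regmatches(ln[1], regexpr("[0-9]+\\.[0-9]+", ln[1]))
      if (length(m)) res <- as.numeric(m)
    }
  } else {
    ln <- grep("^_(refine\\.ls_d_res_high|reflns\\.d_resolution_high)", txt,
               value = TRUE)
    if (length(ln)) {
      m <- regmatches(ln[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", ln[1]))
      if (length(m)) res <- suppressWarnings(as.numeric(trimws(m)))
    }
  }
  attr(pdb, "resolution") <- res
  pdb
}

## Extract, for one chain, the table of standard (or mapped-modified) residues
## and their heavy atoms. Altloc: keep the highest-occupancy conformer per
## atom, ties resolved by alphabetic altloc code.
chainResidueAtoms <- function(pdb, chain) {
  at <- pdb$atom
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) ppStop("chainNotFound", sprintf("chain '%s' not found", chain))
  ## drop waters and hydrogens/deuteriums
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("^[0-9]*", "", trimws(at$elety)), 1L, 1L)
  at <- at[!(toupper(elesy) %in% c("H", "D")), , drop = FALSE]
  ## map residue names to one-letter codes; unknown -> skipped with a warning
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  unknown <- unique(at$resid[aa1 == "X"])
  ## non-polymer hetero groups (ligands, ions) fall out here too
  if (length(unknown))
    ppWarn("nonStandardResidue",
           sprintf("chain %s: skipping residues without a standard mapping: %s",
                   chain, paste(unknown, collapse = ", ")))
  keep <- aa1 != "X"
  at <- at[keep, , drop = FALSE]
  aa1 <- aa1[keep]
  if (nrow(at) == 0L)
    ppStop("emptyChain", sprintf("chain '%s' has no standard residues", chain))
  ## altloc resolution: highest occupancy per (resno, icode, atom name)
  ic <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  akey <- paste(at$resno, ic, at$elety, sep = "\r")
  ord <- order(akey, -occ, alt)
  keep <- sort(ord[!duplicated(akey[ord])])   # dedup winners, file order
  at <- at[keep, , drop = FALSE]; aa1 <- aa1[keep]; ic <- ic[keep]
  ## residue table in order of appearance in the file
  rkey <- paste(at$resno, ic, sep = "\r")
  ridx <- match(rkey, unique(rkey))
  resTab <- data.frame(resno = at$resno[!duplicated(rkey)],
                       icode = ic[!duplicated(rkey)],
                       aa = aa1[!duplicated(rkey)],
                       stringsAsFactors = FALSE)
  list(residues = resTab,
       xyz = cbind(at$x, at$y, at$z),
       atomRes = ridx)
}

#' Extract inter-chain contact residue pairs
#'
#' A contact residue pair is a residue from each chain having at least one
#' pair of heavy (non-hydrogen) atoms within `cutoff` Angstrom of each other
#' (inclusive). Waters and non-polymer hetero groups are excluded; modified
#' residues are mapped to their parent amino acid when a standard mapping
#' exists and skipped (with a warning) otherwise; for alternate locations the
#' highest-occupancy conformer is used.
#'
#' @param structure a parsed structure from [readStructure()] (or any bio3d
#'   `pdb` object).
#' @param chainA,chainB chain identifiers.
#' @param cutoff contact distance cutoff in Angstrom (default 4.5).
#' @return A [ContactMap-class]; pairs ordered by (chain A residue number,
#'   chain B residue number).
#' @export
#' @examples
#' fx <- makeToyDimer(fixtureSpec(seed = 1, nContacts = 5,
#'                                nResiduesPerChain = 12),
#'                    file = tempfile(fileext = ".pdb"))
#' cm <- extractContacts(readStructure(fx$file), "A", "B")
#' nContacts(cm)
extractContacts <- function(structure, chainA, chainB, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  ca <- chainResidueAtoms(structure, chainA)
  cb <- chainResidueAtoms(structure, chainB)
  nA <- nrow(ca$residues); nB <- nrow(cb$residues)
  ## cross heavy-atom distance matrix
  d2 <- outer(rowSums(ca$xyz^2), rowSums(cb$xyz^2), "+") -
    2 * (ca$xyz %*% t(cb$xyz))
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  ## min over atoms within each residue pair
  byResA <- rowsumMin(dmat, ca$atomRes, nA)              # nA x nAtomB
  dmin <- t(rowsumMin(t(byResA), cb$atomRes, nB))        # nA x nB
  hit <- which(dmin <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(chain_a = rep(chainA, nrow(hit)),
                      resno_a = ca$residues$resno[hit[, 1]],
                      icode_a = ca$residues$icode[hit[, 1]],
                      aa_a = ca$residues$aa[hit[, 1]],
                      pos_a = hit[, 1],
                      chain_b = rep(chainB, nrow(hit)),
                      resno_b = cb$residues$resno[hit[, 2]],
                      icode_b = cb$residues$icode[hit[, 2]],
                      aa_b = cb$residues$aa[hit[, 2]],
                      pos_b = hit[, 2],
                      min_dist = dmin[hit],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$resno_a, pairs$icode_a, pairs$resno_b,
                       pairs$icode_b), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactMap", pairs = pairs, cutoff = cutoff)
}

## column-group minima: min of rows of `m` grouped by `g` (1..n)
rowsumMin <- function(m, g, n) {
  out <- matrix(Inf, n, ncol(m))
  for (i in seq_len(nrow(m))) {
    gi <- g[i]
    out[gi, ] <- pmin(out[gi, ], m[i, ])
  }
  out
}

#' Construct a TemplateDimer from a structure file or parsed structure
#'
#' @param structure path to a structure file or a parsed structure from
#'   [readStructure()].
#' @param chainA,chainB chain identifiers.
#' @param cutoff contact cutoff in Angstrom.
#' @param id template identifier (defaults to the file basename).
#' @param domains optional domain annotation data.frame with columns
#'   `chain`, `domain`, `start`, `end` (author numbering; a domain may span
#'   several ranges and several chains).
#' @param resolution override the resolution parsed from the file.
#' @return A [TemplateDimer-class].
#' @export
templateDimer <- function(structure, chainA, chainB, cutoff = 4.5,
                          id = NULL, domains = NULL, resolution = NULL) {
  if (is.character(structure)) {
    if (is.null(id)) id <- sub("\\.(pdb|cif)$", "", basename(structure))
    structure <- readStructure(structure)
  }
  if (is.null(id)) id <- "dimer"
  if (is.null(resolution))
    resolution <- attr(structure, "resolution") %||% NA_real_
  cm <- extractContacts(structure, chainA, chainB, cutoff)
  ra <- chainResidueAtoms(structure, chainA)$residues
  rb <- chainResidueAtoms(structure, chainB)$residues
  if (is.null(domains))
    domains <- data.frame(chain = character(), domain = character(),
                          start = integer(), end = integer())
  new("TemplateDimer", id = id, chainA = chainA, chainB = chainB,
      residuesA = ra, residuesB = rb,
      resolution = as.numeric(resolution), contactMap = cm,
      domains = domains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Template quality control
#'
#' Applies the template selection criteria: resolution strictly below
#' `maxResolution`, each chain longer than 35 residues, more than 25 contact
#' residue pairs, and more than 5 distinct contact residues on each chain.
#' All comparisons are strict, following the criteria's wording ("smaller
#' than", "more than", "greater than").
#'
#' @param dimer a [TemplateDimer-class].
#' @param minChainLen minimum chain length (pass when length >= this;
#'   default 36, i.e. more than 35 residues).
#' @param minPairs minimum contact residue pairs (default 26, i.e. more
#'   than 25).
#' @param minContactResPerChain minimum distinct contact residues per chain
#'   (default 6, i.e. more than 5).
#' @param maxResolution resolution bound in Angstrom, strict (default 3.0).
#' @param missingResolutionPasses logical: whether an `NA` resolution passes
#'   the resolution check (default `FALSE`).
#' @return A list of class `QCReport` with elements `passed` (logical) and
#'   `checks` (data.frame: criterion, observed, threshold, pass).
#' @export
qcTemplate <- function(dimer, minChainLen = 36L, minPairs = 26L,
                       minContactResPerChain = 6L, maxResolution = 3.0,
                       missingResolutionPasses = FALSE) {
  p <- contactPairs(dimer)
  resOK <- if (is.na(dimer@resolution)) missingResolutionPasses
           else dimer@resolution < maxResolution
  checks <- data.frame(
    criterion = c("resolution", "chain_a_length", "chain_b_length",
                  "min_pairs", "contact_res_chain_a", "contact_res_chain_b"),
    observed = c(dimer@resolution, nrow(dimer@residuesA),
                 nrow(dimer@residuesB), nrow(p),
                 length(unique(p$pos_a)), length(unique(p$pos_b))),
    threshold = c(maxResolution, minChainLen, minChainLen, minPairs,
                  minContactResPerChain, minContactResPerChain),
    pass = c(resOK,
             nrow(dimer@residuesA) >= minChainLen,
             nrow(dimer@residuesB) >= minChainLen,
             nrow(p) >= minPairs,
             length(unique(p$pos_a)) >= minContactResPerChain,
             length(unique(p$pos_b)) >= minContactResPerChain),
    stringsAsFactors = FALSE)
  structure(list(passed = all(checks$pass), checks = checks),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %s\n", if (x$passed) "PASSED" else "FAILED"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' Interacting domain pairs of a contact map
#'
#' Maps the contacts onto domain annotations and reports the domain pairs
#' that interact: a domain pair is interacting when each domain contains more
#' than `minResidues` of its chain's contact residues (strict). A domain may
#' span both chains (cross-chain domain); its residue ranges then contribute
#' on whichever side of a contact they cover.
#'
#' @param contactMap a [ContactMap-class] (or [TemplateDimer-class]).
#' @param domains data.frame with columns `chain`, `domain`, `start`, `end`
#'   in the structure's author numbering; a domain may have several rows.
#' @param minResidues strict minimum contact residues per domain (default 3:
#'   report when the count is greater than 3).
#' @return data.frame with columns `domain_a`, `domain_b`,
#'   `n_contact_residues_a`, `n_contact_residues_b`.
#' @export
interactingDomains <- function(contactMap, domains, minResidues = 3L) {
  if (is(contactMap, "TemplateDimer")) contactMap <- contactMap@contactMap
  p <- contactPairs(contactMap)
  stopifnot(all(c("chain", "domain", "start", "end") %in% names(domains)))
  ## overlapping ranges of *different* domains within one chain are a conflict
  for (ch in unique(domains$chain)) {
    d <- domains[domains$chain == ch, , drop = FALSE]
    if (nrow(d) > 1L) {
      for (i in seq_len(nrow(d) - 1L)) for (j in (i + 1L):nrow(d)) {
        if (d$start[i] <= d$end[j] && d$start[j] <= d$end[i])
          ppStop("annotationConflict",
                 sprintf("overlapping domain ranges on chain %s (%s, %s)",
                         ch, d$domain[i], d$domain[j]))
      }
    }
  }
  domOf <- function(chain, resno) {
    hit <- domains$chain == chain & domains$start <= resno & domains$end >= resno
    if (any(hit)) domains$domain[which(hit)[1L]] else NA_character_
  }
  if (nrow(p) == 0L)
    return(data.frame(domain_a = character(), domain_b = character(),
                      n_contact_residues_a = integer(),
                      n_contact_residues_b = integer()))
  dA <- mapply(domOf, p$chain_a, p$resno_a)
  dB <- mapply(domOf, p$chain_b, p$resno_b)
  keep <- !is.na(dA) & !is.na(dB)
  if (!any(keep))
    return(data.frame(domain_a = character(), domain_b = character(),
                      n_contact_residues_a = integer(),
                      n_contact_residues_b = integer()))
  tab <- unique(data.frame(dA = dA[keep], dB = dB[keep]))
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
    sel <- keep & dA == tab$dA[k] & dB == tab$dB[k]
    data.frame(domain_a = tab$dA[k], domain_b = tab$dB[k],
               n_contact_residues_a = length(unique(p$pos_a[sel])),
               n_contact_residues_b = length(unique(p$pos_b[sel])),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_contact_residues_a > minResidues &
             out$n_contact_residues_b > minResidues, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ContactMap to TSV or JSON
#'
#' The TSV carries one row per contact pair; the JSON form additionally
#' records the cutoff and serializes positions 0-based.
#'
#' @param x a [ContactMap-class].
#' @param file output path.
#' @param format "tsv" or "json".
#' @return `file`, invisibly.
#' @export
writeContactMap <- function(x, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  p <- contactPairs(x)
  if (format == "tsv") {
    utils::write.table(
      p[, c("chain_a", "resno_a", "icode_a", "aa_a",
            "chain_b", "resno_b", "icode_b", "aa_b", "min_dist")],
      file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    p0 <- p
    p0$pos_a <- p0$pos_a - 1L   # 0-based in serialized artifacts
    p0$pos_b <- p0$pos_b - 1L
    jsonlite::write_json(list(cutoff = x@cutoff, pairs = p0), file,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(file)
}
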