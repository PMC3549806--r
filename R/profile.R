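# Profile builder: per-chain multiple sequence alignments, row pairing
# across the two alignments, and per-contact-position residue-pair counts.

#' Construct an Msa
#'
#' @param ids character row identifiers.
#' @param seqs character aligned sequences (equal width; gaps `-` or `.`).
#' @param keys character pairing keys (e.g. source organism); `NA` allowed.
#' @param templateRow index of the template (query) row, default 1.
#' @return An [Msa-class].
#' @export
msa <- function(ids, seqs, keys = rep(NA_character_, length(ids)),
                templateRow = 1L) {
  new("Msa", ids = as.character(ids), keys = as.character(keys),
      seqs = toupper(as.character(seqs)), templateRow = as.integer(templateRow))
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA (via Biostrings) or Stockholm. Pairing keys are taken
#' from a `key=<tag>` field in each description line, or from a two-column
#' TSV (`row_id`, `key`) given as `keysFile`.
#'
#' @param file alignment path.
#' @param format "fasta" (default) or "stockholm".
#' @param templateRow index or row identifier of the template row (default:
#'   first row).
#' @param keysFile optional TSV path mapping row ids to pairing keys.
#' @return An [Msa-class].
#' @export
readMsa <- function(file, format = c("fasta", "stockholm"), templateRow = 1L,
                    keysFile = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(file)
    heads <- names(ss)
    seqs <- as.character(ss)
  } else {
    lns <- readLines(file, warn = FALSE)
    lns <- lns[!grepl("^(#|//)", lns) & nzchar(trimws(lns))]
    parts <- strsplit(trimws(lns), "\\s+")
    nm <- vapply(parts, `[[`, "", 1L)
    sq <- vapply(parts, function(p) paste(p[-1L], collapse = ""), "")
    ## interleaved blocks: concatenate per name, preserving first appearance
    heads <- unique(nm)
    seqs <- vapply(heads, function(h) paste(sq[nm == h], collapse = ""), "")
  }
  ids <- sub("\\s.*$", "", heads)
  keys <- rep(NA_character_, length(ids))
  hasKey <- grepl("key=", heads)
  keys[hasKey] <- sub("^.*key=([^ ]+).*$", "\\1", heads[hasKey])
  if (!is.null(keysFile)) {
    kt <- utils::read.delim(keysFile, header = FALSE,
                            stringsAsFactors = FALSE)
    keys <- kt[[2L]][match(ids, kt[[1L]])]
  }
  if (is.character(templateRow)) {
    templateRow <- match(templateRow, ids)
    if (is.na(templateRow)) ppStop("formatError", "template row id not found")
  }
  msa(ids, seqs, keys, templateRow)
}

msaGapCount <- function(m, row) {
  sum(seqToChars(m@seqs[row]) %in% GAP_CHARS)
}

#' Purge rows nearly identical to the template
#'
#' Removes every non-template row whose identity to the template row exceeds
#' `threshold`. Identity is the number of matching residues over columns
#' where both rows are non-gap, divided by the shorter of the two ungapped
#' lengths. The template row itself is always retained.
#'
#' @param x an [Msa-class].
#' @param threshold identity fraction above which a row is purged
#'   (default 0.95, strict: a row exactly at the threshold is kept).
#' @return The purged [Msa-class].
#' @export
purgeSimilar <- function(x, threshold = 0.95) {
  tch <- seqToChars(x@seqs[x@templateRow])
  tgap <- tch %in% GAP_CHARS
  tlen <- sum(!tgap)
  keep <- vapply(seq_along(x@seqs), function(i) {
    if (i == x@templateRow) return(TRUE)
    rch <- seqToChars(x@seqs[i])
    rgap <- rch %in% GAP_CHARS
    both <- !tgap & !rgap
    denom <- min(tlen, sum(!rgap))
    if (denom == 0L) return(TRUE)
    ident <- sum(tch[both] == rch[both]) / denom
    ident <= threshold
  }, logical(1))
  newTemplate <- sum(keep[seq_len(x@templateRow)])
  msa(x@ids[keep], x@seqs[keep], x@keys[keep], newTemplate)
}

#' Map ungapped template positions to alignment columns
#'
#' @param x an [Msa-class].
#' @return Integer vector: element t is the alignment column holding the
#'   t-th (1-based) non-gap residue of the template row.
#' @export
#' @examples
#' m <- msa("t", "AC-GT")
#' mapColumns(m)   # columns 1, 2, 4, 5
mapColumns <- function(x) {
  tch <- seqToChars(x@seqs[x@templateRow])
  cols <- which(!(tch %in% GAP_CHARS))
  if (length(cols) == 0L)
    ppStop("emptyTemplate", "template row contains only gaps")
  cols
}

#' Pair rows of two alignments by key
#'
#' Rows of the two per-chain alignments that share a pairing key are paired;
#' a key present in only one alignment is dropped (count reported via
#' message). When a key occurs on several rows of one alignment the row with
#' the fewest gaps is kept (warning). The two template rows are always paired
#' with each other, first.
#'
#' @param msaA,msaB [Msa-class] objects for the two template chains.
#' @return A [PairedProfile-class]. When no non-template pair can be formed a
#'   warning of class `insufficientPairs` is raised; the profile is still
#'   usable (scores then come from the pseudocount prior alone).
#' @export
pairRows <- function(msaA, msaB) {
  dedup <- function(m) {
    idx <- setdiff(seq_along(m@seqs), m@templateRow)
    idx <- idx[!is.na(m@keys[idx])]
    if (length(idx) == 0L) return(integer())
    gaps <- vapply(idx, function(i) msaGapCount(m, i), integer(1))
    ord <- idx[order(m@keys[idx], gaps, idx)]
    dup <- duplicated(m@keys[ord])
    if (any(dup))
      ppWarn("duplicateKey",
             sprintf("%d duplicate pairing key row(s) dropped (kept fewest gaps)",
                     sum(dup)))
    ord[!dup]
  }
  ia <- dedup(msaA); ib <- dedup(msaB)
  common <- intersect(msaA@keys[ia], msaB@keys[ib])
  dropped <- (length(ia) - length(common)) + (length(ib) - length(common))
  if (dropped > 0L)
    message(sprintf("pairRows: %d row(s) with unmatched keys dropped", dropped))
  rp <- rbind(c(msaA@templateRow, msaB@templateRow),
              cbind(ia[match(common, msaA@keys[ia])],
                    ib[match(common, msaB@keys[ib])]))
  if (nrow(rp) == 1L)
    ppWarn("insufficientPairs",
           "no non-template row pairs; profile carries pseudocounts only")
  new("PairedProfile", msaA = msaA, msaB = msaB,
      rowPairs = matrix(as.integer(rp), ncol = 2L),
      colmapA = as.integer(mapColumns(msaA)),
      colmapB = as.integer(mapColumns(msaB)))
}

#' Residue-pair counts at one contact position
#'
#' Reads, for every paired row, the residues at the two alignment columns
#' mapped from the given template positions and tallies them as a single
#' symbol: the ordered group pair under `scheme`, or the raw ordered residue
#' pair when `scheme = "raw"`. A row is skipped when either residue is a gap
#' or non-standard (no half counts).
#'
#' @param profile a [PairedProfile-class].
#' @param posA,posB ungapped template positions (1-based) on chains A and B.
#' @param scheme a [GroupScheme-class], or the string "raw".
#' @return A list of class `PairColumnCounts`: `counts` (named integer;
#'   names like `"2:8"` for group pairs or `"L:D"` for raw pairs),
#'   `nEffective` (rows tallied), `nDistinct` (distinct symbols), `posA`,
#'   `posB`.
#' @export
columnPairCounts <- function(profile, posA, posB,
                             scheme = groupScheme("modified")) {
  if (posA < 1L || posA > length(profile@colmapA) ||
      posB < 1L || posB > length(profile@colmapB))
    ppStop("indexError", "contact position outside template length")
  colA <- profile@colmapA[posA]
  colB <- profile@colmapB[posB]
  raw <- identical(scheme, "raw")
  symbols <- character()
  for (k in seq_len(nrow(profile@rowPairs))) {
    ra <- substr(profile@msaA@seqs[profile@rowPairs[k, 1L]], colA, colA)
    rb <- substr(profile@msaB@seqs[profile@rowPairs[k, 2L]], colB, colB)
    if (!isStandardAA(ra) || !isStandardAA(rb)) next
    symbols <- c(symbols,
                 if (raw) paste(ra, rb, sep = ":")
                 else paste(aaGroup(scheme, ra), aaGroup(scheme, rb), sep = ":"))
  }
  counts <- if (length(symbols)) table(symbols) else table(character())
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, nEffective = length(symbols),
                 nDistinct = length(counts), posA = posA, posB = posB),
            class = "PairColumnCounts")
}

#' @export
print.PairColumnCounts <- function(x, ...) {
  cat(sprintf("PairColumnCounts at (%d, %d): n = %d, %d distinct symbol(s)\n",
              x$posA, x$posB, x$nEffective, x$nDistinct))
  print(x$counts)
  invisible(x)
}
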