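# Shared helpers for building small in-code fixtures.

AA20 <- aminoAcids()

## a ContactMap built directly from position/residue vectors (1-based,
## author numbering = position)
mkContactMap <- function(posA, posB, aaA = NULL, aaB = NULL, dist = 4.0,
                         cutoff = 4.5) {
  n <- length(posA)
  if (is.null(aaA)) aaA <- rep("A", n)
  if (is.null(aaB)) aaB <- rep("G", n)
  new("ContactMap",
      pairs = data.frame(chain_a = rep("A", n), resno_a = posA,
                         icode_a = rep("", n), aa_a = aaA, pos_a = posA,
                         chain_b = rep("B", n), resno_b = posB,
                         icode_b = rep("", n), aa_b = aaB, pos_b = posB,
                         min_dist = rep(dist, n), stringsAsFactors = FALSE),
      cutoff = cutoff)
}

## uniform background + constant-S potential, written to temp TSVs and loaded
mkUniformPotential <- function(S = 0) {
  mf <- tempfile(fileext = ".tsv"); cf <- tempfile(fileext = ".tsv")
  m <- matrix(S, 20, 20, dimnames = list(AA20, AA20))
  write.table(data.frame(aa = AA20, m, check.names = FALSE), mf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(aa = AA20, fraction = rep(0.05, 20)), cf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  loadPotential(mf, cf)
}

bundledPotential <- function() {
  loadPotential(
    system.file("extdata", "potential_synthetic.tsv", package = "pairPSSM"),
    system.file("extdata", "composition_synthetic.tsv", package = "pairPSSM"))
}

## one PDB line in fixed columns
pdbLine <- function(ser, name, resn, chain, resno, x, y, z, occ = 1,
                    alt = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ser, name, alt, resn, chain, resno, x, y, z, occ, 0,
          substr(name, 1, 1))
}

writePdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

## independent exhaustive O(n^2) heavy-atom contact scan (oracle); parses the
## file with bio3d directly and compares every inter-chain atom pair.
bruteContacts <- function(file, chainA, chainB, cutoff = 4.5) {
  p <- suppressWarnings(bio3d::read.pdb(file, rm.alt = FALSE, multi = FALSE))
  at <- p$atom
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), ]
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[aa1 != "X", ]
  elesy <- at$elesy
  at <- at[!(toupper(elesy) %in% c("H", "D")), ]
  ## highest-occupancy altloc per atom
  ic <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, ic, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  pick <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[order(-occ[idx], alt[idx])][1]
  }))
  at <- at[sort(pick), ]
  a <- at[at$chain == chainA, ]; b <- at[at$chain == chainB, ]
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    k <- paste(a$resno[i], b$resno[j])
    if (d <= cutoff) hits[[k]] <- min(hits[[k]] %||% Inf, d)
  }
  if (length(hits) == 0L)
    return(data.frame(resno_a = integer(), resno_b = integer(),
                      min_dist = numeric()))
  parts <- do.call(rbind, strsplit(names(hits), " "))
  out <- data.frame(resno_a = as.integer(parts[, 1]),
                    resno_b = as.integer(parts[, 2]),
                    min_dist = unname(unlist(hits)))
  out[order(out$resno_a, out$resno_b), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## an Msa built from plain strings
mkMsa <- function(seqs, keys = NULL, templateRow = 1L) {
  ids <- c("template", sprintf("r%02d", seq_len(length(seqs) - 1L)))
  if (is.null(keys)) keys <- c("template", sprintf("org%02d",
                                                   seq_len(length(seqs) - 1L)))
  msa(ids, seqs, keys, templateRow)
}
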