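# Deterministic synthetic fixture generators: toy dimer structures with
# known contacts, paired MSAs under an explicit conservation model, and
# labelled screening benchmarks. Everything the toolkit consumes can be
# generated here, seeded and byte-reproducible.

#' Fixture generator settings
#'
#' One validated bundle of generator parameters. Identical specs (same seed)
#' give byte-identical outputs. Defaults describe a template that passes
#' quality control (40-residue chains, 30 contacts) and a conservation model
#' in which substitutions at contact columns are mostly conservative
#' (within-group rate 0.3, across-group rate 0.05), while non-contact
#' columns drift freely (uniform substitution rate 0.3).
#'
#' @param seed integer RNG seed.
#' @param nResiduesPerChain residues per chain (default 40).
#' @param nContacts inter-chain contact pairs to engineer (default 30).
#' @param nProfileRows paired profile rows to simulate (default 50).
#' @param withinGroupSubRate per-row probability of a conservative
#'   (within-group) substitution at a contact column (default 0.3).
#' @param acrossGroupSubRate per-row probability of a non-conservative
#'   substitution at a contact column (default 0.05).
#' @param nonContactSubRate per-row uniform substitution probability at
#'   non-contact columns (default 0.3).
#' @param nPositiveCandidates,nNegativeCandidates benchmark class sizes
#'   (default 20 each).
#' @param interfaceAblationFraction fraction of contact positions ablated
#'   (unaligned or mutated across groups) in each negative candidate
#'   (default 0.7).
#' @return list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(seed = 1L, nResiduesPerChain = 40L, nContacts = 30L,
                        nProfileRows = 50L, withinGroupSubRate = 0.3,
                        acrossGroupSubRate = 0.05, nonContactSubRate = 0.3,
                        nPositiveCandidates = 20L, nNegativeCandidates = 20L,
                        interfaceAblationFraction = 0.7) {
  rates <- c(withinGroupSubRate, acrossGroupSubRate, nonContactSubRate,
             interfaceAblationFraction)
  stopifnot(all(rates >= 0), all(rates <= 1),
            withinGroupSubRate + acrossGroupSubRate <= 1,
            nResiduesPerChain > 0, nContacts > 0, nProfileRows > 0,
            nPositiveCandidates > 0, nNegativeCandidates > 0)
  structure(list(seed = as.integer(seed),
                 nResiduesPerChain = as.integer(nResiduesPerChain),
                 nContacts = as.integer(nContacts),
                 nProfileRows = as.integer(nProfileRows),
                 withinGroupSubRate = withinGroupSubRate,
                 acrossGroupSubRate = acrossGroupSubRate,
                 nonContactSubRate = nonContactSubRate,
                 nPositiveCandidates = as.integer(nPositiveCandidates),
                 nNegativeCandidates = as.integer(nNegativeCandidates),
                 interfaceAblationFraction = interfaceAblationFraction),
            class = "FixtureSpec")
}

## substitution helpers under the modified grouping
subWithinGroup <- function(aa, scheme) {
  members <- scheme@groups[[aaGroup(scheme, aa)]]
  others <- setdiff(members, aa)
  if (length(others) == 0L) aa else sample(others, 1L)
}

subAcrossGroup <- function(aa, scheme) {
  members <- scheme@groups[[aaGroup(scheme, aa)]]
  sample(setdiff(AA_CODES, members), 1L)
}

#' Generate a toy dimer structure with known contacts
#'
#' Emits a syntactically valid PDB (or mmCIF) file with two chains in a
#' minimal backbone + CB representation on a lattice. The designated contact
#' residue pairs sit at inter-atomic distances around 3.4-3.7 Angstrom
#' (always below 4.4) and every other inter-chain atom pair is farther than
#' 5.5 Angstrom, so contact extraction at the default 4.5 cutoff recovers
#' exactly the designed pairs with a wide margin.
#'
#' @param spec a [fixtureSpec()].
#' @param file output path (default: a tempfile).
#' @param format "pdb" (default) or "cif".
#' @return list: `file`, `seqA`, `seqB` (character vectors of residues),
#'   `contacts` (data.frame `pos_a`, `pos_b` of designed pairs),
#'   `contactMap` (ground-truth [ContactMap-class] with exact minimum
#'   distances), `resolution`.
#' @export
makeToyDimer <- function(spec, file = tempfile(fileext = ".pdb"),
                         format = c("pdb", "cif")) {
  format <- match.arg(format)
  n <- spec$nResiduesPerChain
  if (spec$nContacts > n)
    ppStop("infeasibleSpec",
           "more contacts requested than residues per chain")
  withSeed(spec$seed, {
    seqA <- sample(AA_CODES, n, replace = TRUE)
    seqB <- sample(AA_CODES, n, replace = TRUE)
    posA <- sort(sample(n, spec$nContacts))
    posB <- sort(sample(n, spec$nContacts))
  })
  ## lattice geometry: chain A along x at y = 0; chain B far away at y = 30
  ## except contact residues, translated to y = 3.9 above their partner.
  offsets <- list(N = c(-0.25, 0, 0), CA = c(0, 0, 0), C = c(0.25, 0, 0),
                  O = c(0.25, 0.25, 0), CB = c(0, -0.25, 0))
  centerA <- function(i) c(8 * i, 0, 0)
  centerB <- function(j) {
    k <- match(j, posB)
    if (!is.na(k)) c(8 * posA[k], 3.9, 0) else c(8 * j, 30, 0)
  }
  resAtoms <- function(aa, center, flip) {
    nm <- names(offsets)
    if (aa == "G") nm <- setdiff(nm, "CB")
    lapply(nm, function(a) {
      o <- offsets[[a]]
      if (flip) o <- c(o[1], -o[2], o[3])   # chain B faces chain A
      list(name = a, xyz = center + o)
    })
  }
  lines <- character()
  ser <- 0L
  emit <- function(chain, seq, centerFun, flip) {
    out <- character()
    for (i in seq_along(seq)) {
      for (at in resAtoms(seq[i], centerFun(i), flip)) {
        ser <<- ser + 1L
        out <- c(out, if (format == "pdb") {
          sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  ser, at$name, AA_THREE[[seq[i]]], chain, i,
                  at$xyz[1], at$xyz[2], at$xyz[3], 1, 0,
                  substr(at$name, 1L, 1L))
        } else {
          sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
                  ser, substr(at$name, 1L, 1L), at$name, AA_THREE[[seq[i]]],
                  chain, i, at$xyz[1], at$xyz[2], at$xyz[3], i,
                  AA_THREE[[seq[i]]], chain, at$name)
        })
      }
    }
    out
  }
  bodyA <- emit("A", seqA, centerA, flip = FALSE)
  bodyB <- emit("B", seqB, centerB, flip = TRUE)
  if (format == "pdb") {
    lines <- c("REMARK   2 RESOLUTION.    2.00 ANGSTROMS.", bodyA, bodyB, "END")
  } else {
    lines <- c("data_toydimer", "_refine.ls_d_res_high 2.00", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                        "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                        "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                        "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
               bodyA, bodyB)
  }
  writeLines(lines, file)
  ## exact ground-truth minimum distance per designed pair
  minDist <- vapply(seq_along(posA), function(k) {
    aA <- resAtoms(seqA[posA[k]], centerA(posA[k]), FALSE)
    aB <- resAtoms(seqB[posB[k]], centerB(posB[k]), TRUE)
    min(vapply(aA, function(p) min(vapply(aB, function(q)
      sqrt(sum((p$xyz - q$xyz)^2)), numeric(1))), numeric(1)))
  }, numeric(1))
  gt <- data.frame(chain_a = "A", resno_a = posA, icode_a = "",
                   aa_a = seqA[posA], pos_a = posA,
                   chain_b = "B", resno_b = posB, icode_b = "",
                   aa_b = seqB[posB], pos_b = posB,
                   min_dist = minDist, stringsAsFactors = FALSE)
  list(file = file, seqA = seqA, seqB = seqB,
       contacts = data.frame(pos_a = posA, pos_b = posB),
       contactMap = new("ContactMap", pairs = gt, cutoff = 4.5),
       resolution = 2.0)
}

#' Generate paired MSAs for a toy dimer
#'
#' Simulates `nProfileRows` paired homologous sequence rows for the two
#' chains. At contact columns a residue is substituted within its
#' (modified-scheme) group with probability `withinGroupSubRate` and across
#' groups with probability `acrossGroupSubRate` — the conservation pattern
#' the pairPSSM model assumes at interfaces. Non-contact columns substitute
#' uniformly at `nonContactSubRate`. Rows are tagged with consistent
#' source-organism keys across the two files.
#'
#' @param dimer result of [makeToyDimer()].
#' @param spec a [fixtureSpec()].
#' @param dir output directory for `msa_a.fasta`, `msa_b.fasta` and
#'   `pairing.tsv` (default: a temporary directory).
#' @return list: `msaA`, `msaB` ([Msa-class] objects), `fileA`, `fileB`,
#'   `keysFile`.
#' @export
makePairedMsas <- function(dimer, spec, dir = tempfile("msas")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- groupScheme("modified")
  contactA <- unique(dimer$contacts$pos_a)
  contactB <- unique(dimer$contacts$pos_b)
  mutate <- function(seq, contactPos) {
    out <- seq
    for (p in seq_along(seq)) {
      u <- stats::runif(1)
      if (p %in% contactPos) {
        if (u < spec$acrossGroupSubRate) {
          out[p] <- subAcrossGroup(seq[p], scheme)
        } else if (u < spec$acrossGroupSubRate + spec$withinGroupSubRate) {
          out[p] <- subWithinGroup(seq[p], scheme)
        }
      } else if (u < spec$nonContactSubRate) {
        out[p] <- sample(setdiff(AA_CODES, seq[p]), 1L)
      }
    }
    out
  }
  withSeed(spec$seed, {
    rowsA <- vapply(seq_len(spec$nProfileRows), function(k)
      paste(mutate(dimer$seqA, contactA), collapse = ""), "")
    rowsB <- vapply(seq_len(spec$nProfileRows), function(k)
      paste(mutate(dimer$seqB, contactB), collapse = ""), "")
  })
  keys <- sprintf("org%03d", seq_len(spec$nProfileRows))
  ids <- sprintf("row%03d", seq_len(spec$nProfileRows))
  fileA <- file.path(dir, "msa_a.fasta")
  fileB <- file.path(dir, "msa_b.fasta")
  keysFile <- file.path(dir, "pairing.tsv")
  writeFasta <- function(file, tmplSeq, rows) {
    lines <- c(">template key=template", paste(tmplSeq, collapse = ""),
               as.vector(rbind(sprintf(">%s key=%s", ids, keys), rows)))
    writeLines(lines, file)
  }
  writeFasta(fileA, dimer$seqA, rowsA)
  writeFasta(fileB, dimer$seqB, rowsB)
  writeLines(c(sprintf("template\ttemplate"),
               sprintf("%s\t%s", ids, keys)), keysFile)
  list(msaA = readMsa(fileA, templateRow = "template"),
       msaB = readMsa(fileB, templateRow = "template"),
       fileA = fileA, fileB = fileB, keysFile = keysFile)
}

#' Generate a labelled screening benchmark
#'
#' Builds homology-hit tables and gold-standard labels for a synthetic
#' screen against a toy dimer. Positive candidates conserve the template
#' residues (allowing within-group substitutes at `withinGroupSubRate`) at
#' every contact position. Negative candidates have
#' `interfaceAblationFraction` of the contact positions ablated: each
#' ablated position is, with equal probability, left unaligned on one side
#' (the missing-interacting-domain pattern) or mutated across groups.
#'
#' @param dimer result of [makeToyDimer()].
#' @param spec a [fixtureSpec()].
#' @param dir optional output directory for `hits_a.tsv`, `hits_b.tsv`,
#'   `labels.tsv` (native tabular formats readable by
#'   [readHomologyHits()]); files are skipped when `NULL`.
#' @return list: `hitsA`, `hitsB` (lists of `HomologyHit`), `labels`
#'   (data.frame `id_a`, `id_b`, `label` for the designed pairs),
#'   `files` (named paths or NULL).
#' @export
makeScreenBenchmark <- function(dimer, spec, dir = NULL) {
  scheme <- groupScheme("modified")
  nA <- length(dimer$seqA)
  nB <- length(dimer$seqB)
  R <- nrow(dimer$contacts)
  fullAln <- function(seq) data.frame(tpos = seq_along(seq),
                                      spos = seq_along(seq), aa = seq,
                                      stringsAsFactors = FALSE)
  conserved <- function(seq) {
    out <- seq
    for (p in seq_along(out))
      if (stats::runif(1) < spec$withinGroupSubRate)
        out[p] <- subWithinGroup(out[p], scheme)
    out
  }
  pctId <- function(a, b) 100 * mean(a == b)
  hitsA <- list(); hitsB <- list(); labels <- NULL
  withSeed(spec$seed, {
    for (i in seq_len(spec$nPositiveCandidates)) {
      sa <- conserved(dimer$seqA); sb <- conserved(dimer$seqB)
      ida <- sprintf("posA%03d", i); idb <- sprintf("posB%03d", i)
      hitsA[[length(hitsA) + 1L]] <- homologyHit(
        "A", ida, 1e-30, pctId(sa, dimer$seqA), fullAln(sa))
      hitsB[[length(hitsB) + 1L]] <- homologyHit(
        "B", idb, 1e-30, pctId(sb, dimer$seqB), fullAln(sb))
      labels <- rbind(labels, data.frame(id_a = ida, id_b = idb,
                                         label = "positive"))
    }
    nAblate <- round(spec$interfaceAblationFraction * R)
    for (i in seq_len(spec$nNegativeCandidates)) {
      sa <- conserved(dimer$seqA); sb <- conserved(dimer$seqB)
      dropA <- integer(); dropB <- integer()
      ablate <- sample(R, nAblate)
      for (r in ablate) {
        pa <- dimer$contacts$pos_a[r]; pb <- dimer$contacts$pos_b[r]
        if (stats::runif(1) < 0.5) {
          ## unaligned on one side
          if (stats::runif(1) < 0.5) dropA <- c(dropA, pa)
          else dropB <- c(dropB, pb)
        } else {
          ## non-conservative mutation on one side
          if (stats::runif(1) < 0.5) sa[pa] <- subAcrossGroup(dimer$seqA[pa], scheme)
          else sb[pb] <- subAcrossGroup(dimer$seqB[pb], scheme)
        }
      }
      alnA <- fullAln(sa); alnB <- fullAln(sb)
      alnA <- alnA[!(alnA$tpos %in% dropA), , drop = FALSE]
      alnB <- alnB[!(alnB$tpos %in% dropB), , drop = FALSE]
      ida <- sprintf("negA%03d", i); idb <- sprintf("negB%03d", i)
      hitsA[[length(hitsA) + 1L]] <- homologyHit(
        "A", ida, 1e-10, pctId(sa, dimer$seqA), alnA)
      hitsB[[length(hitsB) + 1L]] <- homologyHit(
        "B", idb, 1e-10, pctId(sb, dimer$seqB), alnB)
      labels <- rbind(labels, data.frame(id_a = ida, id_b = idb,
                                         label = "negative"))
    }
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeHits <- function(hits, file) {
      alnStr <- vapply(hits, function(h)
        paste(sprintf("%d:%d:%s", h$aln$tpos, h$aln$spos, h$aln$aa),
              collapse = ";"), "")
      tab <- data.frame(chain = vapply(hits, `[[`, "", "chain"),
                        subject_id = vapply(hits, `[[`, "", "subjectId"),
                        evalue = vapply(hits, `[[`, 0, "evalue"),
                        identity = vapply(hits, `[[`, 0, "identity"),
                        aln = alnStr)
      utils::write.table(tab, file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      file
    }
    files <- list(hitsA = writeHits(hitsA, file.path(dir, "hits_a.tsv")),
                  hitsB = writeHits(hitsB, file.path(dir, "hits_b.tsv")),
                  labels = file.path(dir, "labels.tsv"))
    utils::write.table(labels, files$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(hitsA = hitsA, hitsB = hitsB, labels = labels, files = files)
}

#' Emit a complete self-consistent demo workspace
#'
#' Runs all generators with one spec: toy dimer structure, paired MSAs,
#' screening benchmark, and copies of the bundled synthetic potential and
#' composition tables.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory.
#' @return Invisibly, a named list of the emitted paths.
#' @export
makeFixtureWorkspace <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- makeToyDimer(spec, file.path(dir, "dimer.pdb"))
  ms <- makePairedMsas(dm, spec, dir)
  bm <- makeScreenBenchmark(dm, spec, dir)
  for (f in c("potential_synthetic.tsv", "composition_synthetic.tsv"))
    file.copy(system.file("extdata", f, package = "pairPSSM"),
              file.path(dir, f), overwrite = TRUE)
  invisible(list(dimer = dm$file, msaA = ms$fileA, msaB = ms$fileB,
                 keys = ms$keysFile, hitsA = bm$files$hitsA,
                 hitsB = bm$files$hitsB, labels = bm$files$labels,
                 potential = file.path(dir, "potential_synthetic.tsv"),
                 composition = file.path(dir, "composition_synthetic.tsv")))
}
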