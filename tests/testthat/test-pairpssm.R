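test_that("pseudocount blend matches the closed form", {
  expect_equal(pseudocountQ(0.5, 0.01, alpha = 3, beta = 5), 0.19375)
  ## alpha = 0 collapses to the prior
  expect_equal(pseudocountQ(0.9, 0.007, alpha = 0, beta = 5), 0.007)
  ## f = g is a fixed point for any weights
  for (w in list(c(0, 5), c(3, 5), c(10, 1)))
    expect_equal(pseudocountQ(0.2, 0.2, w[1], w[2]), 0.2)
  expect_error(pseudocountQ(0.5, 0.1, 0, 0), class = "degenerateWeights")
})

test_that("position scores equal a direct formula evaluation to 1e-12", {
  sch <- groupScheme("modified")
  pot <- mkUniformPotential(S = 0)          # uniform P = 0.05, S = 0
  cnt <- structure(list(counts = c("2:8" = 3L, "1:8" = 1L),
                        nEffective = 4L, nDistinct = 2L, posA = 1L, posB = 1L),
                   class = "PairColumnCounts")
  got <- positionScores(cnt, pot, sch, beta = 5)
  ## independent spreadsheet-style evaluation, residue pair by residue pair
  g2g <- sch@aaToGroup
  for (x in AA20) for (y in AA20) {
    f <- unname(cnt$counts[paste(g2g[x], g2g[y], sep = ":")])
    if (is.na(f)) f <- 0
    f <- f / 4
    gxy <- 0.05 * 0.05 * exp(0)
    Q <- (1 * f + 5 * gxy) / (1 + 5)
    expect_equal(got[x, y], log(Q / (0.05 * 0.05)), tolerance = 1e-12)
  }
})

test_that("with alpha = 0 the pairPSSM degenerates to the empirical matrix", {
  pot <- bundledPotential()
  cnt <- structure(list(counts = c("2:8" = 7L), nEffective = 7L,
                        nDistinct = 1L, posA = 1L, posB = 1L),
                   class = "PairColumnCounts")
  got <- positionScores(cnt, pot, groupScheme("modified"))
  expect_equal(got, potentialMatrix(pot), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## and Q = P gives score 0: uniform prior with S = 0 and no observations
  got0 <- positionScores(structure(list(counts = c("5:5" = 1L),
                                        nEffective = 1L, nDistinct = 1L,
                                        posA = 1L, posB = 1L),
                                   class = "PairColumnCounts"),
                         mkUniformPotential(S = 0), groupScheme("modified"))
  expect_true(all(abs(got0) < 1e-12))
  ## empty column falls back to alpha = 0 with a warning
  expect_warning(
    gotE <- positionScores(structure(list(counts = integer(0),
                                          nEffective = 0L, nDistinct = 0L,
                                          posA = 1L, posB = 1L),
                                     class = "PairColumnCounts"), pot),
    class = "noObservations")
  expect_equal(gotE, potentialMatrix(pot), tolerance = 1e-12,
               ignore_attr = TRUE)
})

## shared fixture: template + profile + pssm used by several blocks
buildFixturePssm <- function(seed = 3, pot = bundledPotential()) {
  spec <- fixtureSpec(seed = seed)
  dm <- makeToyDimer(spec)
  td <- templateDimer(dm$file, "A", "B")
  ms <- makePairedMsas(dm, spec)
  pp <- pairRows(ms$msaA, ms$msaB)
  list(spec = spec, dm = dm, td = td, pp = pp,
       pssm = buildPairPSSM(td, pp, pot), pot = pot)
}

test_that("pairPSSM construction covers every contact position", {
  fx <- buildFixturePssm()
  expect_equal(nPositions(fx$pssm), nContacts(fx$td))
  expect_true(all(vapply(seq_len(nPositions(fx$pssm)),
                         function(r) all(is.finite(scoreTable(fx$pssm, r))),
                         logical(1))))
  ## self-energy equals the sum of template-pair scores
  tp <- fx$pssm@templatePairs
  self <- sum(vapply(seq_len(nrow(tp)), function(r)
    scoreTable(fx$pssm, r)[tp$aa_a[r], tp$aa_b[r]], numeric(1)))
  expect_equal(selfEnergy(fx$pssm), self, tolerance = 1e-12)

  ## a profile that does not span the contacts fails loudly
  shortA <- msa("t", substr(fx$pp@msaA@seqs[1], 1, 5), "t")
  expect_warning(ppShort <- pairRows(shortA, fx$pp@msaB),
                 class = "insufficientPairs")
  expect_error(buildPairPSSM(fx$td, ppShort, fx$pot), class = "buildError")
})

test_that("an empty profile reproduces the empirical matrix at every position", {
  spec <- fixtureSpec(seed = 8, nResiduesPerChain = 12, nContacts = 4)
  dm <- makeToyDimer(spec)
  td <- templateDimer(dm$file, "A", "B")
  a <- msa("t", paste(dm$seqA, collapse = ""), "t")
  b <- msa("t", paste(dm$seqB, collapse = ""), "t")
  expect_warning(pp <- pairRows(a, b), class = "insufficientPairs")
  pot <- bundledPotential()
  pssm <- buildPairPSSM(td, pp, pot)
  for (r in seq_len(nPositions(pssm)))
    expect_equal(scoreTable(pssm, r), potentialMatrix(pot),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("candidate energies: self-normalization, zero coverage, partial oracle", {
  fx <- buildFixturePssm()
  pssm <- fx$pssm
  tp <- pssm@templatePairs
  tmplAlnA <- data.frame(tpos = seq_along(fx$dm$seqA),
                         spos = seq_along(fx$dm$seqA), aa = fx$dm$seqA)
  tmplAlnB <- data.frame(tpos = seq_along(fx$dm$seqB),
                         spos = seq_along(fx$dm$seqB), aa = fx$dm$seqB)
  self <- specificEnergy(pssm, candidatePair("t", "t", tmplAlnA, tmplAlnB))
  expect_equal(self$normalized, 1.0, tolerance = 1e-12)
  expect_equal(self$covered, nPositions(pssm))

  ## nothing aligned: zero everywhere (the missing-domain case)
  none <- candidatePair("x", "y",
                        data.frame(tpos = integer(), spos = integer(),
                                   aa = character()),
                        tmplAlnB)
  e0 <- specificEnergy(pssm, none)
  expect_equal(e0$specific, 0)
  expect_equal(e0$normalized, 0)
  expect_equal(e0$covered, 0L)

  ## template aligned on a random half of contact positions: brute-force sum
  set.seed(1)
  half <- sort(sample(nPositions(pssm), nPositions(pssm) %/% 2))
  alnA <- tmplAlnA[tmplAlnA$tpos %in% tp$pos_a[half], ]
  eH <- specificEnergy(pssm, candidatePair("h", "h", alnA, tmplAlnB),
                       fx$pot)
  oracle <- sum(vapply(half, function(r)
    scoreTable(pssm, r)[tp$aa_a[r], tp$aa_b[r]], numeric(1)))
  oracleGen <- sum(vapply(half, function(r)
    potentialMatrix(fx$pot)[tp$aa_a[r], tp$aa_b[r]], numeric(1)))
  expect_equal(eH$specific, oracle, tolerance = 1e-12)
  expect_equal(eH$normalized, oracle / selfEnergy(pssm), tolerance = 1e-12)
  expect_equal(eH$general, oracleGen, tolerance = 1e-12)
  expect_equal(eH$covered, length(half))
})

test_that("classification threshold is inclusive", {
  r <- structure(list(normalized = 0.84), class = "EnergyResult")
  expect_true(classifyInteraction(r, 0.5))
  expect_false(classifyInteraction(structure(list(normalized = 0.08),
                                             class = "EnergyResult"), 0.4))
  expect_true(classifyInteraction(structure(list(normalized = 0.4),
                                            class = "EnergyResult"), 0.4))
})

test_that("a non-positive template self-energy is refused for normalization", {
  spec <- fixtureSpec(seed = 8, nResiduesPerChain = 12, nContacts = 4)
  dm <- makeToyDimer(spec)
  td <- templateDimer(dm$file, "A", "B")
  a <- msa("t", paste(dm$seqA, collapse = ""), "t")
  b <- msa("t", paste(dm$seqB, collapse = ""), "t")
  suppressWarnings(pp <- pairRows(a, b))
  ## all-negative potential with an empty profile: self-energy = sum S < 0
  pssm <- buildPairPSSM(td, pp, mkUniformPotential(S = -1))
  expect_equal(selfEnergy(pssm), -4, tolerance = 1e-9)
  cand <- candidatePair("x", "y",
                        data.frame(tpos = 1:12, spos = 1:12, aa = dm$seqA),
                        data.frame(tpos = 1:12, spos = 1:12, aa = dm$seqB))
  expect_error(specificEnergy(pssm, cand), class = "normalizationUndefined")
})

test_that("serialization round-trips scores and self-energy exactly", {
  fx <- buildFixturePssm(seed = 5)
  f <- tempfile(fileext = ".json")
  writePairPSSM(fx$pssm, f)
  back <- readPairPSSM(f)
  expect_identical(back@scores, fx$pssm@scores)
  expect_identical(back@selfEnergy, fx$pssm@selfEnergy)
  expect_identical(back@templatePairs$aa_a, fx$pssm@templatePairs$aa_a)
  expect_equal(back@templatePairs$pos_a, fx$pssm@templatePairs$pos_a)
  ## TSV export covers R x 400 rows
  tf <- tempfile(fileext = ".tsv")
  exportPairPSSMTsv(fx$pssm, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), nPositions(fx$pssm) * 400L)
  expect_equal(tab$score[tab$position == 2 & tab$aa_a == "A" & tab$aa_b == "C"],
               scoreTable(fx$pssm, 2)["A", "C"])
})

test_that("observing the template's own pair cannot lower its score when f > g", {
  pot <- bundledPotential()
  sch <- groupScheme("modified")
  P <- backgroundComposition(pot); S <- potentialMatrix(pot)
  set.seed(11)
  for (rep in 1:20) {
    x <- sample(AA20, 1); y <- sample(AA20, 1)
    sym <- paste(aaGroup(sch, x), aaGroup(sch, y), sep = ":")
    othersym <- "5:5"
    n <- sample(3:30, 1); k <- sample(seq_len(n - 1), 1)
    counts <- c(k, n - k); names(counts) <- c(sym, othersym)
    cnt <- structure(list(counts = counts, nEffective = n, nDistinct = 2L,
                          posA = 1L, posB = 1L), class = "PairColumnCounts")
    got <- positionScores(cnt, pot, sch)[x, y]
    g <- P[x] * P[y] * exp(S[x, y])
    if (k / n > g) expect_gte(got, S[x, y] - 1e-12)
  }
})
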