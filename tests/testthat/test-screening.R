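emptyAln <- function() data.frame(tpos = integer(), spos = integer(),
                                  aa = character())

mkHit <- function(chain, id, evalue = 1e-6, identity = 50)
  homologyHit(chain, id, evalue, identity, emptyAln())

## a RankedHitList straight from scores and labels (distinct scores)
mkRanked <- function(scores, labels) {
  n <- length(scores)
  rankCandidates(data.frame(id_a = sprintf("a%02d", seq_len(n)),
                            id_b = sprintf("b%02d", seq_len(n)),
                            normalized = scores),
                 data.frame(id_a = sprintf("a%02d", seq_len(n)),
                            id_b = sprintf("b%02d", seq_len(n)),
                            label = labels))
}

test_that("candidate enumeration is the E-value-filtered Cartesian product", {
  hitsA <- list(mkHit("A", "x1"), mkHit("A", "x2"))
  hitsB <- list(mkHit("B", "y1"), mkHit("B", "y2"), mkHit("B", "y3"))
  expect_length(buildCandidates(hitsA, hitsB), 6L)

  ## E-value above the cutoff excluded; cutoff inclusive
  hitsA2 <- c(hitsA, list(mkHit("A", "x3", evalue = 1e-2)))
  expect_length(buildCandidates(hitsA2, hitsB), 6L)
  hitsA3 <- c(hitsA, list(mkHit("A", "x3", evalue = 1e-3)))
  expect_length(buildCandidates(hitsA3, hitsB), 9L)

  ## same protein hit by both chains: allowed and flagged
  cands <- buildCandidates(list(mkHit("A", "p")), list(mkHit("B", "p")))
  expect_true(cands[[1]]$selfPair)
})

test_that("the identity limit removes candidates strictly above it", {
  cands <- list(
    candidatePair("a", "b", emptyAln(), emptyAln(), 60, 20),
    candidatePair("c", "d", emptyAln(), emptyAln(), 50, 50),
    candidatePair("e", "f", emptyAln(), emptyAln(), 20, 95))
  out <- applyIdentityLimit(cands, 50)
  expect_equal(vapply(out, `[[`, "", "idA"), c("c"))
  expect_length(applyIdentityLimit(cands, 100), 3L)
})

test_that("average precision and false-positive rate match hand-worked cases", {
  ## positives at the top: AP = 1, FP = 0
  top <- mkRanked(c(0.9, 0.8, 0.3, 0.2),
                  c("positive", "positive", "negative", "negative"))
  expect_equal(averagePrecision(top), c(AP = 1, FP = 0))

  ## K = 4, A = 2, positives at ranks 1 and 3
  mid <- mkRanked(c(0.9, 0.8, 0.7, 0.2),
                  c("positive", "negative", "positive", "negative"))
  expect_equal(averagePrecision(mid)[["AP"]], (1 / 1 + 2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(averagePrecision(mid)[["FP"]], 0.25, tolerance = 1e-12)

  ## K = 3, A = 1, positive last: AP = 1/3, FP at its maximum 1
  worst <- mkRanked(c(0.9, 0.8, 0.1), c("negative", "negative", "positive"))
  expect_equal(averagePrecision(worst)[["AP"]], 1 / 3, tolerance = 1e-12)
  expect_equal(averagePrecision(worst)[["FP"]], 1, tolerance = 1e-12)

  ## degenerate lists are refused
  expect_error(averagePrecision(mkRanked(c(0.9, 0.8),
                                         c("positive", "positive"))),
               class = "fpUndefined")
})

test_that("AP/FP agree with exhaustive enumeration of label placements up to K = 8", {
  for (K in 2:8) {
    for (A in seq_len(K - 1)) {
      placements <- combn(K, A)
      for (col in seq_len(ncol(placements))) {
        pos <- placements[, col]
        labels <- ifelse(seq_len(K) %in% pos, "positive", "negative")
        scores <- seq(1, 0.1, length.out = K)   # distinct, already sorted
        got <- averagePrecision(mkRanked(scores, labels))
        ## independent oracle: precision at each positive via cumulative sums
        lab01 <- as.integer(labels == "positive")
        apOracle <- mean((cumsum(lab01) / seq_len(K))[lab01 == 1])
        fpOracle <- mean((pos - seq_len(A)) / (K - A))
        expect_equal(got[["AP"]], apOracle, tolerance = 1e-12)
        expect_equal(got[["FP"]], fpOracle, tolerance = 1e-12)
        ## bounds and the perfect-ranking equivalence
        expect_gte(got[["AP"]], 0); expect_lte(got[["AP"]], 1)
        expect_gte(got[["FP"]], 0); expect_lte(got[["FP"]], 1)
        expect_equal(got[["AP"]] == 1, got[["FP"]] == 0)
      }
    }
  }
})

test_that("moving a positive down in rank never increases AP", {
  K <- 6
  scores <- seq(1, 0.1, length.out = K)
  for (A in 1:3) {
    placements <- combn(K, A)
    for (col in seq_len(ncol(placements))) {
      pos <- placements[, col]
      base <- ifelse(seq_len(K) %in% pos, "positive", "negative")
      apBase <- averagePrecision(mkRanked(scores, base))[["AP"]]
      for (p in pos) {
        if (p < K && !((p + 1) %in% pos)) {
          moved <- base
          moved[c(p, p + 1)] <- moved[c(p + 1, p)]
          apMoved <- averagePrecision(mkRanked(scores, moved))[["AP"]]
          expect_lte(apMoved, apBase + 1e-12)
        }
      }
    }
  }
})

test_that("pessimistic tie-breaking ranks tied negatives before positives", {
  sc <- data.frame(id_a = c("a1", "a2"), id_b = c("b1", "b2"),
                   normalized = c(0.5, 0.5))
  lab <- data.frame(id_a = c("a1", "a2"), id_b = c("b1", "b2"),
                    label = c("positive", "negative"))
  pess <- rankCandidates(sc, lab)
  expect_equal(pess@entries$label, c("negative", "positive"))
  opti <- rankCandidates(sc, lab, tieRule = "optimistic")
  expect_equal(opti@entries$label, c("positive", "negative"))
  ## unannotated handling: as-negative vs dropped
  lab1 <- lab[1, ]
  asNeg <- rankCandidates(sc, lab1)
  expect_equal(asNeg@K, 2L); expect_equal(asNeg@A, 1L)
  dropped <- rankCandidates(sc, lab1, unannotated = "drop")
  expect_equal(dropped@K, 1L)
})

test_that("mean metrics average per-template AP/FP", {
  expect_equal(meanMetrics(list(c(0.5, 0.2)))[c("MAP", "MFP")],
               c(MAP = 0.5, MFP = 0.2))
  expect_equal(meanMetrics(list(c(1, 0), c(0.5, 0.5)))[c("MAP", "MFP")],
               c(MAP = 0.75, MFP = 0.25))
  set.seed(2)
  m <- matrix(runif(40), ncol = 2)
  expect_equal(unname(meanMetrics(m)[1:2]), unname(colMeans(m)))
  expect_error(meanMetrics(list()), class = "noEvaluableTemplates")
})

test_that("balanced error sweep matches brute-force confusion matrices", {
  sw <- errorSweep(c(0.9, 0.6), c(0.5, 0.8), thresholds = c(0.55, 0.7, 0.85))
  expect_equal(sw$errorRates[2], 0.5)   # FN 1/2, FP 1/2 at t = 0.7

  ## perfectly separated classes reach zero error between the classes
  sep <- errorSweep(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$minError, 0)

  ## identical distributions stay at chance
  same <- errorSweep(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_equal(same$minError, 0.5)

  expect_error(errorSweep(numeric(0), 1), class = "emptyClass")

  set.seed(21)
  for (rep in 1:5) {
    pos <- runif(30); neg <- runif(40, max = 0.8)
    th <- sort(runif(15))
    sw <- errorSweep(pos, neg, th)
    oracle <- vapply(th, function(t) {
      tp <- sum(pos >= t); fn <- sum(pos < t)
      fp <- sum(neg >= t); tn <- sum(neg < t)
      (fn / (tp + fn) + fp / (fp + tn)) / 2
    }, numeric(1))
    expect_equal(sw$errorRates, oracle, tolerance = 1e-12)
    expect_equal(sw$minError, min(oracle))
    expect_equal(sw$bestThreshold, min(th[oracle == min(oracle)]))
    ## literal variant swaps the denominators
    swLit <- errorSweep(pos, neg, th, literal = TRUE)
    oracleLit <- vapply(th, function(t)
      (sum(neg >= t) / length(pos) + sum(pos < t) / length(neg)) / 2,
      numeric(1))
    expect_equal(swLit$errorRates, oracleLit, tolerance = 1e-12)
  }
})

test_that("expression test computes Pearson r and a one-sided Welch test", {
  profiles <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4),
                    g3 = c(-1, -2, -3, -4), g4 = c(2, 4, 5, 4),
                    g5 = c(5, 5, 5, 5))
  pairs <- data.frame(id_a = c("g1", "g1", "g1"), id_b = c("g2", "g3", "g4"))
  null <- data.frame(id_a = c("g3", "g3"), id_b = c("g2", "g4"))
  res <- expressionTest(pairs, null, profiles)
  expect_equal(res$correlations[1], 1)
  expect_equal(res$correlations[2], -1)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$correlations[3], rOracle, tolerance = 1e-12)

  ## self pairs and constant profiles are excluded with counts
  res2 <- expressionTest(data.frame(id_a = c("g1", "g1", "g1", "g2"),
                                    id_b = c("g1", "g5", "g2", "g4")),
                         null, profiles)
  expect_equal(unname(res2$dropped["pred_self"]), 1L)
  expect_equal(unname(res2$dropped["pred_incomplete"]), 1L)
  expect_length(res2$correlations, 2L)
})

test_that("the Welch p-value is uniform when both sets share a distribution", {
  set.seed(31)
  nGenes <- 40; nCond <- 10
  profiles <- matrix(rnorm(nGenes * nCond), nGenes,
                     dimnames = list(sprintf("g%02d", 1:nGenes), NULL))
  pvals <- vapply(1:200, function(i) {
    pick <- function() data.frame(
      id_a = sprintf("g%02d", sample(nGenes, 25, replace = TRUE)),
      id_b = sprintf("g%02d", sample(nGenes, 25, replace = TRUE)))
    suppressWarnings(expressionTest(pick(), pick(), profiles)$pValue)
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
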