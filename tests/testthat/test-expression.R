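test_that("count matrix aggregates non-normalized libraries only", {
  reads <- makeReads(replicate(5, randomDNA(120)),
                     lib = c("LF1", "LF2", "LF1", "NORM", "ROOT"))
  mem <- data.frame(read_id = as.data.frame(readInfo(reads))$read_id,
                    unigene_id = c("U1", "U1", "U1", "U1", "U2"))
  md <- makeMetadata(c("LF1", "LF2", "NORM", "ROOT"),
                     tissue = c("leaf", "leaf", "leaf", "root"),
                     normalized = c(FALSE, FALSE, TRUE, FALSE))
  mat <- buildCountMatrix(mem, reads, md)
  expect_equal(estCounts(mat)["U1", "leaf"], 3L)
  expect_equal(estCounts(mat)["U1", "root"], 0L)
  expect_equal(estCounts(mat)["U2", "root"], 1L)
  expect_equal(unname(tissueTotals(mat)), unname(colSums(estCounts(mat))))

  # reads only from normalized libraries -> zero matrix
  mdAllNorm <- makeMetadata(c("LF1", "LF2", "NORM", "ROOT"),
                            tissue = c("leaf", "leaf", "leaf", "root"),
                            normalized = c(TRUE, TRUE, TRUE, FALSE))
  mat0 <- buildCountMatrix(mem, reads, mdAllNorm)
  expect_equal(sum(estCounts(mat0)), 1L)   # only the ROOT read survives

  # unknown library is a hard error
  expect_error(buildCountMatrix(mem, reads, md[-4, ]), "unknown library")
})

test_that("stekelR matches hand-evaluated values and validates input", {
  expect_equal(stekelR(c(5, 5), c(100, 100)), 0)
  expect_equal(stekelR(c(5, 0), c(100, 100)), 5 * log(2), tolerance = 1e-12)
  expect_equal(stekelR(c(10, 1), c(100, 100)),
               10 * log(10 / 5.5) + 1 * log(1 / 5.5), tolerance = 1e-12)
  expect_error(stekelR(c(0, 0), c(10, 10)), "sum")
  expect_error(stekelR(c(1, 1), c(10, 0)), "positive")
  expect_error(stekelR(5, 10), "length")
})

test_that("2R equals the Poisson likelihood-ratio deviance on random tables", {
  set.seed(61)
  for (i in 1:400) {
    m <- sample(2:5, 1)
    N <- sample(50:2000, m, replace = TRUE)
    x <- rbinom(m, N, runif(1, 0.001, 0.05))
    if (sum(x) == 0) next
    expect_equal(2 * stekelR(x, N), oracleLRT(x, N), tolerance = 1e-8)
  }
})

test_that("R is zero exactly when proportions are equal (small-grid exhaustive)", {
  N <- c(40, 80)
  for (xa in 0:8) for (xb in 0:8) {
    if (xa + xb == 0) next
    R <- stekelR(c(xa, xb), N)
    equalProps <- isTRUE(all.equal(xa / 40, xb / 80))
    expect_true(R >= 0)
    expect_equal(R == 0, equalProps, info = paste(xa, xb))
  }
})

test_that("p-values behave: chisq exact cases and Monte-Carlo agreement", {
  expect_equal(stekelPValue(c(5, 5), c(100, 100)), 1)
  p <- stekelPValue(c(10, 0), c(1000, 1000))
  expect_equal(p, pchisq(2 * 10 * log(2), 1, lower.tail = FALSE))
  expect_equal(p, 1.97e-4, tolerance = 0.01)

  pMC <- stekelPValue(c(20, 5), c(1000, 1000), method = "montecarlo",
                      mcReps = 4000L, seed = 99)
  pChi <- stekelPValue(c(20, 5), c(1000, 1000))
  se <- sqrt(pChi * (1 - pChi) / 4000)
  expect_lt(abs(pMC - pChi), 3 * se + 1e-3)
  expect_error(stekelPValue(c(1, 1), c(10, 10), method = "bogus"))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
  expect_equal(bhFDR(numeric(0)), numeric(0))
})

test_that("null simulation rejects near the nominal rate", {
  set.seed(67)
  N <- c(2000, 2000)
  p0 <- 0.005   # expected count 10 per group
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(i) {
    x <- rbinom(2, N, p0)
    if (sum(x) == 0) return(1)
    stekelPValue(x, N)
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci)
})

test_that("tissue-specificity calling implements the full rule", {
  tissues <- paste0("t", 1:7)
  counts <- matrix(0L, nrow = 3, ncol = 7,
                   dimnames = list(c("gSpec", "gLow", "gFlat"), tissues))
  counts["gSpec", 1] <- 10L          # 10 vs 0 everywhere else
  counts["gLow", 2] <- 3L            # every pair totals 3 < 5: no test
  counts["gFlat", ] <- 5L            # uniform
  # pad the totals so each tissue has 1000 ESTs
  pad <- matrix(0L, nrow = 1, ncol = 7, dimnames = list("pad", tissues))
  pad[1, ] <- 1000L - colSums(counts)
  mat <- ESTCountMatrix(rbind(counts, pad))
  res <- callTissueSpecific(mat)
  expect_true(any(res$calls$unigene == "gSpec" & res$calls$tissue == "t1"))
  expect_false("gLow" %in% res$tests$unigene)
  expect_false("gLow" %in% res$calls$unigene)
  expect_false("gFlat" %in% res$calls$unigene)
  # gFlat pairwise tests exist but R = 0
  expect_true(all(res$tests$R[res$tests$unigene == "gFlat"] == 0))
  # ratio with a zero denominator is infinite
  sp <- res$tests[res$tests$unigene == "gSpec" & res$tests$tissue_a == "t1", ]
  expect_true(all(is.infinite(sp$ratio_ab)))
  # a comparison blocked by the count filter vetoes the call
  counts2 <- counts
  counts2["gSpec", 2] <- 2L   # pair (t1,t2) total 12, fine; (t2,tx) pairs 2<5
  # make gSpec fail one pair: set t1 count low so (t1,t7) total < 5
  counts3 <- matrix(0L, nrow = 1, ncol = 7,
                    dimnames = list("gVeto", tissues))
  counts3[1, 1] <- 4L
  mat3 <- ESTCountMatrix(rbind(counts3, pad0 = matrix(
    1000L - colSums(counts3), 1, 7, dimnames = list("pad", tissues))))
  res3 <- callTissueSpecific(mat3)
  expect_false("gVeto" %in% res3$calls$unigene)
  expect_error(callTissueSpecific(ESTCountMatrix(counts[, 1, drop = FALSE])),
               "2 tissues")
})

test_that("heatmap matrix export normalizes per 10,000 and orders by tissue", {
  tissues <- paste0("t", 1:3)
  counts <- matrix(c(10L, 0L, 0L,
                     0L, 0L, 20L,
                     990L, 1000L, 980L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "pad"), tissues))
  mat <- ESTCountMatrix(counts)
  calls <- data.frame(unigene = c("g2", "g1"), tissue = c("t3", "t1"))
  out <- exportHeatmapMatrix(calls, mat)
  expect_equal(out$unigene, c("g1", "g2"))   # grouped by tissue of specificity
  expect_equal(out$t1[1], 100)               # 10/1000 per 10k
  expect_equal(out$t3[2], 200)
  f <- tempfile(fileext = ".tsv")
  empty <- exportHeatmapMatrix(calls[0, ], mat, path = f)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.delim(f)), 0L)
})
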