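# A hand-built two-cultivar unigene used across the SNP tests:
# consensus columns 1..12, cultivar A reads carry C at column 6,
# cultivar B reads carry T.
makeSnpFixture <- function(aBases = c("C", "C", "C"), bBases = c("T", "T"),
                           gapped = FALSE) {
  backbone <- "ACGTAXGTACGT"
  mk <- function(base) sub("X", base, backbone)
  nA <- length(aBases); nB <- length(bBases)
  aligned <- c(vapply(aBases, mk, character(1)),
               vapply(bBases, mk, character(1)))
  reads <- sprintf("r%02d", seq_len(nA + nB))
  libs <- c(rep("LA", nA), rep("LB", nB))
  members <- data.frame(
    read_id = reads, unigene_id = "U1", strand = "+", offset = 1L,
    aligned = aligned, stringsAsFactors = FALSE)
  cons <- sub("X", names(sort(table(c(aBases, bBases)),
                              decreasing = TRUE))[1], backbone)
  ug <- UnigeneSet(c(U1 = cons), members)
  md <- makeMetadata(c("LA", "LB"), cultivar = c("cvA", "cvB"))
  rds <- ESTReadSet(gsub("-", "", aligned), read_id = reads,
                    clone_id = reads, end = "5p", library_id = libs)
  list(unigenes = ug, metadata = md, reads = rds)
}

test_that("pileup reports per-column observations with cultivars", {
  fx <- makeSnpFixture()
  p <- unigenePileup(fx$unigenes, "U1", fx$metadata, reads = fx$reads)
  col6 <- p[p$column == 6L, ]
  expect_equal(sort(col6$base), c("C", "C", "C", "T", "T"))
  expect_equal(unname(table(col6$cultivar)["cvA"]), 3L)
  # every read spans every column in this fixture
  expect_equal(nrow(p), 5L * 12L)
  expect_equal(unique(p$consensus_pos - p$column), 0L)
  expect_error(unigenePileup(fx$unigenes, "nope", fx$metadata), "unknown")
})

test_that("reads not spanning a column contribute nothing there", {
  members <- data.frame(
    read_id = c("r1", "r2"), unigene_id = "U1", strand = "+",
    offset = c(1L, 5L), aligned = c("ACGTACGT", "ACGTACGT"),
    stringsAsFactors = FALSE)
  ug <- UnigeneSet(c(U1 = "ACGTACGTACGT"), members)
  md <- makeMetadata("LA")
  rds <- ESTReadSet(c("ACGTACGT", "ACGTACGT"), read_id = c("r1", "r2"),
                    clone_id = c("r1", "r2"), end = "5p", library_id = "LA")
  p <- unigenePileup(ug, "U1", md, reads = rds)
  expect_equal(sum(p$column == 2L), 1L)
  expect_equal(sum(p$column == 6L), 2L)
})

test_that("gap observations appear as '-' at base columns", {
  fx <- makeSnpFixture(aBases = c("-", "-", "-"), bBases = c("T", "T"))
  p <- unigenePileup(fx$unigenes, "U1", fx$metadata, reads = fx$reads)
  col6 <- p[p$column == 6L, ]
  expect_equal(sort(col6$base), c("-", "-", "-", "T", "T"))
})

test_that("the two SNP filters pass and fail as documented", {
  # A {C:3} vs B {T:2} -> PASS
  fx <- makeSnpFixture(c("C", "C", "C"), c("T", "T"))
  got <- detectSNPs(fx$unigenes, fx$metadata, reads = fx$reads)
  expect_equal(nrow(got), 1L)
  expect_equal(got$status, "PASS")
  expect_equal(got$class, "TRANSITION")
  expect_equal(got$column, 6L)
  expect_equal(c(got$allele_a, got$allele_b), c("C", "T"))

  # A {C:1} vs B {T:5} -> FAIL_COVERAGE
  fx2 <- makeSnpFixture("C", rep("T", 5))
  got2 <- detectSNPs(fx2$unigenes, fx2$metadata, reads = fx2$reads)
  expect_equal(got2$status, "FAIL_COVERAGE")

  # A {C:2, T:1} vs B {T:3} -> FAIL_SHARED_BASE
  fx3 <- makeSnpFixture(c("C", "C", "T"), c("T", "T", "T"))
  got3 <- detectSNPs(fx3$unigenes, fx3$metadata, reads = fx3$reads)
  expect_equal(got3$status, "FAIL_SHARED_BASE")

  # N observations are excluded from coverage and disjointness
  fx4 <- makeSnpFixture(c("C", "C", "N"), c("T", "T"))
  got4 <- detectSNPs(fx4$unigenes, fx4$metadata, reads = fx4$reads)
  expect_equal(got4$status, "PASS")
  expect_equal(got4$cov_a, 2L)
})

test_that("gap-vs-base fixed differences classify as indels", {
  fx <- makeSnpFixture(c("-", "-", "-"), c("T", "T"))
  got <- detectSNPs(fx$unigenes, fx$metadata, reads = fx$reads)
  expect_equal(got$status, "PASS")
  expect_equal(got$class, "INDEL")
})

test_that("variant classification matches transition/transversion chemistry", {
  expect_equal(classifyVariant("A", "G"), "TRANSITION")
  expect_equal(classifyVariant("C", "T"), "TRANSITION")
  expect_equal(classifyVariant("A", "T"), "TRANSVERSION")
  expect_equal(classifyVariant("C", "G"), "TRANSVERSION")
  expect_equal(classifyVariant("G", "-"), "INDEL")
  expect_error(classifyVariant("A", "A"), "equal")
  # symmetry over all unordered pairs
  alleles <- c("A", "C", "G", "T", "-")
  for (a in alleles) for (b in alleles) {
    if (a == b) next
    expect_equal(classifyVariant(a, b), classifyVariant(b, a))
  }
})

test_that("snpSummary tabulates types, subtotals and unigene counts", {
  cand <- data.frame(
    unigene = c("U1", "U1", "U2"), position = 1:3, column = 1:3,
    cultivar_a = "cvA", cultivar_b = "cvB",
    allele_a = c("A", "A", "C"), allele_b = c("G", "G", "T"),
    alleles_a = "", alleles_b = "", cov_a = 3L, cov_b = 3L,
    status = "PASS", class = "TRANSITION", stringsAsFactors = FALSE)
  sm <- snpSummary(cand)
  expect_equal(unname(sm$subtotals),
               c(3L, 0L, 0L))
  expect_equal(sm$total, 3L)
  expect_equal(sm$n_unigenes, 2L)
  expect_equal(sum(sm$types$count), sm$total)
  # empty input
  sm0 <- snpSummary(cand[0, ])
  expect_equal(sm0$total, 0L)
  expect_equal(unname(sm0$subtotals), c(0L, 0L, 0L))
})

test_that("error-free two-cultivar simulation yields perfect precision", {
  cfg <- simulationConfig(
    seed = 77, nGenes = 40, clonesPerTissue = 260, nSpecific = 0,
    nSNP = 30, cultivars = c("cvA", "cvB"),
    tissues = c("leaf", "flower", "fruit"),
    ssrPlan = NULL)
  sim <- simulateESTStudy(cfg)
  clean <- preprocessReads(sim$reads)
  ug <- clusterReads(clean$reads)
  snps <- detectSNPs(ug, sim$metadata, reads = clean$reads)
  ev <- evaluateSNPRecovery(snps, ug, sim)
  expect_gt(ev$n_evaluable, 0L)
  expect_equal(ev$recovery, 1.0)
  expect_equal(ev$precision, 1.0)
})
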