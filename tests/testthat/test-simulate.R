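smallCfg <- function(...) {
  simulationConfig(seed = 101, nGenes = 150, clonesPerTissue = 120,
                   nSpecific = 3, nSNP = 25, ...)
}

test_that("the generator is fully deterministic per seed", {
  s1 <- simulateESTStudy(smallCfg())
  s2 <- simulateESTStudy(smallCfg())
  expect_identical(as.character(s1$reference$sequences),
                   as.character(s2$reference$sequences))
  expect_identical(as.character(estSequences(s1$reads)),
                   as.character(estSequences(s2$reads)))
  expect_identical(s1$readMap, s2$readMap)
  expect_identical(s1$ssr, s2$ssr)
  expect_identical(s1$snp, s2$snp)
  # a different seed changes the data
  s3 <- simulateESTStudy(simulationConfig(seed = 102, nGenes = 150,
                                          clonesPerTissue = 120))
  expect_false(identical(as.character(s1$reference$sequences),
                         as.character(s3$reference$sequences)))
})

test_that("every truth CDS starts with ATG and ends with a stop codon", {
  ref <- generateReference(smallCfg())
  a <- ref$annotation
  seqs <- as.character(ref$sequences)
  starts <- substr(seqs, a$cds_start, a$cds_start + 2L)
  stops <- substr(seqs, a$cds_end - 2L, a$cds_end)
  expect_true(all(starts == "ATG"))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  expect_true(all((a$cds_end - a$cds_start + 1L) %% 3L == 0L))
  expect_equal(a$utr5_length + (a$cds_end - a$cds_start + 1L) +
                 a$utr3_length, a$length)
})

test_that("UTR lengths recover the configured means within sampling error", {
  cfg <- simulationConfig(seed = 7, nGenes = 2000, clonesPerTissue = 0,
                          nSpecific = 0, nSNP = 0, ssrPlan = NULL)
  ref <- generateReference(cfg)
  a <- ref$annotation
  for (what in c("utr5_length", "utr3_length")) {
    v <- a[[what]]
    target <- if (what == "utr5_length") cfg$utr5Mean else cfg$utr3Mean
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 2 * se + 2)
  }
})

test_that("planted SSR tandems sit exactly at their recorded coordinates", {
  cfg <- smallCfg()
  marked <- plantMarkers(generateReference(cfg), cfg)
  tr <- marked$ssr
  seqs <- as.character(marked$reference$sequences)
  for (i in seq_len(nrow(tr))) {
    s <- seqs[[tr$gene_id[i]]]
    expect_equal(substr(s, tr$start[i], tr$end[i]),
                 strrep(tr$motif[i], tr$repeat_count[i]))
    # maximality: guards block extension by one more unit
    u <- tr$unit_size[i]
    left <- substr(s, tr$start[i] - u, tr$start[i] - 1L)
    right <- substr(s, tr$end[i] + 1L, tr$end[i] + u)
    expect_false(left == tr$motif[i])
    expect_false(right == tr$motif[i])
  }
})

test_that("planted SNPs put the recorded alleles into the right haplotypes", {
  cfg <- smallCfg()
  marked <- plantMarkers(generateReference(cfg), cfg)
  tr <- marked$snp
  expect_gt(nrow(tr), 0L)
  ref <- as.character(marked$reference$sequences)
  for (i in seq_len(nrow(tr))) {
    expect_equal(substr(ref[[tr$gene_id[i]]], tr$position[i],
                        tr$position[i]), tr$ref_allele[i])
    hap <- as.character(marked$haplotypes[[tr$cultivar[i]]][[tr$gene_id[i]]])
    expect_equal(substr(hap, tr$position[i], tr$position[i]),
                 tr$alt_allele[i])
  }
  # class mix follows the configured weights (2:1 transitions:transversions)
  cfgBig <- simulationConfig(seed = 5, nGenes = 400, clonesPerTissue = 0,
                             nSNP = 300, ssrPlan = NULL)
  mk <- plantMarkers(generateReference(cfgBig), cfgBig)
  frac <- mean(mk$snp$class == "TRANSITION")
  n <- nrow(mk$snp)
  ci <- 2.576 * sqrt(2 / 3 * 1 / 3 / n)
  expect_lt(abs(frac - 2 / 3), ci)
})

test_that("zero planting leaves haplotypes identical to the reference", {
  cfg <- simulationConfig(seed = 9, nGenes = 50, clonesPerTissue = 0,
                          nSNP = 0, ssrPlan = NULL)
  marked <- plantMarkers(generateReference(cfg), cfg)
  for (h in marked$haplotypes)
    expect_identical(as.character(h),
                     as.character(marked$reference$sequences))
  expect_equal(nrow(marked$ssr), 0L)
  expect_equal(nrow(marked$snp), 0L)
})

test_that("error-free reads are exact (rev-complemented) haplotype substrings", {
  sim <- simulateESTStudy(smallCfg())
  rm <- sim$readMap
  seqs <- as.character(estSequences(sim$reads))
  idx <- sample(length(seqs), 200)
  for (i in idx) {
    hap <- as.character(sim$haplotypes[[rm$cultivar[i]]][[rm$gene_id[i]]])
    expected <- substr(hap, rm$start[i], rm$end[i])
    if (rm$strand[i] == "-") expected <- revcomp(expected)
    expect_equal(unname(seqs[i]), expected)
  }
  expect_true(all(rm$n_errors == 0L))
})

test_that("a both-end fraction of 1 gives two reads per full-length clone", {
  cfg <- simulationConfig(seed = 11, nGenes = 40, clonesPerTissue = 60,
                          bothEndFraction = 1, nSNP = 0, ssrPlan = NULL)
  sim <- simulateESTStudy(cfg)
  info <- as.data.frame(readInfo(sim$reads))
  md <- sim$metadata
  flLibs <- md$library_id[md$library_type == "FULL_LENGTH"]
  perClone <- table(info$clone_id[info$library_id %in% flLibs])
  expect_true(all(perClone == 2L))
  stdClones <- table(info$clone_id[!info$library_id %in% flLibs])
  expect_true(all(stdClones == 1L))
})

test_that("clone counts follow the planted per-gene proportions", {
  cfg <- simulationConfig(seed = 13, nGenes = 80, clonesPerTissue = 7000,
                          tissues = "leaf", cultivars = "cvA",
                          nSpecific = 0, nSNP = 0, ssrPlan = NULL,
                          readLengthMin = 40L, readLengthMean = 60,
                          readLengthSd = 5)
  sim <- simulateESTStudy(cfg)
  rm <- sim$readMap[!duplicated(paste(sim$readMap$read_id)), ]
  counts <- table(factor(rm$gene_id, levels = rownames(sim$proportions)))
  n <- sum(counts)
  p <- sim$proportions[, "leaf"]
  # multinomial 99% check per gene with a continuity cushion
  z <- stats::qnorm(0.995)
  dev <- abs(as.integer(counts) - n * p)
  lim <- z * sqrt(n * p * (1 - p)) + 3
  expect_gt(mean(dev <= lim), 0.97)
})

test_that("planted quality tails drive the trimmer as designed", {
  cfg <- simulationConfig(seed = 17, nGenes = 30, clonesPerTissue = 40,
                          tissues = "leaf", cultivars = "cvA",
                          nSpecific = 0, nSNP = 0, ssrPlan = NULL,
                          baseErrorRate = 0.0001,
                          tailLength = 60L, tailErrorRate = 0.2)
  sim <- simulateESTStudy(cfg)
  out <- trimLowQuality(sim$reads)
  w0 <- Biostrings::width(estSequences(sim$reads))
  idx <- match(out$report$read_id,
               as.data.frame(readInfo(sim$reads))$read_id)
  # every read should lose (roughly) its low-quality tail
  expect_true(all(out$report$trimmed_end <= w0[idx] - 60L + 20L))
  expect_true(all(out$report$trimmed_start == 1L))
})
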