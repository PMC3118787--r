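test_that("clone-end pairing classifies concordant, discordant and one-ended clones", {
  reads <- makeReads(rep(randomDNA(120), 4),
                     clone = c("k1", "k1", "k2", "k2"),
                     end = c("5p", "3p", "5p", "3p"))
  mem <- data.frame(read_id = as.data.frame(readInfo(reads))$read_id,
                    unigene_id = c("U1", "U1", "U1", "U2"))
  pr <- pairCloneEnds(reads, mem)
  expect_equal(pr$concordant[pr$clone_id == "k1"], TRUE)
  expect_equal(pr$concordant[pr$clone_id == "k2"], FALSE)

  solo <- makeReads(randomDNA(100), clone = "k3", end = "5p")
  pr3 <- pairCloneEnds(solo, data.frame(
    read_id = as.data.frame(readInfo(solo))$read_id, unigene_id = "U9"))
  expect_true(is.na(pr3$three_prime_unigene))
  expect_false(pr3$concordant)
})

test_that("duplicate (clone, end) reads keep the longest with a warning", {
  reads <- ESTReadSet(c(randomDNA(80), randomDNA(140), randomDNA(90)),
                      read_id = c("r1", "r2", "r3"),
                      clone_id = c("k1", "k1", "k1"),
                      end = c("5p", "5p", "3p"), library_id = "L1")
  mem <- data.frame(read_id = c("r1", "r2", "r3"),
                    unigene_id = c("U2", "U1", "U1"))
  expect_warning(pr <- pairCloneEnds(reads, mem), "longest")
  # the longer 5' read (r2, in U1) wins -> concordant
  expect_true(pr$concordant)
})

test_that("full-length transcripts span 5'-read start to 3'-read end; widest clone wins", {
  set.seed(41)
  tx <- randomDNA(900)
  # clone kA spans [21, 820], clone kB spans [1, 900] (wider)
  rA5 <- substr(tx, 21, 420); rA3 <- revcomp(substr(tx, 401, 820))
  rB5 <- substr(tx, 1, 450); rB3 <- revcomp(substr(tx, 430, 900))
  reads <- makeReads(c(rA5, rA3, rB5, rB3),
                     clone = c("kA", "kA", "kB", "kB"),
                     end = c("5p", "3p", "5p", "3p"))
  md <- makeMetadata("L1")
  ug <- clusterReads(reads)
  expect_length(ug, 1L)
  pr <- pairCloneEnds(reads, ug)
  expect_true(all(pr$concordant))
  fl <- callFullLength(ug, pr, reads, md)
  expect_length(fl, 1L)
  ann <- as.data.frame(transcriptAnnotation(fl))
  expect_equal(ann$clone_id, "kB")
  expect_equal(ann$length, 900L)
  expect_equal(unname(as.character(transcriptSequences(fl))), tx)

  # clones from standard libraries do not qualify
  mdStd <- makeMetadata("L1", library_type = "STANDARD")
  expect_length(callFullLength(ug, pr, reads, mdStd), 0L)
})

test_that("unigenes with only 5' reads yield no transcript", {
  set.seed(43)
  reads <- makeReads(c(randomDNA(200)), clone = "k1", end = "5p")
  ug <- clusterReads(reads)
  pr <- pairCloneEnds(reads, ug)
  fl <- callFullLength(ug, pr, reads, makeMetadata("L1"))
  expect_length(fl, 0L)
})

test_that("predictCDS finds the documented ORFs", {
  # spec'd worked example: ORF ATG AAA TAA inside GGATGAAATAAGG
  got <- predictCDS("GGATGAAATAAGG", minOrf = 6L)
  expect_equal(c(got$cds_start, got$cds_end), c(3L, 11L))
  expect_equal(got$flags, character(0))
  cds <- substr("GGATGAAATAAGG", got$cds_start, got$cds_end)
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(cds))), "MK*")

  # a CDS spanning the whole sequence leaves empty UTRs
  whole <- predictCDS("ATGTAA", minOrf = 6L)
  expect_equal(c(whole$cds_start, whole$cds_end), c(1L, 6L))

  # ATG-initiated frame reaching the end without a stop -> NO_STOP
  ns <- predictCDS(paste0("CC", "ATG", strrep("GCA", 40)), minOrf = 90L)
  expect_equal(ns$flags, "NO_STOP")
  expect_equal(ns$cds_start, 3L)

  # no qualifying ORF at all -> NON_CODING
  nc <- predictCDS("CCCCCCCCCC", minOrf = 9L)
  expect_true(is.na(nc$cds_start))
  expect_equal(nc$flags, "NON_CODING")
})

test_that("predictCDS agrees with the exhaustive ATG..stop enumerator", {
  set.seed(47)
  for (i in 1:150) {
    s <- randomDNA(sample(60:400, 1))
    got <- predictCDS(s, minOrf = 30L)
    exp <- oracleORF(s, minOrf = 30L)
    expect_equal(got[c("cds_start", "cds_end")],
                 exp[c("cds_start", "cds_end")], info = s)
    expect_equal(got$flags, exp$flags, info = s)
  }
})

test_that("UTR extraction partitions every coding transcript exactly", {
  seqs <- Biostrings::DNAStringSet(c(T1 = "GGATGAAATAAGG",
                                     T2 = "ATGTAA"))
  ann <- S4Vectors::DataFrame(transcript_id = c("T1", "T2"),
                              unigene_id = c("U1", "U2"),
                              clone_id = c("k1", "k2"),
                              length = c(13L, 6L),
                              cds_start = NA_integer_,
                              cds_end = NA_integer_,
                              utr5_length = NA_integer_,
                              utr3_length = NA_integer_, flags = "")
  fl <- annotateTranscripts(new("FullLengthSet", sequences = seqs,
                                annotation = ann), minOrf = 6L)
  utr <- extractUTRs(fl)
  expect_equal(utr$utr5_length, c(2L, 0L))
  expect_equal(utr$utr3_length, c(2L, 0L))
  a <- as.data.frame(transcriptAnnotation(fl))
  expect_equal(a$utr5_length + (a$cds_end - a$cds_start + 1L) +
                 a$utr3_length, a$length)
})

test_that("codon usage counts, stop composition and GC are exact on known sets", {
  cu <- codonUsage(c("ATGAAATAA"))
  tab <- cu$table
  expect_equal(tab$count[tab$codon == "ATG"], 1L)
  expect_equal(tab$count[tab$codon == "AAA"], 1L)
  expect_equal(tab$count[tab$codon == "TAA"], 1L)
  expect_equal(sum(tab$count), 3L)
  expect_equal(unname(cu$stop_composition["TAA"]), 1.0)

  cu2 <- codonUsage(c("ATGTAA", "ATGTGA"))
  expect_equal(unname(cu2$stop_composition[c("TAA", "TGA")]), c(0.5, 0.5))

  expect_equal(codonUsage("ATGGGCTAA")$gc_content, 4 / 9)

  bad <- Biostrings::DNAStringSet(c(Tx = "ATGA"))
  expect_error(codonUsage(bad), "Tx")
})

test_that("codon table fractions renormalize and are order-invariant", {
  set.seed(53)
  cdss <- vapply(1:20, function(i) {
    paste0("ATG", paste(oracleSafeCodons(sample(10:40, 1)), collapse = ""),
           "TAA")
  }, character(1))
  cu1 <- codonUsage(cdss)
  cu2 <- codonUsage(rev(cdss))
  expect_equal(cu1$table$count, cu2$table$count)
  fam <- tapply(cu1$table$family_fraction, cu1$table$aa, sum)
  fam <- fam[!is.na(fam)]
  expect_true(all(abs(fam - 1) < 1e-9))
  expect_equal(sum(cu1$table$per_1000), 1000)
})

test_that("size distributions summarize and tolerate empty input", {
  seqs <- Biostrings::DNAStringSet(c(T1 = randomDNA(1230)))
  ann <- S4Vectors::DataFrame(transcript_id = "T1", unigene_id = "U1",
                              clone_id = "k", length = 1230L,
                              cds_start = NA_integer_, cds_end = NA_integer_,
                              utr5_length = NA_integer_,
                              utr3_length = NA_integer_, flags = "")
  fl <- new("FullLengthSet", sequences = seqs, annotation = ann)
  d <- sizeDistributions(fl)
  expect_equal(d$summary$mean[d$summary$class == "transcript"], 1230)

  empty <- new("FullLengthSet", sequences = Biostrings::DNAStringSet(),
               annotation = ann[0, ])
  d0 <- sizeDistributions(empty)
  expect_equal(nrow(d0$bins), 0L)
  expect_equal(d0$summary$n, rep(0L, 4))
})
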