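test_that("assembly summary computes class means and the member histogram", {
  members <- data.frame(
    read_id = sprintf("r%d", 1:5),
    unigene_id = c("U1", "U2", "U3", "U3", "U3"),
    strand = "+", offset = 1L,
    aligned = c("A", "A", "ACG", "ACG", "ACG"), stringsAsFactors = FALSE)
  ug <- UnigeneSet(c(U1 = strrep("A", 100), U2 = strrep("C", 200),
                     U3 = strrep("G", 300)), members)
  sm <- summarizeAssembly(ug)
  s <- sm$stats
  expect_equal(s$n[s$class == "singleton"], 2L)
  expect_equal(s$n[s$class == "contig"], 1L)
  expect_equal(s$mean_length[s$class == "singleton"], 150)
  # contigs + singletons = unigenes
  expect_equal(s$n[s$class == "unigene"],
               s$n[s$class == "singleton"] + s$n[s$class == "contig"])
  expect_equal(sm$members_histogram$n_unigenes[
    sm$members_histogram$n_members == 1L], 2L)
})

test_that("a deeply covered unigene lands in the top histogram bin", {
  n <- 2054L
  members <- data.frame(read_id = sprintf("r%04d", 1:n),
                        unigene_id = "U1", strand = "+", offset = 1L,
                        aligned = "ACGT", stringsAsFactors = FALSE)
  ug <- UnigeneSet(c(U1 = "ACGT"), members)
  h <- summarizeAssembly(ug)$members_histogram
  expect_equal(max(h$n_members), n)
  expect_equal(h$n_unigenes[h$n_members == n], 1L)
})

test_that("library table aggregation reproduces subtotals and grand totals", {
  f <- system.file("extdata", "published", "cdna_libraries.tsv",
                   package = "ESTpipe")
  libs <- utils::read.delim(f, check.names = FALSE)
  got <- summarizeLibraryTable(libs)
  expect_equal(got$total[got$group == "FULL_LENGTH"], 71577L)
  expect_equal(got$total[got$group == "STANDARD"], 22179L)
  expect_equal(got$n5[got$group == "TOTAL"], 91375L)
  expect_equal(got$n3[got$group == "TOTAL"], 2381L)
  expect_equal(got$total[got$group == "TOTAL"], 93756L)
})

test_that("unigene class statistics combine into the full table", {
  f <- system.file("extdata", "published", "unigene_classes.tsv",
                   package = "ESTpipe")
  cls <- utils::read.delim(f)
  got <- combineUnigeneClassStats(cls)
  expect_equal(got$n[got$class == "unigene"], 24444L)
  expect_equal(got$total_bases[got$class == "unigene"], 18984770)
  expect_equal(got$mean_length[got$class == "unigene"], 776.7,
               tolerance = 1e-4)
})

test_that("SNP type aggregation classifies and sums like the summary table", {
  f <- system.file("extdata", "published", "snp_types.tsv",
                   package = "ESTpipe")
  types <- utils::read.delim(f)
  agg <- aggregateSnpTable(types)
  expect_equal(unname(agg$subtotals["transition"]), 1972L)
  expect_equal(unname(agg$subtotals["transversion"]), 976L)
  expect_equal(unname(agg$subtotals["indel"]), 125L)
  expect_equal(agg$total, 3073L)
  expect_equal(sum(agg$subtotals), agg$total)
  # classification of the ten printed types matches classifyVariant
  for (i in seq_len(nrow(agg$types))) {
    al <- trimws(strsplit(agg$types$type[i], "->")[[1]])
    expect_equal(agg$types$class[i],
                 tolower(classifyVariant(al[1], al[2])))
  }
  expect_equal(aggregateSnpTable(c(`A -> G` = 7))$subtotals[["transition"]],
               7L)
  expect_error(aggregateSnpTable(c(`A~G` = 7)), "unrecognized")
})

test_that("ssr unit table totals add up", {
  f <- system.file("extdata", "published", "ssr_unit_sizes.tsv",
                   package = "ESTpipe")
  tab <- utils::read.delim(f)
  tot <- ssrTableTotals(tab)
  expect_equal(tot$count[tot$unit_size == "total"], 4068L)
})

test_that("the pipeline driver reconciles its run summary with the artifacts", {
  sc <- .smallScenario()
  res <- sc$res
  expect_equal(unname(res$summary["reads_in"]), length(sc$sim$reads))
  expect_equal(unname(res$summary["unigenes"]), length(res$unigenes))
  expect_equal(unname(res$summary["contigs"] + res$summary["singletons"]),
               length(res$unigenes))
  expect_equal(unname(res$summary["tissue_specific_calls"]),
               nrow(res$expression$calls))
  expect_equal(unname(res$summary["ssr_loci"]), length(res$ssr$loci))
  expect_equal(unname(res$summary["snp_pass"]),
               sum(res$snp$candidates$status == "PASS"))
  expect_equal(unname(res$summary["full_length_transcripts"]),
               length(res$fullLength))

  # artifact files match the in-memory objects
  outDir <- tempfile()
  ESTpipe:::.writeArtifacts(res, outDir)
  mem <- utils::read.delim(file.path(outDir, "membership.tsv"))
  expect_equal(nrow(mem), nrow(unigeneMembers(res$unigenes)))
  calls <- utils::read.delim(file.path(outDir, "tissue_specific_calls.tsv"))
  expect_equal(nrow(calls), nrow(res$expression$calls))
})

test_that("re-running the pipeline with the same seed reproduces the summary", {
  cfg <- simulationConfig(seed = 5, nGenes = 60, clonesPerTissue = 80,
                          nSpecific = 2, nSNP = 10,
                          ssrPlan = data.frame(motif = "AAG", repeats = 6L,
                                               count = 3L))
  r1 <- runPipeline(cfg)
  r2 <- runPipeline(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(as.character(consensusSequences(r1$unigenes)),
                   as.character(consensusSequences(r2$unigenes)))
})
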