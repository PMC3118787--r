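# Study-level reporting: assembly statistics, published-table shaped
# aggregations, and the end-to-end pipeline driver.

#' Assembly summary (singletons / contigs / all unigenes)
#'
#' @param unigenes A \link{UnigeneSet}.
#' @return A list with \code{stats} (data.frame rows singleton, contig,
#'   unigene: n, mean_length, total_bases) and \code{members_histogram}
#'   (data.frame: n_members, n_unigenes — the EST-per-unigene
#'   distribution).
#' @export
summarizeAssembly <- function(unigenes) {
  singleton <- isSingleton(unigenes)
  w <- Biostrings::width(consensusSequences(unigenes))
  cls <- list(singleton = w[singleton], contig = w[!singleton], unigene = w)
  stats <- do.call(rbind, lapply(names(cls), function(k) {
    v <- cls[[k]]
    data.frame(class = k, n = length(v),
               mean_length = if (length(v)) mean(v) else NA_real_,
               total_bases = sum(as.numeric(v)), stringsAsFactors = FALSE)
  }))
  sizes <- table(table(unigeneMembers(unigenes)$unigene_id))
  hist <- data.frame(n_members = as.integer(names(sizes)),
                     n_unigenes = as.integer(sizes))
  list(stats = stats, members_histogram = hist)
}

#' Aggregate a cDNA library read-count table
#'
#' Sums 5'/3'/total read counts per library type and overall — the
#' totals row of the classic library description table.
#'
#' @param libraries data.frame with columns \code{library_id},
#'   \code{library_type} and the per-library read counts \code{n5},
#'   \code{n3}.
#' @return data.frame rows FULL_LENGTH, STANDARD, TOTAL with n5, n3,
#'   total.
#' @export
summarizeLibraryTable <- function(libraries) {
  need <- c("library_id", "library_type", "n5", "n3")
  if (!all(need %in% colnames(libraries)))
    stop("library table must have columns: ", paste(need, collapse = ", "))
  one <- function(type, rows) {
    data.frame(group = type, n5 = sum(rows$n5), n3 = sum(rows$n3),
               total = sum(rows$n5) + sum(rows$n3),
               stringsAsFactors = FALSE)
  }
  rbind(one("FULL_LENGTH",
            libraries[libraries$library_type == "FULL_LENGTH", ]),
        one("STANDARD", libraries[libraries$library_type == "STANDARD", ]),
        one("TOTAL", libraries))
}

#' Combine unigene class statistics into the full table
#'
#' From printed (or computed) per-class sequence counts and total bases
#' for singletons and contigs, derives the combined unigene row and the
#' mean lengths — the shape of the classic unigene statistics table.
#'
#' @param classStats data.frame with columns \code{class} (containing
#'   "singleton" and "contig"), \code{n}, \code{total_bases}.
#' @return data.frame rows singleton, contig, unigene with n,
#'   total_bases, mean_length.
#' @export
combineUnigeneClassStats <- function(classStats) {
  need <- c("class", "n", "total_bases")
  if (!all(need %in% colnames(classStats)))
    stop("class stats must have columns: ", paste(need, collapse = ", "))
  s <- classStats[match(c("singleton", "contig"), classStats$class), ]
  if (anyNA(s$n)) stop("both 'singleton' and 'contig' rows are required")
  out <- rbind(s[, need],
               data.frame(class = "unigene", n = sum(s$n),
                          total_bases = sum(s$total_bases)))
  out$mean_length <- out$total_bases / out$n
  rownames(out) <- NULL
  out
}

#' Totals of an SSR unit-size count table
#'
#' @param unitCounts data.frame with columns \code{unit_size} and
#'   \code{count}.
#' @return The input with an appended total row.
#' @export
ssrTableTotals <- function(unitCounts) {
  if (!all(c("unit_size", "count") %in% colnames(unitCounts)))
    stop("unit count table must have columns unit_size, count")
  rbind(data.frame(unit_size = as.character(unitCounts$unit_size),
                   count = unitCounts$count, stringsAsFactors = FALSE),
        data.frame(unit_size = "total", count = sum(unitCounts$count)))
}

#' Aggregate per-type SNP counts into class subtotals
#'
#' Takes counts per allele-pair type (labels like \code{"A -> G"} or
#' \code{"T -> -"}), classifies every type with
#' \code{\link{classifyVariant}} and sums the transition, transversion
#' and indel subtotals and the grand total — the shape of the classic
#' SNP statistics table.
#'
#' @param typeCounts Named integer vector (or data.frame with
#'   \code{type}, \code{count}).
#' @return A list with \code{types} (type, class, count),
#'   \code{subtotals} (named: transition, transversion, indel) and
#'   \code{total}.
#' @export
aggregateSnpTable <- function(typeCounts) {
  if (is.data.frame(typeCounts)) {
    counts <- stats::setNames(typeCounts$count, typeCounts$type)
  } else counts <- typeCounts
  parse1 <- function(lbl) {
    parts <- strsplit(lbl, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("unrecognized SNP type label: ", lbl)
    trimws(parts)
  }
  al <- t(vapply(names(counts), parse1, character(2)))
  cls <- tolower(classifyVariant(al[, 1], al[, 2]))
  types <- data.frame(type = names(counts), class = cls,
                      count = as.integer(counts), stringsAsFactors = FALSE,
                      row.names = NULL)
  subtotals <- c(transition = sum(types$count[cls == "transition"]),
                 transversion = sum(types$count[cls == "transversion"]),
                 indel = sum(types$count[cls == "indel"]))
  list(types = types, subtotals = subtotals, total = sum(types$count))
}

#' Run the full EST analysis pipeline on a synthetic study
#'
#' Simulates a study (unless one is supplied), then runs preprocessing,
#' clustering, clone-end pairing and full-length transcript calling,
#' digital expression with tissue-specificity calls, SSR scanning and
#' cross-cultivar SNP discovery, and assembles a run summary whose
#' counts reconcile with the produced objects.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param sim Optional pre-generated study (from
#'   \code{\link{simulateESTStudy}}); when given, \code{config} is only
#'   used for analysis parameters.
#' @param minPairTotal,minRatio,maxFDR Tissue-specificity parameters.
#' @param seedLength Clustering seed length (default 40 =
#'   \code{minOverlap}).
#' @param minOverlap,minIdentity Clustering thresholds.
#' @param minOrf Minimum ORF length for CDS prediction.
#' @param outDir Optional directory; when given, the main artifacts
#'   (clean reads FASTQ, unigene FASTA, membership TSV, tests/calls TSV,
#'   SSR and SNP TSV, summary JSON-like TSVs) are written there.
#' @return A list: sim, clean (preprocessed reads + report), unigenes,
#'   pairings, fullLength, codon, expression (matrix, tests, calls),
#'   ssr (loci, summary), snp (candidates, summary), summary (named
#'   counts), parameters.
#' @export
runPipeline <- function(config = simulationConfig(), sim = NULL,
                        minPairTotal = 5L, minRatio = 2, maxFDR = 0.05,
                        seedLength = NULL, minOverlap = 40L,
                        minIdentity = 0.97, minOrf = 90L, outDir = NULL) {
  if (is.null(sim)) sim <- simulateESTStudy(config)
  clean <- preprocessReads(sim$reads)
  unigenes <- clusterReads(clean$reads, minOverlap = minOverlap,
                           minIdentity = minIdentity,
                           seedLength = seedLength)
  pairings <- pairCloneEnds(clean$reads, unigenes)
  fl <- callFullLength(unigenes, pairings, clean$reads, sim$metadata,
                       minOrf = minOrf)
  codon <- codonUsage(cdsSequences(fl)[
    !grepl("NO_STOP", transcriptAnnotation(fl)$flags)])
  mat <- buildCountMatrix(unigenes, clean$reads, sim$metadata)
  expr <- callTissueSpecific(mat, minPairTotal = minPairTotal,
                             minRatio = minRatio, maxFDR = maxFDR)
  loci <- scanSSRs(consensusSequences(unigenes))
  snps <- detectSNPs(unigenes, sim$metadata, reads = clean$reads)
  asmStats <- summarizeAssembly(unigenes)
  snpSum <- snpSummary(snps)
  ssrSum <- ssrSummary(loci)
  summary <- c(
    reads_in = length(sim$reads), reads_kept = length(clean$reads),
    unigenes = length(unigenes),
    contigs = asmStats$stats$n[asmStats$stats$class == "contig"],
    singletons = asmStats$stats$n[asmStats$stats$class == "singleton"],
    clones = nrow(pairings), concordant_clones = sum(pairings$concordant),
    full_length_transcripts = length(fl),
    expression_tests = nrow(expr$tests),
    tissue_specific_calls = nrow(expr$calls),
    ssr_loci = length(loci), snp_pass = snpSum$total)
  out <- list(sim = sim, clean = clean, unigenes = unigenes,
              pairings = pairings, fullLength = fl, codon = codon,
              expression = c(list(matrix = mat), expr),
              ssr = list(loci = loci, summary = ssrSum),
              snp = list(candidates = snps, summary = snpSum),
              assembly = asmStats, summary = summary,
              parameters = list(minPairTotal = minPairTotal,
                                minRatio = minRatio, maxFDR = maxFDR,
                                minOverlap = minOverlap,
                                minIdentity = minIdentity,
                                seedLength = seedLength, minOrf = minOrf,
                                seed = config$seed))
  if (!is.null(outDir)) .writeArtifacts(out, outDir)
  out
}

.writeArtifacts <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeESTFastq(res$clean$reads, file.path(outDir, "clean.fastq"))
  cons <- consensusSequences(res$unigenes)
  Biostrings::writeXStringSet(cons, file.path(outDir, "unigenes.fa"))
  utils::write.table(as.data.frame(membershipTable(res$unigenes)),
                     file.path(outDir, "membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLibraryMetadata(res$sim$metadata, file.path(outDir, "libraries.tsv"))
  utils::write.table(res$expression$tests,
                     file.path(outDir, "expression_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$expression$calls,
                     file.path(outDir, "tissue_specific_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$ssr$loci),
                     file.path(outDir, "ssr_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(res$ssr$loci))
    writeGFF3(ssrToGFF(res$ssr$loci), file.path(outDir, "ssr_loci.gff3"))
  utils::write.table(res$snp$candidates,
                     file.path(outDir, "snp_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(res$fullLength)) {
    Biostrings::writeXStringSet(transcriptSequences(res$fullLength),
                                file.path(outDir, "full_length.fa"))
    utils::write.table(as.data.frame(transcriptAnnotation(res$fullLength)),
                       file.path(outDir, "full_length.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(key = names(res$summary), value = unname(res$summary)),
    file.path(outDir, "run_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(outDir)
}
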