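# Seed-driven synthetic EST study generator: reference transcripts with
# known UTR/CDS structure, planted SSR motifs and cross-cultivar SNPs,
# and clone-end read simulation across multi-tissue cDNA libraries, with
# machine-readable truth tables for every planted feature.

#' Configuration of a synthetic EST study
#'
#' Defaults describe the study conditions the package is validated
#' against: 2,000 genes across 7 tissues (leaf, flower, fruit, phloem,
#' cotyledon, callus, root) and 4 cultivars, transcripts with mean 5'/3'
#' UTR lengths of 167 and 254 bases and mean CDS length ~814 bases
#' (so mean transcript length ~1,230), coding GC content 45.6%, stop
#' codon usage TGA/TAA/TAG = 44.9/37.2/17.9%, 3,000 clones per tissue
#' with log-normally skewed per-gene abundance, 20 planted 20-fold
#' tissue-specific genes, ~100 planted SSR loci, 300 planted fixed
#' cultivar SNPs (transition:transversion 2:1, no indels by default),
#' Sanger-like 650 +/- 60 base reads, and error-free bases (Q40).
#'
#' @param seed Integer seed; fixes all randomness.
#' @param nGenes Number of reference genes.
#' @param cdsMeanLength,cdsSdLog Log-normal CDS length (bases; rounded to
#'   codons, minimum \code{cdsMinLength}).
#' @param cdsMinLength Minimum CDS length in bases.
#' @param utr5Mean,utr3Mean,utrSdLog,utrMin Log-normal UTR lengths.
#' @param gcCoding,gcUtr GC content of coding / untranslated bases.
#' @param stopWeights Sampling weights of the TAA/TAG/TGA stop codons.
#' @param tissues,cultivars Tissue and cultivar panels.
#' @param clonesPerTissue Clones sequenced per tissue (split over that
#'   tissue's libraries).
#' @param nSpecific,specificFold Number of planted tissue-specific genes
#'   and their fold-change over baseline.
#' @param specificBaseWeight Baseline abundance weight assigned to the
#'   planted specific genes (on the scale of the log-normal weights,
#'   whose median is 1).
#' @param abundanceSdLog Log-sd of the skewed per-gene abundance weights.
#' @param ssrPlan data.frame(motif, repeats, count) of SSR loci to plant
#'   (inserted into 5' UTRs).
#' @param nSNP Number of planted fixed SNP sites.
#' @param snpClassWeights Sampling weights c(transition, transversion,
#'   indel) of planted variant classes.
#' @param readLengthMean,readLengthSd,readLengthMin Read length model.
#' @param jitter5,jitter3 Mean (Poisson) start/end jitter of 5'/3' reads.
#' @param bothEndFraction Probability that a full-length-library clone is
#'   also sequenced from the 3' end.
#' @param baseErrorRate Per-base sequencing error rate.
#' @param tailLength,tailErrorRate Optional low-quality read tail: the
#'   final \code{tailLength} bases get error rate \code{tailErrorRate}
#'   (and matching qualities), emulating the decaying 3' quality of
#'   Sanger traces.
#' @return A \code{SimulationConfig} list.
#' @export
simulationConfig <- function(
    seed = 1L,
    nGenes = 2000L,
    cdsMeanLength = 814, cdsSdLog = 0.45, cdsMinLength = 150L,
    utr5Mean = 167, utr3Mean = 254, utrSdLog = 0.6, utrMin = 10L,
    gcCoding = 0.4561, gcUtr = 0.35,
    stopWeights = c(TAA = 0.372, TAG = 0.179, TGA = 0.449),
    tissues = c("leaf", "flower", "fruit", "phloem", "cotyledon", "callus",
                "root"),
    cultivars = c("Dulce", "PI161375", "PieldeSapo", "Vedrantais"),
    clonesPerTissue = 3000L,
    nSpecific = 20L, specificFold = 20,
    specificBaseWeight = 1.5,
    abundanceSdLog = 1.0,
    ssrPlan = data.frame(
      motif = c("AAG", "AG", "AT", "AAT", "AAAT", "AACCG", "AACGTC"),
      repeats = c(6L, 7L, 6L, 5L, 5L, 5L, 5L),
      count = c(40L, 30L, 12L, 8L, 5L, 3L, 3L),
      stringsAsFactors = FALSE),
    nSNP = 300L,
    snpClassWeights = c(transition = 2, transversion = 1, indel = 0),
    readLengthMean = 650, readLengthSd = 60, readLengthMin = 300L,
    jitter5 = 5, jitter3 = 5,
    bothEndFraction = 0.15,
    baseErrorRate = 0,
    tailLength = 0L, tailErrorRate = 0.2) {
  cfg <- as.list(environment())
  stopifnot(baseErrorRate >= 0, baseErrorRate <= 1,
            bothEndFraction >= 0, bothEndFraction <= 1,
            nGenes >= 1, clonesPerTissue >= 0, specificFold > 0)
  if (cdsMinLength < 6L) stop("CDS must have at least 2 codons")
  structure(cfg, class = "SimulationConfig")
}

.cultivarCode <- function(cultivar) {
  toupper(substr(gsub("[^A-Za-z0-9]", "", cultivar), 1, 3))
}

#' Default cDNA library panel of a simulated study
#'
#' Full-length enriched fruit and flower libraries for every cultivar,
#' full-length leaf/root/cotyledon libraries from one cultivar, standard
#' callus libraries for every cultivar and one standard phloem library —
#' mirroring the multi-tissue, multi-cultivar layout of Sanger EST
#' projects. No library is normalized.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return Library metadata data.frame.
#' @export
defaultLibraries <- function(config) {
  rows <- list()
  add <- function(tissue, cultivar, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      library_id = paste0(toupper(substr(tissue, 1, 3)), "_",
                          .cultivarCode(cultivar)),
      cultivar = cultivar, tissue = tissue, normalized = FALSE,
      library_type = type, stringsAsFactors = FALSE)
  }
  cv <- config$cultivars
  for (tissue in intersect(c("fruit", "flower"), config$tissues))
    for (cc in cv) add(tissue, cc, "FULL_LENGTH")
  solo <- cv[min(3L, length(cv))]
  for (tissue in intersect(c("leaf", "root", "cotyledon"), config$tissues))
    add(tissue, solo, "FULL_LENGTH")
  if ("callus" %in% config$tissues)
    for (cc in cv) add("callus", cc, "STANDARD")
  if ("phloem" %in% config$tissues) add("phloem", cv[1L], "STANDARD")
  extra <- setdiff(config$tissues,
                   c("fruit", "flower", "leaf", "root", "cotyledon",
                     "callus", "phloem"))
  for (tissue in extra) add(tissue, cv[1L], "FULL_LENGTH")
  do.call(rbind, rows)
}

.codonWeights <- function(gc) {
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(codons, function(cd) {
    prod(pb[strsplit(cd, "")[[1]]])
  }, numeric(1))
  list(codons = codons, w = w,
       gc = vapply(codons, function(cd) {
         sum(strsplit(cd, "")[[1]] %in% c("G", "C")) / 3
       }, numeric(1)))
}

.sampleCodingCodons <- function(n, gc) {
  # conditioning on non-stop codons slightly enriches G/C; solve for the
  # per-base GC that makes the expected codon GC hit the target
  expectedGC <- function(t) {
    cw <- .codonWeights(t)
    sum(cw$w * cw$gc) / sum(cw$w) - gc
  }
  t0 <- stats::uniroot(expectedGC, c(0.01, 0.99), tol = 1e-6)$root
  cw <- .codonWeights(t0)
  sample(cw$codons, n, replace = TRUE, prob = cw$w)
}

#' Generate reference transcripts with known structure
#'
#' Each gene is built as \code{UTR5 + ATG ... stop + UTR3}: an in-frame
#' CDS with no internal stop codon, flanked by untranslated regions with
#' the configured length distributions. Deterministic per seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A list with \code{sequences} (DNAStringSet named by gene id)
#'   and \code{annotation} (gene_id, length, utr5_length, cds_start,
#'   cds_end, utr3_length; 1-based inclusive CDS bounds, stop included).
#' @export
generateReference <- function(config) {
  set.seed(config$seed)
  n <- config$nGenes
  rln <- function(meanv, sdlog, minv) {
    pmax(round(stats::rlnorm(n, log(meanv) - sdlog^2 / 2, sdlog)),
         minv)
  }
  u5 <- rln(config$utr5Mean, config$utrSdLog, config$utrMin)
  u3 <- rln(config$utr3Mean, config$utrSdLog, config$utrMin)
  nCodons <- pmax(round(rln(config$cdsMeanLength, config$cdsSdLog,
                            config$cdsMinLength) / 3), 2L)
  stops <- sample(names(config$stopWeights), n, replace = TRUE,
                  prob = config$stopWeights)
  seqs <- vapply(seq_len(n), function(i) {
    body <- if (nCodons[i] > 2L)
      paste(.sampleCodingCodons(nCodons[i] - 2L, config$gcCoding),
            collapse = "") else ""
    paste0(.randomDNA(1, u5[i], config$gcUtr),
           "ATG", body, stops[i],
           .randomDNA(1, u3[i], config$gcUtr))
  }, character(1))
  ids <- sprintf("G%05d", seq_len(n))
  sset <- Biostrings::DNAStringSet(seqs)
  names(sset) <- ids
  ann <- data.frame(gene_id = ids, length = nchar(seqs),
                    utr5_length = u5, cds_start = u5 + 1L,
                    cds_end = u5 + 3L * nCodons, utr3_length = u3,
                    stringsAsFactors = FALSE)
  list(sequences = sset, annotation = ann)
}

.otherBase <- function(base, transition) {
  tr <- c(A = "G", G = "A", C = "T", T = "C")
  if (transition) return(unname(tr[base]))
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  sample(tv[[base]], 1L)
}

#' Plant SSR motifs and cultivar SNPs into the reference
#'
#' SSR tandems are inserted into 5' UTRs of distinct genes (one per
#' gene), bracketed by guard bases chosen so the planted run is maximal
#' and starts exactly at the recorded coordinate. Fixed SNP differences
#' are then applied to one randomly chosen cultivar per site, at
#' positions that avoid planted SSRs and other SNP sites, with classes
#' drawn from the configured transition:transversion:indel weights
#' (an indel is a single-base deletion in the alternate cultivar). No
#' two planted features overlap; sites that cannot be placed are skipped
#' with a warning and the truth tables reflect what was actually
#' planted. Deterministic per seed.
#'
#' @param reference Output of \code{\link{generateReference}}.
#' @param config A \code{\link{simulationConfig}}.
#' @return A list: \code{reference} (SSR-bearing sequences + updated
#'   annotation), \code{haplotypes} (named list cultivar ->
#'   DNAStringSet), \code{ssr} truth (gene_id, start, end, motif,
#'   unit_size, repeat_count) and \code{snp} truth (gene_id, position,
#'   ref_allele, alt_allele, cultivar, class) in reference transcript
#'   coordinates.
#' @export
plantMarkers <- function(reference, config) {
  set.seed(config$seed + 1L)
  seqs <- as.character(reference$sequences)
  ann <- reference$annotation
  n <- length(seqs)

  # --- SSRs into 5' UTRs -------------------------------------------------
  plan <- config$ssrPlan
  ssrRows <- list()
  if (!is.null(plan) && nrow(plan) && sum(plan$count) > 0) {
    wanted <- rep(seq_len(nrow(plan)), plan$count)
    if (length(wanted) > n)
      stop("more SSR loci requested than genes available")
    genes <- sample(n, length(wanted))
    for (j in seq_along(wanted)) {
      g <- genes[j]
      motif <- toupper(plan$motif[wanted[j]])
      reps <- plan$repeats[wanted[j]]
      u <- nchar(motif)
      tandem <- strrep(motif, reps)
      lastB <- substr(motif, u, u); firstB <- substr(motif, 1, 1)
      gl <- sample(setdiff(c("A", "C", "G", "T"), lastB), 1L)
      gr <- sample(setdiff(c("A", "C", "G", "T"), firstB), 1L)
      ins <- paste0(gl, tandem, gr)
      # insert after a position inside the 5' UTR (keep 2 bases of UTR edge)
      u5 <- ann$utr5_length[g]
      at <- if (u5 > 4L) sample(2:(u5 - 2L), 1L) else 1L
      seqs[g] <- paste0(substr(seqs[g], 1, at), ins,
                        substr(seqs[g], at + 1L, nchar(seqs[g])))
      shift <- nchar(ins)
      ann$utr5_length[g] <- ann$utr5_length[g] + shift
      ann$cds_start[g] <- ann$cds_start[g] + shift
      ann$cds_end[g] <- ann$cds_end[g] + shift
      ann$length[g] <- ann$length[g] + shift
      ssrRows[[j]] <- data.frame(
        gene_id = ann$gene_id[g], start = at + 2L,
        end = at + 1L + reps * u, motif = motif, unit_size = u,
        repeat_count = reps, stringsAsFactors = FALSE)
    }
  }
  ssr <- if (length(ssrRows)) do.call(rbind, ssrRows) else
    data.frame(gene_id = character(0), start = integer(0), end = integer(0),
               motif = character(0), unit_size = integer(0),
               repeat_count = integer(0), stringsAsFactors = FALSE)

  # --- SNPs between cultivars --------------------------------------------
  classes <- c("transition", "transversion", "indel")
  w <- config$snpClassWeights
  snpRows <- list()
  taken <- lapply(seq_len(n), function(i) integer(0))
  blocked <- split(ssr, ssr$gene_id)
  if (config$nSNP > 0) {
    geneDraw <- sample(n, config$nSNP, replace = TRUE)
    clsDraw <- sample(classes, config$nSNP, replace = TRUE, prob = w)
    cvDraw <- sample(config$cultivars, config$nSNP, replace = TRUE)
    for (j in seq_len(config$nSNP)) {
      g <- geneDraw[j]
      L <- nchar(seqs[g])
      bl <- blocked[[ann$gene_id[g]]]
      ok <- FALSE
      for (try in 1:20) {
        p <- sample(5:(L - 5L), 1L)
        if (p %in% taken[[g]]) next
        if (!is.null(bl) &&
            any(p >= bl$start - 6L & p <= bl$end + 6L)) next
        ok <- TRUE; break
      }
      if (!ok) next
      taken[[g]] <- c(taken[[g]], p)
      ref <- substr(seqs[g], p, p)
      cls <- clsDraw[j]
      alt <- if (cls == "indel") "-" else
        .otherBase(ref, cls == "transition")
      snpRows[[length(snpRows) + 1L]] <- data.frame(
        gene_id = ann$gene_id[g], position = p, ref_allele = ref,
        alt_allele = alt, cultivar = cvDraw[j], class = toupper(cls),
        stringsAsFactors = FALSE)
    }
    if (length(snpRows) < config$nSNP)
      warning(config$nSNP - length(snpRows),
              " SNP site(s) could not be placed and were skipped")
  }
  snp <- if (length(snpRows)) do.call(rbind, snpRows) else
    data.frame(gene_id = character(0), position = integer(0),
               ref_allele = character(0), alt_allele = character(0),
               cultivar = character(0), class = character(0),
               stringsAsFactors = FALSE)

  # --- build per-cultivar haplotypes -------------------------------------
  haplotypes <- lapply(config$cultivars, function(cc) {
    hap <- seqs
    rows <- snp[snp$cultivar == cc, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$gene_id, -rows$position), , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        g <- match(rows$gene_id[i], ann$gene_id)
        p <- rows$position[i]
        if (rows$alt_allele[i] == "-") {
          hap[g] <- paste0(substr(hap[g], 1, p - 1L),
                           substr(hap[g], p + 1L, nchar(hap[g])))
        } else {
          substr(hap[g], p, p) <- rows$alt_allele[i]
        }
      }
    }
    out <- Biostrings::DNAStringSet(hap)
    names(out) <- ann$gene_id
    out
  })
  names(haplotypes) <- config$cultivars
  refOut <- Biostrings::DNAStringSet(seqs)
  names(refOut) <- ann$gene_id
  list(reference = list(sequences = refOut, annotation = ann),
       haplotypes = haplotypes, ssr = ssr, snp = snp)
}

.errorProfile <- function(len, config) {
  e <- rep(config$baseErrorRate, len)
  if (config$tailLength > 0L && len > 0L) {
    tail <- seq.int(max(1L, len - config$tailLength + 1L), len)
    e[tail] <- config$tailErrorRate
  }
  e
}

.qualityString <- function(errs) {
  q <- as.integer(round(pmin(-10 * log10(pmax(errs, 1e-4)), 40)))
  rawToChar(as.raw(q + 33L))
}

.injectErrors <- function(seq, errs) {
  hit <- which(stats::runif(length(errs)) < errs)
  if (!length(hit)) return(list(seq = seq, n = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in hit) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n = length(hit))
}

#' Simulate clone-end reads across the cDNA library panel
#'
#' Clones are drawn per library in proportion to the per-gene abundance
#' weights (planted tissue-specific genes get their fold-change in their
#' target tissue). Every clone yields a 5' read anchored near the
#' transcript start; clones from full-length enriched libraries also
#' yield a reverse-complemented 3' read anchored near the transcript end
#' with probability \code{bothEndFraction}. Base call errors are
#' injected at the configured rate and the Phred quality strings encode
#' the true per-base error probabilities. Deterministic per seed.
#'
#' @param marked Output of \code{\link{plantMarkers}}.
#' @param config A \code{\link{simulationConfig}}.
#' @param libraries Library metadata; defaults to
#'   \code{\link{defaultLibraries}}.
#' @return A list with \code{reads} (\link{ESTReadSet} with qualities),
#'   \code{metadata} (library table), and truth tables: \code{readMap}
#'   (read_id, gene_id, cultivar, start, end, strand, n_errors —
#'   haplotype coordinates), \code{expression} (gene_id, weight,
#'   specific, specific_tissue), and \code{proportions} (gene x tissue
#'   expected sampling proportions).
#' @export
simulateLibraries <- function(marked, config,
                              libraries = defaultLibraries(config)) {
  set.seed(config$seed + 2L)
  ann <- marked$reference$annotation
  n <- config$nGenes
  w <- stats::rlnorm(n, 0, config$abundanceSdLog)
  specIdx <- integer(0)
  specTissue <- character(0)
  if (config$nSpecific > 0) {
    specIdx <- sample(n, config$nSpecific)
    specTissue <- rep(config$tissues, length.out = config$nSpecific)
    w[specIdx] <- config$specificBaseWeight
  }
  props <- vapply(config$tissues, function(t) {
    wt <- w
    wt[specIdx[specTissue == t]] <- wt[specIdx[specTissue == t]] *
      config$specificFold
    wt / sum(wt)
  }, numeric(n))
  rownames(props) <- ann$gene_id

  haps <- lapply(marked$haplotypes, as.character)
  cloneCounter <- 0L
  readRows <- list()
  for (li in seq_len(nrow(libraries))) {
    lib <- libraries[li, ]
    nLibs <- sum(libraries$tissue == lib$tissue)
    nClones <- config$clonesPerTissue %/% nLibs +
      as.integer(which(libraries$library_id[libraries$tissue == lib$tissue]
                       == lib$library_id) == 1L) *
      (config$clonesPerTissue %% nLibs)
    if (nClones < 1L) next
    geneCounts <- as.integer(stats::rmultinom(1L, nClones,
                                              props[, lib$tissue]))
    genes <- rep.int(seq_len(n), geneCounts)
    m <- length(genes)
    hap <- haps[[lib$cultivar]]
    L <- nchar(hap)[genes]
    cloneIds <- sprintf("c%06d", cloneCounter + seq_len(m))
    cloneCounter <- cloneCounter + m
    # 5' reads
    start5 <- pmin(1L + stats::rpois(m, config$jitter5), pmax(L - 50L, 1L))
    len5 <- pmax(round(stats::rnorm(m, config$readLengthMean,
                                    config$readLengthSd)),
                 config$readLengthMin)
    end5 <- pmin(start5 + len5 - 1L, L)
    seq5 <- substring(hap[genes], start5, end5)
    # 3' reads for a subset of full-length clones
    has3 <- lib$library_type == "FULL_LENGTH" &
      stats::runif(m) < config$bothEndFraction
    readRows[[length(readRows) + 1L]] <- data.frame(
      library_id = lib$library_id, clone_id = cloneIds, end = "5p",
      gene = genes, cultivar = lib$cultivar, start = start5, end_pos = end5,
      strand = "+", seq = seq5, stringsAsFactors = FALSE)
    if (any(has3)) {
      i3 <- which(has3)
      end3 <- pmax(L[i3] - stats::rpois(length(i3), config$jitter3), 1L)
      len3 <- pmax(round(stats::rnorm(length(i3), config$readLengthMean,
                                      config$readLengthSd)),
                   config$readLengthMin)
      start3 <- pmax(end3 - len3 + 1L, 1L)
      seq3 <- .revcompChar(substring(hap[genes[i3]], start3, end3))
      readRows[[length(readRows) + 1L]] <- data.frame(
        library_id = lib$library_id, clone_id = cloneIds[i3], end = "3p",
        gene = genes[i3], cultivar = lib$cultivar, start = start3,
        end_pos = end3, strand = "-", seq = seq3, stringsAsFactors = FALSE)
    }
  }
  rr <- do.call(rbind, readRows)
  rr$read_id <- paste(rr$library_id, rr$clone_id, rr$end, sep = "|")
  # inject errors and derive qualities
  lens <- nchar(rr$seq)
  rr$n_errors <- 0L
  quals <- character(nrow(rr))
  noErr <- config$baseErrorRate == 0 && config$tailLength == 0L
  if (noErr) {
    qchar <- rawToChar(as.raw(40L + 33L))
    quals <- strrep(qchar, lens)
  } else {
    for (i in seq_len(nrow(rr))) {
      errs <- .errorProfile(lens[i], config)
      inj <- .injectErrors(rr$seq[i], errs)
      rr$seq[i] <- inj$seq
      rr$n_errors[i] <- inj$n
      quals[i] <- .qualityString(errs)
    }
  }
  reads <- ESTReadSet(rr$seq, read_id = rr$read_id, clone_id = rr$clone_id,
                      end = rr$end, library_id = rr$library_id,
                      qualities = quals)
  expression <- data.frame(
    gene_id = ann$gene_id, weight = w,
    specific = seq_len(n) %in% specIdx,
    specific_tissue = NA_character_, stringsAsFactors = FALSE)
  expression$specific_tissue[specIdx] <- specTissue
  readMap <- data.frame(read_id = rr$read_id, gene_id = ann$gene_id[rr$gene],
                        cultivar = rr$cultivar, start = rr$start,
                        end = rr$end_pos, strand = rr$strand,
                        n_errors = rr$n_errors, stringsAsFactors = FALSE)
  list(reads = reads, metadata = libraries, readMap = readMap,
       expression = expression, proportions = props)
}

#' Run the whole synthetic study generator
#'
#' Convenience wrapper: \code{\link{generateReference}} then
#' \code{\link{plantMarkers}} then \code{\link{simulateLibraries}}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A list with everything the three stages return: reference,
#'   haplotypes, ssr/snp truth, reads, metadata, readMap, expression,
#'   proportions.
#' @export
simulateESTStudy <- function(config = simulationConfig()) {
  ref <- generateReference(config)
  marked <- plantMarkers(ref, config)
  sim <- simulateLibraries(marked, config)
  c(list(reference = marked$reference, haplotypes = marked$haplotypes,
         ssr = marked$ssr, snp = marked$snp), sim[names(sim) != "metadata"],
    list(metadata = sim$metadata))
}
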