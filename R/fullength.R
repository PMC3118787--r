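# Full-length transcript identification from clone-end pairing, ORF/UTR
# annotation and codon usage statistics.

#' Pair 5' and 3' clone-end reads through unigene membership
#'
#' A clone is concordant when it has reads from both ends and both reads
#' were assembled into the same unigene — the defining evidence for a
#' full-length transcript. Duplicate reads for the same (clone, end) keep
#' the longest read, with a warning.
#'
#' @param reads An \link{ESTReadSet}.
#' @param unigenes A \link{UnigeneSet} (or any data.frame with read_id and
#'   unigene_id columns) assigning every read to a unigene.
#' @return A data.frame with one row per clone: \code{clone_id},
#'   \code{five_prime_unigene}, \code{three_prime_unigene} (NA when that
#'   end was not sequenced or not assembled) and \code{concordant}.
#' @export
pairCloneEnds <- function(reads, unigenes) {
  membership <- if (methods::is(unigenes, "UnigeneSet"))
    as.data.frame(membershipTable(unigenes)) else as.data.frame(unigenes)
  info <- as.data.frame(readInfo(reads))
  info$width <- Biostrings::width(estSequences(reads))
  info$unigene_id <- membership$unigene_id[match(info$read_id,
                                                 membership$read_id)]
  if (anyNA(info$unigene_id))
    stop("membership must map every read to a unigene")
  key <- paste(info$clone_id, info$end, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (clone, end) reads; keeping the longest of each")
    info <- info[order(key, -info$width), ]
    info <- info[!duplicated(paste(info$clone_id, info$end, sep = "\r")), ]
  }
  clones <- sort(unique(info$clone_id))
  i5 <- match(paste(clones, "5p", sep = "\r"),
              paste(info$clone_id, info$end, sep = "\r"))
  i3 <- match(paste(clones, "3p", sep = "\r"),
              paste(info$clone_id, info$end, sep = "\r"))
  u5 <- info$unigene_id[i5]
  u3 <- info$unigene_id[i3]
  data.frame(clone_id = clones, five_prime_unigene = u5,
             three_prime_unigene = u3,
             concordant = !is.na(u5) & !is.na(u3) & u5 == u3,
             stringsAsFactors = FALSE)
}

#' Summarize clone-end pairing
#'
#' @param pairings Output of \code{\link{pairCloneEnds}}.
#' @return A one-row data.frame: clones seen, clones sequenced from both
#'   ends, concordant clones and the concordance percentage.
#' @export
summarizePairing <- function(pairings) {
  both <- !is.na(pairings$five_prime_unigene) &
    !is.na(pairings$three_prime_unigene)
  data.frame(n_clones = nrow(pairings), n_both_ends = sum(both),
             n_concordant = sum(pairings$concordant),
             concordant_pct = if (sum(both)) 100 * sum(pairings$concordant) /
               sum(both) else NA_real_)
}

.consensusSpanSequence <- function(unigenes, ug, s, e) {
  cmap <- unigenes@columnMaps[[ug]]
  if (!is.null(cmap)) {
    within <- cmap[s:e]
    within <- within[!is.na(within)]
    if (!length(within)) return(NULL)
    s <- min(within); e <- max(within)
  }
  cons <- unigenes@consensus[[ug]]
  e <- min(e, length(cons))
  as.character(Biostrings::subseq(cons, start = s, end = e))
}

#' Call full-length transcripts from concordant clones
#'
#' A unigene yields one transcript when at least one clone from a
#' full-length enriched library has its 5' and 3' reads assembled into
#' that unigene. The transcript sequence is the consensus span from the
#' clone's 5'-read start column through its 3'-read end column; when
#' several concordant clones support the unigene, the widest single-clone
#' span is used (ties go to the lexicographically smallest clone id).
#' Clones whose 5' read starts right of their 3' read's end, or whose
#' reads are oriented against the unigene consensus, are skipped with a
#' warning.
#'
#' @param unigenes A \link{UnigeneSet}.
#' @param pairings Output of \code{\link{pairCloneEnds}}.
#' @param reads The \link{ESTReadSet} that was clustered.
#' @param metadata Library metadata (see
#'   \code{\link{readLibraryMetadata}}); only clones from
#'   \code{FULL_LENGTH} libraries qualify.
#' @param minOrf Minimum open reading frame length in bases passed to
#'   \code{\link{predictCDS}} (default 90, i.e. 30 codons).
#' @return A \link{FullLengthSet} with CDS/UTR annotation.
#' @export
callFullLength <- function(unigenes, pairings, reads, metadata,
                           minOrf = 90L) {
  info <- as.data.frame(readInfo(reads))
  libIdx <- .lookupLibraries(info$library_id, metadata)
  cloneLib <- tapply(metadata$library_type[libIdx], info$clone_id,
                     function(x) x[1])
  eligible <- pairings[pairings$concordant &
    cloneLib[pairings$clone_id] == "FULL_LENGTH", , drop = FALSE]
  members <- as.data.frame(unigeneMembers(unigenes))
  members$clone_id <- info$clone_id[match(members$read_id, info$read_id)]
  members$end <- info$end[match(members$read_id, info$read_id)]
  members$len <- nchar(gsub("-", "", members$aligned, fixed = TRUE))

  seqsOut <- character(0)
  rows <- list()
  skipped <- 0L
  for (ug in sort(unique(eligible$five_prime_unigene))) {
    cl <- sort(eligible$clone_id[eligible$five_prime_unigene == ug])
    mm <- members[members$unigene_id == ug & members$clone_id %in% cl, ]
    spans <- lapply(cl, function(cc) {
      r5 <- mm[mm$clone_id == cc & mm$end == "5p", , drop = FALSE]
      r3 <- mm[mm$clone_id == cc & mm$end == "3p", , drop = FALSE]
      if (!nrow(r5) || !nrow(r3)) return(NULL)
      if (r5$strand[1] != "+" || r3$strand[1] != "-") return(NA)
      s <- r5$offset[1]
      e <- r3$offset[1] + r3$len[1] - 1L
      if (s > e) return(NA)
      c(s, e)
    })
    isBad <- vapply(spans, function(x) length(x) == 1L && is.na(x), logical(1))
    skipped <- skipped + sum(isBad)
    keep <- !isBad & !vapply(spans, is.null, logical(1))
    if (!any(keep)) next
    cl <- cl[keep]; spans <- spans[keep]
    widths <- vapply(spans, function(x) x[2] - x[1] + 1L, integer(1))
    best <- spans[[which.max(widths)]]   # which.max: leftmost = smallest clone
    seq <- .consensusSpanSequence(unigenes, ug, best[1], best[2])
    if (is.null(seq)) next
    cloneBest <- cl[which.max(widths)]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = paste0("FL_", ug), unigene_id = ug,
      clone_id = cloneBest, length = nchar(seq), stringsAsFactors = FALSE)
    seqsOut <- c(seqsOut, seq)
  }
  if (skipped)
    warning(skipped, " concordant clone(s) with inconsistent layout skipped")
  if (!length(rows)) {
    ann <- S4Vectors::DataFrame(transcript_id = character(0),
                                unigene_id = character(0),
                                clone_id = character(0), length = integer(0),
                                cds_start = integer(0), cds_end = integer(0),
                                utr5_length = integer(0),
                                utr3_length = integer(0), flags = character(0))
    return(new("FullLengthSet", sequences = Biostrings::DNAStringSet(),
               annotation = ann))
  }
  ann <- do.call(rbind, rows)
  seqs <- Biostrings::DNAStringSet(seqsOut)
  names(seqs) <- ann$transcript_id
  fl <- new("FullLengthSet", sequences = seqs,
            annotation = S4Vectors::DataFrame(
              ann, cds_start = NA_integer_, cds_end = NA_integer_,
              utr5_length = NA_integer_, utr3_length = NA_integer_,
              flags = ""))
  annotateTranscripts(fl, minOrf = minOrf)
}

#' Predict the coding sequence of a transcript
#'
#' Longest forward-strand open reading frame starting at ATG and ending
#' at an in-frame stop codon (stop included in the CDS), searched over all
#' three frames; full-length cDNA clones are directionally cloned, so
#' reverse-strand ORFs are not considered. If no ATG-to-stop ORF of at
#' least \code{minOrf} bases exists, the longest stop-free tail starting
#' at an ATG (truncated to complete codons) is used and flagged
#' \code{NO_STOP}; if that is also shorter than \code{minOrf} the
#' transcript is flagged \code{NON_CODING}. Ties go to the leftmost start.
#'
#' @param sequence A DNA sequence (character or \code{DNAString}).
#' @param minOrf Minimum ORF length in bases (default 90).
#' @return A list with \code{cds_start}, \code{cds_end} (1-based
#'   inclusive; NA for non-coding) and \code{flags} (character vector,
#'   possibly empty, subset of \code{NO_STOP}, \code{NON_CODING}).
#' @export
predictCDS <- function(sequence, minOrf = 90L) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  starts <- integer(0); stops <- integer(0)
  if (L >= 3L) {
    p <- 1:(L - 2L)
    tri <- substring(s, p, p + 2L)
    starts <- p[tri == "ATG"]
    stops <- p[tri %in% c("TAA", "TAG", "TGA")]
  }
  best <- NULL
  for (f in 0:2) {
    fs <- starts[(starts - 1L) %% 3L == f]
    fe <- stops[(stops - 1L) %% 3L == f]
    if (!length(fs)) next
    for (p in fs) {
      q <- fe[fe > p]
      if (length(q)) {
        q <- q[1]
        len <- q + 2L - p + 1L
        if (len >= minOrf && (is.null(best) || len > best$len ||
                              (len == best$len && p < best$start))) {
          best <- list(start = p, end = q + 2L, len = len)
        }
      }
    }
  }
  if (!is.null(best))
    return(list(cds_start = best$start, cds_end = best$end,
                flags = character(0)))
  # stop-free tail from an ATG
  for (f in 0:2) {
    fs <- starts[(starts - 1L) %% 3L == f]
    fe <- stops[(stops - 1L) %% 3L == f]
    if (!length(fs)) next
    open <- fs[vapply(fs, function(p) !any(fe > p), logical(1))]
    for (p in open) {
      len <- 3L * ((L - p + 1L) %/% 3L)
      if (len >= minOrf && (is.null(best) || len > best$len ||
                            (len == best$len && p < best$start))) {
        best <- list(start = p, end = p + len - 1L, len = len)
      }
    }
  }
  if (!is.null(best))
    return(list(cds_start = best$start, cds_end = best$end,
                flags = "NO_STOP"))
  list(cds_start = NA_integer_, cds_end = NA_integer_, flags = "NON_CODING")
}

#' Annotate a transcript set with CDS and UTRs
#'
#' Applies \code{\link{predictCDS}} to every transcript and fills in the
#' CDS coordinates, UTR lengths and flags of the annotation table. For
#' every coding transcript \code{utr5 + cds + utr3} partitions the
#' sequence exactly.
#'
#' @param x A \link{FullLengthSet}.
#' @param minOrf Minimum ORF length in bases.
#' @return The annotated \link{FullLengthSet}.
#' @export
annotateTranscripts <- function(x, minOrf = 90L) {
  a <- x@annotation
  if (!nrow(a)) return(x)
  seqs <- as.character(x@sequences)
  res <- lapply(seqs, predictCDS, minOrf = minOrf)
  a$cds_start <- vapply(res, `[[`, integer(1), "cds_start")
  a$cds_end <- vapply(res, `[[`, integer(1), "cds_end")
  a$flags <- vapply(res, function(r) paste(r$flags, collapse = ","),
                    character(1))
  coding <- !is.na(a$cds_start)
  a$utr5_length <- ifelse(coding, a$cds_start - 1L, NA_integer_)
  a$utr3_length <- ifelse(coding, a$length - a$cds_end, NA_integer_)
  methods::initialize(x, annotation = a)
}

#' Extract UTR coordinates from annotated transcripts
#'
#' The 5' UTR runs from the transcript start to the base before the CDS,
#' the 3' UTR from the base after the stop codon to the transcript end.
#' Non-coding transcripts yield no UTRs; zero-length UTRs are reported
#' with length 0.
#'
#' @param x An annotated \link{FullLengthSet}.
#' @return A data.frame with transcript_id, utr5_start/utr5_end,
#'   utr3_start/utr3_end (1-based inclusive; NA bounds for empty UTRs)
#'   and the two lengths.
#' @export
extractUTRs <- function(x) {
  a <- as.data.frame(x@annotation)
  a <- a[!is.na(a$cds_start), , drop = FALSE]
  if (!nrow(a))
    return(data.frame(transcript_id = character(0), utr5_start = integer(0),
                      utr5_end = integer(0), utr5_length = integer(0),
                      utr3_start = integer(0), utr3_end = integer(0),
                      utr3_length = integer(0)))
  data.frame(
    transcript_id = a$transcript_id,
    utr5_start = ifelse(a$cds_start > 1L, 1L, NA_integer_),
    utr5_end = ifelse(a$cds_start > 1L, a$cds_start - 1L, NA_integer_),
    utr5_length = a$cds_start - 1L,
    utr3_start = ifelse(a$cds_end < a$length, a$cds_end + 1L, NA_integer_),
    utr3_end = ifelse(a$cds_end < a$length, a$length, NA_integer_),
    utr3_length = a$length - a$cds_end,
    stringsAsFactors = FALSE)
}

#' Codon usage of a set of coding sequences
#'
#' Counts each of the 64 codons over the given CDS set and derives the
#' frequency per 1000 codons, the fraction within each amino-acid
#' (synonymous) family, the composition of terminal stop codons, and the
#' GC content of the coding bases.
#'
#' @param cds A \link[Biostrings]{DNAStringSet} (or character vector) of
#'   CDS, each a multiple of 3 long (stop codon included when present).
#' @return A list with \code{table} (data.frame: codon, aa, count,
#'   per_1000, family_fraction), \code{stop_composition} (named fractions
#'   over TAA/TAG/TGA terminal codons), \code{gc_content}, \code{n_cds}
#'   and \code{n_codons}.
#' @export
codonUsage <- function(cds) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(toupper(cds))
  w <- Biostrings::width(cds)
  bad <- which(w %% 3L != 0L)
  if (length(bad)) {
    nm <- names(cds)[bad[1]]
    stop("CDS length not a multiple of 3: ",
         if (is.null(nm) || is.na(nm)) paste0("entry ", bad[1]) else nm)
  }
  counts <- if (length(cds)) {
    colSums(Biostrings::trinucleotideFrequency(cds, step = 3))
  } else {
    f <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet("AAA"),
                                            step = 3)
    stats::setNames(rep(0L, 64L), colnames(f))
  }
  aa <- as.character(Biostrings::GENETIC_CODE[names(counts)])
  total <- sum(counts)
  famTotals <- tapply(counts, aa, sum)
  tab <- data.frame(codon = names(counts), aa = aa, count = as.integer(counts),
                    per_1000 = if (total) 1000 * counts / total else
                      rep(NA_real_, 64L),
                    family_fraction = ifelse(famTotals[aa] > 0,
                                             counts / famTotals[aa],
                                             NA_real_),
                    stringsAsFactors = FALSE, row.names = NULL)
  lastCodon <- if (length(cds))
    as.character(Biostrings::subseq(cds, start = w - 2L, end = w)) else
      character(0)
  stopsSeen <- lastCodon[lastCodon %in% c("TAA", "TAG", "TGA")]
  stopComp <- stats::setNames(rep(NA_real_, 3), c("TAA", "TAG", "TGA"))
  if (length(stopsSeen)) {
    t0 <- table(factor(stopsSeen, levels = c("TAA", "TAG", "TGA")))
    stopComp <- as.numeric(t0) / length(stopsSeen)
    names(stopComp) <- c("TAA", "TAG", "TGA")
  }
  gc <- if (total) {
    sum(Biostrings::letterFrequency(cds, "GC")) / sum(w)
  } else NA_real_
  structure(list(table = tab, stop_composition = stopComp, gc_content = gc,
                 n_cds = length(cds), n_codons = total),
            class = "CodonUsageTable")
}

#' @export
print.CodonUsageTable <- function(x, ...) {
  cat("Codon usage over", x$n_cds, "CDS (", x$n_codons, "codons )\n")
  cat("  coding GC content:", round(100 * x$gc_content, 2), "%\n")
  cat("  stop composition:",
      paste(names(x$stop_composition),
            round(100 * x$stop_composition, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Size distributions of transcripts, CDS and UTRs
#'
#' @param x An annotated \link{FullLengthSet}.
#' @param binWidth Histogram bin width in bases (default 100).
#' @return A list with \code{summary} (class, n, mean, min, max) and
#'   \code{bins} (class, bin_start, bin_end, count). Empty inputs give
#'   zero-row tables.
#' @export
sizeDistributions <- function(x, binWidth = 100L) {
  a <- as.data.frame(x@annotation)
  coding <- a[!is.na(a$cds_start), , drop = FALSE]
  vals <- list(transcript = a$length,
               cds = if (nrow(coding)) coding$cds_end - coding$cds_start + 1L
                 else integer(0),
               utr5 = coding$utr5_length[!is.na(coding$utr5_length)],
               utr3 = coding$utr3_length[!is.na(coding$utr3_length)])
  summ <- do.call(rbind, lapply(names(vals), function(cl) {
    v <- vals[[cl]]
    data.frame(class = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               min = if (length(v)) min(v) else NA_integer_,
               max = if (length(v)) max(v) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  bins <- do.call(rbind, lapply(names(vals), function(cl) {
    v <- vals[[cl]]
    if (!length(v)) return(NULL)
    b <- (v %/% binWidth) * binWidth
    t0 <- table(b)
    data.frame(class = cl, bin_start = as.integer(names(t0)),
               bin_end = as.integer(names(t0)) + binWidth - 1L,
               count = as.integer(t0), stringsAsFactors = FALSE)
  }))
  if (is.null(bins))
    bins <- data.frame(class = character(0), bin_start = integer(0),
                       bin_end = integer(0), count = integer(0))
  list(summary = summ, bins = bins)
}
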