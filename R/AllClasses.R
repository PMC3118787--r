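#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom Biostrings DNAStringSet PhredQuality
NULL

#' Set of EST clone-end reads
#'
#' Container for single-pass Sanger reads from cDNA clone ends. Each read
#' carries its clone identifier, the sequenced end (\code{"5p"} or
#' \code{"3p"}), the cDNA library it came from, and optionally a
#' per-base Phred quality string. Sequences are stored in sequencing
#' orientation; 3' reads are only reverse-complemented inside the
#' clusterer.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} named by read id, with
#'   \code{mcols} columns \code{clone_id}, \code{end}, \code{library_id}.
#' @slot qualities A \link[Biostrings]{PhredQuality} parallel to
#'   \code{sequences}, or \code{NULL} when qualities are unavailable.
#' @export
setClass("ESTReadSet",
  slots = c(sequences = "DNAStringSet", qualities = "ANY"))

setValidity("ESTReadSet", function(object) {
  seqs <- object@sequences
  info <- S4Vectors::mcols(seqs)
  msgs <- character(0)
  if (is.null(names(seqs)) && length(seqs) > 0)
    msgs <- c(msgs, "sequences must be named by read id")
  need <- c("clone_id", "end", "library_id")
  if (is.null(info) || !all(need %in% colnames(info))) {
    msgs <- c(msgs, "mcols must contain clone_id, end, library_id")
  } else {
    if (!all(info$end %in% c("5p", "3p")))
      msgs <- c(msgs, "end must be '5p' or '3p'")
  }
  if (length(seqs) > 0 && any(Biostrings::width(seqs) < 1L))
    msgs <- c(msgs, "all sequences must have length >= 1")
  q <- object@qualities
  if (!is.null(q)) {
    if (!is(q, "PhredQuality"))
      msgs <- c(msgs, "qualities must be a PhredQuality or NULL")
    else if (length(q) != length(seqs) ||
             !all(Biostrings::width(q) == Biostrings::width(seqs)))
      msgs <- c(msgs, "qualities must be length-matched with sequences")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ESTReadSet
#'
#' @param sequences DNAStringSet or character vector of read sequences
#'   (lowercase accepted, uppercased on construction; N allowed).
#' @param read_id,clone_id,end,library_id Character vectors parallel to
#'   \code{sequences}; \code{end} uses the codes \code{"5p"}/\code{"3p"}.
#' @param qualities Optional \link[Biostrings]{PhredQuality}, character
#'   vector of Sanger (phred+33) quality strings, or list of integer
#'   Phred scores.
#' @return An \code{ESTReadSet}.
#' @export
ESTReadSet <- function(sequences, read_id = names(sequences), clone_id,
                       end, library_id, qualities = NULL) {
  if (is.character(sequences)) sequences <- DNAStringSet(toupper(sequences))
  if (is.null(read_id)) stop("read ids are required")
  names(sequences) <- read_id
  S4Vectors::mcols(sequences) <- DataFrame(
    clone_id = as.character(clone_id),
    end = as.character(end),
    library_id = as.character(library_id))
  if (!is.null(qualities)) {
    if (is.list(qualities)) {
      qualities <- PhredQuality(vapply(qualities, function(q) {
        rawToChar(as.raw(as.integer(q) + 33L))
      }, character(1)))
    } else if (is.character(qualities)) {
      qualities <- PhredQuality(qualities)
    }
  }
  new("ESTReadSet", sequences = sequences, qualities = qualities)
}

#' @describeIn ESTReadSet-class Number of reads.
#' @param x An \code{ESTReadSet}.
#' @export
setMethod("length", "ESTReadSet", function(x) length(x@sequences))

#' Accessors for ESTReadSet
#'
#' \code{estSequences} returns the reads as a DNAStringSet;
#' \code{estQualities} the Phred qualities (or NULL); \code{readInfo} a
#' DataFrame with columns read_id, clone_id, end, library_id.
#'
#' @param x An \code{ESTReadSet}.
#' @return See description.
#' @export
estSequences <- function(x) x@sequences

#' @rdname estSequences
#' @export
estQualities <- function(x) x@qualities

#' @rdname estSequences
#' @export
readInfo <- function(x) {
  info <- S4Vectors::mcols(x@sequences)
  DataFrame(read_id = names(x@sequences), clone_id = info$clone_id,
            end = info$end, library_id = info$library_id)
}

#' @export
setMethod("[", "ESTReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ESTReadSet", sequences = x@sequences[i],
      qualities = if (is.null(x@qualities)) NULL else x@qualities[i])
})

setMethod("show", "ESTReadSet", function(object) {
  info <- S4Vectors::mcols(object@sequences)
  cat("ESTReadSet with", length(object), "reads\n")
  if (length(object)) {
    cat("  libraries:", paste(unique(info$library_id), collapse = ", "), "\n")
    cat("  5' reads:", sum(info$end == "5p"),
        " 3' reads:", sum(info$end == "3p"), "\n")
    cat("  qualities:", if (is.null(object@qualities)) "absent" else "present",
        "\n")
  }
})

#' Set of unigenes (EST clusters with consensus)
#'
#' A unigene is a cluster of EST reads laid out against a common consensus.
#' Multi-member unigenes are contigs; single-member unigenes are
#' singletons. The member table records, for each read, the unigene it
#' belongs to, its orientation relative to the consensus (\code{"+"} keeps
#' the sequencing orientation, \code{"-"} means reverse-complemented), the
#' 1-based alignment column at which the oriented read starts, and the
#' oriented (possibly gapped) member sequence.
#'
#' @slot consensus \link[Biostrings]{DNAStringSet} of consensus sequences,
#'   named by unigene id.
#' @slot members \link[S4Vectors]{DataFrame} with columns \code{read_id},
#'   \code{unigene_id}, \code{strand}, \code{offset}, \code{aligned}.
#' @slot columnMaps Named list mapping, for unigenes whose padded alignment
#'   contains gap-majority columns, each alignment column to its consensus
#'   position (\code{NA} for columns dropped from the consensus). Unigenes
#'   absent from the list use the identity map.
#' @export
setClass("UnigeneSet",
  slots = c(consensus = "DNAStringSet", members = "DataFrame",
            columnMaps = "list"))

setValidity("UnigeneSet", function(object) {
  msgs <- character(0)
  m <- object@members
  need <- c("read_id", "unigene_id", "strand", "offset", "aligned")
  if (!all(need %in% colnames(m)))
    msgs <- c(msgs, "members must have read_id, unigene_id, strand, offset, aligned")
  else {
    if (is.null(names(object@consensus)))
      msgs <- c(msgs, "consensus must be named by unigene id")
    else if (!all(m$unigene_id %in% names(object@consensus)))
      msgs <- c(msgs, "every member must map to a consensus sequence")
    if (!all(names(object@consensus) %in% m$unigene_id))
      msgs <- c(msgs, "every unigene must have at least one member")
    if (!all(m$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    if (any(m$offset < 1L))
      msgs <- c(msgs, "offsets are 1-based alignment columns (>= 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a UnigeneSet
#'
#' @param consensus DNAStringSet (or character) of consensus sequences
#'   named by unigene id.
#' @param members DataFrame/data.frame with columns read_id, unigene_id,
#'   strand, offset, aligned (aligned member sequences may contain "-").
#' @param columnMaps Optional named list of alignment-column to
#'   consensus-position maps (see class documentation).
#' @return A \code{UnigeneSet}.
#' @export
UnigeneSet <- function(consensus, members, columnMaps = list()) {
  if (is.character(consensus)) consensus <- DNAStringSet(consensus)
  members <- as(members, "DataFrame")
  members$read_id <- as.character(members$read_id)
  members$unigene_id <- as.character(members$unigene_id)
  members$strand <- as.character(members$strand)
  members$offset <- as.integer(members$offset)
  members$aligned <- as.character(members$aligned)
  new("UnigeneSet", consensus = consensus, members = members,
      columnMaps = columnMaps)
}

#' @describeIn UnigeneSet-class Number of unigenes.
#' @param x A \code{UnigeneSet}.
#' @export
setMethod("length", "UnigeneSet", function(x) length(x@consensus))

#' Accessors for UnigeneSet
#'
#' \code{consensusSequences} returns the consensus DNAStringSet;
#' \code{unigeneMembers} the member table; \code{unigeneIDs} the unigene
#' ids; \code{isSingleton} a named logical vector; \code{membershipTable}
#' a two-column read_id/unigene_id DataFrame.
#'
#' @param x A \code{UnigeneSet}.
#' @return See description.
#' @export
consensusSequences <- function(x) x@consensus

#' @rdname consensusSequences
#' @export
unigeneMembers <- function(x) x@members

#' @rdname consensusSequences
#' @export
unigeneIDs <- function(x) names(x@consensus)

#' @rdname consensusSequences
#' @export
isSingleton <- function(x) {
  n <- table(x@members$unigene_id)
  out <- as.integer(n[names(x@consensus)]) == 1L
  names(out) <- names(x@consensus)
  out
}

#' @rdname consensusSequences
#' @export
membershipTable <- function(x) {
  DataFrame(read_id = x@members$read_id, unigene_id = x@members$unigene_id)
}

setMethod("show", "UnigeneSet", function(object) {
  s <- isSingleton(object)
  cat("UnigeneSet with", length(object), "unigenes (",
      sum(!s), "contigs,", sum(s), "singletons ),",
      nrow(object@members), "member reads\n")
})

#' Unigene x tissue EST count matrix
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding the digital-expression count matrix: one row per unigene, one
#' column per tissue, assay \code{"counts"} = number of ESTs of that
#' unigene sequenced from non-normalized libraries of that tissue.
#' \code{colData} carries the per-tissue EST totals.
#'
#' @export
setClass("ESTCountMatrix", contains = "SummarizedExperiment")

setValidity("ESTCountMatrix", function(object) {
  msgs <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msgs <- c(msgs, "counts must be non-negative integers")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("tissue", "total") %in% colnames(cd)))
      msgs <- c(msgs, "colData must have 'tissue' and 'total'")
    else if (!isTRUE(all(cd$total == colSums(cnt))))
      msgs <- c(msgs, "per-tissue totals must equal column sums")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ESTCountMatrix
#'
#' @param counts Integer matrix, rows = unigenes, columns = tissues.
#' @return An \code{ESTCountMatrix}.
#' @export
ESTCountMatrix <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(tissue = colnames(counts), total = colSums(counts),
                        row.names = colnames(counts)))
  new("ESTCountMatrix", se)
}

#' Accessors for ESTCountMatrix
#'
#' \code{estCounts} returns the count matrix, \code{tissueTotals} the named
#' per-tissue EST totals, \code{tissueNames} the ordered tissue list.
#'
#' @param x An \code{ESTCountMatrix}.
#' @return See description.
#' @export
estCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname estCounts
#' @export
tissueTotals <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(cd$total, cd$tissue)
}

#' @rdname estCounts
#' @export
tissueNames <- function(x) SummarizedExperiment::colData(x)$tissue

#' Set of full-length transcripts
#'
#' Transcripts reconstructed from unigenes supported by at least one
#' concordant full-length cDNA clone, with predicted CDS and UTRs.
#' All coordinates are 1-based inclusive positions on the transcript
#' sequence; \code{cds_start}/\code{cds_end} are \code{NA} for
#' non-coding transcripts. Flags are a comma-separated subset of
#' \code{NO_START}, \code{NO_STOP}, \code{NON_CODING}.
#'
#' @slot sequences \link[Biostrings]{DNAStringSet} of transcript sequences
#'   named by transcript id.
#' @slot annotation \link[S4Vectors]{DataFrame} with one row per
#'   transcript: transcript_id, unigene_id, clone_id, length, cds_start,
#'   cds_end, utr5_length, utr3_length, flags.
#' @export
setClass("FullLengthSet",
  slots = c(sequences = "DNAStringSet", annotation = "DataFrame"))

setValidity("FullLengthSet", function(object) {
  a <- object@annotation
  msgs <- character(0)
  if (nrow(a) != length(object@sequences))
    msgs <- c(msgs, "annotation rows must match sequences")
  coding <- !is.na(a$cds_start)
  if (any(coding)) {
    bad <- coding & ((a$cds_end - a$cds_start + 1L) %% 3L != 0L)
    if (any(bad)) msgs <- c(msgs, "CDS lengths must be divisible by 3")
    if (any(coding & (a$cds_start < 1L | a$cds_end > a$length)))
      msgs <- c(msgs, "CDS must lie within the transcript")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FullLengthSet-class Number of transcripts.
#' @param x A \code{FullLengthSet}.
#' @export
setMethod("length", "FullLengthSet", function(x) length(x@sequences))

#' Accessors for FullLengthSet
#'
#' \code{transcriptSequences} returns the transcript DNAStringSet;
#' \code{transcriptAnnotation} the per-transcript annotation table;
#' \code{cdsSequences} the DNAStringSet of predicted CDS (coding
#' transcripts only).
#'
#' @param x A \code{FullLengthSet}.
#' @return See description.
#' @export
transcriptSequences <- function(x) x@sequences

#' @rdname transcriptSequences
#' @export
transcriptAnnotation <- function(x) x@annotation

#' @rdname transcriptSequences
#' @export
cdsSequences <- function(x) {
  a <- x@annotation
  keep <- !is.na(a$cds_start)
  if (!any(keep)) return(DNAStringSet())
  out <- Biostrings::subseq(x@sequences[keep], start = a$cds_start[keep],
                            end = a$cds_end[keep])
  names(out) <- a$transcript_id[keep]
  out
}

setMethod("show", "FullLengthSet", function(object) {
  a <- object@annotation
  cat("FullLengthSet with", length(object), "transcripts (",
      sum(!is.na(a$cds_start)), "with predicted CDS )\n")
})
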