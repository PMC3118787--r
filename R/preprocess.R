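# Read preprocessing: sliding-window quality trimming, minimum-length
# filtering and exact k-mer contaminant screening.

# Longest clean interval of a single quality vector.
# err: per-base error probabilities; returns c(start, end) (1-based,
# inclusive) or c(NA, NA) when nothing survives. A window of length
# `window` starting at b is "bad" when its mean error exceeds maxError
# (strictly). An interval is clean when it contains no complete bad
# window and, if it is shorter than the window, its own mean error does
# not exceed the threshold (so cleanliness is decided at the interval's
# own scale — this also makes trimming idempotent). The longest clean
# interval is kept; ties go to the leftmost. Reads no longer than the
# window are evaluated as a single window: kept whole or dropped.
.cleanInterval <- function(err, window, maxError) {
  L <- length(err)
  if (L <= window) {
    if (mean(err) > maxError + 1e-12) return(c(NA_integer_, NA_integer_))
    return(c(1L, L))
  }
  eps <- 1e-12   # guard against cumulative-sum round-off at the boundary
  cs <- cumsum(c(0, err))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  bad <- which(means > maxError + eps)
  if (!length(bad)) return(c(1L, L))
  starts <- c(1L, bad + 1L)
  ends <- c(bad + window - 2L, L)
  lens <- ends - starts + 1L
  long <- lens >= window
  if (any(long)) {
    best <- which(long)[which.max(lens[long])]   # leftmost maximum
    return(c(starts[best], ends[best]))
  }
  # no interval reaches a full window: take the longest sub-window
  # stretch whose own mean error passes the threshold
  for (l in seq.int(window - 1L, 1L)) {
    m <- (cs[(l + 1L):(L + 1L)] - cs[1:(L - l + 1L)]) / l
    hit <- which(m <= maxError + eps)
    if (length(hit)) return(c(hit[1L], hit[1L] + l - 1L))
  }
  c(NA_integer_, NA_integer_)
}

#' Quality-trim EST reads with a sliding error window
#'
#' Per-base error probabilities are taken from the Phred qualities
#' (\eqn{e = 10^{-Q/10}}). For each read the longest contiguous clean
#' region is kept, where a region is clean when every complete window of
#' \code{window} bases inside it has mean error \eqn{\le} \code{maxError}
#' (a window exactly at the threshold is clean: the trimming condition is
#' strictly greater) and a region shorter than the window has mean error
#' \eqn{\le} \code{maxError} itself. Reads no longer than the window are
#' evaluated as a single window and kept whole or dropped. Reads without
#' qualities pass through unchanged with a note. Trimming is idempotent
#' and always returns a contiguous substring of the input.
#'
#' @param reads An \link{ESTReadSet}.
#' @param window Window length in bases (default 20).
#' @param maxError Maximum tolerated mean error per window (default 0.01).
#' @return A list with \code{reads} (trimmed \code{ESTReadSet}; reads with
#'   no clean region become zero-length and are dropped) and \code{report}
#'   (data.frame: read_id, kept, trimmed_start, trimmed_end, reason) where
#'   trimmed_start/trimmed_end are 1-based inclusive coordinates on the
#'   original read (NA when nothing was kept).
#' @export
trimLowQuality <- function(reads, window = 20L, maxError = 0.01) {
  .checkScalarNumber(window, "window", min = 1)
  q <- estQualities(reads)
  n <- length(reads)
  widths <- Biostrings::width(estSequences(reads))
  if (is.null(q)) {
    message("reads carry no qualities; passed through untrimmed")
    report <- data.frame(read_id = readInfo(reads)$read_id,
                         kept = rep(TRUE, n),
                         trimmed_start = rep(1L, n), trimmed_end = widths,
                         reason = rep("OK", n), stringsAsFactors = FALSE)
    return(list(reads = reads, report = report))
  }
  scores <- methods::as(q, "IntegerList")
  bounds <- t(vapply(seq_len(n), function(i) {
    .cleanInterval(10^(-as.integer(scores[[i]]) / 10), as.integer(window),
                   maxError)
  }, integer(2)))
  keep <- !is.na(bounds[, 1])
  report <- data.frame(read_id = readInfo(reads)$read_id, kept = keep,
                       trimmed_start = bounds[, 1], trimmed_end = bounds[, 2],
                       reason = ifelse(keep, "OK", "TOO_SHORT"),
                       stringsAsFactors = FALSE)
  info <- readInfo(reads)
  seqs <- estSequences(reads)[keep]
  qual <- q[keep]
  if (any(keep)) {
    seqs <- Biostrings::subseq(seqs, start = bounds[keep, 1],
                               end = bounds[keep, 2])
    qual <- Biostrings::subseq(qual, start = bounds[keep, 1],
                               end = bounds[keep, 2])
  }
  out <- ESTReadSet(seqs, read_id = info$read_id[keep],
                    clone_id = info$clone_id[keep], end = info$end[keep],
                    library_id = info$library_id[keep],
                    qualities = methods::as(qual, "PhredQuality"))
  list(reads = out, report = report)
}

#' Discard reads shorter than a minimum length
#'
#' Reads strictly shorter than \code{minLength} are removed; reads exactly
#' at the boundary are kept.
#'
#' @param reads An \link{ESTReadSet} (already trimmed).
#' @param minLength Minimum length in bases (default 100).
#' @return A list with \code{reads} (kept reads) and \code{report}
#'   (read_id, kept, reason).
#' @export
filterShortReads <- function(reads, minLength = 100L) {
  widths <- Biostrings::width(estSequences(reads))
  keep <- widths >= minLength
  report <- data.frame(read_id = readInfo(reads)$read_id, kept = keep,
                       reason = ifelse(keep, "OK", "TOO_SHORT"),
                       stringsAsFactors = FALSE)
  list(reads = reads[which(keep)], report = report)
}

.kmerSet <- function(seqs, k) {
  seqs <- as.character(seqs)
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character(0))
  both <- c(seqs, .revcompChar(seqs))
  unlist(lapply(both, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }), use.names = FALSE)
}

#' Screen reads against contaminant sequences by exact k-mer match
#'
#' A read sharing any exact \code{k}-mer with a contaminant sequence, on
#' either strand, is flagged \code{CONTAMINANT} and removed. Contaminants
#' shorter than \code{k} are ignored with a warning.
#'
#' @param reads An \link{ESTReadSet}.
#' @param contaminants A \link[Biostrings]{DNAStringSet} (or character
#'   vector) of contaminant sequences; may be empty.
#' @param k k-mer length (default 31).
#' @return A list with \code{reads} (kept) and \code{report} (read_id,
#'   kept, reason).
#' @export
screenContaminants <- function(reads, contaminants, k = 31L) {
  contaminants <- as.character(contaminants)
  tooShort <- nchar(contaminants) < k
  if (any(tooShort))
    warning(sum(tooShort), " contaminant sequence(s) shorter than k = ", k,
            " ignored")
  set <- unique(.kmerSet(contaminants[!tooShort], k))
  flagged <- rep(FALSE, length(reads))
  if (length(set)) {
    seqs <- as.character(estSequences(reads))
    flagged <- vapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(FALSE)
      any(substring(s, 1:(n - k + 1L), k:n) %in% set)
    }, logical(1), USE.NAMES = FALSE)
  }
  report <- data.frame(read_id = readInfo(reads)$read_id, kept = !flagged,
                       reason = ifelse(flagged, "CONTAMINANT", "OK"),
                       stringsAsFactors = FALSE)
  list(reads = reads[which(!flagged)], report = report)
}

#' Full preprocessing: trim, screen, length-filter
#'
#' Applies \code{\link{trimLowQuality}}, then
#' \code{\link{screenContaminants}} (when contaminants are given), then
#' \code{\link{filterShortReads}}, mirroring the processing order of a
#' Sanger EST project (quality trimming, vector/contaminant screening,
#' minimum-length cutoff).
#'
#' @param reads An \link{ESTReadSet}.
#' @param minLength,window,maxError See the individual steps.
#' @param contaminants Optional contaminant sequences.
#' @param k k-mer length for the contaminant screen.
#' @return A list with \code{reads} (clean reads) and \code{report} (one
#'   row per input read: read_id, kept, trimmed_start, trimmed_end,
#'   reason with values OK/TOO_SHORT/CONTAMINANT).
#' @export
preprocessReads <- function(reads, minLength = 100L, window = 20L,
                            maxError = 0.01, contaminants = NULL, k = 31L) {
  tr <- trimLowQuality(reads, window = window, maxError = maxError)
  report <- tr$report
  report$reason[!report$kept] <- "TOO_SHORT"
  cur <- tr$reads
  if (!is.null(contaminants)) {
    sc <- screenContaminants(cur, contaminants, k = k)
    idx <- match(sc$report$read_id[!sc$report$kept], report$read_id)
    report$kept[idx] <- FALSE
    report$reason[idx] <- "CONTAMINANT"
    cur <- sc$reads
  }
  fl <- filterShortReads(cur, minLength = minLength)
  idx <- match(fl$report$read_id[!fl$report$kept], report$read_id)
  if (length(idx)) {
    report$kept[idx] <- FALSE
    report$reason[idx] <- "TOO_SHORT"
  }
  list(reads = fl$reads, report = report)
}
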