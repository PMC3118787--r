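# Perfect microsatellite (SSR) scanning with canonical motif grouping.

#' Canonical label of an SSR motif
#'
#' The canonical motif of a repeat unit is the lexicographically smallest
#' string among all rotations of the motif and all rotations of its
#' reverse complement, so that e.g. AAG and CTT (and GAA, TTC, AGA, TCT)
#' all share the group label AAG — matching the conventional
#' "AAG/CTT"-style reporting of EST SSR surveys.
#'
#' @param motif Character vector of repeat units (2-6 bases, A/C/G/T
#'   only, not themselves tandem repeats of a shorter unit).
#' @return Character vector of canonical labels.
#' @export
canonicalMotif <- function(motif) {
  vapply(toupper(motif), function(m) {
    u <- nchar(m)
    if (grepl("[^ACGT]", m))
      stop("motif must contain only A, C, G, T: ", m)
    if (.isTandemOfShorter(m))
      stop("motif is itself a tandem repeat of a shorter unit: ", m)
    rots <- function(s) {
      vapply(seq_len(u), function(i) {
        paste0(substr(s, i, u), substr(s, 1, i - 1L))
      }, character(1))
    }
    min(c(rots(m), rots(.revcompChar(m))))
  }, character(1), USE.NAMES = FALSE)
}

# Scan one sequence for all maximal perfect tandem runs of one unit size.
.scanUnit <- function(chars, u, minRepeats) {
  n <- length(chars)
  if (n < 2L * u) return(NULL)
  valid <- chars %in% c("A", "C", "G", "T")
  eq <- chars[1:(n - u)] == chars[(u + 1L):n] & valid[1:(n - u)] &
    valid[(u + 1L):n]
  r <- rle(eq)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- which(r$values & r$lengths >= (minRepeats - 1L) * u)
  out <- NULL
  for (ri in runs) {
    s <- starts[ri]
    m <- r$lengths[ri]
    repeats <- (m + u) %/% u
    if (repeats < minRepeats) next
    motif <- paste(chars[s:(s + u - 1L)], collapse = "")
    if (.isTandemOfShorter(motif)) next   # reported at the smaller unit
    out <- rbind(out, data.frame(start = s, end = s + repeats * u - 1L,
                                 motif = motif, unit_size = u,
                                 repeat_count = repeats,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Scan sequences for perfect microsatellites
#'
#' Finds all maximal perfect tandem repeats of unit sizes 2-6 meeting the
#' per-unit-size minimum repeat numbers (defaults: six repeats for
#' dinucleotides, five for tri- through hexanucleotides; mononucleotide
#' runs are not scanned). A locus is maximal — it cannot be extended by
#' one more full unit on either side — and a run reportable at several
#' unit sizes is reported once, at the smallest unit (an (AT)6 run is
#' never also reported as (ATAT)3). Overlapping loci with different
#' canonical motifs are all reported. N breaks a run.
#'
#' @param sequences A named \link[Biostrings]{DNAStringSet} or character
#'   vector (typically unigene consensus sequences).
#' @param thresholds Named integer vector: minimum repeat count for unit
#'   sizes "2" through "6".
#' @return A \link[GenomicRanges]{GRanges} (seqnames = sequence names,
#'   1-based inclusive ranges) with metadata columns \code{motif},
#'   \code{canonical_motif}, \code{unit_size}, \code{repeat_count},
#'   \code{left_flank}, \code{right_flank}.
#' @export
scanSSRs <- function(sequences,
                     thresholds = c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L,
                                    `6` = 5L)) {
  units <- as.integer(names(thresholds))
  if (any(is.na(units)) || any(units < 2L) || any(units > 6L))
    stop("thresholds must be named by unit sizes 2-6")
  nms <- names(sequences)
  seqs <- as.character(sequences)
  if (is.null(nms)) nms <- sprintf("seq%d", seq_along(seqs))
  hits <- list()
  for (si in seq_along(seqs)) {
    chars <- strsplit(toupper(seqs[si]), "", fixed = TRUE)[[1]]
    n <- length(chars)
    for (ui in seq_along(units)) {
      h <- .scanUnit(chars, units[ui], as.integer(thresholds[ui]))
      if (!is.null(h)) {
        h$seqname <- nms[si]
        h$left_flank <- h$start - 1L
        h$right_flank <- n - h$end
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (!length(hits)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motif = character(0), canonical_motif = character(0),
      unit_size = integer(0), repeat_count = integer(0),
      left_flank = integer(0), right_flank = integer(0))
    return(gr)
  }
  df <- do.call(rbind, hits)
  df <- df[order(match(df$seqname, nms), df$start, df$unit_size), ,
           drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqname,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    motif = df$motif, canonical_motif = canonicalMotif(df$motif),
    unit_size = df$unit_size, repeat_count = df$repeat_count,
    left_flank = df$left_flank, right_flank = df$right_flank)
  gr
}

#' Summary statistics of an SSR scan
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}}.
#' @return A list with \code{unit_counts} (data.frame unit_size/count,
#'   the classic unit-size breakdown), \code{motif_ranking} (canonical
#'   motif, count, percentage of all loci, most frequent first),
#'   \code{n_loci} and \code{n_sequences} (distinct sequences carrying at
#'   least one SSR).
#' @export
ssrSummary <- function(loci) {
  mc <- S4Vectors::mcols(loci)
  unit_counts <- data.frame(
    unit_size = 2:6,
    count = vapply(2:6, function(u) sum(mc$unit_size == u), integer(1)))
  if (length(loci)) {
    t0 <- sort(table(mc$canonical_motif), decreasing = TRUE)
    ranking <- data.frame(canonical_motif = names(t0),
                          count = as.integer(t0),
                          pct = 100 * as.integer(t0) / length(loci),
                          stringsAsFactors = FALSE)
  } else {
    ranking <- data.frame(canonical_motif = character(0), count = integer(0),
                          pct = numeric(0))
  }
  list(unit_counts = unit_counts, motif_ranking = ranking,
       n_loci = length(loci),
       n_sequences = length(unique(as.character(
         GenomicRanges::seqnames(loci)))))
}

#' Flank-sufficiency check for primer design
#'
#' A locus is primer-ready when both flanking sequences are at least
#' \code{minFlank} bases long.
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}}.
#' @param minFlank Minimum flank length in bases (default 50).
#' @return Logical vector parallel to \code{loci}.
#' @export
checkFlanks <- function(loci, minFlank = 50L) {
  mc <- S4Vectors::mcols(loci)
  mc$left_flank >= minFlank & mc$right_flank >= minFlank
}

#' Convert SSR loci to GFF3 microsatellite features
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}}.
#' @return A \code{GRanges} ready for \code{\link{writeGFF3}} with type
#'   \code{microsatellite} and motif/repeats attributes.
#' @export
ssrToGFF <- function(loci) {
  gr <- loci
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rep("microsatellite", length(gr)),
    motif = mc$motif, canonical = mc$canonical_motif,
    repeats = mc$repeat_count)
  gr
}
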