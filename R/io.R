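#' Structured EST identifier schema
#'
#' EST read identifiers encode the source library, the physical cDNA
#' clone and the sequenced end. The default layout is
#' \code{<library>|<clone>|<5p|3p>}, e.g. \code{MNRP2|c0001|5p}.
#'
#' @param sep Field separator (single character, default \code{"|"}).
#' @param fields Order of the three fields within the identifier; a
#'   permutation of \code{c("library_id", "clone_id", "end")}.
#' @return A list describing the schema, for use with the readers/writers.
#' @export
estIdSchema <- function(sep = "|",
                        fields = c("library_id", "clone_id", "end")) {
  stopifnot(setequal(fields, c("library_id", "clone_id", "end")))
  list(sep = sep, fields = fields)
}

.parseHeaders <- function(headers, schema) {
  parts <- strsplit(headers, schema$sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)
    stop("malformed read identifier (expected 3 '", schema$sep,
         "'-separated fields) in record(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  m <- do.call(rbind, parts)
  colnames(m) <- schema$fields
  ends <- m[, "end"]
  if (!all(ends %in% c("5p", "3p")))
    stop("read end field must be '5p' or '3p'; offending record(s): ",
         paste(utils::head(which(!ends %in% c("5p", "3p")), 5), collapse = ", "))
  m
}

.buildHeaders <- function(info, schema) {
  cols <- lapply(schema$fields, function(f) info[[f]])
  do.call(paste, c(cols, sep = schema$sep))
}

#' Read EST reads from FASTA/FASTQ
#'
#' Record identifiers must follow the configured schema (see
#' \code{\link{estIdSchema}}). Lowercase bases are uppercased; N is
#' allowed. FASTQ qualities are Sanger-encoded (phred+33); a quality
#' string whose length differs from its sequence is a hard error
#' (raised by the underlying parser).
#'
#' @param path Path to the file.
#' @param schema Identifier schema, default \code{estIdSchema()}.
#' @return An \link{ESTReadSet}. An empty file yields an empty set.
#' @export
readESTFasta <- function(path, schema = estIdSchema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  .readsFromStringSet(seqs, NULL, schema)
}

#' @rdname readESTFasta
#' @export
readESTFastq <- function(path, schema = estIdSchema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # parser notice about dropped mcols; irrelevant here
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual <- methods::as(Biostrings::quality(seqs), "PhredQuality")
  qlen <- nchar(as.character(qual))
  bad <- which(qlen != Biostrings::width(seqs))
  if (length(bad))
    stop("FASTQ quality/sequence length mismatch in record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  .readsFromStringSet(seqs, qual, schema)
}

.readsFromStringSet <- function(seqs, qualities, schema) {
  if (length(seqs) == 0L)
    return(ESTReadSet(Biostrings::DNAStringSet(), read_id = character(0),
                      clone_id = character(0), end = character(0),
                      library_id = character(0)))
  headers <- sub("\\s.*$", "", names(seqs))
  info <- .parseHeaders(headers, schema)
  ESTReadSet(Biostrings::DNAStringSet(seqs), read_id = headers,
             clone_id = info[, "clone_id"], end = info[, "end"],
             library_id = info[, "library_id"], qualities = qualities)
}

#' Write EST reads to FASTA/FASTQ
#'
#' Headers are rebuilt from the read table through the schema, so a
#' write-then-read round trip reproduces all fields. \code{writeESTFastq}
#' requires qualities.
#'
#' @param reads An \link{ESTReadSet}.
#' @param path Output path.
#' @param schema Identifier schema, default \code{estIdSchema()}.
#' @return Invisibly, \code{path}.
#' @export
writeESTFasta <- function(reads, path, schema = estIdSchema()) {
  seqs <- estSequences(reads)
  names(seqs) <- .buildHeaders(readInfo(reads), schema)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' @rdname writeESTFasta
#' @export
writeESTFastq <- function(reads, path, schema = estIdSchema()) {
  q <- estQualities(reads)
  if (is.null(q)) stop("FASTQ output requires qualities")
  seqs <- estSequences(reads)
  S4Vectors::mcols(seqs) <- NULL
  names(seqs) <- .buildHeaders(readInfo(reads), schema)
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, q)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read / write the cDNA library metadata table
#'
#' Tab-separated with columns \code{library_id}, \code{cultivar},
#' \code{tissue}, \code{normalized} (logical), \code{library_type}
#' (\code{FULL_LENGTH} or \code{STANDARD}). Normalized or subtracted
#' libraries are excluded from digital expression, which is why the flag
#' is mandatory.
#'
#' @param path Path to the TSV file.
#' @return \code{readLibraryMetadata}: a data.frame.
#' @export
readLibraryMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validateMetadata(df)
}

#' @rdname readLibraryMetadata
#' @param metadata Library metadata data.frame.
#' @export
writeLibraryMetadata <- function(metadata, path) {
  .validateMetadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.validateMetadata <- function(df) {
  need <- c("library_id", "cultivar", "tissue", "normalized", "library_type")
  if (!all(need %in% colnames(df)))
    stop("library metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$library_id))
    stop("library_id must be unique")
  df$normalized <- as.logical(df$normalized)
  if (anyNA(df$normalized)) stop("'normalized' must be TRUE/FALSE")
  if (!all(df$library_type %in% c("FULL_LENGTH", "STANDARD")))
    stop("library_type must be FULL_LENGTH or STANDARD")
  df
}

.lookupLibraries <- function(library_ids, metadata, what = "read") {
  idx <- match(library_ids, metadata$library_id)
  if (anyNA(idx)) {
    bad <- unique(library_ids[is.na(idx)])
    stop(what, " from unknown library: ", paste(utils::head(bad, 5),
                                                collapse = ", "))
  }
  idx
}

#' Write annotation features to GFF3
#'
#' Features use the standard R/Bioconductor 1-based inclusive coordinates
#' (as \link[GenomicRanges]{GRanges}), which map one-to-one onto GFF3
#' coordinates. Feature types used by the pipeline are \code{CDS},
#' \code{five_prime_UTR}, \code{three_prime_UTR} and
#' \code{microsatellite}; extra metadata columns (e.g. \code{motif},
#' \code{repeats}) are written as GFF3 attributes.
#'
#' @param features A \code{GRanges} with a \code{type} metadata column (or
#'   something coercible to one). Zero-width ranges are rejected.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGFF3 <- function(features, path) {
  features <- methods::as(features, "GRanges")
  if (length(features) && any(GenomicRanges::width(features) < 1L))
    stop("feature end < start: zero-width features cannot be written")
  mc <- S4Vectors::mcols(features)
  if (!is.null(mc$type) && is.null(mc$phase) && any(mc$type == "CDS")) {
    # GFF3 requires a phase on CDS features
    mc$phase <- ifelse(mc$type == "CDS", 0L, NA_integer_)
    S4Vectors::mcols(features) <- mc
  }
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGFF3
#' @return \code{readGFF3}: a \code{GRanges} (round-trips what
#'   \code{writeGFF3} wrote).
#' @export
readGFF3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}
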