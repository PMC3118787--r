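# Cross-cultivar SNP discovery from unigene padded alignments:
# consensus-disagreement candidates filtered by per-cultivar coverage and
# allele disjointness, then classified as transition / transversion / indel.

# Long-format observation table for one unigene's padded alignment.
# Returns data.table: column (alignment column), consensus_pos (NA for
# gap-majority columns), read_id, cultivar, base (A/C/G/T/N/-).
.pileupOne <- function(unigenes, ug, metadata) {
  members <- unigeneMembers(unigenes)
  mm <- members[members$unigene_id == ug, , drop = FALSE]
  if (!nrow(mm)) stop("unknown unigene: ", ug)
  libs <- if (exists(".libLookup", envir = .pileupEnv)) {
    lk <- get(".libLookup", envir = .pileupEnv)
    unname(lk[mm$read_id])
  } else {
    .memberLibraries(mm$read_id)
  }
  if (anyNA(libs)) stop("could not resolve the source library of read(s): ",
                        paste(utils::head(mm$read_id[is.na(libs)], 3),
                              collapse = ", "))
  libIdx <- .lookupLibraries(libs, metadata)
  cultivar <- metadata$cultivar[libIdx]
  cmap <- unigenes@columnMaps[[ug]]
  lens <- nchar(mm$aligned)
  W <- max(mm$offset + lens - 1L)
  if (is.null(cmap)) cmap <- seq_len(W)
  rows <- lapply(seq_len(nrow(mm)), function(i) {
    cols <- seq.int(mm$offset[i], mm$offset[i] + lens[i] - 1L)
    data.table::data.table(
      column = cols, read_id = mm$read_id[i], cultivar = cultivar[i],
      base = strsplit(mm$aligned[i], "", fixed = TRUE)[[1]])
  })
  dt <- data.table::rbindlist(rows)
  dt[, consensus_pos := cmap[column]]
  data.table::setcolorder(dt, c("column", "consensus_pos", "read_id",
                                "cultivar", "base"))
  data.table::setorder(dt, column, cultivar, read_id)
  dt[]
}

.memberLibraries <- function(read_ids) {
  # read ids follow the id schema <library>|<clone>|<end>; used only as a
  # fallback when no read set is supplied alongside the unigenes
  vapply(strsplit(read_ids, "|", fixed = TRUE), `[[`, character(1), 1L)
}

#' Pileup of one unigene's padded alignment
#'
#' One row per (alignment column, spanning read): the observed base
#' (A/C/G/T/N or \code{"-"} for an alignment gap) and the cultivar of the
#' read's source library. Reads not spanning a column contribute nothing
#' there. N observations are recorded but ignored by the downstream SNP
#' filters.
#'
#' @param unigenes A \link{UnigeneSet}.
#' @param unigene A unigene id.
#' @param metadata Library metadata (maps libraries to cultivars).
#' @param reads Optional \link{ESTReadSet}; when given, read libraries
#'   are taken from it instead of being parsed out of the read ids.
#' @return A data.frame with columns column, consensus_pos, read_id,
#'   cultivar, base.
#' @export
unigenePileup <- function(unigenes, unigene, metadata, reads = NULL) {
  if (!is.null(reads)) {
    info <- readInfo(reads)
    # temporary schema-independent lookup table
    assign(".libLookup", stats::setNames(info$library_id, info$read_id),
           envir = .pileupEnv)
    on.exit(rm(".libLookup", envir = .pileupEnv))
  }
  as.data.frame(.pileupOne(unigenes, unigene, metadata))
}

.pileupEnv <- new.env(parent = emptyenv())

#' Detect and filter SNP candidates between two cultivars
#'
#' Candidate columns are alignment columns where the two cultivars'
#' non-N observations are both non-empty and their majority bases
#' differ. A candidate passes when (1) each cultivar has at least
#' \code{minCov} non-N observations at the column, and (2) the two
#' cultivars' observed base sets (gaps included, N excluded) are
#' disjoint — any shared observed base fails. Failures are reported with
#' status \code{FAIL_COVERAGE} (checked first) or
#' \code{FAIL_SHARED_BASE}; passing candidates are classified by
#' \code{\link{classifyVariant}} on the two majority alleles.
#'
#' @param unigenes A \link{UnigeneSet}.
#' @param metadata Library metadata mapping libraries to cultivars.
#' @param cultivars Character vector of length 2, or NULL to analyze all
#'   unordered cultivar pairs present in the data.
#' @param minCov Minimum non-N coverage per cultivar (default 2).
#' @param unigeneIds Optional subset of unigenes to scan (default all).
#' @param reads Optional \link{ESTReadSet} used to resolve read
#'   libraries.
#' @return A data.frame with one row per candidate column and cultivar
#'   pair: unigene, position (consensus coordinate; NA for gap-majority
#'   columns), column, cultivar_a, cultivar_b (alphabetical), allele_a,
#'   allele_b (majority observation), alleles_a, alleles_b (full
#'   base:count maps), cov_a, cov_b, status, class.
#' @export
detectSNPs <- function(unigenes, metadata, cultivars = NULL, minCov = 2L,
                       unigeneIds = NULL, reads = NULL) {
  if (!is.null(reads)) {
    info <- readInfo(reads)
    assign(".libLookup", stats::setNames(info$library_id, info$read_id),
           envir = .pileupEnv)
    on.exit(rm(".libLookup", envir = .pileupEnv))
  }
  if (is.null(unigeneIds)) unigeneIds <- unigeneIDs(unigenes)
  res <- lapply(unigeneIds, function(ug) {
    .detectOne(unigenes, ug, metadata, cultivars, minCov)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(.emptySNPFrame())
  out <- data.table::rbindlist(res)
  data.table::setorder(out, unigene, column, cultivar_a, cultivar_b)
  as.data.frame(out)
}

.emptySNPFrame <- function() {
  data.frame(unigene = character(0), position = integer(0),
             column = integer(0), cultivar_a = character(0),
             cultivar_b = character(0), allele_a = character(0),
             allele_b = character(0), alleles_a = character(0),
             alleles_b = character(0), cov_a = integer(0),
             cov_b = integer(0), status = character(0),
             class = character(0), stringsAsFactors = FALSE)
}

.detectOne <- function(unigenes, ug, metadata, cultivars, minCov) {
  dt <- .pileupOne(unigenes, ug, metadata)
  dt <- dt[base != "N"]
  if (!nrow(dt)) return(NULL)
  pairs <- if (is.null(cultivars)) {
    cs <- sort(unique(dt$cultivar))
    if (length(cs) < 2L) return(NULL)
    utils::combn(cs, 2L, simplify = FALSE)
  } else {
    if (length(cultivars) != 2L) stop("exactly two cultivars are required")
    list(sort(cultivars))
  }
  cnt <- dt[, list(nobs = .N), by = c("column", "consensus_pos", "cultivar",
                                      "base")]
  # quick pre-screen: columns with >1 distinct observed base overall
  nb <- cnt[, list(nb = length(unique(base))), by = "column"]
  cnt <- cnt[column %in% nb$column[nb$nb > 1L]]
  if (!nrow(cnt)) return(NULL)
  out <- list()
  baseOrder <- c("A", "C", "G", "T", "-")
  for (pr in pairs) {
    ca <- pr[1]; cb <- pr[2]
    sub <- cnt[cultivar %in% pr]
    cols <- sort(unique(sub$column))
    for (col in cols) {
      oa <- sub[column == col & cultivar == ca]
      ob <- sub[column == col & cultivar == cb]
      if (!nrow(oa) || !nrow(ob)) next
      majA <- .majorityBase(oa$base, oa$nobs, baseOrder)
      majB <- .majorityBase(ob$base, ob$nobs, baseOrder)
      if (majA == majB) next
      covA <- sum(oa$nobs); covB <- sum(ob$nobs)
      status <- if (covA < minCov || covB < minCov) "FAIL_COVERAGE"
        else if (length(intersect(oa$base, ob$base))) "FAIL_SHARED_BASE"
        else "PASS"
      cls <- if (status == "PASS") classifyVariant(majA, majB) else
        NA_character_
      out[[length(out) + 1L]] <- data.table::data.table(
        unigene = ug, position = oa$consensus_pos[1], column = col,
        cultivar_a = ca, cultivar_b = cb, allele_a = majA, allele_b = majB,
        alleles_a = paste0(oa$base, ":", oa$nobs, collapse = ","),
        alleles_b = paste0(ob$base, ":", ob$nobs, collapse = ","),
        cov_a = covA, cov_b = covB, status = status, class = cls)
    }
  }
  if (!length(out)) return(NULL)
  data.table::rbindlist(out)
}

.majorityBase <- function(bases, counts, baseOrder) {
  o <- order(-counts, match(bases, baseOrder))
  bases[o[1]]
}

#' Classify a variant allele pair
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) substitutions are
#' transitions, all other base pairs transversions; a gap allele on
#' either side makes the variant a single-base indel. Classification is
#' symmetric in its arguments; equal alleles are an error.
#'
#' @param a,b Allele characters (A/C/G/T or \code{"-"}); vectorised.
#' @return Character vector: "TRANSITION", "TRANSVERSION" or "INDEL".
#' @export
classifyVariant <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(a == b)) stop("equal alleles do not form a variant")
  ok <- c("A", "C", "G", "T", "-")
  if (!all(a %in% ok) || !all(b %in% ok))
    stop("alleles must be A, C, G, T or '-'")
  out <- rep("TRANSVERSION", length(a))
  out[a == "-" | b == "-"] <- "INDEL"
  key <- paste(pmin(a, b), pmax(a, b))
  out[key %in% c("A G", "C T")] <- "TRANSITION"
  out
}

#' Tabulate SNP candidates into the classic per-type report
#'
#' Counts passing SNPs per unordered allele-pair type (the smaller base
#' first, gaps written second, e.g. "A -> G", "T -> -"), sums the
#' transition/transversion/indel class subtotals and the grand total, and
#' counts the distinct unigenes carrying at least one passing SNP.
#'
#' @param candidates Output of \code{\link{detectSNPs}}.
#' @return A list with \code{types} (data.frame: type, class, count),
#'   \code{subtotals} (named: transition, transversion, indel),
#'   \code{total} and \code{n_unigenes}.
#' @export
snpSummary <- function(candidates) {
  pass <- candidates[candidates$status == "PASS", , drop = FALSE]
  if (!nrow(pass)) {
    return(list(types = data.frame(type = character(0), class = character(0),
                                   count = integer(0)),
                subtotals = c(transition = 0L, transversion = 0L,
                              indel = 0L),
                total = 0L, n_unigenes = 0L))
  }
  a <- pass$allele_a; b <- pass$allele_b
  gap <- a == "-" | b == "-"
  first <- ifelse(gap, ifelse(a == "-", b, a), pmin(a, b))
  second <- ifelse(gap, "-", pmax(a, b))
  type <- paste(first, "->", second)
  cls <- tolower(classifyVariant(first, second))
  t0 <- table(type)
  types <- data.frame(type = names(t0), count = as.integer(t0),
                      stringsAsFactors = FALSE)
  types$class <- tolower(classifyVariant(sub(" ->.*", "", types$type),
                                         sub(".*-> ", "", types$type)))
  types <- types[order(types$class, -types$count), c("type", "class",
                                                     "count")]
  rownames(types) <- NULL
  subtotals <- c(
    transition = sum(types$count[types$class == "transition"]),
    transversion = sum(types$count[types$class == "transversion"]),
    indel = sum(types$count[types$class == "indel"]))
  list(types = types, subtotals = subtotals, total = sum(types$count),
       n_unigenes = length(unique(pass$unigene)))
}
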