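# Digital differential expression from EST counts: the Stekel-Git-Falciani
# log-likelihood R statistic, chi-square / Monte-Carlo p-values,
# Benjamini-Hochberg correction and the tissue-specificity call.

#' Build the unigene x tissue EST count matrix
#'
#' EST copy numbers from non-normalized libraries approximate relative
#' expression, so counts are aggregated per unigene per tissue over all
#' libraries that are neither normalized nor subtracted; normalized
#' libraries contribute nothing. Reads from a library absent from the
#' metadata are a hard error.
#'
#' @param unigenes A \link{UnigeneSet} (or a data.frame with read_id and
#'   unigene_id) assigning reads to unigenes.
#' @param reads The \link{ESTReadSet} whose reads were assigned.
#' @param metadata Library metadata with the \code{normalized} flag and
#'   \code{tissue} column.
#' @return An \link{ESTCountMatrix} with one row per unigene (all
#'   unigenes of the set, zero rows included) and one column per tissue
#'   present in the non-normalized metadata.
#' @export
buildCountMatrix <- function(unigenes, reads, metadata) {
  membership <- if (methods::is(unigenes, "UnigeneSet"))
    as.data.frame(membershipTable(unigenes)) else as.data.frame(unigenes)
  info <- as.data.frame(readInfo(reads))
  libIdx <- .lookupLibraries(info$library_id, metadata)
  tissues <- unique(metadata$tissue[!metadata$normalized])
  ug <- membership$unigene_id[match(info$read_id, membership$read_id)]
  useRead <- !is.na(ug) & !metadata$normalized[libIdx]
  allUg <- if (methods::is(unigenes, "UnigeneSet")) unigeneIDs(unigenes) else
    sort(unique(membership$unigene_id))
  counts <- table(factor(ug[useRead], levels = allUg),
                  factor(metadata$tissue[libIdx][useRead], levels = tissues))
  m <- matrix(as.integer(counts), nrow = length(allUg),
              dimnames = list(allUg, tissues))
  ESTCountMatrix(m)
}

#' Stekel-Git-Falciani R statistic
#'
#' Log-likelihood ratio statistic for heterogeneity of a gene's EST
#' counts across libraries/tissues:
#' \deqn{R = \sum_i x_i \ln\frac{x_i}{N_i f}, \qquad
#'       f = \frac{\sum_i x_i}{\sum_i N_i},}
#' with \eqn{0 \ln 0 \equiv 0}. \eqn{R \ge 0}, and \eqn{R = 0} exactly
#' when all per-tissue proportions \eqn{x_i/N_i} are equal. Twice R is
#' the Poisson (log-linear) likelihood-ratio statistic for a common
#' proportion, which is what the chi-square p-value relies on.
#'
#' @param x Non-negative integer counts per group (length >= 2, sum >= 1).
#' @param N Positive totals per group, \code{N[i] >= x[i]}.
#' @return The statistic R (a single non-negative number).
#' @export
stekelR <- function(x, N) {
  if (length(x) != length(N) || length(x) < 2L)
    stop("x and N must have equal length >= 2")
  if (any(N <= 0)) stop("all totals N must be positive")
  if (any(x < 0) || any(x > N)) stop("counts must satisfy 0 <= x <= N")
  if (sum(x) < 1) stop("sum(x) must be >= 1 (f undefined otherwise)")
  f <- sum(x) / sum(N)
  terms <- ifelse(x > 0, x * log(x / (N * f)), 0)
  max(sum(terms), 0)
}

#' P-value for the R statistic
#'
#' \code{method = "chisq"}: the asymptotic upper tail of a chi-square
#' distribution with \code{m - 1} degrees of freedom evaluated at
#' \code{2R} (likelihood-ratio equivalence; df = 1 for a pairwise test).
#' \code{method = "montecarlo"}: the total \code{sum(x)} is re-split
#' between the groups under the pooled proportion (multinomial over the
#' \code{N} weights; binomial splitting for two groups) and the p-value
#' is the add-one-corrected fraction of replicates with \code{R* >= R}.
#'
#' @param x,N Counts and totals as in \code{\link{stekelR}}.
#' @param method "chisq" or "montecarlo".
#' @param mcReps Number of Monte-Carlo replicates (default 10000).
#' @param seed Optional seed for the Monte-Carlo method.
#' @return P-value in [0, 1].
#' @export
stekelPValue <- function(x, N, method = c("chisq", "montecarlo"),
                         mcReps = 10000L, seed = NULL) {
  method <- match.arg(method)
  R <- stekelR(x, N)
  m <- length(x)
  if (method == "chisq")
    return(stats::pchisq(2 * R, df = m - 1L, lower.tail = FALSE))
  if (!is.null(seed)) set.seed(seed)
  tot <- sum(x)
  w <- N / sum(N)
  hits <- 0L
  for (i in seq_len(mcReps)) {
    xs <- as.integer(stats::rmultinom(1L, tot, w))
    Rs <- stekelR(xs, N)
    if (Rs >= R - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (mcReps + 1L)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, clipped at 1
#' (delegates to \code{stats::p.adjust(method = "BH")} after validation).
#'
#' @param p Raw p-values in [0, 1].
#' @return Adjusted q-values, same length and order as \code{p}.
#' @export
bhFDR <- function(p) {
  if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1)))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# All pairwise tests for every unigene; vectorised over unigenes per pair.
.pairwiseTests <- function(mat, minPairTotal, pMethod, mcReps) {
  counts <- estCounts(mat)
  totals <- tissueTotals(mat)
  tissues <- tissueNames(mat)
  if (length(tissues) < 2L) stop("at least 2 tissues are required")
  out <- list()
  for (i in seq_len(length(tissues) - 1L)) {
    for (j in (i + 1L):length(tissues)) {
      xa <- counts[, i]; xb <- counts[, j]
      Na <- totals[i]; Nb <- totals[j]
      keep <- (xa + xb) >= minPairTotal
      if (!any(keep)) next
      xa <- xa[keep]; xb <- xb[keep]
      f <- (xa + xb) / (Na + Nb)
      R <- ifelse(xa > 0, xa * log(xa / (Na * f)), 0) +
        ifelse(xb > 0, xb * log(xb / (Nb * f)), 0)
      R <- pmax(R, 0)
      if (pMethod == "chisq") {
        p <- stats::pchisq(2 * R, df = 1L, lower.tail = FALSE)
      } else {
        p <- vapply(seq_along(xa), function(g) {
          stekelPValue(c(xa[g], xb[g]), c(Na, Nb), method = "montecarlo",
                       mcReps = mcReps)
        }, numeric(1))
      }
      pa <- xa / Na; pb <- xb / Nb
      out[[length(out) + 1L]] <- data.frame(
        unigene = rownames(counts)[keep],
        tissue_a = tissues[i], tissue_b = tissues[j],
        x_a = xa, x_b = xb, N_a = Na, N_b = Nb,
        f = f, R = R, p = p,
        ratio_ab = ifelse(pb == 0, Inf, pa / pb),
        ratio_ba = ifelse(pa == 0, Inf, pb / pa),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(out))
    return(data.frame(unigene = character(0), tissue_a = character(0),
                      tissue_b = character(0), x_a = integer(0),
                      x_b = integer(0), N_a = numeric(0), N_b = numeric(0),
                      f = numeric(0), R = numeric(0), p = numeric(0),
                      ratio_ab = numeric(0), ratio_ba = numeric(0),
                      q = numeric(0)))
  tests <- do.call(rbind, out)
  tests$q <- bhFDR(tests$p)
  tests
}

#' Call tissue-specific genes from the count matrix
#'
#' For every unigene and unordered tissue pair with at least
#' \code{minPairTotal} ESTs in the two compared tissues, the R statistic
#' and its p-value are computed; q-values are Benjamini-Hochberg adjusted
#' jointly across all computed tests. The abundance ratio is taken on
#' library-size-normalized proportions \eqn{(x_a/N_a)/(x_b/N_b)}, with a
#' zero denominator mapping to infinity. A unigene is called specific to
#' tissue t when, against \emph{every} other tissue, the comparison
#' exists (was not blocked by the count filter), has ratio >
#' \code{minRatio} with t on the up side, and q < \code{maxFDR}; a
#' blocked comparison vetoes the call.
#'
#' @param mat An \link{ESTCountMatrix}.
#' @param minPairTotal Minimum summed EST count per compared pair
#'   (default 5).
#' @param minRatio Ratio threshold (default 2, strict).
#' @param maxFDR FDR threshold (default 0.05, strict).
#' @param pMethod "chisq" (default) or "montecarlo".
#' @param mcReps Monte-Carlo replicates when \code{pMethod} is
#'   "montecarlo".
#' @return A list with \code{tests} (one row per unigene x pair:
#'   unigene, tissue_a, tissue_b, x_a, x_b, N_a, N_b, f, R, p, q,
#'   ratio_ab, ratio_ba) and \code{calls} (unigene, tissue, n_support).
#' @export
callTissueSpecific <- function(mat, minPairTotal = 5L, minRatio = 2,
                               maxFDR = 0.05, pMethod = c("chisq",
                                                          "montecarlo"),
                               mcReps = 10000L) {
  pMethod <- match.arg(pMethod)
  tests <- .pairwiseTests(mat, minPairTotal, pMethod, mcReps)
  tissues <- tissueNames(mat)
  nOther <- length(tissues) - 1L
  calls <- data.frame(unigene = character(0), tissue = character(0),
                      n_support = integer(0))
  if (nrow(tests)) {
    dt <- data.table::as.data.table(tests)
    up <- rbind(
      dt[, list(unigene, tissue = tissue_a, other = tissue_b,
                ok = ratio_ab > minRatio & q < maxFDR)],
      dt[, list(unigene, tissue = tissue_b, other = tissue_a,
                ok = ratio_ba > minRatio & q < maxFDR)])
    agg <- up[, list(n_pass = sum(ok)), by = c("unigene", "tissue")]
    hit <- agg[agg$n_pass == nOther]
    if (nrow(hit))
      calls <- data.frame(unigene = hit$unigene, tissue = hit$tissue,
                          n_support = hit$n_pass, stringsAsFactors = FALSE)
    calls <- calls[order(calls$tissue, calls$unigene), , drop = FALSE]
    rownames(calls) <- NULL
  }
  list(tests = tests, calls = calls)
}

#' Export the normalized abundance matrix of tissue-specific genes
#'
#' Rows are the called unigenes (grouped by the tissue they are specific
#' to), columns the tissues, values the per-10,000 normalized abundances
#' \eqn{10^4 x/N}. Optionally writes a TSV and renders a heatmap (via
#' the pheatmap package, when installed).
#'
#' @param calls The \code{calls} data.frame from
#'   \code{\link{callTissueSpecific}}.
#' @param mat The \link{ESTCountMatrix}.
#' @param path Optional TSV output path.
#' @param imageFile Optional PNG output path for the heatmap.
#' @return The abundance data.frame (invisibly when \code{path} given).
#' @export
exportHeatmapMatrix <- function(calls, mat, path = NULL, imageFile = NULL) {
  counts <- estCounts(mat)
  totals <- tissueTotals(mat)
  if (nrow(calls)) {
    sel <- calls[order(calls$tissue, calls$unigene), , drop = FALSE]
    vals <- sweep(counts[sel$unigene, , drop = FALSE], 2, totals, "/") * 1e4
    out <- data.frame(unigene = sel$unigene, specific_tissue = sel$tissue,
                      as.data.frame(vals, check.names = FALSE),
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(unigene = character(0), specific_tissue = character(0))
    for (t in tissueNames(mat)) out[[t]] <- numeric(0)
  }
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(imageFile) && nrow(out) > 1L &&
      requireNamespace("pheatmap", quietly = TRUE)) {
    m <- as.matrix(out[, -(1:2), drop = FALSE])
    rownames(m) <- out$unigene
    grDevices::png(imageFile, width = 800, height = 600)
    pheatmap::pheatmap(log2(m + 1), cluster_rows = FALSE,
                       cluster_cols = FALSE)
    grDevices::dev.off()
  }
  if (is.null(path)) out else invisible(out)
}
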