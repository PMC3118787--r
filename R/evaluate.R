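# Truth-based evaluation of a pipeline run against the generator's
# planted features: tissue-specific recall/false calls, SSR recovery
# with exact coordinates, and SNP recovery/precision.

# Map unigenes to (majority truth gene, reference-coordinate anchor).
# With error-free, indel-free synthetic reads, alignment column c of a
# member placed at `offset` corresponds to reference position
# readStart + c - offset of the member's source transcript.
.unigeneAnchors <- function(unigenes, readMap) {
  members <- as.data.frame(unigeneMembers(unigenes))
  idx <- match(members$read_id, readMap$read_id)
  members$gene <- readMap$gene_id[idx]
  members$truth_start <- readMap$start[idx]
  res <- lapply(split(members, members$unigene_id), function(mm) {
    gene <- names(sort(table(mm$gene), decreasing = TRUE))[1]
    mg <- mm[mm$gene == gene, , drop = FALSE]
    list(gene = gene,
         shift = mg$truth_start[1] - mg$offset[1],   # ref = col + shift
         purity = nrow(mg) / nrow(mm))
  })
  res
}

#' Evaluate tissue-specificity calls against the planted truth
#'
#' A planted tissue-specific gene counts as recovered when at least one
#' unigene whose majority of member reads stems from that gene is called
#' specific to the planted tissue. A false call is a call on a unigene
#' whose majority gene was not planted as tissue-specific.
#'
#' @param calls The \code{calls} data.frame from
#'   \code{\link{callTissueSpecific}}.
#' @param unigenes The \link{UnigeneSet}.
#' @param sim The synthetic study (needs \code{readMap} and
#'   \code{expression}).
#' @return A list: n_planted, n_recovered, recall, n_false_calls,
#'   false_call_unigenes.
#' @export
evaluateTissueSpecific <- function(calls, unigenes, sim) {
  anchors <- .unigeneAnchors(unigenes, sim$readMap)
  callGene <- vapply(calls$unigene, function(u) anchors[[u]]$gene,
                     character(1))
  planted <- sim$expression[sim$expression$specific, , drop = FALSE]
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    any(callGene == planted$gene_id[i] &
          calls$tissue == planted$specific_tissue[i])
  }, logical(1))
  isFalse <- !(callGene %in% planted$gene_id)
  list(n_planted = nrow(planted), n_recovered = sum(recovered),
       recall = if (nrow(planted)) sum(recovered) / nrow(planted) else
         NA_real_,
       n_false_calls = sum(isFalse),
       false_call_unigenes = calls$unigene[isFalse])
}

#' Evaluate SSR recovery against the planted truth
#'
#' A planted locus is evaluable when at least one simulated read spans
#' it completely (loci on unsequenced transcripts cannot be assembled);
#' it is recovered when the scan of the unigene consensus reports a
#' locus with exactly the planted motif, repeat count and (reference-
#' mapped) coordinates.
#'
#' @param loci SSR scan results (\code{GRanges} from
#'   \code{\link{scanSSRs}} on the unigene consensus).
#' @param unigenes The \link{UnigeneSet}.
#' @param sim The synthetic study (needs \code{ssr} and \code{readMap}).
#' @return A list: n_planted, n_evaluable, n_recovered, recovery (over
#'   evaluable loci).
#' @export
evaluateSSRRecovery <- function(loci, unigenes, sim) {
  truth <- sim$ssr
  if (!nrow(truth))
    return(list(n_planted = 0L, n_evaluable = 0L, n_recovered = 0L,
                recovery = NA_real_))
  anchors <- .unigeneAnchors(unigenes, sim$readMap)
  geneOf <- vapply(anchors, `[[`, character(1), "gene")
  rm <- sim$readMap
  lociDf <- as.data.frame(loci)
  recovered <- logical(nrow(truth))
  evaluable <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    evaluable[i] <- any(rm$gene_id == g & rm$start <= truth$start[i] &
                          rm$end >= truth$end[i])
    if (!evaluable[i]) next
    for (u in names(anchors)[geneOf == g]) {
      shift <- anchors[[u]]$shift
      hit <- lociDf$seqnames == u &
        lociDf$start + shift == truth$start[i] &
        lociDf$end + shift == truth$end[i] &
        lociDf$motif == truth$motif[i] &
        lociDf$repeat_count == truth$repeat_count[i]
      if (any(hit)) { recovered[i] <- TRUE; break }
    }
  }
  list(n_planted = nrow(truth), n_evaluable = sum(evaluable),
       n_recovered = sum(recovered & evaluable),
       recovery = if (sum(evaluable)) sum(recovered & evaluable) /
         sum(evaluable) else NA_real_)
}

#' Evaluate SNP recovery and precision against the planted truth
#'
#' A planted fixed difference is evaluable when, inside a single unigene
#' of its gene, both the alternate cultivar and at least one reference
#' cultivar have >= \code{minCov} member reads spanning the site; it is
#' recovered when a passing SNP with the planted alleles is reported at
#' the reference-mapped column for a cultivar pair involving the
#' alternate cultivar. Precision is the fraction of passing sites
#' (unique unigene/column/pair) that map onto planted differences.
#'
#' @param candidates Output of \code{\link{detectSNPs}}.
#' @param unigenes The \link{UnigeneSet}.
#' @param sim The synthetic study (needs \code{snp} and \code{readMap}).
#' @param minCov Coverage used in the eligibility condition (default 2).
#' @return A list: n_planted, n_evaluable, n_recovered, recovery,
#'   n_pass, n_true_pass, precision.
#' @export
evaluateSNPRecovery <- function(candidates, unigenes, sim, minCov = 2L) {
  truth <- sim$snp
  anchors <- .unigeneAnchors(unigenes, sim$readMap)
  geneOf <- vapply(anchors, `[[`, character(1), "gene")
  members <- as.data.frame(unigeneMembers(unigenes))
  rm <- sim$readMap
  midx <- match(members$read_id, rm$read_id)
  members$gene <- rm$gene_id[midx]
  members$cultivar <- rm$cultivar[midx]
  members$tstart <- rm$start[midx]
  members$tend <- rm$end[midx]
  pass <- candidates[candidates$status == "PASS", , drop = FALSE]

  evaluable <- logical(nrow(truth))
  recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    p <- truth$position[i]
    cv <- truth$cultivar[i]
    for (u in names(anchors)[geneOf == g]) {
      mm <- members[members$unigene_id == u & members$gene == g &
                      members$tstart <= p & members$tend >= p, ,
                    drop = FALSE]
      if (!nrow(mm)) next
      covAlt <- sum(mm$cultivar == cv)
      covRef <- table(mm$cultivar[mm$cultivar != cv])
      if (covAlt < minCov || !length(covRef) || max(covRef) < minCov) next
      evaluable[i] <- TRUE
      col <- p - anchors[[u]]$shift
      hit <- pass$unigene == u & pass$column == col &
        (pass$cultivar_a == cv | pass$cultivar_b == cv)
      if (any(hit)) {
        h <- pass[hit, , drop = FALSE]
        altSide <- ifelse(h$cultivar_a == cv, h$allele_a, h$allele_b)
        refSide <- ifelse(h$cultivar_a == cv, h$allele_b, h$allele_a)
        if (any(altSide == truth$alt_allele[i] &
                refSide == truth$ref_allele[i]))
          recovered[i] <- TRUE
      }
      if (evaluable[i]) break
    }
  }
  # precision over unique passing sites
  nTrue <- 0L; nPassSites <- 0L
  if (nrow(pass)) {
    siteKey <- paste(pass$unigene, pass$column)
    sites <- !duplicated(siteKey)
    nPassSites <- sum(sites)
    truthKey <- paste(truth$gene_id, truth$position)
    siteTrue <- vapply(which(sites), function(r) {
      u <- pass$unigene[r]
      refPos <- pass$column[r] + anchors[[u]]$shift
      paste(geneOf[u], refPos) %in% truthKey
    }, logical(1))
    nTrue <- sum(siteTrue)
  }
  list(n_planted = nrow(truth), n_evaluable = sum(evaluable),
       n_recovered = sum(recovered & evaluable),
       recovery = if (sum(evaluable)) sum(recovered & evaluable) /
         sum(evaluable) else NA_real_,
       n_pass = nPassSites, n_true_pass = nTrue,
       precision = if (nPassSites) nTrue / nPassSites else NA_real_)
}
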