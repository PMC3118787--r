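# Greedy overlap clustering of EST reads into unigenes.
#
# This is a deliberately simple stand-in for a dedicated EST assembler:
# ungapped overlap detection with the classic Sanger-EST thresholds
# (minimum overlap 40 bp, minimum identity 97%), single-linkage transitive
# closure, spanning-tree layout and per-column majority consensus.

#' Find the best ungapped overlap between two sequences
#'
#' Enumerates every dovetail or containment offset of \code{b} against
#' \code{a}, in both the given orientation (\code{FF}) and with \code{b}
#' reverse-complemented (\code{FR}), and scores each candidate by
#' \code{overlap_length * identity} (ungapped identity over the overlapped
#' region; N never matches). The best candidate meeting both thresholds is
#' returned; ties are broken by longer overlap, then FF before FR, then
#' the smaller offset.
#'
#' @param a,b DNA sequences (character or \code{DNAString}).
#' @param minOverlap Minimum overlap length in bases (default 40).
#' @param minIdentity Minimum ungapped identity over the overlap
#'   (default 0.97).
#' @return \code{NULL} if no candidate meets both thresholds, otherwise a
#'   list with \code{orientation} ("FF"/"FR"), \code{offset} (start of the
#'   oriented \code{b} relative to the start of \code{a}: \code{b} begins
#'   at position \code{offset + 1} of \code{a}'s coordinate system; may be
#'   negative), \code{overlap_length}, \code{identity} and \code{score}.
#' @export
findOverlap <- function(a, b, minOverlap = 40L, minIdentity = 0.97) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  La <- nchar(a); Lb <- nchar(b)
  if (La < minOverlap || Lb < minOverlap)
    stop("both sequences must be at least minOverlap long")
  ca <- .baseCodes(a)
  cands <- list(FF = .baseCodes(b), FR = .baseCodes(.revcompChar(b)))
  best <- NULL
  for (ori in c("FF", "FR")) {
    cb <- cands[[ori]]
    for (d in seq.int(-(Lb - minOverlap), La - minOverlap)) {
      s <- max(1L, d + 1L); e <- min(La, d + Lb)
      len <- e - s + 1L
      if (len < minOverlap) next
      xa <- ca[s:e]; xb <- cb[(s - d):(e - d)]
      ident <- sum(xa == xb & xa <= 4L) / len
      if (ident < minIdentity) next
      score <- len * ident
      if (is.null(best) || score > best$score ||
          (score == best$score && len > best$overlap_length)) {
        best <- list(orientation = ori, offset = d, overlap_length = len,
                     identity = ident, score = score)
      }
    }
  }
  best
}

# --- internal: seed-and-extend clustering machinery ------------------------

# Verify an ungapped overlap between read a (forward) and read b placed with
# orientation `bstrand` (relative to a's forward frame) at offset `doff`
# (oriented b starts at a-position doff + 1). Returns c(len, matches) or NULL.
.verifyOffset <- function(ca, cb, doff, minOverlap) {
  La <- length(ca); Lb <- length(cb)
  s <- max(1L, doff + 1L); e <- min(La, doff + Lb)
  len <- e - s + 1L
  if (len < minOverlap) return(NULL)
  xa <- ca[s:e]; xb <- cb[(s - doff):(e - doff)]
  c(len, sum(xa == xb & xa <= 4L))
}

# Majority consensus over a padded layout given integer base codes
# (A=1,C=2,G=3,T=4,N=5,-=6) and 1-based start columns. Ties between bases
# resolve in the fixed order A<C<G<T; N never wins a tie; columns in which
# gaps hold a strict majority are removed from the consensus but kept in
# the column map (NA entries).
.consensusCore <- function(codeList, offsets) {
  lens <- lengths(codeList)
  W <- max(offsets + lens - 1L)
  pos <- unlist(lapply(seq_along(codeList), function(i) {
    seq.int(offsets[i], offsets[i] + lens[i] - 1L)
  }), use.names = FALSE)
  codes <- unlist(codeList, use.names = FALSE)
  tab <- tabulate((pos - 1L) * 6L + codes, nbins = 6L * W)
  m <- matrix(tab, nrow = 6L)
  cov <- colSums(m)
  gapMajority <- m[6L, ] * 2L > cov
  baseCounts <- m[1:5, , drop = FALSE]
  winner <- max.col(t(baseCounts), ties.method = "first")
  winner[colSums(baseCounts) == 0L] <- 5L        # uncovered -> N
  keep <- !gapMajority
  columnMap <- rep(NA_integer_, W)
  columnMap[keep] <- cumsum(keep)[keep]
  list(consensus = .codesToString(winner[keep]), columnMap = columnMap,
       width = W)
}

#' Build a majority consensus from a padded layout
#'
#' Per-column majority vote over aligned member sequences. Ties between
#' bases are broken in the fixed order A < C < G < T; N never wins a tie;
#' columns where gaps (\code{"-"}) hold a strict majority are removed from
#' the consensus but retained in the padded alignment (their entry in the
#' returned column map is \code{NA}).
#'
#' @param aligned Character vector of aligned member sequences (may
#'   contain \code{"-"}), already oriented to the common strand.
#' @param offsets 1-based alignment column at which each member starts.
#' @return A list with \code{consensus} (character), \code{columnMap}
#'   (integer vector over alignment columns giving the consensus position,
#'   \code{NA} for removed gap columns) and \code{width} (number of
#'   alignment columns).
#' @export
buildConsensus <- function(aligned, offsets) {
  stopifnot(length(aligned) == length(offsets), length(aligned) >= 1L)
  .consensusCore(lapply(toupper(aligned), .baseCodes), as.integer(offsets))
}

#' Cluster EST reads into unigenes
#'
#' Single-linkage transitive closure over accepted pairwise overlaps
#' (see \code{\link{findOverlap}} for the acceptance rule). Candidate read
#' pairs are proposed by shared \code{seedLength}-mers (canonical over
#' both strands), each shared seed implying a candidate ungapped offset;
#' the best passing offset per pair is used. Accepted overlaps form a
#' spanning tree from which every member gets an orientation and a layout
#' position; 3' reads typically end up reverse-complemented (FR
#' orientation). The layout orientation is normalized so that the
#' majority of 5' reads are forward. Members whose ungapped identity to
#' the final consensus falls below \code{minIdentity} are demoted to
#' singletons with a warning (the layout-conflict error path).
#'
#' Reads are processed in lexicographic read-id order, so the result does
#' not depend on input order.
#'
#' @param reads An \link{ESTReadSet} (preprocessed).
#' @param minOverlap Minimum overlap in bases (default 40).
#' @param minIdentity Minimum ungapped identity (default 0.97).
#' @param seedLength Seed k-mer length used to propose candidate pairs;
#'   defaults to \code{minOverlap}. Two reads can only be linked directly
#'   if they share an exact seed, so for noisy reads a seed shorter than
#'   \code{minOverlap} is appropriate.
#' @return A \link{UnigeneSet}.
#' @export
clusterReads <- function(reads, minOverlap = 40L, minIdentity = 0.97,
                         seedLength = NULL) {
  if (is.null(seedLength)) seedLength <- minOverlap
  k <- as.integer(seedLength)
  info <- readInfo(reads)
  ord <- order(info$read_id, method = "radix")
  ids <- info$read_id[ord]
  ends <- info$end[ord]
  seqs <- as.character(estSequences(reads))[ord]
  n <- length(seqs)
  if (n == 0L)
    return(UnigeneSet(Biostrings::DNAStringSet(),
                      DataFrame(read_id = character(0),
                                unigene_id = character(0),
                                strand = character(0), offset = integer(0),
                                aligned = character(0))))
  lens <- nchar(seqs)
  rcs <- .revcompChar(seqs)
  codesF <- lapply(seqs, .baseCodes)
  codesR <- lapply(rcs, .baseCodes)

  edges <- .candidateEdges(seqs, rcs, lens, k)
  acc <- .acceptOverlaps(edges, codesF, codesR, lens, minOverlap, minIdentity)
  comp <- acc$component
  layout <- .layoutComponents(acc$edges, comp, lens, ends, n)

  # consensus per component, then demote members that disagree with it
  res <- .finalizeUnigenes(comp, layout, codesF, codesR, lens, seqs, rcs,
                           ids, minIdentity)
  res
}

# Candidate edge table from shared canonical k-mers.
# Returns data.table with columns a, b, bstrand ("+"/"-" relative to a's
# forward frame), doff (offset of oriented b in a's forward frame).
.candidateEdges <- function(seqs, rcs, lens, k) {
  n <- length(seqs)
  nk <- pmax(lens - k + 1L, 0L)
  if (sum(nk) == 0L) {
    return(data.table::data.table(a = integer(0), b = integer(0),
                                  bstrand = character(0), doff = integer(0)))
  }
  read <- rep.int(seq_len(n), nk)
  pos <- unlist(lapply(nk, seq_len), use.names = FALSE)
  kf <- substring(seqs[read], pos, pos + k - 1L)
  # position of the same physical k-mer on the reverse-complement strand
  posr <- lens[read] - pos - k + 2L
  kr <- substring(rcs[read], posr, posr + k - 1L)
  fwd <- kf <= kr
  canon <- kr; canon[fwd] <- kf[fwd]
  entry <- data.table::data.table(kmer = canon, read = read,
                                  pos = ifelse(fwd, pos, posr), fwd = fwd)
  rm(kf, kr, canon, pos, posr, read, fwd)
  entry <- entry[!grepl("N", kmer, fixed = TRUE)]
  if (nrow(entry) == 0L)
    return(data.table::data.table(a = integer(0), b = integer(0),
                                  bstrand = character(0), doff = integer(0)))
  data.table::setorder(entry, kmer, read, -fwd)
  entry[, grp := data.table::rleidv(entry, "kmer")]
  # anchor per group: first forward entry if any, else first entry
  anchors <- entry[entry[["fwd"]]][!duplicated(grp)]
  noFwd <- setdiff(unique(entry$grp), anchors$grp)
  if (length(noFwd))
    anchors <- rbind(anchors, entry[grp %in% noFwd][!duplicated(grp)])
  data.table::setnames(anchors, c("read", "pos", "fwd"),
                       c("aread", "apos", "afwd"))
  # first entry per (group, read)
  tgt <- entry[!duplicated(data.table::rleidv(entry, c("grp", "read")))]
  rm(entry)
  tgt <- anchors[, c("grp", "aread", "apos", "afwd")][tgt, on = "grp"]
  tgt <- tgt[read != aread]
  if (nrow(tgt) == 0L)
    return(data.table::data.table(a = integer(0), b = integer(0),
                                  bstrand = character(0), doff = integer(0)))
  # place oriented b in a's forward frame
  sameStrand <- tgt$afwd == tgt$fwd
  doff <- ifelse(tgt$afwd,
                 tgt$apos - tgt$pos,
                 lens[tgt$aread] - tgt$apos + tgt$pos - lens[tgt$read])
  bstrand <- ifelse(sameStrand, "+", "-")
  edges <- data.table::data.table(a = tgt$aread, b = tgt$read,
                                  bstrand = bstrand, doff = as.integer(doff))
  edges <- unique(edges)
  data.table::setorder(edges, a, b, bstrand, doff)
  edges
}

# Union-find over candidate edges with lazy overlap verification.
.acceptOverlaps <- function(edges, codesF, codesR, lens, minOverlap,
                            minIdentity) {
  n <- length(codesF)
  parent <- seq_len(n)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  accA <- integer(0); accB <- integer(0)
  accS <- character(0); accD <- integer(0)
  if (nrow(edges)) {
    pairId <- data.table::rleidv(edges, c("a", "b"))
    starts <- which(!duplicated(pairId))
    stops <- c(starts[-1L] - 1L, nrow(edges))
    ea <- edges$a; eb <- edges$b; es <- edges$bstrand; ed <- edges$doff
    for (g in seq_along(starts)) {
      i0 <- starts[g]
      a <- ea[i0]; b <- eb[i0]
      ra <- findRoot(a); rb <- findRoot(b)
      if (ra == rb) next
      best <- NULL
      for (i in i0:stops[g]) {
        cb <- if (es[i] == "+") codesF[[b]] else codesR[[b]]
        v <- .verifyOffset(codesF[[a]], cb, ed[i], minOverlap)
        if (is.null(v)) next
        ident <- v[2] / v[1]
        if (ident < minIdentity) next
        score <- v[1] * ident
        if (is.null(best) || score > best$score ||
            (score == best$score && v[1] > best$len)) {
          best <- list(score = score, len = v[1], strand = es[i],
                       doff = ed[i])
        }
      }
      if (!is.null(best)) {
        parent[ra] <- rb
        accA <- c(accA, a); accB <- c(accB, b)
        accS <- c(accS, best$strand); accD <- c(accD, best$doff)
      }
    }
  }
  component <- vapply(seq_len(n), findRoot, integer(1))
  list(component = component,
       edges = data.frame(a = accA, b = accB, bstrand = accS, doff = accD,
                          stringsAsFactors = FALSE))
}

# Assign each member an orientation and 1-based layout column by BFS over the
# accepted spanning edges; orient components so most 5' reads are forward.
.layoutComponents <- function(edges, component, lens, ends, n) {
  strand <- rep("+", n)
  pos <- rep(1L, n)
  if (nrow(edges)) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(edges))) {
      a <- edges$a[i]; b <- edges$b[i]
      adj[[a]] <- c(adj[[a]], i)
      adj[[b]] <- c(adj[[b]], -i)
    }
    visited <- rep(FALSE, n)
    for (root in seq_len(n)) {
      if (visited[root]) next
      visited[root] <- TRUE
      queue <- root
      while (length(queue)) {
        u <- queue[[1L]]; queue <- queue[-1L]
        for (se in adj[[u]]) {
          i <- abs(se)
          if (se > 0L) { v <- edges$b[i] } else { v <- edges$a[i] }
          if (visited[v]) next
          visited[v] <- TRUE
          if (se > 0L) {
            bs <- edges$bstrand[i]; d <- edges$doff[i]
          } else {
            # invert the transform: edge stored as a -> b
            bs <- edges$bstrand[i]
            d <- if (bs == "+") -edges$doff[i] else
              edges$doff[i] + lens[edges$b[i]] - lens[edges$a[i]]
          }
          if (strand[u] == "+") {
            strand[v] <- bs
            pos[v] <- pos[u] + d
          } else {
            strand[v] <- if (bs == "+") "-" else "+"
            pos[v] <- pos[u] + lens[u] - d - lens[v]
          }
          queue <- c(queue, v)
        }
      }
    }
  }
  # normalise each component: shift to column 1, orient by 5'-read majority
  for (root in unique(component)) {
    m <- which(component == root)
    votePlus <- sum(ends[m] == "5p" & strand[m] == "+") +
      sum(ends[m] == "3p" & strand[m] == "-")
    voteMinus <- sum(ends[m] == "5p" & strand[m] == "-") +
      sum(ends[m] == "3p" & strand[m] == "+")
    if (voteMinus > votePlus) {
      W <- max(pos[m] + lens[m] - 1L)
      pos[m] <- W - (pos[m] + lens[m] - 1L) + 1L
      strand[m] <- ifelse(strand[m] == "+", "-", "+")
    }
    pos[m] <- pos[m] - min(pos[m]) + 1L
  }
  list(strand = strand, pos = pos)
}

.finalizeUnigenes <- function(component, layout, codesF, codesR, lens, seqs,
                              rcs, ids, minIdentity) {
  n <- length(ids)
  strand <- layout$strand
  pos <- layout$pos
  comps <- split(seq_len(n), component)
  demoted <- integer(0)
  consensus <- character(0)
  groups <- list()
  for (m in comps) {
    if (length(m) > 1L) {
      codes <- lapply(m, function(i) {
        if (strand[i] == "+") codesF[[i]] else codesR[[i]]
      })
      cons <- .consensusCore(codes, pos[m])
      consCodes <- .baseCodes(cons$consensus)
      ok <- vapply(seq_along(m), function(j) {
        i <- m[j]
        span <- seq.int(pos[i], pos[i] + lens[i] - 1L)
        x <- codes[[j]]
        sum(x == consCodes[span] & x <= 4L) / lens[i] >= minIdentity
      }, logical(1))
      if (!all(ok)) {
        demoted <- c(demoted, m[!ok])
        m <- m[ok]
        if (length(m) > 1L) {
          codes <- codes[ok]
          pos[m] <- pos[m] - min(pos[m]) + 1L
          cons <- .consensusCore(codes, pos[m])
        }
      }
      if (length(m) == 0L) next
      if (length(m) == 1L) {
        strand[m] <- "+"; pos[m] <- 1L
        groups <- c(groups, list(list(members = m, cons = seqs[m])))
      } else {
        groups <- c(groups, list(list(members = m, cons = cons$consensus)))
      }
    } else {
      groups <- c(groups, list(list(members = m, cons = seqs[m])))
    }
  }
  if (length(demoted)) {
    warning(length(demoted),
            " read(s) inconsistent with their cluster consensus; demoted to singletons")
    for (i in demoted) {
      strand[i] <- "+"; pos[i] <- 1L
      groups <- c(groups, list(list(members = i, cons = seqs[i])))
    }
  }
  # deterministic unigene order: by smallest member read id
  minId <- vapply(groups, function(g) min(ids[g$members]), character(1))
  groups <- groups[order(minId, method = "radix")]
  ugid <- sprintf("U%05d", seq_along(groups))
  memberRows <- lapply(seq_along(groups), function(gi) {
    m <- groups[[gi]]$members
    o <- order(ids[m], method = "radix")
    m <- m[o]
    data.frame(read_id = ids[m], unigene_id = ugid[gi],
               strand = strand[m], offset = pos[m],
               aligned = ifelse(strand[m] == "+", seqs[m], rcs[m]),
               stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, memberRows)
  cons <- Biostrings::DNAStringSet(vapply(groups, `[[`, character(1), "cons"))
  names(cons) <- ugid
  UnigeneSet(cons, members)
}
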