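# Independent brute-force oracles used to verify the implementations.

# Longest clean interval by exhaustive enumeration of all intervals and
# all windows inside each.
oracleTrimInterval <- function(qual, window, maxError) {
  err <- 10^(-qual / 10)
  L <- length(err)
  eps <- 1e-12
  if (L <= window) {
    if (mean(err) > maxError + eps) return(c(NA_integer_, NA_integer_))
    return(c(1L, L))
  }
  best <- c(NA_integer_, NA_integer_)
  bestLen <- 0L
  for (i in 1:L) {
    for (j in i:L) {
      len <- j - i + 1L
      clean <- TRUE
      if (len >= window) {
        for (b in i:(j - window + 1L)) {
          if (mean(err[b:(b + window - 1L)]) > maxError + eps) {
            clean <- FALSE
            break
          }
        }
      } else {
        # short intervals are judged at their own scale
        clean <- mean(err[i:j]) <= maxError + eps
      }
      if (clean && len > bestLen) {
        best <- c(i, j)
        bestLen <- len
      }
    }
  }
  best
}

# Exhaustive ORF enumerator: walk codon by codon from every ATG.
oracleORF <- function(s, minOrf = 90L) {
  s <- toupper(s)
  L <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  bestOpen <- NULL
  for (p in seq_len(max(L - 2L, 0L))) {
    if (substr(s, p, p + 2L) != "ATG") next
    q <- p
    hitStop <- FALSE
    while (q + 2L <= L) {
      cod <- substr(s, q, q + 2L)
      if (cod %in% stops) { hitStop <- TRUE; break }
      q <- q + 3L
    }
    if (hitStop) {
      len <- q + 2L - p + 1L
      if (len >= minOrf && (is.null(best) || len > best$len))
        best <- list(start = p, end = q + 2L, len = len)
    } else {
      len <- 3L * ((L - p + 1L) %/% 3L)
      if (len >= minOrf && (is.null(bestOpen) || len > bestOpen$len))
        bestOpen <- list(start = p, end = p + len - 1L, len = len)
    }
  }
  if (!is.null(best))
    return(list(cds_start = best$start, cds_end = best$end,
                flags = character(0)))
  if (!is.null(bestOpen))
    return(list(cds_start = bestOpen$start, cds_end = bestOpen$end,
                flags = "NO_STOP"))
  list(cds_start = NA_integer_, cds_end = NA_integer_, flags = "NON_CODING")
}

# Brute-force SSR scan: at every run start try every unit size, count
# whole repeat units one by one.
oracleSSR <- function(s, thresholds = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                        `5` = 5L, `6` = 5L)) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  isPrimitive <- function(motif) {
    u <- nchar(motif)
    for (d in seq_len(u - 1L)) {
      if (u %% d != 0L) next
      if (strrep(substr(motif, 1L, d), u / d) == motif) return(FALSE)
    }
    TRUE
  }
  out <- NULL
  for (u in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(u)]]
    i <- 1L
    while (i + 2L * u - 1L <= n) {
      # run start: previous position must not continue the period
      if (i > 1L && ok[i - 1L] && ok[i + u - 1L] &&
          ch[i - 1L] == ch[i + u - 1L]) { i <- i + 1L; next }
      seg <- i:(i + u - 1L)
      if (!all(ok[seg])) { i <- i + 1L; next }
      # needs at least two full units to be a run at all
      if (!all(ok[seg + u]) || !all(ch[seg] == ch[seg + u])) {
        i <- i + 1L; next
      }
      motif <- paste(ch[seg], collapse = "")
      r <- 2L
      while (i + (r + 1L) * u - 1L <= n) {
        nxtSeg <- (i + r * u):(i + (r + 1L) * u - 1L)
        if (!all(ok[nxtSeg]) || !all(ch[nxtSeg] == ch[seg])) break
        r <- r + 1L
      }
      if (r >= thr && isPrimitive(motif)) {
        out <- rbind(out, data.frame(start = i, end = i + r * u - 1L,
                                     motif = motif, unit_size = u,
                                     repeat_count = r,
                                     stringsAsFactors = FALSE))
      }
      i <- i + 1L
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit_size = integer(0),
                      repeat_count = integer(0)))
  }
  out[order(out$start, out$unit_size), , drop = FALSE]
}

# Independent likelihood-ratio route for the R statistic: deviance of the
# Poisson log-linear null model (common proportion across groups).
oracleLRT <- function(x, N) {
  fit <- stats::glm(x ~ 1 + offset(log(N)), family = stats::poisson())
  fit$deviance
}

# random non-stop codons (for building valid CDS bodies)
oracleSafeCodons <- function(n) {
  all <- names(Biostrings::GENETIC_CODE)
  sample(setdiff(all, c("TAA", "TAG", "TGA")), n, replace = TRUE)
}

randomDNA <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
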