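# Internal helpers shared across modules.

# Byte codes used for vectorised base arithmetic: A=1, C=2, G=3, T=4, N=5, -=6.
.BASE_LEVELS <- c("A", "C", "G", "T", "N", "-")

.baseCodes <- function(x) {
  # x: character scalar -> integer vector of base codes
  m <- match(charToRaw(x), charToRaw(paste(.BASE_LEVELS, collapse = "")))
  if (anyNA(m)) stop("sequence contains letters outside {A,C,G,T,N,-}")
  as.integer(m)
}

.codesToString <- function(codes) {
  rawToChar(charToRaw(paste(.BASE_LEVELS, collapse = ""))[codes])
}

.revcompChar <- function(x) {
  # vectorised reverse complement on plain character vectors (keeps N, '-')
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.randomDNA <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

# Is `motif` a tandem repetition of a strictly shorter unit?
.isTandemOfShorter <- function(motif) {
  u <- nchar(motif)
  if (u < 2L) return(FALSE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (paste(rep(unit, u / d), collapse = "") == motif) return(TRUE)
  }
  FALSE
}

.checkScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop("'", name, "' must be a single number >= ", min)
  invisible(x)
}
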