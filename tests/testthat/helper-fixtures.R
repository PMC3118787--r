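# Small in-code fixtures shared across tests.

makeReads <- function(seqs, clone = NULL, end = NULL, lib = "L1",
                      qual = NULL) {
  n <- length(seqs)
  if (is.null(clone)) clone <- sprintf("c%03d", seq_len(n))
  if (is.null(end)) end <- rep("5p", n)
  lib <- rep_len(lib, n)
  ids <- paste(lib, clone, end, sep = "|")
  ESTReadSet(seqs, read_id = ids, clone_id = clone, end = end,
             library_id = lib, qualities = qual)
}

makeMetadata <- function(library_id, cultivar = "cvA", tissue = "leaf",
                         normalized = FALSE, library_type = "FULL_LENGTH") {
  data.frame(library_id = library_id,
             cultivar = rep_len(cultivar, length(library_id)),
             tissue = rep_len(tissue, length(library_id)),
             normalized = rep_len(normalized, length(library_id)),
             library_type = rep_len(library_type, length(library_id)),
             stringsAsFactors = FALSE)
}

# Quality string helper: integer scores -> Phred+33 string
qstring <- function(scores) rawToChar(as.raw(as.integer(scores) + 33L))

# Reads tiled across a transcript with the given step and length.
tileReads <- function(transcript, step, len, lib = "L1") {
  L <- nchar(transcript)
  starts <- unique(c(seq(1L, max(L - len + 1L, 1L), by = step),
                     max(L - len + 1L, 1L)))
  seqs <- substring(transcript, starts, pmin(starts + len - 1L, L))
  makeReads(seqs, lib = lib)
}

# The default study scenario (2,000 genes, 3,000 clones/tissue), run once
# and cached for the end-to-end recovery and invariant tests.
.defaultScenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(seed = 1)
      sim <- simulateESTStudy(cfg)
      res <- runPipeline(cfg, sim = sim)
      cache <<- list(cfg = cfg, sim = sim, res = res)
    }
    cache
  }
})

# A shared medium-size synthetic scenario for cross-module tests (cheap:
# ~100 genes). Cached per session.
.smallScenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(
        seed = 42, nGenes = 120, clonesPerTissue = 260, nSpecific = 6,
        nSNP = 40,
        ssrPlan = data.frame(motif = c("AAG", "AG", "AAT"),
                             repeats = c(6L, 7L, 5L),
                             count = c(6L, 4L, 3L),
                             stringsAsFactors = FALSE))
      sim <- simulateESTStudy(cfg)
      res <- runPipeline(cfg, sim = sim)
      cache <<- list(cfg = cfg, sim = sim, res = res)
    }
    cache
  }
})
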