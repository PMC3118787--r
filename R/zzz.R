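.datatable.aware <- TRUE

utils::globalVariables(c(
  "kmer", "grp", "fwd", "read", "pos", "aread", "apos", "afwd",
  "a", "b", "bstrand", "doff", "unigene", "cultivar", "base", "nobs",
  "column", "tissue_a", "tissue_b", "q", "ratio_ab", "ratio_ba", "x_a",
  "x_b", "N_a", "N_b", "R", "p", "up_ok", "n_pass", "tissue"
))
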