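# Fixture builders used across the suite. All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Splice `insert` into `sequence` so that it *overwrites* starting at
# 0-based `pos`.
plant <- function(sequence, pos, insert) {
  paste0(substr(sequence, 1, pos), insert,
         substr(sequence, pos + nchar(insert) + 1, nchar(sequence)))
}

cas9_motif <- function() parse_motif("N{17}|N{3}>NGG")

# A compact design-ready genome: one feature planted mid-contig with a
# QC-passing Cas9 site planted a bit upstream so expansion succeeds fast.
design_fixture <- function(seed = 42, len = 20000, feature_pos = NULL) {
  feature_pos <- feature_pos %||% (len %/% 2)
  generate_synthetic_genome(synthetic_spec(
    len, seed = seed,
    planted_features = list(list(pos = feature_pos, seq = "TTAAAGTTT",
                                 name = "site1"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
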