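# Randomized alignments for property-style tests. Uses the caller's RNG
# stream; tests set a fixed seed before looping.
rand_aln <- function(max_taxa = 30L, max_sites = 200L, datatype = "dna") {
  nt <- sample.int(max_taxa, 1L)
  ns <- sample.int(max_sites + 1L, 1L) - 1L
  taxa <- paste0(
    "tx", seq_len(nt), "_",
    vapply(seq_len(nt), function(i) {
      paste(sample(c(letters, LETTERS, 0:9), sample.int(10L, 1L),
                   replace = TRUE), collapse = "")
    }, character(1))
  )
  sim_alignment(nt, ns, datatype, missing_rate = 0.1, ambiguity_rate = 0.03,
                taxa = taxa, source_name = paste0("rand", nt, "x", ns))
}

# Literal, loop-based site classifier used as the independent oracle: counts
# each unambiguous state's multiplicity explicitly and applies the
# two-states-twice rule verbatim.
oracle_classify <- function(column, datatype = "dna") {
  alphabet <- if (datatype == "dna") c("a", "c", "g", "t") else
    strsplit("acdefghiklmnpqrstvwy", "")[[1]]
  states <- character(0)
  for (ch in tolower(column)) {
    if (ch %in% alphabet) states <- c(states, ch)
  }
  uniq <- unique(states)
  if (length(uniq) <= 1L) return("constant")
  n_doubled <- 0L
  for (u in uniq) {
    if (sum(states == u) >= 2L) n_doubled <- n_doubled + 1L
  }
  if (n_doubled >= 2L) "parsimony_informative" else "variable_uninformative"
}

# name -> sequence map for order-insensitive alignment comparison
aln_as_map <- function(aln) {
  stats::setNames(aln$seqs, aln$taxa)[order(aln$taxa, method = "radix")]
}
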