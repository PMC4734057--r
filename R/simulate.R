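#' Simulate a toy multiple sequence alignment
#'
#' Generates a randomized alignment with site-wise structure: each site
#' draws an ancestral state from the canonical alphabet, each taxon then
#' deviates from it with probability `mutation_rate` (to a uniformly chosen
#' other state), after which cells are independently overwritten by missing
#' characters (`?`, `-`, or the datatype's full-ambiguity code, uniformly)
#' at `missing_rate` and by a partial-ambiguity code at `ambiguity_rate`.
#' This yields a realistic mix of constant, variable-uninformative and
#' parsimony-informative columns. Sampling uses the caller's RNG stream, so
#' `set.seed()` before calling makes the output reproducible.
#'
#' @param n_taxa Number of taxa.
#' @param n_sites Number of sites (0 allowed).
#' @param datatype `"dna"` or `"aa"`.
#' @param mutation_rate Per-cell probability of deviating from the site's
#'   ancestral state.
#' @param missing_rate Per-cell probability of a missing character.
#' @param ambiguity_rate Per-cell probability of a partial-ambiguity code.
#' @param taxa Optional taxon names (default `t01`, `t02`, ...).
#' @param source_name Source name recorded on the alignment.
#' @return A validated [alignment()].
#' @export
sim_alignment <- function(n_taxa, n_sites, datatype = c("dna", "aa"),
                          mutation_rate = 0.3, missing_rate = 0.05,
                          ambiguity_rate = 0.01, taxa = NULL,
                          source_name = "sim") {
  datatype <- match.arg(datatype)
  sets <- datatype_chars(datatype)
  if (is.null(taxa)) {
    taxa <- sprintf("t%02d", seq_len(n_taxa))
  }
  stopifnot(length(taxa) == n_taxa, n_taxa >= 1L)
  if (n_sites == 0L) {
    return(alignment(rep("", n_taxa), taxa = taxa, source_name = source_name))
  }
  alpha <- toupper(sets$alphabet)
  anc <- sample(alpha, n_sites, replace = TRUE)
  m <- matrix(rep(anc, each = n_taxa), nrow = n_taxa)
  mut <- matrix(stats::runif(n_taxa * n_sites) < mutation_rate,
                nrow = n_taxa)
  if (any(mut)) {
    m[mut] <- sample(alpha, sum(mut), replace = TRUE)
  }
  amb <- matrix(stats::runif(n_taxa * n_sites) < ambiguity_rate,
                nrow = n_taxa)
  if (any(amb)) {
    m[amb] <- sample(toupper(sets$ambiguous), sum(amb), replace = TRUE)
  }
  mis <- matrix(stats::runif(n_taxa * n_sites) < missing_rate,
                nrow = n_taxa)
  if (any(mis)) {
    m[mis] <- sample(toupper(sets$missing), sum(mis), replace = TRUE)
  }
  alignment(apply(m, 1L, paste, collapse = ""), taxa = taxa,
            source_name = source_name)
}

#' Simulate a set of single-locus alignments
#'
#' Emulates a desk-scale phylogenomic locus set: `n_loci` alignments over a
#' shared taxon pool, each locus sampling taxa at the given `occupancy`
#' (with at least two taxa retained) and drawing its length uniformly from
#' `sites_range`. Loci are named `locus001`, `locus002`, ...
#'
#' @param n_loci Number of loci.
#' @param n_taxa Size of the shared taxon pool.
#' @param sites_range Length-2 integer vector: min and max sites per locus.
#' @param occupancy Probability that a pool taxon is present in a locus.
#' @param datatype `"dna"` or `"aa"`.
#' @param ... Further arguments passed to [sim_alignment()].
#' @return A list of [alignment()] objects.
#' @export
sim_alignment_set <- function(n_loci = 20L, n_taxa = 8L,
                              sites_range = c(30L, 120L), occupancy = 0.7,
                              datatype = c("dna", "aa"), ...) {
  datatype <- match.arg(datatype)
  pool <- sprintf("sp%02d", seq_len(n_taxa))
  lapply(seq_len(n_loci), function(i) {
    present <- pool[stats::runif(n_taxa) < occupancy]
    if (length(present) < 2L) present <- sample(pool, 2L)
    L <- sample(seq.int(sites_range[1], sites_range[2]), 1L)
    sim_alignment(length(present), L, datatype, taxa = present,
                  source_name = sprintf("locus%03d", i), ...)
  })
}

#' Write simulated fixture files to a directory
#'
#' Generates `n_files` toy alignments with [sim_alignment_set()] and writes
#' them in the requested dialect, together with a `manifest.tsv` recording
#' each file's true summary statistics (computed from the in-memory objects
#' before writing). Useful for self-contained testing of batch operations.
#'
#' @param dir Output directory (created if needed).
#' @param n_files Number of alignment files.
#' @param format Output dialect.
#' @param datatype `"dna"` or `"aa"`.
#' @param ... Further arguments passed to [sim_alignment_set()].
#' @return Invisibly, the character vector of written alignment file paths.
#' @export
sim_fixture_files <- function(dir, n_files = 10L, format = "fasta",
                              datatype = "dna", ...) {
  check_format(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alns <- sim_alignment_set(n_loci = n_files, datatype = datatype, ...)
  paths <- vapply(alns, function(a) {
    p <- file.path(dir, paste0(a$source_name, ".", FORMAT_SUFFIX[[format]]))
    write_alignment_file(a, p, format, datatype)
    p
  }, character(1))
  tab <- summary_table(lapply(alns, summarize_alignment, datatype = datatype),
                       datatype)
  write_summary_table(tab, file.path(dir, "manifest.tsv"))
  invisible(paths)
}
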