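#' Construct a multiple sequence alignment object
#'
#' An `alignment` is an ordered collection of taxon/sequence records of equal
#' length plus the name of the source it came from (used later for partition
#' naming during concatenation). Record order is preserved exactly as given.
#'
#' @param seqs Character vector of sequences (one element per taxon). A named
#'   vector may be given, in which case `taxa` defaults to its names.
#' @param taxa Character vector of taxon names, parallel to `seqs`.
#' @param source_name Single string identifying the origin of the alignment,
#'   typically a file stem.
#' @return An object of class `alignment` with fields `taxa`, `seqs` and
#'   `source_name`.
#' @examples
#' aln <- alignment(c(t1 = "ACGT", t2 = "ACGA"))
#' n_taxa(aln)
#' n_sites(aln)
#' @export
alignment <- function(seqs, taxa = names(seqs), source_name = "alignment") {
  if (is.null(taxa)) {
    stop("taxon names are required (either via `taxa` or as names of `seqs`)")
  }
  obj <- structure(
    list(
      taxa = as.character(taxa),
      seqs = unname(as.character(seqs)),
      source_name = as.character(source_name)[1]
    ),
    class = "alignment"
  )
  validate_alignment(obj)
}

#' Validate an alignment against the data-model invariants
#'
#' Checks that all sequences have identical length, that taxon names are
#' unique, non-empty and free of line breaks, and that at least one record is
#' present. Validation is idempotent: a valid alignment is returned unchanged.
#'
#' @param x An `alignment`, a named character vector of sequences, or a list
#'   of two-element character vectors `c(taxon, sequence)`.
#' @return The validated `alignment` object.
#' @export
validate_alignment <- function(x) {
  x <- as_alignment_input(x)
  taxa <- x$taxa
  seqs <- x$seqs
  if (length(taxa) != length(seqs)) {
    stop("taxon and sequence vectors differ in length")
  }
  if (length(taxa) == 0L) {
    stop("empty alignment: no records")
  }
  if (anyNA(taxa) || anyNA(seqs)) {
    stop("NA taxon name or sequence")
  }
  bad_name <- !nzchar(taxa) | grepl("[\r\n]", taxa)
  if (any(bad_name)) {
    stop("invalid taxon name at record ", which(bad_name)[1],
         ": names must be non-empty and contain no line breaks")
  }
  dup <- duplicated(taxa)
  if (any(dup)) {
    stop("duplicate taxon name: '", taxa[dup][1], "'")
  }
  lens <- nchar(seqs, type = "chars")
  if (length(unique(lens)) > 1L) {
    ref <- lens[1]
    off <- which(lens != ref)[1]
    stop("ragged alignment: taxon '", taxa[off], "' has length ", lens[off],
         " but '", taxa[1], "' has length ", ref)
  }
  x
}

# Coerce the accepted input shapes into the internal record structure.
as_alignment_input <- function(x) {
  if (inherits(x, "alignment")) return(x)
  if (is.character(x)) {
    return(structure(
      list(taxa = names(x) %||% character(0), seqs = unname(x),
           source_name = "alignment"),
      class = "alignment"
    ))
  }
  if (is.list(x)) {
    taxa <- vapply(x, function(r) as.character(r[[1]]), character(1))
    seqs <- vapply(x, function(r) as.character(r[[2]]), character(1))
    return(structure(list(taxa = taxa, seqs = seqs, source_name = "alignment"),
                     class = "alignment"))
  }
  stop("cannot interpret input as an alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of taxa in an alignment
#' @param aln An `alignment`.
#' @return Integer count of records.
#' @export
n_taxa <- function(aln) length(aln$taxa)

#' Number of sites (columns) in an alignment
#' @param aln An `alignment`.
#' @return Integer alignment length; 0 for a zero-site alignment.
#' @export
n_sites <- function(aln) {
  if (length(aln$seqs) == 0L) return(0L)
  nchar(aln$seqs[1], type = "chars")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment '%s': %d taxa, %d sites>\n",
              x$source_name, n_taxa(x), n_sites(x)))
  show <- utils::head(seq_along(x$taxa), 5L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %s  %s\n", x$taxa[i], s))
  }
  if (n_taxa(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Convert an alignment to a character matrix
#'
#' @param x An `alignment`.
#' @param ... Unused.
#' @return A character matrix with one row per taxon (rownames = taxon names)
#'   and one column per site.
#' @export
as.matrix.alignment <- function(x, ...) {
  if (n_sites(x) == 0L) {
    return(matrix(character(0), nrow = n_taxa(x), ncol = 0L,
                  dimnames = list(x$taxa, NULL)))
  }
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$taxa
  m
}

#' @method all.equal alignment
#' @export
all.equal.alignment <- function(target, current, ...) {
  if (!inherits(current, "alignment")) return("current is not an alignment")
  msg <- character(0)
  if (!identical(target$taxa, current$taxa)) msg <- c(msg, "taxa differ")
  if (!identical(target$seqs, current$seqs)) msg <- c(msg, "sequences differ")
  if (length(msg)) msg else TRUE
}

# ---- alphabet regimes ------------------------------------------------------

#' Character sets for a declared datatype
#'
#' The declared datatype (`"dna"` or `"aa"`) governs which characters count
#' as missing/undetermined, which are partial-ambiguity codes, and what the
#' canonical residue alphabet is. All sets are matched case-insensitively.
#'
#' Missing characters convey no state information: `?`, the gap `-`, and the
#' full-ambiguity code (`N` for nucleotides, `X` for amino acids). Partial
#' IUPAC ambiguity codes (e.g. `R`, `Y` for DNA; `B`, `Z`, `J` for protein)
#' are counted in per-character tallies but are excluded from site-class
#' state counting and from base-composition denominators.
#'
#' @param datatype `"dna"` or `"aa"`.
#' @return A list with components `missing`, `ambiguous` and `alphabet`,
#'   each a lowercase character vector.
#' @export
datatype_chars <- function(datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  if (datatype == "dna") {
    list(
      missing = c("?", "-", "n"),
      ambiguous = c("r", "y", "s", "w", "k", "m", "b", "d", "h", "v"),
      alphabet = c("a", "c", "g", "t")
    )
  } else {
    list(
      missing = c("?", "-", "x"),
      ambiguous = c("b", "z", "j"),
      alphabet = c("a", "c", "d", "e", "f", "g", "h", "i", "k", "l", "m",
                   "n", "p", "q", "r", "s", "t", "v", "w", "y")
    )
  }
}

# Supported alignment file dialects and their output suffixes.
FORMATS <- c("fasta", "phylip", "phylip-int", "nexus", "nexus-int")
FORMAT_SUFFIX <- c(
  "fasta" = "fas", "phylip" = "phy", "phylip-int" = "int-phy",
  "nexus" = "nex", "nexus-int" = "int-nex"
)

check_format <- function(format) {
  if (length(format) != 1L || !format %in% FORMATS) {
    stop("unknown format '", paste(format, collapse = ","),
         "'; supported: ", paste(FORMATS, collapse = ", "))
  }
  format
}
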