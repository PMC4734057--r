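#' Construct a named partition
#'
#' A partition is a named, ordered list of 1-based site indices locating a
#' locus (or any character set) inside a supermatrix.
#'
#' @param name Partition name (non-empty string).
#' @param sites Integer vector of 1-based site indices, strictly increasing.
#' @return An object of class `partition` with fields `name` and `sites`.
#' @export
partition <- function(name, sites) {
  name <- as.character(name)[1]
  if (!nzchar(name)) stop("partition name must be non-empty")
  sites <- as.integer(sites)
  if (length(sites) == 0L) stop("partition '", name, "' has no sites")
  if (any(sites < 1L)) stop("partition '", name, "' has site indices < 1")
  if (any(diff(sites) <= 0L)) {
    stop("partition '", name, "' sites are not strictly increasing")
  }
  structure(list(name = name, sites = sites), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition '%s': %d site(s), %s>\n",
              x$name, length(x$sites), format_site_runs(x$sites)))
  invisible(x)
}

# Compress a strictly increasing site vector into "a-b,c-d" run notation.
format_site_runs <- function(sites) {
  breaks <- c(0L, which(diff(sites) != 1L), length(sites))
  runs <- vapply(seq_len(length(breaks) - 1L), function(i) {
    s <- sites[(breaks[i] + 1L):breaks[i + 1L]]
    if (length(s) == 1L) as.character(s) else paste0(s[1], "-", s[length(s)])
  }, character(1))
  paste(runs, collapse = ",")
}

#' Concatenate alignments into a supermatrix
#'
#' Joins single-locus alignments horizontally over the union of their taxa,
#' sorted lexicographically (byte order, so output is locale-independent).
#' A taxon absent from a locus receives a run of `?` spanning that locus:
#' `?` means unknown, which is the correct semantics for an unsampled locus
#' (a `-` would assert an indel). One contiguous partition per input locus
#' is recorded, named by the locus `source_name`, in input order.
#'
#' @param alignments Non-empty list of validated [alignment()] objects.
#' @param datatype `"dna"` or `"aa"` (carried to writers; the fill character
#'   is `?` for both).
#' @return An object of class `supermatrix`: a list with fields `alignment`
#'   (the concatenated [alignment()]) and `partitions` (list of
#'   [partition()] objects tiling `1..length`).
#' @examples
#' a <- alignment(c(sp1 = "AAA", sp2 = "CCC"), source_name = "locus1")
#' b <- alignment(c(sp2 = "GG", sp3 = "TT"), source_name = "locus2")
#' sm <- concatenate(list(a, b))
#' sm$alignment$seqs  # "AAA??" "CCCGG" "???TT"
#' @export
concatenate <- function(alignments, datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  alignments <- lapply(alignments, validate_alignment)
  taxa <- sort(unique(unlist(lapply(alignments, `[[`, "taxa"))),
               method = "radix")
  lens <- vapply(alignments, n_sites, integer(1))
  chunk <- vapply(alignments, function(a) {
    idx <- match(taxa, a$taxa)
    out <- a$seqs[idx]
    out[is.na(idx)] <- strrep("?", n_sites(a))
    out
  }, character(length(taxa)))
  if (length(taxa) == 1L) chunk <- matrix(chunk, nrow = 1L)
  seqs <- apply(chunk, 1L, paste, collapse = "")

  pnames <- vapply(alignments, `[[`, character(1), "source_name")
  if (anyDuplicated(pnames)) {
    dups <- unique(pnames[duplicated(pnames)])
    aln_log("WARNING", sprintf(
      "duplicate source name(s) %s among inputs; partition names disambiguated with numeric suffixes",
      paste(sQuote(dups), collapse = ", ")))
    for (d in dups) {
      at <- which(pnames == d)
      pnames[at] <- paste0(d, "_", seq_along(at))
    }
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  partitions <- lapply(seq_along(alignments), function(i) {
    if (lens[i] == 0L) NULL else partition(pnames[i], starts[i]:ends[i])
  })
  partitions <- partitions[!vapply(partitions, is.null, logical(1))]

  structure(list(
    alignment = alignment(seqs, taxa = taxa, source_name = "concatenated"),
    partitions = partitions
  ), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix: %d taxa, %d sites, %d partition(s)>\n",
              n_taxa(x$alignment), n_sites(x$alignment),
              length(x$partitions)))
  invisible(x)
}

#' Compose a partition file
#'
#' One line per partition, `<name> = <start>-<end>` with 1-based inclusive
#' coordinates, in partition order. Non-contiguous partitions are written as
#' comma-separated runs, which [parse_partition_file()] reads back.
#'
#' @param partitions List of [partition()] objects.
#' @return A single string (possibly empty for an empty list).
#' @export
write_partition_file <- function(partitions) {
  if (length(partitions) == 0L) return("")
  paste0(vapply(partitions, function(p) {
    sites <- p$sites
    runs <- format_site_runs(sites)
    # single-run single-site partitions still get explicit range form
    if (!grepl("[-,]", runs)) runs <- paste0(runs, "-", runs)
    paste0(p$name, " = ", runs, "\n")
  }, character(1)), collapse = "")
}

#' Parse a partition scheme file
#'
#' Accepts `name = start-end` lines, stride notation `start-end\k` (every
#' k-th site from start, as used for codon positions), comma-separated
#' multi-range entries, single-site entries, and an optional leading
#' data-type token before the name (`DNA, gene1 = 1-100`, RAxML style).
#' Blank lines are ignored. Sites claimed by more than one partition are
#' permitted (loci may share sites) but logged as a warning.
#'
#' @param text File content: a single string or character vector of lines.
#' @return A list of [partition()] objects in file order.
#' @examples
#' parse_partition_file("codon1 = 1-6\\3")[[1]]$sites  # 1 4
#' @export
parse_partition_file <- function(text) {
  lines <- as_lines(text)
  keep <- nzchar(trimws(lines))
  parts <- list()
  for (ln in which(keep)) {
    line <- trimws(lines[ln])
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq == -1L) stop("malformed partition line ", ln, ": '", line,
                        "' (no '=')")
    lhs <- trimws(substr(line, 1L, eq - 1L))
    rhs <- trimws(substr(line, eq + 1L, nchar(line)))
    # drop a leading "DNA," / "WAG," style type token
    lhs_toks <- trimws(strsplit(lhs, ",", fixed = TRUE)[[1]])
    name <- lhs_toks[length(lhs_toks)]
    if (!nzchar(name)) stop("malformed partition line ", ln, ": empty name")
    pieces <- trimws(strsplit(rhs, ",", fixed = TRUE)[[1]])
    if (length(pieces) == 0L || any(!nzchar(pieces))) {
      stop("malformed partition line ", ln, ": empty site range")
    }
    sites <- unlist(lapply(pieces, function(pc) expand_range(pc, ln)))
    if (anyDuplicated(sites) || is.unsorted(sites, strictly = TRUE)) {
      aln_log("WARNING", sprintf(
        "partition '%s' (line %d): sites reordered/deduplicated to strictly increasing order",
        name, ln))
      sites <- sort(unique(sites))
    }
    parts[[length(parts) + 1L]] <- partition(name, sites)
  }
  all_sites <- unlist(lapply(parts, `[[`, "sites"))
  if (anyDuplicated(all_sites)) {
    aln_log("WARNING", "partitions overlap: some sites are claimed by more than one partition")
  }
  parts
}

expand_range <- function(piece, line_no) {
  if (grepl("^[0-9]+$", piece)) return(as.integer(piece))
  m <- regmatches(piece,
                  regexec("^([0-9]+)\\s*-\\s*([0-9]+)(\\\\([0-9]+))?$", piece))[[1]]
  if (length(m) == 0L) {
    stop("malformed partition line ", line_no, ": cannot parse range '",
         piece, "'")
  }
  from <- as.integer(m[2]); to <- as.integer(m[3])
  by <- if (nzchar(m[5])) as.integer(m[5]) else 1L
  if (to < from) stop("malformed partition line ", line_no, ": range '",
                      piece, "' runs backwards")
  if (by < 1L) stop("malformed partition line ", line_no, ": stride must be >= 1")
  seq.int(from, to, by = by)
}

#' Split an alignment by partitions
#'
#' Extracts, for each partition, the characters at the partition's sites (in
#' order) for every taxon, yielding one alignment per partition named after
#' it. With `remove_empty`, taxa whose extracted sequence consists entirely
#' of missing characters for the declared datatype are dropped from that
#' output — this makes splitting invert concatenation, since taxa padded in
#' with `?` fill come back out.
#'
#' @param aln The supermatrix [alignment()] to split.
#' @param partitions List of [partition()] objects.
#' @param remove_empty Drop all-missing taxa from each output alignment.
#' @param datatype `"dna"` or `"aa"`; governs the missing-character set used
#'   by `remove_empty`.
#' @return A list of [alignment()] objects, one per partition, in order.
#' @export
split_alignment <- function(aln, partitions, remove_empty = FALSE,
                            datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  aln <- validate_alignment(aln)
  L <- n_sites(aln)
  m <- as.matrix(aln)
  miss <- datatype_chars(datatype)$missing
  lapply(partitions, function(p) {
    if (max(p$sites) > L) {
      stop("partition '", p$name, "' refers to site ", max(p$sites),
           " beyond alignment length ", L)
    }
    sub <- m[, p$sites, drop = FALSE]
    seqs <- apply(sub, 1L, paste, collapse = "")
    if (length(aln$taxa) == 1L) seqs <- paste(sub[1L, ], collapse = "")
    keep <- rep(TRUE, length(seqs))
    if (remove_empty) {
      keep <- vapply(seq_along(seqs), function(i) {
        any(!(tolower(sub[i, ]) %in% miss))
      }, logical(1))
      if (!any(keep)) {
        stop("partition '", p$name,
             "' would be empty after removing all-missing taxa")
      }
    }
    alignment(seqs[keep], taxa = aln$taxa[keep], source_name = p$name)
  })
}

#' Remove taxa from an alignment by name
#'
#' Records whose taxon name is listed are dropped; the order of the
#' remaining records is preserved. Names not present in the alignment are
#' tolerated with a logged warning.
#'
#' @param aln A validated [alignment()].
#' @param names Character vector of taxon names to remove (may be empty).
#' @return The pruned [alignment()].
#' @export
remove_taxa <- function(aln, names) {
  aln <- validate_alignment(aln)
  absent <- setdiff(names, aln$taxa)
  if (length(absent)) {
    aln_log("WARNING", sprintf("taxa not found in alignment: %s",
                               paste(sQuote(absent), collapse = ", ")))
  }
  keep <- !(aln$taxa %in% names)
  if (!any(keep)) stop("empty alignment would result from removing all taxa")
  if (all(keep)) return(aln)
  alignment(aln$seqs[keep], taxa = aln$taxa[keep],
            source_name = aln$source_name)
}

#' Build randomized jackknife replicate supermatrices
#'
#' Each replicate concatenates `loci_per_replicate` alignments sampled
#' uniformly without replacement from the input set, independently across
#' replicates. The same seed over the same inputs reproduces the replicates
#' exactly; the caller's RNG state is left untouched.
#'
#' @param alignments List of validated [alignment()] objects (the locus pool).
#' @param n_replicates Number of replicates to build.
#' @param loci_per_replicate Loci drawn per replicate; must not exceed
#'   `length(alignments)`.
#' @param seed Integer seed controlling all sampling.
#' @param datatype `"dna"` or `"aa"`.
#' @return A list of `n_replicates` supermatrices (see [concatenate()]).
#' @export
make_replicates <- function(alignments, n_replicates, loci_per_replicate,
                            seed, datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  n_avail <- length(alignments)
  if (loci_per_replicate > n_avail) {
    stop("loci_per_replicate (", loci_per_replicate,
         ") exceeds the number of available alignments (", n_avail, ")")
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  lapply(seq_len(n_replicates), function(i) {
    concatenate(alignments[sample.int(n_avail, loci_per_replicate)],
                datatype)
  })
}
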