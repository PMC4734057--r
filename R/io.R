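#' Parse a multiple sequence alignment from text
#'
#' Parses the full content of one alignment file in the declared dialect.
#' The dialect is never auto-detected: correct declaration is the caller's
#' responsibility. For interleaved dialects, per-taxon blocks are
#' concatenated in block order. FASTA description lines are truncated at the
#' first whitespace to form the taxon name (the remainder is dropped with a
#' notice) and wrapped sequence lines are joined.
#'
#' @param text The file content: a single string or a character vector of
#'   lines.
#' @param format One of `"fasta"`, `"phylip"`, `"phylip-int"`, `"nexus"`,
#'   `"nexus-int"`.
#' @param source_name Name recorded on the returned alignment (defaults to
#'   `"alignment"`; file readers pass the file stem).
#' @return A validated [alignment()].
#' @seealso [read_alignment_file()], [write_alignment()]
#' @export
read_alignment <- function(text, format, source_name = "alignment") {
  check_format(format)
  lines <- as_lines(text)
  if (all(!nzchar(trimws(lines)))) stop("empty input")
  aln <- switch(format,
    "fasta" = parse_fasta(lines),
    "phylip" = parse_phylip(lines, interleaved = FALSE),
    "phylip-int" = parse_phylip(lines, interleaved = TRUE),
    "nexus" = ,
    "nexus-int" = parse_nexus(lines)
  )
  aln$source_name <- source_name
  validate_alignment(aln)
}

as_lines <- function(text) {
  if (length(text) == 0L) return(character(0))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE),
                  use.names = FALSE)
  sub("\r$", "", lines)
}

# ---- FASTA -----------------------------------------------------------------

parse_fasta <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) stop("no FASTA records found (no '>' header line)")
  if (!is_hdr[1]) stop("FASTA content found before the first '>' header")
  idx <- cumsum(is_hdr)
  headers <- trimws(sub("^>", "", lines[is_hdr]))
  if (any(!nzchar(headers))) stop("FASTA record with empty description line")
  taxa <- sub("\\s.*$", "", headers)
  dropped <- headers != taxa
  if (any(dropped)) {
    aln_log("INFO", sprintf(
      "FASTA descriptions truncated at first whitespace for %d record(s)",
      sum(dropped)))
  }
  body <- ifelse(is_hdr, "", gsub("\\s", "", lines))
  seqs <- vapply(split(body, idx), paste, character(1), collapse = "")
  structure(list(taxa = taxa, seqs = unname(seqs), source_name = "alignment"),
            class = "alignment")
}

# ---- PHYLIP ----------------------------------------------------------------

# Relaxed-name PHYLIP: names are whitespace-terminated tokens of any length;
# strict 10-column files parse too as long as names contain no spaces.
parse_phylip <- function(lines, interleaved) {
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty input")
  hdr <- strsplit(trimws(nonblank[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("PHYLIP header must be two integers 'ntaxa nsites'; found: '",
         nonblank[1], "'")
  }
  ntax <- as.integer(hdr[1])
  nsites <- as.integer(hdr[2])
  body <- nonblank[-1]
  if (length(body) < ntax) {
    stop("PHYLIP header declares ", ntax, " taxa but only ", length(body),
         " record lines found")
  }
  taxa <- character(ntax)
  seqs <- character(ntax)
  if (interleaved) {
    for (i in seq_len(ntax)) {
      tk <- split_name_line(body[i])
      taxa[i] <- tk$name
      seqs[i] <- tk$seq
    }
    rest <- body[-seq_len(ntax)]
    if (length(rest)) {
      tgt <- rep_len(seq_len(ntax), length(rest))
      for (j in seq_along(rest)) {
        seqs[tgt[j]] <- paste0(seqs[tgt[j]], gsub("\\s", "", rest[j]))
      }
    }
  } else if (length(body) == ntax) {
    # one line per record; any site-count disagreement is a header error
    for (t in seq_len(ntax)) {
      tk <- split_name_line(body[t])
      taxa[t] <- tk$name
      seqs[t] <- tk$seq
    }
  } else {
    i <- 1L
    for (t in seq_len(ntax)) {
      if (i > length(body)) {
        stop("PHYLIP header declares ", ntax, " taxa but content ended at ",
             t - 1L)
      }
      tk <- split_name_line(body[i])
      taxa[t] <- tk$name
      seqs[t] <- tk$seq
      i <- i + 1L
      # wrapped sequential records continue on unnamed lines
      while (nchar(seqs[t]) < nsites && i <= length(body)) {
        seqs[t] <- paste0(seqs[t], gsub("\\s", "", body[i]))
        i <- i + 1L
      }
    }
    if (i <= length(body)) {
      stop("PHYLIP header declares ", ntax, " taxa but extra content remains ",
           "after parsing them")
    }
  }
  lens <- nchar(seqs)
  if (any(lens != nsites)) {
    off <- which(lens != nsites)[1]
    stop("PHYLIP header declares ", nsites, " sites but taxon '", taxa[off],
         "' has ", lens[off])
  }
  structure(list(taxa = taxa, seqs = seqs, source_name = "alignment"),
            class = "alignment")
}

split_name_line <- function(line) {
  line <- trimws(line)
  m <- regexpr("\\s", line)
  if (m == -1L) {
    list(name = line, seq = "")
  } else {
    list(name = substr(line, 1L, m - 1L),
         seq = gsub("\\s", "", substr(line, m + 1L, nchar(line))))
  }
}

# ---- NEXUS -----------------------------------------------------------------

# Tolerant NEXUS reader: case-insensitive keywords, DATA or CHARACTERS
# blocks, square-bracket comments stripped, sequential or interleaved
# matrices. Interleaved blocks must repeat taxa in the same order; files
# violating that are rejected rather than silently reordered.
parse_nexus <- function(lines) {
  text <- paste(lines, collapse = "\n")
  text <- gsub("\\[[^]]*\\]", "", text)
  block <- regmatches(
    text,
    regexpr("(?is)begin\\s+(data|characters)\\s*;.*?end\\s*;", text,
            perl = TRUE))
  if (length(block) == 0L) {
    stop("NEXUS input lacks a recognizable DATA or CHARACTERS block")
  }
  dims <- regmatches(
    block, regexpr("(?is)dimensions[^;]*;", block, perl = TRUE))
  exp_ntax <- exp_nchar <- NA_integer_
  if (length(dims)) {
    exp_ntax <- extract_int(dims, "ntax")
    exp_nchar <- extract_int(dims, "nchar")
  }
  mat <- regmatches(
    block, regexpr("(?is)matrix\\s.*?;", block, perl = TRUE))
  if (length(mat) == 0L) {
    stop("NEXUS input lacks a MATRIX section")
  }
  body <- sub("(?is)^matrix\\s", "", mat, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  mlines <- as_lines(body)
  mlines <- mlines[nzchar(trimws(mlines))]
  if (length(mlines) == 0L) stop("NEXUS MATRIX section is empty")
  toks <- lapply(mlines, split_name_line)
  names_seen <- vapply(toks, `[[`, character(1), "name")
  chunks <- vapply(toks, `[[`, character(1), "seq")
  taxa <- unique(names_seen)
  ntax <- length(taxa)
  if (length(names_seen) %% ntax != 0L ||
      !identical(names_seen, rep_len(taxa, length(names_seen)))) {
    stop("NEXUS interleaved blocks do not repeat taxa in a consistent order")
  }
  seqs <- vapply(split(chunks, factor(names_seen, levels = taxa)),
                 paste, character(1), collapse = "")
  if (!is.na(exp_ntax) && exp_ntax != ntax) {
    stop("NEXUS DIMENSIONS declares NTAX=", exp_ntax, " but ", ntax,
         " taxa found")
  }
  if (!is.na(exp_nchar) && any(nchar(seqs) != exp_nchar)) {
    off <- which(nchar(seqs) != exp_nchar)[1]
    stop("NEXUS DIMENSIONS declares NCHAR=", exp_nchar, " but taxon '",
         taxa[off], "' has ", nchar(seqs[off]))
  }
  structure(list(taxa = taxa, seqs = unname(seqs), source_name = "alignment"),
            class = "alignment")
}

extract_int <- function(text, key) {
  m <- regmatches(
    text,
    regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"), text, perl = TRUE))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

# ---- writers ---------------------------------------------------------------

#' Compose alignment text in a given dialect
#'
#' The emitted text, re-read with [read_alignment()] under the same dialect,
#' yields an alignment identical to `aln` (names, residues and record order).
#' PHYLIP output carries a correct `ntaxa nsites` header; NEXUS output
#' carries correct `DIMENSIONS` and a `FORMAT` line declaring the datatype,
#' `MISSING=?` and `GAP=-`. Interleaved dialects are wrapped at 60 residues
#' per block. Sequence case is preserved verbatim.
#'
#' @inheritParams read_alignment
#' @param aln A validated [alignment()].
#' @param datatype `"dna"` or `"aa"`; only used for the NEXUS `FORMAT` line.
#' @return A single string (the file content, newline-terminated).
#' @export
write_alignment <- function(aln, format, datatype = c("dna", "aa")) {
  check_format(format)
  datatype <- match.arg(datatype)
  aln <- validate_alignment(aln)
  if (format != "fasta" && any(grepl("\\s", aln$taxa))) {
    stop("taxon names must not contain whitespace for ", format, " output")
  }
  switch(format,
    "fasta" = compose_fasta(aln),
    "phylip" = compose_phylip(aln),
    "phylip-int" = compose_phylip_int(aln),
    "nexus" = compose_nexus(aln, datatype, interleave = FALSE),
    "nexus-int" = compose_nexus(aln, datatype, interleave = TRUE)
  )
}

compose_fasta <- function(aln) {
  paste0(paste0(">", aln$taxa, "\n", aln$seqs, "\n", collapse = ""))
}

pad_names <- function(taxa) {
  formatC(taxa, width = max(nchar(taxa)), flag = "-")
}

compose_phylip <- function(aln) {
  paste0(n_taxa(aln), " ", n_sites(aln), "\n",
         paste0(pad_names(aln$taxa), " ", aln$seqs, "\n", collapse = ""))
}

seq_blocks <- function(seqs, width = 60L) {
  L <- nchar(seqs[1])
  if (L == 0L) return(list(rep("", length(seqs))))
  starts <- seq.int(1L, L, by = width)
  lapply(starts, function(s) substr(seqs, s, min(s + width - 1L, L)))
}

compose_phylip_int <- function(aln) {
  blocks <- seq_blocks(aln$seqs)
  padded <- pad_names(aln$taxa)
  out <- paste0(n_taxa(aln), " ", n_sites(aln), "\n")
  parts <- vapply(seq_along(blocks), function(b) {
    if (b == 1L) {
      paste0(padded, " ", blocks[[b]], "\n", collapse = "")
    } else {
      paste0(blocks[[b]], "\n", collapse = "")
    }
  }, character(1))
  paste0(out, paste(parts, collapse = "\n"))
}

compose_nexus <- function(aln, datatype, interleave) {
  ndt <- if (datatype == "dna") "DNA" else "PROTEIN"
  padded <- pad_names(aln$taxa)
  blocks <- if (interleave) seq_blocks(aln$seqs) else list(aln$seqs)
  matrix_txt <- paste(vapply(blocks, function(bl) {
    paste0("  ", padded, " ", bl, "\n", collapse = "")
  }, character(1)), collapse = "\n")
  paste0(
    "#NEXUS\n\n",
    "BEGIN DATA;\n",
    "  DIMENSIONS NTAX=", n_taxa(aln), " NCHAR=", n_sites(aln), ";\n",
    "  FORMAT DATATYPE=", ndt, " MISSING=? GAP=-",
    if (interleave) " INTERLEAVE" else "", ";\n",
    "  MATRIX\n",
    matrix_txt,
    "  ;\nEND;\n"
  )
}

# ---- file-level wrappers ---------------------------------------------------

#' Read an alignment file
#'
#' @param path Path to the file.
#' @inheritParams read_alignment
#' @return A validated [alignment()] whose `source_name` is the file stem.
#' @export
read_alignment_file <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path)
  read_alignment(readLines(path, warn = FALSE), format,
                 source_name = tools::file_path_sans_ext(basename(path)))
}

#' Write an alignment file
#'
#' @inheritParams write_alignment
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_file <- function(aln, path, format, datatype = "dna") {
  txt <- write_alignment(aln, format, datatype)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Batch-convert alignment files between dialects
#'
#' Converts each input file from `in_format` to `out_format`, writing one
#' output per input named `<input stem>.<suffix>` (suffixes: `fas`, `phy`,
#' `int-phy`, `nex`, `int-nex`). Input files are never modified. Files that
#' fail to parse are logged and skipped; the remaining files still convert.
#' Output bytes are identical regardless of `cores`.
#'
#' @param paths Character vector of input file paths.
#' @param in_format,out_format Input and output dialects.
#' @param cores Number of worker processes for parsing/composing.
#' @param out_dir Output directory; defaults to each input's own directory.
#' @param datatype `"dna"` or `"aa"` (NEXUS `FORMAT` line).
#' @return Invisibly, a data frame with columns `input`, `output`, `ok`,
#'   `error`; `ok` is `FALSE` for files that failed.
#' @export
convert_files <- function(paths, in_format, out_format, cores = 1L,
                          out_dir = NULL, datatype = "dna") {
  check_format(in_format)
  check_format(out_format)
  if (length(paths) == 0L) stop("no input files")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  composed <- aln_apply(paths, function(p) {
    tryCatch({
      aln <- read_alignment_file(p, in_format)
      list(ok = TRUE, text = write_alignment(aln, out_format, datatype),
           error = NA_character_)
    }, error = function(e) {
      list(ok = FALSE, text = NULL, error = conditionMessage(e))
    })
  }, cores = cores)
  outs <- file.path(
    if (is.null(out_dir)) dirname(paths) else out_dir,
    paste0(tools::file_path_sans_ext(basename(paths)), ".",
           FORMAT_SUFFIX[[out_format]])
  )
  ok <- vapply(composed, `[[`, logical(1), "ok")
  err <- vapply(composed, `[[`, character(1), "error")
  clash <- ok & normalizePath(outs, mustWork = FALSE) ==
    normalizePath(paths, mustWork = FALSE)
  if (any(clash)) {
    ok[clash] <- FALSE
    err[clash] <- "output path would overwrite the input file"
  }
  for (i in seq_along(paths)) {
    if (ok[i]) {
      writeLines(composed[[i]]$text, outs[i], sep = "")
    } else {
      aln_log("ERROR", sprintf("failed to convert '%s': %s",
                               paths[i], err[i]))
    }
  }
  invisible(data.frame(input = paths, output = ifelse(ok, outs, NA_character_),
                       ok = ok, error = err, stringsAsFactors = FALSE))
}
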