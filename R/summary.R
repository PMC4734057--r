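#' Classify one alignment column
#'
#' Sites fall into exactly one of three mutually exclusive classes. Let S be
#' the multiset of column characters that are neither missing nor ambiguity
#' codes for the declared datatype, case-folded. The site is `constant` when
#' S holds at most one distinct state (including when S is empty),
#' `parsimony_informative` when at least two distinct states each occur at
#' least twice in S, and `variable_uninformative` otherwise. Characters
#' outside the known alphabet are treated as ambiguous and excluded from S,
#' with a logged notice.
#'
#' @param column Character vector of single characters (one per taxon).
#' @param datatype `"dna"` or `"aa"`.
#' @return One of `"constant"`, `"variable_uninformative"`,
#'   `"parsimony_informative"`.
#' @examples
#' classify_site(c("A", "A", "T", "T"), "dna")  # parsimony_informative
#' classify_site(c("A", "A", "A", "T"), "dna")  # variable_uninformative
#' classify_site(c("A", "A", "-", "?"), "dna")  # constant
#' @export
classify_site <- function(column, datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  if (length(column) == 0L) stop("column must be non-empty")
  sets <- datatype_chars(datatype)
  ch <- tolower(column)
  unknown <- !(ch %in% c(sets$alphabet, sets$missing, sets$ambiguous))
  if (any(unknown)) {
    aln_log("INFO", sprintf(
      "unknown character(s) %s treated as ambiguous and excluded from site classification",
      paste(sQuote(unique(column[unknown])), collapse = ", ")))
  }
  states <- ch[ch %in% sets$alphabet]
  classify_state_counts(table(states))
}

# Shared decision rule on a table of unambiguous state multiplicities.
classify_state_counts <- function(tab) {
  if (length(tab) <= 1L) return("constant")
  if (sum(tab >= 2L) >= 2L) return("parsimony_informative")
  "variable_uninformative"
}

# Column classes for a whole alignment at once.
classify_columns <- function(m, datatype) {
  sets <- datatype_chars(datatype)
  ncols <- ncol(m)
  if (is.null(ncols) || ncols == 0L) return(character(0))
  ml <- tolower(m)
  f <- matrix(match(ml, sets$alphabet), nrow = nrow(m))
  nstates <- length(sets$alphabet)
  vapply(seq_len(ncols), function(j) {
    counts <- tabulate(f[, j], nbins = nstates)
    counts <- counts[counts > 0L]
    classify_state_counts(counts)
  }, character(1))
}

#' Summary statistics of one alignment
#'
#' Computes the per-alignment statistic battery: number of taxa, alignment
#' length, total matrix cells, count of undetermined characters and percent
#' of missing data, AT and GC contents (DNA only), counts and proportions of
#' variable and parsimony-informative sites, and counts of all characters.
#'
#' Undetermined characters are `?`, `-` and the full-ambiguity code (`N` for
#' DNA, `X` for amino acids), case-insensitive. AT/GC contents are computed
#' over unambiguous A/C/G/T residues only, so `at_content + gc_content = 1`
#' whenever any such residue is present. Proportions over a zero-site or
#' zero-cell alignment are reported as 0. Character counts are case-folded
#' and always include zero entries for the canonical alphabet of the
#' declared datatype.
#'
#' @param aln A validated [alignment()].
#' @param datatype `"dna"` or `"aa"`.
#' @return An object of class `aln_summary`: a list with fields `name`,
#'   `n_taxa`, `length`, `total_cells`, `undetermined_count`,
#'   `missing_percent`, `at_content`, `gc_content` (both `NA` for amino
#'   acids), `variable_count`, `variable_prop`, `informative_count`,
#'   `informative_prop` and `char_counts` (named integer vector).
#' @examples
#' aln <- alignment(c(t1 = "ACGT", t2 = "AC-T", t3 = "?CGA"))
#' s <- summarize_alignment(aln, "dna")
#' round(s$missing_percent, 2)  # 16.67
#' @export
summarize_alignment <- function(aln, datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  aln <- validate_alignment(aln)
  sets <- datatype_chars(datatype)
  nt <- n_taxa(aln)
  L <- n_sites(aln)
  total <- nt * L

  m <- as.matrix(aln)
  cells <- tolower(as.vector(m))
  undet <- sum(cells %in% sets$missing)

  counts <- table(cells)
  char_counts <- stats::setNames(integer(length(sets$alphabet)),
                                 sets$alphabet)
  observed <- stats::setNames(as.integer(counts), names(counts))
  char_counts[intersect(names(observed), names(char_counts))] <-
    observed[intersect(names(observed), names(char_counts))]
  extra <- sort(as.character(setdiff(names(observed), names(char_counts))),
                method = "radix")
  char_counts <- c(char_counts, observed[extra])

  if (datatype == "dna") {
    base <- char_counts[c("a", "c", "g", "t")]
    denom <- sum(base)
    at <- if (denom > 0) unname(base["a"] + base["t"]) / denom else NA_real_
    gc <- if (denom > 0) unname(base["c"] + base["g"]) / denom else NA_real_
  } else {
    at <- gc <- NA_real_
  }

  cls <- classify_columns(m, datatype)
  n_var <- sum(cls != "constant")
  n_inf <- sum(cls == "parsimony_informative")

  structure(list(
    name = aln$source_name,
    n_taxa = nt,
    length = L,
    total_cells = total,
    undetermined_count = undet,
    missing_percent = if (total > 0) 100 * undet / total else 0,
    at_content = at,
    gc_content = gc,
    variable_count = n_var,
    variable_prop = if (L > 0) n_var / L else 0,
    informative_count = n_inf,
    informative_prop = if (L > 0) n_inf / L else 0,
    char_counts = char_counts
  ), class = "aln_summary")
}

#' @export
print.aln_summary <- function(x, ...) {
  cat(sprintf(
    "<alignment summary '%s'>\n  taxa: %d  sites: %d  cells: %d\n",
    x$name, x$n_taxa, x$length, x$total_cells))
  cat(sprintf("  undetermined: %d (%.2f%%)\n",
              x$undetermined_count, x$missing_percent))
  if (!is.na(x$at_content)) {
    cat(sprintf("  AT: %.3f  GC: %.3f\n", x$at_content, x$gc_content))
  }
  cat(sprintf("  variable sites: %d (%.3f)  parsimony-informative: %d (%.3f)\n",
              x$variable_count, x$variable_prop,
              x$informative_count, x$informative_prop))
  invisible(x)
}

# Fixed leading column order of the summary table.
SUMMARY_COLUMNS <- c(
  "Alignment_name", "No_of_taxa", "Alignment_length", "Total_matrix_cells",
  "Undetermined_characters", "Missing_percent", "No_variable_sites",
  "Proportion_variable_sites", "Parsimony_informative_sites",
  "Proportion_parsimony_informative", "AT_content", "GC_content"
)

#' Assemble summaries into a table
#'
#' One row per alignment, in input order. Leading columns are the fixed
#' statistic battery; per-character count columns follow, covering the union
#' of characters observed across all rows (canonical alphabet first).
#'
#' @param summaries A list of `aln_summary` objects.
#' @param datatype `"dna"` or `"aa"` (fixes the canonical alphabet columns).
#' @return A `data.frame`; numeric columns carry full precision.
#' @export
summary_table <- function(summaries, datatype = c("dna", "aa")) {
  datatype <- match.arg(datatype)
  if (length(summaries) == 0L) stop("no summaries to tabulate")
  alpha <- datatype_chars(datatype)$alphabet
  all_chars <- unique(unlist(lapply(summaries, function(s) names(s$char_counts))))
  extra <- sort(setdiff(all_chars, alpha), method = "radix")
  char_cols <- c(alpha, extra)
  rows <- lapply(summaries, function(s) {
    cc <- stats::setNames(integer(length(char_cols)), char_cols)
    cc[names(s$char_counts)] <- s$char_counts
    c(list(
      Alignment_name = s$name,
      No_of_taxa = s$n_taxa,
      Alignment_length = s$length,
      Total_matrix_cells = s$total_cells,
      Undetermined_characters = s$undetermined_count,
      Missing_percent = s$missing_percent,
      No_variable_sites = s$variable_count,
      Proportion_variable_sites = s$variable_prop,
      Parsimony_informative_sites = s$informative_count,
      Proportion_parsimony_informative = s$informative_prop,
      AT_content = s$at_content,
      GC_content = s$gc_content
    ), as.list(cc))
  })
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
}

#' Summarize a batch of alignment files
#'
#' Parses each file under the declared dialect and datatype and returns the
#' combined summary table, one row per file in input order regardless of
#' `cores`. Files that fail to parse are logged and omitted from the table;
#' their paths are recorded in the `failures` attribute of the result.
#'
#' @param paths Character vector of input file paths (must be non-empty).
#' @param in_format Input dialect.
#' @param datatype `"dna"` or `"aa"`.
#' @param cores Number of worker processes.
#' @return A `data.frame` as from [summary_table()], with attribute
#'   `failures` (character vector of failed paths, possibly empty).
#' @export
summarize_files <- function(paths, in_format, datatype = c("dna", "aa"),
                            cores = 1L) {
  datatype <- match.arg(datatype)
  check_format(in_format)
  if (length(paths) == 0L) stop("no input files")
  res <- aln_apply(paths, function(p) {
    tryCatch(
      list(ok = TRUE, s = summarize_alignment(
        read_alignment_file(p, in_format), datatype), error = NA_character_),
      error = function(e) list(ok = FALSE, s = NULL,
                               error = conditionMessage(e)))
  }, cores = cores)
  ok <- vapply(res, `[[`, logical(1), "ok")
  for (i in which(!ok)) {
    aln_log("ERROR", sprintf("failed to summarize '%s': %s",
                             paths[i], res[[i]]$error))
  }
  if (!any(ok)) stop("no input files could be summarized")
  tab <- summary_table(lapply(res[ok], `[[`, "s"), datatype)
  attr(tab, "failures") <- paths[!ok]
  tab
}

#' Write a summary table as TSV
#'
#' Renders `Missing_percent` to 2 decimal places and proportion/content
#' columns to 3 (the underlying data frame keeps full precision); `NA`
#' contents (amino-acid data) are rendered as empty fields.
#'
#' @param tab A data frame from [summary_table()] or [summarize_files()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(tab, path) {
  out <- tab
  out$Missing_percent <- sprintf("%.2f", out$Missing_percent)
  for (col in c("Proportion_variable_sites", "Proportion_parsimony_informative",
                "AT_content", "GC_content")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.3f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
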