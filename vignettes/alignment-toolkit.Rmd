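---
title: "Alignment manipulation and summary statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment manipulation and summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnkit)
```

`alnkit` manipulates multiple sequence alignments the way phylogenomic
pipelines need them manipulated: format conversion, supermatrix
concatenation with partition bookkeeping, partition-scheme splitting,
jackknife replicate construction, taxon removal, and a per-alignment
statistic battery. This vignette records the model behind each operation,
the conventions chosen where several are defensible, and what the package
deliberately does not do.

## The data model

An `alignment` is an ordered list of (taxon name, sequence) records of
equal length plus a `source_name` (the file stem, reused as the partition
name at concatenation time). Invariants enforced by `validate_alignment()`:
equal sequence lengths, unique non-empty taxon names without line breaks,
at least one record. Record order is preserved from input exactly;
sequence case is preserved verbatim in every output, while all statistics
are computed case-insensitively — this keeps conversion lossless and
statistics stable at the same time.

Zero-length alignments (0 sites) are valid objects, and every proportion
over zero sites or zero cells is reported as 0 rather than `NaN`: a batch
run over thousands of files must not fall over on a degenerate member.

### Alphabet regimes

The declared datatype governs three character sets (matched
case-insensitively):

| datatype | missing | partial ambiguity | canonical alphabet |
|----------|---------------|----------------------------|--------------------|
| `dna`    | `?`, `-`, `N` | `R Y S W K M B D H V`      | `A C G T`          |
| `aa`     | `?`, `-`, `X` | `B Z J`                    | 20 standard residues |

`?`, the gap and the full-ambiguity code convey no state information and
are what the missing-data percentage counts. Partial ambiguity codes are
counted in per-character tallies but are excluded from site
classification and from base-composition denominators: resolving `R` to A
or G would require an arbitrary choice, and excluding it keeps
AT + GC = 1 exactly. Characters outside all three sets are treated like
ambiguity codes (excluded, with a logged notice) rather than raising an
error, again to protect batch runs. Lowercase `n`/`x` are treated the
same as uppercase; treating them differently would make statistics depend
on cosmetic case conventions.

## Parsing and writing the five dialects

FASTA, sequential PHYLIP, interleaved PHYLIP, sequential NEXUS and
interleaved NEXUS are supported for both reading and writing. The caller
must declare the dialect; nothing is auto-detected, which keeps parsing a
single cheap pass and failure modes explicit.

* **FASTA**: the taxon name is the description line up to the first
  whitespace (the remainder is dropped with a logged notice, since no
  other dialect can carry it); wrapped sequence lines are joined.
* **PHYLIP**: relaxed names — a name is any whitespace-terminated token,
  of any length. Strict 10-column files still parse because whitespace
  splitting subsumes them when names contain no internal spaces; real
  phylogenomic taxon labels routinely exceed 10 characters, so relaxed is
  the only usable writing convention. The `ntaxa nsites` header is
  verified against the parsed content and any disagreement is an error
  citing expected versus found. Sequential files with exactly one line
  per record are parsed as such (so a site-count mismatch is reported as
  a header error, not a mangled record); files with more lines than taxa
  are treated as wrapped, with unnamed continuation lines appended until
  each record reaches the declared length. Interleaved files name taxa in
  the first block only; later blocks are assigned cyclically in taxon
  order.
* **NEXUS**: keyword matching is case-insensitive, both `DATA` and
  `CHARACTERS` blocks are accepted, and square-bracket comments are
  stripped first. `DIMENSIONS`, when present, is verified like the PHYLIP
  header. Interleaved matrices must repeat taxa in the same order in
  every block; files violating that are rejected rather than silently
  reordered, because silent reordering masks corruption. Written NEXUS
  declares `DATATYPE`, `MISSING=?` and `GAP=-` (which is why
  `write_alignment()` takes a `datatype` argument the read side does not
  need).

Interleaved output wraps at 60 residues per block, the conventional
width. Taxon names containing whitespace cannot survive the
whitespace-delimited dialects, so writers other than FASTA reject them
instead of mangling them.

The contract tying all of this together is round-trip closure:
`read(write(A, F), F)` is identical to `A` for every dialect `F` and
every valid alignment, including zero-site ones. The test suite checks
this property on hundreds of randomized alignments and additionally
checks that an independent parser (`ape`) reads our output to the same
records.

## Summary statistics

`summarize_alignment()` reports: taxa, length, total cells (= taxa ×
length), undetermined count, missing percent (100 × undetermined /
cells), AT and GC content for DNA, counts and proportions of variable and
parsimony-informative sites, and per-character counts (case-folded, with
zero entries for the canonical alphabet so tables over many files share
columns).

Site classification uses the standard parsimony rule, applied to the
column's unambiguous residues only: **constant** if at most one distinct
state remains (a column of nothing but gaps and `N`s is constant),
**parsimony-informative** if at least two states each occur at least
twice, **variable but uninformative** otherwise. The three classes are
mutually exclusive and exhaustive, so constant + variable = length always
holds. Because ambiguity codes are excluded rather than resolved, counts
on real data can differ slightly from tools that resolve ambiguities;
this definitional choice is deliberate and is the one to check first when
comparing outputs across programs.

The full-precision values live in the returned object; the TSV rendering
rounds missing percent to 2 decimals and proportions/contents to 3,
matching how such tables are conventionally printed. The multi-file table
(`summarize_files()`) keeps one row per input file in input order
regardless of the worker count, logs and omits files that fail to parse,
and records them in a `failures` attribute.

## Concatenation, splitting, replicates

`concatenate()` takes the union of input taxa, **sorted
lexicographically in byte order** — input-order unions would depend on
file arrival order under parallel reading, and byte order is
locale-independent, so the same inputs give the same supermatrix
everywhere. A taxon absent from a locus is padded with `?`, not `-`: a
gap asserts an indel, whereas an unsampled locus is simply unknown. Each
input contributes one contiguous partition named by its `source_name`
(duplicated names get numeric suffixes with a warning); emitted
partitions always tile `1..L` with no gaps or overlaps.

The emitted partition file is the bare `name = start-end` dialect with
1-based inclusive coordinates, which every downstream phylogenetics
program understands. The parser is deliberately more liberal than the
writer: RAxML-style leading type tokens (`DNA, gene1 = 1-100`),
comma-separated multi-range entries, single sites and codon strides
(`1-99\3`) all parse, because published partition schemes use all of
them. Sites within one partition are kept strictly increasing; entries
that are out of order or duplicated are sorted/deduplicated with a logged
warning, and sites claimed by two partitions are permitted (loci may
legitimately share sites) but warned about.

`split_alignment()` extracts each partition's sites in order. With
`remove_empty`, taxa whose extracted sequence is entirely missing are
dropped; since concatenation fills exactly those slots with `?`,
splitting a supermatrix by its own partitions then recovers the original
loci (up to taxon order, which the supermatrix sorts). `split_alignment()`
takes a `datatype` argument beyond the obvious inputs because "entirely
missing" depends on the datatype's missing set.

`make_replicates()` samples loci uniformly **without replacement** within
a replicate, independently across replicates — the phylogenetic jackknife
convention; a bootstrap-style with-replacement variant would be a
different resampling design and is intentionally not conflated with this
one. Sampling is driven by an explicit seed and the caller's RNG state is
saved and restored, so replicate construction is reproducible without
side effects on the session.

## Parallelism and the command line

The parallel unit is one input file per worker task, matching the
many-small-loci shape of phylogenomic datasets; results are reassembled
in input order before anything is written, so outputs are byte-identical
for any `cores` value (forked workers via the `parallel` package; serial
fallback where forking is unavailable). Input files are never modified —
a conversion whose output path would equal its input is refused. Per-file
failures are logged to standard error and skipped; the exit status is
zero only if every file succeeded.

The CLI (`exec/alnkit`, a thin wrapper over `aln_parse_args()`/
`aln_run()`) performs exactly one action per invocation, takes its flags
in any order, and always requires the input files, the input format and
the datatype. A `gen-fixtures` action exposes the synthetic-alignment
generator so a pipeline can be smoke-tested without real data.

## The synthetic generator, and what passing tests do not show

`sim_alignment()` draws an ancestral state per site, mutates each cell
away from it with probability 0.3, then overwrites cells with missing
characters (5%) and partial-ambiguity codes (1%). `sim_alignment_set()`
defaults to 20 loci over a pool of 8 taxa, 30–120 sites per locus, 70%
taxon occupancy — a desk-scale caricature of a phylogenomic locus set,
chosen once as realistic for exercising every code path (partial
occupancy produces `?` fill; the mutation rate produces a healthy mix of
constant, uninformative and informative columns).

The generator emulates the *combinatorial* features the toolkit cares
about — alphabets, missing data, occupancy, interleaving — and none of
the evolutionary ones: there is no phylogenetic correlation among taxa,
no indel structure (gaps appear as isolated missing cells, not runs), no
among-site rate variation, and sequence composition is uniform. Passing
tests therefore demonstrate that parsing, bookkeeping and counting are
exact, not that the statistics are biologically calibrated; on real data
the interesting risks are definitional (see the ambiguity-exclusion note
above), not computational.

Test problem sizes are the package's own choices: the exhaustive
classifier check enumerates all 8^5 = 32,768 five-character columns over
`{A,C,G,T,-,?,N,R}`; round-trip closure runs 500 randomized alignments of
up to 30 taxa × 200 sites through all five dialects; split-of-concat
inversion runs 200 randomized locus sets; parallel determinism compares
serial and 8-worker conversion of 1,000 generated files byte for byte;
replicate uniformity draws 1,000 single-locus replicates from 4 loci and
applies a chi-square goodness-of-fit test at α = 0.01.

## Known limitations

* CLUSTAL and other input dialects beyond the five are out of scope, as
  are automatic format detection, per-taxon statistics, translation or
  recoding, consensus sequences, and anything involving trees.
* Sequential NEXUS matrices are expected to hold one line per taxon (the
  layout the writer emits); wrapped sequential NEXUS without repeated
  names is not reconstructed. Quoted NEXUS taxon names are not supported.
* PHYLIP parsing is relaxed-name only by design; a strict-width file
  whose names contain internal spaces will misparse — declare your
  format honestly.
* Replicate sampling is without replacement only; a with-replacement
  flag would be a straightforward extension but is not present.
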