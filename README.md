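# alnkit

Alignment manipulation and summary statistics for phylogenomics, in R.

Modern phylogenomic studies juggle hundreds to thousands of single-locus
multiple sequence alignments: loci are concatenated into supermatrices,
supermatrices are split back into loci by partition schemes, replicate
datasets are resampled for jackknife analyses, problem taxa are trimmed,
files are converted between the formats that different inference programs
demand, and per-locus statistics (missing data, variability, base
composition) drive filtering decisions. `alnkit` packages all of these
operations as plain R functions plus a thin command-line wrapper, so they
can sit inside a scripted pipeline.

## What it does

* **Read/write five dialects** — FASTA, PHYLIP (sequential and
  interleaved, relaxed whitespace-terminated names), NEXUS (sequential and
  interleaved `DATA`/`CHARACTERS` blocks). Writing then reading any valid
  alignment is the identity, so any-to-any conversion is lossless.
* **Concatenate** loci into a supermatrix over the union of their taxa
  (sorted lexicographically). A taxon unsampled for a locus is padded with
  `?` across that locus, and a partition file records each locus's 1-based
  inclusive coordinates (`locus1 = 1-3`).
* **Split** a supermatrix by a partition scheme (RAxML-style type
  prefixes, comma-separated ranges and codon strides `1-99\3` are
  understood), optionally dropping taxa that are entirely missing within a
  partition — which makes splitting invert concatenation.
* **Resample** jackknife replicates: each replicate concatenates *k* loci
  drawn uniformly without replacement from the input set, reproducibly
  under a seed.
* **Remove taxa** by name, preserving record order.
* **Summarize** each alignment: taxa, length, total matrix cells,
  undetermined characters and percent missing, AT/GC content (DNA),
  counts and proportions of variable and parsimony-informative sites, and
  per-character counts — written as a TSV, one row per file.
* **Batch, in parallel** — per-file operations fan out over forked
  workers (`cores =`), with results reassembled in input order so output
  bytes never depend on the worker count. Input files are never modified;
  a file that fails to parse is logged and skipped without stopping the
  batch.

The site classifier follows the standard parsimony rule on a column's
unambiguous residues (case-folded; `?`, `-` and `N`/`X` are missing, IUPAC
partial codes are excluded): a column is **constant** if at most one state
remains, **parsimony-informative** if at least two states each occur in at
least two sequences, and **variable but uninformative** otherwise. AT
content is `(A + T) / (A + C + G + T)` over unambiguous bases, so AT + GC
= 1 whenever any unambiguous base is present.

## Worked example

```r
library(alnkit)
a <- alignment(c(sp1 = "AAA", sp2 = "CCC"), source_name = "locus1")
b <- alignment(c(sp2 = "GG", sp3 = "TT"), source_name = "locus2")
sm <- concatenate(list(a, b))
print(sm$alignment)
#> <alignment 'concatenated': 3 taxa, 5 sites>
#>   sp1  AAA??
#>   sp2  CCCGG
#>   sp3  ???TT
cat(write_partition_file(sm$partitions))
#> locus1 = 1-3
#> locus2 = 4-5
summarize_alignment(sm$alignment, "dna")
#> <alignment summary 'concatenated'>
#>   taxa: 3  sites: 5  cells: 15
#>   undetermined: 5 (33.33%)
#>   AT: 0.500  GC: 0.500
#>   variable sites: 5 (1.000)  parsimony-informative: 0 (0.000)
```

`sp1` and `sp3` are each missing one locus, so 5 of the 15 matrix cells
are `?` fill — 33.33% missing. Every column holds two distinct states but
each state only once among the unambiguous residues, so all 5 sites are
variable yet none is parsimony-informative. The two partition lines map
each locus back to its coordinates in the supermatrix, ready for a
per-locus model in RAxML or IQ-TREE.

The same operations are available from a shell (one action per
invocation; input files, input format and datatype are always required):

```sh
exec/alnkit concat -i locus1.fas locus2.fas -f fasta -d dna -u phylip -o out/
exec/alnkit summary -i *.fas -f fasta -d dna -c 8 -o out/
exec/alnkit split -i out/concatenated.phy -f phylip -d dna -l out/partitions.txt -e
exec/alnkit replicate -i *.fas -f fasta -d dna -r 100 50 --seed 42 -o reps/
```

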