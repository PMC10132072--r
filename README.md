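# ksclf

Annotation-free discovery of type II polyketide synthase (PKS)
ketosynthase/chain-length-factor (KS–CLF) gene pairs in raw nucleotide
sequence.

## The problem

Type II polyketides (tetracyclines, doxorubicin and relatives) are made by
type II PKSs, whose minimal core is a KS–CLF heterodimer encoded by two
adjacent genes inside a biosynthetic gene cluster (BGC). Mining public
nucleotide data for these clusters usually leans on existing genome
annotation, which misses environmental contigs, draft genomes and anything
annotated before current models existed. `ksclf` implements an
annotation-free workflow for scientists doing natural-product genome mining:
it starts from raw translated-homology hits (tblastn-style tabular output)
against unannotated nucleotide sequence and ends with candidate KS–CLF pairs,
merged cluster regions and phylogeny-ready alignments and trees.

## The method

For each homology hit the pipeline:

1. **Filters hits** at a permissive e-value ≤ 1 (distant homologs survive;
   later stages remove spurious alignments).
2. **Calls the longest containing ORF**: within a window 500 nt before and
   after the hit, in the hit's own frame and strand, an ORF runs from the
   first of six accepted start codons (ATG, CTG, GTG, TTG, ATT, ATC) after a
   stop codon (or sequence edge) to the next in-frame stop (or edge). The
   retained ORF must be ≥ 300 nt long and cover ≥ 50 % of the hit with an
   identical translated sequence.
3. **Classifies translations with profile HMMs**. Candidate proteins are
   scored in bits (log2 odds against a background null) against KS and CLF
   profile models. Retention thresholds are *calibrated*, not guessed: the
   threshold for each model is the score of a distantly related reference
   cluster's protein, and anything scoring greater than or equal to that
   reference is retained (so the reference itself always survives).
4. **Pairs genes by proximity**: every KS–CLF combination on one nucleotide
   record with intergenic distance ≤ 2 kb (overlap counts as 0) and both gene
   lengths < 6 kb becomes a pair; one KS near two CLFs yields two pairs.
5. **Extracts cluster regions** 30 kb either side of each pair, merging
   overlapping regions, and categorizes their condensation-domain content
   (`t2ks`/`t2clf`/`t2fas` tokens → KS+CLF, KS+FAS, FAS+FAS pairings).
6. **Prepares phylogenies**: alignment columns with > 5 % gaps are removed,
   tree nodes with < 70 % support are collapsed into polytomies, and trees
   are rooted on a named outgroup (classically an *E. coli* FabF sequence).

A synthetic-genome generator (`synthetic_study()`, `generate_genome()`,
`simulate_blast_hits()`) plants KS/CLF-like genes and FAS-like decoys with
ground truth, so the whole pipeline can be exercised and tested without any
database download.

## Worked example

```r
library(ksclf)

st  <- synthetic_study(seed = 1)        # 20 kb contig: 3 planted pairs + 2 decoys
cls <- classifier_config(st$ks_threshold, st$clf_threshold)
run <- run_scan(st$record, st$hits, st$models$ks, st$models$clf, cls)
run
#> <ksclf_run>
#>   hit_filter         8 ->     8
#>   orf_calling        8 ->     8
#>   orf_dedup          8 ->     8
#>   classification     8 ->     6
#>   pairing            6 ->     3
#>   regions            3 ->     1
```

All eight planted genes (three KS, three CLF, two decoys) yield hits and
ORFs; classification drops exactly the two FAS-like decoys; the six labelled
genes pair into the three planted KS–CLF pairs, which merge into one 30 kb
region:

```r
run$pairs[, c("record_id", "ks_start", "ks_end", "ks_strand",
              "clf_start", "clf_end", "gap_nt")]
#> # A tibble: 3 x 7
#>   record_id ks_start ks_end ks_strand clf_start clf_end gap_nt
#> 1 synth_1        600    975 +              1025    1466     50
#> 2 synth_1       4445   4952 +              5752    6181    800
#> 3 synth_1       9178   9724 -             11555   11996   1831
```

Coordinates are 0-based half-open on the forward strand. Called ORFs may
begin 5' of the planted start codon (the method deliberately takes the first
alternative start codon after a stop, so 5' ends can be generous); stop-codon
ends are exact. `glance(run)` gives one-row counts, `tidy(run)` the pair
table, `autoplot(run)` the stage funnel, and `plot_scores()` the KS/CLF bit
scores against the calibrated thresholds.

Tree and alignment post-processing work on standard objects:

```r
tr <- read_newick("(((A:1,B:2)0.69:0.5,(C:1,D:1)0.70:0.4)0.71:0.3,G:2);")
collapse_low_support(tr, min_support = 0.70)  # contracts only the 0.69 node
root_with_outgroup(tr, "G")
```

A thin command-line front end ships in `inst/scripts/ksclf` with
`simulate`, `run`, `trim-aln`, `collapse-tree` and `reroot` subcommands.

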