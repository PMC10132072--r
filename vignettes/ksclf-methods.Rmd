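---
title: "Methods: annotation-free KS-CLF discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-free KS-CLF discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksclf)
```

`ksclf` finds candidate type II polyketide synthase KS–CLF gene pairs in
unannotated nucleotide sequence. This vignette documents the model behind
each stage, the parameters that matter, the numerical and design choices that
were genuinely open, and what the synthetic-data tests do and do not
establish about real data.

## Coordinate conventions

Every interval in the package is 0-based and half-open (`[start, end)`) on
the forward strand; minus-strand features carry forward coordinates plus a
strand flag. One arithmetic convention serves both strands, and conversion to
the 1-based inclusive coordinates of tabular homology output happens only in
`read_blast_hits()`/`hit_intervals()`. Only `N` is accepted as an ambiguity
code: a codon containing `N` translates to `X`, and is treated as neither
start nor stop — a conservative, deterministic rule that can shorten an ORF
but never invent one.

## Hit-anchored ORF calling

The entry point is a table of translated-homology hits (tblastn style), kept
when the e-value is at most 1. The permissive cutoff is intentional: distant
homologs are wanted, and the downstream coverage, classification and
proximity stages remove spurious alignments.

For each hit a window extending `flank_nt = 500` nt on either side is
scanned in the hit's own frame and strand. Only that frame needs scanning:
retention requires the ORF to reproduce the hit's translated sequence, which
an out-of-frame ORF cannot do (its identity coverage is 0). An ORF begins at
the first of six accepted start codons (ATG, CTG, GTG, TTG, ATT, ATC) after a
stop codon or sequence edge, and runs to the next in-frame stop codon or
edge. Alternative start codons mean called 5' ends can be upstream of the
biological start; the 3' (stop-codon) end is exact. Candidates must be at
least `min_orf_nt = 300` nt long and cover at least
`min_hit_coverage = 0.5` of the hit residues with an identical translation;
the longest qualifying ORF is returned.

Three decisions here were open and are now fixed (and configurable):

* **Window edges delimit ORFs like sequence edges** (`window_bounded = TRUE`).
  The alternative — following an ORF beyond the window until a real stop —
  is available as `window_bounded = FALSE`.
* **Edge-truncated ORFs are retained**: a segment flush against an edge with
  no start codon still yields an ORF, flagged `has_start_codon = FALSE`. The
  definition attaches the edge alternative to the delimiting stop, so a
  truncated gene at a contig boundary is not silently lost.
* **The terminal stop codon is part of the ORF interval**, and the 300 nt
  minimum is measured on that interval (300 nt = 99 codons plus stop).
  Coverage scoring compares hit residues against the raw genomic translation;
  positions translating to `*` or `X` never count as identical.

Ties in "longest" cannot occur within one frame (stop-delimited segments are
disjoint); across degenerate edge cases the earliest-starting ORF is taken,
deterministically.

## Profile HMM scoring and calibration

Classification uses profile HMMs built from seed alignments
(`build_profile()`): columns with under 50 % gaps become match states; match
emissions are counts regularized by background-proportional pseudocounts of
total weight 1 (the upstream models' training recipe is not part of this
package's contract, so the simplest standard regularizer is used); insert
states emit the background; transitions are estimated from the observed
alignment paths with +1 smoothing.

Scoring (`score_sequence()`) is local: entry is uniform over the `L` match
states, exit is permitted from every match state (probability
`1/(L - j + 1)` at column `j`, so exit is certain at the last column), and
residues outside the aligned core are emitted by the background null, which
cancels out of the reported log2-odds bit score. All probability arithmetic
is in log2 space with max-shifted summation, so forward scores are
underflow-safe. The forward score sums all alignments; Viterbi takes the
best one, so forward ≥ Viterbi always. This scorer is deliberately minimal —
small enough that an exhaustive path-enumeration oracle verifies it exactly
on tiny models — and it is **not** bit-compatible with HMMER: externally
published thresholds (such as KS = 352 / CLF = 66 from HMMER-scored models)
apply only when scores come from that same external scorer, for which
`classifier_config(scorer = "external", score_fun = ...)` is the hook.

In builtin mode thresholds are *calibrated*: `calibrate_threshold()` scores a
distantly related reference protein (the aurachin-cluster principle) and
retention is `score >= threshold`, boundary inclusive, so the reference
itself is always retained. A protein meeting both thresholds takes the label
with the higher score; an exact tie resolves to KS, deterministically.

One subtlety is documented rather than hidden: padding a sequence with
null-equivalent residues (`X`, emitted with background probability in every
state) leaves the best alignment's score exactly unchanged, but the forward
*sum* can grow marginally, because flank residues open additional low-mass
entry paths. The package's tests pin the exact statement (Viterbi equality at
1e-9; bounded non-negative forward drift). Arbitrary random flanking residues
perturb forward scores slightly more — expected behaviour of any local
scorer, since real residues can align productively.

`sample_sequence()` draws a full core-domain path (first to last match
column); the uniform entry/exit is an alignment device of the scorer, not
part of the generative core, so a model with all emission mass on its
consensus samples exactly the consensus.

## Proximity pairing and regions

Labelled KS and CLF ORFs on the same record pair when their intergenic
distance is at most `max_gap_nt = 2000` and both gene lengths are under
`max_gene_nt = 6000`. Distance is measured between closest interval ends;
overlapping or abutting genes score 0 — the only definition under which
"overlapping matches pass" is natural. "Over 2 kb removed" is read strictly
(2000 retained, 2001 removed) and "less than 6 kb" strictly (5999 retained,
6000 removed). Strand concordance is *not* required — proximity, not
orientation, is the published criterion — but both orientations are recorded.
Every KS x CLF combination is emitted, so one KS near two CLFs gives two
pairs (pair counts can exceed distinct gene counts).

Regions extend each pair's bounding interval by `flank_nt = 30000` on both
sides, clip to the record, and merge overlapping extensions. Under this rule
two pairs up to 60 kb apart merge; an alternative reading — regions distinct
whenever the pair intervals themselves are more than 30 kb apart — is
available as `merge_rule = "pair_gap"`. Region categorization follows the
token truth table: KS+CLF needs ≥ 1 `t2ks` and ≥ 1 `t2clf`; KS+FAS needs ≥ 1
`t2ks` and ≥ 1 `t2fas`; FAS+FAS needs ≥ 2 `t2fas`; the categories are not
exclusive and running a cluster annotator is out of scope — the package
consumes its label table (or a trivial text scan, `scan_gene_functions()`).

## Phylogeny preparation

`trim_gap_columns()` removes alignment columns whose gap fraction exceeds
0.05, computed over all rows (fully gapped rows included); exactly 5 % is
kept. `collapse_low_support()` contracts internal edges whose child support
is strictly below 0.70, adding the contracted branch length to the
reattached children, so leaf sets and root-to-leaf path lengths are
preserved (to 1e-9) and the operation is idempotent. Support values stored as
FastTree-style internal labels may be fractions or percentages;
`support_scale = "auto"` treats any value above 1 as a percentage. Nodes
without support are kept by default (with a warning) — collapsing them would
destroy topology on the basis of missing data; `"zero"` and `"error"`
policies are available. `root_with_outgroup()` splits the outgroup leaf's
edge at its midpoint, conserving total branch length; rerooting on a leaf
already subtending the root is the identity. Alignment and tree inference
themselves (MAFFT, FastTree) are external tools; the package reads and
writes their standard FASTA/Newick formats.

## What the synthetic generator emulates — and what it does not

`generate_genome()` plants genes (start codon + reverse-translated body +
stop codon, reverse-complemented on the minus strand) into i.i.d. background
sequence at a chosen GC fraction, and `simulate_blast_hits()` derives one
identity hit per gene covering the central 80 % of its coding codons with
exact frame/phase arithmetic. `synthetic_study()` assembles the standard
fixture: a 20 kb contig with three KS–CLF pairs at gaps of 50, 800 and
1900 nt — spanning the allowed range up to near the 2 kb bound — plus two
FAS-like decoy genes, with pairs separated by 3 kb spacers chosen so that 5'
ORF extension (bounded by the 500 nt window flank) cannot manufacture a
spurious cross-pair. Proteins are sampled from three divergent toy profile
families (140 columns, six seed sequences at 90 % consensus identity);
calibration references are family consensi with 55 % of positions mutated —
clearly diverged from the family yet far above the score of an unrelated
sequence, mirroring the role of a distantly related reference cluster. All
randomness flows from one seed through named substreams, so fixtures are
reproducible.

The generator deliberately does **not** emulate: evolutionary divergence with
indels along a phylogeny, genuine tblastn alignment behaviour (gapped,
mismatched, partial-frame hits), compositional bias or repeats, or real
KS/CLF sequence motifs. Background sequence does contain incidental ORFs and
decoys do receive hits, so the coverage and classification stages — not
generator tricks — must reject negatives. Passing tests therefore establish
the *mechanics* (coordinates, boundaries, calibration, pairing semantics,
determinism) at the stated study sizes; they do not establish recall against
real databases, which depends on query choice and model quality.

## Problem sizes and runtime choices

The test and acceptance workloads are desk-scale by design: 500 random
windows of up to 3 kb for the ORF oracle; exhaustive forward-vs-path-sum
checks for models of 1–3 match states against all 4-letter sequences up to
length 4 plus 200 random length-5 sequences; 200 samples per family for
classification recovery; five 20 kb synthetic studies end to end. Toy
profiles use 140 columns so planted genes (~420 nt) sit comfortably above
the 300 nt ORF minimum even after sampled deletions.

## Known limitations

* The builtin scorer is single-hit local (one aligned core per sequence);
  HMMER-style multi-hit scoring, E-values and posterior calibration are out
  of scope.
* ORF 5' ends are systematically generous under alternative start codons;
  downstream users should treat called starts as upper bounds on gene extent.
* Pairing ignores strand and operon structure beyond distance.
* `D->I` and `I->D` profile transitions are excluded (standard minimal
  architecture); alignments requiring them contribute nothing to training
  counts.
* The delete track must rejoin the match track before the final column
  (`M_{L-1} -> D` is disabled), so probability never leaks into dead-end
  paths.
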