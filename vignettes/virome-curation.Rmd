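---
title: "Curating virus genome scaffolds from mixed metagenomic assemblies"
author: "virosieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating virus genome scaffolds from mixed metagenomic assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virosieve)
```

## The problem

Viromes are sequenced from the sub-0.2 µm fraction of an environmental
sample, but filtration is imperfect: dissolved genomic DNA, plasmids and
small organelles (mitochondria in particular) survive into the library.
After assembly, a substantial fraction of the large scaffolds is therefore
not viral at all. This package implements a curation workflow for that
situation: pool assemblies built at several k-mer lengths, remove
redundant contigs, detect circular genome scaffolds (strong evidence of a
complete, correctly assembled genome), separate genuine virus scaffolds
from cellular/plasmid/mitochondrial contamination using database-hit
ratios, compare the circular genomes to each other, and extract host
evidence (attP/tRNA matches, CRISPR spacer links).

Because the workflow's inputs at full scale are large external read sets
and reference databases, the package pairs every stage with a synthetic
community generator that plants the exact features each stage must
recover. The tests and the acceptance analysis run entirely against this
planted truth plus the published summary counts bundled as
`cryoconite_counts()`.

## Pooling and redundancy removal

Assemblies built at k = 24–63 are pooled per virome after a 5 kb export
cutoff, then swept for redundancy in descending length order. A contig is
removed when it has a self-search hit of more than 1000 bp at ≥ 97%
identity (E ≤ 1e-5) to a *strictly longer contig that is still retained*
at the moment it is considered. Two readings of "matched larger ones"
exist; we resolve against the currently retained set because it prevents
cascade removal through an already-removed intermediary (a chain A>B>C
where C matches only B keeps C once B is gone). The alternative sweep is
available via `against = "all-larger"`. Thresholds apply per hit row
(per HSP): several sub-1000 bp HSPs do not sum to a qualifying match.
Equal-length mutual matches drop the lexicographically later id, a
deterministic tie-break for a case the criteria leave open.

Retained scaffolds then pass a length gate — 15 kb for linear scaffolds,
relaxed to 10 kb for circular ones, since circularity itself argues for a
complete genome — and a 10× minimum mean coverage, below which chimeric
assembly becomes too likely.

## Circularity

Paired reads are mapped back to scaffolds with a concordant paired
distance of 0–900 bp; `classify_pairs()` partitions pairs at that span. A
discordant pair is *circularly mapped* when one mate's alignment lies
entirely within the first 1000 bp of the scaffold and the other's within
the last 1000 bp; three or more such pairs call the scaffold circular.
Containment is by full alignment interval rather than midpoint — with
100 bp reads the difference is negligible and the stricter reading never
overcalls. Mate orientation is not required (no strand constraint is part
of the rule); scaffolds shorter than twice the window truncate both
windows at the midpoint and are flagged `short`. Complete genomes whose
assembler ran past the origin are caught independently by
`detect_terminal_overlap()`, the longest exact prefix–suffix repeat of at
least 20 bp.

The read simulator draws fragment lengths from N(400, 80²) (truncated to
[2 × read length, mean + 4 sd]) and fragment starts uniformly on the
genome. On circular genomes a fragment may wrap the origin, which is what
produces end-spanning pairs after linearization; starts that would make a
*single read* cross the origin are redrawn, since such a read could not
align contiguously. Under this model the expected number of end-spanning
pairs is `n_pairs * (insert - 2*(read_len - 1)) / L`.

Read depth in all simulations is tied to the community's nominal
coverage, `n_pairs = coverage × L / (2 × read length)`, with coverage
defaulting to 40× (the middle of the 39–49× range typical of confidently
assembled virome scaffolds). At a fixed small pair count (say 500) the
expected end-spanning count for a long genome sits uncomfortably close to
the 3-pair threshold — around 2–5 — and occasional misses would reflect
sampling noise, not detector error. At 40× the expectation is 20–50 and
recovery of the planted circular/linear labels is complete across the
full 200-genome community; the acceptance analysis runs at exactly that
scale (~1.5 million read pairs).

## Triage

Most predicted genes on environmental virus scaffolds have no database
match, so all ratio rules are normalized to the number of Pfam-A hits
rather than to all gene predictions. The decision list, in order:

1. coverage < 10× → reject (chimera risk);
2. ≥ 1 Silva SSU/LSU hit → cellular review;
3. mitochondrion hits > 50% of Pfam hits → mitochondrial review;
4. ACLAME plasmid hits > 50% of Pfam hits → plasmid review;
5. ≥ 1 hit to the phage-exclusive POGs-7 families → viral;
6. RefSeq-virus ≥ 50% *and* POGs-10 ≥ 10% of Pfam hits → viral;
7. otherwise ambiguous.

Precedence is a genuine design choice: a scaffold can satisfy the viral
rule and still carry a Silva hit. We put the contamination flags first —
the review labels are queues for manual inspection, not final verdicts,
so a conservative order costs nothing and keeps the automatic viral call
strict. Two further choices: the POGs-7 rule requires ≥ 1 hit (any
weaker threshold would be vacuous, and the families are phage-exclusive,
so a single hit is informative); and although the mitochondrion search is
scaffold-level tblastx, its ratio rule is normalized, like the others, to
Pfam-A hits, applying one normalization convention uniformly. With zero Pfam
hits the ratio rules evaluate false rather than dividing by zero, and the
rationale records it.

`triage_batch()` also reproduces assembly-table style summaries: each
database's gene-hit count over total gene predictions at one decimal
place, and the confirmed-viral fraction of candidates.

## Whole-genome comparison

Circular genome scaffolds are compared by all-vs-all translated search;
the package consumes the tabular hits. Hits must exceed 30% identity,
span ≥ 30 aligned residues and have E < 0.01. Bitscores are summed per
genome *pair*, with both query directions pooled so S is symmetric by
construction (a directional mode exists behind a flag). Similarity is
the Dice coefficient over summed scores,

D(a, b) = 2 S(a, b) / (S(a, a) + S(b, b)),

with D = 0 (and a flag) where a self-score is missing, and dissimilarity
1 − D feeds neighbor joining. Dice-style genome similarities are
sometimes normalized by hit counts instead of self-scores; the
self-score form is the one implemented and documented here, since it
makes a duplicated genome score exactly 1 against itself.

NJ is the textbook Saitou–Nei algorithm with the Studier–Keppler
Q-criterion, implemented in-package so tie-breaking is deterministic:
among Q-minimizing pairs, the lexicographically smallest pair of clade
labels (a clade is labelled by its smallest leaf id) is joined. Negative
branch lengths, possible on non-additive input, are clamped to zero with
the deficit moved to the sibling branch of the same join — the standard
correction — and the unclamped tree is retained in a `raw_newick`
attribute. On additive matrices NJ is consistent, and the tests require
exact recovery (topology and path lengths) of random 4–8 taxon trees,
cross-checked against `ape::nj`.

Genome groups are single-linkage components of the graph with edges
D ≥ 0.05. There is no canonical cutoff for calling two phage genomes
"grouped", so the threshold is exposed as a free parameter with 0.05 as a
deliberately permissive default: any reproducible shared-protein signal
links genomes, and singletons are reported separately as "unique".

## Host links

Integrating phages carry an attachment site (attP) that is an exact copy
of part of a host tRNA gene, so `find_attp()` reports all maximal exact
shared substrings (both strands, no mismatches or gaps) between scaffolds
and a tRNA database. The minimum reported length defaults to 25 bp: the
observed significant matches span 28–60 bp, and below ~20 bp exact
matches arise by chance in databases of realistic size. Matching is
seed-and-extend over an indexed dictionary of query k-mers — contractually
equivalent, for exact hits, to a BLASTN search filtered at 100% identity.
Assignments are restricted to scaffolds with an annotated integrase gene
(keyword-matched, configurable) and capped at class rank, because tRNA
conservation does not support finer host calls; conflicting phyla are
reported and flagged rather than resolved.

CRISPR arrays are external inputs (detection is a separate tool's job);
`match_spacers()` finds exact full-length spacer occurrences on both
strands, excluding the source array's own locus. Spacers under 15 bp are
searched but flagged as chance-match risks. In the pipeline the search
runs against the curated (post-dedup) assembly — searching the redundant
copies too would trivially re-find every planted motif inside them.

## The synthetic community

`community_spec()` fixes the study conditions: 100 bp paired-end reads,
400 ± 80 bp inserts, a 60–650 bp concordant range, 40× coverage, genome
lengths 15–60 kb (bracketing typical assembled phage scaffolds), and
abstract genes as 900 bp windows laid head-to-tail (~1.1 genes/kb, a
typical phage coding density). Genomes are uniform random DNA; planted
features are the only structure: exact tRNA segments of 28–60 bp plus an
integrase annotation (attP), repeat–spacer–repeat CRISPR loci whose
penultimate spacer is copied into another genome (spacers are acquired
chronologically, so the penultimate one is the most recent plausible
target), exact substring copies at 60% length (redundancy), and
class-conditional hit-table regimes that satisfy the triage rules by
construction. One root seed drives per-scaffold child streams, so output
is byte-reproducible and adding a scaffold does not perturb the others.

What the generator does **not** emulate — sequence evolution, sequencing
error, quality variation, abundance skew, shared gene content between
unrelated genomes — bounds what the tests show: they demonstrate that
each stage recovers exactly the signal it is defined on, with no false
positives at realistic sequence scale, not that the thresholds are
optimal for real data. Hit tables are emitted from class regimes rather
than by running real HMMER/BLAST because the pipeline's contract is over
tabular hits; the search engines are replaceable. The all-vs-all
cross-hit emitter (`emit_cross_hits()`) uses a deliberately minimal
score-per-alignable-bp model — sufficient to verify the Dice/NJ/grouping
arithmetic, not a sequence-similarity simulation.

## Problem sizes and numerics

The analysis drivers under `analysis/` run a 60-genome community; the
acceptance analysis and the end-to-end test run 200 genomes (plus 8
planted redundant contigs) at full 40× read depth, about 1.5 million
pairs, a few minutes on one CPU. Percentages mirror mixed reporting
precision: table-style gene-hit summaries use one decimal place
uniformly; read fractions use one decimal place at ≥ 1% and two below
(0.16%-style), with an integer mode for headline shares ("20% of viral
reads"). Composition normalization is the plain hit-per-bp ratio
renormalized to one; the iterative length-normalized abundance estimation
some tools layer on top is out of scope, and the divergence is
documented here.

## Known limitations

* Review labels are queues, not decisions; the downstream manual searches
  (GenBank BLASTX for plasmid queues, organelle annotation for
  mitochondrial queues) are outside the package.
* Concatemers and circular permutation are not distinguished from true
  circularity; rotation normalization is out of scope.
* The Dice grouping threshold is a free parameter; group counts on real
  data depend on it and on the reference genomes included.
* PCR duplicates among circularly mapped pairs are counted as given.
* `find_attp()` does not test whether a match is intergenic; gene overlap
  is not considered.
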