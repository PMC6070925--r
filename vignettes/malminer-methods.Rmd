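---
title: "Methods: mining and classifying MAL clusters in yeast genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and classifying MAL clusters in yeast genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malminer)
```

## The problem

Genes for the utilization of α-glucosidic sugars (maltose, isomaltose,
sucrose, palatinose, …) are among the few examples of metabolic gene
clustering in yeasts. A *MAL* locus minimally couples an α-glucosidase
(**AG**, a GH13 hydrolase) with an α-glucoside transporter (**AGT**, a
permease), usually as a divergent gene pair sharing a bidirectional
promoter, often accompanied by one or two Zn(2)-Cys(6) transcriptional
activators (**MAL-activators**). malminer implements the computational side
of a comparative survey of such loci: it scans annotated genomes for *MAL*
clusters, describes their geometry (divergent pairs, introns, distance from
the contig end), predicts the substrate specificity of the encoded
α-glucosidases from nine sequence positions, and builds neighbor-joining
phylograms of the proteins.

Everything is driven by tabular data (tibbles of genes, candidates,
clusters, signatures), so the package is organized tidyverse-style: data
frames in, tibbles out, `tidy()`/`glance()` accessors and `autoplot()`
methods for the result types. Trees are `ape::phylo` objects, the
lingua franca of R phylogenetics.

## Cluster mining

`find_candidates()` assigns a role (AG, AGT, ACT) to genes by global
alignment of their proteins against one reference per role, accepting a hit
at **identity ≥ 30 %** and **coverage ≥ 50 %** of the reference. Both
thresholds are deliberately permissive — comparative surveys of this kind
rest on BLAST-style hits without hard cut-offs, and the cluster definition
(below) provides the real specificity — and both are configurable and
echoed into every report. A gene whose annotation text matches a role keyword (most
importantly `Zn(2)-Cys(6)` for activators, whose sequences diverge too fast
for reliable homology calls) is kept as a candidate even below the
thresholds. Score ties across roles fall back to identity; unresolved ties
are flagged ambiguous and never satisfy the AG requirement.

`find_clusters()` applies the field's cluster definition: **at least two
candidate *MAL* genes, at least one encoding an AG**. Candidates are chained
along a contig while consecutive inter-candidate gaps stay within
`max_gap = 10 000` bp. The field's definition carries no explicit distance
rule (clusters are read off synteny maps); 10 kb is a proxy chosen to span
a couple of intervening hypothetical genes — which real loci do contain —
while keeping unrelated candidates tens of kilobases apart in separate
clusters. Non-candidate genes between members do not break a run.

`annotate_clusters()` adds the geometry: a divergent pair is two adjacent
members (no annotated gene between them) with the left gene on `-` and the
right on `+`, 5′ ends facing, within `max_promoter_span = 2 000` bp — the
scale of a yeast bidirectional promoter. The distance to the nearest contig
end is `min(start − 1, length − end)`; a cluster is called subtelomeric
below **50 kb**. That threshold is a judgment call: loci ~400 kb from the
chromosome end are unambiguously internal, loci within a few tens of
kilobases are conventionally called subtelomeric, and the value is recorded
in every report header so downstream users can re-call it.

## The nine-residue signature and substrate specificity

Crystal structures of *S. cerevisiae* isomaltase IMA1 identify nine residues
bordering the substrate-binding pocket — positions **158, 216, 217, 218,
219, 278, 279, 307 and 411** in IMA1 numbering. `extract_signature()` maps
these anchors onto any α-glucosidase by end-to-end pairwise alignment to the
reference and reads off the aligned residues; a deletion over an anchor
yields `-`. The convention extends to every anchor, not just 158 (the one
gapped case among the bundled references).

`classify_signature()` applies a fixed-order decision procedure:

1. **Val216 → isomaltase.** Mutagenesis shows Val at 216 is the key
   determinant of isomaltose-type activity.
2. **TV or AI at 216–217 → maltase.** Both motifs belong to experimentally
   characterized maltases.
3. **VI at 216–217 → isomaltase** (unreachable after rule 1; retained so
   reports can name the motif).
4. Otherwise the signature is maltose-capable (e.g. TAG at 216–218), and the
   label is decided by a **nearest-reference vote**: the match count
   (identical non-gap positions, 0–9) against every experimentally studied
   maltase and maltase-isomaltase reference; the top label wins, and a tie
   across labels is reported as `ambiguous`, never silently resolved. A gap
   at 216 is likewise `ambiguous`.

The vote pool is restricted to *studied* references because the procedure
exists to transfer experimentally established specificity onto unstudied
sequences; isomaltase references are excluded from the vote because
isomaltase-type signatures are already fully captured by the Val216 rule.
When a studied reference is itself classified the vote trivially finds it at
9/9 — that self-consistency is intended, and the bundled reference table is
reproduced row by row by the test suite (all three classes represented).

One bundled-table note: the literature quotes six matching positions
between *Cf* AG1.1 and *Sc* IMA5, but a position-by-position comparison of
the two signatures as tabulated (`MVCSLVGSQ` vs `FVGSMVGSE`) gives five.
The package reports the computed count.

```{r}
match_count("MVCSLVGSQ", "FVGSMVGSE")
```

## Alignment engine

All residue-level operations ride on one Gotoh three-state global aligner
(Rcpp): **BLOSUM62, gap open 10, gap extension 0.5**, a gap of length
*L* costing `open + (L − 1) · ext`. Surveys of this kind traditionally rely
on ClustalW-style aligners without reporting parameters; these defaults are
the common protein-alignment workhorse values and are exposed via
`alignment_scoring()`. Ties in the
dynamic program are broken deterministically (match, then gap in the second
sequence, then gap in the first, applied identically in the recursion and
traceback), because co-optimal alignments would otherwise make
reference-anchored signatures nondeterministic. Percent identity divides
identities by alignment columns **excluding terminal-gap columns**, so a
fragment scores 100 % against its full-length parent; coverage is the
fraction of reference residues aligned to query residues. The test suite
checks the optimizer against exhaustive enumeration of all alignments for
short sequences and against an independent aligner (Biostrings) for longer
ones.

The progressive multiple aligner reuses the same machinery: pairwise
p-distances feed an NJ guide tree, profiles are merged in guide-tree order
by profile–profile alignment of expected column scores. It is deliberately
plain — determinism and residue preservation are its contract; it makes no
claim to match ClustalW column for column.

## Distances, trees, bootstrap

`p_distance()` uses pairwise deletion (columns gapped in either row are
skipped); complete deletion is available as a switch since gapped homologs
would otherwise dominate, and neither choice is asserted as "the" published
setting. `dayhoff_distance()` is the Dayhoff (PAM) model correction realized
as the inversion of the model's expected-difference curve: the branch length
*t* at which a Dayhoff Markov chain (exchangeabilities and equilibrium
frequencies as shipped with phangorn, rate-normalized to one substitution
per site) is expected to show the observed proportion of differing sites.
This matrix-based correction — the behavior of distance-matrix phylogeny
packages — is zero at identity, strictly increasing in *p*, and never below
*p*. It is found by `uniroot` on [10⁻⁶, 10] substitutions/site at tolerance
10⁻⁸; an observed *p* beyond the model's saturation range returns `Inf` with
a warning (as a scalar), and is capped at the bracket's upper bound inside
distance matrices, where NJ cannot accept infinities. Per-pair maximum
likelihood (which weighs *which* residues differ, and can legitimately drop
below *p* for conservative exchanges) was rejected because the pipeline's
contract is a composition-independent, monotone correction. A Jukes–Cantor
nucleotide distance is provided for rRNA species trees in place of the
composite-likelihood model, which is out of scope.

`neighbor_joining()` is the standard Q-criterion agglomeration, written
in-package so its determinism is inspectable: ties on Q resolve to the
smallest (row, column) pair in taxon-sorted order, negative branch length
estimates are clamped to zero (count recorded in an attribute), and two taxa
yield a single evenly split edge. On additive matrices it recovers the
generating topology and branch lengths to numerical precision (checked on
200 random trees of 4–8 taxa per run); topologies agree with `ape::nj` as an
independent cross-check. `bootstrap_support()` resamples alignment columns
with replacement, rebuilds the tree per replicate, and scores each internal
bipartition of the reference tree as a percentage; the conventional 1000
replicates is the default, while tests and examples use 100–200, which is
plenty to exercise determinism (same seed, same supports) and the support
scale.

## Synthetic data: what it emulates, and what it cannot show

No genome assemblies ship with the package, so the generator is the test
bed. `make_synthetic_genome()` emulates the *structures* the miner must
detect: contigs of random sequence carrying planted clusters in the layouts
seen in real *MAL* loci — a divergent AGT/AG pair alone, with one activator,
or the four-gene activator-flanked arrangement — with configurable
intergenic gaps, strands, intron counts (GT…AG-bounded, recorded in the
GFF3) and distance from the contig end. Member proteins derive from bundled
role references at a 5 % substitution rate (≈95 % identity, comfortably
above threshold); AG members carry a signature drawn from the reference
table, recorded in the truth file. Decoys are composition-preserving
shuffles of the references, accepted only below 20 % identity to every
reference — hard negatives without accidental homology — and are kept out
of planted cluster spans, since an intervening gene would alter the
divergent-pair truth. Reverse translation uses one fixed codon per amino
acid and never emits CTG, except that under the CTG-clade configuration
serine is written as CTG — so translating with the wrong code demonstrably
corrupts the proteome. All randomness flows from one seed; identical seeds
give byte-identical files.

Because the references themselves cannot be redistributed, the scaffold
standing in for *Sc* IMA1 is **synthetic**: a 589-residue random protein of
realistic composition with the isomaltase signature YVGSLMQDE planted at the
canonical anchor positions (`inst/extdata/ima1_scaffold_synthetic.fasta`,
and likewise the AGT/ACT references). Any real reference FASTA can be
substituted via `signature_profile()` and the `references` argument of
`find_candidates()`.

What passing these suites shows: the scanner's chaining, geometry and
bookkeeping are exact; signature extraction survives 10 % non-anchor
divergence and anchor deletions; the classifier reproduces its reference
table. What they cannot show: behavior on real gene models (fragmented
annotations, pseudogenes, frameshifts), on AGs more remote than the planted
~95 % identity regime, or on genuinely novel signature combinations —
claims about real genomes still require real genomes.

## Problem sizes and numerical choices

The shipped suites use 20 synthetic genomes of 2 × 200 kb with 1–8 clusters
and 50 decoys each, 100 planted-signature proteins, 200 additive matrices,
and 200 bootstrap replicates — sizes chosen so the whole suite runs in a few
minutes on one core while still exercising every code path; all of them
scale up by argument. Alignment scores are doubles throughout; the
brute-force oracle is exhaustive for short sequences and sampled across
every length combination beyond that. Degenerate inputs fail loudly:
empty sequences, unknown residues, gap-only comparisons, non-symmetric or
negative distance matrices, infeasible simulation layouts.

## Known limitations

* The GH31 family is out of scope: the signature applies to GH13
  α-glucosidases only, and no family gate is applied beyond the caller's
  choice of inputs.
* The progressive aligner is a utility MSA, not a ClustalW reimplementation;
  for publication-grade alignments an external MSA can be imported as a
  `tibble(id, aligned)` and fed to `msa_distances()` directly.
* The classifier transfers labels; it does not predict activity levels, and
  `ambiguous` is a real output that callers must handle.
* Cluster calling depends on annotation quality — genes missing from the
  GFF3 are invisible to the scanner.
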