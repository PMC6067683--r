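---
title: "Delimiting cryptic species from genome pairs and multilocus markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic species from genome pairs and multilocus markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placodelim)
```

## The problem

Many microscopic animal groups — placozoans being the extreme case, but
also some nematodes, rotifers, copepods and mites — harbour deeply
diverged genetic lineages with no diagnosable morphological differences.
Classical taxonomy has no characters to work with, so species boundaries
must be established from molecular data alone, and defensibly: a single
gene tree is not evidence of reproductive isolation, and a single distance
threshold is not evidence of rank. `placodelim` implements a multilevel
molecular case for species status, built from four mutually independent
lines of evidence plus the plumbing to test all of them on synthetic data
with planted ground truth:

1. **Genome architecture** — how much of the gene order is conserved
   (microsynteny, collinearity), and how many genes moved or flipped;
2. **Sequence divergence** — protein and CDS p-distances and
   counting-based dN/dS per one-to-one ortholog, with a codon-saturation
   check;
3. **Gene duplication structure** — MCL clusters of the joint proteome
   classified into duplication categories;
4. **Reproductive isolation** — allele sharing across isolates summarised
   as a conspecificity matrix, plus fixed diagnostic nucleotide positions
   and a rank-placement comparison against related phyla.

## Ortholog clustering and duplication categories

The similarity graph is built from an all-vs-all protein search table
(12-column tabular format). Rows with e-value above `1e-3` are dropped;
reciprocal rows collapse to one undirected edge weighted by the maximum
bitscore. Bitscore is preferred over `-log10(evalue)` because e-values
underflow to zero for near-identical proteins and would produce infinite
weights.

`mcl_cluster()` is a dense, canonical Markov clustering: self-loops set to
each node's maximum incident weight (a common MCL convention that damps
oscillation), column normalisation, then alternating expansion (matrix
squaring) and inflation (entrywise power, here defaulting to 2.0, then
renormalisation), pruning entries below `1e-5`, until the largest
entrywise change drops below `1e-8` or 100 iterations pass. Clusters are
weak components of the limiting matrix's support, which guarantees two
structural properties the tests rely on: clusters never straddle connected
components of the input graph, and the result is deterministic and
invariant under node relabelling. Inflation, pruning and convergence are
exposed because reasonable MCL wrappers differ in them; the defaults are
this package's own convention.

Duplication categories are a pure function of the per-cluster species
counts `(a, b)`: `(1,1)` one-to-one; `(1,>1)` one-to-many on the singleton
side and many-to-one on the expanded side; `(>1,>1)` many-to-many;
one-species clusters many-to-zero. A gene left alone in its cluster is
binned *no-hit* only when it had no incident edge at all; a singleton that
had edges (split off by clustering) is treated as many-to-zero, since the
gene demonstrably has homology signal in the graph.

## Codon-aware divergence and dN/dS

CDS are never aligned directly: `backalign_cds()` replaces each residue of
an existing protein alignment with its codon and each protein gap with
`---`, stripping one terminal stop codon when present. A CDS whose length
or translation disagrees with its protein row raises a `regap_error`; such
pairs should be reported and dropped rather than guessed at, because any
repair would silently shift the reading frame.

`codon_pair_stats()` implements unweighted Nei–Gojobori (1986) counting:

* **Potential sites.** For each codon and position, the fraction of
  synonymous changes among the single-base changes that do not create a
  stop codon; summed over positions and averaged across the two rows. This
  keeps the invariant `S + N = 3 × codons compared` exactly.
* **Observed substitutions.** Codons differing at *k* bases are resolved
  over all `k!` substitution orderings; orderings passing through a stop
  codon are excluded, and when every ordering does, all are weighted
  equally. Sd and Nd are the pathway-averaged synonymous and
  nonsynonymous step counts.
* **Codon classes.** Each compared codon pair is also binned as unchanged,
  synonymous (same amino acid, ≥1 base change) or dN1/dN2/dN3 (amino acid
  changed; 1, 2, 3 differing bases). The dN2/dN3 fractions are the
  saturation diagnostic: a rising share of multi-hit nonsynonymous codons
  signals that third positions are approaching saturation.
* Codons containing gaps or ambiguity codes in either row are excluded
  from **all** counts; an internal stop in a compared codon is a hard
  error.

`omega = (Nd/N)/(Sd/S)` is reported as undefined (`NA`) when `Sd = 0`,
not as infinity: sorting and thresholding (`< 0.5` purifying, `> 1`
positive) operate on defined values only, with undefined pairs counted
separately. No multiple-hit (Jukes–Cantor-style) correction is applied
anywhere — all distances in the package are raw p-distances with pairwise
deletion, and the dN/dS counting is kept on the same raw scale.

Two numerical caveats are worth knowing. First, pathway averaging can
assign fractional `Nd > 0` to a codon pair whose rows encode the same
amino acid (e.g. Leu `TTA` vs `CTC`: one ordering is synonymous twice, the
other nonsynonymous twice), so a divergence process that accepted only
synonymous changes can still show a minute nonzero mean dN/dS — about
`4e-4` under the test conditions below. Second, the per-pair ratio
`pN/pS` is noisy in its denominator at realistic event counts, so the
*mean of per-pair* omega estimates sits slightly above the generating
value (a standard ratio-estimator bias; about +0.05 at omega 0.5 with 60
events per 300-codon pair). Pooling counts across pairs before taking the
ratio removes the bias; both behaviours are exercised in the tests.

## Microsynteny and rearrangement classes

`reciprocal_best_hits()` reduces two directed best-hit lists to strict
mutual best pairs, ranking by bitscore, then lower e-value, then subject
id. (Pipelines around MCScanX often feed best-5 hit lists instead; strict
best-1 is chosen here because it is deterministic and sufficient for a
one-to-one map. The difference is deliberate and documented.)

`detect_syntenic_blocks()` chains ortholog pairs that are consecutive in
genome A and monotonically increasing (`same`) or decreasing (`inverted`)
in genome B, allowing at most `max_skip` intervening genes on either
genome between consecutive pairs (default 1, matching the one-gene skip
rule commonly used for microsynteny). Chains shorter than
`min_block_size` (default 3) are discarded. Each pair joins at most one
block: blocks are extracted greedily — longest chain first, ties broken by
leftmost A position, then `same` before `inverted`, then the
lexicographically smallest A-position sequence — so output is fully
deterministic. The test suite proves the extraction equal to an
exhaustive chain-enumeration oracle on hundreds of random ≤12-gene
instances. One honest caveat: reversal duality (flipping genome B flips
every orientation) and skip monotonicity hold for the *set* of valid
chains and for realistic inputs, but adversarial ties between overlapping
equal-length chains of opposite orientation can break them at the
block-assignment level; the tests state the properties at the level where
they are true.

Per-gene labels follow from blocks: for each A-contig the B-contig
carrying most of its block genes is its *dominant partner*, and within
that pairing the majority orientation is dominant. Genes in
dominant-orientation blocks are `collinear`; opposite-orientation blocks
`inverted`; mapped genes outside blocks or on a non-dominant partner
`translocated`; unmapped genes `unplaced`. "Translocated relative to the
dominant partner" is this package's formalisation — figure legends in the
comparative-genomics literature describe translocation relative to the
matching scaffold without giving an algorithm.

`collinearity_summary()` weights per-contig collinear fractions by each
contig's *evaluated span* (base pairs from first to last mapped gene).
Assembly length would over-weight contigs whose ends carry no orthologs;
the evaluated span is the region the analysis actually saw.

## Haplowebs and the conspecificity matrix

For one marker, the haploweb's nodes are distinct allele sequences (exact
string identity after upper-casing and de-gapping — alleles phased from
chromatograms are short and accurate enough that mismatch tolerance would
only blur pools; a `k`-mismatch collapse could be added but defaults to
exact). Each heterozygous isolate contributes one edge joining its two
alleles. Connected components are *fields for recombination* (FFRs):
isolates whose alleles fall in one FFR are connected by actual or
potential gene flow at that marker.

The conspecificity matrix scores each isolate pair as the number of
markers supporting conspecificity (both have data, same FFR) minus the
number opposing it (both have data, different FFRs). A marker missing in
either isolate contributes 0 — the pair is simply evaluated over fewer
markers, and the per-pair evaluated count is reported alongside. The
diagonal holds each isolate's sequenced-marker count. With three markers
and no missing data every score lies in `{-3, …, +3}`, and the package's
planted-truth tests require exactly `+3` within species and `-3` between.

For display ordering, `upgma_order()` builds per-isolate consensi (IUPAC
ambiguity codes at heterozygous sites — a majority-base consensus would
hide exactly the heterozygosity the method relies on), concatenates
markers, removes every column containing a gap, computes JC69 distances
`d = -(3/4)·log(1 - 4p/3)` where a site mismatches only if the two IUPAC
state sets are disjoint, and runs average-linkage UPGMA with a
deterministic tie rule (the pair whose lexicographically smallest member
label sorts first). `p >= 0.75` is outside the JC69 domain and raises an
error naming the pair.

## Diagnostic sites and rank placement

`find_diagnostic_sites()` screens columns of a grouped alignment inside a
region-of-interest intersected with a user-supplied column mask (for rRNA,
typically the stem regions — the package does not infer secondary
structure; the mask is an input). In strict mode a column is diagnostic
when all focal sequences share one unambiguous non-gap state, no other
sequence carries that state, and the whole column is free of gaps and
ambiguities. Relaxed mode tolerates gaps/ambiguities in the non-focal
pool, which matters when the comparison pool lumps several heterogeneous
clades; the focal requirement never relaxes. Published diagnosis tables
print single fixed states per taxon, which is what strict mode certifies.

`rank_distance_profile()` computes between-group mean p-distances
(pairwise deletion) for every child pair under each parent taxon — orders
within classes, families within orders, genera within families — and
aggregates grand mean ± SD per rank. `place_candidate_pair()` then scores
a candidate species pair's distance against each rank as a z-score and
suggests the rank with the smallest |z|, ties resolved toward the lower
rank (the more conservative, finer split). This is a deliberate
formalisation of the usual qualitative comparison ("the distance is
comparable to genera within families"); ranks with zero SD fall back to
absolute differences and are flagged.

## The synthetic-data generators

The generators produce data with the statistical structure the analyses
assume and a complete record of the planted truth. They are conventions,
not fitted models — the real study system provides no generative model —
and they deliberately omit indel evolution, intron structure and
recombination within markers. Consequences: passing tests certify the
algorithms and their contracts, not the behaviour of any particular
genome.

* **Genome pairs** (`simulate_genome_pair()`): genome B's CDS evolve from
  genome A's under a propose-and-filter codon process (default 0.2
  proposals per codon at omega 0.3, giving roughly 10–15% CDS divergence
  — a deep but unsaturated split); events are applied in the fixed order
  inversions → translocations → duplications → losses. Event windows span
  4–6 genes for inversions and 3–5 for translocations, with 3-gene
  buffers between events and contig ends, so at the default synteny
  settings every planted label is exactly recoverable. (A 3-gene
  inversion is avoided on purpose: its middle gene keeps its position and
  a same-orientation chain can absorb it through the 1-gene skip.)
  Translocations move windows to a different contig because the
  rearrangement classifier defines translocation against the dominant
  contig pairing. Duplicated copies mutate at 0.02/site so similarity
  ranks self > paralog > ortholog, and the emitted within-family
  similarity table drives clustering and RBH without an external search
  tool.
* **Codon pairs** (`simulate_codon_orthologs()`): defaults of 200 pairs ×
  300 codons × 60 proposals; stop-creating proposals are rejected without
  redrawing so that event counts remain interpretable; accepted
  synonymous/nonsynonymous counts are logged per pair as the recovery
  oracle.
* **Allele datasets** (`simulate_allele_dataset()`): per species and
  marker, alleles form a mutation chain in which each heterozygous
  isolate bridges the current and the next allele, so the species pool is
  one connected haploweb component by construction while species pools
  stay disjoint; missingness is independent per cell.
* **Diagnostic alignments** (`simulate_diagnostic_alignment()`): one
  backbone sequence, `n_diagnostic` fully diagnostic columns planted
  inside region ∩ mask, and noise that is resampled whenever a draw would
  fix a new group-distinguishing state inside the guarded window — so the
  planted sites are provably the only diagnostics there.

All generators derive independent RNG streams from one user seed by fixed
offsets, so outputs are byte-identical across runs and adding a generator
never perturbs the others.

## Problem sizes and numerical conventions

The test suite runs entirely on synthetic data at desk scale: 1,000
random codon pairs against a full pathway-enumeration oracle; 200 random
≤12-gene synteny instances against exhaustive chain enumeration across
`max_skip` 0–2; 200 pairs × 300 codons per omega level for parameter
recovery; 80-gene two-contig genomes for rearrangement recovery; 2–4
species × 3 isolates × 3 markers for conspecificity; 2,551-column
alignments for the 4- and 14-site diagnostic screens; 100 random graphs
for clustering sanity; 20 ultrametric quartets for UPGMA. These sizes
were chosen so the full suite completes in about a minute while every
oracle remains exhaustive.

Conventions collected in one place: coordinates are 1-based inclusive
(GFF3 sense) and never shifted internally; gene order sorts by
`(start, gene_id)`; features without strand are errors, not assumed `+`;
the gap character is `-` with `.` normalised on read; VCF consumption is
restricted to `CHROM/POS/REF/ALT/QUAL` with non-PASS rows dropped when a
FILTER value is present; heterozygosity is SNP density (count-based), not
genotype-frequency heterozygosity; and SNPs exactly on exon boundaries
are exonic (inclusive intervals).

## Known limitations

* MCL wrapper options used by published pipelines are not always
  documented; the inflation/pruning/convergence defaults here are
  explicit package conventions, exposed as arguments.
* The dN/dS counting is counting-based, not maximum likelihood; it is the
  right companion to raw p-distances but not a substitute for codeml-style
  estimates when branch lengths or codon frequencies matter.
* Rearrangement labels depend on the dominant-partner heuristic; genomes
  whose contigs split their orthologs evenly across two partners have no
  well-defined dominant pairing and will classify conservatively toward
  `translocated`.
* The allele-identity rule is exact string match; datasets with
  sequencing error in phased alleles need the mismatch-tolerant collapse
  before trusting FFRs.
* Stem-region masks for rRNA diagnostics must be supplied by the user.
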