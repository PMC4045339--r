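---
title: "Deconvolving metagenomes with proximity-ligation read pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving metagenomes with proximity-ligation read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the signal

Shotgun metagenomics lyses a whole community at once, so the assembly
yields contigs whose cell of origin is lost. Hi-C (proximity ligation)
restores part of that information: DNA is cross-linked *inside intact
cells*, digested with a restriction enzyme (a 6-cutter such as HindIII),
and free ends are ligated under dilute conditions so that ligation
products overwhelmingly join two loci that were physically co-located —
in the same cell — at the time of cross-linking. Sequenced as read
pairs, these products link loci megabases apart on one chromosome, and
loci on *different replicons of one cell*, e.g. a plasmid and its host
chromosome. Counting such pairs over assembly contigs gives an
association signal dominated by cell co-residence, which this package
turns into genome bins.

hicdecon implements the full analysis chain:

1. **links** — ingest read pairs (SAM/BAM or a plain TSV) and apply
   mapping-quality, alignment-completeness and insert filters.
2. **assoc** — build the contig×contig association matrix, filter it,
   and normalize for contig length.
3. **mcl** — cluster the normalized graph with Markov Clustering.
4. **evaluation** — score cluster solutions against ground-truth labels
   with a size-weighted sampled-pair statistic.
5. **contact_map** — binned contact maps with log and Spearman-rank
   transforms.
6. **variant_graph** — SNP graphs quantifying how much strain-level
   (haplotype) signal a library design carries.
7. **community_sim** — a synthetic community generator providing ground
   truth for all of the above.

## Association matrix and normalization

Let $c_{ij}$ be the number of read pairs with one end in contig $i$ and
the other in contig $j$, and $l_i$ the contig lengths with $L$ the set
of lengths. Long contigs accumulate more pairs purely by target size,
so raw counts are normalized as

$$ c'_{ij} = \frac{\max(L)^2 \, c_{ij}}{l_i\, l_j}. $$

Two pre-normalization filters control noise: a **contig size minimum**
(default 5 kb — a 6-cutter cuts on average every $4^6 = 4096$ bp, and
`intersite_gap_fraction()` shows that more than 25% of a 4 Mb genome is
expected to lie in inter-site gaps over 10 kb, so short contigs often
carry no restriction site and link poorly), and a **contact minimum**
$k$ (default 5: edges supported by 5 or fewer pairs are dropped —
strictly-greater-than semantics). `max(L)` is taken over the post-filter
contigs so the normalization is well defined on the clustered graph;
$c'$ is invariant to rescaling all lengths by a common factor, which the
tests assert.

## Markov Clustering

`mcl_cluster()` is a from-scratch sparse MCL: add self-loops (each
column's maximum edge weight, standard practice to damp oscillation),
column-normalize to a stochastic flow matrix, then iterate *expansion*
(matrix power, default 2), *inflation* (elementwise power $r$ followed
by column re-normalization) and *pruning* (entries below $10^{-5}$
dropped, columns re-normalized) until the iterate changes by less than
$10^{-6}$ (cap 200 iterations; non-convergence returns a flagged
best-effort solution). Clusters are read off as the weakly connected
attractor systems of the converged flow. Inflation is the granularity
knob: low values near 1 give few, coarse clusters; the default 2 gives
many fine ones. Inflation values at or below 1 are rejected — identity
inflation never contracts the flow to attractors, so a sweep "spanning
[1, 2]" must start strictly above 1. Contigs that drop out of the
clustered graph are appended as singleton clusters by
`complete_solution()`.

## Evaluating a clustering

`sample_pair_quality()` draws `n_pairs` (default $10^5$) random contig
pairs, each contig sampled with probability proportional to its length
(a pair of two identical draws is redrawn *as a pair*, keeping the
joint law proportional to $p_i p_j$ over distinct pairs — the
exhaustive-enumeration oracle in the tests checks exactly this). A
same-label pair in one cluster is a TP, split across clusters an FN; a
different-label pair in one cluster is an FP, otherwise a TN, and
TPR/FPR/PPV/NPV follow the standard formulae. Scoring runs at two
levels: **species** (the near-identical strain pair counts as one
class) and **strain** (strains distinct; co-assembled shared contigs,
which have no single strain of origin, form their own class). The
sampling universe is the post-size-filter contig set — the clustering
run's input — so the statistic measures what the run could in principle
get right.

`assign_labels_by_substring_vote()` reproduces the reference-based
labeling route: every 70 bp substring of a contig is matched against
the labeled references (both strands) and the contig takes the
plurality label. A substring hitting references of more than one
species is ambiguous and casts no species vote, mirroring a
mapping-quality cutoff; with a strain pair at 99.5% identity most
substrings are strain-ambiguous while substrings overlapping SNPs vote
a strain. In synthetic runs, simulator ground truth (`truth_labels()`)
is the primary label source and the voting route is cross-checked
against it.

## The synthetic community

`default_community_spec()` mirrors the structural cases the method must
resolve: a cell with a chromosome and two plasmids (Lac0/Lac1/Lac2), a
two-chromosome cell (Bur1/Bur2), a plain single-chromosome cell (Ped),
and two *E. coli*-like strain cells (K12, BL21) generated from one
ancestor with i.i.d. per-base substitutions at rate 0.005 (99.5%
identity), the planted positions returned as SNP ground truth.
Chromosomes are scaled to roughly a tenth of the source organisms
(0.18–0.46 Mb) so a full pipeline run takes seconds; plasmids keep
realistic sizes (13.4 kb, 35.6 kb) and all replicons keep realistic GC.

The Hi-C simulator (`simulate_hic_pairs()`) encodes the assumptions the
method rests on, each exposed as a parameter:

| parameter | default | meaning |
|---|---|---|
| `noise_rate` | 0 (pipeline: 0.01) | probability a pair joins two different cells (spurious inter-cell ligation) |
| `frac_fragment` | 0.97 | fraction of pairs that are uninformative local fragments (insert < 1 kb) |
| `insert_short_mean/sd` | 300/100 bp | Normal law of the fragment class |
| `insert_long_min` | 1000 bp | long-range inserts are log-uniform on [1 kb, L/2]: a heavy-tailed, 1/d-decaying law over the circular chromosome |
| `p_cross_replicon` | 0.2 | within-cell pairs joining two replicons of a multi-replicon cell |
| `site_anchoring` / `site_jitter` | 0.9 / 500 bp | pair anchor ends placed near restriction sites |
| `read_length` | 160 bp | read length |

Contig sets come from `fragment_to_contigs()`: tile lengths are
`min + Exp(mean − min)` laid end to end (a renewal process, so the
contig count concentrates at `L/mean`), partitioning each replicon
exactly; a liftover table re-expresses any replicon coordinate as
(contig, offset). For the strain pair, which is colinear by
construction, an assembler's collapse of near-identical regions is
emulated stochastically: each tile becomes a single *shared* contig
(receiving links from both strain cells) with probability
`coassembly_prob` (default 0.5), otherwise two strain-specific contigs.
A strict "emit one contig where the strains are identical" rule would
never fire at 0.5% divergence — a 5 kb interval is SNP-free with
probability $0.995^{5000} \approx 10^{-11}$ — while real assemblies of
such strain pairs demonstrably do contain co-assembled contigs, so the
collapse is modeled as a rate rather than by exact identity. These
shared contigs are what lets cluster solutions merge the strain pair,
exactly as observed with real co-assemblies.

What the simulator deliberately does **not** model: GC and mappability
bias, chimeric reads, base-calling error, restriction-fragment-length
bias, and uneven DNA extraction across cell-wall types. Passing tests
therefore demonstrate the correctness and statistical behavior of the
*analysis*, not robustness to every artifact of real libraries.

## Variant graphs and library design

For strain resolution, SNP sites become nodes and a read pair whose two
ends cover two sites adds an edge (all cross combinations when an end
covers several sites). `sample_shortest_paths()` samples node pairs
uniformly and measures BFS path lengths; unreachable pairs are recorded
and excluded from the mean/max, with the same-component fraction
reported separately. `bin_paths_by_distance()` averages path lengths in
20 kb separation bins (with a LOWESS curve for display; on circular
scaffolds separation is the minimum-path distance, since linear
coordinate differences fold the curve symmetrically about L/2 and mask
the trend). `compare_library_designs()` runs the whole chain per
library design at a fixed read count: mate-pair libraries can only hop
`insert` bp at a time, so their path lengths grow with genomic
distance, while Hi-C inserts span the chromosome and their variant
graphs stay shallow and flat — the property that makes proximity
ligation attractive for strain/haplotype phasing.

## Numerical and convention choices

- Coordinates are 0-based half-open throughout; link positions are
  leftmost aligned bases; "insert size" is the minimum-path (circular)
  distance between leftmost coordinates.
- The fragment/Hi-C boundary reads "within 1,000 nt" as `< 1000`:
  a pair at exactly 1,000 bp is Hi-C. Configurable.
- Intra-replicon pairs closer than the insert minimum are filtered;
  pairs joining two replicons are never insert-filtered.
- Edge filtering is strictly-greater-than the contact minimum.
- Spearman map entries with a constant row or column are `NA`, never 0
  (0 would fake anticorrelation); ranks use average-rank ties.
- Contact-map bins are left-closed, the last bin absorbs remainders and
  intra-replicon maps count each pair once on the unordered bin pair.
- Degenerate inputs: empty link sets give zero matrices/empty graphs;
  an all-fragment library gives an empty insert histogram with a
  warning; MCL rejects asymmetric or negative input.
- `run_pipeline()` derives one seed per stage from the global seed, so
  stages are independently reproducible and identical configs give
  byte-identical artifacts.

## Problem sizes

The shipped configuration (`default_pipeline_config()`) runs the
five-cell community with ~340 contigs (6 kb mean), $10^5$ informative
Hi-C pairs at 1% inter-cell noise, filters (5 kb, k = 5) and inflation
1.1; it completes in well under a minute on one CPU and recovers the
four species groups with species-level PPV and TPR at 1.0 within
sampling error, the strain pair merged. Design comparisons use 30,000
read pairs per library and 10,000 sampled SNP pairs. All sizes are
configuration values and scale up directly.

## Known limitations

- The simulator's noise is uniform across cell pairs; real inter-cell
  noise may correlate with abundance and extraction chemistry.
- `transform_spearman()` is restricted to square maps; inter-replicon
  maps with different axis bin widths are rendered raw or log-scaled.
- The substring-vote labeler uses exact matching; it is intended for
  synthetic (error-free) contigs and cross-checks, not for labeling
  error-containing real assemblies.
- MCL granularity interacts with coverage: at very high per-pair
  coverage the default contact minimum may under-filter (see the
  parameter sweep in the tests), and the contact minimum should be
  scaled with depth.
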