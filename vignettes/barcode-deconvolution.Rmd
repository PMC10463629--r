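---
title: "Graph-based barcode deconvolution for synthetic long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based barcode deconvolution for synthetic long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readclouds)
library(dplyr)
```

## The problem

Synthetic long-read (SLR) technologies tag short reads with a 3'
unique molecular identifier (UMI) shared by all reads derived from the
same long DNA fragment.  The set of reads carrying one UMI is a *read
cloud*.  In practice a UMI is attached to several fragments at once —
typically 2–20 — so a read cloud mixes reads from multiple genomic
loci, and in a metagenome usually from multiple species.  Each
fragment is also only fractionally covered by its reads (roughly
10–20% of its bases), so the linkage signal is sparse.  *Barcode
deconvolution* is the problem of splitting each cloud into
single-fragment subgroups, called *enhanced read clouds*.

With `S` equally abundant species and a mean of `m` fragments per UMI,
the probability that a cloud mixes species is at least
`1 - (1/S)^(m - 1)` (`mixed_cloud_probability()`): deconvolution is
the rule, not the exception.

## The algorithm

The deconvolver works on a condensed de Bruijn assembly graph built
from the reads themselves (or ingested as GFA1 from an external
assembler):

1. **Graph and mapping paths.**  All k-mers of the input (plus reverse
   complements; `N` breaks k-mer extraction rather than being
   substituted) form a doubled de Bruijn graph whose maximal
   non-branching paths are condensed into unitig edges.  Each read is
   anchored by exact k-mer lookup, giving its mapping path — the
   ordered distinct unitigs it touches — and the junction vertices
   bordering them.
2. **Bounded Dijkstra neighborhoods.**  For each read in a cloud, a
   forward Dijkstra search is run from the read's 3'-terminal vertex
   and a reverse search into its 5'-terminal vertex, both bounded by
   the search distance `d`.  Edge weights are *novel lengths*
   (sequence length minus the k−1 overlap), so `d` is measured in
   genomic bases.  A cloud-mate whose vertex sequence — or its
   conjugate — intersects either neighborhood is *connected* to the
   read.
3. **Enhanced clouds.**  Connected read-sets that share at least one
   read are merged; equivalently, the enhanced clouds are the
   connected components of the symmetrized connection relation,
   extracted with a union–find.  Mates of a pair are always unioned
   first: a read pair is physically one molecule.  Components of two
   or fewer reads and unmapped reads go to a separate *disconnected*
   set; clouds at or below the size cutoff pass through intact.

Two design points deserve emphasis because the underlying procedure
can be anchored in more than one way:

* **Vertex anchoring.**  Distances are measured from the terminal
  *vertices* of a read's path, not from the read's base offset within
  an edge.  Consequently reads on the same unitig always connect,
  whatever their separation — the graph cannot resolve loci that
  assembly did not separate.  This matches the search's purpose
  (fragments are subgraphs around a read) and keeps the search
  exact.
* **Symmetrization.**  Per-read connected sets need not be symmetric
  (neighborhoods are direction-dependent); taking connected
  components of the symmetric closure makes the output independent of
  read order and thread count.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 31 | bp | single fixed k; large enough that random 31-mer collisions are negligible at desk scale, small enough that 150 bp reads carry ~120 anchors |
| `d` (search distance) | 5000 | bp | a conservative fraction of the expected 40 kbp fragment length; larger `d` risks under-deconvolution and costs time |
| `size_cutoff` | 6 | reads | clouds of ≤ 6 reads pass through intact; splitting trivially small clouds creates noise |
| `max_frag` / region size | 200000 | bp | the maximum span of a gold fragment and of a purity "region"; halving/doubling it is a supported sensitivity analysis |

## Gold standard and metrics

`reference_deconvolve()` groups each cloud's aligned reads per
reference by a greedy left-to-right sweep over start positions,
opening a new group when a read starts more than `max_frag` beyond
the current group's minimum.  The sweep is the minimal such grouping
for sorted positions and is deterministic; the published description
fixes only the span constraint, so the greedy sweep is this package's
explicit choice.  Mates are grouped by their own starts and then
unioned.  On simulator output the truth table substitutes for
alignment (`truth_alignments()`).

Cloud quality uses the composition over categories (reference,
200 kbp region), with regions computed by the same sweep so that
"region" means the same thing in the metrics and the gold standard:

* purity `P = max(p)`;
* Shannon entropy `H = -sum(p * ln p)` (natural log; the quantity is
  reported as a positive number and is zero exactly for single-origin
  clouds — output headers state the log base since printed formulas
  in the literature vary in sign and base);
* class against the gold partition: *under* (spans ≥ 2 gold
  fragments), *complete* (equals one), *over* (proper subset of one).

Summaries exclude clouds of size ≤ 2, which are trivially pure.
`fragments_per_umi()` divides the mean non-deconvolved cloud size by
the mean reference-deconvolved size.

## Taxonomic promotion

Reads of one (enhanced) cloud should share a fragment and hence a
taxon.  `promote_cloud()` finds the deepest rank at which one taxon
is carried by a strict majority of the cloud's *classified* reads
(unclassified reads are excluded from the denominator; the root is
never a consensus target), then relabels every classified read that
sits strictly above that rank *and* whose lineage is an ancestor
prefix of the consensus.  Conflicting lineages are left alone:
relabeling contradictory evidence is avoided.  Promotion counts are
per read, never per pair.  The procedure is idempotent, and
`promotion_matrix()` tabulates events by (from rank, to rank).

```{r seven}
cl <- as_classifications(tibble::tibble(
  read_id = paste0("read", 1:7), cloud_id = "c1",
  lineage = c("k_0;p_0;c_0;o_0;f_0;g_0;s_0",
              "k_0;p_0;c_0;o_0;f_0;g_0;s_0",
              "k_0;p_0;c_0;o_0;f_0;g_0;s_1",
              "k_0;p_0;c_0;o_0;f_0;g_1",
              "k_0;p_0;c_0;o_0;f_0",
              "k_0;p_0;c_0;o_0",
              "k_0")))
promote_cloud(cl)$events
```

## The simulator and what it does (not) emulate

`sim_library()` draws, per UMI, a fragment count (default 2–20),
then per fragment a uniform genome, start, and length (default
uniform 5–100 kbp, clipped to the genome), and finally samples
read-pair positions until the union of their 300 bp inserts covers
the target fraction (default 15%) of the fragment.  Sampling until
coverage — rather than a Poisson read count — makes the per-fragment
pair count predictable (about `ln(1-c)/ln(1-insert/len)` pairs) and
mirrors the "fractionally covered" character of real SLR fragments.
Errors are substitution-only at 0.1% by default, which keeps k-mer
anchoring analyzable; genomes are i.i.d. uniform DNA and
equal-abundance unless weights are given.

What passing tests on this generator shows — and what it does not:
random genomes have no repeats, no conserved genes, no GC structure,
and no chemistry-specific UMI biases, so simulated fragments from
different genomes essentially never overlap on the graph.  Results
here demonstrate algorithmic correctness (exact search, exact
partitioning, correct bookkeeping), not the repeat-robustness of
deconvolution on real communities.

Desk-scale defaults are 5 genomes × 200 kbp and 2000 UMIs (~350k
reads, ~47× depth); the property suite runs the full pipeline at that
size in a few minutes on one CPU, and unit tests use 60 kbp genomes
with tens of clouds.  Real SLR datasets with 10^6–10^7 UMIs are out
of desk scope by design.

## Numerical choices and degenerate inputs

* Dijkstra ties are broken by vertex id; distances are exact, so the
  result is tie-break independent.  The search never expands a vertex
  beyond `d`.
* Edge and vertex ids are assigned by lexicographic order of unitig
  sequence, making graph construction deterministic for a fixed
  input.
* Ambiguous k-mers (present in several unitigs, i.e. repeats) anchor
  to the lexicographically smallest unitig.
* Self-conjugate (palindromic) unitigs and vertices are their own
  conjugates.  At k = 3 a doubled graph shares junction vertices
  between strands whenever a palindromic 2-mer occurs; this is
  inherent to the representation and harmless at practical k.
* Empty inputs, all-`N` reads, unknown vertices, unsorted sweep
  input, and empty compositions raise explicit errors; an unmappable
  read is a *value* (routed to the disconnected set), not an error.
* Subgroups are numbered by their smallest member read id, and GFA
  output orders canonical segments by id, so all artifacts are
  byte-stable across runs, thread counts and input orderings.

## Limitations

* Vertex anchoring cannot split same-unitig loci (see above); on a
  finished assembly of a small genome, deconvolution degenerates to
  per-component grouping.
* Exact k-mer anchoring tolerates errors only through redundancy: a
  read whose every k-mer is corrupted goes to the disconnected set.
  At 0.1% substitutions and k = 31 about 86% of 150 bp reads retain
  all anchors and virtually all retain some.
* The mapper does not perform gapped or mismatch-tolerant alignment,
  and no graph simplification (tip clipping, bulge removal) is done;
  graphs from high-error reads should be assembled and simplified
  externally, then ingested as GFA.
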