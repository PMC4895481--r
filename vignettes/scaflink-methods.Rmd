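---
title: "Homology-evidence scaffolding and map consensus: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-evidence scaffolding and map consensus: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaflink)
```

# The model

`scaflink` treats a genome as a set of *signed gene orders*: for every
sequence, the ordered list of gene-family symbols, each carrying an
orientation sign from the gene's strand. Gene families — the homology
alphabet — are an input (a two-column table), not something the package
infers; whatever orthology pipeline produced them is upstream of this
analysis.

In the breakpoint-graph formalism, a signed occurrence `+g` exposes its
*tail* on the left and its *head* on the right (and `−g` the reverse),
and an *adjacency* is the unordered pair of extremities of two adjacent
genes. The central assumption is that an adjacency observed in several
related genomes is likely ancestral, and therefore likely present in the
target genome too; when the two extremities of such an adjacency sit at
the exposed ends of two different target scaffolds, it is evidence that
those scaffold ends were adjacent before the assembly fragmented them.

Three deviations from a naive conserved-adjacency count make the method
usable on real annotations:

* **Insertion/deletion tolerance.** Each reference order is projected
  onto the target's family content (`restrict_to_shared()`): occurrences
  of families the target lacks are removed before adjacencies are read
  off, so a lineage-specific gene inserted between two conserved genes
  does not hide their adjacency.
* **Duplication damping.** Within each reference genome, any family with
  more than `max_copy` occurrences (default 10) is removed entirely from
  that genome's projection. Low-copy paralogs remain usable evidence;
  repeat-like families, which would generate quadratically many spurious
  endpoint matches, are suppressed. The cap is per reference genome;
  target-side multi-copy families are retained, because the ambiguity
  they create is resolved globally by the matching step.
* **Phylogenetic weighting.** Each genome's vote is `1/d` with `d` its
  patristic distance to the target (`genome_weights()`); a conserved
  adjacency in a close relative outweighs one in a distant outgroup.
  When any branch length is missing the tree is treated as topology-only
  and all weights are 1, so the method still runs on a bare topology.

## Candidate scoring and selection

`candidate_links()` scores every pair of extremities of *distinct*
scaffolds (a join between the two ends of the same scaffold would
circularise it; chromosomes are linear, so such pairs are excluded).
With the default terminal window `k = 1` only the outermost gene of each
scaffold end provides evidence. Setting `k > 1` lets the `o`-th gene
from the terminus contribute with multiplicative decay `delta^o`
(default `delta = 0.5`), an opt-in robustness knob for annotations where
terminal genes are unreliable; a genome still supports a given candidate
at most once, with its best-decay occurrence pair.

Each extremity can participate in at most one true join, so accepted
links must form a matching on extremities. `select_links()` first
applies the multi-witness rule — at least `min_genomes = 2` supporting
genomes, since a single genome's adjacency may be a lineage-specific
rearrangement rather than ancestral state — then computes an exact
maximum-total-weight matching by branch-and-bound within each connected
component of the conflict graph. Components are small in practice (an
endpoint matches few extremities), so exact search is cheap; ties
between equal-weight matchings are broken toward the lexicographically
smallest sorted edge list, making the output deterministic. Greedy
selection was rejected because it has no optimality guarantee and cannot
be validated against enumeration.

`build_chains()` turns the matching into oriented chains. Scaffold
degree is at most two, so components are paths or simple cycles; each
cycle is broken at its lowest-weight link (least-supported join, least
trusted). Orientation propagates from the link sides: a `+` scaffold
exits right through its 3' end, so a link arriving at a 5' end keeps the
next scaffold `+` and a link arriving at a 3' end flips it. A chain's
canonical form is the lexicographically smaller of itself and its
reverse complement — chains have no intrinsic left-to-right direction,
and canonicalisation makes artifacts byte-reproducible.

## Map integration

Chains are anchored to linkage groups by marker majority
(`anchor_chains()`): a chain goes to the group holding at least 2/3 of
the markers found on its member scaffolds across both maps. The 2/3
threshold tolerates one stray marker in a tally of three while refusing
50/50 conflicts; chains failing it are reported as `ambiguous` rather
than force-placed, and marker-less chains as `no_markers`.

`build_constraint_graph()` works at chain granularity: the joins are the
method's own evidence and a weak map edge should not be able to
contradict them by ordering two members of one chain. Within each map
and group, placed chains are ranked by the mean cM of their markers, and
edges connect consecutive distinct ranks only — the transitive closure
is the same as all-pairs edges, but the graph is smaller and each
removal during cycle resolution has a single, interpretable provenance
(map, weaker endpoint's marker count, cM gap). Equal means yield no
edge: the maps provide no order information there. The edge model also
carries a `chain_internal` type that cycle resolution must never remove
(and an all-internal cycle is an error, since it would mean the chains
themselves are inconsistent); with chain-granularity nodes such edges
cannot arise from map evidence, but the invariant is enforced so any
future scaffold-level graph reuses the same resolution contract.

`resolve_cycles()` removes, from some deterministically found cycle, the
edge with the lowest marker support, then the smallest cM gap, then
lexicographically smallest endpoints — discarding the least-attested map
claim first. `topological_consensus()` is a Kahn sort whose tie-break
among simultaneously available chains is the mean cM over both maps
(marker-less chains rank last), then chain id. Output positions are
ordinals only: once scaffolds from two different maps interleave, no
consistent centimorgan coordinate exists for them, so none is invented.

# The simulator

The simulator is the package's test bed, emulating the real inputs the
pipeline is designed for: a target genome inside a seven-taxon fish
phylogeny with six reference genomes, a fragmented assembly, and male
and female linkage maps that only partially overlap.

The root genome has `n_families` single-copy signed families spread over
`n_chrom` chromosomes (defaults 1,000 and 19, matching the scale of a
teleost draft-genome project at the gene-family resolution this method
sees). Along each branch, event counts are Poisson with mean
`rate x branch length`; events are inversions (reverse + flip signs),
translocations (move an interval between chromosomes), fusions,
fissions, deletions, insertions of novel families, and tandem
duplications, each acting on an interval of at most `max_span` genes
(default 5). Impossible draws (e.g. fission of a one-gene chromosome)
are retried a bounded number of times, then skipped with a log entry, so
the event log exactly accounts for every applied change — which the
tests exploit as a conservation oracle (leaf gene count = root
+ insertions + duplicated spans − deleted spans).

The default tree keeps the seven-taxon topology but sets **every branch
length to 1**, so a rate is directly the expected number of events per
branch; the moderate-noise regime used for calibration (5 inversions, 1
translocation, 1 deletion, 1 insertion, 0.5 duplications expected per
branch) is then stated in the same units. Inverse-distance weighting
stays meaningful (distance = edge count).

Fragmentation cuts each target chromosome at Poisson(`breaks_per_chrom`,
default 7) inter-gene positions — with 19 chromosomes this gives the
~150-scaffold instances used in the recovery tests — and records every
broken adjacency, orientation-aware, as ground truth. Maps place
`markers_per_scaffold` markers per scaffold at `ordinal x spacing_cM`
with Gaussian noise truncated at zero (the simplest defensible noise
model; parameters exposed), drop each marker independently with
probability `dropout` per map (default 0.25, giving partially
overlapping male/female maps), and optionally swap adjacent ordinals
with probability `swap_prob` to emulate local map errors.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: sequence-level artifacts (chimeric
scaffolds, misassemblies within a scaffold), annotation errors
(wrong gene models, family misassignment), dispersed duplications
(duplications are tandem only, sufficient to exercise the copy cap and
multi-copy matching), marker genotyping error beyond positional noise,
and non-uniform gene spacing. Real-data precision will be bounded by the
quality of the family table above all else.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; GFF3 and AGP stay 1-based
  inclusive on disk. All conversions happen at the I/O boundary.
* N50/N90 use the "first cumulative sum ≥ fraction × total" convention
  on descending lengths, ties inclusive — the standard reading
  consistent with both informal prose definitions of N50 and N90; an
  empty length set is an error, not NA.
* Matching weights are sums of `1/d` terms; the branch-and-bound
  compares exact floating sums and applies the lexicographic tie rule
  only at exact equality. The enumeration oracle in the test suite uses
  weights that are exact binary fractions so tie cases are reproducible.
* Empty inputs flow through: empty GFF3 yields an empty gene table,
  an all-empty gene order filters to nothing, zero candidates yield
  singleton chains only, and an empty constraint graph yields an empty
  consensus.
* `evaluate_links()` reports precision as `NA` (not 0) when nothing was
  inferred, and recall `NA` when the truth set is empty.

# Problem sizes used in the checks

The recovery checks run at 1,000 families / 19 chromosomes / ~150
scaffolds / 6 references (the perfect-conservation limit) and at 400
families / 10 chromosomes / ~60 scaffolds over 20 seeds (the
moderate-noise regime); the matching oracle uses 200 random instances of
up to 12 extremities, and the Nx oracle 500 random multisets. These
sizes were chosen as the smallest instances that still exercise every
code path at realistic density; results at them are stated in the test
suite and recomputed by `scripts/acceptance.R`, and nothing beyond what
those runs compute is claimed here.

# Known limitations

* Link inference cannot recover a join whose flanking genes were lost,
  duplicated beyond recognition, or rearranged away in every reference;
  recall is bounded by terminal-evidence survival.
* A chain flipped as a whole relative to the chromosome cannot be
  detected from adjacency evidence alone; map evidence orders chains but
  does not re-orient their interiors.
* Anchoring is majority-vote only; a chain genuinely spanning a real
  chromosome fusion relative to the map will be reported `ambiguous`.
* The precedence graph ignores marker density gradients within a
  scaffold; a chain's position is its marker mean, nothing finer.
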