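---
title: "Tracing whole-genome duplications and karyotype evolution with KaryoTracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing whole-genome duplications and karyotype evolution with KaryoTracer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

KaryoTracer re-implements, as tested code, a comparative-genomics
workflow for palm-like plant genomes: detection of collinear (syntenic)
gene blocks, Ks-based dating of whole-genome duplications (WGDs),
reconstruction of ancestral proto-chromosomes and of the rearrangement
trajectory that produced an extant karyotype, and presence/absence
variation (PAV) calling between two close accessions.  Because the real
genomes this kind of analysis is performed on are large external
datasets, the package also ships a genome-evolution simulator with a
complete ground-truth log; every method is exercised, and its parameter
recovery quantified, on simulated genomes whose true history is known.

This vignette explains the models, the defaults and the design choices;
the test suite and `scripts/acceptance.R` compute every number referred
to here.

# The simulator

`buildProtoKaryotype()` creates an ancestral genome of `A1..An`
proto-chromosomes whose genes carry random coding sequences (100-300
codons, standard genetic code, no internal stops) and singleton family
labels, so descent is traceable.  `applyEvent()` implements the
karyotype operations of a telomere-centric repatterning model:

* **WGD / WGT** multiply every chromosome by 2 or 3;
* **EEJ** (end-to-end joining) concatenates two chromosomes, removing
  the two joined telomeres (count −1);
* **nested fusion** inserts a whole chromosome at an internal breakpoint
  of another, removing both insert telomeres (count −1);
* **arm exchange** reciprocally swaps two chromosome tails (count
  unchanged);
* **inversion** reverses an internal gene run;
* **fractionation** deletes duplicated gene copies independently with a
  given probability, never deleting a family's last copy.

Chromosome counts therefore always obey
`count' = m * count - #EEJ - #nested_fusion` with `m` the ploidy
multiplier, which the suite checks over random histories.

## Sequence divergence

`evolveCds()` marks each codon position for synonymous change with
probability `f * p`, where `f` is that position's NG86 synonymous
fraction and `p = (3/4)(1 - exp(-4d/3))` the Jukes-Cantor expected
difference proportion at the requested distance `d`; marked positions
are replaced by a random synonymous alternative (nonsynonymous changes
are placed analogously from the `dnds` target, never creating stops).
This placement makes the expected Nei-Gojobori estimate of the
input/output pair equal the requested branch length by construction.  A
per-site Poisson process was considered instead; it biases the NG86
estimate downwards at two-fold degenerate sites (the Jukes-Cantor
correction assumes three equally likely targets), so the
distance-matched placement was preferred.  The acceptance suite verifies
the calibration: the mean NG86 Ks of 1000 simulated 300-codon pairs at
branch length 0.2 lies within [0.19, 0.21].

## The packaged trajectory fixture

`coconutFixture()` encodes the descent of a 16-chromosome coconut-like
genome from ten monocot proto-chromosomes: two EEJ reduce 10 to 8
(node B); the tau WGD doubles them to 16 (node C); five EEJ, two arm
exchanges and two nested fusions reduce them to 9 (node D); the omega
WGD doubles them to 18 (node E); five arm exchanges and two nested
fusions then form the extant 16 chromosomes.  Side lineages provide an
unduplicated basal outgroup, a sigma-WGT lineage that shares tau, and an
unduplicated eudicot-like calibrator branching at the root.

Ages use the calibration midpoints: the root (monocot-eudicot split) at
173.5 My (range 163-184), tau at 137.5 My (range 129-146), omega at
50 My (range 47-53).  The base synonymous rate is 0.003 substitutions
per site per My; the WGT lineage runs 1.5x faster so that the rate
correction has real work to do.  Proto-chromosomes default to 100 genes;
fractionation removes 20% of duplicate copies after each WGD and 35%
after the WGT.  Event breakpoints are free parameters of the fixture;
they are placed mid-segment and spaced apart so that successive events
remain distinguishable at gene resolution, as they must have been in the
real, resolvable history.  The fixture is shipped as human-readable JSON
under `inst/extdata/`.

# Collinearity

`findAnchorPairs()` resolves a homology table (BLASTP-like input; for
simulated genomes `familyHomology()` derives it from family labels)
against two gene orders; tandem arrays within a five-gene window are
collapsed first.  `chainAnchors()` runs a weighted
longest-increasing-subsequence dynamic programme per chromosome pair and
orientation, extracts the best chain, removes its anchors and repeats —
with at most 50 intervening genes between consecutive anchors and at
least 5 anchors per block (the gap matching the published setting, the
block minimum a common synteny-tool default).  On every random instance
of up to 12 anchors the chained score equals exhaustive search.

`attachBlockKs()` computes the block median over defined, unsaturated
anchor Ks values, requiring at least three; `bestMatchRatio()`
operationalises the "best-matched homologous regions" ratio as one plus
the modal number of within-genome paralog blocks younger than the
observed ortholog divergence that cover a gene, evaluated per genome
over genes covered by between-genome blocks.  On the packaged fixture
this yields 2:3 for the WGD lineage against the WGT lineage, and 2:1
when one lineage carries one extra WGD.

# Ks dating

`neiGojobori()` implements NG86 counting: fractional synonymous sites
per codon (changes to stops count as nonsynonymous so `S + N` is three
times the compared codons), site counts averaged over both sequences,
differences averaged over all minimal mutational pathways with
stop-containing pathways excluded, and the Jukes-Cantor correction.
Saturation (`ps >= 3/4`) sets a flag rather than failing; ambiguous
codons are skipped and counted.

`kdeDensity()` uses a Gaussian kernel with bandwidth 0.025 on a fixed
0.001-step grid over [0, 3], renormalised over the grid (no boundary
reflection).  `fitKsMixture()` least-squares fits sums of Gaussians to
the curve (mirroring a kernel-density-plus-curve-fitting workflow rather
than EM on the raw values), initialised at the highest local maxima,
selecting the component count by the penalised residual
`RSS + 3k log(G)`.  Within-genome distributions of a twice-duplicated
genome are fitted with two components, the count indicated by the 4:1
block depth against the unduplicated outgroup.

Rate correction follows the shared-divergence argument: all study
species split from the calibrator at the same time, so their
ortholog-versus-calibrator peaks `K_i` estimate the same age, and
`c_i = mean(K) / K_i` multiplicatively aligns them.  Within-species
paralog values scale by `c_i`, cross-species values by
`sqrt(c_i c_j)`.  This is the simplest model satisfying the premise;
when the calibrator's own rate differs from a lineage's, corrected
paralog peaks align only approximately (the simulation quantifies the
residual, about 20% under a 1.5x asymmetry with a mid-rate calibrator).
Dating is then linear: an event at corrected peak `P` spans
`[163 P / K, 184 P / K]` My.  On simulated data with a true WGD at
50 My this yields approximately 47-53 My, and on the packaged fixture
the tau event dates to approximately 129-146 My — the intervals these
methods are known for.

# Karyotype reconstruction

The reconstruction walks backwards through the two polyploidies.

1. **Painting.**  `paintGenome()` partitions the target chromosomes by
   the outgroup chromosome their blocks hit (merge gap 30 genes,
   minimum segment 10 genes — chosen on the simulator; the published
   analyses performed this step expertly by eye).  Gene-level labels
   come from each gene's own anchor where available, because a chained
   block may legitimately bridge a short foreign insertion.
2. **Proto-chromosomes.**  `inferProtoKaryotype()` clusters painted
   segments with the outgroup chromosomes into connected components
   under tree-expected multiplicity bounds (4 copies for two WGDs, 6
   for WGD+WGT), splitting over-full components at their weakest link.
   Components are labelled `A1..An` by descending gene content.
3. **Undoing a WGD.**  `.ancestorStep()` (used through
   `reconstructNodeKaryotypes()`) takes a duplicate-partner map — genes
   paired through the youngest paralog layer, each anchor classified to
   the layer whose fitted component mean is nearest its own Ks — and
   cuts chromosomes wherever the partner copies contradict an
   adjacency (partners must be co-located within about twice the local
   gene spacing).  Fragments are grouped into homoeolog classes, and
   classes are rejoined from three kinds of evidence: extant adjacency
   across a cut, partner-side continuation past a fragment end, and the
   requirement that a rejoin reconnect pieces of one segment — which
   makes its junction genes share a proto label and their older-layer
   duplicates co-locate.  Joins are accepted per candidate group by the
   end-matching that covers the most ends at the highest support, with
   two hard rules from the telomere-centric model: a class end lying at
   a chromosome end in either copy was a real chromosome end (fusions
   delete the joined telomeres), and only coherence-supported joins are
   admissible.  A label-guided fallback joins the unique pair of free,
   non-telomeric ends sharing a terminal label, covering segments whose
   partner witnesses were lost to fractionation.
4. **The older layer.**  The same step is applied to the reconstructed
   pre-omega genome; since the young layer is already removed there,
   each family has at most two copies left and the older-layer partner
   of a gene is simply its family mate.
5. **Events.**  `classifyBranchEvents()` compares karyotypes as
   squashed proto-label sequences (orientation ignored — inversions are
   normalised away): identical chromosomes match first, then EEJ,
   nested-fusion and arm-exchange patterns (breakpoints inside a label
   are allowed), then a bounded breadth-first search over residual
   groups (content-covering parents, depth 3, deterministic work caps).
   A repair pass can undo an earlier greedy match that consumed the
   parents a later child needs.  Ties prefer the simplest mechanism:
   EEJ, then nested fusion, then arm exchange.

Arm exchanges leave a genuine two-fold ambiguity at the gene-order
level (either reciprocal pairing of the four involved arms explains the
data); the older-layer coherence usually resolves it to the true
pairing, and either resolution preserves all chromosome counts and
event tallies.  `validateBookkeeping()` checks
`count(child) = m count(parent) - #EEJ - #NF` on every branch.

On the packaged fixture (seed 1) the full pipeline recovers the ten
proto-chromosomes, the node counts 8/16/9/18/16, and the branch event
tallies (2 EEJ; 5 EEJ + 2 arm exchanges + 2 nested fusions; 5 arm
exchanges + 2 nested fusions) exactly; `runDemo()` completes in a few
minutes at the default 100 genes per proto-chromosome.

# PAV calling

`pavCandidates()` takes one-to-one whole-genome alignment blocks (the
output a genome aligner produces; the simulator emits them with known
truth) and complements their coverage per genome, dropping intervals
under 100 bp.  `validatePavs()` re-searches each candidate against the
other genome with an exact 31-mer scan — a deterministic,
dependency-free stand-in for a BLASTN search — and rejects candidates
with coverage strictly greater than 80%.  `pavGenes()` reports genes
whose length is overlapped strictly more than 80% by retained segments.
Both thresholds are deliberately strict inequalities, and coverage is
computed over the candidate length.  On simulated accession pairs with
known insertions and deletions, retained-segment precision and recall
exceed 0.95 at the defaults.

# What the simulation does and does not show

The simulator emulates multi-lineage descent with polyploidy,
telomere-centric rearrangement, fractionation and rate asymmetry — the
features the methods are built to exploit.  It does not emulate tandem
expansion, transposable elements, gene conversion between paralogs,
segmental (non-whole-genome) duplication, or annotation error; passing
tests therefore demonstrate correctness of the algorithms and their
calibration under the model, not robustness to every artefact of real
assemblies.  Homology input for simulated genomes is family-exact,
standing in for a BLASTP table already filtered at `E < 1e-5`.

# Problem sizes and determinism

Defaults were chosen so a full demonstration (four genomes, about 8000
genes total) runs in minutes: 100 genes per proto-chromosome, 1500
block medians per dating distribution, 500-oracle-pair estimator
checks.  All stochastic steps consume a single seed; reruns with the
same configuration are identical.  Bounded searches carry deterministic
expansion budgets, so results do not depend on machine speed.
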