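---
title: "Progressive reconstruction of ancestral gene orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive reconstruction of ancestral gene orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procars)
```

## The problem and the model

Given the signed synteny-block orders of a set of extant genomes — every
genome containing the same set of non-duplicated blocks, arranged on
linear and/or circular chromosomes — and a rooted species tree with one
tagged internal, binary node, the package reconstructs the block order
of the genome at that node as a set of Contiguous Ancestral Regions
(CARs). A CAR is an ordered sequence of oriented blocks hypothesised to
be (part of) an ancestral chromosome.

The method is *homology-based*: it never infers a rearrangement
scenario. Instead it collects *adjacencies* — ordered pairs of
consecutive signed blocks, invariant under the flip identity
$(x\,y) = (-y\,-x)$ — whose conservation pattern across the extant
genomes makes them credible ancestral features, and assembles a
non-conflicting subset of them progressively. Two adjacencies *conflict*
when they involve the same block extremity; a genome can contain at most
one of them.

The tagged node splits the leaves into two ingroup sets $I_1, I_2$ (its
two child subtrees) and the outgroup $O$. An adjacency is *conserved*
when present in two genomes from two different sets (their tree path
then passes through the ancestor), *fully-conserved* when present in all
three sets. The *homoplasy cost* grades this: 0 (fully), 1 (partly,
i.e. conserved but not fully), 2 (one set only), 3 (absent) — costs 2
and 3 mean the adjacency is not conserved at the node.

## The progressive loop

Reconstruction starts from one single-block CAR per block and iterates
three kinds of step until no adjacency can be added:

* **Step a — non-conflicting conserved adjacencies.** The *CAR
  adjacencies* of every extant genome are detected against the current
  CARs (below), pooled, and classified. Fully-conserved adjacencies
  compatible with all other fully-conserved ones (FS~NC~) are retained;
  partly-conserved adjacencies conflicting with FS~NC~ are discarded
  permanently; the partly-conserved survivors compatible with each other
  and with every fully-conserved adjacency (PS~NC²~) are retained too.
  The retained set NC = FS~NC~ ∪ PS~NC²~ is added to the CARs. What
  remains is a set C in which every adjacency conflicts with another.
* **Step b — conflict resolution.** Runs when a step a retained nothing
  but left C nonempty. Each adjacency in C is scored by its *mutation
  cost*: the minimum number of presence/absence state changes along the
  tree edges, with the leaves clamped to the adjacency's occupancy and
  the ancestor clamped to present (a two-state small-parsimony dynamic
  program, exact for arbitrary out-degree). A non-conflicting subset of
  C of maximum size and minimum total cost is added; the rest is
  discarded permanently.
* **Step c — DCJ-reliable adjacencies.** Runs when both NC and C are
  empty. A candidate adjacency $(a_n\,b_1)$ between two free CAR ends is
  *DCJ-reliable* when some adjacency $(x\,y)$ inside the current CARs
  and some genome $G_1$ containing $(x\,b_1)$ and $(a_n\,y)$ exist, and
  the corresponding CAR adjacency is seen in a genome $G_2$ from a
  different partition set: the candidate plus $(x\,y)$ then explain the
  two $G_1$ adjacencies by a single Double-Cut-and-Join event. A maximum
  non-conflicting subset of the candidates is added, the rest discarded
  permanently.

After any productive step the loop returns to step a. Only productive
steps are numbered in the step log; an unproductive detection pass is
silent, which is why logged trajectories read like `a, a, b, c, a`.

## CAR adjacencies and micro-rearrangement tolerance

A *CAR adjacency* (car~a~ car~b~) is witnessed in an extant genome by a
pair of consecutive segments $S_a, S_b$, where $S_a$ contains only
blocks of car~a~ and, for the chosen orientation of car~a~ ending in
$a_n$, satisfies one of three tiers:

* **i.** $S_a$ is exactly the single signed block $a_n$;
* **ii.** $S_a$ is longer and ends with the unsigned block $|a_n|$;
* **iii.** $S_a$ is longer and is syntenic to (same block set as) a
  contiguous segment of car~a~ containing $|a_n|$.

The symmetric tiers govern $S_b$ against the leading block $b_1$.
Tiers ii/iii tolerate micro-rearrangements at CAR ends; the
corresponding block adjacency recorded for assembly is always
$(a_n\,b_1)$.

Two reading choices were genuinely open and are resolved as follows.
First, tier i alone governs single-block segments: a lone block whose
orientation disagrees with $a_n$ is *not* accepted through tier iii.
Allowing it would make the orientation of isolated blocks meaningless
and inflates the worked three-CAR instance (see
`car_adjacency_example()`) to four CAR adjacencies instead of its three.
Second, all four orientation combinations of (car~a~, car~b~) are tested
at every boundary, so both orientations of one partner can be witnessed;
consequently the at-most-two guarantee per signed CAR end holds for
*distinct partner CARs* (which is what its segment-overlap argument
actually bounds), and the test suite asserts it in that form.

## Exactness and determinism

* Steps b and c solve their selection problems exactly: the conflict
  graph is split into connected components and each component is
  searched exhaustively with a cardinality bound (maximum size first,
  then minimum cost). Conflict components are small in practice — a
  component is a cluster of adjacencies sharing extremities — so the
  search is far from its worst case; the test suite checks optimality
  against full $2^n$ enumeration.
* Every tie anywhere (step b/c optima, processing order in
  concatenation) is broken lexicographically on the canonical adjacency
  encoding — the writing of $(x\,y)$ vs $(-y\,-x)$ whose first block is
  smallest under (block id, then + before −). Runs are therefore
  bit-reproducible.
* An adjacency whose addition would close a CAR into a circle is
  skipped deterministically, logged as cycle-deferred, and treated as
  permanently discarded: the method's output chromosomes are linear
  sequences.
* Telomeres are not modelled as adjacency partners; chromosome ends
  simply bound segment enumeration, and a single-block linear chromosome
  has no adjacency. For the same reason a DCJ rewiring that would glue
  the two extremities of one block (circularising it) is rejected by
  `apply_dcj()` with an explicit error.

The homoplasy cost never orders candidates inside step a: the
fully-before-partly precedence is the whole of that step's priority
scheme, and the cost is recorded per adjacency for reporting only.

## The simulator

`simulate_genomes()` emulates block-order evolution so the
reconstruction can be scored against a known truth. The root genome is
blocks $1..n$, all positive, split evenly into linear chromosomes
(labels are arbitrary, so randomising the root would add nothing). On
every branch a fixed number of events is applied, drawn from inversions,
translocations, fusions and fissions with weights 0.70/0.15/0.075/0.075
— inversion-dominated, as in typical rearrangement inference settings —
and placed uniformly within each type. Defaults are 100 blocks, 5
chromosomes, 2 events per branch; tests use 20–50 blocks so whole-suite
runtime stays in seconds, and the acceptance checks below are at those
sizes.

What the simulator does *not* emulate: block gain/loss, duplication,
unequal block content, convergent rearrangement hotspots, or
branch-length-dependent rates. Passing recovery tests therefore shows
correctness of the machinery under the method's own assumptions (equal
content, non-duplicated blocks), not robustness to content evolution —
the method is explicitly not applicable to duplications or losses.

Under zero events the leaves equal the root and the reconstruction
returns the root exactly (this is asserted). Under light rearrangement
the suite computes precision and recall of reconstructed adjacencies
against the simulated ancestor and asserts precision stays high;
occasional convergent events can create genuinely misleading signal, so
perfect precision is not asserted.

## Degenerate inputs and validation

Parsers reject rather than repair: duplicate blocks, missing blocks
relative to the shared universe, empty chromosomes, unknown terminators
and orphan chromosome lines each name the genome and line. The tagged
ancestral node must be internal and binary with a nonempty outgroup; the
tree's leaf labels must match the genome names exactly. Branch lengths
are parsed and discarded — the method is parameter-free and never uses
them.

## Known limitations

* Equal, non-duplicated block content is assumed, as in the underlying
  model; there is no support for gene families, duplications or losses.
* Step c is only as strong as the extant witnesses; an adjacency
  destroyed in all lineages is unrecoverable by design.
* The exhaustive component search in steps b/c is exponential in the
  size of a single conflict component; pathological inputs (hundreds of
  mutually conflicting adjacencies over the same few extremities) would
  be slow, though they cannot arise from genomes, where each extremity
  occurs once per genome.
* One ancestral node is reconstructed per run; reconstructing several
  nodes means several runs.
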