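# procars

Progressive reconstruction of ancestral gene orders from signed
synteny-block data.

## What it does

Given (1) the block orders of a set of extant genomes — every genome an
arrangement of the same *n* non-duplicated signed synteny blocks on
linear and/or circular chromosomes — and (2) a rooted species tree with
one tagged internal binary node, `procars` reconstructs the gene order
of the genome at that node as a set of **Contiguous Ancestral Regions
(CARs)**: ordered sequences of oriented blocks, each a hypothesis for
(part of) an ancestral chromosome. Typical users are comparative
genomicists reconstructing, e.g., a mammalian ancestor from extant
genome assemblies after synteny-block construction.

The method is homology-based and parameter-free (no branch lengths, no
thresholds). Its currency is the **adjacency**: an ordered pair of
consecutive signed blocks, with the flip identity *(x y) = (−y −x)*.
Writing *I₁*, *I₂* for the leaf sets of the tagged node's two child
subtrees and *O* for the outgroup, an adjacency present in ≥ 2 genomes
from ≥ 2 of these sets is *conserved* (the genomes' path crosses the
ancestor); present in all three sets it is *fully-conserved*. The
**homoplasy cost** grades the pattern: 0 fully, 1 partly, 2 one set
only, 3 absent.

Starting from *n* single-block CARs the method loops over three steps:

- **a)** detect *CAR adjacencies* — contiguity between current CAR ends
  witnessed in extant genomes, with a three-tier segment matching that
  tolerates micro-rearrangements at CAR ends — and add the conserved
  ones that are conflict-free, fully-conserved first;
- **b)** when only mutually conflicting candidates remain, add an
  exactly optimal subset: maximum size, then minimum total *mutation
  cost* (two-state small-parsimony count of presence/absence changes on
  the tree, ancestor clamped to present);
- **c)** when no conserved candidate remains, add *DCJ-reliable*
  adjacencies: candidates which, together with an adjacency already
  inside the CARs, explain two adjacencies of an extant genome by a
  single Double-Cut-and-Join event, with support crossing the ancestor.

Adjacencies rejected in b) and c) (and those conflicting with retained
fully-conserved ones) are discarded permanently; every tie is broken
lexicographically, so runs are bit-reproducible. The loop ends when no
step can add anything.

## Worked example

The bundled five-genome instance (blocks 1..8; ancestor = parent of D
and E, so I₁ = {D}, I₂ = {E}, O = {A, B, C}):

```r
library(procars)
ex  <- five_genome_example()
run <- run_procars(ex$genomes, ex$tree)
write_step_log(run$steps)
#>   step kind n_cars size_min size_max n_added
#> 1    0 init      8        1        1       0
#> 2    1    a      4        1        3       4
#> 3    2    b      2        4        4       2
cat(write_cars(run$cars))
#> >ANCESTOR
#> 5 -3 1 2 $
#> 8 -7 -6 4 $
```

Step 1 adds the four conflict-free conserved adjacencies (among them the
fully-conserved `(6 7)`). Step 2 is a conflict resolution: for the
conflicting pair `(7 8)` / `(7 -8)` the mutation costs are 3 and 2, so
`(7 -8)` wins and `(7 8)` is discarded permanently:

```r
run$discarded
#>    u v step         reason
#> 1 -1 5    2         step-b
#> 2  2 3    2         step-b
#> 3  7 8    2         step-b
#> 4  2 5    2 cycle-deferred
```

(The `cycle-deferred` row is an optimal adjacency whose addition would
have closed a CAR into a circle; ancestral chromosomes are kept linear.)
The ancestor comes out as two CARs; per-adjacency homoplasy costs on
this instance are, e.g., `(6 7)` → 0, `(1 2)` → 1, `(1 -2)` → 2,
`(1 3)` → 3.

A command-line wrapper with `run`, `simulate` and `compare` subcommands
lives at `inst/scripts/procars.R`; the input grammar is one `>name`
header per genome followed by one chromosome per line, signed integers
terminated by `$` (linear) or `@` (circular).

## Simulation and evaluation

`simulation_config()` + `simulate_genomes()` evolve a root genome along
the tree by inversions, translocations, fusions and fissions and keep
the true genome at every internal node; `breakpoint_distance()`,
`shared_adjacencies()` and `reconstruction_accuracy()` score a
reconstruction against the truth or against other reconstructions.

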