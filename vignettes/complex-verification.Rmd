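---
title: "Verifying protein complexes through domain-domain interaction topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying protein complexes through domain-domain interaction topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddicomplex)
```

## The problem and the model

Graph-clustering methods predict protein complexes as densely connected
regions of a PPI network. Density alone, however, ignores a structural
constraint: proteins bind through interfaces, and one interface — here
approximated by one domain instance — engages at most one partner at a time.
A clique of three proteins that each carry a single mutually cognate domain
*looks* like a complex, but its members cannot all bind simultaneously: any
one domain-domain interaction occupies both interfaces it touches and blocks
the other two edges. `ddicomplex` filters candidate complexes by deciding,
per candidate, whether enough of its PPIs can be realized *at the same time*
given the members' domain complements and a catalog of interacting domain
types.

For a candidate with member set $C$, let $\Omega$ be the experimental PPI
edge set. The binding model has

* a binary variable $P_{i,j}$ for each pair $\{p_i, p_j\} \subseteq C$ with
  $\{p_i,p_j\} \in \Omega$ ($P_{i,j}=1$ means the PPI is realized);
* a binary variable $D_{i,j,k}$ for each pair of domain instances — one in
  $p_i$, one in $p_j$ — whose types form a catalog pair ($k$ indexes the
  instance combinations available to that protein pair).

The program maximizes $\sum P_{i,j}$ subject to

$$P_{i,j} = \sum_k D_{i,j,k} \qquad\text{and}\qquad
  \sum_{D \in D(d_l)} D \le 1 \;\text{ for each domain instance } d_l ,$$

where $D(d_l)$ collects the DDI variables touching instance $d_l$. Because
$P_{i,j}$ is binary, the equality simultaneously ties a realized PPI to
**exactly one** mediating DDI and forbids two parallel DDIs across the same
protein pair; we keep the equality form deliberately rather than relaxing it
to an inequality. A pair with no cognate instance combination has its $P$
fixed to 0. The all-zero assignment is always feasible, so the program is
never infeasible.

A candidate is accepted when the graph of active PPIs contains a connected
component of at least `min_size = 3` proteins; each such component becomes
one verified complex carrying its explicit PPI and DDI topology. A connected
3-protein component necessarily contains at least two active DDIs, so this
component rule implements "three or more proteins connected by more than one
domain-domain interaction". One candidate may yield several verified
complexes (all are returned), or none.

### Assumptions

* **One interface ≈ one domain instance.** Cases where a single domain
  genuinely binds several partners at once are deliberately excluded; the
  false negatives this causes are quantified by
  `false_negative_report()`, which subtracts complexes that could never be
  verified for lack of any cognate DDI annotation before attributing losses
  to the exclusivity assumption.
* **Inter-protein binding only.** DDI variables never pair two instances of
  the same protein, and a homotypic type pair (d, d) requires two distinct
  instances on two distinct proteins.
* **Candidates are independent.** A protein shared by two candidates may use
  the same domain in both; exclusivity is enforced within a candidate.

### Which exclusivity rows are emitted

An instance whose DDI variables all lie within a single protein pair is
already capped by that pair's equality constraint, so explicit
$\le 1$ rows are emitted only for instances whose variables span two or more
protein pairs. In the bundled worked example (`worked_example_fixture()`) this
yields exactly the two rows on p1's domains and none on d2/d3, matching the
model a reader would write down by hand; the optimum is unaffected either
way.

## Solving: exact, deterministic, twice

`solve_binding()` is a depth-first branch and bound over the DDI variables
in canonical order (sorted by protein pair, then instance pair). The
0-branch is explored first and the incumbent is replaced only on strict
improvement, so the returned solution is the lexicographically smallest
optimal assignment — a determinism choice made for testability, since the
model itself is silent on solution multiplicity (the worked example has two
symmetric optima; the tie-break picks d4–d2 / d1–d3). The bound used for
pruning is current objective + number of still-coverable pairs among the
remaining variables.

`solve_bruteforce()` enumerates all $2^n$ assignments (vectorized constraint
matrices) under the same tie-break and is the independent oracle: the test
suite checks objective *and* assignment equality on hundreds of random
models, and re-validates exclusivity and pair consistency outside either
solver. It refuses models above `max_vars = 20` by default; candidates of
realistic size (3–8 proteins) typically build far fewer variables, and
`solve_binding()` handles larger models without the exponential memory cost.

## Step-1 parameters

| parameter | default | meaning |
|---|---|---|
| `inflation` (MCL) | 3.6 | granularity of Markov clustering; tuned-for-recall value for yeast BioGrid-scale networks |
| `prune_threshold` (MCL) | 1e-5 | entries zeroed after each inflation step |
| convergence (MCL) | max entry change < 1e-8 | fixed, with a 100-iteration cap (warning on non-convergence) |
| `threshold` (`cc_cluster`) | 0.4 | minimum local clustering coefficient for a seed protein (degree ≥ 2) |
| `min_size` | 3 | smallest verified complex |
| `threshold` (`precision_recall`) | 0.25 | overlap score V must be **strictly** greater to count as a match |

MCL here is the standard expansion/inflation iteration with unit self loops,
read off attractor rows, with overlap ties resolved to the lexicographically
smallest cluster so the output partitions the proteins. The
clustering-coefficient extractor emits, for every seed passing the
threshold, the seed plus its neighborhood, deduplicated and sorted — the
simplest construction consistent with "dense region around a
high-coefficient node". The original tooling behind published yeast results
is not fully specified, so numerical agreement with published cluster tables
is not expected from either step-1 method; MCODE is intentionally not
reimplemented and enters through the cluster-file importer instead.

## Evaluation conventions

* Overlap score $V = |N_p \cap N_k|^2 / (|N_p|\,|N_k|)$; a prediction
  matches when $V > 0.25$ (strict), several predictions may match one known
  complex, and recall counts known complexes matched at least once.
* `same_function_ratio()` compares flat GO molecular-function term ids (no
  ontology traversal). Pairs where either protein is unannotated or carries
  only "molecular function unknown" (GO:0003674/GO:0005554) are excluded
  from the denominator — a documented choice where the convention was
  genuinely open; with no eligible pair the ratio is reported as missing
  rather than 0.
* `suggest_functions()` proposes terms only for complexes with exactly one
  uncharacterized member whose other members share at least one term.
* Verified complexes with identical member sets are deduplicated keeping the
  higher-objective record; the dedup key is the member set only.

## The synthetic benchmark

`generate_scenario()` emulates the two regimes the verification must
separate. **True complexes** are cliques built witness-first: every clique
edge gets a fresh cognate domain-type pair with one instance on each
endpoint, so a full-clique assignment exists by construction (the witness is
validated during generation — no solver call, hence no circularity).
**Decoys** are cliques whose members carry exactly one copy of a single
promiscuous self-interacting domain type, so active PPIs form a matching and
cap at $\lfloor \text{size}/2 \rfloor$ — every component stays below 3 and
the decoy is rejected. A sparse Erdős–Rényi layer (default 40 background
proteins, edge probability 0.03) supplies noise; background proteins carry
inert domains and random GO terms, with 10% marked function-unknown.

Defaults are 10 true complexes (sizes 3–6) and 10 decoys (sizes 3–5), the
benchmark design used by `scripts/acceptance.R`; generation is a pure
function of one integer seed and write/read round-trips are byte-stable.

What the generator does **not** emulate: scale-free degree distributions,
false-positive PPI edges inside planted complexes, incomplete or wrong
domain annotations, and DDI catalog noise. Passing the synthetic benchmarks
therefore demonstrates the combinatorial correctness of the
extract–verify–evaluate chain, not performance on real interactome data,
where annotation coverage dominates recall.

## Numerical and degenerate-input choices

* All file formats are strict TSV with `#` comments; malformed rows abort
  with the line number rather than being dropped.
* Edge canonicalization (lexicographically smaller protein first, no self
  loops, no duplicates) is idempotent; identifiers are opaque,
  case-sensitive strings and no gene-name mapping is attempted.
* Empty inputs degrade explicitly: an empty domain annotation or GO table
  warns; a network with no usable edges is a hard error; an empty candidate
  list yields an empty, well-typed result.
* Test and acceptance problem sizes — random models capped at ~12–14 DDI
  variables, 200 oracle-agreement replicates, benchmark networks of ~60–100
  proteins — were chosen as the package's own balance between coverage and a
  suite that runs in about a minute.

## Known limitations

* Catalog monotonicity of the *objective* is guaranteed; monotonicity of
  *acceptance* ("a verified candidate stays verified when the catalog
  grows") is not a theorem under a deterministic tie-break, because a larger
  catalog can change which co-optimal assignment is lexicographically
  smallest and co-optimal assignments can differ in component structure. It
  holds throughout the randomized suites at the tested scales.
* Only one optimal topology is reported per candidate; enumerating
  alternative optima is out of scope.
* Weighted networks, DDI confidence scores in the objective, and
  approximate solvers for very large candidates are out of scope.
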