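# ddicomplex

Protein complexes predicted from a protein–protein interaction (PPI) network
by graph clustering alone contain many false positives: a densely connected
cluster is not necessarily a set of proteins that can all bind **at the same
time**, because each binding interface (here approximated by a protein
domain) can engage only one partner at once. `ddicomplex` implements a
two-step prediction for systems biologists working with yeast-style PPI
networks, domain annotations, and domain–domain interaction (DDI) catalogs:

1. **Extraction** — candidate complexes are dense regions of the PPI
   network, found by deterministic Markov clustering (MCL, default inflation
   3.6), by a clustering-coefficient seed rule (default threshold 0.4), or
   imported from any external tool (e.g. MCODE).
2. **Verification** — each candidate is turned into a binary integer
   program. For every candidate pair *(p<sub>i</sub>, p<sub>j</sub>)* in the
   experimental edge set Ω there is a binary PPI variable *P<sub>i,j</sub>*,
   and for every pair of domain instances whose types form a catalog DDI
   there is a binary DDI variable *D<sub>i,j,k</sub>*. The program

   maximize Σ *P<sub>i,j</sub>*  subject to
   *P<sub>i,j</sub>* = Σ<sub>k</sub> *D<sub>i,j,k</sub>* (each realized PPI
   is mediated by exactly one DDI) and
   Σ<sub>D ∈ D(d<sub>l</sub>)</sub> *D* ≤ 1 for each domain instance
   *d<sub>l</sub>* (binding-interface exclusivity)

   is solved exactly. A candidate is accepted when three or more of its
   proteins are connected by the active, DDI-mediated PPIs; accepted
   complexes carry their explicit PPI/DDI topology.

The package also ships the full evaluation protocol (Bader-style overlap
score *V* = |N<sub>p</sub> ∩ N<sub>k</sub>|²⁄(|N<sub>p</sub>|·|N<sub>k</sub>|)
with strict matching at *V* > 0.25, precision/recall, same-function GO
ratio, false-negative accounting for the exclusivity assumption, function
suggestions for uncharacterized proteins), strict TSV readers/writers for
all five input tables, and a seeded synthetic-data generator with planted
ground truth so the whole pipeline is testable without downloads.

## Worked example

The canonical three-protein instance: `p1` carries domains `d1` and `d4`,
`p2` carries `d2`, `p3` carries `d3`; the network holds the potential PPIs
`p1–p2` and `p1–p3`; the catalog allows `d1–d2`, `d4–d2`, `d1–d3`, `d4–d3`.

```r
library(ddicomplex)

fx <- worked_example_fixture()
m  <- build_binding_model(c("p1", "p2", "p3"), fx$network, fx$domains, fx$ddis)
format_lp(m)
#> maximize P(p1,p2) + P(p1,p3)
#> subject to
#>   P(p1,p2) = D(p1,p2,p1:d1/1,p2:d2/1) + D(p1,p2,p1:d4/1,p2:d2/1)
#>   P(p1,p3) = D(p1,p3,p1:d1/1,p3:d3/1) + D(p1,p3,p1:d4/1,p3:d3/1)
#>   D(p1,p2,p1:d1/1,p2:d2/1) + D(p1,p3,p1:d1/1,p3:d3/1) <= 1   [p1:d1/1]
#>   D(p1,p2,p1:d4/1,p2:d2/1) + D(p1,p3,p1:d4/1,p3:d3/1) <= 1   [p1:d4/1]
#> binary all variables

s <- solve_binding(m)
glance(s)
#> # A tibble: 1 × 4
#>   status  objective n_active_ppis n_active_ddis
#>   <chr>       <int>         <int>         <int>
#> 1 optimal         2             2             2

extract_verified(c("p1", "p2", "p3"), s)$ddi_edges[[1]]
#> # A tibble: 2 × 6
#>   protein_i domain_i copy_i protein_j domain_j copy_j
#>   <chr>     <chr>     <int> <chr>     <chr>     <int>
#> 1 p1        d4            1 p2        d2            1
#> 2 p1        d1            1 p3        d3            1
```

Both PPIs are simultaneously realizable (objective 2) because `p1` serves
its two partners through two different domains: `d4` binds `d2` in `p2`
while `d1` binds `d3` in `p3`. One verified complex of all three proteins is
returned. Had each protein carried a single promiscuous domain, any one
active DDI would block the other two (objective 1) and the candidate would
be rejected — exactly the false-positive pattern the verification filters
out.

On a synthetic benchmark with 10 planted feasible complexes, 10
domain-starved decoy cliques and sparse background noise:

```r
sim   <- generate_scenario(synthetic_scenario(seed = 1))
cands <- cc_cluster(sim$network)
res   <- verify_all(cands, sim$network, sim$domains, sim$ddis)
res
#> # Verification: 20 candidates -> 10 verified complexes (reduction 50.0%)
#> #   mean size 4.20, max size 6
precision_recall(cands, sim$known)
#> # Complex evaluation (V > 0.25): precision 0.500 (10/20), recall 1.000 (10/10)
precision_recall(res$verified, sim$known)
#> # Complex evaluation (V > 0.25): precision 1.000 (10/10), recall 1.000 (10/10)
```

Verification doubles the precision here by rejecting every decoy while
keeping every planted complex. `autoplot()` works on both result objects,
and `plot_complex_topology()` draws one complex with its PPIs (thick) and
mediating DDIs (dashed).

## Command line

A thin driver wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ddicomplex.R", package="ddicomplex"))')" \
  run --ppi ppi.tsv --domains domains.tsv --ddis ddis.tsv \
      --known known_complexes.tsv --method cc --out out/
```

Subcommands `cluster`, `verify`, `evaluate`, `simulate` run each stage
separately on the same TSV formats; a flat `key = value` config file
(`--config`) mirrors the flags.

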