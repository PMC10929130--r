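# gmem — maximal exact matches between sequences and labeled graphs

Seed-chain-extend alignment needs anchors. `gmem` computes the classical
anchor — the **maximal exact match** (MEM) of length at least a threshold
κ — between DNA queries and **labeled sequence graphs**, the reference
representation used in computational pangenomics.

A match in a graph G = (V, E, ℓ) is a graph substring (i, P, j): a path
P = v₁…v_k matched from offset i of ℓ(v₁) to offset j of ℓ(v_k). The pair
([x..y], (i, P, j)), with Q[x..y] equal to the spelled string, is a κ-MEM
when y − x + 1 ≥ κ and, on each side, the match is maximal **or** the graph
extension set on that side is not a singleton:

```
LeftMax:  x = 1  ∨  lext(i,P,j) = ∅  ∨  Q[x−1] ∉ lext(i,P,j)
κ-MEM:    (LeftMax ∨ |lext| ≥ 2) ∧ (RightMax ∨ |rext| ≥ 2) ∧ y−x+1 ≥ κ
```

where lext is the label character before offset i (when i > 1) or the set of
final characters of v₁'s in-neighbors, and rext symmetrically. The
non-singleton escape keeps matches that extend along one path but not
another — exactly the seeds chaining must see.

What the package implements:

* **String MEMs** (`find_string_mems`): candidate exploration over
  bidirectional BWT-style indexes of Q and T with a cross product over
  one-symbol extension classes; plus the asymmetric query-centric variant
  (`find_asymmetric_mems`) and batched queries with unique separators
  (`batch_queries`).
* **Node MEMs and exact-L MEMs** (`find_node_mems`, `find_l_mems`): the
  same machinery over delimiter-separated node-label / sentinel-wrapped
  length-L path concatenations, with a D-array + range-minimum filter that
  keeps only matches spanning all L nodes.
* **Elastic founder graphs** (`find_efg_mems`): semi-repeat-free validation
  (`validate_semi_repeat_free`), unary-path merging (`merge_unary_paths`),
  the relaxed unrestricted-length classes (full-node, edge-prefix,
  edge-suffix) via per-edge scans of the query index, and stitching of
  those pieces into explicit ≥3-node MEMs, re-validated against the
  definition.
* **Oracle** (`brute_force_graph_mems`): a direct implementation of the
  definition, used throughout the tests as the independent ground truth.
* **I/O and tooling**: GFA v1 subset (S/L lines, `0M` overlaps, `+`
  orientations, optional `bl:i:` block tags), FASTA via Biostrings, TSV MEM
  output, seeded synthetic generators, and a CLI.

## Worked example

The bundled four-node toy graph has node v = `ACCGTA` with two in-neighbors
(w = `GATTA`, u = `GATTC`) and one out-neighbor (s = `GTT`):

```r
library(gmem)
fx <- toy_graph_fixture()
lext(fx$graph, 1, "v", 6)
#> [1] "C" "A"
rext(fx$graph, 1, "v", 6)
#> [1] "G"

find_l_mems(fx$graph, fx$query, kappa = 1, L = 2)
#>   query_id qstart qend i path j length nodes mem_class
#> 1        1      1    7 5  u>v 6      7     2      edge
```

With Q = `CACCGTAT`, the two-node MEM ([1..7], (5, u>v, 6)) is reported:
`C·ACCGTA` matched from the last character of u through all of v, maximal on
both sides. At L = 1 the run also reports ([2..7], (1, v, 6)) — not
left-maximal (Q[1] = C ∈ lext), but kept because lext(1, v, 6) = {A, C} is
not a singleton.

String MEMs between Q = `GAAT` and T = `AGAAAG` at κ = 2:

```r
r <- find_string_mems("GAAT", "AGAAAG", kappa = 2, collect_candidates = TRUE)
r$mems
#>   query_id qstart qend tstart tend length
#> 1        1      1    3      2    4      3     # GAA
#> 2        1      2    3      4    5      2     # AA
r$candidates
#> [1] "AA"  "GAA"                               # "GA" was pruned: every
#>                                               # occurrence extends with A
```

On a founder graph, the full pipeline:

```r
cfg <- generator_config(seed = 1)           # 20 blocks, height <= 4,
bg  <- random_block_graph(cfg)              # labels 4-8 bp, semi-repeat-free
qs  <- sample_queries(bg, cfg)              # 30 reads, 100 bp, 2 mutations
mems <- find_efg_mems(bg, qs, kappa = 12, stitch = TRUE)
table(mems$mem_class)
#>        edge edge-prefix edge-suffix   full-node    stitched
#>          43          90         402         270         648
```

The `stitched` rows are the explicit MEMs spanning three or more nodes,
reconstructed from the unrestricted-length pieces and identical to what the
brute-force definition yields.

## Command line

A thin Rscript shim is installed under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gmem.R", package="gmem"))')" \
    efg-mems --graph g.gfa --query q.fa --kappa 12 --stitch --out mems.tsv
```

Subcommands: `string-mems`, `graph-mems`, `efg-mems`, `validate-efg`,
`synth`, `stats`, `compare`. Exit codes: 0 success, 2 validation failure,
3 usage/parse error.

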