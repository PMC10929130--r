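---
title: "Finding maximal exact matches between sequences and labeled graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding maximal exact matches between sequences and labeled graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmem)
```

## The problem

Seed-chain-extend aligners need *anchors*: exact matches between a query and
a reference that can be chained into an alignment. The classical anchor is
the maximal exact match (MEM) — an equal substring pair that cannot be
extended in either direction — usually restricted to MEMs of length at least
a threshold $\kappa$ to keep their number manageable. When the reference is
a *labeled graph* $G=(V,E,\ell)$, as in computational pangenomics, a match
lives on a path: a graph substring is a triple $(i,P,j)$ with $P=v_1\dots
v_k$ a path, the match starting at offset $i$ of $\ell(v_1)$ and ending at
offset $j$ of $\ell(v_k)$.

This package enumerates $\kappa$-MEMs between DNA queries and labeled
graphs, with a dedicated fast path for indexable elastic founder graphs
(EFGs), the graph class for which pattern matching escapes the
quadratic-time conditional lower bounds that hold for arbitrary graphs.

## The MEM definition on graphs

A pair $([x..y],(i,P,j))$ with $Q[x..y]$ equal to the spelled string of
$(i,P,j)$ is a $\kappa$-MEM when $y-x+1\ge\kappa$ and, on each side, the
match is either maximal or the corresponding *graph extension set* is not a
singleton. The left extension $\mathrm{lext}(i,P,j)$ is the single label
character before offset $i$ when $i>1$, and otherwise the set of final
characters of the in-neighbors of $v_1$; the right extension is symmetric.
The non-singleton escape matters: a match that continues along one path but
not another must still be reported, or chaining misses seeds. On the bundled
toy graph:

```{r}
fx <- toy_graph_fixture()
fx$graph
lext(fx$graph, 1, "v", 6)   # {A, C}: two in-neighbors end differently
find_l_mems(fx$graph, fx$query, kappa = 1, L = 2)
```

`brute_force_graph_mems()` implements this definition literally (a filtered
start enumeration plus depth-first extension); it is the oracle every
index-based finder in the package is tested against, and deliberately shares
no code with them.

## String MEMs over a bidirectional index

`find_string_mems()` follows the classical two-index scheme. Both the query
and the text are indexed with suffix arrays of the string and its reverse
plus the two Burrows–Wheeler transforms, supporting `extend_left` /
`extend_right` with synchronized forward/reverse intervals. All strings that
occur in both sequences and are right-maximal in the virtual concatenation
$T \# Q$ are explored by left extensions; each explored string of length at
least $\kappa$ that is also left-maximal is a *MEM candidate*, and a cross
product over its one-character extension classes $(a,b)$ in $Q$ and $(c,d)$
in $T$ with $a\ne c$, $b\ne d$ emits the MEMs. Reaching a string boundary
counts as maximal: the end marker contributes a distinct sentinel per side.
Suffix-array positions convert to text coordinates through the stored
suffix arrays.

```{r}
fx <- toy_string_fixture()
r <- find_string_mems(fx$Q, fx$T, kappa = 2, collect_candidates = TRUE)
r$mems
r$candidates   # "GA" is explored but pruned: every occurrence extends with A
```

The exploration and cross product are implemented in C++ (as the hot loops
of string indexes usually are); every R-level index operation (`extend_*`,
`enumerate_*`, `is_*_maximal`) is also available for inspection and is
cross-checked against naive scanning in the tests.

## Exactly L nodes: sentinel wrapping and the D array

Node MEMs (string MEMs between $Q$ and single labels) come from running the
same machinery on the delimiter-separated label concatenation
$T_{\text{nodes}} = \mathbf{0}\,\prod_v \ell(v)\,\mathbf{0}$. For MEMs
spanning exactly $L$ nodes, `build_t_l()` concatenates every length-$L$
path, wrapping each unit in extension sentinels: the unique in-extension
character of the first node (or `#` when the set is empty or non-singleton)
on the left, symmetrically on the right. A unique sentinel letter suppresses
matches that should instead be reported on a longer path; `#` always lets a
match through, implementing the non-singleton escape.

Two details required decisions the underlying scheme leaves open:

* **Filtering matches to span all L nodes.** Each suffix-array position $k$
  of $T_L$ carries $D[k]$, the distance from the suffix start to the
  beginning of its path's last node, defined only when the position one
  later falls inside the first node (infinite otherwise). Because the
  text-side cross-product string $cQ'd$ starts one character *before* the
  match, a threshold of $|Q'|+1$ would also admit matches whose own span
  stops at the first-node boundary, with only the trailing extension
  character inside the last node — mapping to $j=0$. The package therefore
  reports positions with $D[k]\le |Q'|$, the convention under which the
  output equals the definitional oracle (verified exhaustively in the test
  suite). The reporting itself uses recursive range-minimum probing
  (`rmq_report_leq`), which lists all below-threshold entries with at most
  $2\cdot\text{output}+1$ probes.
* **Delimiter artifacts.** When a sentinel is a concrete letter, a match may
  begin or end *on* the sentinel; such occurrences carry a `0`-delimiter
  extension and are skipped in the cross product.

Within one $L$ the same graph MEM never arises twice (paths are distinct
units and extension classes partition occurrences), but the output is
deduplicated anyway as cheap insurance.

## Elastic founder graphs and the relaxed scheme

An EFG partitions the nodes into blocks $V_1..V_k$ with edges only between
consecutive blocks, and is *semi-repeat-free*: every node label occurs in
the graph only starting at the beginning of a same-block node (prefix
sharing within a block is allowed). `validate_semi_repeat_free()` checks
this by exhaustively matching every label from every (node, offset) start
along the graph — occurrences spanning three or more nodes can start
mid-label, so checking single labels and edge concatenations alone would
miss violations; the exhaustive walk is cheap at the scales the package
targets and is itself tested against an all-path-strings oracle.

Path enumeration is exponential in $L$, so for long MEMs the package uses
the engineered scheme that practical founder-graph indexes use: besides node
($L=1$) and edge ($L=2$) $\kappa$-MEMs, it reports three unrestricted-length
piece classes per edge $(u,v)$ — *full-node* MEMs ($Q[x..y]=\ell(v)$),
*edge-suffix* MEMs ($Q[x..y]=\ell(u)[i'..]\,\ell(v)$) and *edge-prefix* MEMs
($Q[x..y]=\ell(u)\,\ell(v)[..j']$) — found by backward (resp. forward)
searching $\ell(u)\ell(v)$ in the query index and reporting, from the node
boundary on, the occurrences that fail to extend with the next label symbol.
No length threshold applies to these classes, so the output-sensitivity
guarantee is deliberately given up; what is kept is coverage: any MEM
spanning $\ge 3$ nodes splits into a suffix-edge piece, interior whole-node
(or whole-edge) pieces, and a prefix-edge piece, all of which the scans
report.

**Stitching.** With `stitch = TRUE`, `find_efg_mems()` chains pieces back
into explicit long MEMs. Pieces chain when they abut exactly in the query
(previous piece ends at a node boundary, next starts at a node start, the
nodes joined by an edge) *or* overlap by exactly one full node label. The
overlap rule is necessary: a 3-node MEM decomposes into a suffix-edge piece
over $(u_1,u_2)$ and a prefix-edge piece over $(u_2,u_3)$ which share
$\ell(u_2)$ — abutting pieces alone cannot tile it. Reconstruction is
guaranteed because, inside any long MEM, the scan for each interior edge
$(u_t,u_{t+1})$ always survives to the end of $\ell(u_t)\ell(u_{t+1})$ and
reports the whole-edge occurrence. Since many tilings rebuild the same
chain, the chaining DFS deduplicates states on (start, node path, query
end). Every stitched chain is re-validated against the MEM definition
before being reported, so stitched output equals the $\ge3$-node MEMs of
the definitional oracle — an equality the acceptance tests assert on 100
random founder graphs with 30 queries each.

Below-threshold special pieces stay in the output under their class labels
(callers filter as needed); they are the raw material of stitching and some
downstream chaining schemes want them.

## Batched queries and occurrence filtering

Concatenating queries with unique separator symbols (`batch_queries()`)
preserves MEM semantics — no match can span a separator — so one index run
serves a whole query set, with `batch_project()` mapping global coordinates
back. `filter_by_text()` keeps only MEMs whose spelled string occurs in a
row collection (e.g. the MSA rows a founder graph was built from), using a
plain substring search; the semantics, not the compressed-index engineering,
is what the package implements.

## The synthetic generators

All generators are pure functions of a `generator_config()` (seeded;
identical configurations give identical outputs):

* `random_block_graph()` draws k blocks of 1..H nodes and connects
  consecutive blocks so every node lies on a source-to-sink path. Labels
  are drawn by rejection so the result is always semi-repeat-free: each
  candidate label is redrawn until it conflicts with nothing placed so far,
  and a final whole-graph validation redraws any label involved in an
  edge-crossing occurrence. A uniformly random 4-mer almost surely recurs
  in several hundred bases of labels, so valid graphs are naturally biased
  toward longer labels within the configured 4–8 range — a bias inherent to
  conditioning on the semi-repeat-free property, not a generator artifact.
* `sample_queries()` emulates read sampling: a random substring of a random
  path string, with a configured number of positions substituted uniformly
  over A/C/G/T (possibly silently — the substitution may redraw the
  original base).
* Defaults (20 blocks, height 4, labels 4–8 bp, 30 queries of length 100
  with 2 substitutions, $\kappa=12$) are the package's documented study
  conditions, chosen to resemble short-read seeding on a virus-scale
  pangenome block graph.

What the generator does *not* emulate: real MSAs (no indels, no shared
ancestry between block labels, no gap-aware block construction), realistic
base composition, or sequencing error profiles. Passing tests therefore
demonstrate algorithmic correctness — set equality against a definitional
oracle under these conditions — not biological performance on real
pangenomes.

## Numerical and engineering choices

* Suffix arrays are built by prefix doubling ($O(n\log^2 n)$), adequate for
  texts up to the tens of kilobases these tools index at desk scale;
  asymptotically optimal construction and succinct/compressed structures
  (wavelet trees, run-length BWTs) are out of scope.
* The symbol order `0 < # < $ < separators < A < C < G < T` is arbitrary but
  frozen: only equality and occurrence semantics matter to the algorithms.
* The BWT uses the circular convention (the character before position 1 is
  the end marker), so an occurrence at position 1 enumerates `$` as its
  left context.
* Exploration pushes left extensions in fixed alphabet order; the
  largest-interval-first order of space-optimal variants targets a working
  space bound the package does not claim.
* `enumerate_paths()` caps its output (default $10^5$ paths) and fails
  loudly beyond the cap; cycles are allowed, so the cap is the only guard
  on arbitrary graphs.
* Degenerate inputs: empty texts, $\kappa \le 0$, non-ACGT symbols, GFA
  dialect violations (non-`0M` overlaps, `-` orientations, sequence-less
  S-lines) and inconsistent block layerings are rejected with specific
  errors rather than propagated.

## Problem sizes in the test suite

The bundled tests run the string-MEM finder against a brute-force oracle on
200 random pairs (lengths up to 50, $\kappa\in\{1,2,3\}$), the exact-L
finder against the definitional oracle on 200 random graphs (up to 12
nodes, labels up to 6, $L\in\{1,2,3\}$, $\kappa\in\{1,2\}$), and the full
founder-graph pipeline (coverage and stitched equality) on 100 random EFGs
with 30 queries each; the recursion-count experiment uses a 200-block graph
and query lengths 100–1000. These sizes keep the whole suite in the
minutes range on one core while exercising every code path the package
exposes.

## Known limitations

* Path enumeration makes `find_l_mems()` practical only for small $L$; long
  MEMs on general (non-EFG) graphs have no fast path here.
* The suffix-tree-over-edge-triples machinery that yields output-sensitive
  reporting of $>3$-node MEMs on EFGs is not implemented; stitching of
  relaxed pieces (with definitional re-validation) plays that role at desk
  scale.
* Reverse-complement matching, bidirected graphs and GFA v2 are out of
  scope; graphs are used exactly as labeled.
* `merge_unary_paths()` can, on graphs where one label is a prefix of a
  same-block neighbor's, relocate an allowed occurrence off-start and so
  change the semi-repeat-free verdict; the function warns rather than
  fails, since MEM semantics (which the tests verify through coordinate
  translation) are unaffected.
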