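---
title: "Balanced decision-tree SNP tagging of barcode alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced decision-tree SNP tagging of barcode alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcstag)
```

## The problem and the model

A DNA barcode reference set holds one aligned sequence per species — for
animals typically the ~650 bp COI fragment. Identification against such a
set does not need the whole sequence: it needs only enough variable columns
to separate every pair of species. `dcstag` finds a small such set greedily,
organised as a binary decision tree.

At a tree node holding a subgroup of $n$ species, every alignment column
$p$ is scored

$$\mathrm{score}_p = \frac{\mathrm{mid} - \mathrm{diff}_p}{\mathrm{mid}} + \mathrm{weight}_p,
\qquad \mathrm{mid} = \lfloor n/2 \rfloor,$$

where $\mathrm{diff}_p = \min_i |\mathrm{mid} - f_i^p|$ over the alleles
$i \in \{A,C,G,T\}$ *observed* in the subgroup ($f_i^p$ their counts), and
$\mathrm{weight}_p$ is 0, 1, 0.66 or 0.33 for 1, 2, 3 or 4 distinct
alleles. The two terms encode two preferences: splits that halve the
subgroup (small `diff`), and biallelic columns, which induce a clean
two-way routing. The constants 0.66 and 0.33 are the method's fixed decimal
definitions, not rounded thirds, and comparisons between scores are exact.

Useful consequences, all tested as properties:

* a balanced biallelic column scores exactly 2.0 (even $n$);
* every polymorphic column scores at least $1/\mathrm{mid} + 0.33 > 0$,
  while monomorphic columns score $\le 0$ — so a variable column is always
  preferred;
* for a fixed allele count, the score strictly decreases with imbalance.

The lowest position attaining the maximal score becomes the node; the
allele whose count is nearest `mid` is routed "up" and all other observed
alleles "down". On a biallelic column this is the natural one-vs-one split.
For tri- and quadallelic columns the method's worked examples do not fix a
bipartition; we chose *the `diff`-achieving allele versus the rest*, which
reduces exactly to the biallelic behaviour and reuses the quantity the
score already minimises. Ties between positions go to the lowest position;
ties between alleles are broken in A<C<G<T order (either choice would be
valid; a fixed order makes runs byte-reproducible).

Recursion stops at singleton subgroups. The per-species **tag** is the
projection of its row onto the ascending union of node positions — not a
path string through the tree — so a tag can be read off a sequence without
the tree, and its length equals the number of distinct selected positions.
Uniqueness is guaranteed: any two species are separated at some node, whose
position is in the projection and where their alleles differ.

## Parameters that matter

* **Trim ranges** (`trimAlignment`): barcode alignments have ragged,
  gap-rich ends; scoring them would select artefactual columns. `explicit`
  mode removes exactly the requested head/tail column counts (units:
  alignment columns); `auto` mode removes the maximal terminal runs of
  columns containing at least one gap. Interior columns are never removed.
  A 696-column COI alignment trimmed by 35 head and 24 tail columns keeps
  637; the package always reports the computed width.
* **Strategy** (`buildTree`): `dcst` (default, balanced) versus two
  imbalanced baselines — `first_diff` splits on the first variable
  position, `max_divergence` on the position with the largest majority
  allele. Both produce valid unique tags but systematically worse balance
  (larger `balanceIndex` in `treeStats`), which is the argument for the
  balanced rule.
* **Reference record** (`referenceId`, default: first record): node labels
  like `CT(57)` and the tag position table report coordinates on the
  *ungapped, untrimmed* reference sequence, computed as the count of
  non-gap reference characters up to the column plus the residues trimming
  removed from its 5' end (`trimAlignment` records these in `metadata()`).
  Columns where the reference carries a gap are flagged and mapped to the
  nearest preceding residue.

## Degenerate inputs and numerical choices

Characters outside A/C/G/T (gaps, N, IUPAC codes) are carried through but
never counted as alleles; `mid` always uses the subgroup size, not the
count of unambiguous rows. A column with no A/C/G/T character at all in the
current subgroup is unsplittable and scores $-\infty$ rather than raising.
A species carrying a non-ACGT character at a chosen split position is
routed "down" with a warning, so the leaves always partition the species
set. Two species with no differing A/C/G/T column are reported as an
indistinguishable-species error naming the offending rows, with the
subtree path. One sequence per species is assumed; duplicate identifiers
are an error, not a consensus computation.

Tree construction re-scores each subgroup independently; the total work is
$\sum_{\text{nodes}} n_{\text{node}} \times M \le N \cdot M \cdot D$ for
depth $D$, which the suite checks structurally (sum of node subgroup sizes
$\le N D$) rather than by timing. The recursion depth equals the tree
depth, far below R's evaluation limits at barcoding scale (hundreds to a
few thousand species).

## Code 128 rendering

Tags are ASCII over {A,C,G,T}, so code set B suffices; no code-set
switching is attempted. `encodeCode128` emits Start-B, one symbol per
character, the weighted mod-103 checksum and the stop pattern (11 modules
per symbol + 13). The pattern table is validated in the tests against the
symbology's designed self-check structure (every symbol: 3 bars + 3 spaces,
11 modules, even bar-module parity), and an independent width-pattern
decoder round-trips every encoding. SVG output is deterministic text with
\>= 10-module quiet zones and a human-readable payload line; PNG output
draws bars only (rasterising text would require bundling a font).

## What the synthetic generators emulate — and what they don't

`makeBalancedCodeAlignment(k, seed)` plants $k$ exactly balanced biallelic
columns encoding each of $2^k$ species' binary index among monomorphic
filler, with seed-shuffled column order: the ideal-case input on which the
balanced strategy must recover depth $k$, exactly those $k$ columns,
balance index 0, and tags equal to the planted codes.
`makeRandomAlignment` plants columns with exact allele counts (e.g.
C:3/T:3/A:2 in 8 rows, the canonical tie case with `diff` = 1).
`makeWorkedExampleAlignment` is a frozen 8×13 matrix exhibiting the
canonical scoring quantities (balanced column scoring 2.0; triallelic
column with counts A:6/C:1/G:1 scoring 1.16; selected positions
{1,2,3,4,7} with 3 and 4 each used twice). It was constructed once to
satisfy those constraints and is asserted byte-for-byte in the tests —
failures are treated as regressions, never fixed by editing the fixture.

None of the generators simulate molecular evolution: no substitution
model, no rate heterogeneity, no correlation between columns, no gaps or
ambiguity codes unless planted. Passing tests therefore demonstrate the
combinatorial correctness of scoring, splitting, tagging and encoding —
not that any particular real alignment yields a particular SNP count, tag
length or phylogenetically meaningful grouping. The tree is an
identification structure, not a phylogeny: it ignores distances between
selected positions and is unsuitable for evolutionary inference. For real
data the test suite's problem sizes (up to $2^6$ species and a few hundred
columns in the property checks; 200 random 8×15 alignments against a
brute-force oracle) were chosen as comfortably representative of
barcoding-scale inputs while keeping the default run fast.

## Known limitations

* Tags discriminate only the *known* species of the input set; assigning
  an unknown query is out of scope, and adding a species generally changes
  the selected positions.
* Greedy selection is not guaranteed minimal over all position sets; it is
  minimal per split step only.
* Species represented by multiple conspecific sequences are not modelled —
  the input contract is one record per species.
* The end-to-end counts for a full curated COI set (hundreds of variable
  columns reduced to a few dozen selected positions) depend on the
  upstream aligner and exact trim ranges; `checkFullDataReproduction`
  exists to run that integration check when such a curated alignment is
  supplied externally.
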