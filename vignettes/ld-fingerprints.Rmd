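---
title: "Length-disorder fingerprints: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-disorder fingerprints: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

Two coarse attributes separate proteomes surprisingly well: protein length
and intrinsic disorder. `ldspace` reduces a whole proteome to the joint
distribution of

* `ln(L)` — the natural log of the protein's residue count, and
* `ID` — the fraction of its residues predicted to be in a disordered state,

over the "LD space" `[0, Inf) x [0, 1]`. The space is cut into an `M x N`
grid of blocks; the fraction of proteins falling in each block,
`X_ij = n_ij / n_tot`, is the proteome's *fingerprint* — a normalized density
grid that sums to one. Proteomes are then compared without any sequence
alignment: the distance between proteomes A and B is the Euclidean distance
between their fingerprints,

```
r_AB = sqrt( sum_ij (A_ij - B_ij)^2 ),
```

and a distance matrix over many proteomes feeds classical neighbor joining to
produce an unrooted tree. Because both attribute distributions are close to
linear in rank (ranked `ln(L)` grows almost linearly from the shortest to the
longest protein, and likewise ranked `ID`), a modest uniform grid captures
the architecture of a proteome rather than noise.

Both levels of disorder summary are kept distinct:

* `id_pep` (per protein): the fraction of residues whose score reaches the
  disorder threshold, `N_D / L`. A residue counts as disordered when its
  score is **greater than or equal to 0.5**; the threshold is inclusive, so a
  residue scored exactly 0.5 is disordered. A protein with `id_pep >= 0.5` is
  classified as an intrinsically disordered protein (IDP).
* `id_res` (per proteome): the plain mean of raw scores over every residue in
  the proteome — no threshold involved.

## Preparing a proteome

`build_proteome()` applies a fixed preparation order:

1. **Read all sequences.** Trailing `*` stop characters are stripped before
   lengths are computed. Sequences may contain the 20 standard letters plus
   `X`; anything else is rejected.
2. **Primary-isoform selection.** One protein per gene locus — the longest
   isoform. Locus identity comes from the header: by default a trailing
   `.\d+` isoform suffix is stripped from the protein id (so `AT1G01010.2`
   groups under `AT1G01010`); the regex is configurable because id schemes
   differ between databases, and ids without a suffix are their own locus.
   When two isoforms tie for maximal length, the lexicographically smallest
   protein id wins — an arbitrary but deterministic convention.
3. **Unknown-residue exclusion, after isoform selection.** Proteins
   containing `X` have a known length but cannot be scored for disorder.
   They stay in the length-statistics view (`records_all`) and are excluded
   from the disorder view (`records`). `summarize_proteome()` therefore
   computes `ave/med/max/min` length over *all* primary proteins and the two
   disorder percentages over the X-free scored subset. The accounting
   identity `nrow(records) == n_total_loaded - n_excluded_x -
   n_alternative_removed` always holds.

Disorder scores are an external input: any per-residue predictor producing
values in `[0, 1]` can be used via a plain-text score file (one line per
protein, or `>id` blocks of position/score pairs). For self-contained runs,
`proxy_scores()` provides a deterministic propensity-based scorer: a fixed
TOP-IDP-style per-residue propensity table (frozen in
`disorder_propensity_scale()`, maximum at proline 0.987, minimum at
tryptophan -0.884) smoothed by a centred moving window (default 21 residues,
truncated at the ends; windows longer than the protein are clamped to its
length) and min-max rescaled to `[0, 1]` with those two fixed constants. The
proxy is *not* a trained predictor and must not be read as one — every run
log records which score source was used.

## The partition

The reference grid is `M = N = 10`: ln-length edges

```
0, 4.6, 4.9, 5.2, 5.5, 5.8, 6.1, 6.4, 6.7, 7.0, Inf
```

(uniform 0.3 spacing between 4.6 and 7.0, open-ended first and last bins)
and disorder edges `0, 0.1, ..., 1.0`. Conventions:

* Bins are half-open `[lo, hi)`; the last bin of each axis is closed above,
  so `ID = 1.0` lands in the top disorder bin and every `(L, ID)` pair maps
  to exactly one block. In particular `L = 100` (`ln 100 = 4.605 >= 4.6`)
  falls in the second length bin, while `L = 99` stays in the first.
* The integer length bound of an edge `b` is `ceiling(exp(b))` — the
  smallest integer length whose log reaches the edge (`length_bound()`),
  e.g. 4.6 → 100, 4.9 → 135, 7.0 → 1097. Printed integer interval tables for
  such grids are rounded displays; the ln edges are the defining quantity.
* For other `M`, interior edges are spread uniformly over `[4.6, 7.0]` (for
  `M = 2`, the single interior edge sits at the midpoint 5.8); `N` disorder
  bins are equal-width on `[0, 1]`. Coarser grids are therefore *not*
  edge-nested inside the 10x10 grid in general; when exact coarsening is
  needed (e.g. to verify the block-merging identity), pass explicitly nested
  edges to `ld_partition()`. We chose the uniform generalization over forced
  nesting because it keeps every grid self-similar and leaves nesting as an
  explicit user decision.
* Display clamping — drawing the open-ended outer bins at `ln(L) = 4.3` and
  `7.3` (`L = 74` and `1481`) in `render_contour()` — is purely cosmetic and
  never affects binning.

Two disorder-threshold conventions circulate for *category counts* (e.g.
"short and disordered"): strict `ID > 0.5` and inclusive `ID >= 0.5`. The
protein-level IDP classification in summaries always uses the inclusive
form; `count_category()` takes the predicate explicitly, and the pipeline
config records which convention is active, because counts of proteins
sitting exactly at 0.5 differ between them.

## Distances and the tree

`fingerprint_distance()` is the Euclidean metric on density grids; it is
bounded by `sqrt(2)` (two disjointly supported distributions) and typically
much smaller — with normalized densities spread over 100 blocks, realistic
inter-proteome distances are of order 0.01-0.2, which is why branch lengths
of the resulting trees are small.

`nj_tree()` implements classical Saitou-Nei neighbor joining in the package
(agglomeration by the minimal `Q_ij = (r-2) d_ij - R_i - R_j`, standard
branch-length formulas, final trifurcation), rather than delegating to an
external tree server, so the whole workflow is reproducible offline. Choices
worth stating:

* **Variant.** Classical NJ, not BioNJ: it is the canonical choice, exact on
  additive matrices, and deterministic given the tie rule below. An
  independent NJ implementation (`ape::nj`) is used in the test suite as a
  cross-check, never as the implementation.
* **Ties.** When several pairs share the minimal `Q` (within a relative
  1e-12), the pair whose (sorted) representative leaf labels are
  lexicographically smallest is joined. This makes the tree a pure function
  of the distance matrix.
* **Negative branches.** NJ can estimate negative lengths on non-additive
  input; estimates are clamped to zero with the deficit moved to the sister
  branch, preserving the path length between the joined pair. Tree edge
  lengths are therefore always non-negative.
* **Rooting.** The output is unrooted (the natural NJ product). Any rooted
  display is a rendering decision; midpoint rooting is a reasonable default
  for figures.

`clade_check(tree, group)` asks whether some edge bipartitions the leaves
exactly into `group` versus the rest — the unrooted notion of "the group
forms a clade". Single leaves are trivially clades; the full leaf set is
rejected.

## What the synthetic generator emulates — and what it does not

`generate_proteome()` builds fixtures that reproduce the two rank-linear
regularities the method relies on:

* sorted `ln(L)` equally spaced over a configurable range (linear fit
  `R^2 > 0.99` after integer rounding of lengths; the minimum allowed length
  is 5 residues, about the shortest annotated protein);
* ranked disorder targets equally spaced over `mean ± sqrt(3)·sd` (the
  linear ranked profile with exactly that mean and standard deviation),
  paired with lengths by a seeded random permutation so the two axes are
  independent by construction.

Scores are *planted*, not predicted: a protein with target disorder `id`
gets `round(id * L)` residues at score 0.9 and the rest at 0.1, so the
realized `id_pep = N_D / L` is exact, far from the 0.5 boundary, and
recoverable bit-for-bit from the emitted score file. This deliberately
decouples generator correctness from the proxy scorer. Unknown residues
(one `X` per selected protein, default rate 0.3%) and shorter alternative
isoforms are injected at configurable rates, and a truth table records every
planted quantity, so the preparation steps can be verified exactly.

The group presets encode the robust empirical contrast between domains of
life: "eukaryote-like" proteomes target mean `id_pep` 0.41 with a longer
length range (`ln L` in `[ln 16, 8.6]`, sd 0.20), "prokaryote-like" ones
target 0.16 with a shorter range (`[ln 25, 7.4]`, sd 0.09). The disorder
means follow the observed eukaryote/prokaryote proteome averages; the sds
are the widest uniform profiles that keep the ranked targets inside `[0, 1]`
near those means, and the length ranges bracket typical minimum/median/
maximum lengths for the two groups.

What the generator does **not** emulate: real amino-acid sequence evolution
or homology (sequences are i.i.d. draws from a fixed background
composition), correlation structure between length and disorder, predictor
noise, or multimodal length distributions. Passing tests on these fixtures
therefore validate the *machinery* — preparation, binning, distances, NJ —
and the separability of genuinely distinct disorder/length profiles; they do
not certify biological conclusions about any real proteome.

## Numerical choices and degenerate inputs

* Natural logarithms throughout.
* Fingerprint normalization is exact up to floating error; tests assert
  `|sum - 1| < 1e-12`.
* Median length: mid-point convention (mean of the two central order
  statistics for even counts).
* Correlations between `ln(L)` and `id_pep` (`ld_correlation()`): Pearson
  and Spearman with mid-rank ties, computed on the pooled scored proteins of
  the proteome. Zero-variance input returns an explicit
  undefined-correlation result (`defined = FALSE` plus a reason), never a
  silent `NaN`. Fewer than three scored proteins is an error.
* Tabular output rounds percentages to one decimal for display; all internal
  computation keeps full precision.
* Empty proteomes, empty score vectors, score/length mismatches, scores
  outside `[0, 1]`, mismatched partitions, duplicate labels and sub-3-taxon
  matrices are all rejected with named errors rather than propagating NA.

## Problem sizes used by the test suite

The automated suite exercises: 10,000-protein binning cross-checks against a
brute-force binner; 200 random fingerprint triples for the metric
properties; 100 random additive matrices (6-12 taxa) plus 20
fingerprint-derived matrices for NJ; and 100 independent synthetic cohorts
of eight 1,000-protein proteomes (four per group preset) for end-to-end
clade recovery, requiring at least 95 successes. These sizes make the
statistical checks stable while keeping a full run in the low minutes on one
core.

## Limitations

* The fingerprint discards everything about a proteome except its
  length/disorder architecture; identical fingerprints do not imply related
  organisms, and the Euclidean distance is not an evolutionary distance with
  units of substitutions.
* Results inherit the biases of the score source; the bundled proxy scorer
  is a smoothed propensity profile and systematically differs from trained
  predictors, especially on short proteins.
* NJ topology can be sensitive to the partition (`M`, `N`); comparing trees
  across partitions (e.g. via Robinson-Foulds distance) is the supported way
  to probe that sensitivity.
* No bootstrap or other support values are computed for the trees.
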