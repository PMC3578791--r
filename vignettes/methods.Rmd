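---
title: "Methods: distance-based diversity and tree-shape statistics for 18S rDNA groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based diversity and tree-shape statistics for 18S rDNA groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protistdiv)
```

`protistdiv` characterizes taxonomic groups of marine microbial
eukaryotes along two complementary axes: how much genetic distance a
group's 18S rDNA sequences span (and how its OTU counts collapse under
clustering), and how its lineages are arranged in time on a rooted
phylogeny. This vignette documents the models, the tunable parameters,
the numerical conventions, and the choices made where the design was
genuinely open.

## Distances

Pairwise distances use the Jukes–Cantor model,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, where $p$ is the observed
proportion of differing sites. Its assumptions — equal base frequencies
and a single exchange rate — are crude for rRNA, but the statistic is
the field's standard for OTU work on this gene and keeps distances
comparable with the mothur/PAUP lineage of tools.

Conventions:

- **Pairwise deletion.** A column contributes to a pair only when both
  sequences carry an unambiguous base (A/C/G/T). Gaps *and* IUPAC
  ambiguity codes are excluded. Pairwise (not complete) deletion keeps
  per-pair information maximal on ragged environmental alignments;
  ambiguity codes are excluded rather than fractionally matched because
  the fractional scheme changes $p$ by amounts that cannot be audited
  per site.
- **Saturation is an error, not a clamp.** At $p \ge 0.75$ the distance
  is undefined; silently clamping would corrupt the Max statistic that
  the whole analysis leans on. The region-calibration path, which must
  tolerate occasional saturated pairs in a fast region, requests
  `on_saturation = "na"` and drops (and counts) those pairs.
- **Full precision here, grid in the clusterer.** Avg and Max are
  computed on unrounded distances; rounding to the clustering grid
  happens only inside the clusterer. The two choices differ below
  $10^{-4}$, invisible at the 2-decimal reporting scale.

## OTU clustering

Furthest-neighbor (complete-linkage) agglomeration: the distance
between clusters is the maximum over cross-pairs, so every OTU carries
the guarantee that all its internal distances are at or below the
cutoff. Three numerical conventions make runs reproducible:

- **Precision grid.** Input distances are rounded to the nearest
  $1/\text{precision}$ (default 10 000, i.e. 4 decimals) before
  agglomeration, half rounded up. Cutoffs are compared on the same
  grid, with a closed interval (`height <= cutoff`).
- **Tie rule.** Among equal-height candidate merges, the pair whose
  lexicographically smallest member names sort first wins. Any rule
  would do for the counts; a fixed rule makes dendrograms and list
  files byte-reproducible.
- **Max_c slack.** Because Max_c lives on the grid while Max is
  unrounded, Max_c may exceed Max by up to half a grid step
  ($5 \times 10^{-5}$); the container treats that as equal.

The **maximum corrected distance** (Max_c) is the smallest merge height
at which at least a fraction $f$ (default 0.9) of the group's sequences
sit in one OTU; the comparison is $\text{size} \ge f \cdot n$ on the
real value, with no integer ceiling — the literal reading of "90% of
the sequences". For $n = 4$, $0.9 \cdot 4 = 3.6$ means all four are
required. Max_c discounts single divergent sequences — fast-evolving or
erroneous — that dominate the raw maximum.

The **clustering pattern** divides each cutoff's OTU count by the count
at distance 0, so groups of very different sampling depth can be
compared; a group retaining a high percentage at 0.05–0.10 harbors many
high-rank lineages.

## Region calibration

`paired_region_fit()` regresses partial-region distances ($y$) on
full-gene distances ($x$) by ordinary least squares over all unordered
pairs, reporting slope, intercept and Pearson $R$. Two open choices
were fixed as follows:

- **Orientation.** $y =$ partial, $x =$ full. A region more variable
  than the gene must show $m > 1$ in this orientation, which is how
  slopes of ~1.4 for V4–V5 are conventionally quoted.
- **Free intercept.** The intercept is estimated, not constrained to 0,
  and reported — a constrained refit is then trivial, and the free fit
  exposes any systematic offset the constrained fit would hide in the
  slope.

Under the package's own generator the recovered V4–V5-type slope sits
slightly below the configured multiplier (≈1.35 for 1.4 with a
500/5000-column region) because the fast region is part of the full
gene and raises $x$ as well; the short V9-type region scatters widely
from seed to seed while always showing the lower $R$ — exactly the
qualitative behavior that motivates preferring the longer region.

## Tree structure

**Ultrametricization** uses mean-path-length smoothing: each internal
node's height above the present is set to the mean path length to its
descendant tips; processing root-ward, any child whose smoothed height
exceeds its parent's is pulled down to the parent, clamping that branch
to zero and keeping all branch lengths non-negative. Model-based dating
(penalized likelihood) was deliberately not used: only the relative
order and spacing of nodes matter for LTT and $\gamma$, and the
smoothing is deterministic and parameter-free. On mild perturbations of
ultrametric trees it changes total tree length by well under 20%.

**LTT curves** are standardized for comparability: relative time runs
from $-1$ at the root (crown origin — the trees are extracted clades,
so the crown, not the stem, is the natural origin) to $0$ at present,
and lineage counts are percentages of the count at present. The count
starts at 2 at the root.

**The $\gamma$ statistic.** With $g_j$ the duration during which the
tree holds $j$ lineages ($j = 2..n$), $T_i = \sum_{k=2}^{i} k g_k$ and
$T = T_n$:

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i \; - \; T/2}
                {T\sqrt{1/(12(n-2))}}$$

Under constant-rate pure birth $\gamma$ is approximately standard
normal; $\gamma < 0$ indicates early cladogenesis (concave LTT),
$\gamma > 0$ late. The constant-rate null is tested **one-tailed in the
direction of the observed sign** ($p = \Phi(-|\gamma|)$, $\alpha =
0.05$) — the classification into negative / zero / positive panels is
descriptive, grouping lineages by their apparent tempo, which is a
sign-conditional question. Polytomies are resolved with zero-length
branches (logged); $\gamma$ is invariant to the resolution order
because the internode intervals are unchanged.

**MPD, trunk, intergroup distances** are patristic-distance summaries
on the full tree: MPD averages within-group tip pairs, the trunk is the
stem branch under a monophyletic group's MRCA (a single-tip group's
trunk is its terminal branch, flagged — needed for degenerate
fixtures), and intergroup entries average cross-group tip pairs, with
each group's minimum identifying its closest neighbor.

## The synthetic generator

The generator emulates the *shape* of a curated environmental 18S
dataset, not its content:

- **Yule trees** with the exact constant-rate null for $\gamma$:
  internode intervals are exponential with rate $j\lambda$, split
  lineages chosen uniformly. Extinction is not simulated; the paper's
  reference null is the pure-birth one, and tempo departures are
  produced instead by the time warp.
- **Time warp.** Node ages rescaled as $a \mapsto a^\beta$: one
  parameter moves $\gamma$'s expectation smoothly through negative
  ($\beta < 1$), zero ($\beta = 1$), positive ($\beta > 1$) — directly
  testable sign control.
- **Sequences** evolve under Jukes–Cantor (via `phangorn::simSeq`) at
  `base_rate` times a per-region multiplier; defaults place a
  520-column V4–V5-like region and a 160-column V9-like region at 1.4×
  inside an 1800-column gene, matching the reported relative
  variability of those regions. Default `base_rate = 0.05`
  substitutions/site/time keeps intra-group distances in the 0.05–0.5
  range seen across real groups without approaching saturation.
- **Group fixtures** attach per-group Yule clades to a ladder backbone
  by configurable trunk branches (defaults 0.3–0.7, backbone 0.2),
  with group sizes 40/25/15/10/10 spanning well-sampled classes to
  small ribogroups, and per-group warps $1/3$, $1$, $3$, $1$, $1$
  providing one early, one late, and three constant-tempo groups.

What the generator does **not** emulate: indels and alignment error
(alignments are gap-free; the length filter and pairwise deletion are
exercised with constructed gapped fixtures instead), among-site rate
variation beyond the region blocks, base-composition bias, chimeras,
and uneven taxon sampling. Passing tests therefore demonstrate the
pipeline's correctness and calibration under its own model assumptions,
not robustness to those real-data artifacts.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
the complete battery finishes in minutes: the $\gamma$ null on 1000
Yule trees of 50 tips; tempo recovery on 100 trees per warp; the
clustering oracle on 200 random matrices up to $n = 12$; region-slope
recovery on 20 replicates of 30 taxa × 5000 columns; structure
recovery on trees up to 20 tips. At these sizes the Monte-Carlo bands
used (e.g. null mean within ±0.1, sd within ±1.0 ± 0.1) have
comfortable margins.

## Known limitations

- The pure-R agglomerator is $O(n^2)$ per merge; it is comfortable to a
  few thousand sequences per group but was not built for
  hundred-thousand-sequence HTS datasets.
- Jukes–Cantor only; K2P/GTR distances, and likelihood distances, are
  out of scope.
- $\gamma$ inherits its known sensitivities: incomplete taxon sampling
  biases it negative ("push of the past"), and only-surviving-lineage
  conditioning biases recent rates upward ("pull of the present");
  the package computes the statistic, it does not correct for
  sampling.
- The ultrametric transform is a smoothing, not a dating method; node
  times are not calibrated ages.
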