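# protistdiv

Clustering patterns and phylogenetic structure of marine microeukaryote
18S rDNA.

## The problem

Environmental 18S rDNA surveys of marine plankton recover thousands of
sequences spread over dozens of eukaryotic lineages — classical taxa
(classes such as Dinophyceae or Chrysophyceae) alongside "ribogroups"
known only from molecular data (MALV and MAST clades, RAD groups).
Comparing these groups requires more than counting sequences: how much
genetic distance does each group span, how fast do its OTU numbers
collapse as the clustering cutoff grows, and did its lineages diversify
early, late, or at a constant rate? `protistdiv` implements this
characterization as a tested R pipeline, for microbial ecologists and
molecular evolutionists working with per-group alignments and rooted
phylogenies.

## What it computes

**Distances and OTUs.** From a gapped alignment, pairwise distances are
computed under the Jukes–Cantor model with pairwise deletion,

d = −(3/4) · ln(1 − 4p/3),

where p is the proportion of differing sites among columns where both
sequences have an unambiguous base. Sequences are clustered into OTUs by
furthest-neighbor (complete-linkage) agglomeration on a 1/10 000
distance grid, and each group is summarized by

- **Avg** and **Max** — mean and maximum pairwise distance;
- **Max_c** (maximum corrected distance) — the smallest cutoff at which
  90% of the group's sequences fall into a single OTU, a robust
  alternative to Max when a single divergent (or error-ridden) sequence
  inflates it;
- **OTU counts** at cutoffs 0 / 0.01 / 0.05 / 0.10, and the **clustering
  pattern**: counts expressed as percentages of the count at distance 0.

**Region calibration.** Partial-gene distance matrices (e.g. the V4–V5
or V9 hypervariable regions, located by degenerate IUPAC primers) are
regressed on full-gene distances; the slope m says by what factor the
region over- or under-states whole-gene divergence, and the Pearson R
how reliably.

**Phylogenetic structure.** Group clades extracted from a rooted tree
are transformed to ultrametric by mean-path-length smoothing and
summarized by standardized lineage-through-time (LTT) curves (relative
time −1…0, lineages as % of present), the Pybus–Harvey γ statistic with
a one-tailed test of the constant-rate null (γ < 0: early cladogenesis;
γ > 0: late), the mean phylogenetic distance (MPD) within each group,
the **trunk** (stem branch) length subtending each monophyletic group,
and mean intergroup patristic distances.

**Synthetic data.** A generator produces Yule trees, time-warped trees
with controlled cladogenesis tempo, Jukes–Cantor alignments with
region-specific rate multipliers, and multi-group fixtures with known
trunk lengths — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(protistdiv)

aln <- group_alignment(
  rows  = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA",
            "ACGAACGAACGTACGTACGT", "ACGAACGAACGAACGAACGA"),
  names = c("s1", "s2", "s3", "s4"),
  group_id = "demo")
m <- distance_matrix(aln)
round(m$d, 4)
#>        s1     s2     s3     s4
#> s1 0.0000 0.0517 0.1073 0.3041
#> s2 0.0517 0.0000 0.1674 0.2326
#> s3 0.1073 0.1674 0.0000 0.1674
#> s4 0.3041 0.2326 0.1674 0.0000

group_diversity(m, group_id = "demo")
#> Group 'demo': 4 seqs, Avg 0.1718, Max 0.3041, Max_c 0.3041
#>   OTUs: 0.00=4, 0.01=4, 0.05=4, 0.10=3
```

All four sequences stay distinct up to cutoff 0.05 (every pairwise
distance exceeds 0.05 once corrected), and only at 0.10 do s1/s2 merge —
the clustering pattern is 100/100/100/75% of the OTUs at distance 0.
Max_c equals Max here because 90% of 4 sequences means all four.

On the tree side:

```r
st <- structured_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
gamma_statistic(st)
#> gamma = -0.3464 (n = 3, one-tailed p = 0.365)
ltt_curve(st)$points
#>   relative_time lineage_percent
#> 1          -1.0        66.66667
#> 2          -0.5       100.00000
#> 3           0.0       100.00000
```

Two of the three lineages already exist at the root (67%), the third
appears halfway (relative time −0.5): a mildly early pattern, not
distinguishable from constant-rate at n = 3 (p = 0.37).

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a synthetic
dataset and write their tables under `results/`:

1. `analysis/01_simulate_fixture.R` — builds five monophyletic groups
   (40/25/15/10/10 tips) with known trunks, early/constant/late tempo,
   and 1800-column alignments with faster V4–V5/V9-like regions.
2. `analysis/02_region_calibration.R` — region-vs-full-gene regressions.
3. `analysis/03_otu_diversity.R` — the group report and clustering
   patterns.
4. `analysis/04_phylo_structure.R` — γ classification, LTT curves, MPD,
   trunks, and intergroup distances.

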