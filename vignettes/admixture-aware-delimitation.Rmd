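---
title: "Admixture-aware species delimitation: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture-aware species delimitation: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(admixdelim)
```

admixdelim delimits candidate species from target-capture phylogenomic data
in systems where gene flow is pervasive: recently radiated groups in which
mitochondrially defined lineages hybridize at contact zones, mitochondrial
genomes are occasionally captured across species boundaries, and concatenated
phylogenies are visibly distorted by admixed individuals. This vignette is
the package's own account of the models it fits, the parameters that matter,
and the places where the design was genuinely open.

## The analysis in one paragraph

Phased per-locus alignments are trimmed (haplotypes with >80% missing data or
>5% ambiguous bases removed; individuals with >50% missing data excluded from
SNP-based analyses but retained for tree building), biallelic SNPs with <20%
missing data are extracted per clade with singletons removed, and individual
ancestry coefficients are estimated by regularized nonnegative matrix
factorization with held-out cross-entropy used to choose both the
regularization weight and the number of clusters K. Individuals with more
than 20% ancestry from a secondary cluster are classified as hybrids
(10–20%: "notable"; maximum ancestry ≤ 0.8: "highly admixed"; many small
contributions: "streaks"). Gene flow between candidate species is quantified
with Patterson's D, f4-ratio admixture fractions and the tree-aware f-branch
matrix, all with block-jackknife significance over loci. A rule engine turns
clusters, tree monophyly and hybrid calls into a candidate table (lump /
split / lineage / hybrid-flagged), and two distortion statistics quantify how
admixture degrades the concatenated tree: terminal gene-concordance factors
versus maximum individual ancestry, and PDA-normalized Colless imbalance of
candidate subtrees versus the standard deviation of members' maximum
ancestry.

## The ancestry model

The estimator factorizes the one-hot expanded genotype matrix: each site
contributes three indicator columns (genotype 0/1/2), missing genotypes are
all-zero and excluded from the loss, and

$$\min_{Q, G}\; \lVert X - QG \rVert_F^2 + \alpha \lVert Q \rVert_F^2$$

subject to each row of $Q$ (a specimen's ancestry coefficients over $K$
clusters) lying on the probability simplex and each per-site 3-column block
of $G$ (cluster-specific genotype-class frequencies) likewise. Optimization
is alternating ridge least squares followed by Euclidean simplex projection;
a backtracking damping step guarantees the observed-entry objective never
increases, and missing or held-out entries are imputed with the current
reconstruction each iteration (an EM-style completion).

Model choice follows the cross-entropy protocol: a fraction of non-missing
genotypes (default 5%, the cited method's default; the masking fraction is
exposed in `fit_snmf()`) is masked before fitting, and
$\mathrm{CE} = -\overline{\log P(\text{observed genotype})}$ over the masked
entries scores the model. `select_alpha()` scans
$\alpha \in \{1, 5, 10, 50, 100, 500, 1000\}$ and takes the minimizer of the
median CE across replicates (ties break toward the smallest weight — the
least interference with $Q$). `select_K()` first looks for an elbow (the
largest positive second difference of the median-CE curve where the curve is
still decreasing); when no elbow forms it falls back to the boxplot notch
rule, taking the smallest K whose notch interval
($\mathrm{median} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$, the standard
approximation of a 95% interval for the median) separates from K−1 while
K+1's overlaps. If neither rule fires the argmin is returned with an
explicit `no_elbow` flag rather than a silent choice.

Hybrid thresholds are deliberately simple and exposed: secondary ancestry
> 0.20 → hybrid; (0.10, 0.20] → notable; maximum ancestry ≤ 0.8 → highly
admixed (an orthogonal flag, since it co-occurs with the hybrid class); minor
ancestry totalling ≥ 0.10 spread over ≥ 3 clusters each < 0.10 → streak.
Cluster labels are matched to a-priori populations by the best permutation of
mean per-population ancestry (exhaustive for K ≤ 8, greedy above).

## Introgression statistics

`patterson_d()` uses population allele frequencies polarized by an outgroup:
$\mathrm{ABBA} = \sum (1-p_1)p_2 p_3 (1-p_4)$ and
$D = (\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+\mathrm{BABA})$, with a
delete-one block jackknife over loci for the standard error (loci are the
natural linkage blocks in target-capture data; within-locus linkage violates
site independence). P1/P2 are oriented so $D \ge 0$ by convention, with the
swap recorded. Two practical constraints matter and are enforced by the
package rather than left to the user:

* **Trios must be tree-consistent.** `tree_consistent_trio()` arranges each
  trio so the sister pair occupies P1/P2. Testing arbitrary orderings
  confounds topology with gene flow and produces enormous spurious Z scores.
* **Polarization needs a genuine outgroup.** Polarizing by a population
  inside the radiation biases every trio that contains its relatives; the
  study-shaped simulation model therefore offers a basal outgroup
  population, mirroring the use of the earliest-diverging clade for rooting
  in this kind of analysis.

`f4_ratio()` estimates the admixture fraction as
$\hat f = S(A,B,C_a,O)/S(A,C_b,C_a,O)$ with the donor's haplotypes split at
random into halves per site (a hypergeometric draw from the allele counts);
reusing one sample for both donor positions would bias the denominator by
$p_3^2$. Estimates are clamped to $[0,1]$ with the raw value retained.
`f_branch()` assigns excess sharing to (branch, donor) pairs:
$f_b(C) = \mathrm{median}_{A \in \mathrm{sister}(b)}\,
\min_{B \in \mathrm{desc}(b)} \hat f(A,B,C)$, with donors inside the
recipient clade structurally masked, negative medians clamped to zero, and
jackknife p-values composed from the per-trio delete-one-block estimates.
Display follows the convention of showing a cell only when $f_b > 0.20$ and
p < 0.05; the full matrix is always retained.

**Directionality is genuinely ambiguous.** With a heavily admixed recipient,
"reverse" cells — rows on the donor's side of the tree with the recipient as
the donor column — are structurally inflated, because admixture shrinks the
recipient's allele-frequency variance and that variance sits in the f4-ratio
denominator. The package's localization test therefore uses the identifiable
regime (an isolated, deeply diverged donor lineage and a recipient flanked by
an equidistant cherry); in other geometries the matrix maximum can land on
the reverse cell, which is the same ambiguity that leads analyses of real
data to remain agnostic about direction.

## Concordance, imbalance and distortion

`gene_concordance()` computes, for every internal branch, the percentage of
decisive gene trees (those with at least one taxon in each of the branch's
four adjacent clades) whose taxon-restricted splits contain the branch's
bipartition; branches with no decisive tree are `NA` with a flag, never
silently zero. `site_concordance()` samples quartets (default 100 per
branch) and averages the percentage of decisive sites (two states, two taxa
each) supporting the branch. `terminal_gcf()` reports the gCF of the branch
immediately ancestral to each specimen's terminal edge; specimens in a
cherry share that branch and thus duplicate values by design.

`colless()` is the raw imbalance sum $I = \sum_v |L_v - R_v|$ over internal
nodes. The normalization divides by $n^{3/2}$, the scaling of the expected
index under the proportional-to-distinguishable-arrangements null — the
appropriate null at phylogeographic depth where a Yule process is not
credible; `normalization = "max"` (caterpillar maximum $(n-1)(n-2)/2$) is
available as a switch. Polytomies are rejected rather than silently
resolved; `resolve_polytomies()` exists for callers who want a seeded random
resolution.

The two distortion statistics tie these together. `gcf_vs_ancestry()` tests
the constraining, triangular relationship between a specimen's maximum
ancestry and its terminal gCF: q_max is cut into ten equal-width bins, the
bin maxima are tested for a nondecreasing trend (one-sided Spearman), and
the plain Pearson correlation is reported alongside.
`imbalance_vs_admixture()` regresses PDA-normalized subtree imbalance on the
standard deviation of members' maximum ancestry (zero when all members are
pure parentals), excluding single-specimen candidates and subtrees with
fewer than three tips; raw SD is used, untransformed. `rootward_shift()`
compares hybrids against pure conspecifics by divergence rank — the number
of nodes between the candidate's crown and each member's attachment point —
measured on the candidate's *induced* subtree, so a hybrid pulled outside
the candidate's core registers as basal; node-count ranks are preferred to
substitution depth for robustness to rate variation, and terminal branch
lengths are compared separately (hybrids accumulate conspicuously long
terminal branches, often the strongest single signal).

## The delimitation rubric

`delimit()` is deterministic and ordered. Reciprocal monophyly of
geographically distinct clusters is the strongest evidence: such clusters
become candidate species (`split` when they subdivide a prior candidate).
Prior candidates collapsed into a single cluster and not reciprocally
monophyletic are lumped under a joined name. Clusters distinct in ancestry
but non-monophyletic, with at least 10% of the enclosing candidate's members
hybrid-classified (the threshold is exposed; the source analyses leave it
qualitative), become phylogeographic lineages within the enclosing
candidate. Candidates none of whose members reaches 50% single-source
ancestry are flagged as putative hybrid clusters. A cluster spanning
disjoint monophyletic prior clades with neither monophyly nor admixture
evidence is reported `unresolved`, never silently assigned. "Geographically
distinct" is an input column: geography is qualitative context here, not a
computed quantity.

## The synthetic-data generators

Two tiers, matching which assumptions each downstream stage actually uses.

The **frequency tier** is Balding–Nichols: ancestral frequencies
$p \sim \mathrm{Uniform}(0.05, 0.95)$, population frequencies
$p_k \sim \mathrm{Beta}(p(1-F_k)/F_k,\,(1-p)(1-F_k)/F_k)$ so that
$\mathrm{Var}(p_k) = F_k\,p(1-p)$, genotypes
$g \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$. The star model backs
the ancestry-estimation tests. The tree-structured variant drifts
frequencies segment-wise along the population tree with
$F = 1 - e^{-0.1\,\Delta t}$ per segment; the 0.1 scale keeps compounded
drift quasi-additive, the regime in which f4-type statistics are consistent
estimators (with saturating drift the ratios distort badly). Pulse events
mix the recipient's frequency with the donor lineage's frequency *at the
pulse point* — the segment-wise simulation exists precisely so that the
introgressed material shares all drift above the pulse with the donor's
sampled frequencies.

The **coalescent tier** simulates gene trees under the multispecies
coalescent on the population tree (exponential within-branch coalescence,
pairwise rate 1), with pulse events rerouting recipient-branch lineages to
the donor with probability a, hybrid individuals implemented by per-locus
haplotype routing (F1: one haplotype per parent; BC1: second haplotype a
coin flip; clinal: both haplotypes Bernoulli at the target fraction), and
Jukes–Cantor sequences via standard phylogenetic simulation machinery.
Missingness is missing-completely-at-random by default with a per-individual
"degraded specimen" mode; ambiguity codes are injected at a configurable
rate; a maternal locus can be captured from a donor population (carriers
receive one donor-derived haplotype carrying shared post-capture
substitutions plus a little private variation, so they form their own clade
nested in the donor lineage).

The default study-shaped scenario is a quarter-scale analogue of a large
target-capture radiation: 12 populations in 3 clades of 4, 60 loci of 2 kb,
8 diploids per population, with an optional basal outgroup. Fixed seeds give
byte-identical datasets, and the emitted genotype matrix is recomputable
from the emitted alignments.

What the generators do **not** emulate: within-locus recombination,
selection, realistic growth/decline demography beyond pulses, base-calling
error structure, or spatially explicit clines. Tests passing on these data
show the statistics behave correctly under their own model assumptions; they
cannot show robustness to, e.g., intralocus recombination or alignment
error in real data.

## Problem sizes and numerical choices

The shipped experiments are sized for a desk machine: the null-calibration
runs use the 12-population model with 60 loci (100 tree-consistent trios for
D; 20 replicates for the f-branch null), estimator-consistency runs use
2×10⁴–5×10⁴ frequency-tier sites, ancestry recovery uses 60 individuals ×
5000 SNPs with K selection repeated over 20 seeds, and the distortion
experiment uses 24 candidate species × 6 structured members × 30 loci of
500 bp over 20 replicates. Numerical details worth knowing: NMF convergence
is declared at a relative loss change below 1e−6 (cap 200 iterations, best
iterate returned with a flag on non-convergence); genotype probabilities are
clipped to [1e−10, 1] before logs; NJ ties are broken by sorting taxa
labels, and negative NJ branch lengths are clamped to zero with the length
transferred to the adjacent branches below so path lengths are preserved;
f-branch's donor haplotype splits are seeded per donor; the f4-ratio
denominator guard flags non-positive denominators as undefined rather than
returning a sign-flipped ratio.

## Known limitations

The NJ builder is a stand-in: the intended primary input is an externally
estimated ML topology in Newick, and every downstream operation is agnostic
to how the tree was inferred. The ancestry model assumes unlinked biallelic
SNPs; linked sites within loci will overstate confidence (the jackknife in
the D/f-branch statistics accounts for linkage, the NMF does not). f-branch
cannot determine the direction of gene flow outside the identifiable regime
described above, and cannot separate ghost admixture from admixture with a
sampled relative of the ghost. The delimitation rubric encodes the source
analyses' qualitative rules; it is a transparent bookkeeping device, not a
model-based delimitation method, and its thresholds (hybrid fraction 0.10,
majority-ancestry 0.5) are exposed for sensitivity analysis.
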