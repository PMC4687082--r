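---
title: "Detecting spatial and metabolic clustering of horizontal gene transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatial and metabolic clustering of horizontal gene transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtclust)
```

## The question

Prokaryotic genomes acquire DNA horizontally, and the physical mechanisms of
transfer (transformation, transduction, conjugation) move stretches of DNA
that frequently span more than one gene. If several neighbouring genes are
taken up and integrated together, recently transferred genes should sit
closer to each other along the recipient chromosome than randomly chosen
genes. Likewise, a gene whose product is useless without a partner enzyme is
unlikely to be retained unless the partner arrives with it, so transferred
genes should also be enriched for functional (here: metabolic) coupling.

hgtclust quantifies both effects for any set of candidate transfers: it
computes an observed count of "clustered" candidate pairs, an analytic null
expectation under no association, their ratio (the clustering score
*CC*), and a one-sided permutation p-value. Because better candidate sets
(fewer false positives) cluster more strongly, the same machinery doubles as
a benchmark that ranks competing HGT-detection methods or parameter
settings, with the caveat that it probes specificity, not sensitivity — set
sizes are always reported alongside.

## Inferring recent transfers by generalized parsimony

Input is a gene-family presence/absence matrix over the tips of a rooted
phylogeny that represents vertical inheritance. For each family the
minimum-cost explanation of its phyletic pattern in terms of gains
(cost $P_g$) and losses (cost $P_l$) is found by Sankoff's dynamic
programme over the tree; both states are free at the root, so presence in
the ancestor is never charged as a gain. Two penalty conventions are used
side by side:

* $P_g/P_l = 1$ — gains and losses balance, as expected if genome sizes are
  roughly constant over time; the looser candidate set (`terminal.pen1`
  analogue).
* $P_g/P_l = 2$ — gains doubly penalized; stricter, fewer false positives,
  at the cost of false negatives (`terminal.pen2` analogue).

Among equally parsimonious reconstructions the DELTRAN (delayed
transformation) rule is applied: during the root-to-tip assignment pass an
ambiguous node inherits its parent's state, pushing changes as close to the
tips as possible. Two conventions needed fixing where the literature is
silent, and both are deliberate, documented choices:

* A cost tie *at the root* is broken toward absence, which again pushes
  gains tipward. On a four-tip tree `((A,B),(C,D))` with the family present
  only in A and $P_g/P_l = 2$, a terminal gain on A ties a loss-based
  scenario at cost 2; the convention selects the terminal gain. This case
  is convention-dependent and is flagged as such in the tests.
* A basal polytomy is read as the Newick convention for an unrooted tree
  and rejected (the gain/loss asymmetry makes the root position material);
  polytomies anywhere else are handled natively by the Sankoff recursion.

Only gains on *terminal* branches become HGT candidates — the most recent,
hence most reliably inferred events. Conservative exclusions: "singleton"
genes (no ortholog in any other analysed genome, prone to annotation
artifacts) are never labelled as transferred, and plasmid replicons can be
dropped entirely. Tree tips without a matrix column (outgroups kept for
rooting) are treated as lacking every family; candidates are only emitted
for genomes in the matrix.

## The spatial statistic

Let a genome carry $n$ genes, $c$ of them candidates, with $H_i = 1$
marking candidates. Gene $i$ scores $C_i = 1$ when $H_i = 1$ and at least
one of its $w$ nearest right-hand neighbours is also a candidate; the
statistic is $\mathrm{Count} = \sum_i C_i$. The default window $w = 3$ (at
most two intervening genes) stays within the length of ~90 % of *E. coli*
operons and partly absorbs rearrangements after insertion. Counting only
right-hand windows avoids double-counting; the count is provably invariant
under sequence reversal.

Under uniform placement of the $c$ candidates the expectation decomposes
by the distance $d$ to the nearest next candidate:

$$
E(\mathrm{Count}) \;=\; \sum_{d=1}^{w} N_d \,\frac{c}{n}
\left[\prod_{j=1}^{d-1}\frac{n-c-j+1}{n-j}\right]\frac{c-1}{n-d},
$$

with $N_d = n-d$ eligible positions on a linear sequence and $N_d = n$ on a
circle. At $w = 3$, linear, this is the familiar three-term product formula.
The linear form is the default because it matches the published convention,
even though bacterial chromosomes are circular; `topology = "circular"` is
provided, and for realistic $n \gg w$ the difference is negligible. The
formula is exact, not asymptotic: the test suite checks it against
exhaustive enumeration of all $\binom{n}{c}$ placements for every
$n \le 12$, $c \le n$, $w \in \{1,2,3\}$ at $10^{-12}$ relative tolerance.

**Gap handling.** Unexamined genes (singletons, excluded genes) occupy
chromosomal positions and thus separate examined genes. The default
`gap_mode = "paper"` computes expectation and randomizations as if the
examined genes were contiguous, while the observed count runs over the real
layout; the expectation is therefore biased upward and both *CC* and the
p-value are conservative. `gap_mode = "exact"` is the statistically faithful
alternative: candidates are redistributed only over examined positions of
the actual layout, and the expectation is taken as the mean randomized
count.

## The metabolic statistic

For one genome with a curated metabolic reconstruction, the input is the
list of *fully coupled* gene pairs — pairs whose reactions carry
proportional fluxes, so each gene is functionally dependent on the other —
plus the universe of $n$ network genes. With $L_1$ coupled pairs, the prior
coupling probability is $p_1 = L_1 / \binom{n}{2}$, and a candidate set of
$n_2$ network genes has null expectation $p_1 \binom{n_2}{2}$ coupled
pairs. The permutation null redraws $n_2$ genes uniformly from the
universe with the graph topology fixed. Candidates absent from the
universe are dropped from $n_2$ (with a message), since the null only
redistributes status within the network.

## Scores and p-values

$CC = \mathrm{observed}/\mathrm{expected}$; $CC \gg 1$ means clustering.
When the expectation is zero the ratio is undefined: `Inf` with a warning
if pairs were observed anyway, `NA` otherwise. p-values are one-sided
(enrichment) permutation tests,

$$p = \frac{r + 1}{R + 1},$$

where $r$ counts randomizations whose statistic is at least the observed
value; the "+1" terms account for the observation itself, so the smallest
attainable p is exactly $1/(R+1)$ and $p = 1$ whenever every randomization
matches or beats the observation. Spatial randomization conserves each
genome's candidate count exactly and permutes over exactly the genomes in
the candidate set's universe; no multiple-testing correction is applied
across candidate sets, matching the reporting convention the scores come
from. All randomness flows from one seed through per-genome substreams
derived from (seed, genome id), so results do not depend on genome
iteration order and reports are byte-identical across reruns.

## What the synthetic generator emulates — and what it does not

The generators produce data in the regime of the real analyses (tens of
genome tips; 2,000–4,500 genes per genome; ~5 % terminal-branch candidates;
a coupling network of 4,242 genes with 701 coupled pairs):

* `simulate_genome_blocks()` plants non-overlapping candidate blocks
  (operon-like lengths 2–4, or length 1 for independent insertions) at
  uniform positions, and can flag a fraction of other genes as singletons.
  Defaults: 5 % candidates, 10 % singletons.
* `simulate_family_evolution()` evolves families on a tree: present at the
  root, lost per branch with probability `loss_rate` (default 0.02, no
  regain), with `terminal_gain_count` new single-tip families per terminal
  branch, inserted contiguously in blocks. Every event is logged, so the
  matrix is exactly reconstructable from the log. Gains are terminal-only
  by default because only terminal events are scored downstream;
  `internal_gain_count` exercises false-negative behaviour.
* `simulate_coupling_network()` samples $L_1$ distinct pairs; planted
  enrichment fills disjoint fully-coupled modules and draws a stated
  fraction of candidates from them.

The generator is a stated world, not a tuning knob: a green calibration or
power test establishes that the statistics behave correctly *under this
model* — uniform insertion positions, independent losses, no insertion
hotspots, no compositional signal, no post-insertion rearrangement beyond
what the window absorbs. Real genomes violate several of these (rearranged
blocks, integration hotspots, biased gene content), which is precisely why
the observed-score machinery reports conservative p-values rather than
model-based ones.

## Numerical and design choices

* Gene positions are 0-based contiguous indices per replicon internally;
  published 1-based formulas are translated once at the boundary.
* GFF3 gene order sorts by start coordinate, ties by end then feature id —
  deterministic and invariant to input line order. Plasmids are identified
  only by explicit flags or replicon-id lists, never heuristics.
* Genomes with several replicons: the gap-free null concatenates the
  genome's examined genes into one sequence (candidate counts are conserved
  per genome); exact mode works on the true per-replicon layouts.
* Counting is done on sorted candidate positions (a candidate qualifies iff
  its successor lies within $w$), which is $O(c)$ per randomization and
  exactly equivalent to scanning the flag sequence.
* Reports serialize numbers at 17 significant digits; the JSON round-trip
  is bit-identical.
* Expectation terms use a running product with the numerator clamped at
  zero, so $c$ close to $n$ cannot produce negative factors, and the sum is
  truncated at $d \le \min(w, n-1)$ for very short replicons.

## Known limitations

* Parsimony, not probabilistic inference: no rate estimation, no posterior
  probabilities; the penalty ratio is declared a priori. This is the
  intended, assumption-light design — probabilistic methods presuppose
  rate constancy that bursty HGT violates — but it caps what the candidate
  sets can express.
* The spatial null assumes insertions are uniform over positions. Strong
  integration hotspots would inflate *CC* without co-transfer; the score
  cannot distinguish the two mechanisms, only document the clustering.
* Expected values printed by upstream sources for a coupling network are
  consumed as given when reproducing score arithmetic, but the package
  always recomputes expectations from $(n, L_1, n_2)$ with the formula
  above.
* DELTRAN tie conventions at the root differ between implementations in
  the literature; the flagged four-tip example documents where this
  matters.

## A worked example

```{r, eval = FALSE}
library(hgtclust)
data <- simulate_paper_scale(n_tips = 10, n_root_families = 1000,
                             terminal_gain_count = 50, seed = 1)
out <- run_pipeline(data$orders, data$matrix, data$tree,
                    penalty_ratios = c(1, 2),
                    network = data$network,
                    network_genome = data$network_genome,
                    spatial = spatial_config(n_randomizations = 199,
                                             seed = 1),
                    metabolic = metabolic_config(199, 1))
out$report
benchmark_sets(out$results)
```

Planted length-3 blocks at 5 % candidate density give spatial *CC* around
4 with $p = 1/(R+1)$, while the metabolic score stays near or below 1 —
the generator plants spatial, not metabolic, structure unless module
enrichment is requested explicitly.
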