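# hgtclust

Do recently transferred genes cluster — along the chromosome, and in the
metabolic network?

Horizontal gene transfer in prokaryotes often moves more than one gene at a
time: a transferred stretch of DNA can carry several neighbouring genes
(frequently a partial or complete operon), and genes that depend on each
other functionally have better odds of being retained when they arrive
together. `hgtclust` is an R package for microbial comparative genomicists
that (i) infers recent horizontal gene transfers from gene-family
presence/absence patterns on a phylogeny, (ii) quantifies how strongly a
candidate set clusters spatially and metabolically, and (iii) uses that
clustering strength as a benchmark to compare HGT-detection methods or
parameter settings against each other.

## The statistics

**Inference.** For each gene family, the phyletic (presence/absence)
pattern across genome tips is explained by minimum-cost gain/loss events on
a rooted tree (Sankoff generalized parsimony; gain cost *P<sub>g</sub>*,
loss cost *P<sub>l</sub>*, both root states free), with DELTRAN resolution
of ties. Gains on terminal branches — the most recent, most reliable events
— become HGT candidates; one candidate set per penalty ratio
(*P<sub>g</sub>/P<sub>l</sub>* = 1 and 2 by default, a looser and a stricter
set). Singletons and plasmid-borne genes are conservatively excluded.

**Spatial clustering.** Gene *i* scores when it is a candidate and at least
one of its *w* = 3 nearest right-hand neighbours is too; summing gives
Count. Under uniform placement of *c* candidates among *n* genes,

E(Count) = Σ<sub>d=1..w</sub> (n−d) · (c/n) ·
Π<sub>j&lt;d</sub> [(n−c−j+1)/(n−j)] · (c−1)/(n−d),

exact for every n, c, w (verified by exhaustive enumeration in the tests).

**Metabolic clustering.** With *L₁* fully flux-coupled gene pairs among *n*
network genes, a candidate set of *n₂* genes has null expectation
p₁ · n₂(n₂−1)/2, where p₁ = L₁/(n(n−1)/2).

**Scores.** CC = observed/expected; permutation p = (r+1)/(R+1), one-sided,
with per-genome candidate counts conserved and the network topology fixed.

## Worked example

Simulate a known world — 10 genomes of ~2,000 genes, 50 transfers per
terminal branch inserted in blocks of 3 — then infer and score:

```r
library(hgtclust)
data <- simulate_paper_scale(n_tips = 10, n_root_families = 1000,
                             terminal_gain_count = 50, seed = 1)
out <- run_pipeline(data$orders, data$matrix, data$tree,
                    penalty_ratios = c(1, 2),
                    network = data$network, network_genome = data$network_genome,
                    spatial = spatial_config(n_randomizations = 199, seed = 1),
                    metabolic = metabolic_config(199, 1))
out$report
```

```
                             set_name statistic n_candidates observed  expected        cc p_value
terminal.pen1.spatial   terminal.pen1   spatial          509      345 81.565926 4.2297074   0.005
terminal.pen1.metabolic terminal.pen1 metabolic           53        2  2.320233 0.8619824   0.660
terminal.pen2.spatial   terminal.pen2   spatial          502      344 79.381097 4.3335254   0.005
terminal.pen2.metabolic terminal.pen2 metabolic           50        1  2.062616 0.4848211   0.865
```

Read: the planted co-transferred blocks produce ~4.2× more neighbouring
candidate pairs than the no-association null (345 observed vs 81.6
expected), at the smallest p the 199 randomizations allow (1/200 = 0.005).
The metabolic score sits near 1 with large p — correctly, because this
simulation plants spatial but not metabolic structure. `benchmark_sets()`
ranks the two candidate sets by spatial CC with their sizes as the explicit
sensitivity caveat.

A command-line wrapper with subcommands (`infer-hgt`, `spatial`,
`metabolic`, `simulate`, `run`, `benchmark`) lives at
`inst/cli/hgtclust.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hgtclust.R",package="hgtclust"))')" \
    simulate --tips 5 --seed 3 --outdir sim
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— simulating a seeded synthetic dataset, inferring candidate sets at both
penalty ratios, and scoring spatial and metabolic clustering — and writes
its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
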