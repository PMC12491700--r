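---
title: "Multi-omics-led, network-driven target prioritisation with omniTarget"
author: "omniTarget authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics-led, network-driven target prioritisation with omniTarget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omniTarget)
```

# The model

omniTarget implements a therapeutic-target prioritisation framework grounded
in the omnigenic view of complex disease: a small set of *core* genes carries
direct multi-omic evidence (GWAS association, expression/protein QTLs,
promoter-capture chromatin contacts), while *peripheral* genes matter through
their network connectivity to core genes.  The pipeline has two stages:
per-predictor evidence scores are first propagated over a protein-interaction
network, and the propagated predictors are then combined meta-analytically
into a single 0–10 priority rating per gene.

## SNP and core-gene scoring

Each SNP is scored against the genome-wide significance threshold
$T$ (default $5\times10^{-8}$), weighted by its linkage disequilibrium with
the lead SNP:

$$S_{SNP} = R^2\left[\log_{10}\frac{1-P}{P} - \log_{10}\frac{1-T}{T}\right].$$

A SNP exactly at the threshold scores zero, as does one with $R^2 = 0$.
LD proxies with $P > T$ would score negative; they are clamped to zero
because SNP scores seed a random walk and must be non-negative.  $P = 0$ is
rejected as an upstream data error rather than clamped.

Core genes collect SNP scores through three predictors:

* **proximity** — the maximum $S_{SNP}$ over SNPs within 20 kb of the gene
  body (1-based closed intervals; the window is anchored on the full gene
  interval, not the TSS);
* **qtl** and **conformation** — each SNP–gene link of strength $s$ (a QTL
  association P-value, or a chromatin-interaction strength) contributes
  $S_{SNP}\cdot \mathrm{eCDF}(-\log_{10} s)$, and the gene keeps the maximum
  contribution.  The eCDF is right-continuous
  ($\mathrm{eCDF}(x) = \#\{x' \le x\}/n$) so the strongest link in a table
  receives weight 1, and it is estimated per evidence table so that each
  predictor is self-contained.

The maximum scoring scheme makes all gene scores idempotent under duplicated
evidence rows.

## Network propagation

Peripheral genes acquire affinity by random walk with restart over the
interaction network,

$$\vec P_{t+1} = (1-\gamma)\,A\,\vec P_t + \gamma\,\vec P_0,$$

where $\vec P_0$ holds the (normalised) seed gene scores and $\gamma$ is the
restart probability (default 0.3).  "Normalised adjacency" is ambiguous
between the symmetric $D^{-1/2}WD^{-1/2}$ operator and the column-stochastic
$WD^{-1}$; both are implemented (plus row-stochastic), with symmetric as the
default and column-stochastic available when strict probability semantics
(exact mass conservation) are wanted.  Iteration stops when the L1 change
drops below $10^{-6}$ (cap 10 000 iterations); the fixed point equals the
direct solve of $(I-(1-\gamma)A)\,p=\gamma \vec P_0$, which the tests use as
an independent oracle.  Seeds are weighted by their scores, not binarised.
One walk per predictor yields the gene × predictor affinity matrix; each
column is rescaled to sum to one.

## Meta-analytic combination and ratings

Within each predictor column, affinities become P-like values through the
*complementary* empirical CDF, $P_{ij} = \#\{AF \ge AF_{ij}\}/K$, so the
top-affinity gene gets $1/K$.  (The literal forward eCDF would hand the best
genes $P \approx 1$ and invert every downstream ranking; the complementary
direction is required for "higher rating = higher priority".)  Cells with
zero affinity are non-informative; each gene combines only its $J \ge 1$
informative predictors:

* **Fisher**: $x=-2\sum\ln P$, upper tail of $\chi^2(2J)$;
* **logit** (Mudholkar–George): $x = -\sum\ln\frac{P}{1-P}
  \sqrt{3(5J+4)/(J\pi^2(5J+2))}$, upper tail of $t(5J+4)$ — boundary values
  $P=1$ are clipped to $1-10^{-6}$ since the logit is undefined there;
* **order statistic** (default): the largest order statistic against the
  lower tail of $\mathrm{Beta}(J,1)$, i.e. $CP = P_{(J)}^J$; a generalised
  mode refers the $k$-th order statistic to $\mathrm{Beta}(k, J-k+1)$.

In every case the "CDF" is read as the significance tail, so that
$-\log CP$ grows with evidence.  Combined P-values are carried in log space
(`pchisq(..., log.p = TRUE)` and friends), which keeps ratings exact even
when $CP$ underflows.  Ratings rescale $-\log CP$ to $[0,10]$ by min–max;
the rescaling is invariant to the logarithm base, and ranks break ties
lexicographically by gene id for reproducibility.

A practical note on the default: the max-order statistic is deliberately
conjunctive — a gene must look good under *all* its informative predictors —
which also makes it sensitive to a pure-noise predictor.  Fisher's method is
the robust choice when predictors of very different quality are mixed; the
leave-one-out harness (`leaveOneOut`) makes the comparison directly.

# Evaluation

Recovery of clinical proof-of-concept targets (genes with phase-III-or-later
drugs, supplied as a plain gene list) is quantified by the area under the
step curve of cumulative target recall versus normalised rank, truncated at
a configurable `top_fraction` and normalised so a perfect ranking scores
$\approx 1$ and a random one $0.5$.  With `top_fraction = 1` this is the
rank-AUC up to a finite-sample plateau term of order $m/n$.  The truncation
is configurable because the original construction is graphical; the
acceptance checks run at `top_fraction = 1`.

# The self-organising prioritisation map

Priority profiles (e.g. ratings in two diseases, $M=2$) are laid out on a
supra-hexagonal lattice of $r$ concentric rings ($3r^2-3r+1$ nodes; $r=5$
gives the 61-node map).  Sequential training picks the best-matching unit by
Euclidean distance and moves every codebook towards the input with a
Gaussian kernel on the lattice locations.

Two schedule decisions matter.  Codebooks are initialised deterministically
on the plane of the first two principal components (reproducible, and
standard practice for fast convergence).  Because that initialisation is
already close to the data, an aggressive high-learning-rate "rough" phase
would largely destroy it and can leave the final quantization error *above*
its initial value; the default schedule therefore uses a gentle organising
phase (learning rate 0.02→0.005, kernel width from about half the map radius
down to 0.4 over $10N$ updates) followed by a convergence phase
(0.05→0.01, width 0.3→0.05 over $20N$ updates) whose vanishing kernel makes
it an online k-means refinement.  Input order is reshuffled each pass under
the schedule seed, so training is deterministic given the seed.  Both phases
are plain data structures (`somSchedule`) the user can replace.

Map partitioning into topology-preserving clusters is not pinned down by the
original description; the package grows regions from U-matrix minima (nodes
whose mean codebook distance to lattice neighbours is locally minimal),
attaches the unassigned node closest to an adjacent region's mean, and
merges the most similar lattice-adjacent regions down to $k$.  Every cluster
is lattice-connected by construction.  Cluster enrichment reports the
one-sided hypergeometric P, a Z-score from the hypergeometric mean and
variance, the sample odds ratio (Haldane 0.5 correction when a cell is
empty) with Woolf logit 95% CI, and BH FDR across sets.

# Pathway crosstalk

Crosstalk discovery seeks a connected, acyclic subnetwork (a tree)
maximising total node prize minus scaled edge cost, with prizes the 0–10
ratings and costs $1-w/\max w$ floored at 0.01 (the cost construction is a
package choice; the original defines none).  The solver is a heuristic:
minimum-spanning and prize-biased spanning scaffolds are strong-pruned by an
$O(n)$ rerooting dynamic program that finds, over all roots, the best pruned
subtree.  On 200 random graphs of up to 12 nodes it stays within 10% of the
exact optimum computed by exhaustive enumeration (tests), and it never
returns less than the best single prize.  A desired crosstalk size is met by
bisecting on the cost scale $\lambda$ (tree size is non-increasing in
$\lambda$); when the exact size is unattainable the closest achievable size
is returned with a warning.

Significance is a degree-preserving permutation test: prizes are shuffled
within degree-quantile bins (default 10, merging bins of fewer than 2 nodes),
the search is re-run with identical settings, and
$P = (1+\#\{perm \ge obs\})/(1+n_{perm})$ with 100 permutations by default,
so the smallest attainable P is $1/101$.  The statistic is the tree
objective by default; the summed selected prize is available as an option
because the original text does not fix the statistic.

The pathway-centric view keeps pathways significantly over-represented among
crosstalk genes, sizes nodes by in-crosstalk member count, weights pathway
pairs by shared crosstalk members and retains only the maximum-weight
spanning forest of those edges.

# Crosstalk follow-ups

*Effect-by-removal*: the disconnected fraction after deleting a node set is
$1-|\text{largest remaining component}|/|V_{original}|$ — a removed node
counts as disconnected, so removing everything gives 1.  Combinatorial
removal enumerates candidate subsets up to `k_max` (guarded at $10^6$
subsets) and ranks them; the fraction is monotone under supersets.

*Drug repurposing*: a one-sided hypergeometric test of approved-drug-target
membership among crosstalk genes over a configurable universe (default: the
supplied gene universe), with the same OR/CI conventions as cluster
enrichment, plus a gene–drug–indication incidence table.

*Modules*: the crosstalk is decomposed by minimising the Reichardt–Bornholdt
Potts Hamiltonian
$H=-\sum_{i<j}(A_{ij}-\gamma p_{ij})\,\delta(\sigma_i,\sigma_j)$ with the
configuration-model null $p_{ij}=k_ik_j/2m$ and $\gamma=1$ (classic
modularity correspondence), via seeded single-spin-flip simulated annealing:
geometric cooling $T_0=1$, factor 0.99 per sweep, 200 sweeps, 20 restarts
keeping the best.  Components are decomposed independently and modules are
relabelled by size.  Each module is then enriched for pathways and for two
separate therapeutic families — approved drug targets (maximum phase in the
drug table) and non-approved phased targets — reported forest-plot-ready.

# The synthetic cohort

`genCohort` emulates the *shape* of the real inputs with planted truth: each
planted target owns a genome-wide-significant lead SNP
($P\sim10^{-U(9,20)}$) inside its 20 kb window with 1–3 LD proxies
($R^2\sim U(0.8,1)$), strong QTL/PCHi-C links ($s\sim10^{-U(6,12)}$), and
high-weight wiring to the other targets on a preferential-attachment
($m=2$) background network, whose heavy-tailed degrees exercise the
degree-binned permutation machinery.  Background loci carry marginally
significant leads ($10^{-U(8,9)}$) and weak links ($10^{-U(0.5,2)}$);
log-uniform draws span the $-\log_{10}$ scales the scoring consumes.
`signal_strength` interpolates every planted component towards the
background draw; crucially, at zero strength loci land on *random* genes, so
planted targets are statistically exchangeable with background and the
recovery area calibrates to 0.5.  `signal_predictors` restricts the signal
to chosen predictors (including the planted wiring, as `"network"`), which
is what the leave-one-out tests exercise.

`genPrizeGraph` plants a connected module as a breadth-first prefix of the
preferential-attachment graph and raises its internal edge weights without
adding edges — the module's degree sequence stays typical of the graph, so
degree-preserving permutation genuinely mixes module and background prizes.
Module prizes are background $U(0,1)$ plus `prize_gap`.

What the generator does **not** emulate: real LD structure (the $R^2$ values
are draws, not haplotypes), realistic pathway topology, gene-density
variation, or confounding between degree and evidence strength.  Passing the
planted-recovery tests therefore demonstrates that the machinery recovers
the signal it is pointed at under controlled conditions, not that real
disease targets would be recovered at the same rate.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately small scale,
chosen as the smallest sizes at which every calibration property is stable:
cohorts of 200 genes / 40 loci / 10 targets over 20 seeds, prize graphs of
60 nodes with 100 permutations, oracle sweeps over graphs of 5–50 nodes
(propagation) and 5–12 nodes (exhaustive tree enumeration), and 20 annealing
runs on the two-clique benchmark.  Other numerical choices: RWR tolerance
$10^{-6}$ (L1) with a $10\times$ residual bound asserted; combined P-values
kept in log space; BMU and assignment ties resolved to the lowest node
index; rank ties lexicographic; permutation P-values +1-corrected; Haldane
0.5 only when a contingency cell is zero.

# Known limitations

* The prize-collecting solver is a scaffold-and-prune heuristic with an
  empirical (not worst-case) quality bound; adversarial cost structures can
  exceed the 10% gap seen on random instances.
* The logit combination clips $P = 1$ cells, which slightly compresses the
  bottom of that method's ranking.
* Spin-glass annealing is stochastic; the defaults are tuned for crosstalk-
  sized graphs (tens of nodes), not thousands.
* The SOM partition algorithm is a documented stand-in for an unspecified
  clustering step; with very flat codebooks the number of U-matrix minima
  can fall below the requested $k$, which is reported as an error rather
  than silently relaxed.
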