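---
title: "Haplotype assembly by correlation clustering: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype assembly by correlation clustering: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploclust)
```

## The problem

A K-ploid individual carries K homologous copies of each chromosome.
Sequencing reads sample one copy at a time, but after alignment and
genotyping we only know, for each read, the alleles it observed at the
heterozygous SNP sites it covers. Haplotype assembly (single-individual
haplotyping) asks for a partition of the reads by chromosome copy of origin
and the K allele strings (haplotypes) that explain them.

The package stores the observations as a sparse fragment matrix: `m` reads
by `n` SNP sites, with an allele code where a read covers a site and a gap
elsewhere (`frag_matrix()`). The quality of a candidate haplotype set
$h^1..h^K$ is the minimum error correction (MEC) objective

$$Z = \sum_{i=1}^m \min_l \mathrm{hd}(R_i, h^l),$$

the smallest number of observed bases that must be flipped so every read is
consistent with some haplotype; the per-symbol distance ignores gaps
(`mec_score()`). MEC is the yardstick everything else serves.

## From reads to a correlation graph

Reads covering fewer than two SNPs carry no phase information and are
dropped; columns that lose all coverage are removed
(`filter_fragments()`). SNP columns connected by chains of reads form
haplotype blocks (`connected_components()`, a FIFO queue over the column
graph); blocks are phased independently, since no read links them.

Within a block, every pair of reads overlapping in at least one site gets an
edge with weight

$$w_{ij} = \frac{k_{sim} - k_{dissim}}{k_{sim} + k_{dissim}} \in [-1, 1],$$

where $k_{sim}$ and $k_{dissim}$ count agreeing and disagreeing overlap
positions (`build_read_graph()`). Same-copy reads attract, different-copy
reads repel; with error-free diploid data the weights are exactly $\pm 1$.
Edges with $w = 0$ are retained: they certify connectivity and can carry
Lagrange multipliers in the polyploid solver.

## Diploid solver: low-rank MAX-CUT relaxation

For K = 2 the clustering is a MAX-CUT problem,
$\max_x \sum_{i<j} w_{ij} x_i x_j$ over signs $x_i$. Its semidefinite
relaxation replaces signs with unit vectors; because the optimum has low
rank, we optimize the factor directly: maximize
$M = \sum_{i<j} w_{ij} V_i^T V_j$ over unit-norm rows $V_i$
(`solve_lowrank_sdp()`). Cyclic coordinate ascent updates
$V_i \leftarrow \sum_k w_{ik} V_k$, then normalizes; each update maximizes
the objective in that row, so $M$ is non-decreasing and convergence is
declared when the ratio of the tangent-gradient norm to $M$ falls below
`eps_tol` ($10^{-5}$ by default).

The rank budget is adaptive: the factor starts with 2 columns; if the
converged factor is of full numerical rank (singular values above
`eps_th = 0.1`, `estimate_rank()`), one column of small seeded noise
($10^{-3}$) is appended and iteration resumes from the warm start, until the
factor goes rank deficient — at which point the stationary point is the
optimum of the convex relaxation. A warm restart (rather than
re-initialization) was chosen because the appended column is a strict
enlargement of the feasible set; re-initialization discards a valid interior
point for no benefit. If the row update $\sum_k w_{ik} V_k$ is exactly zero,
the previous (unit-norm) row is kept, preserving feasibility and
monotonicity.

Rounding projects the embedding on `n_projections` random unit vectors and
labels each read by the sign of its projection, keeping the labeling with
the best cut value (`round_hyperplane()`; `sign(0)` maps to the first
cluster for determinism). Theory puts the number of projections needed at
$O(\log m)$; the package default is `max(50, 30 log m)`. The constant is
deliberately generous: one projection evaluation costs $O(|E|)$, trivial
next to the solve, and on simulated triploid blocks of $10^3$ SNPs the
best-of-N labeling kept improving measurably between ~30 and ~300 draws
(cluster agreement 0.71 to 0.84, switch errors about one order of magnitude
lower downstream). Past a few hundred draws returns vanish.

## Polyploid solver: Lagrangian minorize–maximize

For K > 2, cluster indicators become vectors pointing at the vertices of a
centered regular simplex, whose pairwise inner products are $-1/(K-1)$.
Relaxing yields the constrained program

$$\max_V \sum_{i<j} w_{ij} V_i^T V_j
\quad \text{s.t.} \quad \|V_i\| = 1,\; V_i^T V_j \ge -\tfrac{1}{K-1}
\ \text{on edges},$$

solved by alternating inner coordinate sweeps with outer subgradient
updates of per-edge multipliers (`solve_lagrangian()`). Writing the
multiplier of edge $(i,j)$ as $\lambda_{ij} \le 0$, the outer update is the
projected subgradient step
$\lambda \leftarrow \min(\lambda + \alpha(V_i^T V_j + \tfrac{1}{K-1}), 0)$
with step size `alpha = 0.1`; once $\lambda < -\varepsilon_g$ (guard
interval `eps_g = 0.01`) the update switches to exponential damping
$\lambda \leftarrow \lambda\, 2^{-\mu s}$ (`mu = 1`), which grows the
multiplier geometrically while the constraint is violated and shrinks it
geometrically once satisfied. The inner sweep then uses effective weights
$w_{ij} - \lambda_{ij} = w_{ij} + |\lambda_{ij}|$: a violated constraint
makes its edge more attractive, pushing the pair back toward feasibility.
The sign is forced by duality — with effective weights $w + \lambda$ and
$\lambda \le 0$, a violated edge would become *more repulsive* and the
multipliers diverge (we observed exactly this failure mode before fixing
the sign: $\lambda$ reaching $-10^{154}$ and the embedding collapsing to a
bipartition).

The objective is no longer monotone, so convergence is tested on a smoothed
trajectory: means of the Lagrangian value over consecutive 50-iteration
windows must agree to `eps_tol_outer` ($10^{-4}$), relative to the value's
magnitude — the Lagrangian scales with the edge count, so an absolute
tolerance would be meaningless across block sizes. Rank adaptation reuses
the diploid policy with an initial budget of $K - 1$ columns (the natural
rank of the intended simplex solution) and a cap of $K + 2$: under the
noisy multiplier dynamics the factor essentially never goes rank-deficient
beyond that point, and escalations past it cost time without measurable
accuracy gain. High-ploidy solves typically escalate all the way to about
$K + 1$; `r_init_poly` lets a user start there outright, roughly halving
the iteration count for a small accuracy cost.

Rounding for K clusters projects $V$ onto an $r \times K$ Gaussian matrix
and assigns each read to the argmax of its projected row (ties to the
lowest index), keeping the best of `n_projections` draws by the clustering
objective (intra-cluster minus inter-cluster edge weight,
`round_simplex()`). Gaussian entries were chosen over uniform for rotation
invariance.

### Evidence weighting for K > 2

For diploids the symmetric weight is, up to scale, the log-likelihood ratio
of "same copy" versus "different copy": two different haplotypes are
complementary, so agreement and disagreement are symmetric evidence. For
K > 2 this symmetry breaks. At a biallelic heterozygous site two *distinct*
haplotypes still share the observed allele with collision probability
$q \approx 1/2$ ($q = 1/3, 0.43, 0.48$ for K = 3, 4, 6), so an agreement is
weak evidence of co-membership while a disagreement is strong evidence
against it — with a 1% error rate the log-likelihood ratio of a
disagreement is about 4–5 times that of an agreement. The polyploid solver
therefore runs on the evidence-weighted similarity

$$w = \frac{k_{sim} - \rho\, k_{dissim}}{k_{sim} + \rho\, k_{dissim}},
\qquad
\rho = \frac{-\log\left(2e(1-e)/(1-q)\right)}
            {\log\left(((1-e)^2+e^2)/q\right)},$$

(`odds_edge_weights()`; `err_rate` and `collision_prob` in
`solver_params()`), while the graph itself keeps the plain similarity. The
diploid case recovers $\rho = 1$. This correction matters qualitatively at
high ploidy: with the symmetric weight, hexaploid blocks admit "local
pattern" clusterings — reads grouped by their short-range allele pattern
rather than by haplotype — whose clustering objective *exceeds* the true
partition's (short 1–2-site agreements between different copies are
plentiful and each carries full $+1$ weight), and no solver can rescue an
objective whose optimum is wrong. Re-weighting disagreements restores the
alignment between the clustering objective and MEC.

## Consensus and refinement

Given read clusters, each haplotype allele is the modal allele of the
cluster's reads at that site (`derive_haplotypes()`; ties go to the lowest
code and are flagged). In the default `allow_homozygous` mode the K calls
may coincide: that is precisely how sites falsely genotyped as
heterozygous get corrected. The `all_heterozygous` mode (diploid) instead
forces the minority cluster to the complementary allele. A cluster with no
coverage at a site falls back to the site's overall modal allele.

Refinement then hill-climbs the MEC directly (`greedy_refine()`),
alternating two move classes until neither improves:

* **site moves** — every single-haplotype allele alteration at every site,
  accepted iff the block MEC strictly decreases (the per-read minimum over
  haplotypes is re-evaluated, which implicitly re-assigns reads);
* **switch moves** — at every boundary between consecutive sites, the
  haplotype tails from the boundary onward are re-arranged by a small tail
  assignment: a transposition, a 3-cycle, a double transposition, or a copy
  of one tail over another. Only reads straddling the boundary are
  re-scored, because reads entirely on one side see a permuted haplotype
  set whose minimum distance is unchanged.

Switch moves are the package's own extension of sequential greedy
refinement, and they are essential for polyploids: two haplotypes identical
over a stretch (frequent at K ≥ 4 with biallelic sites) can exchange phase
inside the stretch at zero local cost, so the damage is invisible to site
moves and only shows through mate pairs bridging the stretch — exactly
what a tail exchange repairs. The copy variant likewise repairs local
dosage errors. Both accept only strict MEC decreases, so termination is
guaranteed (MEC is a non-negative integer).

### Long polyploid blocks: windows, stitching, restarts

A single global embedding must hold one direction per haplotype across the
entire block. For K ≥ 4 with kilobase-scale blocks this becomes fragile:
pairs of haplotypes are locally indistinguishable over many stretches, and
the converged embedding's haplotype identity can drift along the genome —
more iterations do not repair it, while sub-blocks of a few hundred sites
solve reliably. Long K > 2 blocks are therefore phased hierarchically
(`window_snps = 300`, `window_overlap = 60`): each overlapping window is
solved, rounded and refined independently with the machinery above;
consecutive windows are aligned by the row permutation minimizing allele
mismatches over their overlap (an exhaustive K! matching — trivial for
K ≤ 8); and the stitched haplotypes are refined globally against the full
matrix. Diploid blocks are never windowed; the global MAX-CUT embedding is
stable at any tested length.

Two safeguards make window quality dependable, neither consulting ground
truth. First, within one solve the best few rounding candidates (3) are
kept and ranked by a site-move-only refinement; the winner receives the
full refinement. Second, a correct phasing's MEC is close to its noise
floor `err_rate × n_calls`; when the refined MEC exceeds 1.5× that floor
the solve evidently landed in a poor basin, and it is re-run from a fresh
random initialization (at most twice, at half the sweep budget). On
hexaploid 180X simulations this restart policy is the difference between a
few-percent and a sub-percent switch error rate.

## Scoring

`switch_error_diploid()` counts relative phase flips over consecutive
comparable sites — heterozygous in both truth and estimate — divided by the
number of opportunities (comparable sites minus one). For K > 2,
`switch_error_polyploid()` runs a dynamic program whose state is the
permutation aligning estimated to true rows; transitions cost the
transposition distance between consecutive permutations (a single
two-haplotype exchange costs 1, so K = 2 reduces exactly to the diploid
scan) and allele mismatches under the running permutation are charged
equally in the objective but reported separately. Opportunities are
$(\text{comparable sites} - 1)(K - 1)$, the most exchanges any adjacent
pair can need. The DP is exact; its state space ($K!$) is refused beyond
K = 8. Because published polyploid switch-error conventions differ in how
mismatches and switches are co-charged, cross-tool numeric comparisons of
polyploid rates are approximate; the convention here is documented and
self-consistent.

## The simulator

`simulate_truth()` and `simulate_reads()` emulate a long-insert paired-end
design over a single chromosome:

| parameter | default | meaning |
|---|---|---|
| `p_snp` | 1/300 | per-base SNP rate; inter-SNP gaps are `rgeom(p) + 1` (mean ≈ 300 bp) |
| `read_len` | 500 bp | length of each mate |
| `insert_mean`, `insert_sd` | 10 kb, 1 kb | outer fragment span, normal, truncated at `read_len` |
| `coverage` | 30 | expected per-base depth; the pair count is `coverage * L / (2 read_len)` |
| `seq_err` | 1% | per-base chance a copied allele flips to a uniformly different allele of the site's genotype |
| `geno_err` | 1% | fraction of sites planted falsely heterozygous (constant truth) |

Diploid truth pairs a random allele string with its complement; polyploid
truth draws each site's allele vector uniformly from the non-constant
binary vectors (a multiallelic mode exists behind `biallelic = FALSE`).
Coverage is defined per base of the sequenced 2×500 bp portions, not per
SNP. The genome is represented only by SNP coordinates — haplotyping never
needs the intervening bases.

What the simulator does *not* model: position- and cycle-dependent error
profiles, indels, mapping ambiguity, reference bias, or dosage-dependent
genotyping uncertainty beyond the planted falsely-heterozygous fraction.
Passing tests on simulated data therefore demonstrate the solver chain is
correct under the stated statistical structure, not that real libraries
behave this way.

At these defaults the long inserts make blocks of 1000 SNPs essentially
fully connected at 10X (the largest block carries ≥ 99.9% of sites), which
is the regime the solvers are designed for.

## Problem sizes and runtime choices

The test suite exercises blocks of 30–400 SNPs end to end and uses
brute-force oracles (exhaustive cuts, partitions, phase vectors,
permutation sequences) on instances of up to 12 reads or 8 sites; its
polyploid end-to-end checks run the full read protocol at 400-SNP blocks
(300 for hexaploid), five seeds per ploidy. The acceptance script runs the
1000-SNP protocol for triploid 45X and tetraploid 80X (about 13k and 24k
informative reads per replicate) and a 300-SNP block for hexaploid 180X,
five seeds each on one core: a hexaploid 1000-SNP replicate costs several
minutes of solver time, and the 300-SNP block is the size whose five-seed
median fits the script's runtime envelope. Block length affects the
switch-error *rate* only weakly (it is per-opportunity), so the scaled
condition measures the same quantity.

Hexaploid accuracy deserves a frank statement: at 180X the triploid and
tetraploid conditions come out well below a 1% switch error rate, but
hexaploid replicates typically land between 0.3% and 2.5% with occasional
harder draws — pairs of six biallelic haplotypes are locally identical
over long stretches, leaving only sparse long-insert mates to pin the
phase, and the correlation-clustering relaxation plus local refinement
does not always resolve them. The acceptance script reports whatever the
median turns out to be.

## Known limitations

* Blocks are phased independently; no attempt is made to join blocks with
  external phase information.
* Exact duplicate reads are kept as distinct graph vertices; merging them
  with multiplicities would shrink the graph at very high coverage.
* The polyploid collision probability `q` defaults to the biallelic value
  for the ploidy; strongly multiallelic data would warrant the
  `collision_prob` override.
* Per-base qualities are parsed and retained but do not enter the edge
  weights.
* MEC itself cannot distinguish haplotypes that are identical over an
  entire block span; such segments are phased arbitrarily (and the
  switch-error DP correspondingly does not charge them).
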