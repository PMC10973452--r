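---
title: "Differential RNA velocity analysis with velodelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential RNA velocity analysis with velodelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velodelta)
```

## The problem

Static single-nucleus RNA-seq gives a snapshot of expression, not its
direction of change. RNA velocity recovers a dynamic signal from the same
libraries by contrasting unspliced (intronic, nascent) with spliced
(exonic, mature) reads: under the kinetic model

$$\frac{du}{dt} = \alpha - \beta u, \qquad \frac{ds}{dt} = \beta u - \gamma s,$$

a gene at transcriptional equilibrium satisfies \(u = (\gamma/\beta)\,s\).
The velocity of a cell for a gene is the residual of its observed
(smoothed) unspliced abundance from this steady-state line: positive
residuals mean the gene is being upregulated, negative ones downregulated.
`velodelta` implements this estimator and a set of group-comparison tools
around it — differential velocity between clinical groups with a
subject-level permutation null, whole-transcriptome cell speed, residual
velocity fields on a 2D embedding, covariate-adjusted association of
subject-mean velocities with quantitative neuropathology traits, and
cross-dataset overlap validation — together with a kinetic cohort
simulator that provides exact ground truth for every stage.

Only the ratio \(\gamma/\beta\) is identifiable from (u, s) data, so
\(\beta \equiv 1\) throughout and all fitted `gamma` values are
\(\gamma/\beta\).

## Velocity estimation

**Normalization.** Each cell's spliced and unspliced rows are divided by
the cell's within-layer total and rescaled to the median layer total
(`normalize_counts(mode = "velocity_layers")`). The rescaling target is a
package choice: dividing by totals alone changes the count scale, and the
median keeps values interpretable as counts. For expression testing the
conventional `log1p(counts / total * 1e4)` transform is used (natural log,
pseudocount 1); fold changes downstream are base-2 explicitly.

**Moments.** Per-cell values are noisy, so all estimation runs on
k-nearest-neighbour averages (`neighbor_moments`): PCA on `log1p` of the
normalized spliced layer (centred, unscaled), Euclidean kNN in PC space
with the cell itself included (self-inclusion stabilises boundary cells
and makes the brute-force test oracle unambiguous), and neighbour means of
\(u\), \(s\), \(s^2\) and \(us\). Defaults are k = 100 neighbours and 30
components, reduced automatically for small data; analyses at a few
thousand cells scale k down (around 30) so neighbourhoods stay local.

Pooling is a consequential choice. By default all cells share one
neighbour graph (`by = NULL`). The alternative, `by = subject_id`,
restricts every cell's neighbours to its own donor's cells. Pooled
smoothing is statistically dangerous for downstream group tests: as soon
as anything separates the groups in PC space, neighbourhoods become
group-pure, smoothing shrinks within-group variance while preserving the
cohort's chance group gap in *every* gene, and even a subject-level
permutation null cannot reproduce that graph alignment — null genes then
reject wholesale. Per-subject smoothing never crosses donors, so
subject-level exchangeability survives smoothing exactly; it is the right
setting whenever the velocities feed a between-group test, at the cost of
noisier moments for donors with few cells.

**Slope fitting** (`fit_gamma`). Cells in the extreme quantiles of the
smoothed spliced abundance (defaults 5% and 95%) proxy the two
equilibria, and the slope is least squares through the origin — the
steady-state relation has no intercept. The `stochastic` mode augments the
first-moment equation with the second-moment relation of the counting
process, \(2E[us] + E[u] = \gamma'(2E[s^2] - E[s])\), stacking both
equation blocks and weighting each by the inverse of its response variance
so neither dominates. Two properties are worth knowing: the second-moment
block is exactly consistent with the first only when the moments obey the
Poisson counting identity \(E[s^2] = E[s]^2 + E[s]\), and it is
deliberately not invariant to rescaling the layers (the counting identity
is count-scale-specific); the plain steady-state fit is exactly scale
equivariant. Genes with an all-zero spliced moment or a non-positive
fitted slope are flagged invalid and their velocities NaN-masked, never
silently zeroed.

**Velocity and ranking.** `compute_velocity` forms
\(V = M_u - \hat\gamma M_s\); `rank_velocity_genes` runs a Welch t-test of
each gene's velocity in one cell type against all others (variance floored
at machine epsilon so constructed zero-variance contrasts stay finite) and
ranks genes by t.

## Differential testing with a subject-level null

Cells from the same donor are correlated — treating cells as independent
replicates (pseudoreplication) makes naive tests anti-conservative. The
package therefore computes the Mann-Whitney U statistic over cells
(average ranks for ties) but builds its null distribution by permuting
*subjects*: whole donors are reassigned between groups (group sizes in
subjects preserved, every cell travelling with its donor), U is recomputed
per permutation (default 5000), and the two-sided empirical p-value uses
the add-one estimator
\((1 + \#\{|U^* - \mu^*| \ge |U - \mu|\}) / (n_{perm} + 1)\) with
\(\mu = n_1 n_2 / 2\) recomputed per permutation because donors carry
different cell counts. The add-one form avoids zero p-values at finite
permutation counts. Benjamini-Hochberg q-values are computed within each
(cell type x metric) family, and calls require q < 0.05 and
|log2 fold change| > 0.25.

Velocities can have negative group means, for which a log ratio is
undefined. The documented rule: both means positive — ordinary
\(\log_2(\text{mean}_{AD}/\text{mean}_{ctrl})\); both negative — the
magnitude ratio; discordant signs or a zero mean — the gene is flagged
`sign_discordant` and treated as exceeding any fold-change threshold,
because a sign flip in mean velocity is itself a strong dynamic
difference. An optional per-gene least-squares residualization on donor
age is available before testing (off by default).

`length_bias_check` correlates per-gene U statistics with gene length to
verify that calls are not driven by the over-representation of long
unspliced transcripts.

Two structural limits on differential calls are worth knowing. First, the
permutation floor: with \(m\) donors per group the null has
\(\binom{2m}{m}\) distinct reassignments, so with 6 per group the
smallest attainable two-sided p is about 2/924 — Benjamini-Hochberg at
q < 0.05 then cannot call a handful of signals among hundreds of genes no
matter how strong they are; the worked validation uses 12 donors per
group. Second, compositional leakage: total-count size normalization
redistributes any genuine group shift in a sizeable fraction of the
transcriptome into *all* genes (the spliced totals move, so every
normalized value moves), producing real, permutation-robust differences
in truth-null genes. With planted effects in about 2% of genes or fewer
this is negligible; simulations planting effects in 10% of genes show it
plainly.

## Cell speed and residual velocity fields

A cell's speed is the Euclidean norm of its velocity vector over valid
genes — a scalar rate-of-change summary compared between groups with a
rank-sum test per cell type. For spatial structure, per-cell velocities
are projected onto a 2D embedding (`embed_velocity`): cosine similarity
between the gene-space velocity and the displacement to each embedding
neighbour becomes softmax transition weights (temperature set adaptively
to the cell's median absolute similarity), and the projected vector is the
weighted mean of unit embedding displacements minus their uniform mean, so
an uninformative velocity projects to zero. External t-SNE/UMAP
coordinates are accepted verbatim; the fallback is the first two PCs
(t-SNE itself is out of scope and nondeterministic across
implementations).

`residual_field` compares two groups' fields on a shared regular lattice
(default 50 x 50) spanning the joint embedding support: Gaussian-kernel
smoothing (bandwidth = lattice spacing) defines each group's field where
it has cells; nodes covered by only one group are filled for the other by
iterative neighbour averaging over its covered nodes, which realises
"interpolate where cells are missing" on coordinates common to both
groups. The residual is the difference of fields; z-scores are computed
from the residual *norms* (not per component) and nodes with |z| > 1.96
are masked. Residual norms are non-negative and roughly Rayleigh under a
shared-field null, so the two-sided 1.96 threshold masks about 4-5% of
nodes there — the null calibration the test suite checks. Field
directions carry no intrinsic biological meaning; only masked
z-magnitudes are interpreted.

## Trait association

For each cell type, each donor's cells are averaged per gene
(`subject_mean_velocity`; donors lacking a type get NaN). Association with
quantitative neuropathology traits (neuritic plaques, NFT counts,
β-amyloid load, PHF tau tangle density) uses a partial Spearman
correlation: x, y and all numeric covariates are rank-transformed, the x
and y ranks are residualized on an intercept plus covariate ranks, and the
Pearson correlation of residuals is tested on \(n - 2 - k\) degrees of
freedom. A trait fully explained by a covariate residualizes to numerical
noise; such cases return a partial correlation of exactly zero by
convention. The default covariate set is {age, sex, education, postmortem
interval}; `covariates = c("age", "sex", "pmi")` reproduces the
education-free variant — both configurations appear in practice and
neither is asserted as canonical. Family-wise error is controlled by Holm
step-down within each (cell type x trait) family (uniformly more powerful
than Bonferroni, assumption-free), with significance at adjusted
p < 0.001. The choice of family granularity is itself a design decision;
per-(cell type x trait) is the narrowest family that matches how results
are reported.

## Cross-dataset overlap

`fisher_overlap` tests whether the significant gene sets of two datasets
overlap more than chance within a universe defined as the genes tested in
*both* datasets for that cell type — the defensible null background when
none is stated. The p-value is the one-sided (enrichment) hypergeometric
tail, matching the "odds ratio > 1" direction of the replication
criterion; the sample odds ratio uses the Haldane 0.5 correction only when
a cell is zero, flagged. `summarize_overlap` adds per-cell-type overlap
counts into a total and a rounded percentage of the replication dataset's
calls.

## The synthetic cohort generator

`generate_cohort` draws a multi-donor, multi-cell-type cohort directly
from the kinetic model so that every downstream stage has exact ground
truth. Design choices, and what they emulate:

- **Study geometry.** Two groups of 24 donors by default (a balanced
  postmortem cohort), six cortical cell types, 100 cells per donor by
  default. Tests and examples scale these down or up explicitly; the
  suite states its own sizes.
- **Kinetics.** \(\beta = 1\); per-gene \(\gamma/\beta\) uniform on
  [0.2, 1]; transcription rates log-normal. The switch time is 8, so both
  branches essentially reach their steady states — the regime the
  extreme-quantile estimator assumes.
- **Phases and desynchronization.** Cells receive one latent time,
  uniform on [0, 1.5 x switch]; every gene observes it through its own
  random phase offset (mod the full cycle). Genes in a real cell do not
  switch in unison, and a synchronized simulator has per-cell totals that
  track kinetic phase, so size normalization would distort the phase
  portrait — an artifact of the simulator, not of real data. The
  sub-cycle sampling window mimics a tissue snapshot: integrating ds/dt
  over a fully and uniformly sampled closed cycle gives every gene a mean
  velocity of zero in both groups, leaving nothing for a group comparison
  to detect.
- **Shared vs independent time.** In the default shared mode one latent
  time per cell drives all genes — cells progress coherently, which the
  embedding and field analyses assume — but every gene then reads the
  same per-donor time draw, so gene-level test statistics are strongly
  correlated across genes within one cohort: a 500-gene "uniformity"
  check on a single shared-time cohort effectively observes one draw.
  `time_mode = "independent"` gives every (cell, gene) pair its own phase
  (asynchronous bursting), making null genes statistically independent;
  calibration studies use it.
- **Truth classes.** Dynamic genes differ between groups only in
  \(\gamma\) (doubled in the affected group by default) and take offsets
  that leave a clear net drift — an unobservable "dynamic" gene would be
  meaningless as ground truth. DE genes are constitutive: their cells sit
  at steady state, where expected velocity is zero in both groups, so a
  transcription-rate effect (doubled \(\alpha\)) changes expression only;
  scaling \(\alpha\) on a trajectory gene would scale velocity too and
  conflate the two classes. Null genes are trajectory genes with identical
  kinetics in both groups.
- **Heterogeneity.** Independent log-normal \(\alpha\) multipliers per
  (donor, gene) (sdlog 0.1) create the within-donor cell correlation that
  subject-level permutation must respect; a single per-donor scalar would
  make all genes' donor means collinear and degenerate. Per-(gene, cell
  type) multipliers (sdlog 0.3) give each type its own dynamics for the
  ranking test. A per-cell log-normal capture-efficiency factor (sdlog
  0.1) is removed by normalization, and counting noise is Poisson by
  default (negative binomial with configurable dispersion as an option) —
  the minimal model absent stated overdispersion.
- **Traits.** Each trait couples to one distinct dynamic gene (weight
  0.8) through the donor-mean true velocity, plus Gaussian noise scaled
  to the pooled *within-group* signal sd (default fraction 0.5):
  pathology severity differs between groups by construction, but
  association analyses run within a group, so that is the variation the
  noise must be commensurate with. Planted-coupling validation is run
  cohort-wide; the group-restricted variant mirrors the real analysis but
  has reduced power at desk scale because donor means share
  trajectory-sampling noise across genes.
- **Equilibrium mode** puts every gene at steady state with independent
  per-(cell, gene) activity fluctuations (sdlog 0.5) spreading cells
  along the line — the regime for slope-recovery experiments. A shared
  per-cell activity factor would be cancelled exactly by size
  normalization and leave no spread. Recovery experiments use around 100
  genes: per-cell normalization couples genes compositionally (one
  gene's fluctuation perturbs the totals by ~1/n_genes), which leaves a
  small slope-bias floor that more cells cannot remove; more genes
  shrink it.

What the generator does **not** emulate: sequencing reads, barcode
errors, doublets, ambient RNA, batch effects, or empirically calibrated
dropout. Passing tests on this cohort demonstrate the estimators and
tests behave as designed under the kinetic model with counting noise —
not that any biological conclusion transfers to a particular real
dataset.

## Numerical and degenerate-input choices

- The closed-form trajectory handles \(\beta = \gamma\) by the limiting
  expression \((e^{-\gamma t} - e^{-\beta t})/(\gamma - \beta) \to
  -t e^{-\beta t}\), switched at a relative tolerance of 1e-10.
- Velocity sign validation excludes cells whose true |velocity| is below
  10% of the gene's maximum: just after the induction-to-repression
  switch the true velocity is briefly still positive and crosses zero, so
  a sign there is undefined at any noise level.
- Permutations that would leave a group without cells are resampled and
  logged. U statistics for genes with non-finite values propagate NA.
- `fisher_overlap` flags fully degenerate tables (a set empty or equal to
  the universe) and never calls them significant.
- kNN is exact (blocked distance computation with partial sort), so test
  oracles can be brute force.

## Problem sizes in the shipped validation

The test suite and acceptance script simulate at desk scale, chosen as
the smallest sizes at which each property is comfortably measurable:
slope recovery on equilibrium cohorts of 200 / 2,000 / 20,000 cells;
permutation calibration on a null cohort of 500 genes, 12 donors and 500
permutations; residual-field null calibration over 50 replicate draws;
kinetics against an adaptive ODE integrator over 100 random parameter
sets. `run_pipeline()` defaults mirror the full analysis (5,000
permutations, k = 100, 30 PCs, 50 x 50 lattice).

## Known limitations

- The steady-state and second-moment estimators share the
  extreme-quantile equilibrium assumption; genes far from saturation in
  the sampled window get biased slopes. The dynamical (latent-time EM)
  model is out of scope.
- The stochastic fit's equation weighting (inverse response variance per
  block) is declared, not asserted identical to any external
  implementation.
- Compositional coupling through per-cell normalization induces small
  cross-gene biases of order 1/n_genes; with transcriptome-scale gene
  counts this is negligible, but it is visible in few-gene simulations.
- Embedding projection interprets only directions to existing neighbours;
  isolated cells project to zero.
- The permutation floor with few donors is coarse: with 4 donors per
  group the smallest attainable two-sided p is about 2/C(8,4).
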