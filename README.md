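# scMatcher

Pairing the *same kind of cell* measured by *different* single-cell
technologies is a recurring obstacle in multi-modal studies: an aliquot of
one cell suspension profiled by scRNA-seq and by CyTOF yields two
cells-by-features matrices with **no shared cells and no shared features**.
scMatcher integrates such datasets into a shared, technology-invariant
latent space with adversarially trained autoencoders and then assigns
concrete cross-technology cell pairs by solving a capacity-extended
minimum-cost maximum-flow problem on the latent codes. It is aimed at
analysts of multi-technology single-cell experiments (scRNA-seq, CyTOF,
and similar) who need per-cell correspondences — not just a joint
embedding — for downstream paired analyses.

## Model

**Latent integration.** Each technology \(k\) has an encoder
\(\psi_k\) and decoder \(\phi_k\). A variational autoencoder is first fit
to the *source* technology by minimizing

\[
L_{\mathrm{vae}} = -\log p_\phi(x\mid \hat z) +
\beta\, D_{\mathrm{KL}}\!\left(q_\psi(z\mid x)\,\|\,\mathcal N(0,I)\right),
\qquad \hat z \sim q_\psi(z\mid x),
\]

with a Gaussian posterior (closed-form KL), a Gaussian decoder, latent
dimension 8, \(\beta = 0.01\). The source posterior means \(\hat z_s\)
are then frozen, and every *target* technology's autoencoder minimizes

\[
L = L_{\mathrm{nll}}(x_t) + \beta_{\mathrm{adv}}\, L_{\mathrm{adv}}(\hat z_t),
\]

where \(L_{\mathrm{adv}}\) is the loss the target encoder incurs when a
shared discriminator — a small spectrally-normalized classifier on
(code ⊕ one-hot label, with a censored class for unlabeled cells) —
recognizes its codes as non-source. The discriminator is updated after
every autoencoder step. Because adversarial optimization is not monotone,
every epoch's latent divergence is logged and the model snapshot of the
best reconstruction-eligible epoch is kept.

**Latent-space quality.** Integration is monitored with a nonparametric
kNN divergence estimate,

\[
\hat D(Z_s \| Z_t) = \tfrac12 \hat D_{KL}(Z_s\|Z_t) + \tfrac12 \hat D_{KL}(Z_t\|Z_s),
\qquad
\hat D_{KL}(P\|Q) = \frac{d}{|P|} \sum_i \log\frac{\nu_k(p_i)}{\rho_k(p_i)}
 + \log\frac{|P|}{|Q|-1},
\]

with \(\nu_k\)/\(\rho_k\) the kth-nearest-neighbor distances in the other /
own sample. `selectModel()` implements threshold-based model selection on
(divergence, reconstruction error).

**Matching.** Candidate pairs are the union of both directed kNN queries
between code sets. The flow network feeds every cell of the bigger side
(size \(n\)) from a root with capacity 1, connects candidates at their
Euclidean cost, drains the smaller side (size \(m\)) into the sink with
balanced capacities \(u_i \in \{\lfloor n/m\rfloor, \lceil n/m\rceil\}\)
(\(\sum u_i = n\)), and adds a *null node* of capacity \(n\) whose cost is
the \(p\)-th percentile of candidate costs, absorbing cells without an
adequate analog. A network simplex solver (Rcpp) finds the integral
min-cost max-flow; unit flows become cell pairs.

**Benchmarking.** A negative-binomial branching-process simulator
generates any number of "technologies" from one lineage tree: per-feature
log-means diffuse along pseudotime (continuous at branch points), cells
are sampled uniformly over tree length, and counts are drawn
\(\mathrm{NB}(\mu, r)\) with \(\mathrm{Var} = \mu + \mu^2/r\). Datasets
share the latent branching structure but have disjoint feature spaces,
with ground-truth branch labels and pseudotime for every cell.

## Worked example

```r
library(scMatcher)

tree <- makeDefaultTree()              # 5 branches, total length 100
sim  <- generateTechnologies(tree, nTech = 2, nCells = 8000,
                             nFeatures = 256, seeds = c(11, 12))

cfg <- scimConfig(vaeEpochs = 64L, scimEpochs = 64L, seed = 1L)
fit <- trainSCIM(sim, sourceIndex = 1, config = cfg)
#> ScimFit: 2 technologies, source = tech1
#>   final epoch divergence: tech2=7.791

matches <- matchCells(fit@codes$tech1, fit@codes$tech2, k = 64, p = 95)
#> MatchResult: 5810 pairs, 2190 null-assigned (k = 64 , p = 95 )
#>   total matched cost 6191.892

report <- evaluateMatches(matches,
  as.data.frame(SummarizedExperiment::colData(sim$tech1)),
  as.data.frame(SummarizedExperiment::colData(sim$tech2)))
#> $ label_accuracy     : num 0.863
#> $ pseudotime_pearson : num 0.964
#> $ pseudotime_spearman: num 0.967
```

86% of matched pairs land on the cell's true branch, and ground-truth
pseudotime correlates at 0.96 across the matched pairs — the two
technologies were generated with completely disjoint features, so all of
this signal flows through the shared latent space. The 2190 null-assigned
cells are those whose best candidate was costlier than the 95th-percentile
null penalty; they are excluded from accuracy, and their share is reported
separately by `matchedFractions()`.

A command-line interface with `simulate`, `train`, `match`,
`evaluate-latent`, `evaluate` and `run` subcommands is installed at
`system.file("cli", "scmatch", package = "scMatcher")`.

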