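# perturbOT

Predicting single-cell perturbation responses with neural optimal
transport.

## The problem

Single-cell measurements (scRNA-seq, multiplexed protein imaging) destroy
the cells they profile, so an experiment comparing untreated and treated
aliquots yields two *unpaired* populations — a control sample
$\{x_i^c\} \sim \rho_c$ and a perturbed sample $\{x_j^k\} \sim \rho_k$ —
and never the before/after trajectory of any one cell. perturbOT is for
computational biologists who want per-cell response predictions out of
such unpaired data: which state a *given* control cell would move to under
the perturbation, including cell-type-specific and bimodal responses that
population-average methods miss.

## The method

The package learns the squared-Euclidean optimal transport map between the
two populations,
$$ T^\star = \arg\min_{T:\,T_\sharp \rho_c = \rho_k}
   \mathbb{E}_{x\sim\rho_c}\lVert x - T(x)\rVert_2^2, $$
via its Kantorovich dual: two convex potentials $(g, f)$ are
parameterized as input-convex neural networks
($h_{i+1} = \sigma_i(W_i^x x + W_i^z h_i + b_i)$, non-negative $W^z$,
convex non-decreasing $\sigma$) and trained on the max-min objective
$$ \max_\phi \min_\theta\;
   f_\phi(\nabla g_\theta(x)) - \langle x, \nabla g_\theta(x)\rangle
   - f_\phi(y) + \lambda R(\theta), $$
with $f$ hard-projected onto the convex cone after every update and $g$
softly penalized through $R(\theta) = \sum_l \lVert\max(-W_l^z, 0)\rVert_F^2$.
By Brenier's theorem the learned $T = \nabla g$ is the optimal map;
applying it to held-out control cells predicts their perturbed states.
Training alternates one Adam ascent step on $f$ with ten descent steps on
$g$ (batch 256, learning rate $10^{-4}$, betas $(0.5, 0.9)$,
$\lambda = 1$, two 4×64 ICNNs) — the forward passes, exact input
gradients, and the second-order parameter gradients of the dual objective
are derived analytically and implemented in compiled code, with plain-R
twins kept as oracles in the test suite.

Around the estimator the package ships the full workflow: population I/O
(CSV/TSV and H5AD), 75th-percentile and library-size normalization,
training-set-only highly-variable-gene selection, i.i.d. /
out-of-sample / out-of-distribution split protocols, an autoencoder
latent pathway (default 50 dimensions) for transcriptome-wide data,
distribution-level evaluation (multiscale unbiased MMD, feature-mean
$\ell_2$ and $r^2$, marker-gene restriction, identity and observed
baselines), and synthetic generators with closed-form Gaussian and exact
discrete-OT oracles.

## Worked example

Train a map between a control population and a perturbed population whose
two subpopulations respond in opposite directions (the regime where
mean-shift predictors fail), then score the prediction against held-out
perturbed cells:

```r
library(perturbOT)

spec <- mixture_spec(c(0.5, 0.5), list(c(-2, 0), c(2, 0)),
                     list(diag(2) * 0.25, diag(2) * 0.25),
                     shifts = list(c(3, 0), c(-3, 0)),
                     n_source = 3000, n_target = 3000, seed = 104)
pair  <- sample_mixture_pair(spec)
pop   <- dplyr::bind_rows(pair$source, pair$target)
split <- make_splits(pop, split_spec("iid", test_size = 500,
                                     eval_size = 500, seed = 7))
take  <- function(s, cond) pop[intersect(split$row[split$split == s],
                                         which(pop$condition == cond)), ]

map <- fit_transport_map(take("train", "control"),
                         take("train", "perturbed"),
                         ot_train_config(n_iter = 4000, seed = 8))
glance(map)
#> # A tibble: 1 x 7
#>   input_dim n_iter selected_iteration  loss_f loss_g    penalty_g  seed
#>       <int>  <int>              <int>   <dbl>  <dbl>        <dbl> <int>
#> 1         2   4000               4000 -0.0674   15.1 0.0000000139     8

pred <- transport(map, take("test", "control"))
glance(evaluate_prediction(pred, take("test", "perturbed")))
#> # A tibble: 1 x 7
#>   baseline mmd_mean l2_means r2_means n_pred n_obs n_features_mmd
#>   <chr>       <dbl>    <dbl>    <dbl>  <int> <int>          <int>
#> 1 model     0.00480    0.147        1    500   500             NA
```

The per-cell displacements `perturbation_effect(map, cells)` move the two
components in opposite directions along the first feature (mean +0.92 and
-0.98 on held-out cells) — each source mode travels to its *nearest*
responding target mode, which is the minimal-displacement answer optimal
transport is defined to give. The model's MMD sits far below the identity
baseline (0.0999 on this fixture) and near the observed-cells noise floor
(0.000166) — the qualitative ordering a sound predictor must show. `autoplot(map)` draws the dual-objective
trajectories; `transport_cost(map, cells)` ranks perturbation severity
per cell group.

The same workflow runs from the shell via the bundled CLI
(`inst/cli/perturbot`): `simulate`, `preprocess`, `train-ae`, `train`,
`predict`, `evaluate`, each writing artifacts plus a manifest with the
resolved configuration and seed.

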