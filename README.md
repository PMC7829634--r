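# scvae

Joint probabilistic modelling of multi-batch single-cell RNA-seq count
matrices with zero-inflated negative binomial (ZINB) variational
autoencoders, in plain R.

The package is for analysts who need to **harmonize** several scRNA-seq
datasets into one batch-corrected latent space, **annotate** cells by
propagating partial or hierarchical cell-type labels, and test
**differential expression** between populations with Bayes factors — all
from a single fitted generative model, without normalizing counts first.

## The model

Each cell `n` from batch `s_n` is generated as

```
c_n ~ Categorical(1/C)                      cell type (may be unobserved)
u_n ~ N(0, I)                               within-type variation
z_n ~ N(f_mu(u_n, c_n), f_sd(u_n, c_n))     biological latent (d = 10)
l_n ~ LogNormal(l_mu[s_n], l_var[s_n])      library scaling factor
x_ng ~ ZINB(mean = l_n f_w(z_n, s_n),  inv-dispersion = theta_g,
            dropout = f_h(z_n, s_n))
```

where `f_w` (softmax head), `f_h`, `f_mu`, `f_sd` are small neural
networks and the ZINB arises from collapsing a
Gamma–Poisson–Bernoulli hierarchy.  Inference is amortized variational
inference with the factorization `q(z|x) q(c|z) q(l|x) q(u|c,z)`,
optimizing the sum of a labeled-cell bound and an unlabeled-cell bound
(label marginalized under `q(c|z)`) by Adam, with deterministic KL warmup.
In unsupervised mode the `z`-prior is a standard Gaussian and the model
performs pure harmonization; in semisupervised mode `q(c|z)` doubles as a
cell-type classifier, including reserved classes for never-annotated
populations.  Differential expression compares decoded expression
frequencies between groups, marginalized over batches:
`K = log p(H1)/(1 - p(H1))` with `H1: E_s f_w(z_a, s) > E_s f_w(z_b, s)`;
`|K| > 3` (odds about 20:1) is the default call.

Everything — including the neural-network training with hand-derived
gradients — is implemented in base R on dense BLAS operations; gradients
are verified against finite differences in the test suite.

## Worked example

```r
library(scvae)

spec <- simulation_spec(n_cells = 1000, n_genes = 80, n_batches = 2,
                        n_labels = 3, seed = 42)
sim <- simulate_dataset(spec)
ds <- sim$dataset
set.seed(1)
ds$labels[sample(ds$n_cells, 900)] <- NA   # keep 10% of the annotations

fit <- scvae(ds, mode = "semisupervised",
             config = vae_config(n_hidden = 48, n_layers = 2, d_latent = 10,
                                 n_epochs = 60, warmup_epochs = 30,
                                 pretrain_epochs = 40, seed = 1))
fit
#> scvae model (semisupervised): 80 genes, 2 batch(es), d_latent = 10
#>   classes: 3 observed + 1 unobserved
#>   final training ELBO: -316.43 (60 epochs)

z <- encode(fit, ds)                       # harmonized embedding
entropy_of_batch_mixing(z, ds$batch, seed = 1)
#> entropy_of_batch_mixing : 0.6722

pred <- predict(fit, ds, type = "labels")  # annotate unlabeled cells
weighted_accuracy(pred[is.na(ds$labels)],
                  sim$truth$labels[is.na(ds$labels)])
#> weighted_accuracy : 0.9944

bf <- de_labels(fit, ds, label_a = 0, label_b = 1, seed = 1)
head(bf[order(-abs(bf$bayes_factor)), ], 3)
#>    gene_id  p_h1 bayes_factor is_de
#> 34  gene34 0.999     6.906755  TRUE
#> 37  gene37 0.001    -6.906755  TRUE
#> 43  gene43 0.001    -6.906755  TRUE
```

The mixing entropy 0.672 is close to its two-batch maximum `log 2 = 0.693`,
i.e. neighborhoods in the latent space are nearly batch-balanced even
though the simulated batches differ three-fold in depth and three-fold in
dropout.  The held-out weighted (per-class-averaged) accuracy of 0.994
comes from only 100 labeled cells.  The top Bayes factors (`|K| = 6.9`, the
largest magnitude reachable with 1,000 posterior draws after clamping) flag
genes whose decoded expression frequency differs between the two types in
(here) every single draw; the sign gives the direction.

Datasets come in via `read_dataset()` (Matrix Market or dense CSV counts +
cell/gene metadata CSVs), multiple studies are merged with
`concat_datasets()`, and `select_genes_by_dispersion()` reproduces the
union-of-top-dispersed-genes selection used for multi-dataset runs.  Label
transfer by k-nearest neighbors (`knn_transfer()`), marker-signature seed
labeling (`signature_scores()` + `pick_seed_cells()`), two-level
hierarchical classification (`hierarchical_classify()`), and the standard
evaluation metrics (entropy of batch mixing, kNN purity, weighted
accuracy, ARI structure preservation, stratified mixing, CITE-seq protein
consistency) are all exported.  A thin command-line front end is installed
as `exec/sctool` (`sctool help`).

See `vignettes/scvae-methods.Rmd` for the full model description, the
semi-supervised bounds, numerical choices, what the synthetic-data
generator does and does not emulate, and known limitations.

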