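# cmimpute

Cross-species imputation of species-tissue mean DNA methylation with a
conditional variational autoencoder (CVAE).

## The problem

Mammalian methylation-array compendia profile hundreds of species and
dozens of tissues, but the species × tissue grid is extremely sparse:
most species are profiled in only a few tissues, so the vast majority of
species-tissue cells have no data at all. The unit of interest here is
the **combination mean sample** — a species' average beta-value profile
(fraction methylated, in [0,1], per CpG probe) within one tissue.
`cmimpute` trains on individual samples labelled by species and tissue
and generates combination mean samples for unprofiled species-tissue
pairs, for comparative epigenomics analyses (tissue signatures,
species signals, lifespan modelling) that need a complete grid.

## The model

The core is a conditional VAE. With beta-value sample *X* and two-hot
label *y* (one-hot species block of size *S* concatenated with one-hot
tissue block of size *T*):

- encoder *Q<sub>φ</sub>(z | X, y)*: a fully connected stack from the
  concatenated (*X*, *y*) input of width *M + S + T* to two linear heads
  — the posterior mean *μ* and log-variance *σ* of a diagonal Gaussian
  over the latent space (dimension *Z*);
- latent draw by reparameterization, *z = μ + exp(σ/2) ε*,
  *ε ~ N(0, I)*;
- decoder *P<sub>θ</sub>(X | z, y)*: a mirrored stack from (*z*, *y*) to
  *M* logits; beta values are the logistic sigmoid of the logits.

Training minimizes the negated empirical lower bound

L = L<sub>RECON</sub> + L<sub>REG</sub>, with
L<sub>RECON</sub> = binary cross-entropy of *X* against sigmoid(logits)
(continuous targets, summed over probes, averaged over the batch) and
L<sub>REG</sub> = ½ Σ<sub>j</sub> [exp(σ<sub>j</sub>) + μ<sub>j</sub>² − 1 − σ<sub>j</sub>],

with the Adam optimizer. **Imputation never touches the encoder**: a
combination mean sample for a target (species, tissue) is decoded from a
standard-normal latent draw and the target's two-hot label, so the
output is individual-agnostic.

The package also provides the comparison methods (species / tissue /
global mean baselines and a per-probe weighted ridge logistic
regression), sample-wise and probe-wise agreement metrics, probe
variance profiles with quartile stratification, species/tissue signal
AUCs, the grouped cross-validation protocol over species-tissue
combinations, leave-one-species-out (LOSO) regression of log maximum
lifespan on combination mean methylation, and a seeded synthetic
compendium generator so the whole pipeline runs without any downloads.

## Worked example

```r
library(cmimpute)

# a synthetic compendium: 10 species x 4 tissues x 120 probes, with known
# ground-truth combination means and some grid cells left unobserved
comp <- generate_compendium(S = 10L, T_ = 4L, M = 120L, seed = 1)

hy  <- cvae_hyperparameters(hidden_dims = c(48L, 24L), latent_dim = 8L,
                            epochs = 120L, batch_size = 64L)
fit <- cvae(comp$values, comp$labels, hy, seed = 1)
fit
#> conditional VAE: 120 probes, 10 species + 4 tissues, Z=8
#>   encoder 134 -> 48 -> 24 -> (8,8); decoder mirrors; activation tanh
#>   trained 120 epochs; final loss 65.3728 (recon 65.2001, kl 0.1726)

imp <- impute_missing_grid(fit, comp$labels, seed = 1)
imp
#> combination_means [cmimpute]: 10 combinations x 120 probes

truth <- true_combination_means(comp$truth,
           data.frame(species = imp$species, tissue = imp$tissue))
sample_wise_agreement(imp, truth)
#> sample-wise agreement over 10 units: mean r 0.7598 (median 0.7698),
#> mean MSE 3.593e-02; 0 undefined r
```

The model imputes the ten species-tissue combinations that were never
observed; against the generator's ground truth it reaches a mean
sample-wise Pearson correlation of 0.76 (the global-mean baseline on the
same keys reaches 0.72). The per-key table in `$per_sample` gives each
combination's correlation and mean squared error.

A command-line front end wrapping the same functions is installed at
`inst/cli/cmimpute.R` with subcommands `simulate`, `train`, `impute`,
`baselines`, `cv`, `evaluate` and `lifespan`.

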