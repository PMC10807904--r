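---
title: "Pseudo-value regression for covariate-adjusted differential co-abundance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-value regression for covariate-adjusted differential co-abundance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microbial taxa do not act alone: their abundances co-vary, and the structure
of that co-variation — the co-abundance network — can differ between groups
of hosts (cases vs controls, one diet vs another). A taxon whose
*connectivity* (how strongly it is associated with all other taxa) changes
between groups is called differentially connected (DC). Existing
differential-network tools for microbiome data compare networks between
groups but cannot adjust for covariates such as age or sex that are
themselves associated with group membership. dcnet addresses this with a
regression formulation: convert per-taxon network connectivity into
per-sample responses and fit an ordinary regression model with the group
indicator and any covariates as predictors.

Two properties of amplicon/metagenomic count data shape the whole design:
the counts are **compositional** (only relative information, constrained by
sequencing depth, so naive correlations are biased) and **sparse** (many
zero cells).

## The model and pipeline

For each group the pipeline runs five stages:

1. **Association matrix.** SparCC estimates correlations between latent
   "basis" abundances from compositional counts: compute fractions with a
   pseudocount, form log-ratio variances
   $t_{kj} = \mathrm{var}_i \log(f_{ik}/f_{ij})$, solve a linear system for
   basis variances $\omega_k$ under the sparsity assumption that most pairs
   are uncorrelated, and set
   $\rho_{kj} = (\omega_k + \omega_j - t_{kj}) / (2\sqrt{\omega_k\omega_j})$,
   clipped to $[-1, 1]$.
2. **Connectivity.** $\hat\theta_k = \sum_{j \ne k} |\rho_{kj}|$, the sum of
   absolute off-diagonal associations. A flag divides by $p-1$; this only
   rescales the response.
3. **Jackknife pseudo-values.** Re-estimate the group's network once per
   leave-one-out sample and form the Tukey pseudo-value
   $\tilde\theta_{ik} = n_g\,\hat\theta_k - (n_g - 1)\,\hat\theta_k^{(-i)}$.
   Row $i$ quantifies sample $i$'s influence on taxon $k$'s connectivity.
   Within a group the pseudo-value mean equals the jackknife estimate of
   $\theta_k$ — an exact identity the test suite checks to $10^{-10}$.
4. **Robust regression.** For each taxon, regress the stacked pseudo-values
   on an intercept, the 0/1 group indicator $Z$ and covariates $X$ with
   least trimmed squares (LTS). The coefficient on $Z$ is the
   covariate-adjusted group difference in connectivity influence; its
   q-value flags DC taxa.
5. **FDR.** Per model term, p-values across taxa are converted to Storey
   q-values; taxa with $q \le 0.05$ (configurable) on the group term are
   reported as DC.

In the paired two-timepoint mode the statistic in stages 1–2 is the
connectivity of the *difference* of the two timepoints' association
matrices within each group, the leave-one-out unit is the subject (both
records removed together, since removing one record would break the
pairing), and the group coefficient contrasts the *change* in connectivity
between groups. Covariates are taken from each subject's baseline record.
We treat the between-group contrast as the $Z$ term in this mode as well.

## Parameters that matter

* `c` (trim proportion, default 0.5): LTS minimizes the sum of the
  $h = \lfloor c\,n\rfloor + \lfloor (m+1)/2 \rfloor$ smallest squared
  residuals; `c = 1` is ordinary least squares. 0.5 is the usual robust
  default; the `dcnet_sweep()` helper tabulates how the DC set moves across
  a grid of `c` values (Jaccard overlaps).
* `pseudocount` (default 1): added to every cell before forming fractions,
  so log-ratios are defined in the presence of zeros. This is also the main
  attenuation knob: for very rare taxa the pseudocount dominates the signal.
* `exclusion_threshold` / `max_exclusion_rounds`: SparCC's iterative
  exclusion of strongly correlated pairs from the basis solve. `sparcc()`
  defaults to the classic threshold 0.1 with up to 10 rounds. **The
  pipeline default is `max_exclusion_rounds = 0`** — see "Numerical and
  design choices".
* `resampling_draws` (default 0): the original SparCC averages over
  Dirichlet-resampled fraction draws. The default here is the deterministic
  posterior-mean fraction (add-pseudocount), so each leave-one-out network
  differs from the full-data network only through the removed sample, never
  through Monte-Carlo noise. Draws remain available (seeded) for one-shot
  estimation.
* `pi0_method` (default `"auto"`): Storey's smoother estimate of the null
  proportion when at least 100 taxa are analyzable, Benjamini–Hochberg
  (`pi0 = 1`) below that. The smoother's spline extrapolation at
  $\lambda = 0.95$ is far too unstable with a few dozen p-values; with 15
  taxa it can collapse toward 0 and flag everything.

## Numerical and design choices

**Per-group pseudo-values.** Networks, connectivities and pseudo-values are
computed separately per group, each with its own $n_g$; rows are then
stacked in the original sample order. This is the only construction under
which the coefficient on $Z$ measures a between-group connectivity
difference.

**No exclusion rounds inside the jackknife.** The exclusion step is
discrete: between two leave-one-out subsets a taxon pair can flip in or out
of the basis solve, which moves the whole correlation matrix by a jump, and
the pseudo-value formula multiplies every leave-one-out perturbation by
$n_g$. With exclusion enabled the group coefficient's sampling noise grows
several-fold and the false positive rate under a complete null reaches
~30% at nominal 5%; without it the same study conditions are calibrated
(see the acceptance tests). The jackknife requires a smooth statistic, so
the pipeline disables the exclusion iteration by default while `sparcc()`
keeps it for one-shot network estimation, where it corrects the basis
variances in the presence of strong correlations.

**LTS search.** Exact enumeration of all $h$-subsets for $n \le 14$
(feasible and used as an oracle in tests); otherwise a seeded FAST-LTS
search: 500 elemental starts, two concentration steps each, and full
concentration iteration (up to 10) on the best 10 candidates. The basis
solve's negative solutions are floored at $10^{-8}$ with a warning rather
than failing, because a leave-one-out subset of sparse data occasionally
produces small negative basis variances and a single failure would abort
the whole jackknife.

**Inference and its calibration.** Standard errors come from an OLS refit
on the observations whose standardized raw-fit residuals are at most 2.5 in
magnitude (the classic reweighting step), with the standard truncation
consistency correction. Two finite-sample effects make the textbook recipe
anti-conservative: the asymptotic consistency factor underestimates the raw
LTS scale at realistic $n$ (so good observations get trimmed), and the
reweighting step retains exactly the observations that agree with the noisy
raw fit (so t-statistics are overdispersed). Because every taxon shares one
design matrix, both effects are removed by a single design-conditional
Monte Carlo calibration (`lts_calibration()`): simulate Gaussian null
responses under the run's own design, re-run the estimator, and estimate
(a) the raw-scale correction and (b) the null overdispersion of the
t-statistics, which multiplies the standard errors. The calibration is
seeded and deterministic; with `c = 1` nothing is trimmed and the output is
exactly classical OLS inference. p-values are reported from the reweighted
fit (the raw LTS fit has very low efficiency and no usable distribution
theory at these sample sizes).

**Degenerate fits.** A taxon whose reweighted residual variance is exactly
zero (e.g. a constant response, as in the two-timepoint self-difference
case) keeps its coefficient estimates but gets `NA` p-values and is
excluded from FDR; per-taxon failures never abort the run.

**Complete-case alignment.** Samples missing any selected model variable
are dropped with a logged count; zero-depth samples are rejected because
fractions are undefined for them. Categorical covariates expand to $k-1$
indicators against the first level in lexical order.

## The synthetic generator

`simulate_dcnet()` draws log-normal basis abundances with a block-structured
correlation matrix per group (the planted DC block is correlated in group A,
not in group B), converts them to fractions, samples counts multinomially at
log-normal sequencing depths, and applies abundance-dependent structural
dropout (probability `zero_inflation * exp(-count/10)`, so rare cells drop
out, dominant taxa never do). It also attaches a numeric covariate whose
mean is shifted between groups and a balanced categorical covariate. The
generator matches SparCC's own assumed model (log-normal basis), which makes
parameter-recovery tests directly interpretable.

Defaults: 40 samples per group, 30 taxa, a 5-taxon block at basis
correlation 0.7 vs 0.0, median depth 10,000 reads, depth log-sd 0.5,
dropout rate 0.05, covariate shift 0.5 sd. What it does **not** emulate:
taxonomic tree structure, over-dispersed (non-multinomial) technical noise,
abundance-dependent group effects, batch effects, and the extreme
(60%+ zero) sparsity of real 16S tables. Passing tests therefore show that
the machinery is correct and calibrated under the generator's model, not
that real-data discoveries are guaranteed at these sample sizes.

`simulate_dcnet_paired()` adds a per-subject log-abundance random intercept
shared across two timepoints and shifts the block correlation at timepoint
2 in one group only.

## Problem sizes used in validation

The packaged checks run at the scale a laptop handles in minutes: null
calibration at $2\times20$ samples, 15 taxa over 20 seeds; recovery at
$2\times40$ samples, 30 taxa over 20 seeds; SparCC parameter recovery at
$n = 1000$, $p = 20$; LTS-vs-enumeration at $n \le 13$ over 50 fixtures.

## Known limitations

* **Per-taxon power is modest.** The jackknife bias-correction term
  $n_g(\hat\theta - \hat\theta^{(-i)})$ amplifies the sampling noise of a
  non-smooth statistic (absolute values of estimated correlations). At
  $2\times40$ samples with a 5-taxon block (0.7 vs 0) the planted taxa are
  strongly enriched at the top of the ranking (AUC ≈ 0.8, most of the top
  5 planted) but a clean sweep — all five planted taxa ahead of every null
  taxon — is rare. Users should read the DC list as a ranking with FDR
  control, not an oracle.
* The two-timepoint mode differences two estimated networks, doubling
  estimation noise; it needs larger groups than the single-timepoint mode
  for comparable power.
* SparCC's sparsity assumption fails when most pairs are truly correlated;
  the basis-variance solve then biases all correlations.
* Calibration of the regression inference is design-conditional and
  Gaussian-null based; heavy-tailed pseudo-value distributions are handled
  by the LTS trimming, but exotic error laws are not re-calibrated.

## A worked run

```{r, eval = FALSE}
library(dcnet)

sim <- simulate_dcnet(simulation_design(n_per_group = 40, p = 30,
                                        dc_taxa = 1:5,
                                        dc_cor = c(A = 0.7, B = 0),
                                        seed = 11))
res <- dcnet(sim$counts, sim$meta, group_var = "group",
             covariates = c("x_num", "x_cat"), seed = 1)
res
head(qval(res, "group"))
dc_taxa(res)
write_results(res, "dcnet_out")
```
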