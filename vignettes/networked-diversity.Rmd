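---
title: "Estimating diversity in networked communities: model, algorithm, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diversity in networked communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdiv)
```

## The estimand and the model

An α-diversity index is a function $f$ of a community's relative-abundance
vector $z$ on the simplex (Shannon entropy $-\sum_q z_q \log z_q$, Simpson
$\sum_q z_q^2$); a β-diversity index is a function $g$ of two such vectors
(Bray–Curtis $1 - \sum_q \min(z_{1q}, z_{2q})$, Euclidean distance). The
target of estimation in this package is the diversity of the *community* a
sample was drawn from — a population quantity — not a summary of the sample
itself, which is what plug-in estimates describe.

The model is the logistic-normal multinomial. Fix a base taxon $D$ and let
$\phi$ be the additive log-ratio transform,
$\phi(z)_q = \log(z_q / z_D)$ for $q \neq D$, a bijection between the open
simplex and $\mathbb{R}^{Q-1}$. For communities $i = 1, \dots, n$ with
covariates $X_i \in \mathbb{R}^p$:

$$
Y_i \sim N_{Q-1}(X_i^\top \gamma, \Sigma), \qquad
Z_i = \phi^{-1}(Y_i), \qquad
W_i \mid Z_i \sim \mathrm{Multinomial}(M_i, Z_i).
$$

The multinomial layer captures sequencing noise at depth $M_i$; the
Gaussian layer captures biological variation, and its off-diagonal
covariance is exactly the co-occurrence network a multinomial-only model
forbids. As $\lVert \Sigma \rVert_\infty \to 0$ the model collapses to a
single multinomial per covariate profile, and the estimates collapse to the
pooled plug-in — a limit the test suite verifies.

Diversity estimates are
$\hat{\alpha}_i = f(\phi^{-1}(X_i^\top \hat\gamma))$ and
$\hat{\beta}_{ij} = g(\hat{Z}_i, \hat{Z}_j)$. Two consequences worth
stating plainly:

* Estimates are properties of the *covariate profile* (the unique row of
  $X$): samples sharing a profile share estimates, and the β-diversity
  between two samples with the same profile is zero by construction.
  Within-profile dissimilarity is not an estimand of this model; the
  package reports a sample-to-profile map rather than pretending otherwise.
* Profiles never seen in the survey can be estimated from their covariates
  alone (`fitted_compositions(fit, newdata = ...)`).

**Assumptions.** Counts are conditionally independent across samples given
$X$ — the model does not apply to temporally or spatially correlated
series. Taxa absent from *every* sample are invisible to it; no
missing-taxa correction is attempted (the Chao–Shen classical estimator is
provided for users who need one and can live with its restrictions).

## Fitting: Monte-Carlo EM

$\eta = (\gamma, \Sigma)$ is estimated by maximum likelihood via EM,
treating $Y$ as missing data. The E-step expectation is approximated with
$R$ Metropolis draws from $Y_i \mid W_i, \eta^{(t)}$; the M-step is closed
form:
$\gamma^{(t+1)} = \frac{1}{R}\sum_r (X^\top X)^\dagger X^\top Y^{(r)}$ and
$\Sigma^{(t+1)} = \frac{1}{nR}\sum_{r,i}
(Y_i^{(r)} - \mu_i^{(t)})(Y_i^{(r)} - \mu_i^{(t)})^\top$, where $\dagger$
is the Moore–Penrose generalized inverse. Residuals are centered at the
*previous* iteration's mean by default, matching the update as usually
printed; `em_config(center_at_updated_mean = TRUE)` switches to the
standard-EM choice of centering at $X\gamma^{(t+1)}$. The two differ by a
term of order of the per-iteration change in $\gamma$ and agree at
convergence.

Initialization is deterministic: $\gamma^{(0)}$ is the least-squares fit of
the observed perturbed log-ratios on $X$ and $\Sigma^{(0)}$ the residual
covariance (divided by $n$, the MLE convention). The multinomial
coefficient is dropped throughout — it cancels in every Metropolis ratio
and does not affect maximization.

### The proposal distribution, and why the default is coordinate-wise

The conditional density of $Y_i$ combines
$\log \Pr(W_i \mid Y_i) = \sum_{q \neq D} W_{iq} Y_{iq} -
M_i \log(\sum_{q \neq D} e^{Y_{iq}} + 1)$ with the Gaussian term. A
spherical joint proposal $Y^* \sim N(Y^{(r-1)}, vI)$ has expected
log-acceptance-ratio approximately $-\tfrac{v}{2}\,\mathrm{tr}(H)$ at
stationarity, and the multinomial Hessian trace is
$\mathrm{tr}(H) \approx M_i (1 - Z_{iD})$. At a realistic sequencing depth
$M_i = 10^4$ and the conventional step size $v = 0.01$ this is $\approx
-50$: the joint proposal essentially never accepts, the chain never moves,
and the E-step silently degenerates to the initialization. For this reason
the default sampler updates *one coordinate at a time* with $N(y_q, v)$
proposals in a systematic sweep (one retained draw = one full sweep,
implemented in C++ with $O(Q)$ incremental density updates). Per-coordinate
curvature is $\approx M_i Z_{iq} + \Omega_{qq}$, small for the many rare
taxa of a real community, so acceptance stays high — around 80% on
model-simulated data at depth $10^4$–$10^5$, comfortably above the 30%
floor the acceptance suite checks. The printed-form joint proposal remains
available (`mh_config(proposal = "joint")`) and is cross-validated against
the same quadrature oracle on a two-taxon toy posterior.

Chains are initialized at the observed log-ratios
$\phi(W_i^{(\rho)} / M_i)$ — the posterior is centered near them — which is
also why perturbation must precede sampling: the transform is undefined at
zero counts.

### Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `v` | 0.01 | proposal variance per coordinate (log-ratio scale); the conventional step size, giving high per-coordinate acceptance |
| `burn`, `r_draws` | 500, 500 | discarded / retained sweeps; trace diagnostics (`plot_trace`) justify these at microbiome scale |
| `n_iter` | 6 | EM iterations; parameter norms stabilise well before this on simulated data |
| `rho` | 0.5 | zero perturbation, added to *all* counts; the conventional half-count. Estimates depend noticeably on $\rho$ near 0 — scan it (`sensitivity_scan(scan = "rho")`) when zeros are plentiful |
| base taxon | auto | most abundant taxon present in every sample: $\partial \log(x/y)/\partial y = -1/y$ is smallest for abundant denominators, and estimates are empirically near-invariant among such choices (tested: < 5% relative spread) |
| `precision_method` | `"naive"` | how $\Sigma^{(t)\,-1}$ is formed for the E-step: generalized inverse (default; cheapest, permits networks), `"diagonal"` (overdispersion only), `"glasso"` (sparse network) |
| `b_reps` | 5 | bootstrap replicates; the benchmark studies used 3 to limit cost, 5 is a mildly safer default with the flag exposed |
| `n_sub` | `n` | nonparametric resample size |

### Precision-matrix variants and the in-package graphical lasso

When $Q - 1 \gg n$, the generalized inverse of the sample covariance is a
poor precision estimate. Two regularized alternatives are provided. The
diagonal MLE allows within-taxon overdispersion but no interactions. The
graphical lasso maximizes the $\ell_1$-penalized Gaussian likelihood; no
penalized-precision package ships with the environments this package
targets, so the classic block coordinate-descent algorithm (lasso
subproblems solved by coordinate descent) is implemented here. The penalty
is chosen by stability selection: edge-selection frequencies over 12 row
subsamples of the residual matrix, on an 8-point log-spaced penalty path
padded 1.5× above the largest off-diagonal covariance (so the sparsest path
point is empty on subsamples too), monotonized instability
$\overline{D}(\lambda)$, and the densest $\lambda$ with
$\overline{D} \le 0.05$ — the convention of the stability-selection
literature for microbial networks. When no residual observations are
available, Gaussian pseudo-observations drawn from $\Sigma$ stand in.

### Determinism

Every stochastic API takes a seed, and per-sample chain seeds are derived
by hashing the master seed with the EM iteration and the *sample label*
(falling back to the row index). Consequently a fit is bit-identical across
runs, invariant to the order in which per-sample chains execute, and
permuting the rows of a labelled count table permutes — but does not
change — each sample's draws. All derived seeds stay below $2^{31}$.

## Bootstrap variance

The parametric bootstrap simulates $B$ datasets from the fitted model (same
$X$, same depths $M_i$), refits each with the original MH/EM configuration,
and takes the sample variance of the resulting estimates; the variance thus
reflects the whole pipeline, including Monte-Carlo noise. Bootstrap refits
re-run the full precision-estimation procedure (including glasso penalty
selection when selected) — costly, but anything less would understate
variance. The nonparametric bootstrap resamples rows with replacement,
redrawing (up to 10 times) resamples whose design matrix loses rank.

Two facts, both reproduced by the acceptance suite, temper interpretation
at very small $B$: (i) a $B = 3$ sample variance is $\chi^2_2$-skewed, so
its *median* is about 69% of its mean even for a perfectly calibrated
scheme; (ii) simulating and refitting attenuates $\Sigma$ slightly (zero
counts cap the perturbed log-ratios), so parametric bootstrap variances
lean low. In the package's calibration study the nonparametric scheme's
median error is negative (it underestimates), as expected; the parametric
scheme's median error is also negative rather than centered at zero — the
two mechanisms above account for this, and the suite records the
discrepancy rather than papering over it. The parametric scheme remains the
default: its replicates live on the original design (every profile always
present) and its variance reflects the model actually fitted.

## The synthetic-data generator

`simulate_dataset()` draws $(Y, Z, W)$ exactly along the generative model,
so tests can use the latent truth as an oracle. `design_from_template()`
builds the benchmark world this package uses throughout: $n = 12$
communities, intercept-plus-binary-group design with a third of samples in
the second group, sequencing depths uniform on $[10^4, 10^5]$ — the shape
of a small 16S rock-biofilm survey. Random parameters are: intercept
log-ratios $N(0, 2^2)$, chosen so latent compositions span the 4–5 orders
of magnitude of abundance typical of amplicon data; group effects
$N(0, 0.5^2)$; and a factor-model covariance
$\Sigma = s_{\mathrm{net}} A A^\top / k + s_{\mathrm{diag}} I$ with
$k = \max(2, (Q-1)/10)$ factors. `network_strength` ($s_{\mathrm{net}}$) is
the documented knob for co-occurrence strength: 0 means no network, 1 a
moderate one, 5 the "strongly networked" regime in which the model-based
estimator shows its largest gains over the plug-in (a fixed-seed MSE
comparison in the acceptance suite). A real survey's latent covariance —
whose top eigenvalue can be in the hundreds — is not reproduced
spectrally; eigenvalue scale is exposed rather than imitated.

`design_from_counts()` implements the benchmark *calibration* construction:
given a mother dataset, $\gamma$ and $\Sigma$ are the OLS fit and residual
covariance of its perturbed observed log-ratios, with the observed depths.
Simulation from such a design is self-consistent with how the model is
fitted, which is what makes bootstrap-calibration studies meaningful.

What the generator does **not** emulate: taxa absent from all samples,
phylogenetic structure, batch effects, and temporal or spatial correlation.
A green test on simulated data therefore establishes correctness of the
algorithmic pipeline under the model's own assumptions — not robustness to
their violation.

## Numerical choices and degenerate inputs

* Simplex membership is validated to $10^{-10}$ absolute on the sum
  (double precision); $\phi^{-1}$ is computed with a max-shift and
  normalised last, so its output sums to 1 exactly and round-trips to
  $10^{-12}$.
* Generalized inverses and pseudo-determinants treat eigenvalues below
  $\dim \times \varepsilon_{\mathrm{mach}} \times \lambda_{\max}$ as zero;
  the Gaussian log-density is finite for singular $\Sigma$ whenever the
  displacement lies in the column space.
* $0 \log 0 = 0$ throughout; zero-count taxa contribute nothing to plug-in
  indices and are excluded from Chao–Shen sums. The Chao–Shen exponent is
  the sample total $M$ (the source notation is ambiguous between $n$ and
  $M$; for a single community the original estimator's sample size *is*
  its total count). The "corrected" Simpson multiplies the plug-in by
  $M/(M-1)$ — the literal benchmark scaling; note the classical unbiased
  estimator $\sum_q W_q(W_q - 1)/(M(M-1))$ differs, negligibly for
  $M > 1000$.
* Base-taxon ties break to the lowest index; if no taxon is present in all
  samples the overall most abundant taxon is used, with the same
  tie-break.
* Rank-deficient designs are handled by generalized inverse (no error);
  all-zero covariate columns, $p > n$, and $\rho = 1$ warn; $n = 1$ with
  $p > 1$, $\rho \le 0$, all-singleton Chao–Shen input, and all-zero count
  tables are errors with messages naming the offender.

## Known limitations

Beyond the model assumptions above: the number of parameters in $\gamma$
grows with $Q$, and no sparsity is imposed on it; $\Sigma$'s estimate is
attenuated by the zero perturbation when data are very sparse, and the MLE
$1/n$ scaling shrinks it further at small $n$; estimates depend materially
on $\rho$ when a large fraction of counts is zero (scan it); and the
within-profile β-diversity is structurally zero, so questions about
replicate-to-replicate dissimilarity need a different tool.
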