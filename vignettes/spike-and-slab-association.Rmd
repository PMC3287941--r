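---
title: "Spike-and-slab Bayesian variable selection for variant association"
author: "snpBVS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-and-slab Bayesian variable selection for variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpBVS)
```

## The model

Single-variant tests are underpowered for rare variants (minor allele
frequency, MAF, below 1%): each carries too few carriers to reach
significance on its own.  `snpBVS` instead models **all SNPs
simultaneously** in one linear regression and lets a sparsity prior decide
which of them carry signal:

$$
y = \mu 1 + X (\theta \circ \alpha) + \epsilon, \qquad
\epsilon \sim N(0, \sigma^2_\epsilon I),
$$

where $y$ is the quantitative trait over $n$ individuals, $X$ the
$n \times p$ dosage matrix (0/1/2 copies of the alternate allele),
$\alpha_j$ the effect of SNP $j$ and $\theta_j \in \{0, 1\}$ a latent
inclusion indicator; $\circ$ is the element-wise product.  The prior
structure is the classic spike-and-slab with a shared slab variance:

* $\theta_j \sim \mathrm{Bernoulli}(\pi)$, the same $\pi$ for every SNP,
  with $\pi \sim \mathrm{Beta}(a_0, b_0)$ (uniform by default), so the
  prior on the model size $k = \sum_j \theta_j$ is Binomial$(p, \pi)$
  with $\pi$ learned from the data;
* $\alpha_j \mid \theta_j = 1 \sim N(0, \sigma^2_\alpha)$, with
  $\sigma^2_\alpha \sim \mathrm{ScInv}\chi^2(v_\alpha, S_\alpha)$;
* $\sigma^2_\epsilon \sim \mathrm{ScInv}\chi^2(v_\epsilon, S_\epsilon)$;
* flat prior on the intercept $\mu$.

All full conditionals are conjugate, so the posterior is explored with a
plain Gibbs sampler.  Each scan updates, in order:
$\sigma^2_\epsilon$, then $\mu$, then each pair $(\theta_j, \alpha_j)$
for $j = 1 \dots p$ in fixed ascending column order, then
$\sigma^2_\alpha$, then $\pi$.

The $(\theta_j, \alpha_j)$ update is *partially collapsed*: with the
contribution of SNP $j$ removed from the residual,
$r_{-j} = r + \theta_j \alpha_j x_j$, the sufficient scalar
$u_j = x_j' r_{-j}$ has distribution $N(0, c_{jj}\sigma^2_\epsilon)$ when
the SNP is excluded and $N(0, c_{jj}\sigma^2_\epsilon +
c_{jj}^2\sigma^2_\alpha)$ when its effect is integrated over the slab
($c_{jj} = x_j'x_j$).  The indicator is drawn from the resulting posterior
odds (computed in log space for numerical safety), and only if
$\theta_j = 1$ is a new effect drawn, from
$N(u_j / c_j, \sigma^2_\epsilon / c_j)$ with $c_j = c_{jj} +
\sigma^2_\epsilon / \sigma^2_\alpha$.  Excluded effects contribute exactly
zero — no phantom draw is stored.  Collapsing makes the indicator update
valid without conditioning on a current $\alpha_j$ and mixes much better
than updating $\theta_j$ given $\alpha_j$.

The per-SNP **posterior probability of association (PPA)** is the
proportion of post-burn-in samples with $\theta_j = 1$, and the reported
effect is the posterior mean of $\theta_j \alpha_j$.  The default
protocol is 15,000 iterations with the first 1,000 discarded (no
thinning); the number of associated SNPs is summarised by the posterior
mode of $k$, with ties broken toward the smaller model (parsimony).

## Defaults and tunable parameters

| parameter | default | units / rationale |
|---|---|---|
| `nIter`, `burnIn` | 15000, 1000 | the standard analysis protocol |
| `vEps`, `sEps` | 10, $\mathrm{var}(y)/2$ | weakly informative, centres the residual variance on half the trait variance |
| `vAlpha`, `sAlpha` | 4, $\mathrm{var}(y)/(2\,k_{exp})$ | slab sized so that $k_{exp}$ (default 10) effects could absorb half the trait variance |
| `a0`, `b0` | 1, 1 | uniform prior on $\pi$ |
| `recomputeResidEvery` | 1000 | period of the from-scratch residual recomputation |

Everything is overridable through `bvsPriors()` / `defaultPriors()`, and
the testing hooks `fixSigma2Eps`, `fixSigma2Alpha`, `fixPi`, `fixMu`
freeze a parameter and silently skip its update — these are what make the
sampler exactly comparable with the enumeration oracle below.

Two design points were genuinely open and are worth recording.  First,
the slab variance could be shared across loci or per-locus (BayesB
style).  The shared form is the default because the conditional update
pools the whole vector of non-zero effects; the per-locus alternative is
available via `sharedSlab = FALSE` and uses the same scan with one
scaled-inverse-chi-square draw per locus.  Second, whether the indicator
or the effect is drawn first is not uniquely determined by the conjugate
algebra; the collapsed order (indicator first, effect only if included)
is used because it is a valid partially-collapsed Gibbs scheme and is
validated against exact enumeration.

## Numerical choices

* Inclusion odds are computed from log-densities; the implementation
  uses the algebraically identical one-log form
  $\mathrm{logit}(\pi) - \tfrac12\log(v_1/v_0) + \tfrac12 u_j^2(1/v_0 -
  1/v_1)$.
* The residual vector is updated incrementally ($O(\mathrm{carriers})$
  per SNP thanks to a sparse column representation in the compiled
  engine) and recomputed from scratch every 1,000 iterations; after any
  number of scans the drift stays below $10^{-6}$ relative to the
  phenotype scale.
* Monomorphic SNPs (constant dosage) are excluded from updates, keep
  PPA 0, and are flagged.  Missing dosages are imputed to the SNP's mean
  observed dosage before fitting.
* A pure-R reference engine (`engine = "R"`) consumes the identical
  random stream as the compiled engine; the test suite asserts that the
  two produce identical inclusion trajectories from the same seed.
* Rank ties (identical scores) are broken by ascending SNP index.

## The exact enumeration oracle

For $p \le 14$, `enumeratePosterior()` computes the posterior over all
$2^p$ inclusion patterns exactly at fixed $(\sigma^2_\epsilon,
\sigma^2_\alpha, \pi)$: the slab effects integrate out to the marginal
likelihood $N(y; 0, \sigma^2_\epsilon I + \sigma^2_\alpha X_\gamma
X_\gamma')$, evaluated through the $k \times k$ matrix
$I + (\sigma^2_\alpha/\sigma^2_\epsilon) X_\gamma'X_\gamma$ and
normalised by log-sum-exp (weights under $10^{-300}$ are flushed to
zero).  The intercept is handled by centring $y$, matched on the sampler
side by the fix-$\mu$-at-0 hook.  This gives exact PPAs and the exact
distribution of $k$, against which the Gibbs inclusion frequencies are
required to agree within $\pm 0.02$ at 50,000 iterations — the package's
primary correctness gate.

```{r oracle, message = FALSE}
set.seed(5)
X <- sapply(runif(6, 0.1, 0.4), function(m) rbinom(120, 2, m))
y <- 0.6 * X[, 2] + rnorm(120); y <- y - mean(y)
pr <- bvsPriors(fixSigma2Eps = 1, fixSigma2Alpha = 0.3, fixPi = 0.1,
                fixMu = 0)
fit <- runChain(X, y, pr, bvsChainConfig(nIter = 20000, seed = 1))
exact <- enumeratePosterior(X, y, 1, 0.3, 0.1)
round(rbind(gibbs = ppa(fit), exact = ppa(exact)), 3)
```

## The simulator: what it emulates, and what it does not

`simulateGenotypes()` / `simulatePhenotypes()` produce a mini-exome
benchmark patterned on the replication design of shared exome-study
benchmark datasets: a **fixed**
genotype matrix of unrelated individuals (697 by default) and many
(200 by default) phenotype vectors re-drawn over it, so that estimates
can be averaged across replicates exactly as in the real analysis.
Specifics:

* MAFs are drawn **log-uniform** over 0.000717–0.499283 so the rare tail
  is well populated, with a configurable fraction (default 0.5) forced
  below 1%; dosages are Binomial(2, MAF) under Hardy–Weinberg.
* SNPs fall into contiguous gene blocks; causal SNPs are placed inside
  designated blocks.  Presets: `q1` (39 causal SNPs in 9 genes), `q2`
  (72 in 13), `q4` (a null trait), and `q1scaled` — a desk-scale
  recovery benchmark with 500 individuals, 1,000 SNPs, 10 causal of
  which exactly 5 are rare.
* Effect sizes are log-uniform in magnitude with random sign; the
  `invmaf` mode scales $|\beta_j| \propto 1/\sqrt{2\,\mathrm{MAF}(1-
  \mathrm{MAF})}$ so rare variants carry larger per-allele effects, the
  regime the rare-variant literature postulates.  `q1scaled` uses this
  mode so that rare causal SNPs remain detectable at $n = 500$.
* $\beta$ is rescaled once, at genotype-simulation time, so that
  $\mathrm{Var}(X\beta) = h^2$ against unit total variance
  ($\sigma^2_e = 1 - h^2$); the heritability default $h^2 = 0.4$ is a
  package choice, not an external value.

Deliberately **not** simulated: linkage disequilibrium (columns are
independent; a duplicate-column injector exists to create one
perfect-LD pair on demand, the scenario that produces a linked false
positive), population structure, relatedness, and ascertainment.
Passing the recovery tests therefore says the method ranks independent
causal variants correctly under HWE at the stated $n$, $p$ and $h^2$;
it does not certify behaviour under strong LD or stratification.

## Evaluation

Replicate fits are averaged per SNP (mean |posterior effect| and mean
PPA), ranked in decreasing order under each score with index
tie-breaking, and a SNP is **called** associated when its rank is within
the replicate range maximum of the estimated number of SNPs under
*both* rankings (the conjunction being the stricter and better-calibrated
rule; single-score calling is a flag).  ROC curves sweep every distinct
score as a cutoff plus a sentinel so the curve starts at (0, 0); the
trapezoidal AUC equals the causal-vs-null concordance probability with
ties counted one half, which the tests verify against an independent
pairwise implementation.  The rare-variant ROC restricts both numerators
and denominators to SNPs below the MAF threshold (default 1%).

## Validation scales

The checked-in validation uses problem sizes chosen to exercise the
claims while staying desk-sized: the enumeration comparison at
$n = 100$, $p = 8$ with 50,000 iterations; the conjugate intercept-only
check with 20,000 retained draws; the `q1scaled` recovery benchmark
(10 independent repetitions of 20 replicate chains at the default
protocol); and null calibration at $n = 200$, $p = 100$ with $\pi$ fixed
at 0.01 over 5 seeds of 5 replicates each.  The same quantities are
recomputed end-to-end by `scripts/acceptance.R`.

## Known limitations

* Only an intercept besides the SNPs: no covariate adjustment and no
  binary-trait (probit/liability) variant of the model.
* A shared $\pi$ across SNPs means power concentrates on the variants
  with the largest variance contributions; weak rare effects shrink
  toward zero, so rare-variant power is expected to trail common-variant
  power unless effects scale inversely with MAF.
* Perfectly correlated SNPs split inclusion mass between them; with
  rank-based calling both members of a perfect-LD pair can be called
  (one being a linked false positive).  Collapsing correlated SNPs into
  blocks is out of scope here.
* No convergence diagnostics beyond the hyperparameter trace
  (`hyperTrace()`); the enumeration oracle is the intended correctness
  instrument at small $p$.
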