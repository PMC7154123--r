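---
title: "Methods: haplotype and SNP mixed models in haploblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype and SNP mixed models in haploblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`haploblup` fits

$$ y = Xb + Z\,(W_\alpha \alpha_o + W_\delta \delta_o + W_{\alpha h}\alpha_{ho}) + e $$

where $y$ holds the $N$ training observations, $X$ the fixed effects
(intercept, class factors as treatment contrasts, covariates, optionally
individual SNPs), and $Z$ the $N \times n$ incidence allocating
observations to the $n$ genotyped individuals — the identity when every
individual has one record, a row-selection matrix when validation
individuals have none. The three random terms are SNP additive values,
SNP dominance values, and haplotype additive values; any subset can be
fitted, giving seven models selected in the parameter file by which
starting variances are active.

**Codings.** A haplotype block is a set of consecutive mapped SNPs; each
distinct phased allele string within it is one allele of a multi-allelic
locus. Alleles are numbered by descending frequency (ties broken
lexicographically on the string), which pins down allele 1 — the
reference whose substitution effect is not parameterized — without any
arbitrary choice. For allele $k \ge 2$ with frequency $p_k$ the coding
of an individual is $2p_k$ (no copy), $-(1-2p_k)$ (one copy) or
$-2(1-p_k)$ (two copies); all three cases equal $2p_k$ minus the copy
number, so the SNP additive coding $2p - x$ is the biallelic special
case and, for single-SNP blocks, the haplotype matrix reproduces the SNP
matrix up to the sign of the allele-labeling choice (which cancels in
every downstream quantity). Dominance uses the single-SNP values
$-2q^2,\ 2pq,\ -2p^2$. All frequencies are observed sample frequencies
over **all** individuals, training and validation alike, because the
relationship matrices must cover everyone who will receive a prediction;
columns built this way sum to exactly zero.

**Relationship matrices.** Each component's genomic relationship matrix
is $G = WW'/k$ with $k = \mathrm{tr}(WW')/n$, the mean diagonal of
$WW'$. This normalization forces $\mathrm{tr}(G) = n$, so the attached
variance component is the average individual variance of that term and
heritabilities are comparable across components and across populations
(including inbred ones). The alternative normalization by total
heterozygosity is deliberately not provided. The numerator is additive
over column chunks, $WW' = \sum_i W_iW_i'$, provided no haplotype
block's columns are split across chunks; `partial_numerator()` /
`combine_partials()` implement exactly that contract so chunks can be
computed by independent processes, and a binary cache
(`save_grm_cache()`) lets validation folds 2..k reload matrices computed
once. The cache records a digest of the ordered sample identifiers and
refuses to load against a different set or order — reuse across runs
makes silent misalignment the dominant failure mode.

## GREML

With $V = \sum_i \sigma_i^2 Z K_i Z' + \sigma_e^2 I_N$ and
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-}X'V^{-1}$, the restricted
log-likelihood is $-\tfrac12(\log|V| + \log|X'V^{-1}X| - \log|X'X| +
y'Py)$; the $\log|X'X|$ term makes the value invariant to
reparameterizing $X$, and $X$ is reduced to full column rank on the
training rows (first level of each factor dropped) so the generalized
inverse is an ordinary inverse in practice.

Iterations use the hybrid schedule: iterations 1–2 are always EM-REML,

$$ \sigma_i^2 \leftarrow \sigma_i^2 +
   (\sigma_i^2)^2\,[\,y'PV_iPy - \mathrm{tr}(PV_i)\,]/n, $$

(residual analogous with divisor $N$), and from iteration 3 (the
`ai_start_iteration` control) AI-REML proposes the Newton-type step
$\theta' = \theta + \mathrm{AI}^{-1}s$ with scores
$s_i = -\tfrac12[\mathrm{tr}(PV_i) - y'PV_iPy]$ and
$\mathrm{AI}_{ij} = \tfrac12\, y'PV_iPV_jPy$. AI *fails* — a signaled
outcome, not an error — when its matrix is not positive definite, a
proposed variance is non-positive, or the restricted likelihood would
decrease; the iteration then falls back to a single EM step. Because EM
is monotone in the likelihood, the hybrid cannot diverge, and both
schedules maximize the same function, so EM-only and hybrid runs agree
at convergence; the test suite verifies this agreement and checks both
against a direct numerical maximization of the restricted likelihood on
small fixtures.

**Stopping and tolerances.** Iteration stops when *either* the largest
relative variance change $\max_i|\Delta\sigma_i^2|/\sigma_P^2$ drops
below `tolerance_var` (default $10^{-8}$) or the largest absolute
heritability change drops below `tolerance_h2` (default $10^{-6}$).
Heritabilities are rarely reported beyond three decimals, so the looser
heritability tolerance cuts the long EM tail near a boundary without
affecting reported precision. Variances are floored at
$10^{-10}\sigma_P^2$ rather than zero to keep $V$ invertible; a
component pinned at the floor for ten consecutive iterations is flagged
`near_zero`, supporting the recommended workflow of starting from the
full model and pruning negligible components. Heritability standard
deviations use the delta method with the inverse AI matrix at
convergence as the asymptotic covariance of the variance estimates (the
pseudo-inverse when AI is numerically singular).

Each iteration costs one Cholesky factorization of the
$N \times N$ matrix $V$; traces $\mathrm{tr}(PV_i)$ are elementwise sums
$\sum P \circ V_i$ and the AI quadratic forms are matrix-vector
products, so nothing beyond that single $O(N^3)$ factorization is cubic.

## GBLUP, reliability, marker partitions

At converged variances, $\hat b = (X'\hat V^{-1}X)^{-}X'\hat V^{-1}y$
and each component's BLUP is $\hat u_i = \hat\sigma_i^2 K_i Z'\hat Py$,
an $n$-vector: validation individuals are predicted purely through
relationship covariances (a zero relationship row gives BLUP 0). The
reliability of the BLUP sum over a component subset $S$ is

$$ R^2_{(i)} = \frac{\big(G_S\, Z'PZ\, G_S\big)_{ii}}
                    {\sum_{j\in S} (K_j)_{ii}\,\hat\sigma_j^2},
   \qquad G_S = \sum_{j\in S}\hat\sigma_j^2 K_j , $$

whose expansion over ordered component pairs reproduces the full
cross-term formula (nine terms for three components); singleton $S$
gives component reliabilities. The denominator uses the individual's own
prior variance $(K_j)_{ii}\hat\sigma_j^2$, so reliabilities lie in
$[0,1]$ individual by individual.

Per-SNP effects are back-solved on the original scale,
$\hat\alpha_o = (\hat\sigma_\alpha^2/k_\alpha) W_\alpha' Z'\hat Py$,
which reconstructs $W_\alpha\hat\alpha_o = \hat a$ exactly. The
per-marker heritability of SNP $j$ is defined here as
$(\hat\sigma_\alpha^2/k_\alpha)\,\overline{w_{\cdot j}^2}/\hat\sigma_P^2$
(mean squared coding value over individuals), and per block as the sum
over the block's columns. This definition was an open design point — the
output exists in the workflow this package implements but no formula is
published for it — and was chosen because it is nonnegative and
partitions each component heritability *exactly*: the per-SNP values sum
to $\hat h^2_\alpha$ by construction, which the tests assert to
$10^{-12}$. Genomic + non-genetic prediction is
$\hat y = X\hat b + \hat g$ per the fitted model's component sum; it
requires at most one observation per individual so the individual-level
fixed-effect row is unambiguous.

## Validation machinery

`make_folds()` draws a seeded uniform partition with fold sizes
differing by at most one (no stratification). `run_validation()` masks
each fold in turn, refits, and reports; relationship matrices are built
exactly once and reloaded from the binary cache for the remaining folds
— they do not depend on which phenotypes are masked. Observed accuracy
is the Pearson correlation between the predicted genetic values and the
held-out phenotypes of a fold; expected genetic accuracy averages
$\sqrt{R^2}$ over the fold's validation individuals and then over folds,
and expected phenotypic accuracy multiplies by $\sqrt{h^2}$, taking
$h^2$ as the training-fold heritability of the predicted component sum
averaged over folds (the choice is left to the analyst in the original
workflow; this is the package's default).

## The synthetic-data generator

Haplotypes follow a mosaic-of-founders model: per chromosome, a panel of
$f$ founder haplotypes (allele frequencies uniform in `maf_range`), and
each of the $2n$ sample haplotypes copies a random founder, switching to
a new random founder with probability $r$ per SNP. This produces
blockwise LD and — crucially for exercising the multi-allelic coding —
recurrent haplotypes, so blocks carry $h \ll 2n$ distinct alleles
(at most $f$ when $r = 0$). A coalescent simulator would add realism
(variable allele ages, recombination hotspots, rare variants) but no
additional test power for the estimator's contracts, which is why the
lighter model was chosen. What the generator does **not** emulate:
genotyping error, phasing error (inputs are perfectly phased by
construction), pedigree structure, selection, and population
stratification. Passing recovery tests therefore demonstrate
correctness of the estimator under a correctly specified model, not
robustness to those real-data complications.

Phenotype components are simulated on the model's own codings (standard
normal effects at `n_causal` random SNPs/blocks) and each component
vector is rescaled so its *sample* variance (denominator $n-1$) equals
the target exactly; the residual is rescaled likewise. Recovery tests
thus have sharp truth instead of an $O(1/\sqrt n)$ fuzz around it.
Dominance effects are drawn directly on the dominance coding so the
fitted model is correctly specified.

## Identifiability of SNP-additive versus haplotype-additive variance

The SNP additive coding of any SNP is a linear combination of its
block's haplotype allele codings, so the column space of $W_\alpha$ is
nested inside that of $W_{\alpha h}$. The two *relationship matrices*
still differ (they weight those directions differently), so the
variance components are identified — but weakly: the restricted
likelihood has a flat ridge along trades between
$\sigma_\alpha^2 A_g$ and $\sigma_{\alpha h}^2 A_{gh}$. At the test
scale (n = 1000, m = 2000, 5-SNP blocks) single-replicate estimates of
$h^2_\alpha$ carry asymptotic SDs above 0.1 while their *sum* with
$h^2_{\alpha h}$ is tight; the recovery criterion is accordingly stated
on means over 20 replicates. This is a property of the model class, not
of the implementation, and is the statistical reason the workflow
recommends comparing the seven models by validation accuracy rather than
by the variance split alone.

## Numerical choices and problem sizes

* Sign convention $w = 2p - x$ (the haplotype formula's biallelic
  limit); the common $x - 2p$ is its negative and changes nothing
  downstream.
* Allele frequencies and haplotype frequencies use exact integer counts
  over $2n$; allele-code ties break lexicographically with radix
  ordering, independent of locale.
* kb blocking anchors windows at each chromosome's first SNP position,
  making partitions invariant to global coordinate shifts; whether the
  upstream tool anchors at zero is unknown, so equivalence with it is
  not claimed.
* Missing genotypes or alleles are hard errors (phasing/imputation is an
  upstream step); the missing-phenotype token defaults to `NA` and is
  configurable.
* EM near a variance boundary converges geometrically with factor
  approaching 1; runs that pin a component near zero may need thousands
  of iterations under the default tolerances, which is expected and is
  why the heritability tolerance exists.
* Test-suite problem sizes: unit fixtures n = 25–200; recovery studies
  n = 1000, m = 2000 (20 replicates) and a null study at n = 500
  (10 replicates); validation calibration n = 1000 with 10 folds. These
  sizes make the whole suite run in tens of minutes on one CPU while
  keeping the statistical bands meaningful.

## Known limitations

Haplotype dominance is not modeled (many block genotype classes are
unobserved at realistic sample sizes, leaving those effects
undefined). Single-trait only. No pedigree relationships, no
LD-based or annotation-based block *discovery* (user-supplied intervals
cover those use cases), and no VanRaden-normalized relationship matrix.
Multi-node processing is realized as independent chunk processes plus a
combine step — the mathematical and file contract — not a cluster
scheduler.
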