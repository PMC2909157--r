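---
title: "Methods: the multibreed maternal animal model and its Gibbs sampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multibreed maternal animal model and its Gibbs sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Consider weaning-weight records `y` on animals descending from two breeds,
A and B, connected by a pedigree that includes purebreds, F1–F4 inter-se
crosses, backcrosses and rotational crosses. The package fits the maternal
(Willham-type) multibreed animal model

```
y = X b + sum_X ( Z_oX a_oX + Z_mX a_mX ) + Z_p e_p + e,     X in {A, B, S}
```

* `b` — fixed effects: sex, age-of-dam class, day of birth (covariate),
  plus direct and maternal *breed* (expected breed-A fraction of the animal
  and of its dam) and *heterosis* (expected probability that a random locus
  pairs one A with one B allele) regressors that absorb mean differences
  between breed groups.
* `a_oX`, `a_mX` — direct and maternal breeding values *by breed origin*:
  one pair of random vectors per source of variability (breed A, breed B,
  and the segregation term S). They are defined only for the `q_X`
  *contributors* to source X; animals with null contribution are excluded
  rather than carried as structural zeros.
* `e_p` — maternal permanent-environment effects, one per dam with at
  least one progeny record, shared by all her progeny.
* `e` — residual.

The additive covariance is heterogeneous across breed groups. Its
decomposed form is

```
Var(stack(a_oX, a_mX)) = G0X (x) A*_X,
G = sigma2_A A_A + sigma2_B A_B + sigma2_S A_S    (totals)
```

where `G0X` is a 2×2 direct/maternal covariance matrix per source, `A_X`
is the *partial numerator relationship matrix* of source X and `A*_X` its
restriction to contributors. Together with the permanent-environment and
residual variances this gives eleven scalar (co)variance components.

Assumptions inherited from the underlying theory: additive inheritance at
many unlinked loci, gametic-phase equilibrium within the two parental
breeds, and known breed composition for every base animal.

## Partial relationship matrices

All matrices are built from two per-animal scalars:

* the expected breed fraction `f_X(i)`, from the parent-average recursion
  `f(i) = (f(sire) + f(dam)) / 2` started at the declared base fractions;
* the segregation coefficient
  `s_i = 2 [ f_A(s) f_B(s) + f_A(d) f_B(d) ]`, the weight of the
  segregation variance in the Mendelian-sampling variance of `i`
  (0 when both parents are purebred, 1 for an F2 from F1 parents,
  0.5 for a first backcross).

The tabular recursion in pedigree order uses the common parent-average
rule off the diagonal and `a_X(i,i) = b_i + a_X(s,d)/2` on it, with base
term `b_i = f_X(i)` for the breed sources and `b_i = s_i` for segregation.
An animal contributes to a breed source iff `f_X(i) > 0` and to S iff its
segregation coefficient is positive or a parent contributes; these sets
coincide with the non-null diagonal of the tabular matrix (tested).

The within-family (Mendelian-sampling) coefficient that drives both the
sparse inverse and the simulator is

```
d_X(i) = b_i − [ a_X(s,s) + a_X(d,d) ] / 4
```

with absent-parent terms zero. This is the exact conditional variance of
the parent-average decomposition `A_X = T D_X T'` even when the parents
are related (it equals `a_X(i,i) − (a_ss + a_dd)/4 − a_sd/2`); the package
computes it row-wise, tracing the parent-average operator against the
already-known coefficients in the style of the Meuwissen–Luo inbreeding
algorithm, without storing any full matrix. The collapsed inverse is then
assembled by the Henderson/Quaas rules restricted to contributors
(`w = 1/d_X(i)` on the diagonal, `−w/2` to contributing parents, `w/4`
between them). Two contracts gate this construction in the tests: the
inverse times the collapsed matrix is the identity to 1e-8, and
`A_A + A_B` equals the classical single-population relationship matrix to
1e-10.

Completely inbred contributing parents would drive `d_X -> 0`; the package
raises an error naming the animal instead of switching to a pseudo-inverse,
because the collapsed system is only guaranteed non-singular when every
contributor has positive within-family variance.

## BLUP and the collapsed-system equivalence

At fixed components the mixed-model equations are

```
C = W'W / sigma2_e + blockdiag( K^-1, { G0X^-1 (x) A*X^-1 }, I / sigma2_pe )
```

with `W = [X | Z_oA Z_mA | Z_oB Z_mB | Z_oS Z_mS | Z_p]`, each source
ordered (all direct | all maternal) so the Kronecker structure holds. The
fixed effects carry a proper but vague normal prior `K = k I`, `k = 1e7`
(configurable upward, never below), which keeps `C` positive definite
while leaving the solutions numerically indistinguishable from the flat
limit. Total breeding values are reconstructed by scattering each
collapsed per-source solution over its contributor map and summing — the
package's equivalent of weighting by the null-pattern expansion matrices.
The test suite verifies on pedigrees of a few dozen animals that these
totals agree (to 1e-6) with BLUP from a dense model carrying one genetic
effect pair per animal with covariance `sum_X G0X (x) A_X`.

## The Gibbs sampler

A single-site, systematic-scan sampler draws, in a fixed order (fixed
effects; for each source direct then maternal breeding values; permanent
environment), each scalar location parameter from

```
theta_j | rest ~ N( (r_j − sum_{k != j} C_jk theta_k) / C_jj, 1 / C_jj )
```

followed by the conjugate variance updates:

* `sigma2_e` and `sigma2_pe` from scaled inverse chi-squared full
  conditionals with degrees of freedom `nu + n` (or `nu + d`) and scale
  `(SS + nu s2_0) / (nu + n)`;
* each `G0X` from an inverse Wishart with degrees of freedom `nu_X + q_X`
  and scale `Psi_X + S_X`, where
  `S_X = [u_o' A*inv u_o, u_o' A*inv u_m; ., u_m' A*inv u_m]`.

Priors follow the animal-breeding convention in which the scale matrix is
stated as a prior "location": `Psi_X = nu_X G0X^(0)` (and `nu s2^(0)` for
the scalars). Under this convention the prior *mean* of a 2×2 inverse
Wishart is `nu G0^(0) / (nu − 3)`, slightly above the stated location for
small degrees of belief; the package documents rather than hides this gap,
and the prior-domination test pins the posterior at the scale values as
`nu -> infinity`. Degrees of belief must exceed 1 so the 2×2 Bartlett
draw is proper. Default priors are the published Angus × Hereford values
(`nu` = 20 for the breed sources, 5 for segregation, 100 for the scalar
components).

Implementation: the coefficient matrix is kept in one fixed sparsity
pattern (the union of `W'W` and all prior blocks); each iteration only its
values are refreshed from the current components, the scan runs over the
pattern in compiled code (Rcpp), and the quadratic forms reuse the fixed
collapsed inverses. The sampler consumes R's own seeded RNG stream, so
`set.seed()`/`mb_chain_control(seed = )` makes chains bit-reproducible; an
R-level reference implementation of each full conditional is kept and
tested against closed forms independently of the compiled path. Starting
values are zeros for locations and the prior scales for variances;
non-finite draws abort with the iteration number.

Default chain settings are a desk-scale 20 000 iterations with 2 000
burn-in and thinning 10. The motivating analysis ran 3.5 million
iterations on the real data; that scale is a target for production runs,
not something the defaults attempt. Autocorrelations are large for all
components and extreme for the segregation ones (their posteriors are
strongly right-skewed, mode well below mean) — short chains drift high on
these before settling, so interval summaries from chains much shorter than
a few thousand iterations should not be trusted. `chain_diagnostics()`
reports effective sample sizes (initial-positive-sequence estimator),
lag-1 autocorrelations and a split-chain z-score for exactly this reason.

## Posterior summaries and derived parameters

`summarize_chain()` reports mean, SD, median, the mode of a Gaussian-kernel
density estimate (Silverman's rule-of-thumb bandwidth, 512-point grid —
chosen because only "a Gaussian kernel" is fixed by the method, and
Silverman is the standard default), and the 95% HPD interval computed as
the shortest window over the sorted draws (the behaviour of the usual MCMC
summary tools; the window holds between 94% and 96% of the draws by
construction and is never longer than the central interval).

Derived parameters for a reference breed group with weights
`(w_A, w_B, w_S)` — F2 uses `(0.5, 0.5, 1)`, applied to direct, maternal
and covariance components alike:

```
V_o  = w_A sigma2_Ao + w_B sigma2_Bo + w_S sigma2_So     (and V_m, C_om)
V_P  = V_o + V_m + C_om + sigma2_pe + sigma2_e
h2_o = V_o / V_P,  h2_m = V_m / V_P,  r_om = C_om / sqrt(V_o V_m)
```

The direct–maternal covariance enters the phenotypic variance with
coefficient 1; this definition reproduces the published derived values
exactly from the published component means, which is how the package
validates it. Because the published tables are plug-ins at the posterior
means, `posterior_parameters()` reports both the plug-in values and the
posterior summaries of the per-draw ratios; the two differ by a Jensen
gap on skewed chains and both are of interest.

## The simulator and the gene-dropping oracle

`simulate_pedigree()` realizes a mating plan whose default emulates the
genotype classes of the Angus × Hereford design: the 25 classes with their
published record counts (scaled by a single factor), purebred base
populations (120 A and 80 B at scale 1, roughly matching the experiment's
parent counts), polygynous sires (about 15 progeny per sire) and dams
cycled so they average about 2.5 progeny — the repeat-dam structure that
maternal-effect estimation requires (the experiment reports 2.28 calves
per dam). Default true components are the published prior scale values.
What the generator does **not** emulate: selection during the pedigree,
environmental trends across years, missing or mis-assigned breed
compositions, unknown parents, and non-additive inheritance beyond the
mean heterosis regressors. Passing recovery tests therefore demonstrate
correctness of the estimator under the model's own assumptions, not
robustness to violations real field data may show.

`simulate_breeding_values()` generates per-source breeding-value pairs
sequentially (parent average plus a bivariate Mendelian deviation with
covariance `d_X(i) G0X`), which reproduces `G0X (x) A*_X` by construction.
The independent check is `gene_drop_oracle()`: explicit alleles at
`n_loci` unlinked loci (default 100) are dropped through the pedigree by
fair Mendelian transmission, with base-animal allele effects drawn from
breed-specific distributions whose per-locus variances and mean difference
are chosen so the implied components are exactly the targets
(`v_X = sigma2_X / (2 n_loci)` per allele,
`delta = sqrt(2 sigma2_S / n_loci)` between breed means — the relationship
identities are exact for any number of loci under additivity, so the locus
count only affects higher moments). The empirical covariance of genotypic
values over replicates is compared entrywise with the assembled
`G`; Monte-Carlo standard errors are estimated empirically from 20
independent replicate batches because the genotypic values of segregating
crosses are non-normal (breed-origin mixtures) and the normal-theory SE
formula understates their sampling error. With roughly 350 correlated
entries compared at once, the largest |z| is expected to approach 3 even
under perfect agreement; the keystone test uses 2×10^5 replicates on five
fixed pedigrees covering every mating type.

## Numerical choices

* Null-contribution threshold 1e-12: breed fractions are dyadic rationals,
  so true zeros are exact and the threshold only guards arithmetic noise.
* Sparse solves go through Matrix's Cholesky; a relative residual above
  1e-8 is treated as singularity rather than silently returned.
* Identifiers are opaque strings mapped to dense integer codes in
  topological order; unknown parents are the sentinel 0. A record with one
  unknown parent is completed by a phantom base parent whose breed
  fraction must be supplied explicitly — the package refuses to guess,
  because every downstream quantity depends on parental fractions. Base
  animals are purebred by default; crossbred base animals additionally
  need declared parental fractions before segregation coefficients or
  heterosis covariates can be formed.
* Two breeds are the implemented contract; the data structures store a
  fraction vector so a p-breed extension (with pairwise segregation
  sources) is not blocked, but only A/B/S is built and tested.
* Test problem sizes: recovery runs use ~650-animal designs with
  6 000-iteration chains across 20 replicates; the oracle equivalences use
  pedigrees of 6–60 animals. These sizes were chosen so each check has
  clear statistical power while a full suite run stays comfortable on a
  single desktop core.

## Known limitations

* No REML path; estimation is Bayesian only, and the exploratory
  variance-screening stage practitioners often run first must come from
  other software.
* Single trait (direct + maternal pair); no multi-trait extension.
* No genomic (marker-based) breed composition or relationship matrices;
  breed fractions must be deducible from the pedigree.
* The single-site scan mixes slowly when breed/heterosis covariates are
  nearly collinear with the genetic effects — as in the real design —
  so production-scale chains need to be long, exactly as the motivating
  analysis found. Blocked or matrix-free samplers would be the natural
  next optimization and are deliberately out of scope.
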