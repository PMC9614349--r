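# ihtlm — informative hypothesis testing for linear regression

`ihtlm` is an R package for frequentist *informative* (order-restricted)
hypothesis testing in the Gaussian linear model. Instead of testing
`H0: Rβ = 0` against "not H0", it tests directional hypotheses such as

    H0: Rβ = 0    vs.    Ha: Rβ ≥ 0,

where each row of the constraint matrix **R** encodes a linear combination
of regression coefficients (e.g. `β₁ > 0`, or `β₁ > 0 ∨ … ∨ β₅ > 0`). This
lets applied researchers — the typical use case is treatment-order
hypotheses in the social and biomedical sciences — test the hypothesis they
actually hold in one step, without the multiple-testing detour of classical
two-sided testing.

## What it computes

For data `y = Xβ + ε`, `ε ~ N(0, σ²I)`, the package fits three models by
exact quadratic programming (Goldfarb–Idnani dual active-set method):
unconstrained OLS `β̂`, the inequality-constrained estimate `β̃`
(projection onto the cone `{Rβ ≥ 0}`), and the equality-constrained
estimate `β̄`. From these it computes:

- **Classical statistics** — Wald, likelihood ratio, score,
  `F = (RSS̄ − RSS^)/(h·Ŝ²)` and `t`, each in a *naive* (`RSS/n`) and a
  degrees-of-freedom-*corrected* variance version;
- **Informative statistics** — the informative LRT; the informative Wald
  `(n/Ŝ²)(Rβ̃)'(R W⁻¹R')⁻¹(Rβ̃)` with `W = X'X/n` and its VCOV form; the
  distance statistic `d(β̄) − d(β̃)` in the `W` metric; the F̄ statistic
  `(RSS̄ − RSS̃)/Ŝ²`; and the U, null-information and
  information/Robertson/VCOV score forms — with the documented identities
  between them (`D = Wald_info = Wald_VCOV`, `F̄ = F̄_info`,
  `Score_info = Robertson = Score_VCOV`, `t² = F`, `F̄ = max(t,0)²`)
  enforced to 1e-8 in the test suite;
- **Mixture p-values** — χ̄² and F̄ tail probabilities
  `Σᵢ wᵢ P(χ²_{h−q+i} ≥ c)` and `Σᵢ wᵢ P((h−q+i)F_{h−q+i,n−k} ≥ c)`, with
  level probabilities `wᵢ` computed from the cone geometry by closed forms,
  Kudo's subset decomposition with multivariate-normal orthant
  probabilities, or Monte-Carlo projection counting;
- **Error-rate studies** — a deterministic, seeded Monte-Carlo harness for
  type-I and type-II error rates over grids of sample sizes and effect
  sizes `f² = R²/(1−R²)`, with ggplot output.

## Worked example

Five predictors, all slopes truly 0.1 (a large joint effect, `f² = 0.35`),
n = 50, testing `Ha: β₁ > 0 ∨ β₂ > 0 ∨ β₃ > 0 ∨ β₄ > 0 ∨ β₅ > 0`:

```r
library(ihtlm)
cons <- build_constraints("R2")          # inequalities on all five slopes
X <- generate_design(50, 5, seed = 1)    # orthogonalized standard-normal design
y <- generate_alt_response(X, rep(0.1, 5), f2 = 0.35, seed = 2)
iht_test(data.frame(y = y, X[, -1]), cons,
         statistics = c("fbar", "wald_info", "lrt", "f"))
#> # A tibble: 4 × 10
#>   statistic version   value distribution pvalue     h     q     n     k
#>   <chr>     <chr>     <dbl> <chr>         <dbl> <int> <int> <int> <int>
#> 1 fbar      corrected  9.94 fbar         0.0249     5     5    50     6
#> 2 wald_info corrected  9.94 chibar       0.0173     5     5    50     6
#> 3 lrt       corrected  9.79 chibar       0.0184     5     5    50     6
#> 4 f         corrected  2.00 f(5,44)      0.0974     5     0    50     6
#>   weights
#>   <list>
#> 1 <dbl [6]>
#> 2 <dbl [6]>
#> 3 <dbl [6]>
#> 4 <NULL>
```

The informative tests reject at the 5% level (p ≈ 0.02) while the classical
two-sided `F` test does not (p ≈ 0.10): directing the alternative at the
ordered hypothesis buys real power. The F̄ statistic equals the informative
Wald here (an exact identity at `rhs = 0`); its p-value differs because it
is drawn from the F̄ rather than the χ̄² mixture — the mixture weights for
this orthogonal design are the exact binomials
`(1, 5, 10, 10, 5, 1)/32`:

```r
chibar_weights(constraint_kernel(regression_data(y, X), cons))
#> <chibar_weights: q = 5, method = closed_form>
#> w0 = 0.031250, w1 = 0.156250, w2 = 0.312500, w3 = 0.312500, w4 = 0.156250, w5 = 0.031250
#> sum = 1
```

See the vignette (`vignettes/informative-testing.Rmd`) for the statistic
definitions, the variance conventions, and the design decisions behind the
mixture machinery.

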