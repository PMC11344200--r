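# nidmlm

Linear regression on linked-data (NIDM-lite) study documents.

Multi-site studies store the same phenotype under different study-local
variable names — `age` at one site, `AGE_yrs` at another. Linked-data study
descriptions resolve this by annotating each local variable with a concept
URL from a shared terminology. `nidmlm` is for researchers who want to know,
*before* committing to full data integration, whether relationships between
variables hold up across pooled datasets: it reads study documents
serialized as RDF 1.1 Turtle under a small documented profile ("NIDM-lite"),
pools per-subject observations across sites, and fits user-specified linear
models.

A variable can be addressed three ways: by element identifier token
(`fs_000008`), by study-local variable name (`DX_GROUP`), or by concept URL
(`http://uri.interlex.org/ilx_0100400`), which pools differently named
variables measuring the same thing across sites.

The model core:

- Model strings `DV = IV1 + IV2 + IV1*IV2` (`=`/`~` interchangeable,
  whitespace irrelevant; `*` builds the product term only — main effects are
  listed explicitly).
- Ordinary least squares with the full inferential battery: coefficient
  table (estimate, SE, *t*, two-sided *p*), residual SD, R², adjusted R²,
  overall *F*, Gaussian log-likelihood.
- Five categorical contrast codings — treatment, simple, sum, backward
  difference, Helmert — each with an exact balanced-data estimand contract,
  plus the joint contrast *F*-test
  F = (Cβ̂)′[C(X′X)⁻¹C′]⁻¹(Cβ̂)/(qσ̂²) per contrast variable.
- Optional L1 (lasso, cyclic coordinate descent with soft-thresholding) or
  L2 (ridge, closed form) regularization; the penalty weight is selected by
  10-fold cross-validated held-out Gaussian log-likelihood over a wide
  log-spaced grid.
- A synthetic multi-site study generator with known linear ground truth, so
  the whole pipeline is testable offline.

## Worked example

Generate the default two-site fixture (50 subjects per site; age stored as
`age` vs `AGE_yrs` but tied by its concept URL), then fit the model with a
treatment-coded contrast on diagnostic group and L1 regularization:

```r
library(nidmlm)
docs <- generate_multisite(seed = 7)                  # or paths to .ttl files
write_multisite(docs, default_truth(), "demo")        # demo/siteA.ttl, demo/siteB.ttl

list_data_elements(c("demo/siteA.ttl", "demo/siteB.ttl"))  # what can be modelled

fit <- nidm_lm(
  "fs_000008 = DX_GROUP + PIQ_tca9ck + http://uri.interlex.org/ilx_0100400",
  c("demo/siteA.ttl", "demo/siteB.ttl"),
  contrast = "DX_GROUP", regularization = "L1", seed = 3)
summary(fit)
```

```
Linear model on NIDM-lite documents
model: fs_000008 = DX_GROUP + PIQ_tca9ck + http://uri.interlex.org/ilx_0100400 
pooled n = 100 (dropped for missing values: 0) across document(s): siteA (50), siteB (50)

Coefficients:
                                      Estimate Std. Error t value Pr(>|t|)    
(Intercept)                          1.200e+03  3.924e-01  3059.1   <2e-16 ***
DX_GROUP[2-1]                       -2.502e+01  1.112e-01  -225.1   <2e-16 ***
PIQ_tca9ck                           1.196e+00  3.442e-03   347.5   <2e-16 ***
http://uri.interlex.org/ilx_0100400  3.503e+00  3.478e-03  1007.1   <2e-16 ***

Residual SD: 0.539 on 96 degrees of freedom
R-squared: 0.9999, adjusted R-squared: 0.9999
F-statistic: 4.106e+05 on 3 and 96 DF, p-value: 4.995e-197
log-likelihood: -78.058

Contrast on 'DX_GROUP' (treatment coding):
              Estimate Std. Error t value Pr(>|t|)    
DX_GROUP[2-1] -25.0242     0.1112  -225.1   <2e-16 ***
joint F(1, 96) = 5.068e+04, p = 1.533e-132

L1 regularization (10-fold cross-validation over 30 weights):
  chosen weight: 0.00259294
  coefficients at the chosen weight:
                        (Intercept)                       DX_GROUP[2-1] 
                        1200.309419                          -25.020203 
                         PIQ_tca9ck http://uri.interlex.org/ilx_0100400 
                           1.195798                            3.502945
```

The fixture's ground truth is intercept 1200, group-2 effect −25, IQ slope
1.2, age slope 3.5, with noise SD 0.5 — the estimates above land on it to
within sampling error, and the age coefficient demonstrates pooling across
the two differently named age variables via the concept URL. The fitted
object answers the usual generics: `coef`, `confint`, `predict` (raw new
data), `residuals`, `fitted`, `simulate`, `plot`, `logLik`.

Command-line front ends (thin wrappers over the same functions) live in
`inst/cli/`:

```sh
Rscript inst/cli/nidm-lm-synth --sites 2 --n 50 --noise 0.5 --seed 7 --out demo/
Rscript inst/cli/nidm-lm -nl demo/siteA.ttl,demo/siteB.ttl \
    -model "fs_000008 = DX_GROUP + PIQ_tca9ck + http://uri.interlex.org/ilx_0100400" \
    -contrast DX_GROUP -r L1 --format json -o report.json
```

The CLI echoes the normalized command before touching any file, lists
unresolved variables per document and exits without fitting, and warns (and
prompts) when fewer than 20 pooled datapoints remain.

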