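---
title: "Methods: linear modelling over NIDM-lite study documents"
author: "nidmlm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear modelling over NIDM-lite study documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nidmlm)
```

## The problem

Multi-site neuroimaging and phenotyping studies describe the same quantity —
a participant's age, say — under different study-local variable names
(`age` at one site, `AGE_yrs` at another). Linked-data study descriptions
solve this by annotating each local variable with a concept URL from a
shared terminology, so that semantically equivalent variables can be found
and pooled across datasets before anyone commits to the heavy work of full
data integration. `nidmlm` implements the analysis half of that idea: it
reads study documents serialized as RDF 1.1 Turtle under a small documented
profile ("NIDM-lite"), pools per-subject observations across sites, and fits
user-specified linear models with contrasts and optional regularization, so
a researcher can quickly see whether cross-dataset relationships are worth
pursuing.

## The NIDM-lite profile

Full linked-data experiment descriptions carry provenance graphs far richer
than a regression needs. NIDM-lite is the minimal, self-contained projection
this package defines and documents (see `?read_nidm`): a *study* node with a
label, *data element* nodes (identifier token, study-local source variable,
human label, zero or more `nlite:isAbout` concept URLs, a value type, and —
for categorical elements — an ordered level list), and *observation* nodes
(subject id, element reference, literal value). Everything outside the
profile is ignored on read, with a count reported, so NIDM-lite documents
can live inside richer graphs. Real-world compatibility with full
provenance-based experiment serializations is an explicit non-goal: the
mapping from those richer graph shapes onto this profile is left open.

The Turtle layer itself is a deliberately restricted subset (prefix
declarations, IRIs, prefixed names, literal datatypes and language tags,
predicate/object lists, comments; no anonymous blank nodes or collections),
which is exactly what the profile's writer emits. The test suite checks the
reader and writer against an independent RDF parser, including a round trip
through a foreign serializer.

Two parsing rules matter for data integrity: duplicate
`(subject, element)` observations with equal values collapse to one with a
message, while conflicting duplicates are a hard error (silently overwriting
one would corrupt the regression); and numeric literals are carried as
lexical forms that round-trip doubles exactly (17 significant digits), so a
generated document refits to the bit.

## Variable addressing and pooling

A model variable can be addressed three ways: by element identifier token,
by study-local source variable name, or by concept URL (any token starting
with `http://` or `https://`). Identifier and name are syntactically
indistinguishable, so resolution tries the identifier first and the source
name second; matching is exact and case-sensitive. Within one document more
than one match is an ambiguity error naming the candidates.

Each document is one site or dataset: rows *stack* across documents, and
identical subject ids in different documents are different people. Within a
document, a subject's observations are joined on subject id; subjects
missing any model variable are dropped listwise, with the count reported.
Listwise deletion is the simplest defensible default for ordinary least
squares; nothing fancier (imputation, pairwise deletion) is attempted. If
any reference fails to resolve in any document, the per-document listing of
unresolved tokens is produced and no table is built — failing loudly before
a half-specified model burns compute.

## Model syntax

`"DV = IV1 + IV2 + IV1*IV2"`, with `=` and `~` interchangeable and
whitespace ignored. One deliberate divergence from R's formula algebra: `*`
builds **only** the product term. Main effects are taken literally from the
formula, as in the canonical example above, where both mains and the
product are spelled out. Chained `*` builds higher-order products. The
dependent variable reappearing as a predictor halts immediately with an
explicit message, before any file is read.

## Contrast codings

Categorical factors are expanded by a $k \times (k-1)$ coding matrix. Five
schemes are supported, each defined by its estimand contract on balanced
one-way data with level means $m_1, \dots, m_k$:

| scheme | coefficient $j$ | intercept |
|---|---|---|
| treatment | $m_{j+1} - m_1$ | $m_1$ |
| simple | $m_{j+1} - m_1$ | grand mean |
| sum | $m_j - \bar m$ | grand mean |
| backward difference | $m_{j+1} - m_j$ | grand mean |
| Helmert | $m_{j+1} - \mathrm{mean}(m_1..m_j)$ | grand mean |

Helmert conventions vary between software packages (forward vs reverse,
scaling); this package fixes "level $j+1$ versus the mean of the preceding
levels, scaled so the coefficient equals that difference exactly", because
that contract is directly testable. Rather than hard-coding each scheme's
matrix, the coding is obtained by inverting the scheme's hypothesis matrix
(intercept estimand row plus the $k-1$ contrast rows), which makes the
contracts hold by construction; the tests verify them against a brute-force
OLS oracle for $k = 2..5$.

Contrast variables use the scheme selected for the run; all other
categorical factors get treatment coding with the *first declared level* in
the document's data dictionary as reference — deterministic and
user-controllable by editing the document. Numeric predictors enter in raw
units, uncentered and unscaled, so OLS coefficients keep their natural
interpretation; standardization happens only inside the penalized fitters.
Rank deficiency of the assembled design is a hard error listing the aliased
columns, never silent dropping.

## Estimation

OLS solves the normal equations by Cholesky factorization, with
$SE_j = \hat\sigma\sqrt{[(X'X)^{-1}]_{jj}}$, $\hat\sigma^2 = RSS/(n-p)$,
two-sided $t$ p-values, $R^2$, the overall $F$ over all non-intercept
columns, and the Gaussian log-likelihood
$-\tfrac n2(\log 2\pi + \log(RSS/n) + 1)$. The joint contrast test for a
factor's $q$ columns is
$F = (C\hat\beta)'[C(X'X)^{-1}C']^{-1}(C\hat\beta)/(q\hat\sigma^2)$ on
$F(q, n-p)$; a single-df contrast satisfies $F = t^2$ identically. An exact
fit ($RSS = 0$ up to roundoff, detected relative to the fitted sum of
squares) is reported as the $\sigma \to 0$ limit, $F = \infty$, $p = 0$.

Ridge solves $(Z'Z + \lambda I)^{-1}Z'y_c$ in standardized space. Lasso
minimizes $\frac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda\lVert
\beta_{-0}\rVert_1$ by cyclic coordinate descent with soft-thresholding,
converging when the largest coefficient change in a sweep drops below
$10^{-6}$ (cap $10^4$ sweeps, with a warning on hitting it). Both
standardize predictors internally to unit *population* variance (divisor
$n$) and never penalize the intercept — the conventional choice, and with
the $\frac{1}{2n}$ objective scaling it gives the clean boundary
$\lambda_{\max} = \max_j |z_j' y_c|/n$ above which every slope is exactly
zero. Coefficients are always returned on the original scale. The unit
tests cross-check the coordinate-descent path against an independent
penalized-regression implementation.

## Cross-validated weight selection

The regularization weight is chosen over a wide default grid — 30 points
log-spaced on $[10^{-3}, 10^3]$, overridable — by 10-fold cross-validation.
"Maximum likelihood" is read as the held-out Gaussian log-likelihood: each
fold's test rows are scored under the training fit using the training
residual variance (MLE), and the weight maximizing the mean held-out
log-likelihood per observation wins; with the variance fixed per fold this
ranks weights like held-out MSE, and both curves are reported. Ties break
toward the larger weight (more shrinkage, fewer effective parameters). The
fold shuffle is seeded and the global RNG state is restored afterwards, so
selection is a pure function of (data, grid, seed). The final coefficients
are refit on all rows at the chosen weight. Whether the original tooling
scored training or held-out folds, and its exact grid, are not specified
anywhere we could follow; these are this package's documented defaults.

## Input validation

The front end echoes the fully normalized command (whitespace stripped, `~`
canonicalized to `=`, the file list expanded) *before* opening any file, so
syntax errors are traceable. Unresolvable variables are listed per document
and abort the run. Fewer than 20 pooled datapoints prints a warning that
the result will not be as accurate and asks whether to proceed;
non-interactive sessions treat the prompt as "abort unless `--yes`", the
safe default for scripting. Twenty datapoints exactly passes silently.

## The synthetic-data generator

`generate_multisite()` emulates the target scenario: per-site documents
sharing one linear ground truth, with concept URLs identical across sites
while local names and element ids differ. Numeric covariates are drawn
uniformly over their declared ranges and categorical levels uniformly —
simple, documented, and sufficient for design identifiability. The default
fixture is two sites of 50 subjects: a numeric response (`fs_000008`,
"brainvol"), diagnostic group (`DX_GROUP`, levels 1/2, effect $-25$ for
level 2), performance IQ (element `PIQ_tca9ck`, slope 1.2, range 70–130),
and age (slope 3.5, range 6–60), stored as `age` vs `AGE_yrs` and tied by
the concept URL `http://uri.interlex.org/ilx_0100400`; intercept 1200,
Gaussian noise SD 0.5 by default.

What the generator does **not** emulate: correlated covariates, site-level
confounding or batch effects, non-Gaussian noise, and structured
missingness. Passing tests therefore demonstrate correctness of the
pipeline's algebra and inference under clean conditions, not robustness to
the messiness of real pooled studies.

## Verification sizes and numerical choices

The test suite and `scripts/acceptance.R` verify, at sizes chosen to make
the checks statistically sharp yet quick: OLS against an independent
pseudo-inverse oracle on 100 random instances ($n \in [25,100]$,
$p \in [2,8]$, agreement to $10^{-8}$); every coding scheme's estimand
contract for $k = 2..5$ to $10^{-10}$; the joint-F test's type-I error at
$\alpha = 0.05$ over 1000 null replicates ($n = 60$, three equal groups);
ridge against an independent eigendecomposition closed form; lasso against
the soft-threshold closed form on designs orthonormalized against the
intercept, and the $\lambda_{\max}$ boundary; cross-validation determinism
and support recovery on a sparse truth (2 of 8 slopes nonzero,
$\sigma = 0.5$, $n = 200$); end-to-end recovery of the two-site fixture's
truth exactly (noiseless, through disk serialization) and 95% CI coverage
over 500 noisy replicates (checked per coefficient against a
$[93\%, 97\%]$ binomial band); and write→read identity on 50 random
generator outputs. The 500-replicate coverage loop runs on in-memory
documents — the identical code path minus file I/O, which the noiseless and
round-trip checks already exercise through disk.

## Known limitations

- NIDM-lite is this package's own profile; arbitrary real-world experiment
  serializations will generally not parse (by design).
- `*` never implies main effects; users of R formulas may be surprised
  (documented above).
- Raw p-values only — no multiple-testing correction (deliberately out of
  scope; this is a screening tool, not a confirmatory analysis).
- Listwise deletion assumes missingness unrelated to the model; pooled
  fits assume a common coefficient vector across sites (no site fixed
  effects are added automatically, though a site variable can be modelled
  explicitly if the documents carry one).
- Two-way interactions between categorical variables are supported in
  models, but the generator's ground-truth vocabulary covers only
  numeric×numeric and numeric×categorical interactions.
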