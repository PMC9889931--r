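---
title: "Scoring flexibility in divergent thinking from word embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring flexibility in divergent thinking from word embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtflex)
```

## The measurement problem

Verbal divergent-thinking (DT) tasks — "list unusual uses for a bottle" —
are traditionally hand-scored for three dimensions: *fluency* (how many
ideas), *originality* (how unusual each idea is), and *flexibility* (how
widely the ideas range across conceptual categories). Hand scoring of
flexibility is the most labor-intensive of the three because a rater must
assign every response to a category scheme and count the switches.

`dtflex` scores flexibility automatically from a word-embedding space.
The key observation is that switching idea categories shows up as a large
*semantic distance between consecutive responses*: a participant who says
"vase" right after "decoration" has stayed in one region of semantic
space, while one who jumps from "vase" to "musical instrument" has moved
far. With responses embedded as vectors, the distance between responses
at positions $i$ and $i+1$ is

$$d(u, v) \;=\; 1 - \cos(u, v) \;=\; 1 - \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert},$$

which lives on $[0, 2]$: 0 for identical directions, 1 for orthogonal
ones. The same comparison can be reported as the angle
$\arccos\,\cos(u,v)$ in degrees, which is convenient for worked examples.

## From free text to vectors

Responses are free text, so each one is tokenized (lower-cased, split on
non-word characters), stoplisted (a bundled ~100-word English
function-word list, overridable by file), and its surviving in-vocabulary
tokens are averaged:

$$v(\text{response}) = \frac{\sum_t w(t)\, v(t)}{\sum_t w(t)},$$

a *weighted mean*, not a weighted sum. The mean makes the representation
invariant to rescaling all weights by a constant, which the test suite
asserts directly; with the default uniform weights the weighting is a
no-op. Term weights (a `token,weight` file) let users down-weight
frequent words beyond the stoplist.

Two deliberate choices about failure states:

* **Out-of-vocabulary tokens are dropped and counted, never imputed.**
  Imputation would make scores depend on the imputation scheme rather
  than the embedding space.
* **A response with no surviving tokens gets an *undefined* vector, not
  a zero vector.** A zero vector has no direction, so any cosine against
  it is arbitrary; zero-filling would fabricate distances. Undefined
  vectors propagate: every pair or prompt comparison touching one is
  skipped, and aggregates over zero defined comparisons are themselves
  undefined (`NA`, emitted as empty cells — a printed 0 means "identical
  adjacent ideas", which is real information).

## The scores and the fluency confound

For one participant and one prompt with $n$ responses, consecutive pairs
$(1,2), (2,3), \dots, (n-1,n)$ are formed in the order the responses
were produced — order preservation is essential, since flexibility is a
property of the *sequence*. Then:

| score | definition |
|---|---|
| fluency | $n$, the response count (undefined-vector responses included) |
| flex_sum | $\sum$ defined pair distances |
| flex_mean | flex_sum $/\, n$ |
| flex_max | largest defined pair distance |
| orig_sum / orig_mean / orig_max | same aggregations of the prompt-to-response distances |

Summed scores rise mechanically with the number of responses — the
classic *fluency confound* that entangles hand-scored flexibility with
sheer productivity. Dividing by fluency corrects this: appending a
duplicate of the last response adds a zero-distance pair, leaving
flex_sum unchanged while strictly decreasing flex_mean. The test suite
asserts exactly this property.

Note the divisor: flex_mean divides by the *response count* $n$, not by
the pair count $n-1$. Dividing by $n$ is the fluency-correction
convention this scoring follows; since it slightly deflates the mean
relative to a per-pair average, `mean_divisor = "pairs"` offers the
$n-1$ variant. The simulation suite shows the practical difference: with
the per-fluency divisor the mean score carries a residual mechanical
$(n-1)/n$ factor (about 20% between fluency ranges 3–5 and 9–12 under
the default generator), while the per-pair mean is stable to within a
few percent.

Battery aggregation averages and maximizes across items: mean fluency is
the sum of item fluencies divided by the number of items, maximum
fluency the highest item fluency, and the flexibility/originality
aggregates are averaged over items with defined scores.

## The synthetic study conditions

Because real DT datasets are proprietary or restricted, the package
ships generators that plant known structure:

* **Toy embedding space** (`make_toy_embeddings`): $k$ cluster centroids
  as a random orthonormal frame (when $k \le d$, between-centroid cosine
  is exactly 0), each token a unit-normalized
  centroid $+$ `spread`$\times$ isotropic noise. For any spread below 1
  the mean within-cluster cosine exceeds the between-cluster mean; the
  suite brute-forces this over all token pairs across several seeds.
* **Ideation sequences** (`simulate_responses`): per participant × item,
  fluency drawn uniformly on a configurable range (default 3–12,
  a realistic span for 2–3-minute verbal DT prompts), a first cluster
  drawn at random, then each next response staying in-cluster with
  probability $1-p_{\text{switch}}$. Responses are single vocabulary
  tokens by default so cluster membership — hence expected flexibility —
  is exactly known; a two-token option exercises multiword averaging.
  All randomness flows from one seed via named sub-streams (fluency,
  cluster walk, token choice), so adding a stream does not shift the
  others.
* **Factor-model indicators** (`simulate_factor_data`): multivariate
  normal draws with covariance $\Lambda\Phi\Lambda^{\top} + \Theta$.

What the generator does *not* emulate: real responses are multiword,
spelled creatively, and sometimes off-task; real semantic categories
overlap and have unequal sizes; real response sequences show serial-order
effects (later ideas tend to be more original). Passing tests therefore
demonstrate that the *scoring machinery* is correct and that the scores
respond to planted category switching as designed — not that any
particular embedding space recovers human flexibility ratings. That
external claim depends on the pretrained space used; the worked
44°/86° example ("decoration"–"vase", "vase"–"musical instrument")
reproduces only under the same pretrained GloVe space as the original
scoring service, which is why the package treats the embedding file as a
recorded, user-supplied input rather than fixing one.

## The psychometric toolkit

Validating a new score means showing internal consistency, a coherent
factor structure, and sensible criterion correlations. The package
implements the standard toolkit:

* **Correlations**: Spearman's $\rho$ (average ranks for ties) and
  Pearson's $r$, both with Fisher $r$-to-$z$ confidence intervals using
  $\mathrm{SE} = 1/\sqrt{n-3}$. Two independent correlations are
  compared with
  $z = (\operatorname{atanh} r_2 - \operatorname{atanh} r_1)\big/\sqrt{\tfrac{1}{n_1-3}+\tfrac{1}{n_2-3}}$;
  a Steiger-style dependent-correlation variant is provided but is not
  the default, because the published comparison this arithmetic is
  checked against is the independent-samples form.
* **Reliability**: Cronbach's
  $\alpha = \frac{k}{k-1}\left(1 - \frac{\sum \sigma_i^2}{\sigma_{\text{total}}^2}\right)$,
  McDonald's $\omega = (\sum\lambda)^2 / ((\sum\lambda)^2 + \sum\theta)$,
  and coefficient
  $H = \left(1 + 1\big/\sum \frac{\lambda_i^2}{1-\lambda_i^2}\right)^{-1}$.
  Under homogeneous loadings with $\theta_i = 1 - \lambda_i^2$, $\omega$
  and $H$ coincide exactly — a closed-form identity the suite checks to
  $10^{-10}$; with heterogeneous loadings $H \ge \omega$.
* **CFA**: plain maximum likelihood, minimizing
  $F = \ln|\Sigma(\theta)| + \operatorname{tr}(S\,\Sigma(\theta)^{-1}) - \ln|S| - p$
  by BFGS with the analytic gradient
  $\partial F/\partial\Sigma = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$
  chained through $\Sigma = \Lambda\Phi\Lambda^\top + \Theta$.
  Identification fixes factor variances at 1 (all loadings free).
  Simple structure is enforced at spec time: no cross-loadings, and
  residual covariances only between indicators on *different* factors —
  the correlated-uniqueness pattern for the same item scored under
  several dimensions. $\chi^2 = (n-1)\,F_{\min}$;
  $\mathrm{df} = p(p+1)/2 - (\text{free parameters})$. Robust
  (Satorra–Bentler) corrections are out of scope: published
  robust-corrected chi-squares are treated as comparison points, not
  exact targets.
* **Fit indices**: $\mathrm{RMSEA} = \sqrt{\max(\chi^2-\mathrm{df},0) / (\mathrm{df}\,(n-1))}$
  with its confidence interval by noncentrality search on the noncentral
  $\chi^2$; CFI and TLI against the independence baseline (closed form:
  $F_b = -\ln|R|$); SRMR as the root mean square of standardized
  residual covariances, diagonal included. All chi-square-based indices
  reduce to their perfect-fit values whenever $\chi^2 \le \mathrm{df}$.
  The $n-1$ RMSEA denominator is used because it reproduces published
  RMSEA values exactly from their printed $\chi^2$, df, and $n$.

### Numerical choices

Start values are half the observed standard deviation for loadings and
half the observed variance for residuals (i.e., loadings 0.5 and
residuals 0.5 on standardized data), factor correlations 0; convergence
requires the BFGS run to terminate normally and a second polish run to
improve the discrepancy by less than $10^{-8}$. Non-convergence is
flagged in the result and echoed by the command-line report — never
silently replaced by a fallback. A non-positive-definite sample
covariance (relative eigenvalue below $10^{-10}$) is a data error.
Missing data are handled complete-case per analysis with the retained
$n$ reported. Ties in flex_max need no index tie-break (the value is
reported); where an index is wanted, the earliest pair wins. No
multiple-testing correction is applied; confidence intervals are
reported instead.

## Problem sizes in the test suite

The property suites run at sizes chosen to make Monte-Carlo tolerances
honest while keeping the suite quick: cosine-oracle checks at 25–50
random vector pairs ($10^{-12}$ tolerance), switch-probability
monotonicity at 100–200 participants per level, one-factor CFA recovery
at $n = 5000$ (loadings within $\pm 0.05$), the three-factor
correlated-uniqueness recovery at $n = 2000$ (factor correlations within
$\pm 0.1$), and generator-covariance convergence at $n = 20000$
(element-wise within 0.05).

## Known limitations

* Scores inherit the biases of the supplied embedding space; nothing in
  the package certifies a space as comparable to the one behind any
  published worked example.
* Sub-word handling, spell correction, lemmatization, and contextual
  (transformer) embeddings are out of scope; misspelled tokens are
  simply out-of-vocabulary.
* The CFA estimator is plain ML — no robust corrections, modification
  indices, or invariance testing.
* Category-count ("categorical") flexibility over whole response sets is
  a different construct from this sequential semantic-distance measure
  and is not implemented.

## A worked example

```{r worked}
emb <- tempfile(fileext = ".txt")
writeLines(c("alpha 1 0", "beta 0.8 0.6", "gamma 0 1"), emb)
model <- load_embeddings(emb)
resp <- data.frame(participant_id = "p1", item_id = "alpha",
                   order_index = 1:3,
                   response = c("alpha", "beta", "gamma"))
score_item(resp, model, prompt_text = "alpha")
```

The consecutive cosines are 0.8 and 0.6, so the pair distances are 0.2
and 0.4: flex_sum 0.6, flex_max 0.4, and flex_mean 0.6/3 = 0.2 — the
divisor is the fluency 3, not the pair count 2.
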