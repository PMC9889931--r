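# dtflex

Automated, embedding-based scoring of verbal divergent-thinking (DT)
tasks — the Alternate/Unusual Uses Task and similar open-ended ideation
prompts — for creativity researchers who want flexibility scored without
hand-coding category switches.

## What it computes

**Flexibility** is measured as the semantic distance between
*consecutive* responses to the same prompt. Each response is embedded as
the weighted average of its word vectors (after tokenization and
stoplisting) in a GloVe-format embedding space, and each adjacent pair
(1st–2nd, 2nd–3rd, ...) is scored

d(u, v) = 1 − cos(u, v) = 1 − (u·v)/(‖u‖‖v‖)  ∈ [0, 2],

so a participant who jumps between idea categories accumulates large
pair distances. Alongside flexibility the package scores **originality**
(distance between the prompt and each response) and **fluency** (the
response count), each aggregated per item three ways:

* `sum` — total across pairs/responses (rises mechanically with fluency);
* `mean` — sum divided by fluency, the *fluency-confound-corrected* score;
* `max` — the single largest pair/response score.

A psychometric toolkit supports validating the scores: Spearman/Pearson
correlations with Fisher r-to-z confidence intervals, comparison of two
correlations via Fisher's z, Cronbach's alpha, McDonald's omega,
coefficient H, and maximum-likelihood confirmatory factor analysis with
RMSEA (noncentrality CI), CFI, TLI, and SRMR. Seeded generators produce
planted-cluster embedding spaces, response sequences with a known
category-switching probability, and factor-model indicator data, so the
whole pipeline runs and tests offline.

## Worked example

Three toy tokens whose consecutive cosines are 0.8 and 0.6:

```r
library(dtflex)
emb <- tempfile(); writeLines(c("alpha 1 0", "beta 0.8 0.6", "gamma 0 1"), emb)
model <- load_embeddings(emb)
resp <- data.frame(participant_id = "p1", item_id = "alpha",
                   order_index = 1:3, response = c("alpha", "beta", "gamma"))
score_item(resp, model, prompt_text = "alpha")
#>   participant_id item_id fluency n_pairs_scored flex_sum flex_mean flex_max
#> 1             NA      NA       3              2      0.6       0.2      0.4
#>   orig_sum orig_mean orig_max
#> 1      1.2       0.4        1
```

The pair distances are 0.2 (alpha–beta) and 0.4 (beta–gamma): their sum
is 0.6, the maximum 0.4, and the mean 0.6/3 = 0.2 — note the divisor is
the fluency (3 responses), not the pair count, which is what corrects
the fluency confound: padding the list with a duplicate idea adds a
zero-distance pair and *lowers* the mean.

A full simulated battery:

```r
cfg <- ideation_sim_config(
  embedding = toy_embedding_config(4, 10, dimension = 20,
                                   within_cluster_spread = 0.1, seed = 3),
  n_participants = 4, switch_probability = 0.5, seed = 11)
sim <- simulate_responses(cfg)
sc <- score_responses(sim$responses, sim$model)
head(sc[, c("participant_id", "item_id", "fluency", "flex_sum",
            "flex_mean", "flex_max", "orig_mean")], 4)
#>   participant_id item_id fluency flex_sum flex_mean flex_max orig_mean
#> 1           p001   c1_t1       6     3.01     0.502    1.041     0.855
#> 2           p001   c2_t1       3     2.01     0.669    1.013     0.658
#> 3           p001   c3_t1       6     1.02     0.169    0.974     0.987
#> 4           p001   c4_t1      11     6.06     0.551    1.060     0.555

aggregate_battery(sc)[, 1:6]
#>   participant_id n_items fluency_mean_across_items fluency_max_across_items
#> 1           p001       4                      6.50                       11
#> 2           p002       4                      7.25                       11
#> ...
```

With switch probability 0.5, roughly half the consecutive pairs cross
planted clusters (distance near 1) and half stay within one (distance
near 0), so `flex_mean` sits around 0.5 scaled by the (n−1)/n pair
ratio; participant–items with more in-cluster runs (row 3) score lower.

## Command line

A thin front end over the same functions ships at
`system.file("cli", "dtflex", package = "dtflex")`:

```sh
dtflex score --embeddings glove.txt --responses responses.csv \
       --out-item item_scores.csv --out-battery battery.csv
dtflex psych --scores battery.csv --analysis reliability --out rel.csv
dtflex simulate --config sim.cfg --out-dir fixtures/
```

Logs go to standard error, tables to files; identical inputs give
byte-identical outputs.

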