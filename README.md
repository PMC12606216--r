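# playnet

Network analysis of touchscreen food-sharing gameplay.

`playnet` characterises how young children organise goal-directed play in a
tablet food-sharing game. In each game cycle a food item on the foreground
serving table splits into four pieces, to be dragged to the plates of four
expectant characters; the game rewards sharing the pieces evenly. Children
may instead stack pieces on one plate and redistribute them later, play with
other screen regions, or tap idly. The package turns raw touch logs of such
sessions into quantitative descriptions of the sharing strategy, for
researchers in digital phenotyping and developmental psychology who want the
full pipeline — from contact samples to cohort statistics — in one place.

## What it computes

1. **Swipe assembly** (`assemble_swipes()`): raw multi-touch contact streams
   become continuous swipes. Ambiguous contacts (no hardware `touch_id`) are
   assigned to the concurrent swipe whose predicted next location — a cubic
   through the last four contacts, extrapolated in time — is nearest.
2. **Zone transitions** (`build_raw_network()`): each swipe maps to a
   directed edge between the zones of its first and last contact, over a
   16-zone layout *V* containing the food zone *f*, four snap-to-plate zones
   *s*, four nested plate zones *ψ* and seven others. Within-zone swipes and
   taps are excluded (*T<sub>ii</sub>* = 0).
3. **Delivery rewiring** (`apply_direct_rules()`, `apply_indirect_rules()`):
   the direct variant counts only food-zone-to-plate deliveries
   (destinations unified to *ψ*); the indirect variant additionally counts
   inter-plate redistribution, except plate-to-own-snap returns.
4. **Sharing score** (`compute_sharing_score()`): with
   *A* = *T*/Σ*T* + *C* (baseline *C<sub>ij</sub>* = 0.01) and the perturbed
   matrix *P* = *A* − *q*·diag(**1**<sub>ψ</sub>), the score is the largest
   *q* for which the four plate vertices still carry the four largest
   entries of the first left eigenvector *x*<sub>1</sub> of *P*. It is
   located by bisection (tolerance 1e-4), with an independent dense-grid
   power-iteration cross-check (`sharing_score_grid()`). The *sharing score
   difference* (indirect − direct) isolates two-step,
   stack-then-redistribute sharing.
5. **Cohort analysis** (`analyze_cohort()`): Wilcoxon rank-sum contrasts,
   Spearman age correlations, optional sex/severity stratification, notched
   box summaries.
6. **Synthetic cohorts** (`simulate_session()`, `simulate_cohort()`):
   seeded gameplay simulation with ground-truth swipe labels, used by all
   tests and demonstrations in place of restricted participant data.

## Worked example

```r
library(playnet)

zm <- default_zone_map()
session <- simulate_session(strategy_profile(p_stack = 0.5, seed = 1), zm)
m <- compute_participant_metrics(session$events, zm, participant_id = "demo")
m[, c("n_food_delivery", "n_inter_plate", "direct_score",
      "indirect_score", "score_difference")]
#>   n_food_delivery n_inter_plate direct_score indirect_score score_difference
#> 1              48             9    0.0359313     0.08045015       0.04451885
```

Half of this simulated participant's twelve cycles were played by stacking:
48 deliveries reached the characters, 9 of them via inter-plate
redistribution. The direct sharing score 0.036 says plate dominance of the
eigenvector survives only a small penalty when stacked redistribution is
ignored; counting it (indirect score 0.080) raises the score, and the
positive difference 0.045 is the signature of the two-step strategy.

```r
co <- simulate_cohort(recovery_cohort_spec(n_per_group = 25, seed = 1), zm)
tab <- compute_cohort_metrics(co, zm)
res <- analyze_cohort(tab, contrasts = "direct:stacker",
                      correlates = c("direct_score", "score_difference"))
subset(res, method != "spearman vs age")
#>   contrast_or_group           metric n1 n2 median1 median2 stat        p
#> 1    direct:stacker     direct_score 25 25  0.0536 -0.0811  613 5.85e-09
#> 2    direct:stacker score_difference 25 25  0.0000  0.1788    0 9.73e-11
```

The never-stacking group has the higher median direct score (0.054 vs
−0.081) and a median score difference of exactly zero (its direct and
indirect networks coincide), while the stacking group's difference (0.179)
is clearly separated — the two strategies are recovered from the touch logs
alone.

A thin command-line interface over the same functions is installed at
`inst/cli/playnet` (subcommands `simulate`, `process`, `score`, `analyze`).

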