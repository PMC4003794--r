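---
title: "Methods: boosted fuzzy rule extraction with a discrete particle swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosted fuzzy rule extraction with a discrete particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzboost)
```

## The model

`fuzzboost` learns a set of fuzzy if-then rules for binary classification of
tabular records whose attributes have been min-max scaled into $[0,1]$. A
rule has the form

$$\text{if } x_1 \text{ is } A_1 \text{ and } \ldots \text{ and } x_n
\text{ is } A_n \text{ then class } C \text{ with } CF,$$

where each $A_j$ is one of 15 symbols: *don't care* (membership identically
1, also used for missing values) or one of the triangular fuzzy sets of the
uniform partitions of $[0,1]$ at granularities $K = 2,3,4,5$
($2+3+4+5 = 14$ sets). The $i$-th set of granularity $K$ is the triangle
with apex at $(i-1)/(K-1)$ and half-width $1/(K-1)$; at every point of
$[0,1]$ the $K$ memberships of one granularity sum to 1 (a Ruspini
partition). Antecedents are encoded as strings over
`0 1 2 ... 9 a b c d e` (`fuzzy_symbols()` lists the alphabet), so a rule is
a word like `"0150b0"`.

**Compatibility.** The compatibility of an instance $x$ with a rule is the
product of the per-attribute memberships
$\mu(x) = \prod_j \mu_{A_j}(x_j)$.

**Consequent and certainty factor.** Given (weighted) training data, the
class-compatibility of class $h$ is
$\beta_h = \sum_{x \in h} \mu(x) / N_h$, the mean compatibility within the
class. The consequent is the class with the largest $\beta_h$, and its
certainty factor is

$$CF = \frac{\beta_{\text{win}} - \bar\beta_{\text{others}}}{\sum_h \beta_h},$$

the winner's margin over the mean of the other classes, normalized by the
total. A rule with $CF \le 0$, or with tied class-compatibilities, is never
stored; `certainty_factor()` reports ties explicitly (for the symmetric
two-class case the factor is exactly 0).

**Inference.** Classification is *single winner rule*: the predicted class
is that of the rule maximizing $\mu(x) \cdot CF$. If the maximum is 0 (no
rule covers the instance) or is attained by rules of different classes, the
instance is left unclassified (`NA`). In the evaluation module an
unclassified instance counts as an error against its true class.

## The rule-edit algebra and the discrete swarm

The search space is the set of rule antecedent strings. Movement through
the space is expressed with an algebra of *rule antecedent modifiers*: a
single edit `ram(k, s)` replaces the symbol at position $k$ with $s$;
sequences of edits are applied left to right; merging two sequences (`⊕`)
concatenates and reduces to *basic form* (the last edit at each position
wins); `brams(r1, r2)` is the minimal sequence turning `r1` into `r2` (one
edit per differing position); and scaling a sequence by a coefficient
$c \in [0,1]$ keeps each edit independently with probability $c$.

A particle of the swarm is a set of $B$ candidate antecedent strings (one
candidate rule set); its velocity is one edit sequence per rule slot. Each
iteration:

1. every candidate's consequent, certainty factor and pruning score are
   re-derived from the current (weighted) training data;
2. a particle's fitness is the weighted winner-rule training accuracy of its
   *acceptable* candidates — those with $CF > 0$ and pruning score
   $g \le$ `g_threshold`, where $g$ is the ratio of covered misclassified
   weight to covered correctly classified weight;
3. local and global bests are updated (strict improvement only);
4. velocities are updated as
   $V \gets \omega V \oplus c_1\,\mathrm{brams}(r, L) \oplus
   c_2\,\mathrm{brams}(r, G)$ and applied to the positions, with inertia
   $\omega = 1/\text{iteration}$ and $c_1, c_2 \sim U(0,1)$.

The run stops when the global best has not improved for `stall_limit`
consecutive iterations (default 5; hard cap `max_iter = 200`) and returns
the acceptable rules of the global best, deduplicated.

### Implementation notes

* **Velocities as matrices.** A basic-form edit sequence is a partial map
  from positions to symbols, so the whole swarm's velocities are stored as
  one $(L \cdot B) \times n$ integer matrix with `NA` meaning "no edit".
  Merging is masked assignment and coefficient scaling is per-cell Bernoulli
  retention; all candidates of all particles are evaluated in one stacked
  matrix pass through a per-attribute membership cache. This is an exact,
  vectorized implementation of the algebra, not an approximation.
* **Coefficient draws.** The stochastic acceleration coefficients are
  redrawn from $U(0,1)$ every iteration *for every rule slot*, mirroring the
  per-dimension stochastic factors of classical particle swarms. Coarser
  sharing (one draw per iteration, or per particle) searches noticeably
  worse on planted-rule benchmarks; fixed values can be supplied via
  `swarm_config(c1 =, c2 =)`.
* **Ties.** Earliest index wins when two particles reach the same fitness;
  candidate rules whose class-compatibilities tie exactly are rejected.

## Boosting and the training loop

`train()` initializes every instance weight to 1 and alternates swarm runs
with a boosting re-weighting. After a new rule $R$ is accepted, its
compatibility-weighted error is

$$ER = \frac{\sum_{\text{label} \ne C} w\,\mu}{\sum w\,\mu}$$

(0 if the rule covers nothing), and every instance whose label matches $C$
and that the rule covers ($\mu > 0$) has its weight multiplied by

$$\alpha = \left(\frac{1}{1 + e^{\mu/(ER + w)}}\right)^{\mu} \in (0, 1],$$

so well-covered, correctly classified instances lose weight fastest and the
next swarm run concentrates on what remains. Misclassified and uncovered
instances are left bitwise unchanged, and weights never increase. Training
stops when the total weight falls to `K` (default 12), after `max_runs`
swarm runs (default 50), or after two consecutive runs contributing no new
rule.

Two numerical edge cases are handled explicitly: instances whose weight has
underflowed to exactly 0 are skipped by the update (the factor cannot move
them and its exponential is unstable at $w = 0$), and `alpha_factor()`
refuses the degenerate case $\mu > 0$ with $ER + w = 0$.

### A caveat on learning curves

Appending a rule is *not* guaranteed to increase — or even preserve —
cumulative training accuracy: a late rule fitted to a small residual weight
mass can win ties against earlier, broader rules and flip previously
correct predictions. We observed occasional dips of a few points in the
per-run training accuracy log. The per-run log returned by `train()`
records `train_accuracy` and `total_weight` per run so this can be
inspected; the total weight itself is monotone non-increasing by
construction.

## Data handling

* `read_uci()` parses the 14-field comma-separated heart-disease record
  layout (13 predictors plus the angiographic outcome `num`), with `"?"`
  for missing values. The outcome is binarized: 0 → `"healthy"`, 1–4 →
  `"patient"`. Predictors are min-max scaled to $[0,1]$; missing values
  stay `NA` and match every fuzzy set with membership 1 (the same
  convention as *don't care*).
* `cross_validate()` performs stratified $k$-fold cross-validation, fitting
  the scaling schema on the training folds only and clipping held-out
  values to $[0,1]$ — held-out information never leaks into the scaling.
* Zero-denominator metrics (e.g. precision with no positive predictions)
  are reported as `NA` rather than raising errors.

## The synthetic generator

`generate_synthetic()` draws instances uniformly on $[0,1]^n$ and labels
them by winner-rule inference over a small set of *planted* rules (their
certainty factors fixed at 1), with a fallback class for uncovered points
and independent label flips at a configurable noise rate. It emulates the
core structural assumption of the method — that the classes are separable
by a few axis-aligned fuzzy regions — and deliberately does **not** emulate
correlated attributes, class imbalance, systematically missing values, or
measurement noise on the attributes themselves.

Planted rules must occupy disjoint high-membership regions (each rule's
apex point must have compatibility below 0.5 with every other rule), so the
planted labeling is unambiguous. `planted_demo_spec()` fixes the canonical
benchmark used in the package's own tests: 5 attributes, two
single-antecedent rules splitting the first attribute at granularity 3, 200
instances, 5% label noise — a problem with a known Bayes ceiling of about
95% accuracy.

```{r demo, eval = FALSE}
sim <- generate_synthetic(planted_demo_spec(), seed = 1)
rs  <- train(sim$data, train_config(seed = 1001))
mean(predict(rs, sim$data$X) == sim$data$labels, na.rm = TRUE)
```

## Parameter defaults

| Parameter | Default | Role |
|---|---|---|
| `swarm_size` | 25 | particles per swarm run |
| `B` | 20 | candidate rules per particle |
| `g_threshold` | 1 | prune candidates with more covered misclassified than correctly classified weight |
| `stall_limit` | 5 | iterations without global-best improvement before stopping |
| `max_iter` | 200 | hard iteration cap |
| `omega` | `1/iteration` | inertia schedule |
| `c1`, `c2` | `U(0,1)` per slot | acceleration toward local/global best |
| `K` | 12 | total-weight stopping threshold of the training loop |
| `max_runs` | 50 | cap on swarm runs per training |

All defaults are the reference parameterization; every one can be
overridden programmatically (`swarm_config()`, `train_config()`) or from a
YAML config file on the command line (`load_config()`).

## Known limitations

* Binary classification only in the evaluation module; the core inference
  and certainty factors support any number of classes.
* Training accuracy is not monotone across boosting runs (see above).
* The stochastic search gives no optimality guarantee; on hard or noisy
  data individual runs vary, which is why the package's own acceptance
  checks are stated over 10 independent seeds with an 8-of-10 pass
  criterion.
* With the default `K = 12` and several hundred training instances, the
  weight decay requires many swarm runs, so trained rule sets can be large
  (hundreds of rules); raise `K` or lower `max_runs` for smaller, faster,
  slightly less accurate models.
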