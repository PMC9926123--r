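---
title: "Multidimensional phenotyping of group-housed rats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional phenotyping of group-housed rats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbsphen)
```

## What the pipeline computes

`vbsphen` implements an analysis pipeline for behavioral phenotyping of rats
housed in groups of six inside a visible burrow system (VBS): a
semi-naturalistic home cage with an open area (feeder, water) connected to a
covered burrow, instrumented with a grid of 32 RFID detectors. Three data
streams feed the pipeline:

1. **Detection streams** — per-animal dwell intervals on the detector grid,
   from which activity, roaming entropy, place preference and open-area
   preference are computed.
2. **Ethogram events** — scan-sampled, directed dyadic behavior records
   (actor, receiver, behavior, duration, zone) scored during the first 4 h
   of each dark and light phase, from which behavior counts, social
   networks and dominance hierarchies are derived.
3. **Task and physiology records** — operant decision-making logs (gambling
   task, reversed task, delay and probability discounting, fixed-interval /
   extinction), classical tests (social recognition, odor discrimination,
   dark–light box), and paired body weights and fecal corticosterone
   metabolite levels.

The per-animal scores are assembled into a 16-variable feature table and the
unsupervised discrimination stage asks which variables separate the two
genotypes: a random forest with leave-one-out cross-validation and Gini
(mean decrease in impurity) importances, a k-means clustering of the
importance profiles, and a centered/scaled PCA.

## Models and formulas

**Roaming entropy.** For animal $i$ on day $d$, with $p_{i,j,d}$ the
frequency of 1-second detections at detector $j$,
$$\mathrm{RE}_{i,d} = -\sum_j p_{i,j,d}\,\log p_{i,j,d} \,/\, \log k,$$
with $k = 32$ detectors and $0\log 0 \equiv 0$. Natural logarithms are used
in numerator and denominator; the ratio is base-invariant. Detection streams
are sliced to 1-second resolution first so that longer stays weigh more.
Daily RE uses one day's dark-phase frequencies; *total* RE pools detections
over the dark phases of the four analyzed days (a pooled entropy, not the
mean of daily entropies — the two summaries are named separately and the
pooled variant is what enters the feature table).

**Social networks.** For each dyadic behavior category the events of a
window are tallied into a weighted directed matrix ($c_{ij}$ = events $i$
initiated toward $j$, zero diagonal). Density, average path length and
Freeman out-degree centralization
($\sum_i (\max_j d^{out}_j - d^{out}_i)/(n-1)^2$) use binary edge existence;
weighted variants of the node metrics operate on the count matrix where the
metric admits weights (hub scores). Betweenness and closeness use the
directed unweighted graph; closeness uses outgoing distances and excludes
unreachable nodes. Bonacich power centrality uses attenuation
$\beta = 0.9/\lambda_{max}$ of the binary adjacency by default. Graph
computations are delegated to igraph; brute-force path enumeration serves as
an independent oracle in the test suite.

**Glicko hierarchy.** Every aggressive or sexual dark-phase interaction is a
rating period: initiator wins (score 1), receiver loses (score 0), and both
participants are updated with Glickman's equations ($q = \ln 10/400$,
$g(\mathrm{RD}) = 1/\sqrt{1 + 3q^2\mathrm{RD}^2/\pi^2}$, expected score
$E = 1/(1+10^{-g\,\Delta r/400})$). Defaults $r_0 = 2200$,
$\mathrm{RD}_0 = 300$, $c = 15$ follow the convention of the rating toolkit
commonly used for dyadic animal interaction data; no parameters are imposed
by the analysis itself and all are configurable. The *maximum rating
contrast* of a group is the difference between the highest and lowest final
ratings. The dominance rule — "rating higher than 1/3 of the maximum rating
contrast" — is ambiguous about its baseline; the default reading is
$r_{final} > r_0 + \text{contrast}/3$ (strict), which identifies exactly one
dominant in despotic synthetic groups; the alternative baseline (group
minimum) is available behind `rule = "minimum"` and flags the upper third of
the group instead. Neither reading is asserted to be the original one.

**Change points.** Rating trajectories are scanned with online Bayesian
change-point detection: constant hazard $h = 1/50$, Gaussian observations
with conjugate normal–inverse-gamma (unknown mean and variance) prior, and a
Student-t predictive. A change point is an index where the MAP run length
resets. The observation scale is initialized from the median absolute
deviation of first differences (floored at $10^{-6}$ so constant input
stays proper and yields zero change points). Counts are normalized by the
group's total number of interactions because interaction totals differ
between groups. The hazard and prior strengths are this package's choices,
stress-tested on step fixtures (a single 200-point step is localized within
±3 indices); absolute change-point counts should not be compared across
differently parameterized analyses.

**Blanchard dominance score.** Within a group of six, time in the open area
and weight loss are each ranked 1–6 (mean ranks on ties) and averaged. More
open-area time ranks higher; *less* weight loss ranks higher (the orientation
is a documented decision; wound counts, part of the original score, are
omitted as too sporadic to rank). Group means are always 3.5 by rank-sum
conservation.

**Task scores.** Gambling-task classification uses the percentage of
advantageous choices in the last 20 min with strict thresholds: good
decision-makers above 70%, poor below 30%, intermediates otherwise; a value
exactly at a boundary falls in the middle class, following the strict
inequalities of the definitions. The flexibility score is the percentage of
last-20-min reversed-session choices at the side holding the formerly
non-preferred options (flexible > 60%, inflexible < 40%). Discounting
curves are normalized to the training preference and plotted against
delay/max-delay or odds/max-odds with $\text{odds} = 1/P - 1$; the AUC uses
the trapezoid rule with an $x = 0$ anchor at the training level when no
zero level was measured (the quadrature and anchor are package choices; the
anchor can be dropped). The fixed-interval/extinction profile excludes the
first interval of the session and the first after the first extinction (12
of 14 analyzed), binning responses at 10 s within intervals and 1 min
within extinctions. The dark–light box risk index is the cohort maximum of
(first dark-visit duration + risk assessments + total dark time) minus the
animal's own composite — seconds and counts are summed without rescaling,
as the index is defined. Weight and corticosterone changes are reported as
grams lost (before − after) and percent variation
$100(\text{after}-\text{before})/\text{before}$.

**Discrimination stage.** The 16 canonical variables are: sexual,
defensive, maintenance, aggressive and affiliative occurrence totals;
weight and corticosterone percent variation; total distance; total roaming
entropy; open-area preference; delay-discounting AUC; aggression-network
hub centrality; flexibility score; gambling-task last-20-min preference and
reward latency; and the Blanchard score. Neither the forest nor the PCA
handles missing values, so the table is validated to be complete. Each of
the (default 100) runs performs a full leave-one-out cross-validation (500
trees, default $\sqrt p$ feature subsampling, run seed = master seed + run
index) and records the Gini importance of a full-data forest. k-means
($k = 4$, 25 restarts, seeded) groups variables by their importance profile
across runs; clusters are relabeled by decreasing mean importance so
cluster 1 is always the top group. PCA centers and unit-variance scales the
variables — they mix grams, percentages, counts and seconds, so scaling is
necessary — and reports squared-loading contribution shares, group
centroids and 0.95 normal confidence ellipses.

**Statistics.** Genotype contrasts use the Wilcoxon rank-sum $W$ in the R
convention ($W = \sum \text{ranks}(x) - n_x(n_x+1)/2$, control group
first); one-sample t-tests against theoretical values, exact sign tests and
Spearman correlations are thin wrappers over the standard implementations.

## The synthetic colony generator

Real deposited data require a download; the generator produces studies with
the statistical structure the analysis assumes, so every stage is testable
offline. Its defaults describe the reference design: 8 control + 5 depleted
groups of six males (48 + 30 animals), four analyzed days, two scored 4-h
phases per day.

* **Events** are Poisson per behavior category and scored phase
  (group total $\sim$ Poisson($6\lambda$), so per-animal means equal the
  configured rates). Initiators of aggressive and sexual interactions are
  drawn with a despotic propensity (top animal weight 4 in controls, 8 in
  the depleted genotype, others 1); receivers are uniform. Control rates
  (events/animal/phase) put affiliation and maintenance high; the depleted
  genotype quadruples general aggression, sextuples sexual behavior,
  quadruples defensive behavior and halves maintenance and huddling —
  effect sizes of roughly $d \approx 2$ on the category totals, matching a
  phenotype that separates strongly on home-cage variables.
* **Movement** is a first-order jump chain over the rook adjacency of the
  4×8 detector grid: dwell times are geometric (per-second leave
  probability 0.15 control / 0.30 depleted, making the depleted genotype
  more locomotive), and jumps choose neighbors proportional to
  genotype-specific zone weights (depleted: burrow- and tunnel-biased,
  giving restricted territories, lower roaming entropy, and near-zero
  open-area preference). Each scored phase is sampled for 3600 s at 1 Hz —
  occupancy frequencies and distance indices are stable well before that,
  and the span keeps full-study simulation fast.
* **Physiology**: weight loss 5 ± 3 g control vs 15 ± 4 g depleted;
  corticosterone multiplier 1.1 ± 0.25 vs 3.0 ± 0.6 (baseline
  ≈ 2 µg/g feces).
* **Cognition is null by design**: both genotypes share the decision-maker
  mixture (74% good / 9% intermediate / 17% poor), flexibility mixture,
  hyperbolic discounting steepness ($k \sim$ log-normal around 0.2 s⁻¹, the
  value that puts large/small indifference at a 20 s delay for a 5:1 reward
  ratio) and choice temperature. Cognitive variables therefore carry no
  genotype signal, and the discrimination stage must find them unimportant.
* **Seeds**: a master seed expands into per-component child seeds by a
  fixed counter scheme (`child_seed`), so identical configurations are
  byte-identical and components are independent across seeds.

What the generator does **not** emulate: learning during operant
acquisition (criterion sessions are emitted as already passed), circadian
modulation of event rates within phases, wounds, temporal autocorrelation
of behavior beyond the Markov walk, the day-by-day normalization of network
densities seen in real colonies, and hierarchy *instability* (the depleted
genotype's higher normalized change-point counts would need a time-varying
dominance process; the generator's propensities are static). Passing tests
therefore demonstrate that the pipeline recovers structure it is pointed
at — not that real colonies look like the generator.

## Numerical and design choices

* Dwell gap handling: streams are interval-based; an animal occupies its
  last-seen detector for the recorded duration. Overlapping intervals are
  rejected rather than resolved.
* Behavior counting uses occurrences, not durations (durations are carried
  but unused), and the "most expressed" filter keeps categories with cohort
  median strictly greater than 5.
* Day windows: analyses default to days 1–4; longer stays are retained but
  not analyzed by default.
* Hub scores of an edgeless network are all-zero; closeness of a node that
  reaches no one is NA; average path length of an edgeless network is NA.
* Classification boundaries (70/30, 60/40) are strict everywhere; boundary
  values fall to the middle class.
* The discrimination acceptance checks run 10 seeds × 5 leave-one-out runs
  (defaults stay at 100 runs) and the acceptance script uses 20 runs —
  problem sizes chosen so the whole verification remains comfortably
  interactive while the estimates (mean accuracy, importance ranking) are
  already stable at that depth.

## Known limitations

* The dominance-rule baseline and the change-point parameters are package
  decisions where the method description is silent; both are configurable
  and results should be reported with the settings used.
* The Wilcoxon p-value delegates to the standard implementation's exact /
  normal-approximation switch; on heavily tied data it is approximate.
* The generator's absolute event rates are calibrated to reproduce
  directions and separability, not the absolute counts of any real colony.
* Weighted betweenness/closeness (weights as distances) are not the
  default anywhere; the unweighted convention is used and a weighted mode
  is not currently exposed.
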