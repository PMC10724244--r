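---
title: "Discordance as an internal cluster-validity metric: methods and design notes"
author: "hplus package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discordance as an internal cluster-validity metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hplus)
```

## The problem

Given a dissimilarity matrix $D$ over $n$ observations and a candidate
cluster labelling $L$ with $k$ groups, internal validity metrics quantify
how well the labels fit the dissimilarity structure without reference to
ground truth. Metrics built directly on distance values (within-cluster
sums of squares, silhouette widths) inherit the scale of the chosen
dissimilarity, which makes them awkward for comparing different metrics on
the same data. Discordance statistics avoid this by using only the *ranks*
of the $N_d = n(n-1)/2$ pairwise dissimilarities: split them into the
within-cluster set $D_W$ (both observations share a label) and the
between-cluster set $D_B$, and count the violations
$$s = \#\{(w, u) : w \in D_W,\; u \in D_B,\; w > u\},$$
the number of within-distances strictly exceeding a between-distance. A
tight, well-separated clustering has small $s$.

## G+, its balance bias, and H+

The classical index $G_+ = s / \binom{N_d}{2}$ normalises $s$ by the number
of ways to compare any two distances. Writing $\alpha = |D_W| / N_d$ for
the proportion of within-cluster pairs, its expectation is
$$E[G_+] = \frac{N_d}{N_d - 1}\, 2\alpha(1 - \alpha)\, P,
\qquad P = P(d_{\text{within}} > d_{\text{between}}),$$
so $G_+$ depends on $\alpha$ -- and $\alpha$ is a pure function of the
group-size balance $b$ (and of $k$):
$$\alpha = \frac{1}{n-1} \sum_{j=1}^k b_j (n b_j - 1)$$
(`alpha_from_balance()`; for integer group counts this equals the empirical
proportion exactly). Two labellings of *null* data with different balance
therefore get systematically different $G_+$: with $n = 1000$, two equal
groups give $\alpha \approx 0.5$ and $E[G_+] \approx 0.25$, while a 900/100
split gives $\alpha = 819/999 \approx 0.82$ and $E[G_+] \approx 0.148$,
with no difference in cluster quality whatsoever.

$H_+$ repairs this by normalising $s$ by the number of comparisons actually
made:
$$H_+ = \frac{s}{|D_W|\,|D_B|}, \qquad E[H_+] = P,$$
the probability that a within-distance strictly exceeds a between-distance
-- a Mann--Whitney-type functional of the two distance sets, free of
$\alpha$ and hence of balance and $k$. `discordance()` reports $s$, $G_+$,
$H_+$, $\alpha$ and a cross-set tie count in one pass.

### Ties and degenerate partitions

The indicator in $s$ is strict, so exactly-equal cross pairs contribute
nothing; with heavily tied inputs (e.g. the binary metric) this can pull
$H_+$ down, which is why the tie count is surfaced as a diagnostic rather
than folded into the statistic. A partition with $k = 1$ (no between
distances) or all singletons (no within distances) leaves $H_+$ undefined:
the low-level `h_plus()` raises a classed error naming the offending side,
while `discordance()` and the sweep report degrade to `NA` with a warning
so that candidate scans survive degenerate entries. $G_+$ is still defined
there ($s = 0$) and is reported as 0.

### Exact computation is sub-quadratic in $N_d$

The naive count is $O(|D_W||D_B|)$ -- $O(n^4)$ pairwise comparisons, which
is what historically made these statistics impractical. Sorting $D_B$ once
and locating each within-distance by binary search gives the exact count in
$O(N_d \log N_d)$; `count_s()` does this via `findInterval()` with
left-open intervals, which counts *strictly* smaller values, so tie
handling is exact by construction. A deliberately naive double-loop twin
lives in the test suite and is required to agree exactly on hundreds of
random instances. Exact $H_+$ at $n = 3000$ (4.5 million distances) takes
well under a second this way.

## Quantile-sketch estimation (HPE)

For very large $n$ one may not want to hold or sort all $N_d$ distances.
Both sketch estimators compress each distance set into $p + 1$ percentile
values at levels $i/p$ (`quantile_sketch()`; linear interpolation between
order statistics -- `quantile type 7` -- whose endpoints are exactly the
min and max, as the construction requires). Exact $H_+$ equals the area,
over the unit square of (within-level, between-level) pairs, of the region
where the within quantile function strictly exceeds the between quantile
function. On the $p \times p$ level grid the sketches bracket that region
between a lower Darboux sum (cells verifiably inside) and an upper Darboux
sum (cells possibly touched):
$$H_e = \frac{1}{2p^2}\left(\sum_{i=0}^{p-1} \max(s_i - 1, 0)
      + \sum_{i=1}^{p} \min(s_i, p)\right),$$
where $s_i$ is the number of between quantiles strictly below
$q(D_W)_i$. Taking the midpoint of the bracket gives the guarantee
$$|H_e - H_+| \le \tfrac{1}{p}:$$
each of the $p$ columns contributes at most one cell of quantisation slack,
and the boundary's rises across columns telescope to at most one more
cell-row in total, so the bracket's width is at most $2p$ cells of area
$1/p^2$. We verified the guarantee empirically on a thousand adversarial
instance/resolution combinations (including heavily tied sets), where the
naive "count cells and divide" estimator fails it: counting the full
$(p{+}1)^2$ grid against $p^2$ inflates the estimate by roughly $H/p$, and
simply switching the denominator to $(p{+}1)^2$ leaves a $(1-H)/p$ bias
from the min-quantile row. The midpoint construction is the one that makes
the resolution parameter honestly interpretable.

Two algorithms produce the same per-column counts: `hpe_brute_force()`
compares all $(p+1)^2$ quantile pairs, and `hpe_grid_search()` walks the
monotone boundary with two pointers in $O(p)$ comparisons, recording the
count where each column meets the boundary. Columns whose within quantile
exceeds every between quantile receive the terminal count, which is exactly
what the full comparison would produce, so the two algorithms agree to the
last bit; both short-circuit to exactly 1 or 0 when the sketch supports are
disjoint. The default resolution is $p = 101$, which bounds the error by
about 0.01 while keeping the sketch negligible in memory; override it
freely.

Two caveats are worth stating. First, the guarantee concerns the
*compression* regime $p \ll \min(|D_W|, |D_B|)$ -- the regime the method
exists for, and automatic for distance sets of size $\sim n^2/2$. When $p$
rivals the set size, percentile interpolation itself contributes error of
order one over the set size and the strict $1/p$ bound can be exceeded
slightly; the property suite therefore exercises sets of 2000--8000 values
with $p \le 64$, plus a $p$-doubling ladder up to 1024 on 20000-value sets.
Second, $H_e$ inherits the sampling noise of the underlying data; the bound
is relative to the exact $H_+$ of the same data, not to a population value.

### The $\gamma_W \gamma_B$ decomposition

$H_+ \approx \gamma_W \gamma_B$ can be read as "$100\gamma_W\%$ of the
within distances strictly exceed $100\gamma_B\%$ of the between
distances"; the decomposition is not unique ($0.4 = 1.00 \times 0.40 =
0.80 \times 0.50$), and distinct factorisations with equal products need
not imply each other. `estimate_gammas()` reports the candidates the
grid-search walk has actually visited: column $i$ pairs the within level
$i/p$ with the bracketed fraction $(s_i - 1/2)/p$ (clipped to $[0,1]$) of
between distances below that quantile, filtered to products inside
$H_e \pm 1/(p-1)$ -- the window stated for this purpose, deliberately not
reconciled with the convergence bound $1/p$, and kept as such. At very
small $p$ the window may contain no visited cell; the function then returns
an empty table with a warning rather than widening the window. Fully
separated sets return the single pair $(1, 1)$.

## Bootstrap estimation (HPB)

HPE still requires the full $n \times n$ dissimilarity matrix. `hpb()`
avoids it: each of $r$ bootstrap replicates draws $t_j$ observations with
replacement from cluster $j$ -- $t_j$ allocated by largest-remainder
rounding of $b_j t$ with a floor of one per cluster, so the parts sum to
$t$ exactly and no cluster is starved -- computes the $t \times t$
dissimilarity sub-matrix on the fly, and evaluates exact $H_+$ on it
($t = 100$ means 4950 distances per replicate, so exactness is cheap and no
second layer of approximation is introduced). $H_b$ is the mean over
replicates; the per-replicate standard deviation is reported, and a fixed
seed makes the whole run reproducible. Resampling with replacement can
duplicate an observation and contribute zero within-distances; that is
ordinary bootstrap behaviour and is retained. Defaults follow the
recommendation $r = 0.05\,n$ (floored at 30) and $t = 100$; at $n = 3000$
with moderate separation this tracks the $p = 10001$ sketch estimate to
within 0.01 (median absolute discrepancy across seeds in our runs was
about $10^{-3}$).

## Simulation designs

`gaussian_mixture()` reproduces the two-group design used throughout: $n$
observations, $f$ independent Gaussian features, a fraction $b$ of
observations shifted by $\delta$ in every feature, common $\sigma$
(default 1, exposed as a parameter since the per-panel value is a free
choice). Group sizes are the deterministic `round(b * n)` rather than
Bernoulli draws so that $\alpha$ is exactly reproducible -- the fixed
$\alpha$ reported per simulation panel requires fixed group sizes.
`gaussian_distance_sets()` skips the data and models the two distance sets
directly as normals, which buys a closed-form oracle
$P(W > B) = \Phi((\mu_W - \mu_B)/(\sigma\sqrt2))$: with means $\pm 0.3$ and
unit variance this is $\approx 0.664$, the worked example the sketch
estimators are checked against. `balance_sweep()` crosses $\delta$ with $b$
and averages exact $G_+$ and $H_+$ on the true labels over `reps`
replicates per cell: the $\delta = 0$ row shows mean $H_+$ pinned at $1/2$
for every balance while mean $G_+$ tracks $2\alpha(1-\alpha)/2$.

These generators emulate the balance/effect-size geometry of the design,
not real expression data: features are independent and Gaussian, so there
is no count noise, no gene--gene correlation, and -- due to concentration
of high-dimensional distances -- much cleaner distance separation than a
real single-cell matrix would show. Passing the suite demonstrates the
estimators' properties (unbiasedness in balance, the $1/p$ bound, bootstrap
agreement), not that any particular clustering of real data is good.

Problem sizes in the test suite are chosen to keep Monte-Carlo error well
inside the tolerances being asserted: the null-balance sweep uses 25
replicates per cell at $n = 1000$, $f = 500$ (per-replicate sd of $H_+$ is
$\approx 0.02$ at $b = 0.05$, so the standard error of a cell mean is
$\approx 0.004$ against a $\pm 0.01$ assertion), ten seeds for the null
$G_+$ means, and five seeds for the bootstrap/sketch agreement at
$n = 3000$.

## Companion metrics and the k-sweep

`k_sweep_report()` evaluates candidate labellings side by side: exact $H_+$
(reported also as $1 - H_+$ so that larger is better), mean silhouette,
within-cluster sums of squares, and -- when reference labels are supplied
-- the adjusted Rand index. ARI and silhouette are implemented from their
standard formulas (pair counting with chance correction; $(b-a)/\max(a,b)$
with singletons scored 0) so the package carries no hard dependency for
them; the test suite cross-checks both against independent reference
implementations. WCSS is recovered from the dissimilarity matrix via
$\text{WCSS}_j = \sum_{i<i' \in j} d_{ii'}^2 / n_j$, which is exact for
Euclidean distances and documented as an approximation for anything else.
On synthetic three-group data with candidates built by merging and
splitting the true groups, $1 - H_+$ peaks at the true $k$, mirroring the
behaviour of the silhouette peak and the WCSS elbow, and ranking candidates
consistently with ARI.

Two degeneracies deserve attention when scanning over $k$: a labelling that
dumps almost everything into one cluster drives $\alpha \to 1$, and one
that shatters the data into many tiny clusters drives $\alpha \to 0$; both
can look spuriously concordant. `penalized_h_plus()` offers the exploratory
penalties $H_+/\max(\alpha, 1-\alpha)$ and $H_+/\min(\alpha, 1-\alpha)$ for
these two failure modes respectively (the latter may exceed 1); they are
flagged experimental and kept out of the core statistic.

## Numerical and interface choices

* Ingested matrices must be symmetric to a relative tolerance of $10^{-8}$
  (asymmetries below it are averaged away, beyond it rejected) with a zero
  diagonal; `dist` objects are accepted directly.
* Condensed files store the upper triangle in row-major $i < j$ order, one
  value per line -- the storage order of a `dist` object.
* The five supported metrics (Euclidean, maximum, Manhattan, Canberra,
  binary) follow the standard definitions; Canberra is computed as the
  plain sum $\sum |x_i - y_i| / (|x_i| + |y_i|)$ with zero-denominator
  positions skipped and *not* renormalised, and all-zero observation pairs
  under binary/Canberra are assigned distance 0 with a warning.
* Counts and products that can exceed integer range ($s$, $|D_W||D_B|$,
  $N_d^2$) are held in doubles throughout.
* `alpha_from_balance()` accepts fractional group sizes as the continuous
  extension of the formula; empirical $\alpha$ always comes from integer
  counts, and the two coincide exactly when `n * b` is integral.
* The command-line driver (`inst/cli/hplus.R`, dispatching to
  `cli_main()`) writes results to stdout or `--out` as JSON/CSV and
  messages to stderr; exit codes are 0 (success), 1 (degenerate
  partition), 2 (input error).

## Known limitations

* The $1/p$ guarantee is a compression-regime statement (see above); with
  tiny distance sets prefer exact `discordance()`, which is cheap there
  anyway.
* $H_+$ compares distance *sets*; it does not model the dependence between
  distances sharing an observation, so its sampling variance across data
  replicates is larger than an i.i.d. Mann--Whitney calculation would
  suggest -- visible in the balance sweep at extreme imbalance.
* No significance testing is provided; $H_+$ is an effect-size-like
  descriptive, and permutation inference is out of scope.
* The bootstrap reports a mean and a per-replicate sd, not confidence
  intervals.
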