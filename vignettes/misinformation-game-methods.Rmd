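---
title: "Models and methods behind misinfogame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind misinfogame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misinfogame)
```

# The game

`misinfogame` studies an asymmetric, infinitely repeated game between a
news *transmitter*, who each round publishes a story that is either true
or false, and one or more *receivers*, who decide whether to engage with
it. Receivers gain utility $\pi_t$ from engaging with a true story and
$\pi_f$ from a false one ($\pi_t > 0 > \pi_f$ describes truth-seeking
readers); transmitters gain $b_t$ or $b_f$ per engaged true/false story
(a misinformation outlet has $b_f > 0 = b_t$, a mainstream outlet the
reverse). Non-engagement pays nobody.

**Transmitter strategies** condition the next story's veracity on the
previous story's veracity and the engagement it drew. The polynomial form
is

$$ r_k^t = \alpha + \sum_l \gamma_l (k/N)^l, \qquad
   r_k^f = \beta + \sum_l \theta_l (k/N)^l, $$

with $k$ of $N$ receivers engaged; a strategy is *viable* when both rules
stay in $[0,1]$ for all $k$. With linear feedback and a single receiver
this is exactly the set where the endpoint action probabilities
$(\alpha, \alpha{+}\gamma, \beta, \beta{+}\theta)$ each lie in $[0,1]$ --
the parameterization used both for uniform sampling and for
co-optimization proposals. A sigmoidal form
$r_k^i = 1/(1+\exp[\lambda(k/N - m_i)])$ provides the sharp-switching
demonstration strategy ($\lambda = 100$, midpoints $0.5$/$0.25$).

**Receiver strategies** are attention-limited: with probability $a_0$ the
reader assesses the current story directly (engaging iff true); failing
that, with probability $a_1$ they consult their memory of the source via
the behavioural vector $p = \{p_{ct}, p_{cf}, p_{nt}, p_{nf}\}$ indexed by
(engaged?, was it true?) for the previous story; otherwise they engage at
a flat rate $p_0$.

**Noise.** Every intended action -- the transmitter's veracity choice and
each engagement decision -- is flipped independently with the execution
error $\varepsilon$ (default $10^{-3}$). The transmitter additionally
mislabels its memory of the previous story's veracity with the perception
error $\eta$ (default $0.3$) before choosing which rule to apply; payoffs
and all measured outcomes always use the true veracity.

# Exact dynamics for a single receiver

With one receiver the joint state (previous engagement, previous
veracity) is a four-state Markov chain whose transition matrix
`transition_matrix()` assembles in closed form. The stationary outcome
frequencies $v = (v_{tc}, v_{fc}, v_{tn}, v_{fn})$ come from a direct
linear solve; if the chain is reducible (possible only at
$\varepsilon = 0$, e.g. a receiver that never engages) the Cesàro limit of
power iteration from the uniform distribution is used, so degenerate
inputs have a deterministic, documented answer. Sums are accurate to
about $10^{-12}$.

A fixed polynomial transmitter strategy *enforces*, at stationarity of the
noise-free game and regardless of the receiver's strategy,

$$ v_f \;=\; \frac{1-\alpha}{1-\alpha+\beta}
   \;-\; \frac{\theta}{1-\alpha+\beta}\, v_{fc}
   \;-\; \frac{\gamma}{1-\alpha+\beta}\, v_{tc}, $$

the analogue of the unilateral linear constraints known from
zero-determinant strategies in iterated games.
`enforced_constraint_residual()` verifies this identity (it vanishes to
$10^{-10}$ at the exact stationary distribution with
$\varepsilon = \eta = 0$, and is $O(\varepsilon)$ otherwise), and
`classify_enforcement()` analyses its geometry (below).

# Strategy optimization

Strategy updating is a myopic noisy process: a candidate strategy is
drawn, both incumbent and candidate are scored by their stationary
payoffs, and the candidate is adopted with the Fermi probability
$1/(1+\exp[\sigma(w_i - w_j)])$, where $\sigma$ is attention to payoffs
($\sigma = 0$ is random drift; large $\sigma$ approaches hill climbing).

Numerical and protocol choices, several of which the source material
leaves open:

* **Payoff evaluation** uses the exact stationary distribution of the
  single-receiver chain at every update event (not finite play), so the
  process is a clean reversible chain whose stationary strategy density is
  $\propto e^{\sigma w}$.
* **Local proposals** perturb one uniformly chosen free behavioural
  component by a uniform draw on $[-0.1, 0.1]$, reflected into $[0,1]$.
  The kernel width is not pinned down by the source material; 0.1 mixes
  each component well within the $10^4$-event burn-in, and the package's
  tests check that the qualitative engagement-region results are unchanged
  at widths 0.05 and 0.2. A `global` kind (uniform redraw of the chosen
  component) is available.
* **Attention is exogenous**: $a_0$ and $a_1$ are never updated.
* **Initialization**: receivers start from the never-engage strategy
  (all behavioural components 0); the first round of any simulation starts
  from state (not engaged, previous story true).
* **Co-optimization** alternates one receiver event and one transmitter
  event per time-step (the asynchronous order is a convention);
  transmitter proposals act on the endpoint action probabilities, keeping
  every proposal viable by construction.
* **Measurement**: after a burn-in of $10^4$ update events, outcome
  frequencies are averaged over $10^4$ further events; per-story
  engagement rates are ratios of these time averages
  ($\bar v_{fc}/\bar v_f$), i.e. engagement per false story over the whole
  window.

The receiver's attention profile differs by experiment, following the
settings each analysis states: strategy-search ensembles use $a_0 = 0$,
$a_1 = 1$ -- the initialization $q = \{0,0,0,0\}$ of the four memory
components is only meaningful for a memory-using receiver -- while the
sigmoid demonstration and the region scans use $a_0 = a_1 = 0$ (flat
engagement probability only) with local exploration.

# Strategy-search ensembles and the responsive classification

`run_ensemble()` samples viable strategies uniformly (optionally with
$\gamma = \theta = 0$), optimizes an inattentive ($\sigma = 1$) receiver
against each, and records outcomes. *Successful misinformation* strategies
share misinformation more often than not ($v_f > 0.5$) and land in the top
decile of per-false-story engagement across all records (the top-fraction
cutoff uses the "higher" order-statistic convention, so at most
$\lceil 0.1 n \rceil$ records qualify up to ties); successful accurate
strategies are the mirror image.

The constraint above makes $v_f$ an affine function
$v_0 + c_t v_{tc} + c_f v_{fc}$ of engagement. A strategy is classified
**responsive (misinformation)** when the constraint guarantees
$v_f \ge v_{fc} + v_{tc}$ at every vertex of the feasible outcome polytope
$\{v_{tc}, v_{fc} \ge 0,\; v_{fc} \le v_f,\; v_{tc} \le 1 - v_f\}$ at
which the inequality is attainable. Three of the four vertices hold
automatically (two with equality); the all-engage corner would force
$v_f = 1$, which only the boundary family
$\alpha = 1, \gamma = \theta = -\beta$ can deliver, so no interior
strategy can satisfy it and it is excluded from the test. The condition
then reduces to $\gamma \le 1 - \alpha - \beta$, equivalently: *even
against a perfectly discriminating truth-seeking receiver (engage with
every true story, never with a false one), the strategy still delivers a
majority of false stories*. The accurate mirror is
$\theta \ge 1 - \alpha - \beta$. A `*_strict` flag records the literal
unit-simplex vertex test ignoring feasibility; it is satisfiable only on
the boundary of the viable set and is provided as a diagnostic.
**Extortion-like** strategies are those within max-norm distance
$\Delta = 0.05$ (in $(\alpha,\beta,\gamma,\theta)$) of one of the
equality-enforcing families ($v_f = v_{fc}+v_{tc}$ or
$1-v_f = v_{fc}+v_{tc}$); enrichment among successful strategies is tested
with a one-sided exact binomial test against the ensemble prevalence.

The package's default ensemble size is $10^4$ strategies (the acceptance
script's setting) -- a deliberate desk-scale reduction of the $10^8$-scale
random search the analysis emulates; because success is quantile-based the
reported proportions are insensitive to ensemble size beyond sampling
noise of a few percentage points. At these settings roughly 60--70% of
successful misinformation strategies and ~70% of successful accurate
strategies classify as responsive. The known discrepancy -- reported
responsive shares of 72% (misinformation) and 56% (accurate), with the
misinformation share the larger -- could not be reproduced in ordering
under any reversible Fermi protocol we examined; the unpublished details
of the original optimization protocol evidently matter, and we chose to
keep the documented defaults rather than calibrate unobserved protocol
parameters against reported outputs.

# Engagement regions and the sigmoid demonstration

`region_scan()` sweeps receiver preference $\pi_f$ (with
$\pi_t = -\pi_f$) against attention $\sigma$ (log-spaced in
$[10^{-2}, 10^2]$ by default; the published axes are not numerically
specified), co-optimizing transmitter ($\sigma = 100$) and receiver at
each cell and recording the mean per-story engagement difference
$v_{fc}/v_f - v_{tc}/v_t$. Against a misinformation transmitter the sign
pattern is: negative for attentive truth-seekers, positive for inattentive
truth-seekers (the transmitter's feedback drives engagement with false
stories despite the reader's preference), positive when readers prefer
false stories; mirrored for an accurate transmitter. Note the high-
attention aligned regions have small magnitudes when $a_0 = a_1 = 0$,
because a flat engagement probability cannot condition on veracity -- the
sign there is carried by feedback-induced correlation alone.

`sigmoid_demo()` plays the sigmoidal switch strategy against $N = 100$
receivers sharing one behavioural strategy updated by population-level
Fermi events ($\sigma = 1$): each epoch plays 50 recorded rounds, then
scores a candidate on 50 unrecorded rounds from a copied game state.
Low engagement yields mostly true stories; as engagement drifts up the
transmitter switches to false output, pushing engagement back down -- the
oscillation that makes the average engagement probability per false story
exceed that per true story even though receivers value truth.

# Story sequences and the rank experiment

`simulate_story_sequence()` plays 20 stories of a transmitter strategy
against a population of $10^5$ receivers sharing one behavioural strategy.
The population's memory-state distribution (the fraction who engaged with
the previous story) evolves exactly; one binomial draw per story converts
the engagement probability into a realized engaged fraction, which both
updates that distribution and drives the transmitter's feedback (evaluated
at the fractional engagement level). Perceived accuracy is the binary
veracity flipped with probability $\eta$. Between stories the shared
receiver strategy continues its myopic optimization (50 update events at
$\sigma = 1$ by default), reflecting the game's two-timescale structure;
with a frozen receiver the engagement-accuracy correlation is
statistically null at these noise levels, so the continued-optimization
design is load-bearing and documented as such.

`engagement_accuracy_slope()` is the OLS slope of z-scored engagement on
z-scored perceived accuracy (the sample correlation); zero-variance inputs
return 0 with a warning so degenerate always-true transmitters do not
break ensembles. `rank_experiment()` draws 20 successful accurate and 20
successful misinformation (transmitter, receiver) pairs per replicate,
ranks the 40 slopes, and averages slope and type composition per rank.
Sorting alone makes extreme ranks large in magnitude; the substantive
signature is the composition. In this implementation the per-type slope
separation (about 0.03 standardized units) is weak relative to pool
sampling noise, so misinformation over-representation at the lowest ranks
is directionally present but marginal -- a direct consequence of the
ensemble-selection discrepancy described above. Without feedback the
composition is exchangeable (about 50/50 at every rank), which the tests
verify.

# The statistical toolkit

These are the analysis methods for site-level engagement tables and
rating-level survey tables; the package validates them entirely on
synthetic data with known ground truth.

* `site_slope()`: within-site OLS of z-scored $\log_{10}$ engagement on
  z-scored mean headline accuracy, so the slope is the correlation
  coefficient; conventional SE and t-test. Sites containing a zero
  engagement count use $\log_{10}(x+1)$ for all their rows, recorded in
  the output.
* `fishers_combined()`: $-2\sum\log p_i \sim \chi^2_{2k}$.
* `random_effects_meta()`: DerSimonian--Laird via
  `metafor::rma(method = "DL")` (the moment estimator, $\tau^2$ truncated
  at zero; normal-approximation p). Slopes are pooled untransformed (no
  Fisher z), matching a "standardized average correlation" readout.
* `clustered_rating_regression()`: rating-level OLS of the z-scored
  outcome on z-scored accuracy with two-way cluster-robust covariance
  $V_{subject} + V_{headline} - V_{subject\times headline}$
  (inclusion-exclusion via `sandwich::vcovCL`, HC0, no small-sample
  adjustment unless `cadjust = TRUE`). When each headline cluster is a
  singleton this provably collapses to one-way clustering on subject,
  which the tests check against an independent computation.
* `analyze_site_table()` chains these per site type and carries both the
  Fisher and meta-analysis p-values; the type-I calibration test uses the
  Fisher p, which is exact under the null generator.

# Synthetic data generators

`generate_site_table()` draws per-site headline accuracies from the site
type's clipped normal (mainstream sites more plausible on average:
means 4.8 vs 3.4 on the 1--7 scale, SD 1) and sets
$\log_{10}$ engagement $= \mu_e + \sigma_e[\rho\, z(\text{acc}) +
\sqrt{1-\rho^2}\,\varepsilon]$, so the within-site population correlation
equals the type's `true_slope` exactly (defaults $0.13$ and $-0.11$,
mirroring typical empirical magnitudes); engagement is rounded to counts
(location 3, i.e. about a thousand interactions, scale 0.5 decades).
Accuracies are clipped normals rather than ordinal draws because the
downstream analysis consumes means; an ordinal mode is out of scope.

`generate_rating_table()` builds a fully crossed subject x headline design
with independent normal random intercepts and a latent accuracy perception
shifted by $\pm 0.3$ with headline veracity. With the default variance
components ($0.5^2$ each, effect 0.5) the outcome variance is exactly 1,
so the standardized rating-level effect equals `true_effect` by
construction. Ratings map to the 1--7 scale by an affine shift and
clipping at $\pm 3$ SD (a mild distortion covered by the recovery
tolerances).

What passing these tests shows -- and does not show: the generators are
Gaussian, balanced and missing-free, so they validate the estimators'
algebra and calibration, not their behaviour under skewed engagement
counts, ordinal ratings, or unbalanced designs typical of real platform
data.

# Scale and limitations

Test-suite and acceptance runs use deliberately reduced problem sizes
(ensembles of $10^3$--$10^4$ strategies, $10^2$ rank replicates, 50
demonstration replicates, $10^4$-event optimization windows), chosen so
the full cycle completes in minutes on one CPU while keeping quantile-based
summaries stable to a few percent. Known limitations: only linear feedback
is exercised by the samplers (higher polynomial orders are supported in the
types but collapse to linear for a single receiver); multi-transmitter
competition, social-learning receivers, and perfectly rational receivers
are architectural extension points, not implemented; and the two ensemble
proportions discussed above reproduce magnitude but not ordering.
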