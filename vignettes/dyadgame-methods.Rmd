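---
title: "Simulating and analysing dyadic joint steering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dyadic joint steering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadgame)
```

# The paradigm

`dyadgame` models a cooperative two-player computer game in which a dyad
jointly steers a single ball across a two-dimensional arena to collect
targets while avoiding obstacles that slow the ball to 10% of its speed.
Both players' 2-D inputs act simultaneously on the same ball: in joint play
the two inputs accumulate (capped at a force of 0.6, against 0.5 in
individual play), so aligned steering moves the ball fast, orthogonal
steering moves it slowly, and opposed steering not at all. Some obstacles
are invisible to one or both players, which makes momentary slow-downs
ambiguous: is my partner disagreeing with me, or did we hit something
neither of us can see? The package provides the full chain needed to study
this setting quantitatively without human data: a deterministic 60 Hz game
engine, synthetic steering agents with known ground-truth coupling, the
interpersonal movement-coordination measures, synthetic experience ratings,
and the statistical machinery that links game-concurrent measures to rated
experience.

A study cohort consists of 23 pairs. Each pair plays 60 one-minute trials:
10 individual, 40 joint, 10 individual. Joint play alternates between two
obstacle-visibility conditions in 10-trial sets -- SAME (both players see
the same six of nine active obstacles; three are invisible to the team) and
DIFF (three obstacles visible to both, three only to player 1, three only
to player 2) -- with the starting condition counterbalanced across pairs.
Experience ratings (integers 0--100) are collected after trials
5, 10, 14, 17, 20, 24, 27, 30, 34, 37, 40, 44, 47, 50, 55 and 60; the 12
joint rating moments partition joint play into 12 blocks of 3--4 trials
(sets of 4, 3 and 3), and blocks 1--6 versus 7--12 form sessions 1 and 2.
All pairs play the same 60 landscapes, with order shuffled only within each
10-trial set.

# The game engine

The engine integrates ball kinematics at 60 Hz (`dt` = 1/60 s) with linear
drag:

* per-player input is a 2-D vector capped at 0.5;
* the accumulated force is capped at 0.6 (joint) or 0.5 (individual);
* acceleration = `gain` x force - `drag` x velocity, with `gain` = 3.0
  units/s^2 and `drag` = 2.0 s^-1;
* speed is clamped at 0.6 units/s in joint and 0.55 in individual play
  (joint play enjoys a slightly higher speed cap);
* while the ball overlaps an active obstacle the frame displacement is
  multiplied by 0.1 (the stored velocity is untouched, so the ball resumes
  speed on exit; a velocity-damping variant sits behind
  `default_physics(slowdown = "velocity")`);
* walls clamp the position and zero the offending velocity component.

The arena is $[-1, 1]^2$; ball radius 0.03, target radius 0.06, obstacle
bars 0.3 x 0.06 game units. These geometric and dynamic constants are not
dictated by the paradigm description, which specifies only the force caps,
the 60 Hz frame rate and the 10% slowdown; they were chosen once so that
competent agents collect a few targets per minute, and are all configurable
through `default_physics()` and `default_layout()`.

Landscapes place three outer targets on a ring of radius 0.7 (120 degrees
apart) plus a fourth, initially inactive, target at the arena centre;
collecting a target deactivates it and activates the previously inactive
one, so exactly three targets are active at any time. Nine of fifteen
candidate obstacle slots are activated by rejection sampling until every
straight segment between the three initially active targets is intersected
by at least one active obstacle. Nine of the slots sit on the chords
between targets (guaranteeing the sampling terminates quickly) and six on
an inner ring. The whole layout -- ring and slots together -- is rotated
rigidly by a trial-dependent angle. Rotating only the target ring over
fixed slots would make the blocking constraint rotation-dependent and
frequently unsatisfiable with chord-anchored slots; rigid rotation keeps
the constraint invariant while still changing the scene every trial.

The inner simulation loop (physics plus the built-in steering agents) is
implemented in C++ for speed; a pure-R `step_physics()`/`run_trial()` path
accepts arbitrary R controller functions, and the test suite asserts
frame-for-frame equivalence of the two paths on a noise-free trial.

# Synthetic agents

The agents exist to give the analysis pipeline data with known ground
truth, not to model human cognition. Each agent follows a potential-field
steering law. Its input each frame is the capped unit resultant of

* a goal term towards its current target (nearest active target,
  re-chosen after each collection; with probability `exploration` a
  non-nearest target is chosen instead -- the exploit/explore knob that
  drives target-sequence complexity);
* a partner term: the direction of the partner's input `delay` frames
  earlier, weighted by `partner_gain` (the coupling knob);
* a repulsion-plus-slide term away from every obstacle the agent knows
  about, active within 0.18 units of an obstacle border (the tangential
  slide component prevents the head-on stalls a pure radial repulsion
  produces at bars placed across the direct path);
* a smooth steering wobble: the resultant is rotated by an AR(1) noise
  angle with per-frame correlation 0.97 (about half a second of
  correlation time at 60 Hz) and stationary SD `skill`. White per-frame
  noise was rejected as a model of steering error because intentional
  movement is smooth; a smooth wobble also makes one agent's idiosyncratic
  movement identifiable in the partner's input, which is exactly the
  signal the coordination measures target.

Agents only know the obstacles they can see. When the ball is being slowed
by an obstacle the agent cannot see, the agent infers its location with
per-frame probability `p_learn` (default 0.02) and avoids it from then on;
this memory resets every trial, which is what produces within-trial
improvement in both performance and coordination.

Scenarios fix the ground truth for recovery tests: `coupled` (both
`partner_gain` 0.4), `uncoupled` (0), `heterogeneous` (parameters drawn
from truncated normals -- the default study condition, giving the
between-pair variance the coordination split needs), and
`leader_follower(tau)`, in which the follower is a pure echo (goal and
avoidance weights zero, `partner_gain` 1, small wobble) of the leader's
input `tau` frames back, so the injected delay is the exact ground truth
for the time-lag measure.

Personality traits are drawn from truncated normals within instrument
ranges (five-factor scales 0--48, autism quotient 0--50, empathy aggregate
1--5 excluding personal distress). Pair-level "personality difference" is
the absolute within-pair difference; whether the original analysis used
absolute or signed differences is not documented, and absolute is assumed.

# Coordination measures

All coordination measures operate on the *steering direction*: the angle
of a player's 2-D input, undefined (masked) when the input magnitude is
near zero.

**WLCC.** The windowed lagged cross-correlation computes, for every 2 s
window (advanced in 0.5 s steps) and every lag up to +-1 s, the Spearman
correlation between the two players' steering directions. These window,
step and lag defaults are package choices, exposed in `wlcc_params()` and
recorded in output metadata; the values used by the original analysis are
not recoverable from the paradigm description. Because angles live on a
circle, each window is centred at its circular mean and re-wrapped to
$(-\pi, \pi]$ before ranking. A cumulative per-window unwrap was
implemented first (`circular = "unwrap"`) but rejected as the default: when
a player dwells near the $\pm\pi$ seam with steering noise, unwrap branch
flips corrupt the ranks in a few percent of windows, producing spurious
negative correlations strong enough to bias the time-lag measure upward by
more than a frame; the rotation convention recovers injected delays
exactly.

Five statistics summarise a WLCC matrix: synchrony (grand mean coefficient
over all cells), strength of relation (mean peak-picked coefficient),
variability of relation (sample SD of peak coefficients), time lag (mean
absolute peak lag) and switching (sample SD of signed peak lags). The peak
of a window is the largest interior local maximum of the signed
coefficient over the lag axis, ties broken towards the smaller absolute
lag, falling back to the global maximum when no interior local maximum
exists; a nearest-to-zero variant sits behind `peak_rule = "nearest"`.
Sample (n-1) standard deviations are used throughout. Segment-level
(trial-third) values restrict the aggregation to windows whose centres
fall in the segment.

**Mutual information** is the plug-in estimator on 8 equiprobable marginal
bins, base 2, so identical series give exactly 3 bits; an optional
Miller--Madow correction subtracts the first-order bias (useful when
comparing against a zero-dependence null). Equiprobable binning makes the
estimate invariant under monotone transformations, which also sidesteps
the angular seam.

**Phase slope index** is computed from Welch cross-spectra (4 s Hann
segments, 50% overlap) of the globally unwrapped angle series over the
0.05--5 Hz band, as the imaginary part of the frequency slope of complex
coherency summed over the band. The sign convention is fixed so that a
positive value means the first series leads; an optional jackknife over
segments normalises the value to a z-like score. Whether the original
computed MI/PSI per trial or per block is not documented; per trial with
block averaging is used.

**Surrogate dyads** pair player 1 of one pair with player 2 of another on
trials with the same landscape and condition, providing the baseline level
of movement similarity that the shared landscape alone induces.

# Behaviour measures

Per trial third (20 s): targets collected, fraction of frames on an
obstacle, and path length. Per trial: the complexity index -- the fraction
of collection events that are not part of a back-and-forth between the
same two targets, where event $i$ (from the third event on) is
back-and-forth iff its target equals that of event $i-2$; sequences with
fewer than three events score 1.0, and empty sequences carry a flag so
they can be excluded from aggregates. The prose definition of
"back-and-forth" admits variants; the $i$ vs $i-2$ rule is the one
formalised here and verified against exhaustive enumeration. Finger
movement basics are computed on the player's input series (the simulation
logs inputs at the frame rate; the original hardware sampled finger
bending 40x faster and averaged to frames): movement integrates absolute
per-frame position change over both axes, and direction changes count sign
flips of the per-frame delta on either axis with zero runs collapsed.

# Ratings and the block table

Synthetic ratings are the generative twin of the rating analysis:
block-level latent experience is a linear combination of z-scored block
measures plus a per-pair random intercept (SD 0.5), an AR(1) residual over
blocks ($\rho$ = 0.5, marginal SD 0.7), mapped to the 0--100 scale as
round(50 + 12 x latent) with per-player jitter (SD 3 points) before
rounding. The default coefficients carry the qualitative structure the
analysis layer is designed to recover -- engagement rises with targets,
variability of relation and synchrony, and falls with path length, time
and the SAME condition; agreement and predictability rise with targets and
variability of relation -- at moderate standardised magnitudes (0.2--0.5)
chosen once to represent a realistic signal-to-noise ratio, not fitted to
any empirical estimate.

The analysis table has one row per pair and joint block (276 rows at 23
pairs): outcomes are the two players' mean ratings, with engagement
arcsine-transformed as $\arcsin\sqrt{r/100}$ before averaging; predictors
are 4 behaviour measures, 9 finger-movement measures (basics averaged over
players), 7 absolute trait differences, a continuous time covariate
(block 1--12) and the condition. Predictors are z-scored over the table's
rows (the scaling is stored on the table); whether the original analysis
scaled predictors is unverified, but the small printed coefficient
magnitudes are consistent with some form of scaling, and z-scoring makes
elimination thresholds comparable across predictors.

# Statistical layer

**Mixed models.** `fit_lmm_ar1()` fits, by REML, a linear model with a
pair random intercept and AR(1) residual correlation over blocks within
pair: per-pair marginal covariance
$\sigma_u^2 J + \sigma_e^2 R(\rho)$, $R_{bc} = \rho^{|b-c|}$. The
restricted likelihood is profiled over $\sigma_e^2$ and optimised over
$(\rho, \lambda = \sigma_u^2/\sigma_e^2)$ from several starts; either
parameter can be fixed, which is how the test suite pins the fit against a
generalised-least-squares closed form. t tests use the residual
degrees-of-freedom approximation $N - p$; this is a documented
simplification relative to Satterthwaite-type corrections, and with 276
observations and few retained predictors the difference is negligible. The
fit is cross-checked against `nlme::lme` with `corAR1` in the test suite
(agreement to about 1e-4 on coefficients).

**Backward elimination** starts from the full 22-term fixed-effect set
(behaviour + finger movement + trait differences + time + condition),
repeatedly drops the term with the largest p value above $\alpha = 0.05$,
and refits until all terms are significant; the random intercept and the
AR(1) structure are never eliminated, time and condition are eliminable,
and the full trace is returned. **Leave-one-pair-out validation** refits
the final specification 23 times, predicts each held-out pair's 12 blocks
from fixed effects only, and reports the repeated-measures correlation
between observed and predicted values plus the mean within-pair Pearson
correlation; constant predictions are flagged as degenerate rather than
correlated. `rm_corr()` implements the repeated-measures correlation from
its defining ANCOVA (common slope after removing group intercepts,
$df = N - k - 1$) and is verified against an explicit projection-matrix
oracle.

**ATS/MATS bootstrap tests.** Repeated-measures (M)ANOVAs use the
ANOVA-type statistic (univariate) and the modified ANOVA-type statistic
(multivariate; a Wald-type quadratic form standardised by the diagonal of
the covariance, well-defined under heteroscedasticity and singular
covariances). Effects are encoded as Kronecker products of centering and
averaging matrices over the between factor, the crossed within factors and
the response dimensions. p values come from a parametric bootstrap:
subject vectors are redrawn from centred multivariate normals with the
groups' empirical covariances, and the p value is the exceedance fraction
with the conventional (k+1)/(B+1) correction, so identical seeds give
identical p values. The family analysis tests each observation family
(experience, behaviour, basics, coordination) over session (2) x condition
(2) x block position within set (3), with BH-FDR applied in five groups:
one meta group of the four multivariate tests, and one sub-group per
family covering its per-measure tests and post-hoc contrasts.

# Follow-up analyses

The coordination split ranks pairs on all seven coordination measures,
oriented so that larger ranks mean stronger coordination: synchrony,
strength of relation and MI count upwards; variability, time lag,
switching and |PSI| downwards. The orientation (in particular |PSI|, since
the sign of PSI encodes direction, not amount, of coordination) is a
package choice exposed as an argument. The aggregate rank orders pairs,
the median pair is excluded (23 pairs split 11/11/1), and ties break by
pair id. The transition analyses compare strong versus weak pairs over the
joint-to-individual shift with bootstrap ATS tests (targets in session 2;
ball control early versus late individual play; engagement joint versus
individual). The segment analysis runs the family MANOVA and per-measure
ANOVAs over trial thirds, refusing measures that do not exist at
trial-third resolution (ratings, complexity, MI, PSI). The target-cycle
profile assigns each WLCC window the elapsed fraction of the interval
between the two surrounding collections (windows before the first or after
the last collection are excluded; a window exactly at a collection starts
the next interval at phase 0 -- the complementary "fraction remaining"
convention would simply mirror the profile), pools windows into 20
equal-count bins, and reports across-pair means and SEMs per condition
with per-bin paired tests BH-corrected over the 20 bins. The
obstacle-visibility profile classes each window by the visibility of the
obstacle nearest the ball at the window centre; because SAME trials only
produce classes both/none and DIFF trials both/one, the test runs over the
structurally available condition-by-class cells as a one-way within
factor, plus the condition contrast within the shared "both" class.

# Problem sizes and determinism

The package's own validation runs at these sizes, chosen as a compromise
between statistical resolution and desk-scale runtime: the full 23-pair
cohort for design counts and sign recovery; an 8-pair coupled cohort for
the SAME/DIFF and surrogate contrasts; 200 replicates for coefficient
recovery; 40 replicates for elimination operating characteristics; 500
simulations x 199 bootstraps for type-I calibration; 100 seeded runs for
PSI driver recovery. Every stochastic stage takes an explicit seed, and
identical configurations give identical outputs; bootstrap p values are
reproducible by seed.

# What passing tests do and do not show

The synthetic cohort reproduces the structural features the analysis
relies on -- the design counts, temporal aggregation, condition structure,
within-trial learning, coupling with known delays, and rating models with
known coefficients -- so a green suite shows the measurement and inference
chain is correct and well-calibrated. It does not show that human dyads
behave like potential-field agents: the agents' wobble spectrum, obstacle
time and target rates are stylised, the rating generator is linear by
construction, and the empirical coefficient values reported for the human
cohort are not reproducible from simulation. Conclusions about real data
require rerunning the same pipeline on the deposited behavioural dataset,
which this package deliberately does not ingest.
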