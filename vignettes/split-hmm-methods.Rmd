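---
title: "Modelling splitting as social inference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling splitting as social inference: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splithmm)
```

## The model

`splithmm` implements a two-level discrete Bayesian observer of another
person's behaviour. At the first level the observer tracks, within a *trial*
of a few *epochs*, two hidden chains:

* an **internal state** $s_1$ — the other's intention, on an ordinal grid
  (five states from Bad to Good in simulation mode; eleven harm-aversion
  levels $\kappa = 0, 0.1, \dots, 1$ in task mode), and
* an **external state** $s_2$ — situational favorability on five levels from
  Very Unfavorable to Very Favorable.

Both jointly generate observed behaviour $o_1$ (eleven ordinal bins on
$[0,1]$) through $P(o_1 \mid s_1, s_2)$: each internal state peaks at its own
behaviour level, and external states shift that peak (one internal level per
unit favorability, two for "Very", floored at the second level and capped at
the second-highest). External states also emit a context cue $o_2$ through
$P(o_2 \mid s_2)$. Likelihood spread is controlled by precisions $\pi_{o1}$
and $\pi_{o2}$ via discretized squared-exponential kernels on the bin-index
scale, truncated and renormalized.

At the second level a **person state**
$s_3 \in \{\text{Bad}, \text{Integrated}, \text{Good}\}$ supplies priors over
the first level's *starting* states: a **dispositional prior**
$P(s_1 \mid s_3)$ and a **situational prior** $P(s_2 \mid s_3)$. The
Integrated dispositional row is a broad kernel centred on Neutral with free
precision $\pi_{s1}$; the Bad and Good rows are extreme, precise kernels
(fixed precision 3) pinned to the scale ends. Situational rows let a Bad
person's good behaviour be attributed to favorable circumstances ("ulterior
motives") and a Good person's bad behaviour to unfavorable ones ("excuses"),
with weight $\psi_{Ext}$ on the non-neutral states. The prior over $s_3$
itself is a Dirichlet whose initial concentrations are

$$\delta_{Bad} = \psi_{Bad}\,\psi_{Split}, \qquad
  \delta_{Integrated} = 1 - \psi_{Split}, \qquad
  \delta_{Good} = (1-\psi_{Bad})\,\psi_{Split},$$

so $\psi_{Split}$ weights splitting against integration and $\psi_{Bad}$ its
negative against its positive pole.

Within a trial, inference is variational: the posterior over
$(s_3, s_{1,1:T}, s_{2,1:T})$ is approximated by a fully factorized
distribution whose factors are updated by sequential coordinate ascent on the
variational free energy. Across trials, **learning** accumulates Dirichlet
concentrations: the person prior adds the person posterior, the Integrated
dispositional row and all situational rows add the trial-initial state
posteriors weighted by their person state's responsibility. Split
dispositional rows are rigid by default (and carry an effectively infinite
base count); the relaxed variant (`rigid_split = FALSE`,
`base_count_split = 10`) lets them learn.

## Tunable parameters

| Parameter | Meaning | Default | Range |
|---|---|---|---|
| $\psi_{Split}$ | prior weight of split vs Integrated person states | 0 | $[0,1]$ |
| $\psi_{Bad}$ | weight of Bad vs Good within the split mass | 0.5 | $[0,1]$ |
| $\psi_{Ext}$ | weight on non-neutral external states in split situational priors | 0.6 | $[0,1]$ |
| $\pi_{o1}$ | behaviour (or choice-emission) likelihood precision | 0.25 | $>0$ |
| $\pi_{o2}$ | cue likelihood precision | 0.001 | $>0$ |
| $\pi_{s1}$ | Integrated dispositional precision | 0.5 | $>0$ |
| `stay_prob` | per-epoch persistence of both hidden chains | 0.9 | $(0,1]$ |
| `base_count` | total concentration of each learnable Dirichlet row | 10 | $>0$ |
| `eta` | concentration added per trial | 1 | $>0$ |

Defaults follow the canonical simulation settings; precisions are unitless
inverse variances on the model's ordinal scales.

## Numerical choices

Several numerical decisions shape the package's behaviour and are worth
stating explicitly.

**Floored logarithms.** All probabilities entering inference are floored at
$10^{-16}$ before taking logs. The floored model defines the free energy, so
structural zeros (e.g. non-adjacent transitions) act as extremely improbable
rather than impossible, and the free energy is always finite.

**Coordinate ascent with multistart basin selection.** The mean-field
objective of this model is deliberately multimodal: the split person states
are attractors, and which basin the observer occupies *is* the psychological
state (integration, devaluation, idealization). Sequential full-conditional
updates guarantee a non-increasing free energy (the convergence certificate:
change below `tol = 1e-4`, at most 64 sweeps, no damping by default), but
land in whichever basin the initialization selects. Each trial is therefore
solved from two deterministic starts — a forward filtering pass anchored at
the learned person prior, and one anchored at a uniform distribution over the
person states with non-negligible prior mass — and the fixed point with the
lower free energy is kept. The prior-anchored start carries the persistence
of the current relational phase; the maximum-entropy start lets strong
counter-evidence flip the phase. Person states with prior mass below
$10^{-12}$ never enter a start, which makes a model whose split states carry
no prior mass behave identically (to within floating-point noise) to the
reduced Integrated-only model.

**Dispositional kernel scales.** The Integrated kernel is measured on the
internal-state index scale, which keeps it broad enough to track intention
changes at its canonical precision. The split kernels are measured on the
behaviour-anchor (bin) scale, which makes them near point masses — the
formalization of "extreme and precise". On the eleven-state task grid the two
scales coincide. This combination was chosen once, because it is the one in
which an Integrated observer tracks, split capture is reachable under the
one-pseudo-observation-per-trial learning rule, and the learning-rate and
uncertainty asymmetries between objectively bad and good agents emerge with
the signs reported for this class of model.

**Mean-field accuracy.** Against exhaustive enumeration on single trials, the
factorized posterior matches to total variation $< 0.02$ only in the
near-deterministic regime (precise likelihoods, modal observations, neutral
circumstances), where the exact posterior itself concentrates. Outside it the
exact posterior is graded — the floor/ceiling rule makes several
state-circumstance pairs emit identical behaviour — while coordinate ascent
commits to one explanation: the approximation is overconfident rather than
biased, and the test suite characterizes exactly that.

## Simulation scenarios

Scripted ground-truth paths (48 trials of 2 epochs) generate the canonical
experiments: integrated tracking of external or internal change, devaluation
under a latent all-Bad prior, mixed-valence switching, a behaviour ramp with
a dwell at the worst bin for hysteresis measurement, and an external-change
script for the cue-precision experiment. Exact per-trial values are package
fixtures: because the person prior accumulates one pseudo-observation per
trial, a person-state switch is only reachable while the accumulated
Integrated evidence is small, so the scripts place the onset of worsening in
the opening trials. The ramp dwells at the worst bin so the devalued phase
accrues person counts comparable to the initial idealization; the
cue-precision experiment varies the *circumstances* (intentions constant), so
that informative cues directly contradict the speculative favorable-
circumstance attributions that sustain false devaluation.

The negativity- and positivity-bias configurations remove one side of the
external effect *on behaviour* (the favorable-only variant leaves good
people's lapses inexcusable; the unfavorable-only variant leaves bad people's
improvements unexplainable). Removing a side of the situational prior support
instead was rejected: it turns the remaining row into a point mass whose
precision advantage distorts the comparison.

**A known limitation.** With relaxed split priors the model does not
reproduce a gradual fading of idealization/devaluation across repeated
scenario blocks. Converged coordinate ascent is winner-take-all in the person
factor: counter-evidence flips the person basin (sending the split state's
responsibility to zero) rather than updating the split row, and within an
active split basin the extreme prior pins the internal posterior at the row's
own peak. The split rows therefore only ever self-reinforce. A scheme that
maintains graded person posteriors (e.g. finite-iteration gradient message
passing) would channel counter-evidence into the split rows; fully converged
mean field does not. The corresponding acceptance check is expected to fail
and is retained as documentation of this boundary.

## The moral-inference task

The task module emulates a two-agent paradigm: an observed agent chooses 48
times between money-shocks option pairs, choosing the harmful option exactly
when $V_{harm}(\kappa) = (1-\kappa)\Delta m - \kappa \Delta s > 0$ (a "bad"
agent has $\kappa = 0.3$, a "good" agent $\kappa = 0.7$). The subject model
assumes each internal state emits a harm-aversion setting from a Gaussian
with the state's expected $\kappa$ (shifted $\pm 0.1$ per external
favorability level, $\pm 0.2$ for "Very", clipped to $[0,1]$), precision
$\pi_{o1}$, truncated to $(0,1)$; the harmful-choice probability is the
truncated-Gaussian mass below the option's threshold
$\theta = \Delta m / (\Delta m + \Delta s)$. Trials comprise three epochs
(one rating block); no cues are observed and $\pi_{o2}$ is fixed at 0.001
when fitting. Moral-character ratings (0–100) are discretized onto the
eleven-state grid (bin $k$ covers $[10k-5, 10k+5)$) and treated as samples
from the subject's current internal-state belief, floored at $10^{-6}$ and
renormalized. The pre-observation rating is read from the person-prior
mixture of dispositional rows and enters the likelihood by default (a flag
excludes it). The synthetic option set covers thresholds evenly on
$(0.05, 0.95)$ — the published option table is not reproduced — and ratings
are sampled at bin centres with no additional jitter.

## Fitting, comparison, recovery

Per participant, the summed rating log-likelihood across both agents (one
parameter set, independent runs from the same initial priors) is maximized by
bounded local search (`nlminb`) from 10 Latin-hypercube starting points, with
precisions searched on the log scale within $\pi_{o1} \in (0.1, 200)$,
$\pi_{s1} \in (0.1, 20)$ and weights in $[0,1]$. Reported alongside the ML
estimates: BIC ($k \ln n - 2\ln L$), McFadden pseudo-$R^2$ against a uniform
eleven-bin null, and the per-restart objective table. Nested comparisons
report per-participant log likelihood ratios and BIC differences, the
chi-squared statistic on twice the *mean* log LR (with the summed-LR variant
also emitted, since either aggregation convention is defensible), and the
full model's mean pseudo-$R^2$.

The synthetic-cohort generator defines the study conditions: two agents, 48
choices each, a prior rating and one rating per three choices. The default
groups emulate a control-like population (mean $\psi_{Bad} = 0.30$, moderate
$\psi_{Split}$) and a BPD-like population (mean $\psi_{Bad} = 0.47$, higher
$\psi_{Split}$), with Beta-distributed weights and log-normal precisions;
recovery uses a cohort drawn uniformly over the fitting bounds. Group means
follow the fitted values reported for the corresponding empirical groups;
spreads are a fixed, conventional choice (Beta concentration 10). What
passing recovery shows is that the *model's own* rating data identify
$\psi_{Bad}$ and $\psi_{Split}$ at this design size; it does not show that
empirical raters behave like the generator, whose ratings are noiseless
samples from the model posterior.

**Derived metrics.** The learning rate $\alpha$ is the through-origin
least-squares slope of prediction changes on prediction errors (an intercept
variant is available), computed from MAP point predictions; uncertainty is
the Shannon entropy of the internal-state posterior. In the simulation
experiment (objectively bad/good agents on low-volatility random walks,
$\psi_{Split} = 0.05$, 96 observations per replicate), point predictions are
the behaviour level of the MAP internal state from the post-cue predictive
belief — the internal-state channel of prediction. The full behaviour
predictive is also available, but its external-attribution component lets
predictions track observations through the context channel even while
internal beliefs are frozen, which masks precisely the rigidity the
experiment measures. Problem sizes were fixed at 40 replicates per cell and a
40-participant recovery cohort, which keep the full pipeline comfortably
reproducible on a single workstation core.

## Open design points, resolved

* Within-trial person updating: the person factor is updated jointly with the
  state factors to the shared fixed point, once per trial.
* Learning uses trial-initial state posteriors, because the second-level
  priors are priors over starting states; all-epoch weighting is a plausible
  alternative left unimplemented.
* External influence in the task shifts the expected harm aversion additively
  with clipping; a state re-mapping was the other reading.
* The cue-mistrust effect ("bad people's behaviour is inexcusable" encoded in
  second-level likelihoods) is not implemented.
* No forgetting or decay of concentrations: consolidation is monotone.

## What the simulations do and do not show

The scenario experiments demonstrate the qualitative phenomenology —
integrated tracking, sticky devaluation under a latent all-Bad prior,
bistable switching with hysteresis, one-sided-attribution biases, and
cue-precision amelioration — under scripted, stylized ground truth with
deterministic or model-sampled observations. They do not reproduce any
published figure's exact traces, and real raters' deviations from the
generative assumptions (jittered ratings, lapses, option-set structure) are
outside what the synthetic cohort emulates.
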