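---
title: "Models and methods behind effortframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind effortframe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortframe)
```

## The scientific problem

People trade off rewards against the effort needed to obtain them, and
the trade-off depends on how outcomes are framed. `effortframe`
implements the computational machinery of a three-part experimental
programme on loss aversion in cognitive effort: an adaptive titration
task that measures how much money a person will forgo to avoid a
longer/harder cognitive task, under gain framing ("earn $A for the easy
task") and loss framing ("start with $10, lose $L for the easy task"
with identical net outcomes); parametric discounting models fitted to
the resulting choices; and incentivized performance tasks (sustained
attention with reaction-time payoffs; an N-back working-memory task with
per-response payoffs) together with tonic pupillometry as a
physiological effort index.

Because the human data are external, the package ships a first-class
synthetic-agent generator: every analysis stage runs on simulated
subjects whose ground truth is known, which is what the test suite and
acceptance checks exploit.

## Effort discounting model

An offer of amount $M$ at effort $E$ has subjective value $SV(M, E)$
under one of five families with discount rate $k \ge 0$:

| family      | $SV(M,E)$ |
|-------------|-----------------------------|
| hyperbolic  | $M/(1+kE)$ |
| exponential | $M e^{-kE}$ |
| linear      | $M(1-kE)$ |
| quadratic   | $M(1-kE^2)$ |
| sigmoid     | $M\left[1-\dfrac{g(E)-g(0)}{1-g(0)}\right],\; g(E)=\dfrac{1}{1+e^{-k(E-p)}}$ |

Effort units are task minutes for duration designs (reference level
1 min; high levels 5, 10, 20, 30) and integer memory load for N-back
designs (reference 1-back; high levels 2, 3, 4). The sigmoid is rescaled
so $SV(0)=M$ exactly, following the convention in the effort-discounting
literature; its inflection $p$ is a third free parameter. Linear and
quadratic values can go negative at large $kE$; they are clipped at 0
because a task cannot be worth less than nothing in this design and the
clip keeps likelihoods finite.

Choices follow a softmax:
$P(\text{high effort}) = \text{logistic}\{\beta\,(SV_\text{high}-SV_\text{low})\}$
with inverse temperature $\beta$ per dollar. $\beta = \infty$ gives a
deterministic value maximiser; an exact tie then resolves to the
low-effort option (take the sure small amount) — an arbitrary but
documented and tested rule.

Loss-framed trials are *pegged*: the endowment equals the gain trial's
fixed amount, choosing the easy task loses $L =$ endowment $-$
amount, so net outcomes are identical across frames. Internally all
valuation is done on net outcomes with a frame-specific $k$; any
behavioural asymmetry must therefore come from $k_\text{loss} \ne
k_\text{gain}$, never from the engine.

## Staircase titration

The titration budget is two runs of five dynamically updated offers per
effort level; the update rule itself is an open design choice. We adopt
a midpoint bisection on $[0, 10]$: the first offer is $5; accepting it lowers the
upper bound, rejecting raises the lower bound, the next offer is the
midpoint. After 5 choices the interval has width $10/2^5 = 0.3125$ and
the estimate is its midpoint; two runs are averaged. This choice matches
that trial economy exactly and gives the provable error bound
$|{\hat\tau - \tau}| \le 10/2^5$ for any deterministic threshold
responder, which the acceptance suite verifies on a 100-point threshold
grid. Bounded or asymmetric step variants exist in the titration literature;
the symmetric bisection is this package's declared, tested choice. A replay mode accepts a recorded choice vector so real trial
CSVs can be re-scored by the identical engine.

Interleaved (trial-by-trial gain/loss) presentation keeps separate
staircases per frame. In this implementation each (frame, level)
staircase consumes the agent's private RNG stream in a contiguous
block, so interleaving changes only the recorded presentation order and
blocked/interleaved estimates are equal by construction — the design
intent (separate adaptive tracks) without scheduling artefacts.

## Fitting, BIC comparison, AUC

Models are fitted per subject and frame by trial-level maximum
likelihood over $(k, \beta[, p])$ with L-BFGS-B from a deterministic
multi-start grid. Starts and bounds are scaled by the largest effort in
the data ($k \cdot E_{\max}^{\,o}$ with $o=2$ for quadratic, else 1), so
minutes and load units get equivalent coverage; `parscale` is set
because $k$ and $\beta$ differ by orders of magnitude. $\beta$ is
bounded to $[0.01, 100]$ per dollar. BIC is
$q\ln n - 2\hat\ell$ with $q$ the parameter count and $n$ the trial
count of that subject-frame cell (per-frame convention, recorded in the
fit object). Ties break toward fewer parameters, then a fixed family
order. Simulation tests confirm that quadratic generators are recovered
as the group-level BIC winner, consistent with the field's finding that
effort discounting is best described by a parabolic cost in effort.

The model-free summary is the area under the discounting curve: with
$x_i = E_i/E_{\max}$ (the reference level included, anchored at
$y = 1$) and $y_i = $ indifference$/M_\text{high}$, the trapezoidal
area over $[x_1, x_m]$ is divided by $x_m - x_1$ so AUC $\in [0,1]$ and
larger values mean less discounting. AUC is invariant to positive
rescaling of both axes. The paired gain–loss contrast is a two-sided
paired $t$; discount rates are square-root transformed first to correct
their skew. Zero-variance difference vectors are flagged degenerate
(infinite $t$) rather than returned as NaN.

## Performance scoring

Vigilance runs score response speed $1000/\text{RT}$, the percentage of
responses strictly faster than the subject's baseline median RT
(ties count as not faster; at millisecond resolution the rule must be
deterministic), and ordinary least-squares time-on-task slopes of the
measure on trial onset in minutes (onset, not trial index). RTs below
100 ms are treated as false starts and excluded; RT-cleaning
conventions vary across labs, so the threshold is a configurable
declared default.

N-back runs are tabulated into hits / misses / false alarms / correct
rejections with fixed denominators 16/48; a non-response counts against
the subject (a miss, or a forfeited correct-rejection payment), because
the loss scheme penalises omissions like errors, while the SDT
correct-rejection cell counts every non-target without a target press
so denominators never change. Sensitivity is $d' = z(H) - z(F)$ and bias
$\beta = \exp\{(z(F)^2 - z(H)^2)/2\}$, with perfect/empty cells
corrected by the $1/(2N)$ rule (a rule is mandatory because 16/16 hit
runs occur; the log-linear alternative is noted but not default).
Earnings metadata follow the 6¢-per-target / 2¢-per-non-target scheme,
deducted from a $2 endowment in the loss frame.

## Pupillometry

Only the tonic signal is analysed: the mean diameter in the 1-s window
before each target onset. Cleaning pads invalid runs by ±100 ms,
linearly interpolates gaps ≤ 500 ms, and leaves longer gaps invalid; an
epoch is usable when ≥ 50% of its pre-stimulus samples are valid, and a
subject is included when every condition has ≥ 23 usable epochs. All
four constants are arguments: published eye-tracking pipelines differ
in these details, so the defaults are declared substitutes, not
reproductions of any particular pipeline. Preprocessing is idempotent via a processed-state marker
(a literal second pad-and-interpolate pass would grow the exclusion
zone around long gaps on every application). Time-on-task decline is
again an OLS slope per condition, in mm/min.

## Synthetic data: what it emulates, and what it does not

*Vigilance*: ~80 targets per 10-min run; log-normal RTs (median 400 ms,
log-sd 0.2 — right-skewed, positive support; the source states no RT
distribution), a 5% multiplicative incentive speed-up for gain/loss, an
optional extra loss speed-up (0 under the null of no gain/loss
asymmetry),
additive slowing of 5 ms/min, 2% lapses, uniform 2–10 s ISIs plus the
1-s feedback — arithmetic that yields ≈80 trials/600 s. Intermixed
sequences balance gain/loss/neutral counts to within 1 and never exceed
3 consecutive same-condition trials. The generator schedules trials
before assigning conditions so that balance holds for the realized
count.

*Pupil*: tonic level = baseline (4 mm) + 0.15 mm incentive dilation
around gain/loss events − 0.05 mm/min drift + Gaussian sample noise,
with Poisson blinks flagged invalid. No phasic target-locked response
is modelled — downstream analysis only consumes the pre-stimulus mean.

*N-back*: 64 letters, exactly 16 lag-$N$ matches, and non-target letters
constrained never to match at lag $N$, so SDT denominators are fixed by
construction rather than in expectation. Responses are Bernoulli with
load- and frame-specific hit/false-alarm rates; the defaults make
sensitivity fall with load and place the only frame asymmetry at
4-back (hit rate 0.68 loss vs 0.60 gain, false alarms ~0.07–0.08 —
the group means this design is built to emulate); rates at loads 1–3
are interpolating stand-ins chosen so $d'$ declines and bias grows with load.

*Agents*: population $k_\text{gain}$ is log-normal with median set so
the hardest effort level retains ~20% of its value under quadratic
discounting, log-sd 0.5, $\beta = 10$ per dollar, and
$k_\text{loss} = r\,k_\text{gain}$ with $r = 0.7$ as the default
loss-aversion effect (less discounting of loss-framed outcomes) and
$r = 1$ the null.

A green end-to-end test therefore establishes that the pipeline detects
a multiplicative frame asymmetry in $k$ of the assumed size under
softmax noise — not that real humans behave this way, nor anything
about phasic pupil dynamics, RT distribution shape, sequential
dependencies, or practice effects, none of which are modelled.

## Statistics

The one-way repeated-measures F uses the classical
condition × subject error term with df $(c-1, (c-1)(n-1))$; no
sphericity correction by default (the convention when dfs are reported
uncorrected), Greenhouse–Geisser behind a flag. The Incentive ×
Order mixed 2×2 interaction is computed as the squared two-sample $t$
on per-subject difference scores, df $(1, n-2)$ — exact for this
design; the incentive main effect on the same error term is returned
alongside because relabelling conditions within one group exchanges the
two (a useful invariance check). With the balanced complete designs
generated here, Type II and Type III sums of squares coincide. All
p-values are two-sided and uncorrected for multiplicity; this is
deliberate and stated prominently here. Both tests are calibrated by
simulation (type-I error within [0.04, 0.06] at 2000 Gaussian-null
replicates).

## Numerical and interface choices

* Randomness: every generator takes one named seed and leaves the
  global RNG untouched; agents own a private stream, so simulations are
  bit-reproducible and composable. Pipeline stage seeds derive from one
  master seed.
* Optimiser determinism: fixed start grids, no random restarts; ties on
  BIC break by parameter count then family order.
* Degenerate inputs are errors or flags, never silent NaN: empty trial
  sets, all-invalid traces, zero-variance contrasts, exhausted
  staircases, infeasible ISI ranges.
* I/O: plain CSV with fixed column names for every trial table
  (documented in `?io`), JSON for configs and reports. The CLI
  (`inst/cli/effortframe`, or `effortframe_main()`) accepts JSON configs
  only — a YAML parser is deliberately not a dependency.

## Known limitations

Human-data ingestion is schema-level only (replay and re-scoring);
hierarchical/Bayesian group fitting, delay/probability discounting,
ex-Gaussian RT modelling, phasic pupillometry and NASA-TLX modelling are
out of scope. The staircase update rule, RT cleaning threshold, pupil
cleaning constants and N-back letter pool are declared substitutes for
procedural details that task implementations rarely publish.
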