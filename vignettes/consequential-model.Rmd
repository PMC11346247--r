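---
title: "A three-layer attractor model of consequence-based decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-layer attractor model of consequence-based decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conseqsim)
```

## The task

In the consequential task an agent repeatedly chooses between two offers
("containers" filled to fractions $s_1, s_2 \in [0,1]$ of their height).
Trials are grouped into *episodes* of $n_H + 1$ dependent trials, where
the *horizon* $n_H \in \{0, 1, 2\}$ is the depth of consequence: within
an episode, choosing the smaller offer raises the mean of the next
trial's pair by a gain $G$, choosing the larger one lowers it by $G$.
The two offers of a trial are $M \pm \Delta S / 2$, with the difficulty
$\Delta S \in \{0.01, 0.05, 0.1, 0.15, 0.2\}$ held constant within an
episode. $G$ is large enough ($G = 0.3$ at $n_H = 1$, $0.19$ at
$n_H = 2$) that grabbing the larger offer early never compensates for
the induced loss, so the optimal policy is *small on every trial except
the last, big on the last*. Nothing signals this: there is no
performance feedback, and the only cue is the systematic shift of the
offer means after each choice.

`task_config()` / `build_session()` reproduce the reference session:
one 100-trial horizon-0 block, two 100-trial horizon-1 blocks and three
horizon-2 blocks of 105, 105 and 90 trials (100 episodes per horizon),
with the horizon order randomly permuted. First-trial means are drawn
uniformly from $[n_H G + \Delta S_{\max}/2,\; 1 - n_H G -
\Delta S_{\max}/2]$ so every stimulus stays in $[0,1]$ along any choice
path. The original study showed one shared stimulus list to all
participants; that list is not public, so plans are regenerated from a
seed instead, and a plan (serialized to JSON) plays the same role of a
shared fixture across simulated cohorts. The side of the bigger
stimulus and the presentation order are fair coin flips per trial and
are logged, which keeps exploratory analyses of side- or order-based
strategies possible downstream.

## The agent

The agent stacks three processes on three time scales.

**Perceptual layer.** Two pools of excitatory neurons, selective for
the left and right stimulus, race under recurrent excitation
($\omega_+ = 1.4$), mutual inhibition ($\omega_- = 1.5$) and a sigmoid
transfer $f(x) = F_{\max} / (1 + e^{-(x - \theta)/\tilde k})$
($F_{\max} = 0.04$, $\theta = 0.015$, $\tilde k = 0.022$, all in
ms$^{-1}$):

$$\tau\,\dot r_L = -r_L + f\!\big(\tilde\psi \lambda_L + (1-\tilde\psi)\lambda_R
  + \omega_+ r_L - \omega_- r_R\big) + \sigma\,\xi_L(t),$$

and symmetrically for $r_R$. The drives are linear rescalings of the
stimuli, $\lambda = \alpha + \beta s$. The binary intention
$\tilde\psi$ gates the inputs: at $\tilde\psi = 1$ the larger stimulus
drives its own pool (the default impulse toward "big"); at
$\tilde\psi = 0$ the drives are swapped and the race favors the smaller
stimulus. A choice is committed the first time $|r_L - r_R|$ strictly
exceeds the threshold $\Delta$; that time is the decision time, and the
reported RT adds a constant anticipation offset `rt_shift`.

**Intention layer.** The intention itself is the endpoint of a
double-well attractor process with basins at 0 (small) and 1 (big),

$$\tau_\psi\,\dot\psi = -4 \psi (\psi - 1)(\psi - \tfrac12)
  + \sigma_\psi\, g(t)\, \xi_\psi(t),$$

started from the current strategy value, $\psi(0) = \phi(T_E)$. The
noise acts essentially at onset and decays quadratically in time. The
printed decay factor ($1/t^2$) is singular at $t = 0$ and carries no
time unit, so we regularize it on the equation's own time scale,
$g(t) = (1 + t/\tau_\psi)^{-2}$, giving an effective dispersion
$\sigma_\psi / \sqrt{3 \tau_\psi} \approx 0.073$ at
$\sigma_\psi = 0.4$, $\tau_\psi = 10$ ms. Two regimes anchor this
choice: from $\psi_0 = 0.45$ at $\sigma_\psi = 0.4$ a clear minority
(about a fifth) of trajectories must still escape to the upper basin,
and under the reference learning parameters the optimal strategy must
become behaviorally reliable within roughly 10–20 episodes. A decay
scaled in raw milliseconds instead makes the process ten times too
deterministic and both regimes vanish.

**Strategy layer.** One preference $\phi(E, T_E) \in [0,1]$ per
within-episode position, updated after each episode by reinforcement
comparison:

$$\phi_{E+1} = \phi_E + k\, R\, (2\tilde\psi - 1)\,(\phi_E - 1)^2 \phi_E^2 ,$$

with learning rate $k$ and subjective reward $R$. The quartic factor
vanishes at the bounds, so $\phi$ stays in $[0,1]$ and the bounds are
absorbing. Between consecutive trials the reward is the perceived mean
shift the choice caused, $R = M(E, T_E+1) - M(E, T_E) = \pm G$. Each
position is updated exactly once per episode and its value is not
reused within the episode, so per-trial and end-of-episode batching are
mathematically identical here.

**The terminal reward is an interpretation.** No next trial exists at
the episode's last position, so $R$ is undefined there and must be
chosen. The default assigns $\pm G$ (positive iff the bigger stimulus
was chosen): the final gain is felt on the same scale that the
within-episode mean shifts make salient. With $G = 0$ (horizon 0) this
reduces to the chosen value minus the pair mean, $\pm\Delta S/2$, which
is also available everywhere as `final_reward = "half_delta"`. The
magnitude matters: at $k = 0.4$ a $\pm\Delta S/2$ terminal reward moves
$\phi$ at the last position by less than $0.07$ in 50 episodes, so the
agent could never come to reliably pick "big" at the end of an episode
within a block — contradicting the reference simulations in which a
horizon-1 agent learns the full policy within a few tens of episodes.
Both rules push the last position's preference upward whenever
intention and choice agree; they differ only in speed.

A bound worth knowing: each episode changes a given $\phi$ by at most
$k\,G\,\phi^2(1-\phi)^2$, and summing these maximal steps from
$\phi = 0.5$ shows that reaching $0.2$ (or $0.8$) takes at least about
54 episodes at $k = 0.4$, $G = 0.3$ — even for an agent that makes no
errors at all. Learning is expressed in *behavior* much earlier
(the intention process needs only a modest offset from $0.5$ to become
reliable), which is why learning times of ~5–15 episodes coexist with
terminal $\phi$ values around $0.23$ and $0.77$ after 50 episodes.

## Numerical choices

* Euler–Maruyama with Gaussian increments scaled by $\sqrt{dt}$;
  $dt = 0.5$ ms for the race (cutoff $t_{\max} = 4000$ ms, the task's
  response window) and $dt = 0.1$ ms for the intention process (cutoff
  500 ms). Convergence of the noiseless race to a dense-step reference
  is tested at order one.
* Both rates start at $r(0) = 0$; the source does not state an
  initialization, and the races it depicts start near zero activity.
* The threshold test is a strict inequality checked after each step; a
  tie exactly at $\Delta$ does not commit.
* $\psi$ is clamped to $[-0.2, 1.2]$ against noise-driven escape;
  basins are entered at `eps = 0.02`. A noiseless start exactly on the
  separatrix ($\psi_0 = 0.5$) is resolved by a fair coin flip at the
  cutoff and flagged as unsettled.
* A race that never crosses the threshold is a *no-decision* trial: no
  choice, no reward, no strategy update; the episode's mean chain
  continues unshifted, and the trial counts as zero reward in the
  episode's performance. The task itself is silent about lapsed
  trials, and this mirrors its scoring of error trials.
* All randomness flows through R's global RNG; `set.seed()` makes any
  simulation, including the C++ integrators, bit-reproducible.

## Behavioral metrics

* **PF** — episode performance, the min–max normalized cumulative
  value, where the attainable range comes from exhaustively enumerating
  all $2^{n_H+1}$ choice sequences (`enumerate_episode_outcomes()`).
* **P\_oc** — per-trial indicator of the optimal choice (small on
  non-final, big on final trials).
* **VD** — visual discrimination: the fraction of hardest trials
  ($\Delta S = 0.01$) over the last 80 episodes of the horizon-0 block
  in which the larger stimulus was selected.
* **t\_L** — learning time: the first optimal episode from which the
  optimal strategy is used in at least 9 of the following 10 episodes
  *and* in at least 75% of the remaining episodes of the block, after
  removing the hardest episodes so perceptual lapses do not mask
  strategy knowledge. Whether the 75% tail starts after the 10-episode
  window (default) or right after the candidate episode is exposed as
  `tail_from`. Blocks are scanned in presentation order and the first
  success fixes a single session-level learning time, consistent with
  the observation that the rule, once discovered, transfers across
  horizons.

## Fitting and recovery

The fit is sequential; later steps never revisit earlier estimates.

1. **Perceptual layer** (`fit_neural()`), on the horizon-0 block. The
   noise is fixed at $\sigma = 0.001$ ms$^{-1}$ (RT is insensitive to it)
   and the threshold is tied to the time constant along
   $\Delta = 2.57\times10^{-4}\,\tau + 0.0076$, so the grid is
   $(\tau, \beta)$ with $\alpha = -0.018$ fixed. Each cell simulates a
   horizon-0 block with the intention clamped at "big", aligns the
   simulated decision times to the observed RTs by a median shift
   bounded to $\pm 200$ ms (anticipating or lagging a GO signal is
   sub-second; an unbounded shift would discard the RT location that
   identifies $\tau$), and scores
   $\hat M = \mathrm{KSD} + 0.4\,|VD_{sim} - VD_{obs}|$. The KS
   distance keeps timed-out trials in both denominators (the empirical
   CDFs plateau at the decided fraction), so a cell that stalls far
   more or less often than the data pays for it; the VD probe judges
   races that never cross threshold by the larger firing rate at the
   cutoff. Ties break toward the smaller $\tau$, then $\beta$.
2. **Initial bias** (`estimate_initial_bias()`): per position, the
   frequency $f$ of choosing the bigger stimulus over that position's
   first three decided trials, rescaled toward the center as
   $\phi_0 = (1 + f)/3$ to keep the starting point out of the absorbing
   basins (the rescaling is exposed and other centering factors give
   the same qualitative behavior).
3. **Learning rate** (`fit_learning_rate()`): with $\sigma_\psi$ fixed
   at 0.6, each $k$ on $[0, 2.5]$ re-simulates the fitted block 50
   times; the objective is $L + 0.1 I$, with $I$ the mean-square error
   of performance over the first five episodes and $L$ the absolute
   difference between the block's learning time and the *median*
   simulated one (not-learned runs are imputed one past the block
   length; the median ignores the imputation while only a minority of
   runs fail).

`goodness_of_fit()` reports the triple $(1-\mathrm{KSD},\;
1-\mathrm{MSE}(PF_i),\; 1-|t_L^{obs}-\bar t_L^{sim}|/E)$, each clamped
to $[0,1]$.

**Parameter recovery** (`parameter_recovery()`) draws agents from
uniform priors, simulates one horizon-0 and one horizon-1 block each,
reruns the full three-step fit and reports true-versus-recovered
Pearson correlations. The priors deliberately stay in the network's
workable regime — $\tau \in [30, 85]$ ms, $\beta \in [0.04, 0.062]$ —
where drives land near the sigmoid's sensitive range and races finish
within the response window; the human fits land in the same region.
Initial biases are drawn leaning toward the larger stimulus
($\phi_0 \in [0.5, 0.65]$), the a-priori preference participants show:
an agent whose first-trial preference already starts below 0.5 behaves
optimally almost immediately, its learning time saturates at one or two
episodes, and $k$ is then unidentifiable from a single block — the
informative regime is precisely the one where the natural impulse must
be unlearned.
With $\alpha = -0.018$ fixed, drives outside that band either go
negative (low stimuli) or saturate the transfer (high stimuli), races
stall, and a single block simply carries little information about the
parameters; draws that lapse (time out) on more than 15% of either
block's trials are excluded and redrawn, as unusable participants would
be. Recovery uses a coarser
grid ($\tau$ step 4 ms, $\beta$ step 0.01, $k$ step 0.1) and reduced
Monte-Carlo sizes (200-trial cells, 200 VD races, 20 re-simulations
per $k$), sized so a 20-agent recovery completes in minutes on one
core; correlation is insensitive to the grid resolution itself.

Identifiability has intrinsic limits worth stating plainly. $\tau$ and
$\beta$ trade off along a soft ridge (slower dynamics with stronger
drives mimic faster dynamics with weaker ones, including in how often
races stall); the censored KS distance and the bounded shift break much
of it, but not all, and $\beta$ in particular is weakly identified when
the network discriminates perfectly at the fixed fitting noise (the VD
arm then carries no information). The learning rate is inverted from a
single block's learning time, a one-draw statistic whose run-to-run
spread is several episodes — at high $k$, where $t_L$ saturates at a
few episodes, a unit change in $k$ moves the median $t_L$ by barely one
episode. In repeated 20-agent experiments the package's own recovery
yields true-versus-recovered Pearson correlations of roughly 0.7–0.9
for $\tau$ and 0.5–0.8 for $k$ (and little for $\beta$); that spread is
a property of the sequential single-block design, not of the grid
resolution, and it is what `parameter_recovery()` will show you.

## What the generator does and does not emulate

Synthetic agents reproduce the task's structure (episode dependence,
difficulty levels, block layout), choice stochasticity, RT
distributions with an anticipation offset, perceptual errors at small
$\Delta S$, and learning dynamics. They do not emulate fatigue or
attention lapses, motor/mouse kinematics, inter-block transfer beyond
the per-block bias reset, or participant-specific subjective reward
functions; model races can also time out at weak drives, where humans
would still answer. Passing tests therefore validates the machinery
and the model's internal consistency on this idealized behavior, not
the claim that human data were collected this way.

## Problem sizes used by the test suite

Module tests run on blocks of 5–50 episodes; trend checks use 4-point
grids with 20 blocks per cell; the reference-regime check uses 30
seeded 50-episode horizon-1 blocks; recovery uses 20 agents at the
reduced resolutions above. These sizes were chosen to keep the full
suite in the tens of minutes on a single core while leaving every
qualitative conclusion stable under a seed change.

## Known limitations

* The terminal-reward rule is an interpretation (see above); the
  alternative reading is one switch away.
* With $\alpha$ fixed at $-0.018$, stimuli below $\approx 0.26/\beta$
  yield non-positive drives; the sigmoid tolerates this (the
  transformation is only required to preserve the stimulus order), but
  races
  there are slow and may stall. This is a property of the published
  operating point, not of the implementation.
* $\sigma_\psi$ and $k$ are not jointly identified from one block
  (the fit fixes $\sigma_\psi = 0.6$, following the source); neither
  are $\tau$ and $\Delta$ off the fitting line.
* Session-level learning time assumes the cross-horizon transfer
  finding; per-block assessments are returned alongside it.
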