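---
title: "A cortico-bulbar rate model with adult neurogenesis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cortico-bulbar rate model with adult neurogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`neurobulb` simulates three interacting neuronal populations of the early
olfactory system as firing-rate units:

* **Mitral/tufted cells (MCs)** — the excitatory principal neurons of the
  olfactory bulb. Each MC receives sensory drive $S_i$ plus a spontaneous
  component $M_{sp}$ and is inhibited by the granule cells it contacts.
* **Granule cells (GCs)** — axonless inhibitory interneurons. Each GC forms
  *reciprocal* synapses with a subset of MCs: the same contact excites the
  GC and inhibits the MC. GCs additionally receive top-down excitation from
  cortical cells. This population turns over by adult neurogenesis.
* **Cortical cells (CCs)** — an effective associative population. CCs
  receive feedforward MC input, excite each other through plastic recurrent
  weights $W^{(CC)}$ (bounded in $[0, W^{(CC)}_{max}]$), share uniform
  recurrent inhibition $w_{inh}$, and send top-down projections of weight
  $w_{GC}$ to the GCs. A dedicated block of CCs carries non-olfactory
  context signals instead of MC input.

The dynamics are threshold-linear for MCs and GCs and sigmoidal for CCs:

$$\tau_M \dot M_i = -M_i + S_i + M_{sp} - g \sum_j W^{(MG)}_{ij}\,[G_j - G_{th}]_+,$$
$$\tau_G \dot G_i = -G_i + \sum_j W^{(MG)}_{ji}\,[M_j]_+ + w_{GC} \sum_j W^{(GC)}_{ij}\,\sigma(C_j),$$
$$\tau_C \dot C_i = -C_i + w_{CM} \sum_j W^{(CM)}_{ij}\,[M_j]_+ + \sum_{j \ne i}\left(\alpha W^{(CC)}_{ij} - w_{inh}\right)\sigma(C_j),$$

with $[x]_+ = \max(x, 0)$ and
$\sigma(C) = C_{max}/(1 + e^{-\gamma_C (C - C_{th})})$. Only steady states
matter for the questions the package addresses, so $\tau_G = 0$: the GC
rates are evaluated algebraically inside the solver and the MC/CC equations
are relaxed to their fixed point. Reciprocity is structural — only
$W^{(MG)}$ is stored and the GC-to-MC direction is always its transpose —
so it cannot drift.

Two derived *effective* connectivities summarize what the wiring does:
$W^{(MM)} = W^{(MG)} W^{(MG)\top}$ counts, for each MC pair, the GCs
mediating mutual disynaptic inhibition, and $W^{(MC)} = W^{(MG)} W^{(GC)}$
counts the GCs through which each CC disynaptically inhibits each MC.

## Plasticity

**Cortical (fast, weight-based).** The recurrent CC weights are learned
once at the start of a simulation with a bounded Hebbian rule,
$\Delta W_{ij} = \eta\{(\sigma(C_i) - \Omega)\sigma(C_j) - \kappa\}$,
evaluated at the steady state for the current weights, with the recurrent
excitation scaled down to $\alpha_{learn} \ll 1$ during learning to limit
interference. One subtlety is worth spelling out: with the reference
parameters the decay increment $\eta\kappa = 1$ is more than an order of
magnitude larger than the ceiling $W^{(CC)}_{max} = 0.06$. If the rule were
applied to saturation after each stimulus separately, each stimulus would
erase every assembly except its own; the multi-odor memories the model is
supposed to hold could never coexist. `train_cortex` therefore consolidates
per epoch: it computes the increment for every training stimulus under the
current weights and applies their average, clipped to the bounds. Each
odor's assembly then keeps a positive net drive, cross-odor and silent
pairs still decay to zero, and training is exactly independent of
presentation order. During the neurogenic evolution the cortical weights
are frozen; "task switching" re-runs the same training briefly on a new
stimulus (e.g. a mixture) with the bulb untouched.

**Bulbar (slow, structural).** Each neurogenic step:

1. adds `N_new_G` GCs, each wired to `N_conn_MG` random MCs and
   `N_conn_GC` random CCs;
2. solves the steady state for every training odor, presented **alone**;
3. scores each GC's resilience $R_i = \sum_\beta [G_i(\beta) - G_{th}]_+$
   over the training odors;
4. removes each GC with survival probability
   $P_i = \tfrac12(\tanh(\gamma_R(R_i - R_0)) + 1)$ (independent Bernoulli
   draws per step);
5. adapts the inhibition strength $g$ to hold the GC count near its target.

Step 2 deliberately excludes the context drive. The context-odor
association lives in the cortical weights, and at probe time a context
ignites its odor's assembly through them; that is also how context-evoked,
odorless GC activity arises. If the context drive itself entered the
survival evaluation, GCs whose two CC partners happen to land in the active
context block would survive on contextual input alone, independent of $g$ —
the homeostatic controller then diverges and the odor response collapses.
We observed exactly this failure mode before settling on odor-alone
evaluation.

## Parameters

All rate-model constants default to the reference set (see
`?bulb_params`): $\tau_M = \tau_C = 1$, $M_{sp} = 0.2$, $G_{th} = 3$,
$w_{GC} = 3$, $w_{inh} = 0.05$, $\alpha_{learn} = 0.05$,
$\alpha_{recall} = 1$, $\gamma_C = 3$, $C_{th} = 0.2$, $C_{max} = 1$,
$\eta = 10$, $\Omega = 0.2$, $\kappa = 0.1$, $W^{(CC)}_{max} = 0.06$,
$N^{(MG)}_{conn} = 16$, $N^{(GC)}_{conn} = 2$,
$N^{(G)}_{new} = 0.1\,N^{(aim)}_{GC}$, 48 contextual CCs, $\gamma_R = 5$,
$R_0 = 3$, 110 MCs with one odor-CC per MC (identity feedforward map).
Stimuli are sums of Gaussian profiles over the MC index (amplitude
$A = 2 - M_{sp}$, width $w = 12$ for training odors; $A = 0.72, w = 2$ for
occluded probe targets; $A = 1.08, w = 12$ for distractor-task targets;
contextual drive $A_{context} = 2$).

Choices this package had to make itself:

* **$w_{CM} = 1$.** The feedforward MC$\to$CC weight is named in the model
  but has no reference value; its scale is degenerate with the stimulus
  amplitude, so we fix it at 1.
* **Peak centers.** Only the mixture components have stated positions
  (near MC 30 and 80). Presets place similar odors half a width apart and
  dissimilar pairs far apart, matching the intended overlap structure;
  all centers are overridable.
* **Context split.** The 48 contextual CCs are divided evenly between two
  contexts (24 cells each), configurable.
* **$g$ controller.** The model prescribes only the objective — keep the
  GC count in a band around the target. We use a multiplicative law
  ($\pm$`g_gain` per step outside a $\pm$`g_band` band), defaults
  `g_gain = 0.01`, `g_band = 0.05`, `g_init = 1`. The experiment presets
  use `g_init = 0.05`, `g_gain = 0.03`: the equilibrium $g$ at desk scale
  is $O(10^{-2}-10^{-3})$, and a faster gain reaches the band in tens
  rather than hundreds of steps. The controller's equilibrium — the count
  inside the band — is the same either way; we verified that the final
  network statistics do not depend on the starting point of the controller.
* **Blockade control in the extinction protocol.** "Blocking apoptosis"
  freezes removal *and* addition. Blocking removal alone while addition
  continues grows the GC population without bound (the survival sigmoid no
  longer acts on anything), which is not an interpretable control.
* **Extinction target.** The "respective CCs" of an odor pair are
  operationalized as the union of the CCs whose output exceeds
  $0.5\,C_{max}$ at the steady state of either odor.

## Numerics

The solver is explicit Euler on $M$ and $C$ with the GC rates recomputed
algebraically each step, run from the cold start $M = M_{sp}$, $C = 0$
until the largest absolute rate of change falls below
`steady_tol` = $10^{-6}$ (or $t$ exceeds `t_max` = $10^3$, which raises an
error and indicates runaway recurrent excitation). The cold start makes
steady states independent of presentation order and turns cortical
bistability into a detectable failure rather than silent hysteresis. A
fixed step is not safe here: the MC-block Jacobian is
$-(I + g\,W^{(MG)} D W^{(MG)\top})$ on the active set, so its stiffness
grows with the number of GCs and with $g$, and early in a run (few GCs,
large $g$) a step of $0.05\,\tau$ can be outside the stability region. The
step is therefore initialized from a power-iteration bound on
$\sigma_{max}(W^{(MG)})^2$ and halved whenever the residual grows
persistently. Steady states match brute-force integration of the full
three-population ODE system (with $\tau_G = 1$, via `deSolve`) to within
$10^{-4}$ on small networks; this is a standing test.

Other numerical conventions: $0/0$ channels in the Fisher discriminants
(both patterns silent at an MC) are dropped as the limit of the expression;
the diagonal of $W^{(CC)}$ is stored as exactly 0; the diagonal of
$W^{(MM)}$ (each MC's GC degree) is kept in all computations and zeroed
only for display.

## Read-outs and statistics

Discriminability of two MC patterns uses Fisher discriminants with the
firing rate itself as the variance proxy (Poisson-like spiking):
$F_{opt} = \sum_i ([M^{(1)}_i]_+ - [M^{(2)}_i]_+)^2 / ([M^{(1)}_i]_+ +
[M^{(2)}_i]_+)$ for an optimal linear read-out, and $F_{nonopt}$, the mean
over 5,000 random read-outs with weights uniform in $[-1, 1]$, for an
untrained read-out. $F_{opt}$ is exactly the supremum of the random-readout
discriminant over weights (a standing test against a numerical optimizer).
Pattern similarity is Pearson correlation of rectified rates, with one
exception: context-alone MC patterns sit entirely below threshold, so
context-vs-odor MC correlations use the raw activity variable, where the
"negative image" of the associated odor actually lives.

Because the supplement defining the original connectivity-specificity
measure was not available, `connectivity_selectivity` is this package's own
stand-in: the mean over odors of (within-odor mean entry − between-odor
mean entry) / (within + between), over disjoint odor-aligned index groups.
It is 1 for perfectly block-aligned wiring and 0 for structureless wiring,
and we use it only for qualitative shape and ordering claims (e.g. its
non-monotonic dependence on $w_{GC}$), never for absolute values.

Null models: the selectivity of $W^{(MM)}$ is compared against
degree-preserving random rewiring of every GC's MC partners; the
selectivity of $W^{(MC)}$ and the GC receptive-field matching against a
shuffle of which CC wiring belongs to which GC (which preserves both
marginal wiring distributions and destroys only the pairing).

## What the synthetic scenes emulate — and what they do not

All inputs are synthetic by design: parameterized Gaussian activation
profiles over a one-dimensional MC index, plus binary context signals.
These capture the overlap structure of odor representations (similar odors
share channels) while keeping the learned connectivity easy to visualize.
They do **not** capture natural odor maps (real glomerular patterns are
high-dimensional and not translation-invariant), concentration dynamics,
plumes, or sensory noise; a passing test suite therefore supports claims
about the *mechanism* — activity-dependent survival under joint bottom-up
and top-down drive producing odor-aligned, bidirectional cortico-bulbar
wiring — not about performance on natural stimuli.

Problem sizes: the experiment presets develop networks of ~500 GCs
(`N_GC_aim = 500`, 110 MCs, 150–200 neurogenic steps, 40 epochs of
cortical training), with 2–5 replicate seeds per claim and the top-down
sweep at `N_GC_aim = 400`. These sizes give stable orderings of all the
reported statistics while keeping a full run in tens of seconds; the
original protocols used 2,000–16,000 GCs, and all presets scale up by
setting `N_GC_aim` and `n_steps`.

## Known limitations

* Steady-state rates only: no spike timing, oscillations, synchrony, or
  conductances; mitral and tufted cells are not distinguished.
* The cortical population is an effective model of association and
  pattern completion — one layer, no feedforward inhibition, no separate
  read-out population for fine discrimination.
* At desk scale the extinction protocol reproduces the structural effects
  (GC loss, odor-specific apoptosis, no loss under blockade) but the
  discriminability of the extinguished pair does not degrade: the release
  of top-down inhibition raises response amplitudes, and replacement GCs
  sustained by bulbar drive alone rebuild the mutual-inhibition block
  within a few steps, which together offset the structural loss in
  $F_{opt}$. We verified this is not a scale artifact (it persists at
  2,000 GCs) nor a controller-path artifact; it appears to be a genuine
  regime difference of the reconstructed model.
* For the same reason the cost of a context *without* its occluder is
  delicate: it requires the context-evoked suppression at the target's
  channels to exceed the target amplitude. In our networks that suppression
  is shallower (roughly 0.3–0.5 against a 0.72 target), so the
  context-hurts-detection comparison is inconsistent across seeds at desk
  scale and reverses in larger networks, while every other
  occluder/distractor ordering is robust.
* The homeostatic controller is a design choice (only its objective is
  given); very small GC targets (tens) make single additions/removals
  large perturbations and the band correspondingly noisy.
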