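# neurobulb

Firing-rate simulator of the olfactory bulb and an associative cortical
area, coupled by top-down projections and rewired by adult neurogenesis.

## The scientific problem

The olfactory bulb's granule cells (GCs) — inhibitory interneurons forming
*reciprocal* synapses with the bulb's principal mitral/tufted cells (MCs) —
turn over throughout adult life, and their survival depends on their
activity. They are also the target of massive top-down projections from
olfactory cortex. `neurobulb` implements a computational model of how these
two facts interact: stochastic GC addition with activity-dependent survival
sculpts both the intra-bulbar network and the cortico-bulbar projections
into odor-specific subnetworks, so that cortical cells representing a
learned odor gain disynaptic inhibitory control over exactly the MCs driven
by that odor. The package is for computational neuroscientists who want to
simulate, probe and extend this mechanism.

Three populations are modeled as rate units (`[x]+ = max(x, 0)`,
`σ` a sigmoid):

    τ_M dM_i/dt = −M_i + S_i + M_sp − g Σ_j W^(MG)_ij [G_j − G_th]+
    τ_G dG_i/dt = −G_i + Σ_j W^(MG)_ji [M_j]+ + w_GC Σ_j W^(GC)_ij σ(C_j)
    τ_C dC_i/dt = −C_i + w_CM Σ_j W^(CM)_ij [M_j]+ + Σ_{j≠i} (α W^(CC)_ij − w_inh) σ(C_j)

with τ_G = 0 (GC rates follow their inputs algebraically). The recurrent
cortical weights W^(CC) are learned by a bounded Hebbian rule and then
frozen; the bulbar wiring evolves by neurogenic steps: add randomly wired
GCs, score each GC's *resilience* R_i = Σ_β [G_i(β) − G_th]+ over the
training odors, remove GCs with survival probability
½(tanh(γ_R(R_i − R_0)) + 1), and adapt the inhibition strength g to hold
the GC count near a target. Performance is read out with Fisher
discriminants using the rate as the variance proxy: F_opt for an optimal
linear read-out, F_nonopt for the mean over 5,000 random read-outs.

## Worked example

Develop a network exposed to two pairs of similar odors, then inspect what
it learned:

```r
library(neurobulb)

cfg <- experiment_config("extinction_4odors", seed = 3, n_steps = 200)
dev <- run_development(cfg)   # ~25 s: trains cortex, evolves the bulb
dev$mean_N_G
#> [1] 514
dev$net
#> <bulb_network>
#>   110 MCs, 506 GCs, 158 CCs; g = 0.00823
#>   cortical weights: 728 nonzero of 24806

## odor-aligned structure of the learned wiring (pair-level groups)
groups <- odor_groups(dev$scene)
sel <- selectivity_with_null(dev$net, dev$params, groups, n_shuffle = 50)
round(c(W_MM = sel$mm, null = mean(sel$mm_null), p = sel$mm_p), 4)
#>    W_MM    null       p
#>  0.0405 -0.0022  0.0196

## each GC's sensory and cortical receptive fields match
rf <- receptive_field_matching(dev$net, probe_battery(dev$params), dev$params)
round(c(observed = rf$observed, null = mean(rf$null)), 3)
#> observed     null
#>    0.021   -0.103

## perceptual learning: the trained bulb separates the similar pair better
pr <- dev$scene$probes
naive <- new_network(dev$params)
c(naive   = run_probe(naive,   dev$params, pr$odor1, pr$odor2)$F_opt,
  trained = run_probe(dev$net, dev$params, pr$odor1, pr$odor2)$F_opt)
#>    naive  trained
#> 5.830061 8.730909
```

The GC count settles inside the homeostatic band around the 500-cell
target; the mutual-inhibition matrix W_MM concentrates on MC pairs driven
by the same odor pair (selectivity far above its rewiring null); GCs end up
wired to MCs and to cortical cells with matching odor preference (positive
receptive-field correlation vs. a pairing-shuffled null); and the trained
network discriminates the two *similar* training odors better than a naive
bulb — the model's account of perceptual learning. (For odors that barely
overlap, the same inhibition lowers response amplitudes without a
decorrelation gain, so the benefit is specific to hard discriminations.)

Scripted protocols for the other experiments:
`run_context_recall()` (odorless context reinstates its odor's GC pattern),
`run_extinction_protocol()` (erasing a cortical memory triggers
odor-specific GC apoptosis), `run_probe()` on the `occluder`/`distractor`
scenes (context-gated detection and discrimination in odor clutter),
`run_task_switch()` (brief cortical retraining switches the network to
mixture discrimination), and `run_wgc_sweep()` (selective wiring requires
an intermediate top-down weight). A command-line front end for all of them
is installed at `inst/cli/neurobulb`.

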