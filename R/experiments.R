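#' Experiment configuration
#'
#' Bundles a scene preset, parameter overrides, run length and seed for the
#' scripted protocols. A seed is mandatory: every experiment must be
#' bit-reproducible from its configuration.
#'
#' The desk-scale defaults used by the experiment runners are `N_GC_aim =
#' 500` with a faster homeostatic controller (`g_init = 0.05`, `g_gain =
#' 0.03`) than the conservative [bulb_params()] defaults, so that the GC
#' count settles within a couple of hundred neurogenic steps; the
#' controller's equilibrium (count inside the target band) is the same.
#'
#' @param scene preset name for [build_scene()].
#' @param seed integer RNG seed (required).
#' @param n_steps neurogenic steps of the development run.
#' @param n_epochs cortical training epochs.
#' @param param_overrides named list passed to [bulb_params()].
#' @param scene_overrides named list passed to [build_scene()].
#' @return An object of class `bulb_experiment_config`.
#' @export
experiment_config <- function(scene, seed, n_steps = 200, n_epochs = 50,
                              param_overrides = list(),
                              scene_overrides = list()) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required: experiments must be reproducible")
  base <- list(N_GC_aim = 500, g_init = 0.05, g_gain = 0.03)
  base[names(param_overrides)] <- param_overrides
  params <- do.call(bulb_params, base)
  structure(list(scene = scene, seed = as.integer(seed), n_steps = n_steps,
                 n_epochs = n_epochs, params = params,
                 scene_overrides = scene_overrides),
            class = "bulb_experiment_config")
}

#' Develop a cortico-bulbar network
#'
#' The standard pipeline: build the scene, train the recurrent cortical
#' weights on the training pairs (reduced recurrent excitation), freeze
#' them, then evolve the bulb by neurogenic steps under the homeostatic
#' inhibition controller until a statistically steady state.
#'
#' @param cfg an [experiment_config()].
#' @return list with the developed `net`, the evolution `record`, the
#'   `scene`, the `params`, the estimated `burn_in` step and the
#'   post-burn-in mean GC count.
#' @export
run_development <- function(cfg) {
  set.seed(cfg$seed)
  scene <- do.call(build_scene,
                   c(list(cfg$scene, cfg$params), cfg$scene_overrides))
  net <- new_network(cfg$params)
  net <- train_cortex(scene$env, net, cfg$params, n_epochs = cfg$n_epochs)
  if (cfg$n_steps == 0)
    return(list(net = net, record = NULL, scene = scene,
                params = cfg$params, burn_in = NA, mean_N_G = NA))
  ev <- evolve(net, scene$env, cfg$params, cfg$n_steps)
  bi <- burn_in_step(ev$record, cfg$params)
  post <- if (!is.na(bi)) ev$record$N_G[ev$record$step >= bi] else
    ev$record$N_G[seq(max(1, cfg$n_steps - 19), cfg$n_steps)]
  list(net = ev$net, record = ev$record, scene = scene, params = cfg$params,
       burn_in = bi, mean_N_G = mean(post))
}

#' Probe a developed network with a pair of stimuli
#'
#' Solves the steady state for two probe odors under a given condition and
#' returns the discrimination statistics. Conditions: `"none"` (odor alone),
#' `"context"` (odor plus a context signal), `"blocked"` (top-down
#' projections silenced at probe time only, `w_GC = 0`; development is
#' untouched).
#'
#' @param net a developed `bulb_network`.
#' @param params a [bulb_params()] object.
#' @param S1,S2 probe odor vectors (the two alternatives to discriminate).
#' @param context_id context present during the probe, or `NULL`.
#' @param blocked logical; silence top-down input during the probe.
#' @param n_readouts random read-outs for [fisher_nonopt()].
#' @return one-row data frame: `F_opt`, `F_nonopt`, `r` (pattern
#'   correlation), plus the raw patterns as attributes `M1`, `M2`.
#' @export
run_probe <- function(net, params, S1, S2, context_id = NULL,
                      blocked = FALSE, n_readouts = 5000) {
  w_GC <- if (blocked) 0 else params$w_GC
  ctx <- if (blocked) NULL else context_id
  s1 <- stimulus(S1, context_id = ctx, params = params)
  s2 <- stimulus(S2, context_id = ctx, params = params)
  ss1 <- solve_steady_state(s1, net, params, w_GC = w_GC)
  ss2 <- solve_steady_state(s2, net, params, w_GC = w_GC)
  out <- data.frame(
    F_opt = fisher_opt(ss1$M, ss2$M),
    F_nonopt = fisher_nonopt(ss1$M, ss2$M, n_readouts = n_readouts),
    r = tryCatch(pattern_correlation(ss1$M, ss2$M),
                 error = function(e) NA_real_))
  attr(out, "M1") <- ss1$M; attr(out, "M2") <- ss2$M
  out
}

#' Disjoint odor-aligned index groups of a scene
#'
#' Merges the MC index sets of the scene's odors into groups (by default
#' similar pairs are merged: odors 1,2 and 3,4 in four-odor scenes) and
#' removes any index claimed by more than one group, so the groups are
#' disjoint as required by [connectivity_selectivity()].
#'
#' @param scene a scene from [build_scene()].
#' @param groups list of odor index vectors to merge; default pairs odors
#'   for four-odor scenes, one group per odor otherwise.
#' @return list of disjoint integer index sets.
#' @export
odor_groups <- function(scene, groups = NULL) {
  n <- length(scene$mc_sets)
  if (is.null(groups))
    groups <- if (n == 4) list(1:2, 3:4) else as.list(seq_len(n))
  sets <- lapply(groups, function(g) sort(unique(unlist(scene$mc_sets[g]))))
  all_idx <- unlist(sets)
  dup <- unique(all_idx[duplicated(all_idx)])
  lapply(sets, function(s) setdiff(s, dup))
}

#' Selectivity of a developed network with its shuffled-GC null
#'
#' Computes [connectivity_selectivity()] of `W_MM` and `W_MC` over the
#' scene's odor groups together with null distributions: for `W_MM` the
#' null rewires every GC's MC partners uniformly at random
#' (degree-preserving), for `W_MC` it shuffles which CC wiring belongs to
#' which GC (destroying the MC-side/CC-side pairing). Uses the R RNG stream.
#'
#' @param net a developed `bulb_network`.
#' @param params a [bulb_params()] object.
#' @param mc_groups disjoint MC index groups (see [odor_groups()]).
#' @param n_shuffle null draws.
#' @return list with `mm`, `mc` (observed scores) and `mm_null`, `mc_null`
#'   (null score vectors), plus one-sided permutation p-values.
#' @export
selectivity_with_null <- function(net, params, mc_groups, n_shuffle = 100) {
  eff <- effective_connectivity(net)
  # identity feedforward map: a group's odor-CC columns are its MC indices
  mm <- connectivity_selectivity(eff$W_MM, mc_groups, mc_groups,
                                 exclude_diag = TRUE)
  mc <- connectivity_selectivity(eff$W_MC[, seq_len(params$N_CC_odor)],
                                 mc_groups, mc_groups)
  N_G <- n_gcs(net)
  mm_null <- vapply(seq_len(n_shuffle), function(s) {
    W <- matrix(0L, params$N_MC, N_G)
    for (k in seq_len(N_G)) W[sample.int(params$N_MC, params$N_conn_MG), k] <- 1L
    connectivity_selectivity(tcrossprod(W), mc_groups, mc_groups,
                             exclude_diag = TRUE)
  }, 0)
  mc_null <- vapply(seq_len(n_shuffle), function(s) {
    perm <- sample.int(N_G)
    W_MC <- net$W_MG %*% net$W_GC[perm, , drop = FALSE]
    connectivity_selectivity(W_MC[, seq_len(params$N_CC_odor)],
                             mc_groups, mc_groups)
  }, 0)
  list(mm = mm, mc = mc, mm_null = mm_null, mc_null = mc_null,
       mm_p = (1 + sum(mm_null >= mm)) / (1 + n_shuffle),
       mc_p = (1 + sum(mc_null >= mc)) / (1 + n_shuffle))
}

#' Memory-extinction protocol
#'
#' Develops a network on two odor pairs, freezes the inhibition strength,
#' then erases the cortical memory of pair 1 (the associative weights among
#' its responsive CCs) and continues the neurogenic evolution. Tracks the GC
#' count, the pre-removal odor responses of the GCs removed in each step,
#' and the Fisher discriminant of both pairs before and after extinction.
#' A control branch repeats the post-extinction phase with the structural
#' turnover blocked (no removal — and no addition, since unchecked addition
#' without removal would grow the GC count without bound).
#'
#' @param cfg an [experiment_config()] (scene should be
#'   `"extinction_4odors"`).
#' @param n_pre steps with `g` frozen before extinction (baseline window).
#' @param n_post steps after extinction.
#' @return list with `record` (full evolution record of the unblocked
#'   branch; column `phase` marks pre/post), `N_G_pre`, `N_G_post`,
#'   `removed_resp_extinguished`, `removed_resp_spared` (post-extinction
#'   window means), `F_before`, `F_after`, `F_after_blocked` (data frames
#'   with `pair1`, `pair2`), and the final networks.
#' @export
run_extinction_protocol <- function(cfg, n_pre = 10, n_post = 25) {
  dev <- run_development(cfg)
  params <- dev$params; scene <- dev$scene
  probes <- scene$probes

  pair_F <- function(net) data.frame(
    pair1 = fisher_opt(solve_steady_state(probes$odor1, net, params)$M,
                       solve_steady_state(probes$odor2, net, params)$M),
    pair2 = fisher_opt(solve_steady_state(probes$odor3, net, params)$M,
                       solve_steady_state(probes$odor4, net, params)$M))

  cc_set <- sort(unique(c(
    responsive_cc_set(dev$net, scene$env$training_pairs[[1]], params),
    responsive_cc_set(dev$net, scene$env$training_pairs[[2]], params))))

  F_before <- pair_F(dev$net)

  # unblocked branch: freeze g, run a baseline window, extinguish, continue
  set.seed(cfg$seed + 1L)
  iv <- list(list(step = n_pre + 1L,
                  fn = function(net, params) extinguish_memory(net, cc_set)))
  ev <- evolve(dev$net, scene$env, params, n_pre + n_post,
               flags = list(freeze_g = TRUE), interventions = iv)
  rec <- ev$record
  rec$phase <- ifelse(rec$step <= n_pre, "pre", "post")
  post <- rec[rec$phase == "post", ]

  # blocked branch: same extinction, but structural turnover blocked
  set.seed(cfg$seed + 2L)
  net_b <- extinguish_memory(dev$net, cc_set)
  ev_b <- evolve(net_b, scene$env, params, n_post,
                 flags = list(freeze_g = TRUE, block_removal = TRUE,
                              block_addition = TRUE))

  list(
    record = rec,
    cc_set = cc_set,
    N_G_pre = mean(rec$N_G[rec$phase == "pre"]),
    N_G_post = mean(post$N_G[seq(max(1, nrow(post) - 9), nrow(post))]),
    removed_resp_extinguished = mean(post$removed_resp_1, na.rm = TRUE),
    removed_resp_spared = mean(post$removed_resp_3, na.rm = TRUE),
    F_before = F_before,
    F_after = pair_F(ev$net),
    F_after_blocked = pair_F(ev_b$net),
    net_after = ev$net, net_after_blocked = ev_b$net, dev = dev)
}

#' Context-recall experiment
#'
#' Develops a network on two odors, each associated with its own context,
#' then probes each odor alone (no context) and each context alone (no
#' odor). Returns the 2 x 2 matrices of Pearson correlations between the
#' context-evoked and odor-evoked patterns, separately for the GC and the MC
#' populations. The learned association lets a context alone reinstate the
#' GC pattern of its odor (positive matching correlation) while the
#' context-driven inhibition carves a "negative" image of the odor into the
#' MC pattern (negative matching correlation).
#'
#' @param cfg an [experiment_config()] (scene should be `"context_recall"`).
#' @return list with `gc_corr` and `mc_corr` (rows: contexts, columns:
#'   odors), and the probe steady states.
#' @export
run_context_recall <- function(cfg) {
  dev <- run_development(cfg)
  params <- dev$params
  pr <- dev$scene$probes
  ss <- lapply(pr, solve_steady_state, net = dev$net, params = params)
  gc_corr <- mc_corr <- matrix(NA_real_, 2, 2,
                               dimnames = list(paste0("context", 1:2),
                                               paste0("odor", 1:2)))
  for (ci in 1:2) for (oi in 1:2) {
    gc_corr[ci, oi] <- pattern_correlation(
      ss[[paste0("context", ci)]]$G, ss[[paste0("odor", oi)]]$G)
    mc_corr[ci, oi] <- pattern_correlation(
      ss[[paste0("context", ci)]]$M, ss[[paste0("odor", oi)]]$M,
      rectified = FALSE)
  }
  list(gc_corr = gc_corr, mc_corr = mc_corr, steady_states = ss, dev = dev)
}

#' Cortical task-switching experiment
#'
#' Develops a network on two pairs of similar odors, measures the optimal
#' Fisher discriminant of the 0.55/0.45 cross-pair mixtures, then briefly
#' retrains the cortical weights on the 0.5/0.5 mixture (the bulbar wiring
#' is untouched) and measures again. The retrained cortex inhibits both
#' mixture components jointly, preserving their difference and improving
#' mixture discrimination.
#'
#' @param cfg an [experiment_config()] (scene should be `"mixtures"`).
#' @param retrain_epochs epochs of the brief mixture retraining.
#' @return list with `F_mix_before`, `F_mix_after`, `F_pair_after`
#'   (within-pair odor1-vs-odor2 discriminant after retraining),
#'   `F_pair_naive` (same probe on a naive, untrained network), and the
#'   networks.
#' @export
run_task_switch <- function(cfg, retrain_epochs = 5) {
  dev <- run_development(cfg)
  params <- dev$params; scene <- dev$scene
  pr <- scene$probes

  mix_F <- function(net) fisher_opt(
    solve_steady_state(pr$mix1, net, params)$M,
    solve_steady_state(pr$mix2, net, params)$M)

  F_before <- mix_F(dev$net)

  retrain_env <- environment_of(list(stimulus(pr$retrain, params = params)))
  net2 <- train_cortex(retrain_env, dev$net, params,
                       n_epochs = retrain_epochs)
  F_after <- mix_F(net2)

  naive <- new_network(params)
  F_pair <- function(net) fisher_opt(
    solve_steady_state(scene$odors[[1]], net, params)$M,
    solve_steady_state(scene$odors[[2]], net, params)$M)

  list(F_mix_before = F_before, F_mix_after = F_after,
       F_pair_after = F_pair(net2), F_pair_naive = F_pair(naive),
       net_before = dev$net, net_after = net2, dev = dev)
}

#' Sweep of the top-down weight
#'
#' Repeats the full development of the distractor scene for each value of
#' the top-down weight `w_GC` (and each seed), then scores the selectivity
#' of the effective connectivities and the random-read-out discriminability
#' of the two targets under each probe condition. Each (value, seed) pair is
#' an independent development run.
#'
#' @param cfg an [experiment_config()] (scene should be `"distractor"`).
#' @param w_GC_values numeric vector of top-down weights.
#' @param seeds integer vector of seeds (replicates per value).
#' @param n_readouts random read-outs for [fisher_nonopt()].
#' @return data frame with one row per (w_GC, seed): `sel_mm`, `sel_mc`,
#'   and `F_nonopt` under `correct`, `incorrect`, `none`, `blocked`.
#' @export
run_wgc_sweep <- function(cfg, w_GC_values, seeds = cfg$seed,
                          n_readouts = 2000) {
  rows <- list()
  for (w in w_GC_values) for (sd in seeds) {
    cfg_w <- cfg
    cfg_w$seed <- as.integer(sd)
    cfg_w$params$w_GC <- w
    dev <- run_development(cfg_w)
    params <- dev$params; scene <- dev$scene; pr <- scene$probes
    groups <- odor_groups(scene)
    sel <- selectivity_with_null(dev$net, params, groups, n_shuffle = 0)
    fn <- function(context_id = NULL, blocked = FALSE)
      run_probe(dev$net, params, pr$probe_a, pr$probe_b,
                context_id = context_id, blocked = blocked,
                n_readouts = n_readouts)$F_nonopt
    rows[[length(rows) + 1L]] <- data.frame(
      w_GC = w, seed = sd, sel_mm = sel$mm, sel_mc = sel$mc,
      F_correct = fn(scene$correct_context),
      F_incorrect = fn(scene$incorrect_context),
      F_none = fn(NULL), F_blocked = fn(blocked = TRUE))
  }
  do.call(rbind, rows)
}
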