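#' Add newborn granule cells
#'
#' Appends `N_new_G` new GCs to the network. Each new GC makes `N_conn_MG`
#' reciprocal synapses with MCs drawn uniformly without replacement, and
#' receives `N_conn_GC` top-down synapses from CCs drawn likewise. Existing
#' wiring is untouched. Uses the R RNG stream.
#'
#' @param net a `bulb_network`.
#' @param params a [bulb_params()] object.
#' @param n number of GCs to add; default `params$N_new_G`.
#' @return the network with the new GCs appended (their activities start
#'   at 0 until the next steady-state solve).
#' @export
add_gcs <- function(net, params, n = params$N_new_G) {
  if (n == 0) return(net)
  N_MC <- params$N_MC; N_CC <- params$N_CC
  new_MG <- matrix(0L, N_MC, n)
  new_GC <- matrix(0L, n, N_CC)
  for (k in seq_len(n)) {
    new_MG[sample.int(N_MC, params$N_conn_MG), k] <- 1L
    new_GC[k, sample.int(N_CC, params$N_conn_GC)] <- 1L
  }
  net$W_MG <- cbind(net$W_MG, new_MG)
  net$W_GC <- rbind(net$W_GC, new_GC)
  net$G <- c(net$G, rep(0, n))
  net
}

#' Resilience of each granule cell
#'
#' A GC's resilience is its summed suprathreshold activity over the training
#' stimuli: `R_i = sum_beta [G_i(beta) - G_th]+`. Only stimuli that drive a
#' GC above threshold contribute.
#'
#' @param G_responses numeric matrix, N_G x N_s, of steady-state GC rates,
#'   one column per training stimulus.
#' @param G_th GC activity threshold.
#' @return numeric resilience vector of length N_G.
#' @export
compute_resilience <- function(G_responses, G_th) {
  G_responses <- as.matrix(G_responses)
  rowSums(rectify(G_responses - G_th))
}

#' Per-step survival probability of each granule cell
#'
#' Sigmoid of the resilience, `P_i = (tanh(gamma_R (R_i - R_0)) + 1) / 2`;
#' a GC at the midpoint resilience `R_0` survives a step with probability
#' one half.
#'
#' @param R nonnegative resilience vector.
#' @param params a [bulb_params()] object (uses `gamma_R`, `R_0`).
#' @return probability vector in `(0, 1)`.
#' @export
survival_probability <- function(R, params) {
  (tanh(params$gamma_R * (R - params$R_0)) + 1) / 2
}

#' Stochastic removal of granule cells
#'
#' Each GC independently survives the step with its probability `P_i`
#' (Bernoulli draws from the R RNG stream); removed GCs have their columns
#' and rows deleted from the wiring. With `apoptosis_blocked = TRUE` no
#' removal occurs.
#'
#' @param net a `bulb_network`.
#' @param P survival probability vector of length `n_gcs(net)`.
#' @param apoptosis_blocked logical; block all removal.
#' @return list with the pruned `net` and `removed` (integer indices of the
#'   removed GCs, relative to the pre-removal ordering).
#' @export
remove_gcs <- function(net, P, apoptosis_blocked = FALSE) {
  N_G <- n_gcs(net)
  if (length(P) != N_G) stop("P must have one entry per GC")
  if (apoptosis_blocked || N_G == 0)
    return(list(net = net, removed = integer(0)))
  dies <- stats::runif(N_G) >= P
  removed <- which(dies)
  if (length(removed)) {
    keep <- which(!dies)
    net$W_MG <- net$W_MG[, keep, drop = FALSE]
    net$W_GC <- net$W_GC[keep, , drop = FALSE]
    net$G <- net$G[keep]
  }
  list(net = net, removed = removed)
}

#' Homeostatic adaptation of the inhibition strength
#'
#' Multiplicative controller keeping the GC count near its target:
#' `g` grows by the factor `1 + g_gain` when `N_G` exceeds
#' `N_GC_aim * (1 + g_band)` (stronger inhibition lowers GC activity, hence
#' survival, hence the count), shrinks by `1 - g_gain` below the band, and
#' is left unchanged inside it or when frozen.
#'
#' @param g current inhibition strength (> 0).
#' @param N_G current GC count.
#' @param params a [bulb_params()] object.
#' @param freeze logical; disable adaptation (e.g. during an extinction
#'   protocol where the temporal evolution itself is of interest).
#' @return the updated `g`.
#' @export
adapt_inhibition <- function(g, N_G, params, freeze = FALSE) {
  if (g <= 0) stop("g must be positive")
  if (freeze) return(g)
  if (N_G > params$N_GC_aim * (1 + params$g_band)) g * (1 + params$g_gain)
  else if (N_G < params$N_GC_aim * (1 - params$g_band)) g * (1 - params$g_gain)
  else g
}

#' One neurogenic time step
#'
#' Executes, in order: GC addition; steady-state evaluation of every
#' training odor (recall conditions, odor presented alone) with the newborn
#' GCs participating; resilience and survival-probability computation;
#' stochastic removal; homeostatic update of `g`. The odors are presented
#' without their contexts during these solves: the context-odor association
#' lives in the cortical weights, and the odor's cortical assembly —
#' ignited by the feedforward drive and completed by the recurrent
#' connections — supplies the top-down component of the GC drive. (A GC
#' population sustained by contextual drive alone would decouple survival
#' from the inhibition strength and defeat the homeostatic controller.)
#' The step record includes the mean suprathreshold odor response
#' (`[G - G_th]+`) of the GCs removed this step, for each training odor —
#' measured before their removal.
#'
#' @param net a `bulb_network` with trained (frozen) `W_CC`.
#' @param env a `bulb_environment`.
#' @param params a [bulb_params()] object.
#' @param flags list of switches: `block_addition`, `block_removal`,
#'   `freeze_g` (all default FALSE).
#' @return list with the updated `net` and a one-row data frame `record`
#'   (GC count after removal, `g`, mean survival probability, counts of
#'   added/removed GCs, mean resilience of the newborn cohort and of the
#'   survivors, and `removed_resp_<beta>` columns).
#' @export
neurogenesis_step <- function(net, env, params, flags = list()) {
  fl <- modify_flags(flags)
  n_before <- n_gcs(net)
  if (!fl$block_addition) net <- add_gcs(net, params)
  N_G <- n_gcs(net)
  new_idx <- if (fl$block_addition) integer(0) else
    seq.int(n_before + 1L, length.out = N_G - n_before)

  G_resp <- matrix(0, N_G, env$N_s)
  for (b in seq_len(env$N_s)) {
    odor_alone <- stimulus(env$training_pairs[[b]]$S, params = params)
    ss <- solve_steady_state(odor_alone, net, params,
                             alpha = params$alpha_recall)
    if (N_G > 0) G_resp[, b] <- ss$G
    net$M <- ss$M; net$C <- ss$C; if (N_G > 0) net$G <- ss$G
  }

  R <- compute_resilience(G_resp, params$G_th)
  P <- survival_probability(R, params)
  rem <- remove_gcs(net, P, apoptosis_blocked = fl$block_removal)
  net <- rem$net
  removed <- rem$removed

  resp_thr <- rectify(G_resp - params$G_th)
  removed_resp <- if (length(removed))
    colMeans(resp_thr[removed, , drop = FALSE]) else rep(NA_real_, env$N_s)

  net$g <- adapt_inhibition(net$g, n_gcs(net), params, freeze = fl$freeze_g)

  record <- data.frame(
    N_G = n_gcs(net), g = net$g,
    mean_P = if (N_G > 0) mean(P) else NA_real_,
    n_added = length(new_idx), n_removed = length(removed),
    mean_R_new = if (length(new_idx)) mean(R[new_idx]) else NA_real_,
    mean_R_surv = if (n_gcs(net) > 0) mean(R[setdiff(seq_len(N_G), removed)])
                  else NA_real_
  )
  for (b in seq_len(env$N_s))
    record[[paste0("removed_resp_", b)]] <- removed_resp[b]
  list(net = net, record = record)
}

modify_flags <- function(flags) {
  fl <- list(block_addition = FALSE, block_removal = FALSE, freeze_g = FALSE)
  if (length(flags)) {
    unknown <- setdiff(names(flags), names(fl))
    if (length(unknown)) stop("unknown flag(s): ", paste(unknown, collapse = ", "))
    fl[names(flags)] <- flags
  }
  fl
}

#' Evolve the bulbar network by repeated neurogenic steps
#'
#' Applies [neurogenesis_step()] `n_steps` times, optionally applying
#' scheduled interventions (memory extinction, freezing `g`, blocking
#' apoptosis or addition) at given steps, which is how extinction protocols
#' are scripted. Two runs with the same RNG seed and inputs are identical.
#'
#' @param net a `bulb_network` with trained `W_CC`.
#' @param env a `bulb_environment`.
#' @param params a [bulb_params()] object.
#' @param n_steps number of neurogenic steps (>= 1).
#' @param flags initial flag list, see [neurogenesis_step()].
#' @param interventions list of entries `list(step =, fn = NULL, flags =
#'   NULL)`; at the start of step `step`, `fn(net, params)` (if given) is
#'   applied to the network and `flags` (if given) are merged into the
#'   active flags.
#' @return list with the final `net` and `record`, a data frame with one row
#'   per step (step index plus the columns of [neurogenesis_step()]).
#' @export
evolve <- function(net, env, params, n_steps, flags = list(),
                   interventions = list()) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  fl <- modify_flags(flags)
  rows <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    for (iv in interventions) {
      if (iv$step == step) {
        if (!is.null(iv$fn)) net <- iv$fn(net, params)
        if (!is.null(iv$flags)) fl[names(iv$flags)] <- iv$flags
      }
    }
    out <- neurogenesis_step(net, env, params, flags = fl)
    net <- out$net
    rows[[step]] <- cbind(data.frame(step = step), out$record)
  }
  list(net = net, record = do.call(rbind, rows))
}

#' First step at which the GC count has settled into the target band
#'
#' Burn-in is defined as the first step after which the trailing-window mean
#' of `N_G` stays inside the controller's target band for `n_consecutive`
#' consecutive steps.
#'
#' @param record an evolution record from [evolve()].
#' @param params a [bulb_params()] object.
#' @param window trailing window length for the running mean.
#' @param n_consecutive required number of consecutive in-band steps.
#' @return the burn-in step index, or `NA` if never settled.
#' @export
burn_in_step <- function(record, params, window = 10, n_consecutive = 20) {
  ng <- record$N_G
  n <- length(ng)
  lo <- params$N_GC_aim * (1 - params$g_band)
  hi <- params$N_GC_aim * (1 + params$g_band)
  inband <- logical(n)
  for (i in seq_len(n)) {
    w <- ng[max(1, i - window + 1):i]
    m <- mean(w)
    inband[i] <- (m >= lo && m <= hi)
  }
  run <- 0
  for (i in seq_len(n)) {
    run <- if (inband[i]) run + 1 else 0
    if (run >= n_consecutive) return(i - n_consecutive + 1L)
  }
  NA_integer_
}
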