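# Small-network builders and independent oracles used across test files.

# random valid network with n_g GCs for a given parameter set
random_network <- function(params, n_g, g = 1) {
  net <- new_network(params)
  net$g <- g
  if (n_g > 0) {
    W_MG <- matrix(0L, params$N_MC, n_g)
    W_GC <- matrix(0L, n_g, params$N_CC)
    for (k in seq_len(n_g)) {
      W_MG[sample.int(params$N_MC, params$N_conn_MG), k] <- 1L
      if (params$N_CC > 0)
        W_GC[k, sample.int(params$N_CC, params$N_conn_GC)] <- 1L
    }
    net$W_MG <- W_MG; net$W_GC <- W_GC; net$G <- rep(0, n_g)
  }
  net
}

# tiny parameter set for <= 10-neuron networks
tiny_params <- function(n_mc = 3, n_cc_odor = 3, n_conn_mg = 2,
                        n_conn_gc = 1, ...) {
  bulb_params(N_MC = n_mc, N_CC_odor = n_cc_odor, N_CC_context = 0,
              n_contexts = 0, N_conn_MG = n_conn_mg, N_conn_GC = n_conn_gc,
              N_GC_aim = 10, ...)
}

# Independent oracle: brute-force forward integration of the full
# three-population ODE system with tau_G = 1 (no algebraic reduction),
# using deSolve's stiff integrator.
full_ode_steady_state <- function(stim, net, params, t_end = 1e4,
                                  alpha = params$alpha_recall,
                                  w_GC = params$w_GC) {
  n_mc <- params$N_MC; n_g <- n_gcs(net); n_cc <- params$N_CC
  ctx <- context_drive(stim$context_id, params,
                       if (is.null(stim$A_context)) 2 else stim$A_context)
  rhs <- function(t, y, parms) {
    M <- y[seq_len(n_mc)]
    G <- if (n_g > 0) y[n_mc + seq_len(n_g)] else numeric(0)
    C <- if (n_cc > 0) y[n_mc + n_g + seq_len(n_cc)] else numeric(0)
    sig <- if (n_cc > 0) cc_sigmoid(C, params) else numeric(0)
    dM <- (-M + stim$S + params$M_sp) / params$tau_M
    if (n_g > 0)
      dM <- dM - net$g * drop(net$W_MG %*% pmax(G - params$G_th, 0)) /
        params$tau_M
    dG <- if (n_g > 0) {
      -G + drop(crossprod(net$W_MG, pmax(M, 0))) +
        (if (n_cc > 0) w_GC * drop(net$W_GC %*% sig) else 0)
    } else numeric(0)
    dC <- if (n_cc > 0) {
      (-C + ctx + params$w_CM * drop(net$W_CM %*% pmax(M, 0)) +
         alpha * drop(net$W_CC %*% sig) -
         params$w_inh * (sum(sig) - sig)) / params$tau_C
    } else numeric(0)
    list(c(dM, dG, dC))
  }
  y0 <- c(rep(params$M_sp, n_mc), rep(0, n_g), rep(0, n_cc))
  out <- deSolve::ode(y = y0, times = c(0, t_end), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  y <- out[nrow(out), -1]
  list(M = unname(y[seq_len(n_mc)]),
       G = if (n_g > 0) unname(y[n_mc + seq_len(n_g)]) else numeric(0),
       C = if (n_cc > 0) unname(y[n_mc + n_g + seq_len(n_cc)]) else numeric(0))
}

# explicit triple-loop evaluation of the disynaptic connectivity counts
effective_connectivity_loops <- function(W_MG, W_GC) {
  n_mc <- nrow(W_MG); n_g <- ncol(W_MG); n_cc <- ncol(W_GC)
  W_MM <- matrix(0L, n_mc, n_mc)
  for (i in seq_len(n_mc)) for (j in seq_len(n_mc)) for (k in seq_len(n_g))
    W_MM[i, j] <- W_MM[i, j] + W_MG[i, k] * W_MG[j, k]
  W_MC <- matrix(0L, n_mc, n_cc)
  for (i in seq_len(n_mc)) for (j in seq_len(n_cc)) for (k in seq_len(n_g))
    W_MC[i, j] <- W_MC[i, j] + W_MG[i, k] * W_GC[k, j]
  list(W_MM = W_MM, W_MC = W_MC)
}
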