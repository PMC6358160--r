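#' One Hebbian update of the recurrent cortical weights
#'
#' Applies the covariance-style rule
#' `W_ij <- clip(W_ij + eta * ((sigma(C_i) - Omega) * sigma(C_j) - kappa),
#' 0, W_max_CC)` for `i != j`, where `C` is the converged CC steady state
#' for the current weights. `Omega` is the potentiation threshold and
#' `kappa` a slow uniform decay; hard bounds keep the weights in
#' `[0, W_max_CC]` and the diagonal stays 0.
#'
#' @param W_CC current N_CC x N_CC weight matrix.
#' @param C_steady converged CC activity vector for the current `W_CC`.
#' @param params a [bulb_params()] object.
#' @return the updated weight matrix.
#' @export
hebbian_update <- function(W_CC, C_steady, params) {
  clip_cc(W_CC + hebbian_increment(C_steady, params), params)
}

# raw (unclipped) Hebbian increment for a single steady state
hebbian_increment <- function(C_steady, params) {
  s <- cc_sigmoid(C_steady, params)
  params$eta * ((s - params$Omega) %o% s - params$kappa)
}

clip_cc <- function(W, params) {
  W[W < 0] <- 0
  W[W > params$W_max_CC] <- params$W_max_CC
  diag(W) <- 0
  W
}

#' Train the recurrent cortical network on an environment
#'
#' Hebbian learning of the odor (and odor-context) associations. In each
#' epoch every training pair is solved to steady state with the recurrent
#' excitation scaled down to `alpha_learn` (reducing interference between
#' memories), each odor presented jointly with its associated context, and
#' one Hebbian update is applied per epoch with the increment averaged over
#' the training pairs before clipping. The per-epoch consolidation is
#' essential for retaining more than one memory: the decay increment
#' `eta * kappa` is more than an order of magnitude larger than `W_max_CC`,
#' so updating to saturation after each stimulus separately would erase
#' every assembly except the last one presented. Averaging keeps each
#' odor's net drive positive for its own assembly while cross-odor and
#' silent pairs still decay to 0, and makes training independent of
#' presentation order. Training stops after `n_epochs` epochs or as soon as
#' the largest weight change in an epoch falls below `convergence_tol`.
#' During the subsequent neurogenic evolution the learned weights are held
#' fixed.
#'
#' @param env a `bulb_environment`.
#' @param net a `bulb_network`.
#' @param params a [bulb_params()] object.
#' @param n_epochs maximum number of passes over the environment.
#' @param convergence_tol early-stopping threshold on `max |dW|` per epoch;
#'   default `1e-4 * W_max_CC`.
#' @return the network with trained `W_CC`; attribute `"history"` holds a
#'   data frame (epoch, max |dW|).
#' @export
train_cortex <- function(env, net, params, n_epochs = 50,
                         convergence_tol = 1e-4 * params$W_max_CC) {
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  hist <- data.frame(epoch = integer(0), max_dW = numeric(0))
  for (ep in seq_len(n_epochs)) {
    dW <- 0
    for (stim in env$training_pairs) {
      ss <- solve_steady_state(stim, net, params, alpha = params$alpha_learn)
      dW <- dW + hebbian_increment(ss$C, params) / env$N_s
    }
    W_new <- clip_cc(net$W_CC + dW, params)
    max_dW <- max(abs(W_new - net$W_CC))
    net$W_CC <- W_new
    hist <- rbind(hist, data.frame(epoch = ep, max_dW = max_dW))
    if (max_dW < convergence_tol) break
  }
  attr(net, "history") <- hist
  net
}

#' CCs responsive to a stimulus
#'
#' Identifies the cortical cells whose steady-state output `sigma(C_i)`
#' exceeds a threshold when the stimulus is presented (recall conditions).
#' Used to delimit "the respective CCs" of an odor, e.g. as the target of
#' memory extinction.
#'
#' @param net a `bulb_network`.
#' @param stim a [stimulus()] or odor vector.
#' @param params a [bulb_params()] object.
#' @param threshold output threshold in `[0, C_max]`; default `0.5 * C_max`.
#' @return integer vector of CC indices.
#' @export
responsive_cc_set <- function(net, stim, params,
                              threshold = 0.5 * params$C_max) {
  if (threshold < 0) stop("threshold must be >= 0")
  ss <- solve_steady_state(stim, net, params)
  which(cc_sigmoid(ss$C, params) > threshold)
}

#' Extinguish a cortical odor memory
#'
#' Removes the associative connections among a set of CCs: the `W_CC` block
#' `cc_indices x cc_indices` is set to 0; all other weights are untouched.
#'
#' @param net a `bulb_network`.
#' @param cc_indices integer CC indices whose mutual connections are erased.
#' @return the modified network.
#' @export
extinguish_memory <- function(net, cc_indices) {
  if (length(cc_indices) == 0) {
    warning("empty CC index set; nothing extinguished")
    return(net)
  }
  if (any(cc_indices < 1 | cc_indices > ncol(net$W_CC)))
    stop("cc_indices out of range")
  net$W_CC[cc_indices, cc_indices] <- 0
  net
}
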