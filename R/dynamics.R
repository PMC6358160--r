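#' Construct a stimulus
#'
#' A stimulus is a nonnegative odor drive over the MCs, optionally paired
#' with a non-olfactory context that drives a dedicated block of contextual
#' CCs with constant amplitude `A_context`. Either component may be absent
#' (odorless context, context-free odor).
#'
#' @param S numeric vector of odor drive over MCs (nonnegative), or `NULL`
#'   for an odorless scene (zero drive).
#' @param context_id integer context label (1-based, `<= n_contexts`), or
#'   `NULL` for no context.
#' @param A_context contextual drive amplitude (default 2).
#' @param params a [bulb_params()] object (for sizes).
#' @return An object of class `bulb_stimulus`.
#' @export
stimulus <- function(S = NULL, context_id = NULL, A_context = 2,
                     params = bulb_params()) {
  if (is.null(S)) S <- rep(0, params$N_MC)
  if (length(S) != params$N_MC)
    stop("S must have length N_MC = ", params$N_MC)
  if (any(S < 0)) stop("odor drive must be nonnegative")
  if (!is.null(context_id)) {
    if (context_id < 1 || context_id > params$n_contexts)
      stop("context_id out of range")
  }
  structure(list(S = as.numeric(S), context_id = context_id,
                 A_context = A_context),
            class = "bulb_stimulus")
}

#' Contextual drive vector over the CCs
#'
#' Maps a context label to its additive external input: constant
#' `A_context` on that context's contiguous block of contextual CCs
#' (the `N_CC_context` contextual cells are split evenly over
#' `n_contexts` contexts), zero elsewhere.
#'
#' @param context_id integer context label or `NULL`.
#' @param params a [bulb_params()] object.
#' @param A_context drive amplitude.
#' @return numeric vector of length `N_CC`.
#' @export
context_drive <- function(context_id, params, A_context = 2) {
  drive <- rep(0, params$N_CC)
  if (is.null(context_id)) return(drive)
  drive[context_cc_indices(context_id, params)] <- A_context
  drive
}

#' CC indices belonging to a context
#' @inheritParams context_drive
#' @return integer vector of CC indices.
#' @export
context_cc_indices <- function(context_id, params) {
  block <- params$N_CC_context %/% params$n_contexts
  if (context_id < 1 || context_id > params$n_contexts)
    stop("context_id out of range")
  params$N_CC_odor + (context_id - 1L) * block + seq_len(block)
}

#' Algebraic GC activity
#'
#' With the GC time constant fixed to 0, GC rates follow their inputs
#' instantaneously: `G = W_MG' [M]+ + w_GC * W_GC sigma(C)`. This is an
#' exact evaluation, not an iteration.
#'
#' @param M MC rate vector.
#' @param C CC activity vector.
#' @param net a `bulb_network`.
#' @param params a [bulb_params()] object.
#' @param w_GC top-down weight; defaults to `params$w_GC`, set to 0 to model
#'   blockade of the top-down projections.
#' @return GC rate vector of length `n_gcs(net)`.
#' @export
gc_activity <- function(M, C, net, params, w_GC = params$w_GC) {
  if (length(M) != nrow(net$W_MG) || length(C) != ncol(net$W_GC))
    stop("dimension mismatch between activities and wiring")
  drop(crossprod(net$W_MG, rectify(M))) +
    w_GC * drop(net$W_GC %*% cc_sigmoid(C, params))
}

#' Solve the network to steady state
#'
#' Relaxes the coupled MC/CC rate equations (GC rates evaluated
#' algebraically) for a given stimulus until the fixed point is reached:
#' MCs receive odor drive, spontaneous activity and GC-mediated inhibition
#' of their suprathreshold GC partners; CCs receive feedforward MC input,
#' recurrent excitation scaled by `alpha`, global inhibition, and any
#' contextual drive. Integration always starts from the cold state
#' (`M = M_sp`, `C = 0`) so that the result is independent of presentation
#' order and runaway (bistable) cortical dynamics shows up as
#' non-convergence rather than hysteresis.
#'
#' @param stim a [stimulus()] (or a bare numeric odor vector).
#' @param net a `bulb_network`.
#' @param params a [bulb_params()] object.
#' @param alpha scale of the recurrent cortical excitation; use
#'   `params$alpha_learn` during Hebbian training and `params$alpha_recall`
#'   (the default) during recall and probing.
#' @param w_GC top-down weight; 0 reproduces top-down blockade at probe time.
#' @param must_converge error on non-convergence (default TRUE); otherwise
#'   the non-converged state is returned with `converged = FALSE`.
#' @return list with converged `M`, `G`, `C`, the final `residual`, a
#'   `converged` flag and the iteration count.
#' @export
solve_steady_state <- function(stim, net, params,
                               alpha = params$alpha_recall,
                               w_GC = params$w_GC,
                               must_converge = TRUE) {
  if (!inherits(stim, "bulb_stimulus")) stim <- stimulus(stim, params = params)
  ctx <- context_drive(stim$context_id, params, stim$A_context)
  out <- steady_state_cpp(
    stim$S, ctx, net$W_MG, net$W_GC, net$W_CM, net$W_CC,
    net$g, w_GC, params$w_CM, params$w_inh, alpha,
    params$M_sp, params$G_th, params$gamma_C, params$C_th, params$C_max,
    params$tau_M, params$tau_C, params$dt_max, params$steady_tol,
    params$t_max)
  out$M <- drop(out$M); out$G <- drop(out$G); out$C <- drop(out$C)
  if (length(out$G) == 0) out$G <- numeric(0)
  if (must_converge && !out$converged)
    stop("steady state not reached within t_max (residual ",
         signif(out$residual, 3),
         "); possible runaway cortical excitation / bistability")
  out
}

#' Tabulate a steady state as long-format rows
#'
#' Flattens a solved steady state into one row per cell — population
#' (`"MC"`, `"GC"`, `"CC"`), cell index, rate — ready for
#' [utils::write.csv()] or plotting.
#'
#' @param ss a result of [solve_steady_state()].
#' @return data frame with columns `population`, `index`, `rate`.
#' @export
steady_state_table <- function(ss) {
  data.frame(
    population = rep(c("MC", "GC", "CC"),
                     c(length(ss$M), length(ss$G), length(ss$C))),
    index = c(seq_along(ss$M), seq_along(ss$G), seq_along(ss$C)),
    rate = c(ss$M, ss$G, ss$C))
}
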