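#' Gaussian odor stimulus
#'
#' Builds an odor drive over the MCs as a sum of Gaussian activity profiles,
#' `S_i = sum_k A_k * exp(-(i - x_k)^2 / w_k^2)` for MC index `i = 1..N_MC`.
#' The MC index is treated as a continuous coordinate; centers need not be
#' integers.
#'
#' @param peaks a data frame (or list of lists) with columns/fields `A`
#'   (amplitude, >= 0), `x` (center, MC index units) and `w` (width, > 0).
#'   An empty peak set gives the zero stimulus.
#' @param N_MC number of MCs.
#' @return numeric vector of length `N_MC`.
#' @examples
#' S <- gaussian_stimulus(data.frame(A = 1.8, x = 30, w = 12), 110)
#' S[30]  # peak value A
#' @export
gaussian_stimulus <- function(peaks, N_MC) {
  if (N_MC < 1) stop("N_MC must be >= 1")
  S <- rep(0, N_MC)
  if (is.null(peaks) || NROW(peaks) == 0) return(S)
  peaks <- as.data.frame(peaks)
  i <- seq_len(N_MC)
  for (k in seq_len(nrow(peaks))) {
    A <- peaks$A[k]; x <- peaks$x[k]; w <- peaks$w[k]
    if (A < 0) stop("peak amplitude must be nonnegative")
    if (w <= 0) stop("peak width must be positive")
    S <- S + A * exp(-(i - x)^2 / w^2)
  }
  S
}

#' Linear odor mixture
#'
#' Elementwise combination `c_a * S_a + c_b * S_b` of two odor vectors,
#' used for mixture-discrimination probes such as 0.55/0.45 blends of two
#' learned components.
#'
#' @param S_a,S_b odor vectors of equal length.
#' @param c_a,c_b mixture coefficients.
#' @return numeric vector.
#' @export
odor_mixture <- function(S_a, S_b, c_a, c_b) {
  if (length(S_a) != length(S_b)) stop("odor vectors must have equal length")
  c_a * S_a + c_b * S_b
}

#' Training environment
#'
#' An ordered set of (stimulus, context) training pairs. During cortical
#' training and during the neurogenic evolution each odor is presented
#' jointly with its associated context (if any).
#'
#' @param stimuli list of [stimulus()] objects.
#' @return An object of class `bulb_environment`.
#' @export
environment_of <- function(stimuli) {
  if (length(stimuli) < 1) stop("an environment needs at least one stimulus")
  stopifnot(all(vapply(stimuli, inherits, TRUE, "bulb_stimulus")))
  structure(list(training_pairs = stimuli, N_s = length(stimuli)),
            class = "bulb_environment")
}

default_amp <- function(params) 2 - params$M_sp

#' Build a preset odor scene
#'
#' Returns the training environment and probe stimuli for each simulation
#' protocol. Training odors are single Gaussians with amplitude
#' `A = 2 - M_sp` and width `w = 12` (MC index units); contexts drive their
#' CC block with amplitude 2. Probe parameters follow the protocol:
#' occluded targets are weak and narrow (`A = 0.72, w = 2`), distractor
#' targets weak and broad (`A = 1.08, w = 12`). Peak centers are free scene
#' parameters: similar odors in a pair are offset by half a width, dissimilar
#' pairs by much more than a width; all are configurable via `...`.
#'
#' Presets:
#' \describe{
#'   \item{two_odors}{two dissimilar odors (centers 40, 70), no contexts.}
#'   \item{extinction_4odors}{two similar pairs (30/36 and 80/86), no
#'     contexts; probes are the four training odors.}
#'   \item{context_recall}{two dissimilar odors (30, 80) associated with
#'     contexts 1 and 2; probes are each odor alone and each context alone.}
#'   \item{occluder}{pairs 1,2 (context 1) and 3,4 (context 2); probe target
#'     `A = 0.72, w = 2` centered inside odor 1's footprint (occluder =
#'     training odor 1, correct context = 1). Probes: occluder alone,
#'     occluder + target, target alone, no odor.}
#'   \item{distractor}{same training as `occluder`; two similar weak targets
#'     (`A = 1.08, w = 12`, centers 20, 26) overlapping trained pair 1 but
#'     not the distractor (training odor 3; correct context = 2, incorrect
#'     context = 1). Probes: each target + distractor.}
#'   \item{mixtures}{two similar pairs near MC 30 and 80; probes are the
#'     mixtures `0.55 O1 + 0.45 O3` and `0.45 O1 + 0.55 O3`, and the
#'     retraining stimulus `0.5 O1 + 0.5 O3`.}
#' }
#'
#' @param name preset name (see above).
#' @param params a [bulb_params()] object.
#' @param ... overrides: `centers` (numeric vector of training-odor centers),
#'   `width`, `amplitude`, `A_context`, `target_center(s)`,
#'   `target_amplitude`, `target_width`, `contexts` (integer vector of
#'   context assignments per training odor, NA for none).
#' @return list with `env` (a `bulb_environment`), `probes` (named list of
#'   [stimulus()] objects or odor vectors), and scene metadata (`centers`,
#'   `contexts`, per-odor MC index sets).
#' @export
build_scene <- function(name, params = bulb_params(), ...) {
  ov <- list(...)
  get_ov <- function(key, default) if (!is.null(ov[[key]])) ov[[key]] else default
  A <- get_ov("amplitude", default_amp(params))
  w <- get_ov("width", 12)
  A_ctx <- get_ov("A_context", 2)
  N <- params$N_MC

  mk_odor <- function(center, amp = A, width = w)
    gaussian_stimulus(data.frame(A = amp, x = center, w = width), N)

  scene <- switch(
    name,
    two_odors = list(centers = get_ov("centers", c(40, 70)),
                     contexts = get_ov("contexts", c(NA, NA))),
    extinction_4odors = list(centers = get_ov("centers", c(30, 36, 80, 86)),
                             contexts = get_ov("contexts", rep(NA, 4))),
    context_recall = list(centers = get_ov("centers", c(30, 80)),
                          contexts = get_ov("contexts", c(1, 2))),
    occluder = ,
    distractor = list(centers = get_ov("centers", c(30, 36, 80, 86)),
                      contexts = get_ov("contexts", c(1, 1, 2, 2))),
    mixtures = list(centers = get_ov("centers", c(30, 36, 80, 86)),
                    contexts = get_ov("contexts", rep(NA, 4))),
    stop("unknown preset: ", name)
  )

  odors <- lapply(scene$centers, mk_odor)
  ctxs <- scene$contexts
  stims <- lapply(seq_along(odors), function(i)
    stimulus(odors[[i]],
             context_id = if (is.na(ctxs[i])) NULL else ctxs[i],
             A_context = A_ctx, params = params))
  env <- environment_of(stims)

  probes <- switch(
    name,
    two_odors = ,
    extinction_4odors = stats::setNames(odors,
                                        paste0("odor", seq_along(odors))),
    context_recall = list(
      odor1 = stimulus(odors[[1]], params = params),
      odor2 = stimulus(odors[[2]], params = params),
      context1 = stimulus(NULL, context_id = 1, A_context = A_ctx,
                          params = params),
      context2 = stimulus(NULL, context_id = 2, A_context = A_ctx,
                          params = params)),
    occluder = {
      tc <- get_ov("target_center", scene$centers[1] + w / 2)
      tgt <- mk_odor(tc, get_ov("target_amplitude", 0.72),
                     get_ov("target_width", 2))
      list(occluder = odors[[1]],
           occluder_target = odors[[1]] + tgt,
           target = tgt,
           none = rep(0, N))
    },
    distractor = {
      tcs <- get_ov("target_centers", c(20, 26))
      ta <- get_ov("target_amplitude", 1.08)
      tw <- get_ov("target_width", 12)
      tgt_a <- mk_odor(tcs[1], ta, tw)
      tgt_b <- mk_odor(tcs[2], ta, tw)
      dis <- odors[[3]]
      list(target_a = tgt_a, target_b = tgt_b, distractor = dis,
           probe_a = tgt_a + dis, probe_b = tgt_b + dis)
    },
    mixtures = list(
      mix1 = odor_mixture(odors[[1]], odors[[3]], 0.55, 0.45),
      mix2 = odor_mixture(odors[[1]], odors[[3]], 0.45, 0.55),
      retrain = odor_mixture(odors[[1]], odors[[3]], 0.5, 0.5))
  )

  mc_sets <- lapply(odors, function(S) which(S >= 0.25 * max(S)))
  list(name = name, env = env, probes = probes, odors = odors,
       centers = scene$centers, contexts = ctxs, mc_sets = mc_sets,
       correct_context = switch(name, occluder = 1, distractor = 2, NULL),
       incorrect_context = switch(name, occluder = 2, distractor = 1, NULL))
}
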