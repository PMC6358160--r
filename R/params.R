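#' Model parameters for the cortico-bulbar network
#'
#' Builds the full parameter set of the three-population rate model
#' (mitral/tufted cells MC, granule cells GC, cortical cells CC) together
#' with solver and homeostatic-controller settings. Defaults are the
#' reference parameter set of the model; any field can be overridden.
#'
#' Populations and coupling:
#' \describe{
#'   \item{tau_M, tau_C}{membrane time constants of MCs and CCs (a.u.; time
#'     is measured in units of `tau_M`). The GC time constant is fixed to 0,
#'     so GC rates follow their inputs algebraically.}
#'   \item{M_sp}{spontaneous MC activity added to the odor drive.}
#'   \item{G_th}{GC activity threshold: only the suprathreshold part
#'     `[G - G_th]+` inhibits MCs and counts towards resilience.}
#'   \item{w_GC}{weight of top-down CC->GC projections.}
#'   \item{w_CM}{weight of feedforward MC->CC projections. Not part of the
#'     printed reference set; fixed to 1 here (its scale is absorbed into
#'     the stimulus amplitude).}
#'   \item{w_inh}{all-to-all inhibition among CCs (via an unmodeled
#'     interneuron population).}
#'   \item{alpha_learn, alpha_recall}{scale factor on the recurrent cortical
#'     excitation during Hebbian learning vs. recall; learning uses the
#'     reduced value to limit interference with stored memories.}
#'   \item{gamma_C, C_th, C_max}{gain, threshold and saturation of the CC
#'     sigmoid `sigma(C) = C_max / (1 + exp(-gamma_C (C - C_th)))`.}
#' }
#'
#' Hebbian rule (recurrent CC weights): learning rate `eta`, potentiation
#' threshold `Omega`, weight decay `kappa`, hard bounds `[0, W_max_CC]`.
#'
#' Neurogenesis: each structural step adds `N_new_G = round(0.1 * N_GC_aim)`
#' GCs, each wired to `N_conn_MG` random MCs (reciprocal synapses) and
#' `N_conn_GC` random CCs. (The printed table labels the latter count
#' "Nconn(GP)"; it is the per-GC count of top-down synapses from CCs.)
#' Survival of a GC follows a sigmoid of its resilience with gain `gamma_R`
#' and midpoint `R_0`. The inhibition strength `g` is adapted multiplicatively
#' (`g_gain` per step) to keep the GC count within `g_band` of `N_GC_aim`.
#'
#' Network size: `N_MC` mitral cells; the CC population has one odor cell per
#' MC (`N_CC_odor = N_MC`, identity feedforward map by default) plus
#' `N_CC_context` contextual cells split evenly over `n_contexts` contexts.
#'
#' Solver: explicit Euler on M and C with a stability-aware step bounded by
#' `dt_max * min(tau_M, tau_C)`, run until the maximum absolute rate of
#' change falls below `steady_tol` or time exceeds `t_max`.
#'
#' @param ... named overrides of any parameter listed above.
#' @return An object of class `bulb_params` (a named list).
#' @examples
#' p <- bulb_params()
#' p$w_GC
#' p_small <- bulb_params(N_MC = 20, N_GC_aim = 50)
#' @export
bulb_params <- function(...) {
  p <- list(
    # rate-model constants (reference set)
    tau_M = 1, tau_C = 1,
    M_sp = 0.2, G_th = 3,
    w_GC = 3, w_CM = 1, w_inh = 0.05,
    alpha_learn = 0.05, alpha_recall = 1,
    gamma_C = 3, C_th = 0.2, C_max = 1,
    # Hebbian rule
    eta = 10, Omega = 0.2, kappa = 0.1, W_max_CC = 0.06,
    # neurogenesis
    N_conn_MG = 16, N_conn_GC = 2,
    N_CC_context = 48, n_contexts = 2,
    gamma_R = 5, R_0 = 3,
    N_GC_aim = 500, N_new_G = NULL,
    # network size
    N_MC = 110, N_CC_odor = NULL,
    # homeostatic controller for g
    g_init = 1, g_gain = 0.01, g_band = 0.05,
    # solver
    dt_max = 0.05, steady_tol = 1e-6, t_max = 1000
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), c(names(p), "N_new_G", "N_CC_odor"))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (is.null(p$N_CC_odor)) p$N_CC_odor <- p$N_MC
  if (is.null(p$N_new_G)) p$N_new_G <- round(0.1 * p$N_GC_aim)
  p$N_CC <- p$N_CC_odor + p$N_CC_context
  validate_params(p)
  class(p) <- "bulb_params"
  p
}

validate_params <- function(p) {
  counts <- c("N_MC", "N_CC_odor", "N_CC_context", "N_conn_MG", "N_conn_GC",
              "N_GC_aim", "n_contexts")
  for (nm in counts) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop(nm, " must be a nonnegative integer")
  }
  if (p$N_MC < 1) stop("N_MC must be >= 1")
  if (p$N_conn_MG > p$N_MC)
    stop("N_conn_MG exceeds the number of MCs")
  if (p$N_conn_GC > p$N_CC_odor + p$N_CC_context)
    stop("N_conn_GC exceeds the number of CCs")
  for (nm in c("tau_M", "tau_C", "gamma_C", "C_max", "gamma_R", "dt_max",
               "steady_tol", "t_max", "g_init"))
    if (p[[nm]] <= 0) stop(nm, " must be positive")
  if (p$W_max_CC < 0) stop("W_max_CC must be nonnegative")
  invisible(p)
}

#' Read model parameters from a flat key/value file
#'
#' Loads a YAML or JSON file whose keys are [bulb_params()] field names;
#' keys that are absent keep their defaults. The file format is chosen by
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path path to the parameter file.
#' @return A `bulb_params` object.
#' @export
params_from_file <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is needed to read YAML parameter files")
      yaml::read_yaml(path)
    },
    json = {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("the jsonlite package is needed to read JSON parameter files")
      jsonlite::read_json(path, simplifyVector = TRUE)
    },
    stop("unsupported parameter file extension: ", ext))
  if (!is.list(vals) || is.null(names(vals)))
    stop("parameter file must be a flat key/value mapping")
  do.call(bulb_params, vals)
}

#' @export
print.bulb_params <- function(x, ...) {
  cat("<bulb_params>\n")
  cat(sprintf("  network: %d MCs, %d odor + %d contextual CCs, GC target %d\n",
              x$N_MC, x$N_CC_odor, x$N_CC_context, x$N_GC_aim))
  cat(sprintf("  coupling: w_GC = %g, w_CM = %g, w_inh = %g, G_th = %g\n",
              x$w_GC, x$w_CM, x$w_inh, x$G_th))
  cat(sprintf("  neurogenesis: +%d GCs/step, %d MC + %d CC synapses each\n",
              x$N_new_G, x$N_conn_MG, x$N_conn_GC))
  invisible(x)
}
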