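#' Rectifying nonlinearity
#'
#' Threshold-linear transfer function used for MCs and GCs:
#' `[x]+ = max(x, 0)` elementwise.
#'
#' @param x numeric vector or matrix.
#' @return `x` with negative entries replaced by 0.
#' @examples rectify(c(-1, 0, 2))
#' @export
rectify <- function(x) {
  x[x < 0] <- 0
  x
}

#' Sigmoidal CC nonlinearity
#'
#' Saturating transfer function of the cortical cells,
#' `sigma(C) = C_max / (1 + exp(-gamma_C * (C - C_th)))`. The saturation is
#' what gives the recurrent cortical network its associative, pattern-
#' completing character.
#'
#' @param C numeric vector of CC membrane activities.
#' @param params a [bulb_params()] object (uses `gamma_C`, `C_th`, `C_max`).
#' @return numeric vector in `(0, C_max)`.
#' @examples
#' p <- bulb_params()
#' cc_sigmoid(p$C_th, p)  # midpoint: C_max / 2
#' @export
cc_sigmoid <- function(C, params) {
  params$C_max / (1 + exp(-params$gamma_C * (C - params$C_th)))
}

#' Initialize an empty cortico-bulbar network
#'
#' Creates a network with no granule cells, identity (or user-supplied)
#' feedforward MC->CC map on the odor block, zero recurrent cortical weights,
#' and inhibition strength `g = g_init`. GCs are added by [add_gcs()] or
#' during [evolve()].
#'
#' The state holds: activity vectors `M`, `G`, `C`; binary wiring `W_MG`
#' (N_MC x N_G reciprocal MC-GC synapses; the GC->MC direction is its
#' transpose by construction), `W_GC` (N_G x N_CC top-down synapses), `W_CM`
#' (N_CC x N_MC feedforward map); plastic real-valued `W_CC` (N_CC x N_CC,
#' zero diagonal); and the scalar `g`.
#'
#' @param params a [bulb_params()] object.
#' @param W_CM optional binary N_CC x N_MC feedforward matrix; default is the
#'   identity on the odor-CC block (one CC per MC) and zero rows for
#'   contextual CCs.
#' @return An object of class `bulb_network`.
#' @export
new_network <- function(params, W_CM = NULL) {
  N_MC <- params$N_MC
  N_CC <- params$N_CC
  if (is.null(W_CM)) {
    W_CM <- matrix(0L, N_CC, N_MC)
    for (i in seq_len(min(params$N_CC_odor, N_MC))) W_CM[i, i] <- 1L
  } else {
    W_CM <- check_binary(W_CM, N_CC, N_MC, "W_CM")
  }
  net <- list(
    M = rep(params$M_sp, N_MC),
    G = numeric(0),
    C = rep(0, N_CC),
    W_MG = matrix(0L, N_MC, 0),
    W_GC = matrix(0L, 0, N_CC),
    W_CM = W_CM,
    W_CC = matrix(0, N_CC, N_CC),
    g = params$g_init
  )
  class(net) <- "bulb_network"
  net
}

check_binary <- function(W, nr, nc, name) {
  W <- as.matrix(W)
  if (nrow(W) != nr || ncol(W) != nc)
    stop(name, " must be ", nr, " x ", nc)
  if (!all(W %in% c(0, 1))) stop(name, " must be binary")
  storage.mode(W) <- "integer"
  W
}

#' Number of granule cells in a network
#' @param net a `bulb_network`.
#' @return integer GC count.
#' @export
n_gcs <- function(net) ncol(net$W_MG)

#' Check the structural invariants of a network state
#'
#' Verifies binarity of the wiring matrices, the per-GC synapse counts
#' (`N_conn_MG` MC partners, `N_conn_GC` CC partners), the bounds and zero
#' diagonal of the plastic cortical matrix, dimension consistency, and
#' `g > 0`. Reciprocity of the MC-GC synapses is structural (only `W_MG` is
#' stored; the GC->MC direction is always its transpose) and so cannot be
#' violated.
#'
#' @param net a `bulb_network`.
#' @param params a [bulb_params()] object.
#' @return character vector of violations; empty if the state is valid.
#' @export
validate_network <- function(net, params) {
  v <- character(0)
  N_G <- ncol(net$W_MG)
  if (nrow(net$W_MG) != params$N_MC)
    v <- c(v, sprintf("W_MG has %d rows, expected N_MC = %d",
                      nrow(net$W_MG), params$N_MC))
  if (nrow(net$W_GC) != N_G)
    v <- c(v, sprintf("W_GC has %d rows but W_MG has %d GC columns",
                      nrow(net$W_GC), N_G))
  if (ncol(net$W_GC) != params$N_CC)
    v <- c(v, sprintf("W_GC has %d columns, expected N_CC = %d",
                      ncol(net$W_GC), params$N_CC))
  if (!all(net$W_MG %in% c(0, 1))) v <- c(v, "W_MG has non-binary entries")
  if (!all(net$W_GC %in% c(0, 1))) v <- c(v, "W_GC has non-binary entries")
  if (!all(net$W_CM %in% c(0, 1))) v <- c(v, "W_CM has non-binary entries")
  if (N_G > 0) {
    mg_deg <- colSums(net$W_MG)
    bad <- which(mg_deg != params$N_conn_MG)
    for (i in bad)
      v <- c(v, sprintf("GC %d has %d MC synapses, expected %d",
                        i, mg_deg[i], params$N_conn_MG))
    gc_deg <- rowSums(net$W_GC)
    bad <- which(gc_deg != params$N_conn_GC)
    for (i in bad)
      v <- c(v, sprintf("GC %d has %d CC synapses, expected %d",
                        i, gc_deg[i], params$N_conn_GC))
  }
  if (any(net$W_CC < 0) || any(net$W_CC > params$W_max_CC)) {
    idx <- which(net$W_CC < 0 | net$W_CC > params$W_max_CC, arr.ind = TRUE)
    v <- c(v, sprintf("W_CC[%d,%d] = %g outside [0, W_max_CC]",
                      idx[, 1], idx[, 2], net$W_CC[idx]))
  }
  dg <- which(diag(net$W_CC) != 0)
  for (i in dg) v <- c(v, sprintf("W_CC diagonal nonzero at CC %d", i))
  if (!is.numeric(net$g) || length(net$g) != 1 || net$g <= 0)
    v <- c(v, "g must be a positive scalar")
  if (length(net$M) != params$N_MC) v <- c(v, "M has wrong length")
  if (length(net$C) != params$N_CC) v <- c(v, "C has wrong length")
  v
}

#' @export
print.bulb_network <- function(x, ...) {
  cat("<bulb_network>\n")
  cat(sprintf("  %d MCs, %d GCs, %d CCs; g = %.4g\n",
              nrow(x$W_MG), ncol(x$W_MG), ncol(x$W_GC), x$g))
  cat(sprintf("  cortical weights: %d nonzero of %d\n",
              sum(x$W_CC > 0), length(x$W_CC) - nrow(x$W_CC)))
  invisible(x)
}

#' Write a network snapshot to disk as plain text
#'
#' Serializes the five connectivity matrices, the three activity vectors and
#' `g` into a directory of CSV files (binary matrices as integer CSV).
#'
#' @param net a `bulb_network`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  wr(net$W_MG, "W_MG.csv"); wr(net$W_GC, "W_GC.csv")
  wr(net$W_CM, "W_CM.csv"); wr(net$W_CC, "W_CC.csv")
  wr(net$M, "M.csv"); wr(net$G, "G.csv"); wr(net$C, "C.csv")
  wr(net$g, "g.csv")
  invisible(dir)
}

#' Read a network snapshot written by [write_network()]
#' @param dir directory containing the snapshot.
#' @return a `bulb_network`.
#' @export
read_network <- function(dir) {
  rd <- function(f, int = FALSE) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = ","))
    dimnames(m) <- NULL
    if (int) storage.mode(m) <- "integer"
    m
  }
  net <- list(
    M = drop(rd("M.csv")), G = drop(rd("G.csv")), C = drop(rd("C.csv")),
    W_MG = rd("W_MG.csv", int = TRUE), W_GC = rd("W_GC.csv", int = TRUE),
    W_CM = rd("W_CM.csv", int = TRUE), W_CC = rd("W_CC.csv"),
    g = drop(rd("g.csv"))
  )
  if (length(net$G) == 1 && is.na(net$G)) net$G <- numeric(0)
  class(net) <- "bulb_network"
  net
}
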