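#' Effective disynaptic connectivity
#'
#' GC-mediated inhibition counts: `W_MM = W_MG W_MG'` gives, for each MC
#' pair, the number of GCs providing mutual disynaptic inhibition (its
#' diagonal is each MC's GC degree and is typically large); `W_MC = W_MG
#' W_GC` counts the GCs mediating disynaptic inhibition of each MC by each
#' CC. With `diag_zeroed = TRUE` the `W_MM` diagonal is set to 0 — a display
#' convention only, to reveal the off-diagonal structure; computations use
#' the full matrix.
#'
#' @param net a `bulb_network`.
#' @param diag_zeroed logical display convention for `W_MM`.
#' @return list with integer matrices `W_MM` (N_MC x N_MC, symmetric) and
#'   `W_MC` (N_MC x N_CC), and the `diag_zeroed` flag.
#' @export
effective_connectivity <- function(net, diag_zeroed = FALSE) {
  W <- net$W_MG
  W_MM <- tcrossprod(W)
  W_MC <- W %*% net$W_GC
  if (diag_zeroed) diag(W_MM) <- 0L
  list(W_MM = W_MM, W_MC = W_MC, diag_zeroed = diag_zeroed)
}

#' Optimal Fisher discriminant of two MC activity patterns
#'
#' Discriminability of two activity patterns under the best linear read-out,
#' with rate-proportional variance as the noise proxy (Poisson-like spiking):
#' `F_opt = sum_i ([M1_i]+ - [M2_i]+)^2 / ([M1_i]+ + [M2_i]+)`. MCs at which
#' both rectified rates are 0 carry no information and are skipped (the 0/0
#' limit of the summand).
#'
#' @param M1,M2 MC rate vectors of equal length.
#' @return scalar `F_opt >= 0`.
#' @export
fisher_opt <- function(M1, M2) {
  if (length(M1) != length(M2)) stop("patterns must have equal length")
  a <- rectify(M1); b <- rectify(M2)
  den <- a + b
  keep <- den > 0
  sum((a[keep] - b[keep])^2 / den[keep])
}

#' Non-optimal Fisher discriminant under random read-outs
#'
#' Mean of `n_readouts` Fisher discriminants, each using a random linear
#' read-out of the MCs with weights drawn uniformly from `[-1, 1]`
#' (negative weights allow for read-out cells receiving disynaptic
#' inhibition):
#' `F_random = (sum_i w_i d_i)^2 / sum_i w_i^2 (a_i + b_i)` with
#' `d = [M1]+ - [M2]+`. Models discriminability early in task learning,
#' before read-out weights can be optimized. Draws come from the R RNG
#' stream.
#'
#' @param M1,M2 MC rate vectors of equal length.
#' @param n_readouts number of random read-outs (default 5000).
#' @return scalar mean discriminant.
#' @export
fisher_nonopt <- function(M1, M2, n_readouts = 5000) {
  if (length(M1) != length(M2)) stop("patterns must have equal length")
  if (n_readouts < 1) stop("n_readouts must be >= 1")
  a <- rectify(M1); b <- rectify(M2)
  den <- a + b
  keep <- den > 0
  if (!any(keep)) return(0)
  d <- (a - b)[keep]
  v <- den[keep]
  W <- matrix(stats::runif(n_readouts * length(d), -1, 1),
              nrow = n_readouts)
  num <- (W %*% d)^2
  dd <- (W^2) %*% v
  mean(num / dd)
}

#' Pearson correlation of two activity patterns
#'
#' Correlation of two population activity patterns, by default of the
#' rectified rates (what downstream neurons see). For MC patterns evoked by
#' a context alone the entire population can sit below threshold; the
#' suppression pattern — the "negative image" of the associated odor — then
#' lives in the raw activity variable, so such comparisons should use
#' `rectified = FALSE`. Zero-variance input is an error, since the
#' correlation is undefined.
#'
#' @param a,b activity vectors of equal length.
#' @param rectified correlate `[x]+` (default) or the raw activities.
#' @return Pearson correlation coefficient.
#' @export
pattern_correlation <- function(a, b, rectified = TRUE) {
  if (rectified) { a <- rectify(a); b <- rectify(b) }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pattern_correlation: zero-variance pattern")
  stats::cor(a, b)
}

#' Odor selectivity of an effective connectivity matrix
#'
#' Contrast score quantifying how much of a connectivity matrix's mass sits
#' inside odor-aligned blocks: for each odor, the mean entry between that
#' odor's row set and its own column set ("within") is compared with the
#' mean entry between its row set and the other odors' column sets
#' ("between"); the score is the mean over odors of
#' `(within - between) / (within + between)`. It is 1 for a block-diagonal
#' matrix aligned with the sets, 0 for a structureless (constant) matrix,
#' and negative when between-odor mass dominates. Index sets must be
#' disjoint per odor (merge similar odors into one group before calling).
#' For `W_MM`, pass the same sets for rows and columns and exclude the
#' diagonal via `exclude_diag = TRUE`.
#'
#' @param W connectivity matrix (e.g. `W_MC` or `W_MM`).
#' @param row_sets list of disjoint row index sets, one per odor (MC sets).
#' @param col_sets list of disjoint column index sets, one per odor (CC sets
#'   for `W_MC`, MC sets for `W_MM`).
#' @param exclude_diag drop diagonal entries (for `W_MM`).
#' @return scalar in `[-1, 1]`; 0 if the matrix has no mass at all.
#' @export
connectivity_selectivity <- function(W, row_sets, col_sets,
                                     exclude_diag = FALSE) {
  n_odor <- length(row_sets)
  if (length(col_sets) != n_odor)
    stop("row_sets and col_sets must have the same length")
  if (n_odor < 2) stop("need at least two odor groups")
  check_disjoint <- function(sets, what) {
    idx <- unlist(sets)
    if (any(duplicated(idx))) stop(what, " sets must be disjoint")
    if (any(lengths(sets) == 0)) stop(what, " sets must be nonempty")
  }
  check_disjoint(row_sets, "row"); check_disjoint(col_sets, "column")
  W <- as.matrix(W) * 1.0
  if (exclude_diag) diag(W) <- NA
  scores <- numeric(n_odor)
  for (o in seq_len(n_odor)) {
    within <- mean(W[row_sets[[o]], col_sets[[o]]], na.rm = TRUE)
    others <- unlist(col_sets[-o])
    between <- mean(W[row_sets[[o]], others], na.rm = TRUE)
    scores[o] <- if (within + between == 0) 0 else
      (within - between) / (within + between)
  }
  mean(scores)
}

#' Receptive-field matching of granule cells
#'
#' The structural signature of the learned cortico-bulbar wiring: after
#' development, each surviving GC's MC partners and CC partners should
#' respond to the same odors. For each GC the MC-side response profile
#' (summed rectified MC partner rates per probe odor) is correlated with
#' the CC-side profile (summed CC partner outputs `sigma(C)` per probe
#' odor); the statistic is the mean Pearson correlation over GCs. The null
#' is obtained by shuffling which CC wiring belongs to which GC, which
#' destroys the MC-side/CC-side pairing while preserving both marginal
#' wiring distributions.
#'
#' @param net a developed `bulb_network`.
#' @param probe_stims list of [stimulus()] objects (or odor vectors) used as
#'   the probe battery; needs at least 3 for a meaningful correlation.
#' @param params a [bulb_params()] object.
#' @param n_shuffle number of GC-shuffled null draws (R RNG stream).
#' @return list with `observed` (mean per-GC correlation), `null` (vector of
#'   shuffled means), and `p_value` (one-sided permutation p-value).
#' @export
receptive_field_matching <- function(net, probe_stims, params,
                                     n_shuffle = 200) {
  if (length(probe_stims) < 3)
    stop("need at least 3 probe odors for a correlation profile")
  N_G <- n_gcs(net)
  if (N_G < 2) stop("network has too few GCs")
  n_p <- length(probe_stims)
  Mp <- matrix(0, params$N_MC, n_p)
  Sg <- matrix(0, params$N_CC, n_p)
  for (j in seq_len(n_p)) {
    ss <- solve_steady_state(probe_stims[[j]], net, params)
    Mp[, j] <- rectify(ss$M)
    Sg[, j] <- cc_sigmoid(ss$C, params)
  }
  mc_side <- crossprod(net$W_MG, Mp)       # N_G x n_p
  cc_side_of <- function(W_GC) W_GC %*% Sg # N_G x n_p
  mean_corr <- function(A, B) {
    ok <- apply(A, 1, stats::sd) > 0 & apply(B, 1, stats::sd) > 0
    if (!any(ok)) return(0)
    mean(vapply(which(ok), function(i) stats::cor(A[i, ], B[i, ]), 0))
  }
  obs <- mean_corr(mc_side, cc_side_of(net$W_GC))
  null <- vapply(seq_len(n_shuffle), function(s) {
    perm <- sample.int(N_G)
    mean_corr(mc_side, cc_side_of(net$W_GC[perm, , drop = FALSE]))
  }, 0)
  list(observed = obs, null = null,
       p_value = (1 + sum(null >= obs)) / (1 + n_shuffle))
}

#' Tiling probe battery for receptive-field profiles
#'
#' Convenience set of single-Gaussian probe odors with training-stimulus
#' amplitude and width, centered at evenly spaced MC positions.
#'
#' @param params a [bulb_params()] object.
#' @param n number of probes.
#' @param width Gaussian width.
#' @return list of odor vectors.
#' @export
probe_battery <- function(params, n = 8, width = 12) {
  centers <- seq(width / 2, params$N_MC - width / 2, length.out = n)
  lapply(centers, function(x)
    gaussian_stimulus(data.frame(A = default_amp(params), x = x, w = width),
                      params$N_MC))
}
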