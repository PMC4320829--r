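#' Spike time tiling coefficient
#'
#' Bounded correlation measure for a pair of spike trains.  With coincidence
#' window `dt`, `T_A` is the fraction of the recording covered by the union
#' of windows `[t - dt, t + dt]` around the spikes of `a` (clipped to the
#' recording interval), and `P_A` is the fraction of `a`'s spikes lying
#' within `dt` of some spike of `b` (closed comparison, `|ta - tb| <= dt`).
#' The coefficient is
#' `0.5 * ((P_A - T_B) / (1 - P_A * T_B) + (P_B - T_A) / (1 - P_B * T_A))`.
#'
#' Either train empty gives `NA` (undefined, not zero).  A degenerate
#' denominator (`P * T == 1`, only possible when both equal 1) contributes a
#' 0 term.
#'
#' @param a,b [spike_train] objects sharing the same recording interval.
#' @param dt Coincidence window, seconds; default 0.005 (5 ms).  50 ms and
#'   0.5 ms are common sensitivity settings.
#' @return Scalar in `[-1, 1]`, or `NA` if a train is empty.
#' @examples
#' a <- spike_train(c(1, 2, 3), t_stop = 10)
#' b <- spike_train(c(1.004, 2.004, 3.004), t_stop = 10)
#' sttc(a, b)   # 1: every spike tiled both ways
#' @export
sttc <- function(a, b, dt = 0.005) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"), dt > 0)
  if (a$t_start != b$t_start || a$t_stop != b$t_stop)
    stop("trains must share the recording interval")
  if (!length(a$times) || !length(b$times)) return(NA_real_)
  TA <- tile_fraction(a$times, dt, a$t_start, a$t_stop)
  TB <- tile_fraction(b$times, dt, a$t_start, a$t_stop)
  PA <- tiled_proportion(a$times, b$times, dt)
  PB <- tiled_proportion(b$times, a$times, dt)
  0.5 * (sttc_term(PA, TB) + sttc_term(PB, TA))
}

sttc_term <- function(P, T) {
  d <- 1 - P * T
  if (d == 0) 0 else (P - T) / d
}

# Fraction of [t_start, t_stop] covered by the union of +-dt windows.
# Times are sorted, so overlapping windows merge with a running maximum.
tile_fraction <- function(times, dt, t_start, t_stop) {
  lo <- pmax(times - dt, t_start)
  hi <- pmin(times + dt, t_stop)
  m <- cummax(hi)
  prev <- c(-Inf, m[-length(m)])
  sum(pmax(0, hi - pmax(lo, prev))) / (t_stop - t_start)
}

# Fraction of `x` spikes within dt (closed) of some spike of `ref`.
tiled_proportion <- function(x, ref, dt) {
  idx <- findInterval(x, ref)
  left <- ifelse(idx >= 1, x - ref[pmax(idx, 1)], Inf)
  right <- ifelse(idx < length(ref), ref[pmin(idx + 1, length(ref))] - x, Inf)
  mean(pmin(left, right) <= dt)
}

#' All pairwise tiling coefficients of a recording
#'
#' Computes the STTC for every unordered electrode pair (`N(N-1)/2` pairs,
#' autocorrelations excluded) together with the Euclidean distance between
#' the electrodes.
#'
#' @param rec An [mea_recording] with at least 2 electrodes.
#' @param dt Coincidence window, s.
#' @return Data frame: `electrode_i`, `electrode_j` (labels), `distance`
#'   (um), `sttc` (`NA` where a member train is empty).
#' @export
pairwise_correlations <- function(rec, dt = 0.005) {
  stopifnot(inherits(rec, "mea_recording"), n_electrodes(rec) >= 2)
  n <- n_electrodes(rec)
  ij <- utils::combn(n, 2)
  d <- sqrt((rec$positions[ij[1, ], 1] - rec$positions[ij[2, ], 1])^2 +
            (rec$positions[ij[1, ], 2] - rec$positions[ij[2, ], 2])^2)
  val <- vapply(seq_len(ncol(ij)), function(k)
    sttc(rec$trains[[ij[1, k]]], rec$trains[[ij[2, k]]], dt), numeric(1))
  data.frame(electrode_i = rec$labels[ij[1, ]],
             electrode_j = rec$labels[ij[2, ]],
             distance = d, sttc = val, stringsAsFactors = FALSE)
}

#' Mean pairwise correlation of a recording
#'
#' Arithmetic mean of the defined tiling coefficients; pairs involving an
#' empty train are excluded rather than scored zero (scoring them zero
#' would bias sparse young recordings downwards).
#'
#' @param pairs Data frame from [pairwise_correlations()].
#' @return Scalar mean, or `NA` when no pair is defined.
#' @export
mean_correlation <- function(pairs) {
  v <- pairs$sttc[!is.na(pairs$sttc)]
  if (!length(v)) return(NA_real_)
  mean(v)
}
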