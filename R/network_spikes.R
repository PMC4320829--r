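#' Binned active-electrode counts
#'
#' Divides the recording into bins of `bin_width` seconds and counts, per
#' bin, how many electrodes fired at least one spike (several spikes from
#' the same electrode in one bin count once).  A trailing partial bin is
#' dropped so all bins have equal width.
#'
#' @param rec An [mea_recording].
#' @param bin_width Bin width in seconds; default 0.003 (3 ms).
#' @return An `activity_counts` list: `counts` (integer per bin),
#'   `bin_width`, `t_start`, `n_electrodes`.
#' @export
count_active <- function(rec, bin_width = 0.003) {
  stopifnot(inherits(rec, "mea_recording"), bin_width > 0)
  t0 <- rec$trains[[1]]$t_start
  nb <- floor(duration(rec) / bin_width)
  counts <- integer(nb)
  if (nb > 0) {
    for (st in rec$trains) {
      if (!length(st$times)) next
      b <- floor((st$times - t0) / bin_width) + 1
      b <- unique(b[b >= 1 & b <= nb])
      counts[b] <- counts[b] + 1L
    }
  }
  structure(list(counts = counts, bin_width = bin_width, t_start = t0,
                 n_electrodes = n_electrodes(rec)),
            class = "activity_counts")
}

#' Detect network spikes from binned activity
#'
#' A network spike is a maximal run of consecutive bins whose
#' active-electrode count strictly exceeds `threshold` ("more than n
#' electrodes simultaneously active"); runs separated by at least one
#' sub-threshold bin are distinct events.
#'
#' @param ac An `activity_counts` object from [count_active()].
#' @param threshold Electrode-count threshold; default 10.
#' @return A data frame of class `network_spike_set` with columns `onset`,
#'   `offset` (s, bin-edge aligned), `duration` (s), `peak` (maximum count);
#'   attribute `threshold`.
#' @examples
#' rec <- generate_recording(train_params(), network_params(n_electrodes = 12,
#'   duration = 60, shared_fraction = 1, participation_p = 1, seed = 1))
#' ns <- detect_network_spikes(count_active(rec), threshold = 10)
#' @export
detect_network_spikes <- function(ac, threshold = 10) {
  stopifnot(inherits(ac, "activity_counts"), threshold >= 1)
  above <- ac$counts > threshold
  r <- rle(above)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(
    onset = ac$t_start + (s[keep] - 1) * ac$bin_width,
    offset = ac$t_start + e[keep] * ac$bin_width,
    duration = r$lengths[keep] * ac$bin_width,
    peak = vapply(keep, function(k) max(ac$counts[s[k]:e[k]]), integer(1)))
  class(out) <- c("network_spike_set", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Array-level network-spike summary
#'
#' @param ns A `network_spike_set`.
#' @param duration Recording duration in seconds.
#' @return Named list: `ns_rate` (events per minute), `ns_peak` (median
#'   event peak), `ns_duration` (median event duration, s).  Peak and
#'   duration are `NA` (undefined) when there are no events; the rate is 0.
#' @export
network_spike_summary <- function(ns, duration) {
  stopifnot(duration > 0)
  n <- nrow(ns)
  list(ns_rate = n / (duration / 60),
       ns_peak = if (n) stats::median(ns$peak) else NA_real_,
       ns_duration = if (n) stats::median(ns$duration) else NA_real_)
}
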