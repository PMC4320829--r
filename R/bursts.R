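#' Max-interval burst detection parameters
#'
#' The five thresholds of the max-interval method.  Defaults are the
#' standard values for cultured-network recordings: a burst opens at an
#' interspike interval (ISI) below 0.1 s, extends while ISIs stay below
#' 0.25 s, candidate bursts closer than 0.8 s are merged, and bursts shorter
#' than 0.05 s or with fewer than 6 spikes are discarded.
#'
#' @param max_begin_isi Maximum beginning ISI, s.
#' @param max_end_isi Maximum end ISI, s (must be `>= max_begin_isi`).
#' @param min_ibi Minimum interburst interval, s (merge threshold).
#' @param min_duration Minimum burst duration, s.
#' @param min_spikes Minimum number of spikes in a burst.
#' @param ibi_definition How the interburst interval entering `cv_ibi` is
#'   measured: `"gap"` (end of burst k to start of burst k+1, the scale the
#'   merge threshold works on — default) or `"onset"` (onset-to-onset).
#' @param merge_before_filter Apply the merge phase before the
#'   duration/spike-count filter (default `TRUE`, the classical phase
#'   order); `FALSE` filters first, for sensitivity analysis.
#' @return A `burst_params` list.
#' @export
burst_params <- function(max_begin_isi = 0.1, max_end_isi = 0.25,
                         min_ibi = 0.8, min_duration = 0.05, min_spikes = 6,
                         ibi_definition = c("gap", "onset"),
                         merge_before_filter = TRUE) {
  ibi_definition <- match.arg(ibi_definition)
  if (any(c(max_begin_isi, max_end_isi, min_ibi, min_duration,
            min_spikes) <= 0))
    stop("all burst parameters must be positive")
  if (max_begin_isi > max_end_isi)
    stop("max_begin_isi must not exceed max_end_isi")
  structure(list(max_begin_isi = max_begin_isi, max_end_isi = max_end_isi,
                 min_ibi = min_ibi, min_duration = min_duration,
                 min_spikes = as.integer(min_spikes),
                 ibi_definition = ibi_definition,
                 merge_before_filter = isTRUE(merge_before_filter)),
            class = "burst_params")
}

#' Detect bursts with the max-interval method
#'
#' Three phases.  Phase 1: scan the ISI sequence; a candidate burst opens at
#' the first ISI below `max_begin_isi` and extends over all following ISIs
#' below `max_end_isi` (the burst ends at the last spike before an ISI of at
#' least `max_end_isi`).  Phase 2: consecutive candidates whose gap
#' (next start minus previous end) is below `min_ibi` are merged.  Phase 3:
#' candidates shorter than `min_duration` or with fewer than `min_spikes`
#' spikes are dropped.
#'
#' @param train A [spike_train].
#' @param p A [burst_params] object.
#' @return A data frame of class `burst_set` with one row per burst:
#'   `start_index`, `end_index` (1-based indices into `train$times`),
#'   `start_time`, `end_time` (s), `n_spikes`.  Zero rows when no burst
#'   survives.
#' @examples
#' st <- spike_train(seq(0, 0.25, by = 0.05), t_stop = 10)
#' detect_bursts(st, burst_params())
#' @export
detect_bursts <- function(train, p = burst_params()) {
  stopifnot(inherits(train, "spike_train"), inherits(p, "burst_params"))
  t <- train$times
  empty <- data.frame(start_index = integer(), end_index = integer(),
                      start_time = numeric(), end_time = numeric(),
                      n_spikes = integer())
  class(empty) <- c("burst_set", "data.frame")
  if (length(t) < 2) return(empty)

  gaps <- diff(t)
  # Phase 1, vectorised: within each maximal run of ISIs < max_end_isi a
  # candidate opens at the run's first ISI < max_begin_isi (an ISI >=
  # max_end_isi terminates any burst, so one run holds at most one burst).
  ok_end <- gaps < p$max_end_isi
  r <- rle(ok_end)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  starts <- integer(); ends <- integer()
  for (k in which(r$values)) {
    span <- run_start[k]:run_end[k]
    open <- span[gaps[span] < p$max_begin_isi]
    if (length(open)) {
      starts <- c(starts, open[1])          # spike opening the ISI
      ends <- c(ends, run_end[k] + 1L)      # last spike of the run
    }
  }
  if (!length(starts)) return(empty)

  merge_phase <- function(s, e) {
    if (length(s) > 1) {
      gap <- t[s[-1]] - t[e[-length(e)]]
      grp <- cumsum(c(1, gap >= p$min_ibi))
      s <- tapply(s, grp, min)
      e <- tapply(e, grp, max)
    }
    list(s = as.integer(s), e = as.integer(e))
  }
  filter_phase <- function(s, e) {
    keep <- (e - s + 1L) >= p$min_spikes & (t[e] - t[s]) >= p$min_duration
    list(s = s[keep], e = e[keep])
  }
  if (p$merge_before_filter) {
    m <- merge_phase(starts, ends); f <- filter_phase(m$s, m$e)
  } else {
    f <- filter_phase(starts, ends); f <- merge_phase(f$s, f$e)
  }
  if (!length(f$s)) return(empty)
  out <- data.frame(start_index = f$s, end_index = f$e,
                    start_time = t[f$s], end_time = t[f$e],
                    n_spikes = f$e - f$s + 1L)
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Per-electrode burst statistics
#'
#' Summarises a burst set into the five electrode-level burst features:
#' mean within-burst firing rate (Hz), burst rate (per minute), mean burst
#' duration (s), fraction of the electrode's spikes inside bursts, and the
#' coefficient of variation of interburst intervals.  Quantities that need
#' at least one burst (or two interburst intervals for `cv_ibi`) are `NA`
#' when unavailable; `NA` here means "undefined", never zero.
#'
#' @param train The [spike_train] the bursts were detected on.
#' @param bs A `burst_set` from [detect_bursts()].
#' @param ibi_definition See [burst_params()]; `"gap"` by default.
#' @return Named list: `n_bursts`, `within_burst_rate`, `burst_rate`,
#'   `mean_duration`, `fraction_in_bursts`, `cv_ibi`.
#' @export
burst_statistics <- function(train, bs, ibi_definition = c("gap", "onset")) {
  ibi_definition <- match.arg(ibi_definition)
  dur_min <- (train$t_stop - train$t_start) / 60
  nb <- nrow(bs)
  if (nb == 0)
    return(list(n_bursts = 0L, within_burst_rate = NA_real_,
                burst_rate = 0, mean_duration = NA_real_,
                fraction_in_bursts = if (n_spikes(train)) 0 else NA_real_,
                cv_ibi = NA_real_))
  bdur <- bs$end_time - bs$start_time
  ibis <- if (nb >= 2) {
    if (ibi_definition == "gap") bs$start_time[-1] - bs$end_time[-nb]
    else diff(bs$start_time)
  } else numeric()
  list(
    n_bursts = nb,
    within_burst_rate = mean(bs$n_spikes / bdur),
    burst_rate = nb / dur_min,
    mean_duration = mean(bdur),
    fraction_in_bursts = sum(bs$n_spikes) / n_spikes(train),
    cv_ibi = if (length(ibis) >= 2) stats::sd(ibis) / mean(ibis)
             else NA_real_)
}
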