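#' Analysis configuration
#'
#' Bundles every threshold of the feature pipeline with its conventional
#' default: the max-interval burst thresholds, the 3 ms network-spike bin
#' and 10-electrode threshold, the 5 ms STTC window, the 0.1-0.25 s theta
#' band, and the minimum ISI count for a theta density.
#'
#' @param bursts A [burst_params] object.
#' @param ns_bin Network-spike bin width, s.
#' @param ns_threshold Network-spike electrode threshold.
#' @param sttc_dt STTC coincidence window, s.
#' @param theta_band Theta acceptance band, s.
#' @param theta_min_isi Minimum ISIs per electrode for theta detection.
#' @param min_spikes_per_electrode Electrodes with fewer spikes are dropped
#'   on load (0 = keep all; the default, since no exclusion rule is part of
#'   the feature definitions).
#' @return An `mea_config` list.
#' @export
mea_config <- function(bursts = burst_params(), ns_bin = 0.003,
                       ns_threshold = 10, sttc_dt = 0.005,
                       theta_band = c(0.1, 0.25), theta_min_isi = 10,
                       min_spikes_per_electrode = 0) {
  stopifnot(ns_bin > 0, ns_threshold >= 1, sttc_dt > 0,
            length(theta_band) == 2, theta_band[1] < theta_band[2])
  structure(list(bursts = bursts, ns_bin = ns_bin,
                 ns_threshold = ns_threshold, sttc_dt = sttc_dt,
                 theta_band = theta_band, theta_min_isi = theta_min_isi,
                 min_spikes_per_electrode = min_spikes_per_electrode),
            class = "mea_config")
}

#' Names of the 11 recording-level features
#' @return Character vector of length 11, in canonical order.
#' @export
feature_names <- function() {
  c("firing_rate", "within_burst_rate", "burst_rate", "burst_duration",
    "fraction_in_bursts", "cv_ibi", "ns_rate", "ns_peak", "ns_duration",
    "mean_correlation", "theta_fraction")
}

#' Summarise per-electrode values into an array value
#'
#' Median or mean over the defined (non-`NA`) electrode values; `NA` values
#' are "electrode undefined" markers (e.g. no bursts detected) and are
#' ignored, per the array-value rules of the burst features.
#'
#' @param values Numeric vector, `NA` = undefined.
#' @param rule `"median"` (default for all burst features and firing rate)
#'   or `"mean"`.
#' @return Scalar; `NA` when no value is defined.
#' @export
summarise_electrodes <- function(values, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  if (rule == "median") stats::median(v) else mean(v)
}

#' The 11-feature vector of one recording
#'
#' Computes the recording-level summary used throughout the package:
#' \enumerate{
#'   \item `firing_rate`: median over all electrodes (silent ones count as
#'     0 Hz) of spikes / duration.
#'   \item `within_burst_rate`, 3. `burst_rate`, 4. `burst_duration`,
#'     5. `fraction_in_bursts`, 6. `cv_ibi`: median over electrodes of the
#'     [burst_statistics()] values, ignoring electrodes where the statistic
#'     is undefined (no bursts, or fewer than two interburst intervals for
#'     the CV).
#'   \item `ns_rate`, 8. `ns_peak`, 9. `ns_duration`: network-spike summary
#'     at the configured bin width and threshold.
#'   \item `mean_correlation`: mean STTC over defined electrode pairs.
#'   \item `theta_fraction`: fraction of theta-bursting electrodes.
#' }
#' Undefined features are `NA`, never silently 0; one undefined feature
#' never fails the whole vector.
#'
#' @param rec An [mea_recording].
#' @param config An [mea_config].
#' @return A one-row data frame of class `feature_vector`: the 11 features
#'   plus `region`, `age_div`, `array_id`.
#' @examples
#' rec <- generate_recording(train_params(), network_params(n_electrodes = 10,
#'   duration = 120, seed = 1))
#' feature_vector(rec)
#' @export
feature_vector <- function(rec, config = mea_config()) {
  stopifnot(inherits(rec, "mea_recording"), inherits(config, "mea_config"))
  dur <- duration(rec)
  rates <- vapply(rec$trains, firing_rate, numeric(1))

  stats_el <- lapply(rec$trains, function(st) {
    burst_statistics(st, detect_bursts(st, config$bursts),
                     ibi_definition = config$bursts$ibi_definition)
  })
  pull <- function(f) vapply(stats_el, `[[`, numeric(1), f)
  bursting <- pull("n_bursts") > 0
  # electrodes with no bursts are undefined for features 2-6
  guard <- function(x) { x[!bursting] <- NA_real_; x }

  ns <- network_spike_summary(
    detect_network_spikes(count_active(rec, config$ns_bin),
                          config$ns_threshold), dur)
  mc <- if (n_electrodes(rec) >= 2)
    mean_correlation(pairwise_correlations(rec, config$sttc_dt))
  else NA_real_
  th <- suppressWarnings(
    theta_fraction(rec, band = config$theta_band,
                   min_isi = config$theta_min_isi))

  out <- data.frame(
    firing_rate = stats::median(rates),
    within_burst_rate = summarise_electrodes(guard(pull("within_burst_rate"))),
    burst_rate = summarise_electrodes(guard(pull("burst_rate"))),
    burst_duration = summarise_electrodes(guard(pull("mean_duration"))),
    fraction_in_bursts = summarise_electrodes(guard(pull("fraction_in_bursts"))),
    cv_ibi = summarise_electrodes(pull("cv_ibi")),
    ns_rate = ns$ns_rate, ns_peak = ns$ns_peak, ns_duration = ns$ns_duration,
    mean_correlation = mc, theta_fraction = th,
    region = rec$region, age_div = rec$age_div, array_id = rec$array_id,
    stringsAsFactors = FALSE)
  class(out) <- c("feature_vector", "data.frame")
  out
}

#' Feature table of many recordings
#'
#' @param recs List of [mea_recording] objects (or paths to HDF5 files,
#'   read with [read_mea_h5()]).
#' @param config An [mea_config].
#' @return Tidy data frame, one row per recording: 11 feature columns plus
#'   `region`, `age_div`, `array_id`.  This is the interchange format
#'   consumed by [comparison_table()], [pca_project()] and
#'   [evaluate_classifier()].
#' @export
features_table <- function(recs, config = mea_config()) {
  rows <- lapply(recs, function(r) {
    if (is.character(r)) r <- read_mea_h5(r)
    feature_vector(r, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
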