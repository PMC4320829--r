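#' Parameters of a synthetic bursty spike train
#'
#' Describes one electrode's activity as background Poisson firing plus a
#' renewal process of burst events.  Burst onsets follow gamma-distributed
#' interburst intervals with mean `60 / burst_rate` seconds and coefficient
#' of variation `ibi_cv`; each burst emits a Poisson-distributed number of
#' spikes (mean `spikes_per_burst`) with exponential within-burst intervals
#' at `within_burst_rate`, or theta-band intervals when `theta` is set.
#'
#' @param background_rate Tonic Poisson rate, Hz.
#' @param burst_rate Burst events per minute.
#' @param ibi_cv Coefficient of variation of interburst (onset-to-onset)
#'   intervals; 0 gives clockwork bursting.
#' @param spikes_per_burst Mean spikes per burst.
#' @param within_burst_rate Within-burst firing rate, Hz (ignored for theta
#'   bursts).
#' @param theta If `TRUE`, burst spikes come as doublets (fast within-pair
#'   intervals at `within_burst_rate`) recurring at theta intervals
#'   (lognormal, median 0.15 s, sdlog 0.1).  The tight theta component
#'   places the tallest log-ISI density mode inside the 0.1-0.25 s band
#'   while the fast doublet intervals keep the burst detectable by the
#'   max-interval method (a pure 0.15 s ISI process could never open a
#'   burst, since 0.15 s exceeds the 0.1 s opening threshold).
#' @param jitter_sd Jitter (s) applied to shared network-burst onsets; used
#'   by [generate_recording()].
#' @return A `train_params` list.
#' @export
train_params <- function(background_rate = 0.1, burst_rate = 6, ibi_cv = 0.5,
                         spikes_per_burst = 10, within_burst_rate = 60,
                         theta = FALSE, jitter_sd = 0.005) {
  p <- list(background_rate = background_rate, burst_rate = burst_rate,
            ibi_cv = ibi_cv, spikes_per_burst = spikes_per_burst,
            within_burst_rate = within_burst_rate, theta = isTRUE(theta),
            jitter_sd = jitter_sd)
  num <- unlist(p[c("background_rate", "burst_rate", "ibi_cv",
                    "spikes_per_burst", "within_burst_rate", "jitter_sd")])
  if (anyNA(num) || any(num < 0))
    stop("train_params: all rates and dispersions must be >= 0")
  structure(p, class = "train_params")
}

#' Parameters of array-wide synthetic structure
#'
#' @param n_electrodes Electrode count (>= 2 for a recording).
#' @param duration Recording length, seconds (default 900 = 15 minutes).
#' @param participation_p Probability that an electrode joins any given
#'   shared network burst.
#' @param shared_fraction Fraction of each electrode's bursts drawn from the
#'   common (master) burst-time process rather than its private one.
#' @param theta_fraction Fraction of electrodes generated with theta-band
#'   within-burst intervals (the remainder use `within_burst_rate`).
#' @param seed Master seed; per-electrode streams are derived from it by a
#'   fixed splitting rule so changing `n_electrodes` does not reshuffle
#'   earlier electrodes.
#' @return A `network_params` list.
#' @export
network_params <- function(n_electrodes = 59, duration = 900,
                           participation_p = 0.8, shared_fraction = 0.5,
                           theta_fraction = 0, seed = 1) {
  if (participation_p < 0 || participation_p > 1)
    stop("participation_p must be in [0, 1]")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  if (theta_fraction < 0 || theta_fraction > 1)
    stop("theta_fraction must be in [0, 1]")
  structure(list(n_electrodes = as.integer(n_electrodes),
                 duration = duration, participation_p = participation_p,
                 shared_fraction = shared_fraction,
                 theta_fraction = theta_fraction, seed = as.integer(seed)),
            class = "network_params")
}

# Renewal burst-onset schedule over [0, duration]: gamma intervals with
# mean mu and CV cv; cv = 0 degenerates to a regular schedule.  The first
# onset is uniform on [0, mu] so schedules are stationary-ish from t = 0.
renewal_onsets <- function(rate_per_min, cv, duration) {
  if (rate_per_min <= 0) return(numeric())
  mu <- 60 / rate_per_min
  n_max <- max(16, ceiling(duration / mu * 3 + 10 * sqrt(duration / mu)))
  gaps <- if (cv == 0) rep(mu, n_max)
  else stats::rgamma(n_max, shape = 1 / cv^2, scale = mu * cv^2)
  on <- stats::runif(1, 0, mu) + cumsum(c(0, gaps))
  while (on[length(on)] < duration) {  # pathological cv: extend
    extra <- if (cv == 0) rep(mu, n_max)
    else stats::rgamma(n_max, shape = 1 / cv^2, scale = mu * cv^2)
    on <- c(on, on[length(on)] + cumsum(extra))
  }
  on[on < duration]
}

# Spikes of one burst starting at `onset`.  Theta bursts alternate fast
# within-doublet intervals with theta-band inter-doublet gaps.
burst_spikes <- function(onset, p) {
  n <- stats::rpois(1, p$spikes_per_burst)
  if (n <= 0) return(numeric())
  if (n == 1) return(onset)
  gaps <- if (p$theta) {
    fast <- stats::rexp(n - 1, rate = p$within_burst_rate)
    slow <- stats::rlnorm(n - 1, meanlog = log(0.15), sdlog = 0.1)
    ifelse(seq_len(n - 1) %% 2 == 1, fast, slow)
  } else {
    stats::rexp(n - 1, rate = p$within_burst_rate)
  }
  onset + cumsum(c(0, gaps))
}

# Core generator used by both public entry points.  `master_onsets` is NULL
# for an isolated train; otherwise the shared schedule of the recording.
synth_train <- function(p, duration, master_onsets = NULL,
                        participation_p = 1, shared_fraction = 0) {
  own <- renewal_onsets(p$burst_rate, p$ibi_cv, duration)
  onsets <- own
  if (!is.null(master_onsets) && shared_fraction > 0) {
    keep_own <- stats::runif(length(own)) >= shared_fraction
    join <- stats::runif(length(master_onsets)) <
      participation_p * shared_fraction
    shared <- master_onsets[join] +
      stats::rnorm(sum(join), sd = p$jitter_sd)
    onsets <- sort(c(own[keep_own], shared[shared >= 0 & shared < duration]))
  }
  spk <- unlist(lapply(onsets, burst_spikes, p = p), use.names = FALSE)
  n_bg <- stats::rpois(1, p$background_rate * duration)
  spk <- c(spk, stats::runif(n_bg, 0, duration))
  spk <- sort(unique(spk[spk >= 0 & spk <= duration]))
  spike_train(spk, t_start = 0, t_stop = duration)
}

#' Generate one synthetic spike train
#'
#' @param p A [train_params] object.
#' @param duration Recording length, seconds.
#' @param seed Integer seed; the same seed reproduces the train exactly.
#' @return A [spike_train] over `[0, duration]`.
#' @examples
#' st <- generate_train(train_params(burst_rate = 10), 900, seed = 1)
#' st
#' @export
generate_train <- function(p, duration, seed) {
  stopifnot(inherits(p, "train_params"), duration > 0)
  set.seed(as.integer(seed))
  synth_train(p, duration)
}

# Fixed seed-splitting rule: electrode i of master seed s gets its own
# stream, independent of n_electrodes.  Kept below 2^31.
electrode_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 7919) %% 2147483629
}

#' Generate a synthetic MEA recording
#'
#' Builds `n_electrodes` trains sharing a master renewal burst schedule:
#' each electrode replaces `shared_fraction` of its private bursts with
#' master bursts (joined with probability `participation_p`, onsets jittered
#' by `jitter_sd`).  This master/slave construction yields network spikes
#' and distance-independent pairwise correlations, the two array-level
#' structures the analysis measures.  A fixed fraction of electrodes
#' (`theta_fraction`, rounded to a count) is generated with theta-band
#' within-burst intervals.
#'
#' @param tp A [train_params] object (per-electrode dynamics).
#' @param np A [network_params] object (array-wide structure and seed).
#' @param region,age_div,array_id Metadata stored on the result.
#' @return An [mea_recording].
#' @examples
#' rec <- generate_recording(train_params(), network_params(n_electrodes = 8,
#'                           duration = 60, seed = 1))
#' rec
#' @export
generate_recording <- function(tp, np, region = "CTX", age_div = 14L,
                               array_id = NULL) {
  stopifnot(inherits(tp, "train_params"), inherits(np, "network_params"),
            np$n_electrodes >= 2)
  if (is.null(array_id)) array_id <- sprintf("sim-%d", np$seed)
  set.seed(np$seed)
  master <- renewal_onsets(tp$burst_rate, tp$ibi_cv, np$duration)
  n_theta <- round(np$theta_fraction * np$n_electrodes)
  trains <- vector("list", np$n_electrodes)
  for (i in seq_len(np$n_electrodes)) {
    set.seed(electrode_seed(np$seed, i))
    p_i <- tp
    p_i$theta <- i <= n_theta   # first electrodes carry theta, rest tonic
    trains[[i]] <- synth_train(p_i, np$duration, master_onsets = master,
                               participation_p = np$participation_p,
                               shared_fraction = np$shared_fraction)
  }
  mea_recording(trains, positions = mea_geometry(np$n_electrodes),
                region = region, age_div = age_div, array_id = array_id)
}

#' Region- and age-specific generator presets
#'
#' Returns generator parameters emulating hippocampal (HPC) or cortical
#' (CTX) cultures at a given age in days in vitro.  The presets encode the
#' qualitative developmental profile: burst rate, correlation and firing
#' strengthen from DIV 7 to 14 and then plateau; relative to CTX at the same
#' age, HPC presets have a lower interburst-interval CV, a higher shared
#' (network) burst fraction, and theta-band bursting on a majority of
#' electrodes once mature.  Magnitudes are package conventions, chosen once;
#' only the orderings are treated as ground truth.
#'
#' @param region `"CTX"` or `"HPC"`.
#' @param age_div Days in vitro, 7 to 28.
#' @param n_electrodes,duration,seed Passed through to [network_params()].
#' @return List with elements `train` ([train_params]) and `network`
#'   ([network_params]).
#' @examples
#' preset_profile("HPC", 14)$train$ibi_cv
#' preset_profile("CTX", 14)$train$ibi_cv
#' @export
preset_profile <- function(region = c("CTX", "HPC"), age_div,
                           n_electrodes = 59, duration = 900, seed = 1) {
  region <- match.arg(region)
  if (age_div < 7 || age_div > 28) stop("age_div must be in 7..28")
  r <- min(1, max(0, (age_div - 7) / 7))  # DIV 7 -> 0, DIV >= 14 -> 1
  # Parameters that are not part of the planted region contrast are shared
  # between regions, so the contrasts (interburst regularity, theta
  # prevalence, shared correlated bursting) carry the class signal.
  # within_burst_rate 30 Hz keeps the plain-burst ISI mode (~33 ms) well
  # below the theta band while limiting the nuisance gap between theta
  # (doublet-paced, ~13 Hz) and plain electrodes in the burst-shape
  # features: the class contrast should live in the three planted
  # parameters, not in burst shape.
  base <- list(background_rate = 0.15 + 0.10 * r,
               burst_rate = 4 + 4 * r,            # 4 -> 8 / min
               spikes_per_burst = 9 + 3 * r,
               within_burst_rate = 30,
               jitter_sd = 0.004)
  # NB: an electrode's realised burst train is a thinned union of its
  # private schedule and the master schedule, which pushes the measured
  # per-electrode CV of IBI towards 1 regardless of the planted value; the
  # planted CVs below are therefore wider apart than the target electrode-
  # level contrast.
  if (region == "HPC") {
    tp <- do.call(train_params,
                  c(base, list(ibi_cv = 0.50 - 0.10 * r)))  # regular
    np <- network_params(n_electrodes = n_electrodes, duration = duration,
                         participation_p = 0.90,
                         shared_fraction = 0.40 + 0.35 * r,   # 0.40 -> 0.75
                         theta_fraction = 0.10 + 0.55 * r,    # 0.10 -> 0.65
                         seed = seed)
  } else {
    tp <- do.call(train_params,
                  c(base, list(ibi_cv = 1.10 + 0.20 * r)))   # irregular
    np <- network_params(n_electrodes = n_electrodes, duration = duration,
                         participation_p = 0.60,
                         shared_fraction = 0.10 + 0.25 * r,   # 0.10 -> 0.35
                         theta_fraction = 0.05,
                         seed = seed)
  }
  list(train = tp, network = np)
}

#' Simulate a cohort of recordings from presets
#'
#' Generates `n_per_group` recordings per region at one age, with
#' per-recording seeds derived from `seed`.  On top of the region/age
#' presets, each simulated array receives multiplicative lognormal
#' heterogeneity (`array_effect_sd`, sdlog) on its rate- and size-like
#' parameters (background rate, burst rate, spikes per burst, within-burst
#' rate), emulating the order-of-magnitude spread of firing magnitudes
#' across real cultured arrays of the same age; the patterning contrasts
#' between regions (interburst regularity, theta prevalence, shared
#' bursting) are not jittered.
#'
#' @param age_div Days in vitro.
#' @param n_per_group Recordings per region.
#' @param regions Character vector of regions to simulate.
#' @param n_electrodes,duration Array geometry and length.
#' @param array_effect_sd sdlog of the per-array lognormal heterogeneity
#'   (default 0.5; 0 disables it).
#' @param seed Master seed.
#' @return List of [mea_recording] objects.
#' @export
simulate_cohort <- function(age_div = 14, n_per_group = 10,
                            regions = c("CTX", "HPC"), n_electrodes = 59,
                            duration = 900, array_effect_sd = 0.5,
                            seed = 1) {
  out <- list()
  k <- 0
  for (reg in regions) {
    for (j in seq_len(n_per_group)) {
      k <- k + 1
      s <- electrode_seed(seed, 1000 + k)
      pr <- preset_profile(reg, age_div, n_electrodes = n_electrodes,
                           duration = duration, seed = s)
      if (array_effect_sd > 0) {
        set.seed(electrode_seed(s, 1))
        f <- stats::rlnorm(4, 0, array_effect_sd)
        pr$train$background_rate <- pr$train$background_rate * f[1]
        pr$train$burst_rate <- pr$train$burst_rate * f[2]
        pr$train$spikes_per_burst <- pr$train$spikes_per_burst * f[3]
        pr$train$within_burst_rate <- pr$train$within_burst_rate * f[4]
      }
      out[[k]] <- generate_recording(pr$train, pr$network, region = reg,
                                     age_div = age_div,
                                     array_id = sprintf("%s-d%02d-%02d",
                                                        reg, age_div, j))
    }
  }
  out
}
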