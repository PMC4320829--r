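#' Construct a spike train
#'
#' A spike train holds the sorted spike times (in seconds) recorded on one
#' electrode over a known recording interval.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[t_start, t_stop]`.  May be empty: silent
#'   electrodes are first-class citizens (they enter denominators such as the
#'   theta fraction).
#' @param t_start,t_stop Recording interval in seconds.  Defaults to a
#'   15-minute recording, `[0, 900]`.
#' @param validate Check invariants (default `TRUE`).
#'
#' @return An object of class `spike_train`: a list with elements `times`,
#'   `t_start`, `t_stop`.
#' @examples
#' st <- spike_train(c(0.5, 1.2, 1.25), t_stop = 10)
#' n_spikes(st)
#' firing_rate(st)
#' @export
spike_train <- function(times = numeric(), t_start = 0, t_stop = 900,
                        validate = TRUE) {
  times <- as.numeric(times)
  obj <- structure(list(times = times, t_start = as.numeric(t_start),
                        t_stop = as.numeric(t_stop)),
                   class = "spike_train")
  if (validate) {
    msg <- spike_train_violations(obj)
    if (length(msg)) stop("invalid spike_train: ", paste(msg, collapse = "; "))
  }
  obj
}

# Invariant checks shared by the constructor and validate_recording();
# returns character vector of violations, empty when valid.
spike_train_violations <- function(st) {
  out <- character()
  if (!is.numeric(st$t_start) || !is.numeric(st$t_stop) ||
      !(st$t_stop > st$t_start))
    out <- c(out, "t_stop must be greater than t_start")
  t <- st$times
  if (anyNA(t)) out <- c(out, "spike times contain NA")
  else if (length(t)) {
    if (any(diff(t) <= 0))
      out <- c(out, "spike times not strictly increasing")
    if (t[1] < st$t_start || t[length(t)] > st$t_stop)
      out <- c(out, "spike times outside [t_start, t_stop]")
  }
  out
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) length(x$times)

#' @rdname spike_train
#' @export
firing_rate <- function(x) length(x$times) / (x$t_stop - x$t_start)

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes on [%g, %g] s (%.3f Hz)\n",
              n_spikes(x), x$t_start, x$t_stop, firing_rate(x)))
  invisible(x)
}

#' Interspike intervals of a train
#' @param st A `spike_train`.
#' @return Numeric vector of length `n_spikes(st) - 1` (or length 0).
#' @export
isi <- function(st) diff(st$times)

#' Electrode layout of a 60-electrode MEA
#'
#' Positions (micrometres) of the standard 8 x 8 grid with the four corners
#' absent and one substrate-integrated reference electrode excluded, i.e. the
#' 59 recording electrodes of a 200 um pitch, 30 um diameter array.
#'
#' @param n Number of electrodes requested.  `n <= 59` takes the first `n`
#'   positions; `n > 59` tiles additional rows below the grid (synthetic
#'   geometries only).
#' @return `n` x 2 numeric matrix of (x, y) positions in micrometres,
#'   200 um pitch.
#' @examples
#' pos <- mea_geometry(4)
#' dist(pos)
#' @export
mea_geometry <- function(n = 59) {
  pitch <- 200
  cols <- rep(1:8, each = 8)
  rows <- rep(1:8, times = 8)
  keep <- !((cols %in% c(1, 8)) & (rows %in% c(1, 8)))  # drop 4 corners
  xy <- cbind(x = cols[keep] * pitch, y = rows[keep] * pitch)
  xy <- xy[-15, , drop = FALSE]                         # reference electrode
  if (n <= nrow(xy)) return(xy[seq_len(n), , drop = FALSE])
  extra <- n - nrow(xy)
  ex <- cbind(x = (seq_len(extra) - 1) %% 8 * pitch + pitch,
              y = 9 * pitch + ((seq_len(extra) - 1) %/% 8) * pitch)
  rbind(xy, ex)
}

#' Construct an MEA recording
#'
#' Bundles one spike train per electrode with electrode positions and
#' metadata (brain region of origin, culture age, array identifier).
#'
#' @param trains List of [spike_train] objects, one per electrode, all
#'   sharing the same recording interval.
#' @param positions `N` x 2 numeric matrix of electrode (x, y) positions in
#'   micrometres; defaults to [mea_geometry] of the right size.
#' @param labels Character electrode names; default `"e1"..."eN"`.
#' @param region `"CTX"` (cortical) or `"HPC"` (hippocampal).
#' @param age_div Culture age, days in vitro (integer).
#' @param array_id Free-text array identifier.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `mea_recording`.
#' @examples
#' rec <- mea_recording(list(spike_train(1:5, t_stop = 10),
#'                           spike_train(c(2, 4), t_stop = 10)),
#'                      region = "CTX", age_div = 14)
#' rec
#' @export
mea_recording <- function(trains, positions = NULL, labels = NULL,
                          region = c("CTX", "HPC"), age_div = NA_integer_,
                          array_id = "array", validate = TRUE) {
  region <- match.arg(region)
  n <- length(trains)
  if (is.null(positions)) positions <- mea_geometry(n)
  positions <- as.matrix(positions)
  if (is.null(labels)) labels <- paste0("e", seq_len(n))
  obj <- structure(list(trains = trains, positions = positions,
                        labels = as.character(labels), region = region,
                        age_div = as.integer(age_div),
                        array_id = as.character(array_id)),
                   class = "mea_recording")
  if (validate) {
    bad <- validate_recording(obj)
    if (nrow(bad)) stop("invalid mea_recording: ",
                        paste(unique(bad$violation), collapse = "; "))
  }
  obj
}

#' @export
print.mea_recording <- function(x, ...) {
  ns <- vapply(x$trains, n_spikes, integer(1))
  cat(sprintf(
    "<mea_recording> %s array '%s', DIV %s\n  %d electrodes, %g s, %d spikes (median rate %.3f Hz)\n",
    x$region, x$array_id, x$age_div, length(x$trains),
    duration(x), sum(ns),
    stats::median(ns) / duration(x)))
  invisible(x)
}

#' @rdname mea_recording
#' @param x An `mea_recording`.
#' @export
duration <- function(x) {
  st <- x$trains[[1]]
  st$t_stop - st$t_start
}

#' @rdname mea_recording
#' @export
n_electrodes <- function(x) length(x$trains)

#' Validate a recording without raising
#'
#' Checks every structural invariant of an [mea_recording] and reports
#' violations as data instead of raising, so that suspect files can be
#' triaged.  An empty report means the recording is valid.
#'
#' @param rec An `mea_recording` (possibly malformed).
#' @return A data frame with columns `electrode` (label or `NA` for
#'   array-level problems) and `violation` (message).  Zero rows when valid.
#' @examples
#' rec <- mea_recording(list(spike_train(1:3, t_stop = 10)), region = "HPC")
#' validate_recording(rec)   # 0 rows
#' @export
validate_recording <- function(rec) {
  bad <- function(el, msg) data.frame(electrode = el, violation = msg,
                                      stringsAsFactors = FALSE)
  out <- list()
  n <- length(rec$trains)
  if (nrow(rec$positions) != n)
    out <- c(out, list(bad(NA, "positions/trains length mismatch")))
  if (length(rec$labels) != n)
    out <- c(out, list(bad(NA, "labels/trains length mismatch")))
  if (!rec$region %in% c("CTX", "HPC"))
    out <- c(out, list(bad(NA, sprintf("region '%s' not CTX/HPC", rec$region))))
  if (n) {
    t0 <- vapply(rec$trains, function(s) s$t_start, numeric(1))
    t1 <- vapply(rec$trains, function(s) s$t_stop, numeric(1))
    if (length(unique(t0)) > 1 || length(unique(t1)) > 1)
      out <- c(out, list(bad(NA, "trains do not share t_start/t_stop")))
    for (i in seq_len(n)) {
      v <- spike_train_violations(rec$trains[[i]])
      lab <- if (i <= length(rec$labels)) rec$labels[i] else as.character(i)
      for (m in v) out <- c(out, list(bad(lab, m)))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(electrode = character(), violation = character(),
                  stringsAsFactors = FALSE)
}
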