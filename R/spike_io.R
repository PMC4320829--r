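#' Read an MEA recording from HDF5
#'
#' Reads the HDF5 dialect used for archived spontaneous-activity recordings:
#' `/spikes` (all spike times concatenated electrode by electrode, float64),
#' `/sCount` (per-electrode spike counts), `/epos` (electrode positions, um),
#' `/names` (electrode labels), `/array` (array model string),
#' `/meta/region` ("CTX" or "HPC") and `/meta/age` (days in vitro).
#'
#' @param path Path to an HDF5 file.
#' @param units Units of the stored spike times: `"s"` (seconds, default) or
#'   `"samples"` (sample counts; divided by `sample_rate`).  Archived files
#'   do not declare their unit, hence the option.
#' @param sample_rate Samples per second used when `units = "samples"`
#'   (default 25000, the usual acquisition rate).
#' @param t_start,t_stop Recording interval in seconds.  When `NULL`
#'   (default) `t_start = 0` and `t_stop` is read from the optional
#'   `/duration` dataset, falling back to the last spike time rounded up to
#'   the next full minute.
#' @return An [mea_recording].
#' @seealso [write_mea_h5()], [validate_recording()]
#' @export
read_mea_h5 <- function(path, units = c("s", "samples"), sample_rate = 25000,
                        t_start = NULL, t_stop = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  contents <- rhdf5::h5ls(path)
  have <- file.path(contents$group, contents$name)
  have <- sub("^/+", "/", sub("^//", "/", have))
  need <- c("/spikes", "/sCount", "/epos", "/names", "/meta/region")
  missing <- setdiff(need, have)
  if (length(missing))
    stop("not a recognised MEA HDF5 file; missing dataset(s): ",
         paste(missing, collapse = ", "))

  spikes <- as.numeric(rhdf5::h5read(path, "/spikes"))
  counts <- as.integer(rhdf5::h5read(path, "/sCount"))
  epos <- rhdf5::h5read(path, "/epos")
  labels <- as.character(rhdf5::h5read(path, "/names"))
  region <- as.character(rhdf5::h5read(path, "/meta/region"))[1]
  age <- if ("/meta/age" %in% have)
    as.integer(rhdf5::h5read(path, "/meta/age"))[1] else NA_integer_
  array_id <- if ("/array" %in% have)
    as.character(rhdf5::h5read(path, "/array"))[1] else "unknown"
  stored_dur <- if ("/duration" %in% have)
    as.numeric(rhdf5::h5read(path, "/duration"))[1] else NA_real_

  if (sum(counts) != length(spikes))
    stop("format error: /sCount sums to ", sum(counts),
         " but /spikes holds ", length(spikes), " times")
  if (!region %in% c("CTX", "HPC"))
    stop("metadata error: /meta/region is '", region, "', expected CTX or HPC")
  if (units == "samples") {
    spikes <- spikes / sample_rate
    if (!is.na(stored_dur)) stored_dur <- stored_dur / sample_rate
  }

  epos <- as.matrix(epos)
  if (nrow(epos) != length(counts) && ncol(epos) == length(counts))
    epos <- t(epos)  # rhdf5 preserves on-disk row/column order ambiguity

  if (is.null(t_start)) t_start <- 0
  if (is.null(t_stop)) {
    t_stop <- if (!is.na(stored_dur)) t_start + stored_dur
      else if (length(spikes)) 60 * ceiling(max(spikes) / 60)
      else 900
  }

  idx <- rep.int(seq_along(counts), counts)
  trains <- lapply(seq_along(counts), function(i) {
    tt <- spikes[idx == i]
    if (is.unsorted(tt, strictly = TRUE))
      stop("data error: electrode ", labels[i],
           " has non-monotone spike times")
    spike_train(tt, t_start = t_start, t_stop = t_stop)
  })
  mea_recording(trains, positions = epos, labels = labels, region = region,
                age_div = age, array_id = array_id)
}

#' Write an MEA recording to HDF5
#'
#' Inverse of [read_mea_h5()]; times are always written in seconds.
#'
#' @param rec A valid [mea_recording].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_mea_h5 <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  bad <- validate_recording(rec)
  if (nrow(bad)) stop("refusing to write invalid recording: ",
                      paste(unique(bad$violation), collapse = "; "))
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create HDF5 file at ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  spikes <- unlist(lapply(rec$trains, `[[`, "times"), use.names = FALSE)
  if (is.null(spikes)) spikes <- numeric()
  counts <- vapply(rec$trains, n_spikes, integer(1))
  rhdf5::h5write(spikes, path, "spikes")
  rhdf5::h5write(counts, path, "sCount")
  rhdf5::h5write(unname(rec$positions), path, "epos")
  rhdf5::h5write(rec$labels, path, "names")
  rhdf5::h5write(rec$array_id, path, "array")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(rec$region, path, "meta/region")
  rhdf5::h5write(as.integer(rec$age_div), path, "meta/age")
  rhdf5::h5write(duration(rec), path, "duration")
  invisible(path)
}
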