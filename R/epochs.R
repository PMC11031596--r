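#' Epoched multi-channel EEG around TMS pulses
#'
#' The unit of data every pipeline stage transforms: a `trials x channels x
#' samples` array of voltages (microvolts) with a pulse-locked time axis.
#' Stages are pure - they return a modified copy and never mutate their input.
#'
#' @param data numeric array `[trials, channels, samples]`, microvolts.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample relative to pulse onset, ms.
#' @param channels ordered unique channel labels (length = dim 2 of `data`).
#' @param bad_channels subset of `channels` flagged as unusable.
#' @param bad_trials integer indices of trials flagged as unusable.
#' @param meta optional [block_metadata()] record.
#' @return An object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, fs, t0, channels,
                        bad_channels = character(),
                        bad_trials = integer(),
                        meta = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(channels) != dim(data)[2]) {
    stop("channels length must match dim(data)[2]")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (!all(bad_channels %in% channels)) stop("bad_channels must be a subset of channels")
  bad_trials <- as.integer(bad_trials)
  if (length(bad_trials) && (min(bad_trials) < 1 || max(bad_trials) > dim(data)[1])) {
    stop("bad_trials out of range")
  }
  structure(
    list(data = data, fs = fs, t0 = t0, channels = as.character(channels),
         bad_channels = as.character(bad_channels), bad_trials = bad_trials,
         meta = meta),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_eeg> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
    d[1], d[2], d[3], x$fs, x$t0, x$t0 + (d[3] - 1) * 1000 / x$fs))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  if (length(x$bad_trials)) {
    cat("  bad trials:", paste(x$bad_trials, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pulse-locked time axis of an epoch object, in ms
#' @param ep an [epoched_eeg()].
#' @return numeric vector of length `dim(ep$data)[3]`.
#' @export
time_axis <- function(ep) {
  ep$t0 + (seq_len(dim(ep$data)[3]) - 1) * 1000 / ep$fs
}

n_trials <- function(ep) dim(ep$data)[1]
n_channels <- function(ep) dim(ep$data)[2]

good_channels <- function(ep) setdiff(ep$channels, ep$bad_channels)
good_trials <- function(ep) setdiff(seq_len(n_trials(ep)), ep$bad_trials)

# Reshape [trials, channels, samples] -> [samples, trials*channels] and back;
# the layout used by the FFT stages.
flatten_ts <- function(data) {
  d <- dim(data)
  matrix(aperm(data, c(3, 1, 2)), nrow = d[3])
}
unflatten_ts <- function(mat, d_trials, d_channels) {
  aperm(array(mat, c(nrow(mat), d_trials, d_channels)), c(2, 3, 1))
}

#' Write / read a block in the package's internal epoch format
#'
#' Serialization of one epoched block (data, sampling info, labels, metadata)
#' to a single file. The internal format is R's native RDS container; readers
#' for vendor formats (EEGLAB `.set`, FIF) are out of scope in this
#' implementation because no bindings for those containers are available in
#' the supported dependency set.
#'
#' @param ep an [epoched_eeg()].
#' @param path file path.
#' @return `write_block`: `path`, invisibly. `read_block`: an `epoched_eeg`.
#' @export
write_block <- function(ep, path) {
  stopifnot(inherits(ep, "epoched_eeg"))
  saveRDS(unclass(ep), path, version = 3)
  invisible(path)
}

#' @rdname write_block
#' @export
read_block <- function(path) {
  x <- readRDS(path)
  epoched_eeg(x$data, x$fs, x$t0, x$channels, x$bad_channels, x$bad_trials, x$meta)
}
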