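#' Spike-train sets
#'
#' A `spike_train_set` holds one ordered vector of spike times (seconds) per
#' recording channel, together with the acquisition sampling rate and the
#' recording duration. On construction every spike time is snapped to the
#' sampling grid (time = integer / sampling_rate), sorted, and checked to lie
#' in `[0, duration]`; duplicate same-channel same-sample stamps are collapsed
#' with a warning (a refractory period makes true duplicates
#' non-physiological).
#'
#' @param spikes named list of numeric vectors of spike times in seconds, one
#'   per channel. Names are the channel ids.
#' @param sampling_rate acquisition sampling rate in Hz (e.g. 10000 for the
#'   60-channel arrays, 9046 for the 4096-channel arrays).
#' @param duration recording duration in seconds.
#' @param channel_ids optional character vector of channel labels; defaults to
#'   `names(spikes)`.
#' @return an object of class `spike_train_set` with fields `spikes`
#'   (list of numeric vectors, seconds), `samples` (the same times as integer
#'   sample indices), `channel_ids`, `sampling_rate`, `duration`.
#' @export
spike_train_set <- function(spikes, sampling_rate, duration, channel_ids = NULL) {
  if (is.null(channel_ids)) channel_ids <- names(spikes)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%03d", seq_along(spikes))
  stopifnot(length(channel_ids) == length(spikes))
  if (anyDuplicated(channel_ids)) stop("duplicate channel ids")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  samples <- vector("list", length(spikes))
  out <- vector("list", length(spikes))
  for (i in seq_along(spikes)) {
    t <- spikes[[i]]
    if (length(t) == 0) {
      samples[[i]] <- integer(0); out[[i]] <- numeric(0); next
    }
    if (any(!is.finite(t))) stop("non-finite spike time on channel ", channel_ids[i])
    if (any(t < 0)) stop("negative spike time on channel ", channel_ids[i])
    if (any(t > duration + 0.5 / sampling_rate))
      stop("spike time beyond declared duration on channel ", channel_ids[i])
    s <- sort(as.integer(round(t * sampling_rate)))
    if (anyDuplicated(s)) {
      warning("collapsing duplicate spike stamps on channel ", channel_ids[i])
      s <- unique(s)
    }
    samples[[i]] <- s
    out[[i]] <- s / sampling_rate
  }
  names(out) <- channel_ids
  names(samples) <- channel_ids
  structure(list(channel_ids = channel_ids, spikes = out, samples = samples,
                 sampling_rate = sampling_rate, duration = duration),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  nsp <- vapply(x$spikes, length, integer(1))
  cat(sprintf("spike_train_set: %d channels, %d spikes, %.6g s at %g Hz\n",
              length(x$channel_ids), sum(nsp), x$duration, x$sampling_rate))
  invisible(x)
}

#' Number of spikes per channel
#' @param set a [spike_train_set()].
#' @return named integer vector.
#' @export
spike_counts <- function(set) {
  vapply(set$spikes, length, integer(1))
}

#' Truncate a recording to its first `duration` seconds
#'
#' Used by the recording-length analyses: spikes after `duration` are dropped
#' and the declared duration is shortened.
#' @param set a [spike_train_set()].
#' @param duration new duration in seconds; must not exceed `set$duration`.
#' @return a [spike_train_set()].
#' @export
truncate_recording <- function(set, duration) {
  stopifnot(duration > 0, duration <= set$duration)
  sp <- lapply(set$spikes, function(t) t[t <= duration])
  spike_train_set(sp, set$sampling_rate, duration, set$channel_ids)
}

#' Load spike data from CSV
#'
#' The canonical on-disk format is a two-column CSV `channel_id,time_s` with a
#' header, preceded by comment lines carrying the recording metadata:
#' ```
#' # sampling_rate_hz: 10000
#' # duration_s: 3600
#' # channels: ch001,ch002,...
#' channel_id,time_s
#' ```
#' The `# channels:` line preserves silent channels and channel order.
#' Unsorted times are sorted on load (the representation is canonical).
#'
#' @param path file path.
#' @param sampling_rate,duration overrides for files without metadata lines.
#' @return a [spike_train_set()].
#' @export
load_spike_data <- function(path, sampling_rate = NULL, duration = NULL) {
  if (!file.exists(path)) stop("cannot read spike file: ", path)
  hdr <- readLines(path, n = 10L)
  meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  sr <- meta("sampling_rate_hz"); du <- meta("duration_s"); chs <- meta("channels")
  if (!is.null(sr)) sampling_rate <- as.numeric(sr)
  if (!is.null(du)) duration <- as.numeric(du)
  if (is.null(sampling_rate) || is.null(duration))
    stop("sampling_rate and duration must be in the file header or supplied")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("channel_id", "time_s") %in% names(df)))
    stop("spike CSV needs columns channel_id,time_s")
  ids <- if (!is.null(chs)) strsplit(chs, ",")[[1]] else unique(as.character(df$channel_id))
  sp <- split(df$time_s, factor(as.character(df$channel_id), levels = ids))
  sp <- lapply(sp, function(t) if (is.null(t)) numeric(0) else as.numeric(t))
  names(sp) <- ids
  spike_train_set(sp, sampling_rate, duration, ids)
}

#' Save spike data to CSV
#'
#' Writes the format read by [load_spike_data()]; `load(save(s))` is the
#' identity for times on the sampling grid.
#' @param set a [spike_train_set()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_spike_data <- function(set, path) {
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot write: ", path))
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz: %.10g", set$sampling_rate),
               sprintf("# duration_s: %.10g", set$duration),
               paste0("# channels: ", paste(set$channel_ids, collapse = ",")),
               "channel_id,time_s"), con)
  for (ch in set$channel_ids) {
    t <- set$spikes[[ch]]
    if (length(t)) writeLines(sprintf("%s,%.10g", ch, t), con)
  }
  invisible(path)
}

#' Firing statistics
#'
#' Per-channel mean firing rate (MFR, spikes/s) and a population instantaneous
#' firing rate (IFR) trace: population spike count per time bin divided by
#' (bin width x number of active channels), so that
#' `sum(ifr) * ifr_bin * n_active` equals the total spike count.
#'
#' @param set a [spike_train_set()].
#' @param ifr_bin IFR bin width in seconds (default 0.1 s, fine enough to
#'   resolve network bursts lasting hundreds of milliseconds).
#' @return list with `mfr` (named vector), `ifr` (vector, spikes/s/channel),
#'   `ifr_times` (bin centers, s), `n_active`.
#' @export
firing_statistics <- function(set, ifr_bin = 0.1) {
  stopifnot(ifr_bin > 0)
  if (set$duration <= 0) stop("zero duration")
  nsp <- spike_counts(set)
  mfr <- nsp / set$duration
  all_t <- unlist(set$spikes, use.names = FALSE)
  n_active <- sum(nsp > 0)
  nb <- max(1L, as.integer(ceiling(set$duration / ifr_bin)))
  counts <- if (length(all_t))
    tabulate(pmin(floor(all_t / ifr_bin), nb - 1) + 1L, nbins = nb)
  else integer(nb)
  ifr <- if (n_active > 0) counts / (ifr_bin * n_active) else counts * 0
  list(mfr = mfr, ifr = ifr,
       ifr_times = (seq_len(nb) - 0.5) * ifr_bin, n_active = n_active)
}

#' Single-electrode burst detection
#'
#' A burst is a maximal run of at least `min_spikes` consecutive spikes whose
#' inter-spike intervals are all at most `max_isi`.
#'
#' @param train numeric vector of sorted spike times (seconds), or a
#'   [spike_train_set()] (then all channels are scanned).
#' @param min_spikes minimum spikes per burst (default 5).
#' @param max_isi maximum intra-burst inter-spike interval in seconds
#'   (default 0.100).
#' @param channel_id label used when `train` is a vector.
#' @return data.frame with columns `channel_id`, `start`, `end`, `n_spikes`.
#' @export
detect_bursts <- function(train, min_spikes = 5, max_isi = 0.100,
                          channel_id = "ch") {
  if (inherits(train, "spike_train_set")) {
    out <- lapply(train$channel_ids, function(ch)
      detect_bursts(train$spikes[[ch]], min_spikes, max_isi, ch))
    return(do.call(rbind, out))
  }
  empty <- data.frame(channel_id = character(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0))
  nt <- length(train)
  if (nt < min_spikes) return(empty)
  ok <- diff(train) <= max_isi
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= min_spikes)
  if (!any(keep)) return(empty)
  data.frame(channel_id = channel_id,
             start = train[starts[keep]],
             end = train[ends[keep] + 1L],
             n_spikes = r$lengths[keep] + 1L)
}
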