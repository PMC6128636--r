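#' Normalized cross-correlation histogram of a spike-train pair
#'
#' Counts, for every lag bin in `[-W/2, W/2]`, the (reference, target) spike
#' pairs whose lag falls in that bin, normalized by `sqrt(Nx * Ny)`. Lags are
#' target-minus-reference times: a peak at positive lag means the target
#' tends to fire after the reference. Spike times are assigned to bins of
#' width `delta` on the sampling grid (bin index = floor(sample / bin
#' samples)) and the pair lag is the bin-index difference, so the direct
#' time-stamp sweep is exactly the shifted product of the binned trains. The
#' computation sweeps a pointer over the target train inside the window of
#' each reference spike and never materializes binarized arrays, so its cost
#' scales with the number of spike pairs inside windows, not with
#' duration/delta.
#'
#' @param x,y spike times in seconds (reference and target train), sorted.
#' @param W correlation window in ms (lag axis spans `[-W/2, W/2]`).
#' @param delta lag bin width in ms.
#' @param sampling_rate sampling rate in Hz used to place spikes on the grid.
#' @return object of class `ncch`: `values` (normalized counts, in `[0, 1]`
#'   for physiological trains), `lags_ms` (bin centers), `n_x`, `n_y`, `W`,
#'   `delta`, `empty` (TRUE when either train has no spikes, in which case the
#'   correlogram is all-zero and no link is derivable).
#' @export
ncch_pair <- function(x, y, W = 25, delta = 1, sampling_rate = 10000) {
  stopifnot(W > 0, delta > 0, W / delta >= 2)
  sx <- as.integer(round(x * sampling_rate))
  sy <- as.integer(round(y * sampling_rate))
  bw <- delta * sampling_rate / 1000
  K <- as.integer(floor((W / 2) / delta))
  empty <- length(sx) == 0 || length(sy) == 0
  counts <- if (empty) numeric(2 * K + 1) else ncch_counts_cpp(sx, sy, bw, K)
  norm <- if (empty) 1 else sqrt(length(sx) * length(sy))
  structure(list(values = counts / norm, lags_ms = (-K:K) * delta,
                 n_x = length(sx), n_y = length(sy), W = W, delta = delta,
                 K = K, empty = empty),
            class = "ncch")
}

#' @export
print.ncch <- function(x, ...) {
  cat(sprintf("ncch: %d lag bins (%g ms each), W = %g ms, Nx = %d, Ny = %d\n",
              length(x$values), x$delta, x$W, x$n_x, x$n_y))
  invisible(x)
}

peak_from_bin <- function(corr, k, filtered) {
  entity <- filtered[k + corr$K + 1L]
  structure(list(entity = entity, lag_ms = k * corr$delta,
                 polarity = if (entity > 0) "excitatory" else "inhibitory",
                 null = FALSE), class = "fncch_peak")
}

null_peak <- function() {
  structure(list(entity = 0, lag_ms = NA_real_, polarity = NA_character_,
                 null = TRUE), class = "fncch_peak")
}

# argmax of |F| with tie-breaks: smallest |lag| wins, then positive lag.
argmax_lag <- function(F, K, kmax = K) {
  order_k <- c(0, as.vector(rbind(seq_len(kmax), -seq_len(kmax))))
  best <- 0L; bv <- -1
  for (k in order_k) {
    v <- abs(F[k + K + 1L])
    if (v > bv) { bv <- v; best <- k }
  }
  best
}

#' Filtered peak (entity) of a correlogram
#'
#' Subtracts the within-window mean of the correlogram from every bin and
#' takes the bin with the largest absolute filtered value, retaining the
#' original sign: a positive entity marks an excitatory link, a negative one
#' (a trough in the raw correlogram) an inhibitory link. Ties in the argmax
#' are broken toward the smallest absolute lag, then toward positive lag
#' (favoring causal short-latency links). The filtered peak is invariant to
#' adding a constant to all bins; a flat correlogram yields a null result.
#'
#' @param corr an [ncch_pair()] result.
#' @return object of class `fncch_peak`: `entity` (signed filtered value,
#'   `|entity| <= 1`), `lag_ms`, `polarity` (`"excitatory"`/`"inhibitory"`),
#'   `null`.
#' @export
fncch_peak <- function(corr) {
  stopifnot(inherits(corr, "ncch"))
  if (corr$empty || all(corr$values == 0)) return(null_peak())
  F <- corr$values - mean(corr$values)
  if (all(F == 0)) return(null_peak())
  peak_from_bin(corr, argmax_lag(F, corr$K), F)
}

#' Raw (unfiltered) correlogram peak
#'
#' The plain NCCH estimator: the maximum of the raw normalized correlogram,
#' always non-negative, hence blind to inhibition. Used as the comparison
#' baseline for the filtered estimator.
#' @param corr an [ncch_pair()] result.
#' @return an `fncch_peak` (polarity always excitatory).
#' @export
ncch_peak <- function(corr) {
  stopifnot(inherits(corr, "ncch"))
  if (corr$empty || all(corr$values == 0)) return(null_peak())
  k <- argmax_lag(corr$values, corr$K)
  entity <- corr$values[k + corr$K + 1L]
  structure(list(entity = entity, lag_ms = k * corr$delta,
                 polarity = "excitatory", null = FALSE), class = "fncch_peak")
}

#' Boundary re-filter for inhibitory peaks in the window tails
#'
#' Weakly correlated pairs can place a spurious negative extreme at the edge
#' of the correlation window, producing a false inhibitory link. If the
#' detected peak is inhibitory and its lag lies in the outer `tail_fraction`
#' of the window on either side, the peak search is re-applied restricted to
#' the central `1 - 2 * tail_fraction` region (which may flip the polarity to
#' excitatory). Excitatory peaks and central inhibitory peaks pass through
#' unchanged.
#'
#' @param corr an [ncch_pair()] result.
#' @param peak the [fncch_peak()] result for `corr`.
#' @param tail_fraction fraction of the window discarded at each end
#'   (in `(0, 0.5)`; default 0.25).
#' @return an `fncch_peak`.
#' @export
boundary_refilter <- function(corr, peak, tail_fraction = 0.25) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in (0, 0.5)")
  if (peak$null || peak$polarity != "inhibitory") return(peak)
  kc <- floor(corr$K * (1 - 2 * tail_fraction))
  if (abs(peak$lag_ms) / corr$delta <= kc) return(peak)
  F <- corr$values - mean(corr$values)
  peak_from_bin(corr, argmax_lag(F, corr$K, kmax = kc), F)
}

#' Functional connectivity matrix from all channel pairs
#'
#' Computes one correlogram per unordered channel pair (the symmetry
#' `C_xy(tau) = C_yx(-tau)` makes the role assignment immaterial), extracts
#' the filtered (or raw) peak, and assigns direction from the peak lag: a
#' peak at positive lag with reference `x` yields the link x -> y with delay
#' `|lag|`; zero-lag peaks are stored with delay 0 and flagged (they are
#' pruned later by the minimum-delay rule of the spatio-temporal filter).
#' Pairs where both trains have fewer than `min_spikes` spikes are skipped
#' (correlogram variance dominates there).
#'
#' @param set a [spike_train_set()] with at least 2 non-empty channels.
#' @param W correlation window (ms). Defaults follow the simulation
#'   parameterization (W = 25, delta = 1); use W = 25 / delta = 0.1 for
#'   60-channel arrays and W = 24 / delta = 0.12 for 4096-channel arrays.
#' @param delta lag bin width (ms).
#' @param estimator `"fncch"` (filtered, signed) or `"ncch"` (raw maximum).
#' @param boundary_filter apply [boundary_refilter()] to inhibitory tail
#'   peaks (default TRUE).
#' @param tail_fraction see [boundary_refilter()].
#' @param min_spikes pair-skip threshold (default 10).
#' @return object of class `fcm`: `fcm` (n x n signed entity matrix, entry
#'   `(i, j)` is the detected i -> j strength, 0 if none), `delays_ms`,
#'   `zero_lag` (logical matrix), `channel_ids`, `params`.
#' @export
build_fcm <- function(set, W = 25, delta = 1, estimator = c("fncch", "ncch"),
                      boundary_filter = TRUE, tail_fraction = 0.25,
                      min_spikes = 10) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(set, "spike_train_set"), W > 0, delta > 0, W / delta >= 2)
  nsp <- spike_counts(set)
  if (length(nsp) < 2) stop("need at least 2 channels")
  if (sum(nsp > 0) < 2) stop("need at least 2 non-empty channels")
  bw <- delta * set$sampling_rate / 1000
  K <- as.integer(floor((W / 2) / delta))
  res <- fcm_cpp(unname(set$samples), bw, K, as.integer(min_spikes),
                 if (estimator == "fncch") 1L else 0L,
                 isTRUE(boundary_filter) && estimator == "fncch",
                 tail_fraction)
  delays <- res$lag_bins * delta
  dimnames(res$entity) <- list(set$channel_ids, set$channel_ids)
  dimnames(delays) <- dimnames(res$entity)
  structure(list(fcm = res$entity, delays_ms = delays, zero_lag = res$zero_lag,
                 channel_ids = set$channel_ids,
                 params = list(W = W, delta = delta, estimator = estimator,
                               boundary_filter = boundary_filter,
                               tail_fraction = tail_fraction,
                               min_spikes = min_spikes,
                               sampling_rate = set$sampling_rate,
                               skipped_pairs = res$skipped_pairs)),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("fcm: %d channels, %d excitatory / %d inhibitory entries (W = %g ms, bin = %g ms, %s)\n",
              length(x$channel_ids), sum(x$fcm > 0), sum(x$fcm < 0),
              x$params$W, x$params$delta, x$params$estimator))
  if (!is.null(x$params$thresholds))
    cat("  thresholded (TCM); params recorded in $params\n")
  invisible(x)
}

#' Save / load a functional connectivity matrix as an edge list
#'
#' `<prefix>_edges.csv` holds `source,target,entity,delay_ms`;
#' `<prefix>_params.json` the channel list and full parameter provenance.
#' @param fcm an [build_fcm()] result (or thresholded variant).
#' @param prefix path prefix.
#' @rdname fcm_io
#' @return [load_fcm()] returns an `fcm` object; [save_fcm()] returns
#'   `prefix` invisibly.
#' @export
save_fcm <- function(fcm, prefix) {
  nz <- which(fcm$fcm != 0, arr.ind = TRUE)
  edges <- data.frame(source = fcm$channel_ids[nz[, 1]],
                      target = fcm$channel_ids[nz[, 2]],
                      entity = fcm$fcm[nz], delay_ms = fcm$delays_ms[nz])
  write.csv(edges, paste0(prefix, "_edges.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(fcm$params, list(channel_ids = fcm$channel_ids)),
                       paste0(prefix, "_params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname fcm_io
#' @export
load_fcm <- function(prefix) {
  params <- jsonlite::read_json(paste0(prefix, "_params.json"), simplifyVector = TRUE)
  ids <- params$channel_ids
  params$channel_ids <- NULL
  edges <- read.csv(paste0(prefix, "_edges.csv"), stringsAsFactors = FALSE)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- cbind(match(edges$source, ids), match(edges$target, ids))
  m[i] <- edges$entity; d[i] <- edges$delay_ms
  structure(list(fcm = m, delays_ms = d,
                 zero_lag = m != 0 & d == 0, channel_ids = ids,
                 params = params), class = "fcm")
}
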