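#' Pruning parameters
#'
#' @param v_max maximum physiological propagation velocity in mm/s
#'   (default 400).
#' @param d_min minimum link delay in ms (default 1, compatible with fast
#'   excitatory AMPA transmission; removes zero-lag co-activations).
#' @param n_exc,n_inh hard-threshold multipliers: an excitatory entry
#'   survives if it exceeds `mu + n_exc * sigma` of the positive entries, an
#'   inhibitory one if its magnitude exceeds `mu + n_inh * sigma` of the
#'   negative-entry magnitudes (defaults 2 and 1).
#' @return list of class `pruning_params`.
#' @export
pruning_params <- function(v_max = 400, d_min = 1, n_exc = 2, n_inh = 1) {
  stopifnot(v_max > 0, d_min >= 0, n_exc >= 0, n_inh >= 0)
  structure(list(v_max = v_max, d_min = d_min, n_exc = n_exc, n_inh = n_inh),
            class = "pruning_params")
}

#' Spatio-temporal physiological filter
#'
#' Removes links whose geometry is not compatible with neural propagation: a
#' link i -> j is discarded iff its delay is below `d_min` or the apparent
#' velocity `distance(i, j) / delay` exceeds `v_max` (distance in um, delay in
#' ms, so um/ms = mm/s). Idempotent; raising `v_max` or lowering `d_min`
#' never removes a previously kept link.
#'
#' @param fcm an [build_fcm()] result.
#' @param layout an [electrode_layout()] covering every FCM channel.
#' @param params a [pruning_params()].
#' @return an `fcm` with filtered entries; removal counts in
#'   `$params$spatiotemporal_removed`.
#' @export
spatiotemporal_filter <- function(fcm, layout, params = pruning_params()) {
  stopifnot(inherits(fcm, "fcm"))
  dist_um <- electrode_distances(layout, fcm$channel_ids)
  nz <- fcm$fcm != 0
  delay <- fcm$delays_ms
  vel <- ifelse(delay > 0, dist_um / delay, Inf)
  drop <- nz & (delay < params$d_min | vel > params$v_max)
  fcm$fcm[drop] <- 0
  fcm$delays_ms[drop] <- 0
  fcm$zero_lag[drop] <- FALSE
  fcm$params$spatiotemporal <- list(v_max = params$v_max, d_min = params$d_min,
                                    removed = sum(drop))
  fcm
}

# population standard deviation (divides by N)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Hard threshold: mu + n * sigma per sign class
#'
#' Excitatory entries are kept when strictly above `mu + n_exc * sigma`
#' computed over the positive entries; inhibitory entries when their
#' magnitude is strictly above `mu + n_inh * sigma` of the negative-entry
#' magnitudes. `sigma` is the population standard deviation; strict
#' inequality means a degenerate class (all entries equal, sigma = 0) keeps
#' nothing — the conservative choice. Sign classes are thresholded
#' independently. With `pool = "all_elements"` the moments are instead taken
#' over all n^2 matrix elements including structural zeros (an alternative
#' reading of the thresholding rule; density-dependent, not the default).
#'
#' @param fcm an [build_fcm()] result (typically after
#'   [spatiotemporal_filter()], so non-physiological links do not inflate the
#'   moments).
#' @param params a [pruning_params()].
#' @param pool `"sign_nonzero"` (default) or `"all_elements"`.
#' @return the thresholded connectivity matrix (TCM) as an `fcm` object with
#'   survivors' signed entities and delays; thresholds recorded in
#'   `$params$thresholds`.
#' @export
hard_threshold <- function(fcm, params = pruning_params(),
                           pool = c("sign_nonzero", "all_elements")) {
  stopifnot(inherits(fcm, "fcm"))
  pool <- match.arg(pool)
  # moments come from the matrix being thresholded the first time; they are
  # recorded so that re-applying the threshold is idempotent
  mom <- fcm$params$threshold_moments
  if (is.null(mom) || !identical(mom$pool, pool)) {
    moments <- function(x, what) {
      if (length(x) == 0) {
        warning("no ", what, " entries to threshold")
        return(c(mu = Inf, sigma = 0))
      }
      c(mu = mean(x), sigma = sd_pop(x))
    }
    if (pool == "sign_nonzero") {
      m_exc <- moments(fcm$fcm[fcm$fcm > 0], "excitatory")
      m_inh <- moments(abs(fcm$fcm[fcm$fcm < 0]), "inhibitory")
    } else {
      all_el <- as.vector(fcm$fcm)
      m_exc <- m_inh <- c(mu = mean(all_el), sigma = sd_pop(all_el))
    }
    mom <- list(exc = m_exc, inh = m_inh, pool = pool)
  }
  t_exc <- mom$exc[["mu"]] + params$n_exc * mom$exc[["sigma"]]
  t_inh <- mom$inh[["mu"]] + params$n_inh * mom$inh[["sigma"]]
  keep <- (fcm$fcm > 0 & fcm$fcm > t_exc) | (fcm$fcm < 0 & abs(fcm$fcm) > t_inh)
  fcm$fcm[!keep] <- 0
  fcm$delays_ms[!keep] <- 0
  fcm$zero_lag[!keep] <- FALSE
  fcm$params$threshold_moments <- mom
  fcm$params$thresholds <- list(n_exc = params$n_exc, n_inh = params$n_inh,
                                t_exc = t_exc, t_inh = t_inh, pool = pool)
  fcm
}
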