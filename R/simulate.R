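#' Simulation configuration
#'
#' Parameters of the spiking-network simulation. Dynamics follow the
#' two-variable quadratic integrate-and-reset (Izhikevich) model with the
#' canonical regular-spiking preset for excitatory neurons
#' (a = 0.02, b = 0.2, c = -65, d = 8) and the fast-spiking preset for
#' inhibitory ones (a = 0.1, b = 0.2, c = -65, d = 2). Spontaneous activity is
#' driven by stimulating one uniformly chosen neuron per 1 ms step with a
#' current pulse drawn from N(11, 2^2) for excitatory targets and N(7, 2^2)
#' for inhibitory ones. Excitatory synapses are plastic under an additive
#' pair-based STDP rule with a 20 ms time constant; inhibitory weights are
#' fixed.
#'
#' @param duration simulated time in seconds (default 3600, i.e. 1 h of
#'   spontaneous activity).
#' @param stim_exc,stim_inh `c(mean, sd)` of the stimulation current for
#'   excitatory / inhibitory targets.
#' @param stim_on logical; disable to study the silent limit.
#' @param stim_pulse_ms duration of each stimulation current pulse in ms
#'   (default 3). The stated amplitudes lie in the sustained-current
#'   tonic-firing range of the neuron models, so a pulse of a few
#'   milliseconds makes the stimulated neuron emit about one spike; the
#'   default is calibrated so the full-scale network settles in the 2-3
#'   spikes/s excitatory regime.
#' @param stdp_on logical; excitatory-weight plasticity switch.
#' @param a_plus,a_minus STDP potentiation / depression amplitudes.
#' @param tau_stdp STDP time constant (ms).
#' @param w_max excitatory weight ceiling (weights clipped to `[0, w_max]`).
#' @param i_const constant external current per neuron (scalar or vector;
#'   default 0) — useful for single-neuron characterization.
#' @param v_init_sd standard deviation of initial membrane-potential noise
#'   around -65 mV (default 0: deterministic rest initialization).
#' @param sampling_rate nominal sampling rate attached to the returned spike
#'   trains (Hz).
#' @param seed optional RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration = 3600, stim_exc = c(11, 2), stim_inh = c(7, 2),
                       stim_on = TRUE, stim_pulse_ms = 3, stdp_on = TRUE,
                       a_plus = 0.1, a_minus = 0.12, tau_stdp = 20, w_max = 10,
                       i_const = 0, v_init_sd = 0, sampling_rate = 10000,
                       seed = NULL) {
  stopifnot(duration > 0, tau_stdp > 0, w_max > 0, stim_pulse_ms >= 1)
  structure(list(duration = duration, stim_exc = stim_exc, stim_inh = stim_inh,
                 stim_on = stim_on, stim_pulse_ms = as.integer(stim_pulse_ms),
                 stdp_on = stdp_on, a_plus = a_plus,
                 a_minus = a_minus, tau_stdp = tau_stdp, w_max = w_max,
                 i_const = i_const, v_init_sd = v_init_sd,
                 sampling_rate = sampling_rate, seed = seed),
            class = "sim_config")
}

#' Izhikevich neuron parameter presets
#' @param type `"exc"` (regular spiking) or `"inh"` (fast spiking).
#' @return named numeric vector `(a, b, c, d)`.
#' @export
izhikevich_preset <- function(type = c("exc", "inh")) {
  type <- match.arg(type)
  if (type == "exc") c(a = 0.02, b = 0.2, c = -65, d = 8)
  else c(a = 0.1, b = 0.2, c = -65, d = 2)
}

#' Simulate spiking activity of a structural network
#'
#' Integrates the network on a 1 ms event grid with two 0.5 ms membrane
#' substeps. Presynaptic spikes deliver their weight as an impulse current to
#' the target after the link delay. Returns one spike train per neuron plus
#' the final (post-STDP) synaptic weight matrix.
#'
#' @param net a `structural_network` from [build_random_network()] or
#'   [build_scale_free_network()].
#' @param config a [sim_config()].
#' @return list with `spikes` (a [spike_train_set()], channels named
#'   `n0001...`), `swm_final` (matrix), `net`, `config`.
#' @export
simulate_network <- function(net, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- net$n_neurons
  type_int <- ifelse(net$types == "inh", 1L, 0L)
  pe <- izhikevich_preset("exc"); pi <- izhikevich_preset("inh")
  a <- ifelse(type_int == 0, pe["a"], pi["a"])
  b <- ifelse(type_int == 0, pe["b"], pi["b"])
  cc <- ifelse(type_int == 0, pe["c"], pi["c"])
  d <- ifelse(type_int == 0, pe["d"], pi["d"])
  nz <- which(net$swm != 0, arr.ind = TRUE)
  i_const <- rep_len(config$i_const, n)
  res <- sim_izhikevich_cpp(type_int,
                            as.integer(nz[, 1] - 1L), as.integer(nz[, 2] - 1L),
                            net$swm[nz], as.integer(net$delays_ms[nz]),
                            as.integer(round(config$duration * 1000)),
                            config$stim_exc[1], config$stim_exc[2],
                            config$stim_inh[1], config$stim_inh[2],
                            config$stim_on, config$stim_pulse_ms,
                            i_const, a, b, cc, d,
                            config$stdp_on, config$a_plus, config$a_minus,
                            config$tau_stdp, config$w_max, config$v_init_sd)
  ids <- sprintf("n%04d", seq_len(n))
  sp <- split(res$spike_time_ms / 1000,
              factor(res$spike_neuron, levels = seq_len(n)))
  names(sp) <- ids
  set <- spike_train_set(sp, config$sampling_rate, config$duration, ids)
  swm_final <- matrix(0, n, n)
  swm_final[nz] <- res$weights
  list(spikes = set, swm_final = swm_final, net = net, config = config)
}
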