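---
title: "Inferring excitatory and inhibitory functional connectivity with filtered cross-correlograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring excitatory and inhibitory functional connectivity with filtered cross-correlograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncch)
```

## The problem

Multi-electrode arrays (MEAs) record extracellular spiking from tens to
thousands of sites in cultured neuronal networks. A central analysis task is
to infer a *functional connectivity* graph — which recording sites influence
which — from the spike trains alone. Cross-correlogram methods handle the
excitatory side well: a presynaptic spike transiently raises the firing
probability of its target, producing a peak at a positive lag near the
synaptic delay. Inhibition is much harder: its signature is a *trough* (a
transient deficit of target spikes after a source spike), which is shallow,
requires a background of postsynaptic firing to be visible at all, and is
easily missed when the raw correlogram maximum is taken as the link
strength. This package implements a correlogram post-processing that makes
both signs detectable with one statistic, together with the simulation and
scoring machinery needed to validate it against a known ground truth.

## The estimator

For a reference train $x$ and target train $y$ with $N_x$ and $N_y$ spikes,
the normalized cross-correlation histogram (NCCH) over lag bins
$\tau \in [-W/2, W/2]$ of width $\Delta$ is

$$C_{xy}(\tau) = \frac{1}{\sqrt{N_x N_y}} \sum_{s} x(t_s)\, y(t_s + \tau),$$

i.e. the count of spike pairs at lag $\tau$ (target minus reference time)
normalized by the geometric mean of the spike counts. The normalization
bounds the correlogram in $[0, 1]$ (the autocorrelation of any train has a
unit bin at zero lag) and makes values comparable across pairs with
different rates. The filtered estimator (FNCCH) subtracts the within-window
mean and takes the signed extreme,

$$E_{xy} = F_{xy}(\tau^\*), \qquad
  \tau^\* = \arg\max_\tau \left| F_{xy}(\tau) \right|, \qquad
  F_{xy}(\tau) = C_{xy}(\tau) - \frac{1}{n_{\mathrm{bins}}}\sum_v C_{xy}(v).$$

A positive "entity" $E_{xy}$ is an excitatory link, a negative one an
inhibitory link; the lag $\tau^\*$ estimates the conduction delay and its
sign assigns direction ($\tau^\* > 0$: reference drives target). Mean
subtraction is what rescues inhibition: the trough becomes the largest
absolute deviation even when a modest peak exists elsewhere in the window.

Two conventions matter and are deliberate:

* **Mean over bins.** The subtracted term is the average of the
  $n_{\mathrm{bins}} = 2\lfloor (W/2)/\Delta \rfloor + 1$ lag bins, not a
  division by the window length in milliseconds. Only the true average makes
  a flat correlogram map to an exactly null result.
* **Floor binning on the sampling grid.** Each spike is assigned to the
  $\Delta$-wide bin $\lfloor s/\mathrm{bw} \rfloor$ of its integer sample
  index $s$, and the pair lag is the bin-index difference. Under this
  convention the direct time-stamp sweep (a pointer advanced over the target
  train inside each reference spike's window — cost proportional to the
  number of spike pairs inside windows, never to the recording length) is
  *exactly* the shifted product of the two binned trains, which is what the
  test suite's brute-force oracle computes.

Ties in the argmax are broken toward the smallest absolute lag, then toward
positive lag, favoring causal short-latency links; the tie-break is
deterministic and recorded here because flat-topped filtered correlograms do
occur on short recordings.

### Boundary re-filter

On weakly correlated pairs the filtered extreme occasionally lands as a
spurious negative value at the very edge of the window, producing a false
inhibitory link. `boundary_refilter()` (applied by default inside
`build_fcm()`) re-runs the peak search restricted to the central
$1 - 2 \cdot \texttt{tail\_fraction}$ of the window whenever an inhibitory
peak falls in the outer tails. The default `tail_fraction = 0.25` discards a
quarter of the window at each end during the re-search; the filtered values
themselves are not recomputed — the correction is a restricted argmax, which
may flip the polarity back to excitatory. Excitatory peaks and central
inhibitory peaks are never touched.

### Known limitation: the lag window caps detectable delays

A link whose conduction delay exceeds $W/2$ has its correlogram peak outside
the lag axis and is undetectable *by construction*. With the simulation
default $W = 25$ ms this means links slower than 12.5 ms are invisible; in
the bundled simulator, excitatory delays are uniform on 1–20 ms, so roughly
40% of excitatory ground-truth links cannot be recovered at the default
window, which caps the excitatory ROC AUC well below the inhibitory one
(inhibitory delays are 1 ms and always in-window). Widening the window
(e.g. `W = 50`) recovers those links at the cost of more variance per bin.
We keep $W = 25$ ms as the default because it is the parameterization the
in-silico validation standard prescribes; the cap is a property of that
parameterization, not of the estimator.

## From matrix to graph: pruning

`build_fcm()` returns the full signed functional connectivity matrix (FCM).
Two pruning stages turn it into a thresholded connectivity matrix (TCM):

1. **Spatio-temporal filter.** Links whose geometry is not physiological
   are removed: delay below `d_min` (default 1 ms, compatible with the
   fastest AMPA transmission — this also removes zero-lag co-activations,
   which are common-input artifacts, not synapses) or apparent propagation
   velocity `distance/delay` above `v_max` (default 400 mm/s).
2. **Hard threshold.** Excitatory entries must exceed
   $\mu + n_{exc}\sigma$ of the positive entries; inhibitory magnitudes must
   exceed $\mu + n_{inh}\sigma$ of the negative-entry magnitudes (defaults
   $n_{exc} = 2$, $n_{inh} = 1$). The moments are computed per sign over
   nonzero entries: pooling zeros would make thresholds density-dependent,
   and pooling signs would let the (more numerous) excitatory entries set
   the inhibitory threshold. A pooled mode (`pool = "all_elements"`) is
   available for comparison. $\sigma$ is the population standard deviation,
   and the inequality is strict, so a degenerate class with all entries
   equal keeps nothing — the conservative choice. The filter runs before the
   threshold so that non-physiological links do not inflate the moments; the
   order and all parameters are recorded in the result's provenance.

## The simulator: ground truth for validation

Because no experimental recording comes with its true wiring, validation
uses simulated networks whose synaptic weight matrix (SWM) is known.

**Wiring.** `build_random_network()` creates `n` neurons (4:1
excitatory:inhibitory, the ratio observed in cortical cultures), each
receiving exactly `in_degree` afferents drawn uniformly without
replacement: excitatory neurons get an 80/20 excitatory/inhibitory split
(mirroring the population ratio) and inhibitory neurons receive only
excitatory afferents; autapses are excluded. Weights are drawn from
$N(6, 1)$ for excitatory and $N(-5, 1)$ for inhibitory sources; inhibitory
delays are fixed at 1 ms, excitatory delays uniform on $\{1, \dots, 20\}$ ms
(the 1 ms floor respects the synaptic minimum).
`build_scale_free_network()` substitutes preferential-attachment growth on
the in-degree, with the same type, weight and delay conventions, for
studying the estimator on heavy-tailed topologies.

**Dynamics.** Each neuron follows the two-variable quadratic
integrate-and-reset (Izhikevich) model — regular-spiking preset
($a=0.02, b=0.2, c=-65, d=8$) for excitatory, fast-spiking
($a=0.1, b=0.2, c=-65, d=2$) for inhibitory — integrated on a 1 ms event
grid with two 0.5 ms membrane substeps, the model's reference scheme.
A presynaptic spike adds its weight to the target's input current after the
link delay (impulse synapse). Excitatory weights evolve under an additive
nearest-neighbour pair STDP rule ($\tau = 20$ ms, $A_+ = 0.1$,
$A_- = 0.12$, clipped to $[0, 10]$); inhibitory weights are fixed. The STDP
amplitudes are exposed in `sim_config()`; they are free parameters of the
model family and the defaults give a slight depression bias so that
uncorrelated firing does not inflate weights.

**Spontaneous activity.** One uniformly chosen neuron per 1 ms step
receives a stimulation current pulse drawn from $N(11, 2^2)$ (excitatory
targets) or $N(7, 2^2)$ (inhibitory targets). These amplitudes lie in the
sustained-current tonic-firing range of both neuron presets — a 1 ms
impulse of that size cannot reach threshold from rest, leaving the network
silent — so the pulse duration is a model parameter, `stim_pulse_ms`. Its
default (3 ms) was calibrated once so that the full-scale network (1000
neurons, in-degree 100) settles into the 2–3 spikes/s excitatory regime
with fast-spiking interneurons near 20 spikes/s, the regime the in-silico
validation standard operates in; it was not revisited afterwards. The
simulation is deterministic given the seed, and a zero-stimulation,
zero-noise run produces no spikes at all.

**What the generator emulates, and what it does not.** The simulated
activity reproduces the statistical features the estimator is sensitive to:
sparse random wiring with known signs and delays, mixed spiking/bursting
population dynamics with network-wide rate peaks, and rate asymmetry
between populations. It does *not* emulate electrode mixing (several
neurons per site), spike-detection errors, bursty non-stationarity over
hours, or spatial wiring structure — so green tests here demonstrate
correctness of the estimator on clean point-process data, not robustness to
every artifact of real MEA recordings.

## Scoring against ground truth

`confusion()`, `roc_auc()` and `mcc_curve()` compare a signed prediction
matrix with the SWM over all ordered off-diagonal pairs. Scores for a sign
class are the entity magnitudes of entries with that sign (others score 0);
truth positives are SWM entries of the matching sign. A predicted link
counts as a true positive only on the same ordered pair *with the same
polarity* — a wrong-sign detection on a true link is a false positive for
its own class and leaves the true link missed. No leniency is granted for
polysynaptic paths: a detected i→k link explained by i→j→k counts as a
false positive. The Matthews correlation coefficient uses the convention
MCC = 0 when its denominator vanishes (e.g. the empty-prediction cut).
Degree-distribution fits use closed-form Gaussian maximum likelihood with
R² on a Freedman–Diaconis density histogram, and log-log linear regression
on a logarithmically binned histogram for power laws. Truth is binarized
from the *final* (post-STDP) weight matrix; plasticity changes weights, not
topology, so the link set is essentially that of the initial wiring.

## Topology metrics

Thresholded matrices are projected to simple undirected graphs per sign
class (an edge joins two nodes when either directed link exists; the
metrics below have no directed variant in this workflow):

* **Clustering coefficient** $C_x = 2u / (v_x (v_x - 1))$ with $v_x$ the
  neighbors of $x$ (excluding $x$ — the only reading that gives $C = 1$ on
  a triangle) and $u$ the edges among them; nodes with fewer than two
  neighbors contribute 0.
* **Path length**: mean shortest-path distance over connected unordered
  pairs; disconnected pairs are excluded from numerator and denominator and
  their fraction is reported (the alternative — restricting to the giant
  component — changes both $C$ and $L$; exclusion keeps all detected nodes).
* **Small-world index** SWI $= (C_{net}/C_{rnd}) / (L_{net}/L_{rnd})$
  against the mean of 100 random equivalent surrogates. The default
  surrogate preserves the degree sequence (edge-swap randomization); a
  density-matched mode (same node and edge counts only) is available and is
  the automatic fallback for graphs too sparse to rewire. SWI $\gg 1$
  indicates a clustered yet short-pathed (small-world) topology.
* **Rich-club coefficient** RCC$(k) = 2E_{>k} / (N_{>k}(N_{>k}-1))$, the
  edge density among nodes of degree $> k$; levels with fewer than two such
  nodes are undefined and dropped. The curve is normalized by the surrogate
  ensemble mean, and a maximum normalized value above 1 flags a privileged
  hub sub-network.
* **Decimation study**: the same recording re-analyzed on progressively
  sparser uniform-stride subgrids of the electrode layout (largest stride
  leaving at least the requested electrode count, anchored at the grid
  origin, row-major tie-break). Topology estimates are expected to become
  unstable below roughly 100 recording sites, which is the reason
  high-density arrays are needed for small-world claims.

## Problem sizes used in the bundled checks

The test suite validates the correlogram sweep against a brute-force binned
convolution on hundreds of Poisson pairs, classifies 100 constructed
excitatory/inhibitory motifs, and checks the graph metrics against
enumeration oracles on a thousand random graphs of up to 50 nodes. The
in-silico detection scores are evaluated on two 250-neuron networks
(in-degree 25, same population ratios) simulated for 30 minutes — a
deliberately reduced replica of the full-scale study (1000 neurons,
in-degree 100, 1 hour, ten networks), which the same functions reproduce
unchanged via `build_random_network(1000)` and
`sim_config(duration = 3600)`. Scaling down is not free of scientific
consequences: with a quarter of the afferents, inhibitory interneurons fire
near 6–7 spikes/s instead of ~20, which is precisely the regime where
trough detectability degrades (per-bin counting noise roughly triples), so
inhibitory detection scores at the reduced scale sit well below their
full-scale counterparts. A single full-scale network run through the same
pipeline recovers near-perfect inhibitory classification (ROC AUC ≈ 0.96 at
30 min in our runs, rising with duration).

## Degenerate inputs and numerical choices

* Empty trains yield an all-zero, flagged correlogram and a null peak; pairs
  where both trains have fewer than 10 spikes are skipped in `build_fcm()`
  (correlogram variance dominates there; configurable).
* Duplicate same-channel same-sample spike stamps are collapsed with a
  warning on ingestion (a refractory period makes true duplicates
  non-physiological); times are snapped to the sampling grid and exposed in
  seconds, with integer sample indices carried alongside so binning is
  deterministic.
* Zero-lag peaks are retained in the FCM but flagged, and removed by the
  minimum-delay rule during spatio-temporal filtering.
* All simulation randomness flows through R's RNG: any run is reproducible
  from its seed, and the command-line tool writes a provenance file with
  every parameter needed to re-execute it.
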