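# fncch

Inference of **directed excitatory and inhibitory functional connectivity**
from multi-electrode array (MEA) spike-train recordings, via filtered and
normalized cross-correlation histograms — plus everything needed to validate
the estimator in silico: an Izhikevich spiking-network simulator with STDP
that provides a ground-truth synaptic weight matrix, ROC/MCC scoring of
inferred links, and graph-topology analysis (small-world index, rich-club
curves, electrode decimation).

## The method

For a reference train *x* and target train *y* (spike counts *N<sub>x</sub>*,
*N<sub>y</sub>*), the normalized cross-correlation histogram over lags
τ ∈ [−W/2, W/2] in bins of width Δ is

> C<sub>xy</sub>(τ) = (N<sub>x</sub>N<sub>y</sub>)<sup>−1/2</sup> Σ<sub>s</sub> x(t<sub>s</sub>) y(t<sub>s</sub> + τ)

computed directly on time stamps (a pointer sweep over the target train —
cost scales with coincident spike pairs, not recording length). The filtered
statistic subtracts the within-window mean and takes the signed extreme, the
link **entity**:

> E = F(τ\*), τ\* = argmax<sub>τ</sub> |F(τ)|, F(τ) = C(τ) − mean<sub>v</sub> C(v)

A positive entity is an excitatory link (correlogram peak), a negative one
an inhibitory link (trough) — the mean subtraction is what makes troughs
competitive with peaks in a single statistic. The lag τ\* estimates the
conduction delay and its sign the direction. The raw matrix is then pruned
by a spatio-temporal physiological filter (apparent velocity ≤ 400 mm/s,
delay ≥ 1 ms) and sign-specific hard thresholds (μ + 2σ excitatory,
μ + 1σ inhibitory).

## Worked example

```r
library(fncch)

# a pair with a known 4 ms excitatory motif
set.seed(1)
x <- unique(round(sort(runif(900, 0, 300)) * 1e4)) / 1e4
y <- x + 0.004
pk <- fncch_peak(ncch_pair(x, y, W = 25, delta = 1))
sprintf("entity %.3f at lag %g ms (%s)", pk$entity, pk$lag_ms, pk$polarity)
#> "entity 0.959 at lag 4 ms (excitatory)"

# in-silico validation: simulate a network with known wiring, infer, score
net <- build_random_network(250, in_degree = 25, seed = 11)
sim <- simulate_network(net, sim_config(duration = 1800, seed = 11))
sim$spikes
#> spike_train_set: 250 channels, 1871474 spikes, 1800 s at 10000 Hz

fcm <- build_fcm(sim$spikes, W = 25, delta = 1)
fcm
#> fcm: 250 channels, 21618 excitatory / 9507 inhibitory entries (W = 25 ms, bin = 1 ms, fncch)

roc_auc(fcm, sim$swm_final, "inhibitory")$auc   # vs ground-truth wiring
#> 0.675

tcm <- hard_threshold(fcm)
tcm
#> fcm: 250 channels, 729 excitatory / 1431 inhibitory entries (W = 25 ms, bin = 1 ms, fncch)
#>   thresholded (TCM); params recorded in $params

round(delay_length_distributions(tcm)$inhibitory$summary$delays, 2)
#>     p5    q25 median    q75    p95   mean
#>   0.00   0.00   1.00   3.00   5.00   1.88
```

The entity of the constructed motif is near 1 at exactly the imposed lag.
The simulated example runs a deliberately small network (250 neurons,
in-degree 25, 30 min) so it finishes in under a minute; detection scores
rise steeply with network scale and recording length — a full-scale run
(1000 neurons, in-degree 100) of the same pipeline yields inhibitory ROC
AUC ≈ 0.96, because fast-spiking interneurons then fire at the ~20 spikes/s
needed for trough detection. See the methods vignette
(`vignettes/fncch-methods.Rmd`) for the model, conventions and limitations.

Topology of a thresholded network:

```r
g <- graph_from_tcm(tcm, "excitatory")
small_world_index(g, n_surrogates = 100)   # SWI >> 1 = small world
rich_club_curve(g)$max_norm                # > 1 = rich club present
```

A command-line workflow (`simulate`, `infer`, `prune`, `evaluate`,
`topology`, `decimate`, `reproduce-insilico`) is installed at
`inst/cli/fncch-tools.R`; every run writes a JSON provenance sidecar.

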