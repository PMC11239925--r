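# circuitscope

Quantitative analysis of synaptic imaging, neuronal network activity and
miRNA target expression, built around the experimental readouts used to
study how the neuronal circular RNA Cdr1as buffers miR-7 activity to
control glutamatergic transmission in cortical neurons.

The package covers five analysis stages, each paired with a synthetic-data
generator that records ground truth so every estimator can be scored
without external data:

- **smFISH colocalization** (`otsu_mask`, `distance_map`,
  `spot_structure_distances`, `mutual_nearest_neighbors`,
  `coloc_significance`, `spot_density`) — spot-to-protein distances via an
  exact Euclidean distance transform with bilinear subpixel lookup, and
  RNA-RNA mutual-nearest-neighbor (MNN) colocalization with a uniform
  re-placement randomization null,
  `p = (1 + #{null >= obs}) / (1 + n_random)`.
- **Glutamate-release traces** (`detect_active_synapses`, `extract_traces`,
  `detect_events`, `spontaneous_frequency`, `evoked_probability`,
  `kde_summary`, `fit_standard_curve`) — event detection at 7x the baseline
  noise SD on 20 Hz traces; evoked release probability = successful
  stimuli / 20 field stimuli at 0.5 Hz, counting events exactly one frame
  after each stimulus.
- **MEA network metrics** (`detect_spikes`, `detect_bursts`,
  `detect_network_bursts`, `asynchrony_area`, `isi_cov`, `burst_peak`,
  `well_metrics`, `treatment_delta`) — the six well-level readouts: mean
  firing rate, burst frequency and duration, network asynchrony (area
  under the pooled inter-electrode cross-correlogram; 0 = perfect
  synchrony), oscillation (ISI CoV within network bursts) and burst peak.
- **Expression statistics** (`housekeeping_normalize`, `log2_fold_change`,
  `ddct`, `intersect_targets`, `target_shift_test`, `de_filter`,
  `simple_de_test`) — geometric-mean housekeeping normalization
  (Actb/Tubb5/Vinculin), comparative ddCT (`RQ = 2^-ddCT`), strict
  padj < 0.05 and |log2FC| > 0.5 DE thresholds, and the two-sided
  Mann-Whitney CDF-shift test of predicted miR-7 targets against genes
  lacking sites.
- **Gene-network inference** (`rank_predictors`, `step1_regulators`,
  `step2_connect`, `loso_cv`, `build_network`, `edge_recovery`) — two-step
  random-forest regression: top-10 predictors per phenotype-related gene,
  keep regulators overlapping two or more responses, then connect the kept
  regulators to miR-7 targets the same way; validated by
  leave-one-sample-out RMSE and the cosine similarity of prediction/truth
  differences.

## Worked example

Simulate an evoked-release experiment at the standard protocol (20 stimuli
at 0.5 Hz, 20 Hz imaging, 5 min of spontaneous activity), detect events and
recover the planted release parameters:

```r
library(circuitscope)

stim <- seq(2, 40, by = 2)                       # 20 stimuli at 0.5 Hz
truth <- gen_release_traces(200, frame_rate = 20, duration_s = 300,
                            spont_rate = 0.05, evoked_p = 0.4,
                            amp_sd_units = 10, stim_times = stim, seed = 42)
events <- detect_events(truth$traces, k_sigma = 7)
ep <- evoked_probability(events)
sf <- spontaneous_frequency(events[events$kind == "spontaneous", ],
                            duration_s = 300, synapse_ids = 1:200)
mean(ep$evoked_probability)   # 0.408  -- planted evoked_p was 0.4
mean(sf$freq_hz)              # 0.0488 -- planted spontaneous rate was 0.05 Hz

# perfectly synchronous 16-electrode well: asynchrony area is exactly 0
well <- gen_spike_trains(16, 600, "identical", rate = 1, seed = 42)
asynchrony_area(well$trains)  # 0

# spots planted on a protein mask sit at zero distance
m <- matrix(FALSE, 64, 64); m[20:40, 20:40] <- TRUE
fld <- gen_spot_field(400, m, coloc_fraction = 0.6, jitter_sd = 0.5, seed = 42)
dm <- distance_map(structure_mask(m, pixel_size = 0.215))
median(spot_structure_distances(fld$spots, dm))  # 0 um (most spots on-structure)
```

The mean evoked probability (0.408) and spontaneous frequency (0.0488 Hz)
recover the planted generator parameters within sampling error; the
asynchrony area of a well whose electrodes carry identical spike trains is
exactly 0, the perfect-synchrony limit of the metric.

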