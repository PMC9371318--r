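# sccapacity

Quality metrics for single-cell gene-expression measurements, in bits.

Different single-cell measurement methods — smFISH or HCR labeling read out
by microscopy or flow cytometry, fluorescent protein read out after
different treatments — record the same biology with very different
fidelity, and scale-dependent summaries like signal-to-noise ratio do not
compare across methods. `sccapacity` scores a method by the **channel
capacity** between an environmental stimulus ladder (e.g. 8 inducer
concentrations) and the per-cell measured values: the maximum mutual
information

$$C = \max_p \; \sum_j \sum_k p_j\, Q_{k|j} \log_2
  \frac{Q_{k|j}}{\sum_{j'} p_{j'} Q_{k|j'}}$$

over input distributions $p$, where $Q_{k|j} = n_{k|j}/N_j$ is the
empirical transition matrix built by histogram-binning the per-cell values
at each stimulus level. $C$ is the log2 of the effective number of stimulus
levels the measurement can distinguish; a higher-quality measurement
transmits more bits. The maximization is solved with the Blahut–Arimoto
algorithm with certified upper/lower capacity bounds as the stopping rule.

The package provides:

- `blahut_arimoto()`, `mutual_information()`, `reverse_channel()`,
  `input_update()` — the capacity solver, plus `capacity_bruteforce()`, an
  exhaustive simplex-grid oracle for small channels;
- `freedman_diaconis_width()`, `make_edges()`,
  `empirical_transition_matrix()`, `initial_bin_count()`,
  `select_bin_count()`, `capacity_bin_sweep()` — equal-width binning with a
  Freedman–Diaconis-seeded, capacity-plateau bin-doubling selection rule
  (doubling stops when a doubling adds ≤ 0.1 bits; the previous count is
  kept);
- `run_study()`, `method_capacity()`, `compare_methods()` — the study
  pipeline: per-replicate capacities at the selected bin count, aggregation
  to mean ± sample SD, and measurand-matched method rankings;
- `bio_channel_params()`, `measurement_channel_params()`,
  `simulate_expression()`, `simulate_measurement()`,
  `generate_split_sample_fixture()` — a two-channel (Hill dose–response
  biology → noisy measurement) simulator emulating a split-sample design;
- `read_cell_table()`, `read_transition_matrix()`, `write_report()` and a
  thin command-line interface (`inst/cli/capacity.R`) with `run`, `sweep`,
  `channel` and `simulate` subcommands.

## Worked example

Simulate a split-sample study in which the same simulated cultures are
measured by a low-noise and a high-noise method, then rank the methods:

```r
library(sccapacity)

specs <- list(
  microscopy_like = measurement_channel_params(multiplicative_noise_sd = 0.15,
                                               background_mean = 20, background_sd = 10),
  cytometry_like  = measurement_channel_params(multiplicative_noise_sd = 1.2,
                                               background_mean = 20, background_sd = 10))

cells <- generate_split_sample_fixture(specs, bio_channel_params(),
                                       n_replicates = 3, n_cells_per_level = 1000,
                                       seed = 1)
report <- run_study(cells, eps = 1e-4, threshold_bits = 0.1)
report
#> Method                       Measurand  N_B  Channel capacity
#> microscopy_like              RNA        64   1.81 ± 0.01 bits
#> cytometry_like               RNA        340  0.77 ± 0.05 bits
```

Each row is one measurement method: `N_B` is the number of histogram bins
selected by the doubling rule for that method, and the capacity is the mean
± sample standard deviation over the three biological replicates. The
low-noise method transmits about 1.81 bits of the stimulus ladder (it can
effectively distinguish about $2^{1.81} \approx 3.5$ of the 8 levels) while
heavy multiplicative noise cuts that to 0.77 bits — the capacity gap *is*
the quality difference between the two measurement processes, in an
absolute, method-independent unit. `report$rankings$RNA` holds the same
numbers at full precision, ranked.

Direct capacity of a known channel:

```r
blahut_arimoto(diag(8))$capacity_bits
#> [1] 3
```

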