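# smadtier

Tiered modeling and trajectory analysis of heterogeneous TGF-β/SMAD
signaling in single cells.

Live-cell imaging of fluorescent SMAD reporters shows that genetically
identical epithelial cells answer the same TGF-β dose with qualitatively
different dynamics of the nuclear-to-cytoplasmic (nuc/cyt) SMAD2 ratio:
non-responders, transient pulses, or sustained activation. `smadtier` is
an analysis toolkit for this problem, aimed at quantitative/systems
biologists working with single-cell signaling trajectories. It provides:

* a **mechanistic ODE model** of the pathway — ligand–receptor binding
  and trafficking, SMAD2 phosphorylation, SMAD2–SMAD4 complex formation
  and nucleocytoplasmic shuttling, and a transcriptional negative
  feedback acting on the receptors — with event-driven stimulus
  protocols (ligand steps and replenishment, receptor and transcription
  inhibitors) and the nuc/cyt observables;
* **χ² parameter estimation**: multistart Latin-hypercube +
  Levenberg–Marquardt fitting with profiled measurement noise, and
  *subpopulation* fits in which all kinetic constants stay shared and
  only five protein pools may rescale within 0.5–2×;
* **constrained dynamic time warping** (cDTW): symmetric-step DTW with
  an elastic cap (`max_run`) on consecutive same-direction warp steps,
  local cost |x−y|, path-length normalization; plus hierarchical
  clustering into signaling classes, the jump statistic for the cluster
  number, silhouettes (s = (b−a)/max(a,b)) and class mapping;
* **ensemble simulation** with mean-preserving log-normal protein noise
  split into a correlated (shared) and an uncorrelated (per-protein)
  magnitude, calibrated by comparing distributions of the signaling
  features E (first-peak amplitude), L (300-min level), E/L and T (peak
  time); class-transition, feedback-depletion and parameter-entropy
  analyses (H = −Σ qᵢ log₂ qᵢ over the k classes, max log₂ 6 ≈ 2.585
  bits);
* **heterogeneity statistics**: Gaussian-kernel local density scores,
  mutual-information fractions MI/(H(X)+H(Y)), and sister-cell
  divergence with bootstrap effect sizes;
* a **synthetic trajectory generator** that emulates tracked
  single-cell imaging tables (six latent classes, log-normal protein
  variation, cell-state drift, frame noise, divisions with lineage mode,
  spatial positions), so everything runs without external data.

## Worked example

```r
library(smadtier)

## simulate the pathway under a 100 pM step
p <- default_parameters()
sim <- simulate_pathway(p, step_protocol(100))
r <- sim$observables[, "ratio_s2"]
max(r)                        # 2.51  -- peak nuc/cyt SMAD2 ratio
sim$time[which.max(r)]        # 95    -- peak time (min)

## medium depletion of a 25 pM stimulus
s25 <- simulate_pathway(p, step_protocol(25, 2880), seq(0, 2880, 5))
ligand_depletion_time(s25, 0.05) / 60   # 17.7 h to reach 5 %

## cluster a synthetic dose-response population into signaling classes
cfg <- synthetic_config(n_cells = 600, noise = noise_spec(0.03, 0.03),
                        meas_sd = 0.01, drift_sd = 0.01, seed = 11)
ts  <- generate_population(cfg)
thin <- thin_trajectories(ts, 3)              # 15-min grid
D   <- dissimilarity_matrix(thin, cdtw_config(max_run = 2))
js  <- jump_statistic(D, 2:10)
js$k[which.max(js$J)]                         # 6 -- chosen cluster number
cm  <- hierarchical_classes(D, 6, thin)
mean(silhouette_scores(D, cm$labels) > 0)     # 1.00 by class
mean(silhouette_scores(D, ts$cells$dose_pM) > 0)  # 0.34 by dose
```

The numbers above are what the listed calls print with the stated seeds:
the model's first peak falls inside the first two hours; a 25 pM
stimulus is cell-depleted from the medium in well under 20 h; the jump
statistic selects six classes; and grouping cells by signaling class
separates the trajectories far better than grouping by stimulus dose.

## Analysis workflow

`analysis/` holds the numbered workflow over the package functions, each
step writing tables to `results/`:

| step | what it does |
|------|--------------|
| `01_simulate_data.R` | synthetic dose-response and lineage datasets |
| `02_cluster_classes.R` | cDTW matrix, jump statistic, six classes, silhouettes |
| `03_fit_population.R` | multistart population-average fit, depletion and refractoriness predictions |
| `04_fit_subpopulations.R` | pool-only fits to the 100 pM class medians |
| `05_noise_calibration.R` | correlated/uncorrelated noise grid, direct-ensemble comparator |
| `06_feedback_and_entropy.R` | dose/feedback class shifts, transition matrices, parameter entropy |
| `07_heterogeneity_stats.R` | density, MI fractions, sister-cell divergence |

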