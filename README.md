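# eegcluster

Unsupervised, adaptive clustering of fixed-length epileptic EEG segments.

Supervised seizure-stage classifiers need labeled EEG, and labeling is
expensive expert work. `eegcluster` implements a fully unsupervised
alternative for users working with segmented single-channel recordings
(clinical researchers, BCI/neuro-signal engineers): it discovers the stage
structure of a set of segments without labels and without pre-specifying the
number of clusters.

The chain is:

1. **Joint denoising** — CEEMDAN (complete ensemble empirical mode
   decomposition with adaptive noise) splits each segment into intrinsic mode
   functions (IMFs); modes whose Pearson correlation ρ with the input falls
   below 0.3 are discarded; the reconstruction is then wavelet-thresholded
   (db5, universal threshold σ̂√(2 ln N), σ̂ from the MAD of the finest detail
   level).
2. **Features** — 12 descriptors per segment: mean, RMS, skewness,
   fluctuation index, Hjorth activity/mobility/complexity, Shannon entropy,
   mean Teager energy ψ̄ with ψ(n) = x(n)² − x(n−1)x(n+1), two relative band
   powers (4–13, 13–45 Hz), wavelet energy entropy; z-scored.
3. **Embedding** — exact t-SNE to 2-D/3-D (per-point bandwidths calibrated to
   a target perplexity by bisection; Student-t low-dimensional kernel).
4. **Adaptive DBSCAN** — the sparrow search algorithm (SSA) optimizes
   (Eps, MinPts) by maximizing a silhouette-based fitness over the embedded
   points; cluster count and density parameters come out of the optimization,
   not out of the user's head.
5. **Evaluation** — silhouette (SC), Calinski–Harabasz (CH), Davies–Bouldin
   (DBI), and a coefficient-of-variation composite that weights each
   indicator by its dispersion across algorithms
   (W_j = V_j / ΣV, V_j = S_j / A_j) and scores each algorithm by
   Σ_j W_j·r_ij after inverting negative indicators and normalizing columns.

A seeded generator of EEG-like multi-class segments (`synth_config()`,
`generate_dataset()`) makes the whole chain testable without any recording,
and CSV/EDF readers and writers cover every intermediate artifact.

## Worked example

Three spectrally distinct synthetic stages, end to end:

```r
library(eegcluster)

classes <- list(
  synth_class(c(2.5, 4),  amplitude = 3,   spike_rate = 3,
              spike_amplitude = 2, name = "ictal"),
  synth_class(c(8, 13),   amplitude = 1,   name = "alpha"),
  synth_class(c(25, 45),  amplitude = 1.5, spike_rate = 0.5,
              spike_amplitude = 4, name = "fast"))
ds <- generate_dataset(synth_config(n_per_class = 50, classes = classes,
                                    seed = 0))
ds
#> <labeled_dataset> 150 segments, 3 classes, fs=200 Hz, 1024 samples each

run <- run_pipeline(pipeline_config(ds, out_dir = tempfile(), seed = 0,
                                    denoise = list(method = "wavelet"),
                                    ssa = ssa_params(itermax = 50, pop = 20),
                                    log_level = "error"))
run
#> <pipeline_run> 150 segments -> 3 clusters (noise 0)
#>   eps=30.2 minPts=29 silhouette=0.9447
#>   SC=0.9447 CH=13634.09 DBI=0.0789

table(truth = ds$labels, found = run$labels)
#>      found
#> truth  0  1  2
#>     0 50  0  0
#>     1  0 50  0
#>     2  0  0 50
```

The optimizer settled on Eps = 30.2 (in t-SNE coordinate units) and
MinPts = 29, found three clusters with no noise points, and the clusters
coincide exactly with the generating stages. SC close to 1 and DBI close to
0 say the embedded clusters are tight and far apart; CH is large for the
same reason (its scale grows with separation and sample count, so only
comparisons at fixed data are meaningful).

Scoring a table of quality indices for several algorithms:

```r
tab <- read_metric_table_csv(system.file("extdata",
         "clustering_benchmark_indices.csv", package = "eegcluster"))
cv_composite(tab)
#> Coefficient-of-variation composite scores
#>   weights: SC=0.0464  CH=0.2176  DBI=0.7359
#>   SSA-DBSCAN   0.67955
#>   DBSCAN       0.50866
#>   K-medoids    0.32428
#>   ISODATA      0.28749
#>   K-means      0.20988
#>   GMM          0.07205
```

DBI varies most across the six algorithms, so it gets the largest weight;
the adaptive SSA-DBSCAN row ranks first.

A thin command-line front end with `synth` / `denoise` / `features` /
`embed` / `cluster` / `evaluate` / `run` subcommands lives at
`inst/cli/eegcluster.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/eegcluster.R", package="eegcluster"))')" \
  synth --n-per-class 20 --out demo_data
```

## Methods documentation

`vignettes/eeg-adaptive-clustering.Rmd` documents the model and its
assumptions, all tunable parameters with their defaults and rationale, what
the synthetic generator does and does not emulate, the numerical
conventions, and known limitations (including why joint denoising cannot
beat plain wavelet thresholding at very low input SNR, and why
silhouette-guided selection can merge genuinely similar stages).
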