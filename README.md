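# mitoganglia

Quantification of 3D mitochondrial morphology inside enteric
(submucosal) ganglia from confocal image stacks, with the downstream
group statistics and patient/control classification.

Submucosal ganglia — clusters of enteric neuron cell bodies in the colon
wall — are accessible by routine colonoscopy. Immunofluorescence stacks
of biopsied ganglia carry two kinds of candidate disease markers: the
volume of the ganglion itself, and the morphology of the mitochondrial
network inside it (fragmentation, mass, branching). This package
implements the full analysis chain for such data, for image analysts and
biostatisticians working on enteric neurodegeneration:

* **Segmentation.** Mitochondrial voxels must pass two rules: a local
  contrast rule — the response of a 5×5 Gaussian filter (σ = 2, per
  slice) must be ≥ 1.25 × the background estimated by a 10×10 average
  filter — and a global Otsu threshold computed on the
  illumination-corrected stack (slice minus its 20×20 average, clamped
  at 0; 256-bin histogram; foreground strictly above the threshold that
  maximizes between-class variance). Connected components (26-connected
  by default) with fewer than 8 voxels or more than 10⁶ voxels are
  removed; components intersecting the ganglion mask are kept whole.
* **Morphometrics.** Per object: volume; surface/body split by one
  6-connected erosion; topology-preserving 3D skeletonization; skeleton
  *nodes* (endpoints and branchpoints alike, i.e. skeleton voxels with
  ≠ 2 neighbours) with cumulative node degrees (total skeleton voxels in
  all incident branches); anisotropic skeleton length. Per ganglion:
  GanglionVolume plus 7 mitochondrial features (MitoCount,
  MitoVolumeMean, MitoVolumeTotal, MitoSurfaceFractionMean,
  MitoNodesMean, MitoNodeDegreeMean, MitoSkeletonLengthMean).
* **Statistics.** Permutation test on the absolute mean difference
  (default 100,000 label shuffles, add-one p-value); Spearman
  correlations with an average-linkage clustermap; ROC/AUC (trapezoidal,
  equal to the pairwise-ordering probability); PCA on z-scored features.
* **Classification.** Linear ν-SVM (ν = 0.01, "1% outliers") on the 7
  mitochondrial features with 100 × stratified 5-fold cross-validation,
  and a combined two-threshold classifier: predict *patient* when the
  SVM score is at/above its 0.6 quantile AND the ganglion volume is
  at/below its 0.4 quantile (the quantiles encode a 60/40 prior class
  mix).
* **Simulation.** `simulate_stack()` renders ground-truthed synthetic
  stacks (tubular/branched objects in an ellipsoidal ganglion,
  illumination gradient, Gaussian PSF, Poisson photon noise, 12-bit);
  `simulate_cohort()` draws two-group log-normal feature cohorts with
  imposed effect directions. Everything downstream is testable against
  known truth.

Conventions: voxel arrays are `[y, x, z]` (1-based); lengths in µm; the
axial step defaults to 0.18 µm, the lateral pixel size must be supplied.
See the methods vignette (`vignettes/mitoganglia-methods.Rmd`) for the
full model description and design rationale.

## Worked example

Segment one simulated ganglion stack and extract its feature vector:

```r
library(mitoganglia)

sim     <- simulate_stack(stack_sim_spec(seed = 1))   # 128x128x20, 30 objects
stack16 <- adjust_to_16bit(sim$stack)                 # 12-bit -> 16-bit
seg     <- segment_stack(stack16, sim$truth$ganglion)
seg$report$n_components
#> [1] 30

geom   <- voxel_geometry(0.1, 0.1, 0.18)              # um per voxel
shapes <- lapply(seg$components, component_shape,
                 dim_stack = dim(stack16$voxels), geometry = geom)
ganglion_features(shapes, ganglion_volume(sim$truth$ganglion, geom),
                  metadata = list(ganglion_id = "sim01"))
#>   GanglionVolume MitoCount MitoVolumeMean MitoVolumeTotal ...
#>         196.2864    0.1528         0.1334          0.0204 ...
```

All 30 simulated objects are recovered. `MitoCount` is objects per µm³
of ganglion volume; `MitoVolumeTotal` is the summed mitochondrial volume
as a fraction of ganglion volume (a mitochondrial-mass proxy).

Group statistics and classification on a simulated 65-patient/41-control
ganglion cohort with the default effect directions (patients: smaller
ganglia, more mitochondria, higher mitochondrial mass):

```r
co <- simulate_cohort(cohort_sim_spec(
  n_per_group = c(patient = 65L, control = 41L), seed = 2))

permutation_test(co$GanglionVolume[co$group == "patient"],
                 co$GanglionVolume[co$group == "control"],
                 n_perm = 100000, seed = 3)
#> permutation test: |mean difference| = 9793.84, p = 0.000359996 (100000 shuffles)

mito <- co[, setdiff(names(default_cohort_features()), "GanglionVolume")]
repeated_cv_auc(mito, co$group, n_repeats = 100, k = 5, seed = 4)
#> repeated CV: 100 x 5-fold, mean AUC = 0.822 (range 0.716-0.878)

m <- train_linear_svm(mito, co$group)
combined_classify(m$scores, co$GanglionVolume, co$group)$confusion
#> confusion: TP 22, FP 2, TN 39, FN 43 | sensitivity 0.338, specificity 0.951
```

The smaller-ganglion effect is highly significant, the mitochondrial
feature panel discriminates the groups well above chance, and the
conjunctive combined classifier lands in its characteristic
high-specificity regime.

Full pipelines (stacks → features → stats → classification) run from one
YAML config via `run_pipeline()` or the CLI's `run-all`; outputs are
`features.csv`, per-object tables, JSON reports and a log that records
every threshold and seed, and re-running a config reproduces them
byte-identically.

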