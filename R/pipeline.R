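# End-to-end orchestration: stacks -> segmentation -> features ->
# statistics -> classification, driven by one config with one top-level
# seed. Every stage seed is derived deterministically from it, so a
# stage re-run in isolation reproduces its in-pipeline stream.

#' Read a pipeline configuration
#'
#' YAML (or JSON) with fields: `geometry` (dx, dy, dz), `manifest` (list
#' of entries with `stack`, `ganglion_mask` or `roi`, and metadata:
#' ganglion_id, subject_id, group, side, optional clinical scores),
#' `segmentation` (connectivity, min_voxels, max_voxels), `stats`
#' (n_perm), `classification` (n_repeats, k, q_score, q_volume, rule,
#' outlier_fraction), `subsample` (optional n), `seed`, `output_dir`,
#' `bit_depth` of the input stacks (12 or 16).
#'
#' @param path Config file.
#' @return Config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  for (req in c("geometry", "manifest", "output_dir")) {
    if (is.null(config[[req]])) stop("config is missing '", req, "'")
  }
  for (e in config$manifest) {
    if (is.null(e$stack) || !file.exists(e$stack)) {
      stop("manifest references a missing stack: ", e$stack %||% "<absent>")
    }
    src <- e$ganglion_mask %||% e$roi
    if (is.null(src) || !file.exists(src)) {
      stop("manifest entry '", e$ganglion_id %||% "?",
           "' references a missing ganglion mask/ROI: ", src %||% "<absent>")
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Validates the config (fail-fast, before any computation), then for
#' every manifest entry: reads the stack, adjusts 12-bit input to 16
#' bit, builds the ganglion mask (from a mask TIFF or by rasterizing a
#' ROI JSON), segments mitochondria, computes per-object shapes and the
#' per-ganglion feature vector. Afterwards it runs the group statistics
#' (permutation test per feature) and, when both groups are present and
#' large enough, the repeated-CV SVM and the combined classifier. All
#' thresholds, filter counts and seeds are logged; re-running with the
#' same config reproduces identical outputs.
#'
#' @param config A config list, `pipeline_config`, or path to a YAML file.
#' @return Invisibly, the output directory. Files written:
#'   `features.csv`, `objects.csv`, `segmentation.json`, `stats.json`,
#'   `classify.json` (when applicable), `run.log`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  logmsg <- function(...) {
    cat(sprintf("[%s] %s\n", "INFO", sprintf(...)), file = logf, append = TRUE)
  }
  g <- config$geometry
  geometry <- voxel_geometry(g$dx, g$dy %||% g$dx, g$dz %||% 0.18)
  seg <- config$segmentation %||% list()
  connectivity <- seg$connectivity %||% 26
  min_voxels <- seg$min_voxels %||% 8
  max_voxels <- seg$max_voxels %||% 1e6
  bit_depth <- config$bit_depth %||% 12L
  logmsg("seed %d; geometry dx=%g dy=%g dz=%g um", seed,
         geometry$dx, geometry$dy, geometry$dz)
  logmsg("segmentation: local rule 5px Gaussian sigma 2 vs 1.25 x 10x10 background; 20x20 illumination correction; Otsu 256 bins; component size in [%g, %g]; connectivity %d",
         min_voxels, max_voxels, as.integer(connectivity))

  rows <- list(); obj_rows <- list(); seg_reports <- list()
  for (e in config$manifest) {
    gid <- e$ganglion_id %||% basename(e$stack)
    stack <- read_stack(e$stack, geometry = geometry, bit_depth = bit_depth)
    if (stack$bit_depth == 12L) stack <- adjust_to_16bit(stack)
    gmask <- if (!is.null(e$ganglion_mask)) {
      read_mask(e$ganglion_mask)
    } else {
      rasterize_roi(read_roi(e$roi), dim(stack$voxels))
    }
    sres <- segment_stack(stack, gmask, connectivity = connectivity,
                          min_voxels = min_voxels, max_voxels = max_voxels)
    logmsg("%s: otsu %.1f; components raw %d, removed by size %d, removed by gate %d, kept %d",
           gid, sres$report$otsu_threshold, sres$report$n_components_raw,
           sres$report$n_removed_size, sres$report$n_removed_gate,
           sres$report$n_components)
    shapes <- lapply(sres$components, component_shape,
                     dim_stack = dim(stack$voxels), geometry = geometry)
    meta <- e[intersect(names(e), c("ganglion_id", "subject_id", "group",
                                    "side", "UPDRSIII", "SumMMSE",
                                    "SchwabEngland", "age"))]
    gvol <- ganglion_volume(gmask, geometry)
    rows[[length(rows) + 1L]] <- ganglion_features(shapes, gvol, meta)
    for (i in seq_along(shapes)) {
      s <- shapes[[i]]
      obj_rows[[length(obj_rows) + 1L]] <- data.frame(
        ganglion_id = gid, object_id = i, volume_vox = s$volume_vox,
        volume_um3 = s$volume_um3, surface_vox = s$surface_vox,
        body_vox = s$body_vox, skeleton_vox = s$skeleton_vox,
        skeleton_length_um = s$skeleton_length_um, node_count = s$node_count,
        stringsAsFactors = FALSE)
    }
    seg_reports[[gid]] <- sres$report
  }
  features <- do.call(rbind, rows)

  sub <- config$subsample
  if (!is.null(sub) && !is.null(sub$n) && sub$n < nrow(features)) {
    features <- subsample_ganglia(features, sub$n,
                                  seed = derive_seed(seed, "subsample"))
    logmsg("subsampled to %d ganglia", nrow(features))
  }
  write_feature_table(features, file.path(out_dir, "features.csv"))
  if (length(obj_rows) > 0L) {
    utils::write.csv(do.call(rbind, obj_rows), file.path(out_dir, "objects.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(schema_version = 1L, seed = seed,
                            ganglia = seg_reports),
                       file.path(out_dir, "segmentation.json"),
                       auto_unbox = TRUE, digits = NA)

  feat_cols <- intersect(names(default_cohort_features()), names(features))
  stats_out <- list(schema_version = 1L, seed = seed)
  if (length(unique(features$group)) == 2L &&
      all(table(features$group) >= 2)) {
    n_perm <- (config$stats %||% list())$n_perm %||% 100000L
    pseed <- derive_seed(seed, "stats")
    tests <- list()
    for (f in feat_cols) {
      v <- features[[f]]
      ok <- is.finite(v)
      if (sum(ok & features$group == "patient") < 2 ||
          sum(ok & features$group == "control") < 2) next
      pt <- permutation_test(v[ok & features$group == "patient"],
                             v[ok & features$group == "control"],
                             n_perm = n_perm, seed = pseed)
      tests[[f]] <- list(observed = pt$observed, p_value = pt$p_value,
                         n_perm = n_perm)
    }
    stats_out$permutation_tests <- tests
    logmsg("permutation tests on %d features, %d shuffles", length(tests),
           n_perm)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  cls <- config$classification %||% list()
  mito_cols <- setdiff(feat_cols, "GanglionVolume")
  complete <- stats::complete.cases(features[, mito_cols, drop = FALSE])
  kfold <- cls$k %||% 5L
  if (length(unique(features$group[complete])) == 2L &&
      all(table(features$group[complete]) >= kfold)) {
    cvseed <- derive_seed(seed, "classification")
    cv <- repeated_cv_auc(features[complete, mito_cols], features$group[complete],
                          positive = "patient",
                          n_repeats = cls$n_repeats %||% 100L, k = kfold,
                          outlier_fraction = cls$outlier_fraction %||% 0.01,
                          seed = cvseed)
    m <- train_linear_svm(features[complete, mito_cols],
                          features$group[complete], positive = "patient",
                          outlier_fraction = cls$outlier_fraction %||% 0.01,
                          check_width = FALSE)
    comb <- combined_classify(m$scores, features$GanglionVolume[complete],
                              features$group[complete], positive = "patient",
                              q_score = cls$q_score %||% 0.6,
                              q_volume = cls$q_volume %||% 0.4,
                              rule = cls$rule %||% "AND")
    jsonlite::write_json(
      list(schema_version = 1L, seed = cvseed,
           cv = list(mean_auc = cv$mean_auc, auc = cv$auc,
                     n_repeats = cv$n_repeats, k = cv$k),
           combined = list(score_threshold = comb$score_threshold,
                           volume_threshold = comb$volume_threshold,
                           rule = comb$rule,
                           sensitivity = comb$confusion$sensitivity,
                           specificity = comb$confusion$specificity,
                           tp = comb$confusion$tp, fp = comb$confusion$fp,
                           tn = comb$confusion$tn, fn = comb$confusion$fn)),
      file.path(out_dir, "classify.json"), auto_unbox = TRUE, digits = NA)
    logmsg("classification: mean CV AUC %.3f; combined sensitivity %.3f specificity %.3f",
           cv$mean_auc, comb$confusion$sensitivity, comb$confusion$specificity)
  }
  invisible(out_dir)
}

#' Random ganglion subsampling with a per-subject floor
#'
#' Uniform random selection of `n` rows that, whenever feasible, retains
#' at least `min_per_side` ganglia per subject and colon side (the
#' sampling design of the original cohort). When the mandatory floor
#' alone exceeds `n`, the floor is relaxed to 1 and then 0.
#'
#' @param table Data frame with `subject_id` and `side` columns.
#' @param n Rows to keep (1 <= n <= nrow(table)).
#' @param min_per_side Floor per subject-side stratum (default 2).
#' @param seed Optional seed.
#' @return Subset of `table` (original row order preserved).
#' @export
subsample_ganglia <- function(table, n, min_per_side = 2L, seed = NULL) {
  stopifnot(is.data.frame(table))
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (n > nrow(table)) stop("n exceeds the number of ganglia")
  if (n == nrow(table)) return(table)
  with_seed(seed, {
    strata <- interaction(table$subject_id, table$side, drop = TRUE)
    floor_k <- min_per_side
    repeat {
      mandatory <- integer(0)
      for (s in levels(strata)) {
        idx <- which(strata == s)
        k <- min(floor_k, length(idx))
        if (k > 0L) mandatory <- c(mandatory, sample(idx, k))
      }
      if (length(mandatory) <= n || floor_k == 0L) break
      floor_k <- floor_k - 1L
    }
    mandatory <- mandatory[seq_len(min(length(mandatory), n))]
    rest <- setdiff(seq_len(nrow(table)), mandatory)
    extra <- if (n > length(mandatory)) sample(rest, n - length(mandatory)) else integer(0)
    table[sort(c(mandatory, extra)), , drop = FALSE]
  })
}
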