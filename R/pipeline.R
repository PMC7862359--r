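# End-to-end orchestration: generate/ingest -> featurize -> initial
# classification -> supervised map -> component planes -> tree
# classification -> report. Deterministic under a fixed seed.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a register) or `"files"` (read
#'   `animals.csv`/`movements.csv` from `registry_dir`).
#' @param herds_per_type Herds per archetype in synthetic mode.
#' @param seed Seed propagated to every stochastic stage.
#' @param study_year Study year.
#' @param registry_dir Directory with register CSVs (files mode); if it
#'   contains `truth_labels.csv`, recovery statistics are reported.
#' @param grid Map dimensions `c(X, Y)`.
#' @param epochs Map training epochs.
#' @param tree A `herd_tree`, a path to a tree YAML, or `NULL` for
#'   [build_default_tree()].
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            herds_per_type = 20L, seed = 1L,
                            study_year = 2017L, registry_dir = NULL,
                            grid = c(10L, 10L), epochs = 30L,
                            tree = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(registry_dir)) {
    stop("files mode needs registry_dir")
  }
  structure(list(mode = mode, herds_per_type = as.integer(herds_per_type),
                 seed = as.integer(seed), study_year = as.integer(study_year),
                 registry_dir = registry_dir, grid = as.integer(grid),
                 epochs = as.integer(epochs), tree = tree,
                 out_dir = out_dir),
            class = "pipeline_config")
}

resolve_tree <- function(tree) {
  if (is.null(tree)) build_default_tree()
  else if (inherits(tree, "herd_tree")) tree
  else read_tree(tree)
}

load_stage_registry <- function(config) {
  if (config$mode == "synthetic") {
    gen <- generate_registry(config$herds_per_type, seed = config$seed,
                             study_year = config$study_year)
    list(registry = gen$registry, truth = gen$truth)
  } else {
    reg <- read_registry(file.path(config$registry_dir, "animals.csv"),
                         file.path(config$registry_dir, "movements.csv"),
                         study_year = config$study_year)
    tl <- file.path(config$registry_dir, "truth_labels.csv")
    truth <- if (file.exists(tl)) {
      readr::read_csv(tl, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
    } else NULL
    list(registry = reg, truth = truth)
  }
}

#' Run the full classification pipeline
#'
#' Stages: load or generate the register; compute the nine herd variables;
#' apply the initial breeding/dairy/beef/mixed classification; train a
#' supervised (BDK) map on the nine variables against the initial classes;
#' classify every herd with the decision tree; compute
#' threshold-sensitivity bands for every decision node herds reach; and,
#' when truth labels exist, the per-type and overall label recovery. With
#' `out_dir` set, writes `features.csv`, `classified.csv`, `report.yaml`
#' and a `model/` directory (weights, normaliser, one component-plane CSV
#' per variable). Outputs are identical under identical config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- load_stage_registry(config)
  registry <- stages$registry
  truth <- stages$truth
  herd_ids <- if (!is.null(truth)) {
    truth$herd_id[truth$role == "primary"]
  } else NULL

  features <- compute_features(registry, herd_ids)
  features$initial_class <- initial_classification(features)

  fmat <- as.matrix(features[, the_nine_variables])
  rownames(fmat) <- features$herd_id
  norm <- fit_normalizer(fmat)
  Z <- apply_normalizer(norm, fmat)
  model <- train_bdk(Z, features$initial_class, grid_shape = config$grid,
                     schedule = training_schedule(epochs = config$epochs,
                                                  seed = config$seed),
                     norm = norm)
  resub <- mean(predict_bdk(model, Z) == features$initial_class)

  tree <- resolve_tree(config$tree)
  classified <- classify_herds(tree, features)

  bands <- list()
  for (nid in names(tree$nodes)) {
    bands[[nid]] <- tryCatch(
      threshold_sensitivity(tree, nid, features),
      error = function(e) NULL
    )
  }
  bands <- bands[!vapply(bands, is.null, logical(1))]

  recovery <- NULL
  if (!is.null(truth)) {
    joined <- dplyr::inner_join(
      classified, truth[truth$role == "primary", c("herd_id", "herd_type")],
      by = "herd_id", suffix = c("_pred", "_true")
    )
    recovery <- joined |>
      dplyr::group_by(herd_type = .data$herd_type_true) |>
      dplyr::summarise(
        n = dplyr::n(),
        recovered = sum(.data$herd_type_pred == .data$herd_type_true),
        rate = .data$recovered / .data$n, .groups = "drop"
      )
  }

  report <- structure(list(
    n_herds = nrow(features),
    counts_by_type = dplyr::count(classified, .data$herd_type),
    counts_by_group = dplyr::count(classified, .data$main_group),
    tree_stats = tree_stats(tree),
    bdk_resubstitution = resub,
    sensitivity = bands,
    recovery = recovery,
    recovery_overall = if (!is.null(recovery)) {
      sum(recovery$recovered) / sum(recovery$n)
    } else NA_real_,
    provenance = list(seed = config$seed, mode = config$mode,
                      herds_per_type = config$herds_per_type,
                      grid = config$grid, epochs = config$epochs,
                      package_version =
                        as.character(utils::packageVersion("herdtyper")))
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    write_artifacts(config$out_dir, registry, features, classified, model,
                    tree, report, truth)
  }
  report
}

write_artifacts <- function(dir, registry, features, classified, model,
                            tree, report, truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_registry(registry, file.path(dir, "registry"))
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(dir, "registry", "truth_labels.csv"),
                     progress = FALSE)
  }
  readr::write_csv(features, file.path(dir, "features.csv"), progress = FALSE)
  readr::write_csv(classified[, c("herd_id", "herd_type", "main_group",
                                  "n_decisions")],
                   file.path(dir, "classified.csv"), progress = FALSE)
  mdir <- file.path(dir, "model")
  dir.create(mdir, showWarnings = FALSE)
  utils::write.csv(model$grid$W, file.path(mdir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(variable = model$grid$var_names,
               mean = model$grid$norm$mean, sd = model$grid$norm$sd),
    file.path(mdir, "normalizer.csv"), row.names = FALSE
  )
  for (v in model$grid$var_names) {
    utils::write.csv(component_plane(model$grid, v),
                     file.path(mdir, paste0("plane_", gsub("[^A-Za-z0-9]", "_", v), ".csv")),
                     row.names = FALSE)
  }
  write_tree(tree, file.path(dir, "tree.yaml"))
  yaml::write_yaml(report_as_list(report), file.path(dir, "report.yaml"))
  invisible(dir)
}

report_as_list <- function(report) {
  list(
    n_herds = report$n_herds,
    counts_by_type = setNames(as.list(report$counts_by_type$n),
                              report$counts_by_type$herd_type),
    counts_by_group = setNames(as.list(report$counts_by_group$n),
                               report$counts_by_group$main_group),
    tree_stats = report$tree_stats,
    bdk_resubstitution = report$bdk_resubstitution,
    recovery_overall = report$recovery_overall,
    sensitivity = lapply(report$sensitivity, function(b) {
      list(node = b$node_id, variable = b$variable, threshold = b$threshold,
           low = b$low, high = b$high, n = b$n)
    }),
    provenance = report$provenance
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$n_herds, " herds classified\n", sep = "")
  tab <- x$counts_by_type
  cat("  types: ", paste0(tab$herd_type, "=", tab$n, collapse = " "), "\n",
      sep = "")
  cat("  BDK resubstitution accuracy: ",
      sprintf("%.3f", x$bdk_resubstitution), "\n", sep = "")
  if (!is.na(x$recovery_overall)) {
    cat("  truth-label recovery: ",
        sprintf("%.1f%%", 100 * x$recovery_overall), "\n", sep = "")
  }
  invisible(x)
}

#' Two-variable to three-variable rule-extraction walkthrough
#'
#' Reproduces the canonical rule-extraction episode on synthetic data:
#' a supervised map trained on `pDairyBreed` and `pCalvedAnimals` with the
#' initial classes shows the unclassified non-breeding herds as the
#' low-`pCalvedAnimals` region; adding `pOutMovesToSL` and histogramming
#' that variable over the unclassified region reveals two sub-populations —
#' fattening herds (most out-moves straight to slaughter) and store/rearing
#' herds (almost none) — separated near 0.5. The suggested split is the
#' midpoint of the sparsest bins between the histogram's two peaks.
#'
#' @param config A [pipeline_config()].
#' @return List: `features`, `stage1` / `stage2` (BDK models),
#'   `region_nodes` (unclassified-region node indices on the stage-2 map),
#'   `histogram` (of `pOutMovesToSL` over that region), `plane_means`
#'   (stage-1 `pCalvedAnimals` plane means per node label) and
#'   `suggested_threshold`.
#' @export
rule_extraction_walkthrough <- function(config = pipeline_config()) {
  stages <- load_stage_registry(config)
  truth <- stages$truth
  herd_ids <- if (!is.null(truth)) truth$herd_id[truth$role == "primary"]
              else NULL
  features <- compute_features(stages$registry, herd_ids)
  labels <- initial_classification(features)
  sched <- training_schedule(epochs = config$epochs, seed = config$seed)

  vars1 <- c("pDairyBreed", "pCalvedAnimals")
  m1 <- as.matrix(features[, vars1])
  norm1 <- fit_normalizer(m1)
  stage1 <- train_bdk(apply_normalizer(norm1, m1), labels,
                      grid_shape = config$grid, schedule = sched,
                      norm = norm1)
  plane_calved <- component_plane(stage1$grid, "pCalvedAnimals")
  plane_means <- tapply(as.vector(plane_calved), stage1$node_label, mean)

  vars2 <- c(vars1, "pOutMovesToSL")
  m2 <- as.matrix(features[, vars2])
  norm2 <- fit_normalizer(m2)
  stage2 <- train_bdk(apply_normalizer(norm2, m2), labels,
                      grid_shape = config$grid, schedule = sched,
                      norm = norm2)
  region <- which(stage2$node_label == "unknown")
  asg <- map_records(stage2$grid, apply_normalizer(norm2, m2),
                     record_ids = features$herd_id)
  hist_sl <- region_histogram(asg, region, features$pOutMovesToSL)

  list(
    features = features,
    stage1 = stage1, stage2 = stage2,
    region_nodes = region,
    histogram = hist_sl,
    plane_means = plane_means,
    suggested_threshold = histogram_antimode(hist_sl)
  )
}

# midpoint of the sparsest bins between the histogram's two main peaks
histogram_antimode <- function(h) {
  counts <- h$counts; mids <- h$mids
  i1 <- which.max(counts)
  far <- abs(mids - mids[i1]) > 0.2
  if (!any(far & counts > 0)) return(NA_real_)
  i2 <- which(far)[which.max(counts[far])]
  lo <- min(i1, i2); hi <- max(i1, i2)
  if (hi - lo < 2) return(mean(mids[c(lo, hi)]))
  inner <- (lo + 1):(hi - 1)
  sparsest <- inner[counts[inner] == min(counts[inner])]
  mean(mids[sparsest])
}
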