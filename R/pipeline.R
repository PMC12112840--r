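#' Simulate synthetic inputs to files
#'
#' Writes either a parameter cohort (`what = "cohort"`: `cohort.csv` with
#' an `image_id` and the four parameters, plus `labels.csv` with the
#' generating cluster per row) or a spine annotation file
#' (`what = "annotations"`: native JSON plus the ground-truth parameter
#' table) into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param what `"cohort"` or `"annotations"`.
#' @param cfg A [cohort_config()] (default [table1_config()]).
#' @param n_annotations Number of spines when `what = "annotations"`
#'   (sampled from `cfg`'s first rows of the simulated cohort).
#' @param template [spine_geometry_config()] for annotation generation.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, what = c("cohort", "annotations"),
                         cfg = table1_config(), n_annotations = 20L,
                         template = spine_geometry_config()) {
  what <- match.arg(what)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(cfg)
  if (what == "cohort") {
    rows <- cbind(image_id = sprintf("sim-%04d", seq_len(nrow(sim$parameters))),
                  sim$parameters)
    paths <- list(cohort = file.path(out_dir, "cohort.csv"),
                  labels = file.path(out_dir, "labels.csv"))
    write_parameters_table(rows, paths$cohort)
    utils::write.csv(data.frame(image_id = rows$image_id,
                                cluster = sim$labels),
                     paths$labels, row.names = FALSE)
  } else {
    idx <- seq_len(min(n_annotations, nrow(sim$parameters)))
    gen <- generate_cohort_annotations(sim$parameters[idx, , drop = FALSE],
                                       template)
    paths <- list(annotations = file.path(out_dir, "annotations.json"),
                  truth = file.path(out_dir, "truth.csv"))
    write_annotations(gen$annotations, paths$annotations)
    write_parameters_table(gen$truth, paths$truth)
  }
  message("seed: ", cfg$seed)
  invisible(paths)
}

#' Measure a cohort of annotations
#'
#' Loads an annotation file, validates each record, measures the valid
#' ones and skips (with a message listing the issue codes) the invalid
#' ones. Deterministic, hence idempotent.
#'
#' @param annotations Path to a native annotation JSON file, or a list of
#'   `radiograph_annotation` objects.
#' @param cfg A [measurement_config()].
#' @param out_csv Optional path for the parameter table.
#' @return Data frame with `image_id` and the four parameters, one row per
#'   valid radiograph.
#' @export
run_measure <- function(annotations, cfg = measurement_config(),
                        out_csv = NULL) {
  if (is.character(annotations)) annotations <- load_annotations(annotations)
  rows <- list()
  for (a in annotations) {
    issues <- validate_annotation(a)
    if (length(issues)) {
      message("skipping '", a$image_id, "': ", paste(issues, collapse = ", "))
      next
    }
    m <- measure_radiograph(a, cfg)
    rows[[length(rows) + 1L]] <-
      cbind(image_id = a$image_id, as.data.frame(m$parameters))
  }
  if (!length(rows)) stop("no measurable annotations")
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write_parameters_table(out, out_csv)
  out
}

#' Run the phenotyping analysis end to end
#'
#' Standardize -> (optionally PCA) -> scan candidate k -> select k ->
#' k-means -> per-cluster summaries, phenotype names, comparison table and
#' standardized profiles.
#'
#' @param params Data frame/matrix with the four parameter columns, or a
#'   path to a parameter CSV (an `image_id` column is carried through).
#' @param feature_space `"standardized"` (default) or `"pca_scores"`:
#'   whether k-means runs on the z-scored parameters or on retained PCA
#'   scores.
#' @param k Fixed number of clusters; `NULL` (default) selects k from the
#'   scan via `strategy`.
#' @param strategy Model-selection strategy for [select_k()].
#' @param k_range Candidate k values scanned.
#' @param seed Integer seed for all clustering randomness.
#' @param variance_model Post hoc variance model, `"welch"` or `"pooled"`.
#' @param pca_variance Cumulative explained-variance threshold when
#'   `feature_space = "pca_scores"`.
#' @param out_dir Optional directory; when given, writes `labels.csv`,
#'   `kscan.csv`, `table1.csv` (formatted), `table1_full.csv` (full
#'   precision), `profile.csv` and `pca_scores.csv`.
#' @return List with `model`, `scan`, `k`, `summary`, `phenotypes`,
#'   `assignments`, `table1`, `profile`, `pca`, `scaler`.
#' @export
run_phenotype <- function(params,
                          feature_space = c("standardized", "pca_scores"),
                          k = NULL, strategy = "silhouette_max",
                          k_range = 2:8, seed = 0L,
                          variance_model = "welch", pca_variance = 0.95,
                          out_dir = NULL) {
  feature_space <- match.arg(feature_space)
  if (is.character(params)) params <- read_parameters_table(params)
  params <- as.data.frame(params)
  ids <- params$image_id %||% sprintf("obs-%04d", seq_len(nrow(params)))
  X <- params[, PARAM_NAMES]
  std <- standardize(X)
  pca <- pca_fit_transform(std$Z, variance_threshold = pca_variance)
  F <- switch(feature_space, standardized = std$Z, pca_scores = pca$scores)
  scan <- scan_k(F, k_range = k_range, seed = seed)
  k <- as.integer(if (is.null(k)) select_k(scan, strategy) else k)
  if (k < 2L) stop("the cluster-comparison statistics require k >= 2")
  model <- attr(scan, "models")[[as.character(k)]] %||%
    kmeans_fit(F, k, seed = seed + k)
  summ <- cluster_summary(X, model$labels)
  phen <- label_clusters(summ)
  tab <- build_table1(X, model$labels, variance_model)
  prof <- profile_zscores(summ, std$scaler)
  assignments <- data.frame(image_id = ids, cluster = model$labels,
                            phenotype = unname(phen[as.character(model$labels)]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(assignments, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(scan), file.path(out_dir, "kscan.csv"),
                     row.names = FALSE)
    utils::write.csv(format_table1(tab), file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(out_dir, "table1_full.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(cluster = rownames(prof), as.data.frame(prof)),
                     file.path(out_dir, "profile.csv"), row.names = FALSE)
    utils::write.csv(cbind(image_id = ids, as.data.frame(pca$scores)),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  }
  list(model = model, scan = scan, k = k, summary = summ, phenotypes = phen,
       assignments = assignments, table1 = tab, profile = prof, pca = pca,
       scaler = std$scaler)
}
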