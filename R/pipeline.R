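#' Pipeline configuration
#'
#' Bundles the per-stage configurations, IO paths and the global seed that
#' propagates to every stochastic stage. Can be read from a YAML file whose
#' top-level keys mirror the argument names.
#'
#' @param image_dir directory of input images (PNG/TIFF/CSV) with a
#'   `labels.csv` (`filename,label`), or `NULL` when `simulate` is given.
#' @param out_dir directory for artifacts (created if missing).
#' @param simulate `NULL`, or a list `list(n_per_class =, width =, height =)`
#'   to generate a phantom cohort instead of reading images.
#' @param fcm,glcm,exclusion stage configs.
#' @param selection list: `method` (nsga3/ga/pso/de) and overrides.
#' @param folds outer CV folds.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(image_dir = NULL, out_dir = "thermocad_out",
                            simulate = list(n_per_class = 50L),
                            fcm = fcm_config(), glcm = glcm_config(),
                            exclusion = NULL,
                            selection = list(method = "nsga3"),
                            folds = 10L, seed = 1L) {
  structure(list(image_dir = image_dir, out_dir = out_dir,
                 simulate = simulate, fcm = fcm, glcm = glcm,
                 exclusion = exclusion, selection = selection,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(y), c("image_dir", "out_dir", "simulate",
                                   "selection", "folds", "seed")))
    cfg[[nm]] <- y[[nm]]
  if (!is.null(y$fcm)) cfg$fcm <- do.call(fcm_config, y$fcm)
  if (!is.null(y$glcm)) cfg$glcm <- do.call(glcm_config, y$glcm)
  if (!is.null(y$exclusion)) cfg$exclusion <- do.call(exclusion_config,
                                                      y$exclusion)
  cfg$folds <- as.integer(cfg$folds)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a phantom dataset to disk
#'
#' Renders a balanced phantom cohort and writes one PNG per image plus a
#' `labels.csv` (`filename,label`), the layout [run_pipeline()] reads.
#'
#' @param n_per_class images per class (>= 1).
#' @param seed integer seed.
#' @param out_dir target directory.
#' @param width,height image size.
#' @return invisibly, the labels data.frame.
#' @export
simulate_dataset <- function(n_per_class, seed = 1L, out_dir,
                             width = 64L, height = 64L) {
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  cohort <- phantom_cohort(n_per_class, seed, width, height)
  for (im in cohort$images)
    write_thermal_image(im, file.path(out_dir, im$id))
  labels <- data.frame(filename = vapply(cohort$images, function(im) im$id,
                                         character(1)),
                       label = as.character(cohort$labels))
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  invisible(labels)
}

#' Run the full thermogram analysis pipeline
#'
#' Orchestrates the stages end to end: acquire images (from disk or the
#' phantom generator), segment each one, extract the 25-feature table,
#' select features, and evaluate the classifier suite with cross-validation
#' on the three feature regimes. Intermediates are persisted under
#' `cfg$out_dir`: `features.csv`, `selection.json`, `report.json`,
#' `metrics.csv` and (for the first image) the segmentation masks as PNGs.
#' Deterministic stages reproduce their artifacts bitwise on re-run with the
#' same config.
#'
#' @param cfg a [pipeline_config()].
#' @param progress print stage banners.
#' @return list with `features` (data.frame), `labels`, `selection`
#'   (a `selection_result`), `reports` (per-regime evaluation reports),
#'   `accuracy` (regime x classifier matrix), `selected_report`
#'   (CV report on the selected subset).
#' @export
run_pipeline <- function(cfg = pipeline_config(), progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("[1/5] acquiring images")
  if (!is.null(cfg$image_dir)) {
    lab_path <- file.path(cfg$image_dir, "labels.csv")
    if (!file.exists(lab_path))
      stopf("acquire stage: missing %s", lab_path)
    lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
    imgs <- lapply(file.path(cfg$image_dir, lab$filename), function(p)
      tryCatch(read_thermal_image(p),
               error = function(e) stopf("acquire stage: %s (%s)",
                                         conditionMessage(e), basename(p))))
    labels <- factor(lab$label)
  } else {
    sim <- cfg$simulate
    cohort <- phantom_cohort(sim$n_per_class %||% 50L, cfg$seed,
                             sim$width %||% 64L, sim$height %||% 64L)
    imgs <- cohort$images
    labels <- cohort$labels
  }

  say("[2/5] segmentation + feature extraction (%d images)", length(imgs))
  feats <- feature_table(imgs, fcm = cfg$fcm, glcm = cfg$glcm,
                         exclusion = cfg$exclusion, progress = progress)
  utils::write.csv(cbind(feats, label = labels),
                   file.path(cfg$out_dir, "features.csv"), row.names = FALSE)
  seg1 <- segment_thermogram(imgs[[1]], cfg$fcm, cfg$exclusion)
  png::writePNG(seg1$cluster_map / max(seg1$cluster_map),
                file.path(cfg$out_dir, "cluster_map.png"))
  png::writePNG(seg1$roi_mask * 1,
                file.path(cfg$out_dir, "roi_mask.png"))
  png::writePNG(seg1$binary_image * 1.0,
                file.path(cfg$out_dir, "binary_image.png"))

  say("[3/5] feature selection (%s)", cfg$selection$method %||% "nsga3")
  X <- as.matrix(feats[, setdiff(names(feats), "id")])
  Xs <- scale(X)
  method <- cfg$selection$method %||% "nsga3"
  sel_fun <- switch(method, nsga3 = nsga3_select, ga = ga_select,
                    pso = pso_select, de = de_select,
                    stopf("unknown selection method '%s'", method))
  sel_args <- cfg$selection[setdiff(names(cfg$selection), "method")]
  selection <- do.call(sel_fun, c(list(table = Xs, labels = labels,
                                       seed = cfg$seed), sel_args))
  jsonlite::write_json(
    list(method = selection$method,
         best_scalar = selection$best_scalar,
         chosen_subset = selection$chosen_names,
         history = selection$history,
         pareto = lapply(selection$pareto, function(p)
           list(features = colnames(X)[p$bits], error = p$error,
                nf_frac = p$nf_frac))),
    file.path(cfg$out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  say("[4/5] cross-validated evaluation")
  plan <- make_folds(labels, k = cfg$folds, seed = cfg$seed)
  reports <- run_experiment(X, labels, plan = plan)
  selected_report <- cross_validate(
    X[, selection$chosen_subset, drop = FALSE], labels, plan)

  say("[5/5] writing report")
  acc <- attr(reports, "accuracy")
  metrics_tab <- do.call(rbind, lapply(names(reports), function(reg) {
    m <- t(vapply(reports[[reg]]$classifiers, function(cl) cl$pooled,
                  numeric(4)))
    data.frame(regime = reg, classifier = rownames(m), m, row.names = NULL)
  }))
  utils::write.csv(metrics_tab, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = as.data.frame(acc),
         selected = as.list(selected_report$classifiers$svm$pooled),
         chosen_subset = selection$chosen_names,
         seed = cfg$seed),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)

  list(features = feats, labels = labels, selection = selection,
       reports = reports, accuracy = acc, selected_report = selected_report)
}
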