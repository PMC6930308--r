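#' End-to-end pipeline configuration
#'
#' Collects every tunable of the study workflow for one sample type. The
#' input is either a generator configuration (synthetic run) or a CSV of
#' measured spectra.
#'
#' @param generator a [generator_config()], used when `csv_path` is
#'   `NULL`; its `sample_type` and `seed` drive the run.
#' @param csv_path optional path to a replicate-level spectra CSV.
#' @param sample_type `"dried"` or `"fresh"`; defaults to the generator's.
#' @param preprocess a [preprocess_config()].
#' @param fraction calibration proportion (default 0.70).
#' @param split_method `"kennard_stone"` or `"random"`.
#' @param cv_splits,cv_thickness venetian-blinds parameters (defaults 10
#'   and 1).
#' @param max_lv largest latent-variable count searched (default 20).
#' @param cut_wavenumber spectral truncation point; `NULL` uses
#'   [default_cut()] for the sample type.
#' @param out_dir optional artifact directory; `NULL` keeps everything in
#'   memory.
#' @param seed integer seed for every stochastic stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, csv_path = NULL,
                            sample_type = NULL,
                            preprocess = preprocess_config(),
                            fraction = 0.70,
                            split_method = c("kennard_stone", "random"),
                            cv_splits = 10, cv_thickness = 1,
                            max_lv = 20, cut_wavenumber = NULL,
                            out_dir = NULL, seed = 1L) {
  split_method <- match.arg(split_method)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(csv_path)) {
    if (is.null(generator)) {
      generator <- generator_config(sample_type = if (is.null(sample_type))
        "dried" else sample_type, seed = seed)
    }
    sample_type <- generator$sample_type
  } else {
    if (!file.exists(csv_path)) stop("spectra file not found: ", csv_path)
    if (is.null(sample_type)) sample_type <- "dried"
  }
  structure(
    list(generator = generator, csv_path = csv_path,
         sample_type = sample_type, preprocess = preprocess,
         fraction = fraction, split_method = split_method,
         cv_splits = cv_splits, cv_thickness = cv_thickness,
         max_lv = max_lv,
         cut_wavenumber = if (is.null(cut_wavenumber))
           default_cut(sample_type) else cut_wavenumber,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments
#' (`sample_type`, `fraction`, `split_method`, `cv_splits`,
#' `cv_thickness`, `max_lv`, `cut_wavenumber`, `seed`, `csv_path`,
#' `out_dir`, and the generator fields prefixed `generator_`, e.g.
#' `generator_n_leaves_per_class`).
#'
#' @param path YAML file of `key: value` pairs.
#' @param ... overrides applied after the file is read.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  gen_keys <- grep("^generator_", names(vals), value = TRUE)
  gen_args <- stats::setNames(vals[gen_keys], sub("^generator_", "", gen_keys))
  vals[gen_keys] <- NULL
  if (length(gen_args) || is.null(vals$csv_path)) {
    if (!is.null(vals$sample_type)) gen_args$sample_type <- vals$sample_type
    if (!is.null(vals$seed)) gen_args$seed <- vals$seed
    vals$generator <- do.call(generator_config, gen_args)
  }
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

#' Run the complete varietal-discrimination workflow
#'
#' Sequence: obtain replicate-level spectra (synthetic or CSV), convert to
#' absorbance if needed, average the instrument replicates, apply SNV and
#' the Savitzky-Golay derivative, split each class 70/30 with
#' Kennard-Stone, fit a full-spectrum PLS-DA with venetian-blinds
#' cross-validated latent-variable selection, compute the three
#' variable-importance indicators, truncate the spectra at the configured
#' cut point, refit on the retained window, and report per-class
#' sensitivity/specificity/accuracy for cross-validation and test set of
#' both models.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a list of class `nirs_pipeline_result` with elements `leaves`
#'   (averaged absorbance spectra), `preprocessed`, `split`, `folds`,
#'   `model_full`, `model_truncated`, `importance`, `report` (combined
#'   data frame), `report_lines` (aligned text) and `config`.
#' @export
run_nirs_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)

  if (is.null(config$csv_path)) {
    say("generating synthetic ", config$sample_type, " spectra (seed ",
        config$seed, ")")
    raw <- generate_spectra(config$generator)
  } else {
    say("reading spectra from ", config$csv_path)
    raw <- read_spectra(config$csv_path, expected_type = config$sample_type)
  }
  if (raw$unit == "reflectance") raw <- reflectance_to_absorbance(raw)
  leaves <- average_replicates(raw)
  say(nrow(leaves$x), " leaf spectra after replicate averaging")

  pp_cfg <- config$preprocess
  no_center <- preprocess_config(apply_snv = pp_cfg$apply_snv,
                                 sg_window = pp_cfg$sg_window,
                                 sg_polyorder = pp_cfg$sg_polyorder,
                                 sg_deriv = pp_cfg$sg_deriv,
                                 mean_center = FALSE)
  pp <- preprocess_chain(leaves, no_center)$spectra

  split <- split_per_class(pp, config$fraction, config$split_method,
                           seed = config$seed)
  cal <- subset_samples(pp, match(split$calibration_ids, pp$sample_id))
  test <- subset_samples(pp, match(split$test_ids, pp$sample_id))
  folds <- venetian_blinds(cal$sample_id, config$cv_splits,
                           config$cv_thickness)
  class_order <- class_levels(pp)

  fit_and_report <- function(cal_s, test_s, label) {
    say("fitting ", label, " model (", length(cal_s$axis), " wavenumbers)")
    model <- fit_plsda(cal_s, class_order, max_lv = config$max_lv,
                       folds = folds)
    say("  selected ", model$n_lv, " latent variables")
    cv_cm <- confusion(cal_s$labels, model$cv$assignments[cal_s$sample_id],
                       class_order)
    test_cm <- if (nrow(test_s$x) > 0) {
      confusion(test_s$labels, predict(model, test_s)$assigned, class_order)
    } else {
      matrix(0L, length(class_order), length(class_order),
             dimnames = list(true = class_order, assigned = class_order))
    }
    list(model = model,
         report = class_report(cv_cm, test_cm, label, model$n_lv,
                               length(cal_s$axis)))
  }

  full <- fit_and_report(cal, test, "full_spectrum")
  profile <- importance_profile(full$model, cal, config$cut_wavenumber)
  cal_t <- truncate_spectra(cal, config$cut_wavenumber)
  test_t <- truncate_spectra(test, config$cut_wavenumber)
  say("truncating at ", config$cut_wavenumber, " cm^-1: ",
      length(cal$axis), " -> ", length(cal_t$axis), " variables")
  trunc <- fit_and_report(cal_t, test_t, "truncated")

  report <- rbind(full$report, trunc$report)
  lines <- render_report(report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spectra(leaves, file.path(config$out_dir, "leaf_spectra.csv"))
    write_assignment(split, file.path(config$out_dir, "split.csv"))
    write_assignment(folds, file.path(config$out_dir, "cv_folds.csv"))
    write_plsda_model(full$model, file.path(config$out_dir, "model_full"))
    write_plsda_model(trunc$model, file.path(config$out_dir, "model_truncated"))
    write_importance(profile, file.path(config$out_dir, "importance.csv"))
    render_report(report, file.path(config$out_dir, "report.csv"))
    writeLines(lines, file.path(config$out_dir, "report.txt"))
  }

  structure(
    list(leaves = leaves, preprocessed = pp, split = split, folds = folds,
         model_full = full$model, model_truncated = trunc$model,
         importance = profile, report = report, report_lines = lines,
         config = config),
    class = "nirs_pipeline_result"
  )
}

#' @export
print.nirs_pipeline_result <- function(x, ...) {
  cat("NIR varietal-discrimination pipeline (", x$config$sample_type,
      " leaves)\n", sep = "")
  cat("  calibration ", length(x$split$calibration_ids), " / test ",
      length(x$split$test_ids), " leaves\n", sep = "")
  cat("  full model: ", x$model_full$n_lv, " LVs on ",
      length(x$model_full$axis), " wavenumbers; truncated: ",
      x$model_truncated$n_lv, " LVs on ", length(x$model_truncated$axis),
      " wavenumbers (cut ", x$importance$cut_wavenumber, " cm^-1)\n",
      sep = "")
  cat(x$report_lines, sep = "\n")
  invisible(x)
}
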