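#' Default study configuration
#'
#' Configuration for an end-to-end synthetic study: structure sampling,
#' acquisition plan, tasks to run and their cross-validation settings. Any
#' element can be overridden via `...`; `plan` takes an [acquisition_plan()].
#'
#' @param ... overrides of the default fields.
#' @return A named list (class `study_config`).
#' @export
study_config <- function(...) {
  cfg <- list(
    n_proteins = 35L,
    seed = 7L,
    plan = acquisition_plan(),
    tasks = c("class", "fractions"),
    class_threshold = 0.2,
    n_splits = 3L,
    test_frac = 0.2,
    k_grid = c(25, 50, 100),
    classifier_grid = NULL,     # NULL = default_param_grid("anova_f", "svc_rbf")
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package", call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$plan)) raw$plan <- do.call(acquisition_plan, raw$plan)
  do.call(study_config, raw)
}

#' Run the full synthetic study
#'
#' One call reproduces the whole workflow: sample structures, build the
#' seeded library, bin probe axes, assemble and label frames, and run the
#' requested tasks — `"class"` (ANOVA-F + SVC over random 80:20 group
#' splits), `"class_loo"` (the same pipeline under LOO-by-protein),
#' `"fractions"` (the beta/alpha SVR regression chain under LOO),
#' `"helix_length"` (ANOVA-F + AdaBoost over random splits) and
#' `"sheet_registry"` (independent SVR models with and without the
#' antiparallel feature override). When `out_dir` is set, a summary JSON and
#' per-task tables are written there.
#'
#' @param config a [study_config()] or path to a YAML file.
#' @return List with the library, frames and per-task `eval_report`s plus a
#'   `summary` list of aggregate metrics.
#' @export
run_study <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  known <- c("class", "class_loo", "fractions", "helix_length",
             "sheet_registry")
  unknown <- setdiff(config$tasks, known)
  if (length(unknown))
    stop("unknown task(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  specs <- sample_structures(config$n_proteins, seed = config$seed)
  library <- build_library(specs, config$plan, seed = config$seed)
  library <- bin_probe_axes(library)
  frame <- assemble_frame(library, mode = "full")

  reports <- list()
  summary <- list(n_spectra = length(library$spectra),
                  n_proteins = length(library$structures),
                  n_features = ncol(frame$matrix))

  cls_grid <- config$classifier_grid
  if (is.null(cls_grid)) cls_grid <- default_param_grid("anova_f", "svc_rbf")

  for (task in config$tasks) {
    if (task %in% c("class", "class_loo")) {
      lf <- label_frame(frame, library$structures, "class",
                        threshold = config$class_threshold)
      plan <- if (task == "class")
        cv_plan("random_group_splits", n_splits = config$n_splits,
                test_frac = config$test_frac, seed = config$seed)
      else cv_plan("loo_by_group")
      res <- run_nested_cv(lf, pipeline_spec("anova_f", "svc_rbf",
                                             grid = cls_grid),
                           plan, seed = config$seed)
      rep <- loo_report(res)
      reports[[task]] <- rep
      summary[[task]] <- list(accuracy = rep$aggregate$accuracy,
                              kappa = rep$aggregate$kappa,
                              mean_protein_accuracy = rep$mean_protein_accuracy)
    } else if (task == "fractions") {
      lf <- label_frame(frame, library$structures, "fractions")
      res <- run_chain_loo(lf, k_grid = config$k_grid, seed = config$seed)
      rep <- loo_report(res)
      reports[[task]] <- rep
      summary[[task]] <- stats::setNames(as.list(rep$aggregate$rmse),
                                         paste0("rmse_", rep$aggregate$target))
    } else if (task == "helix_length") {
      lf <- label_frame(frame, library$structures, "helix_length")
      res <- run_nested_cv(lf, pipeline_spec("anova_f", "adaboost"),
                           cv_plan("random_group_splits",
                                   n_splits = config$n_splits,
                                   test_frac = config$test_frac,
                                   seed = config$seed),
                           seed = config$seed)
      rep <- loo_report(res)
      reports[[task]] <- rep
      summary[[task]] <- list(accuracy = rep$aggregate$accuracy,
                              kappa = rep$aggregate$kappa)
    } else if (task == "sheet_registry") {
      lf <- label_frame(frame, library$structures, "sheet_registry")
      fits <- fit_sheet_registry_models(
        lf$matrix, lf$row_meta$parallel_pct, lf$row_meta$antiparallel_pct,
        lf$group_of, override_with_antiparallel = TRUE, seed = config$seed)
      summary[[task]] <- list(
        train_rmse_parallel = rmse(predict(fits$parallel, lf$matrix),
                                   lf$row_meta$parallel_pct),
        train_rmse_antiparallel = rmse(predict(fits$antiparallel, lf$matrix),
                                       lf$row_meta$antiparallel_pct))
      reports[[task]] <- fits
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_label_table(library$structures,
                      file.path(config$out_dir, "labels.csv"),
                      threshold = config$class_threshold)
  }
  list(library = library, frame = frame, reports = reports, summary = summary)
}

#' Build a named fixture library
#'
#' `"tiny"` is a fast six-protein library under a reduced plan (36 spectra);
#' `"full_scale"` reproduces the full accounting of the emulated
#' experimental library: 35 proteins, 3 cycles x 11 waiting times x
#' 2 detectors in triplicate with one duplicate-measured protein in the
#' alpha-enriched class and one single-measured protein in the beta-enriched
#' class, for 6732 spectra in total.
#'
#' @param name `"tiny"` or `"full_scale"`.
#' @param seed integer seed.
#' @param dir optional directory; when given the library is also written
#'   there via [write_library()].
#' @return A `spectral_library`.
#' @export
make_fixture <- function(name = c("tiny", "full_scale"), seed = 7L,
                         dir = NULL) {
  name <- match.arg(name)
  if (name == "tiny") {
    specs <- sample_structures(6, seed = seed)
    plan <- acquisition_plan(n_cycles = 1L, waiting_times = c(250, 275, 300),
                             n_detectors = 1L, n_replicates_default = 2L)
  } else {
    specs <- sample_structures(35, seed = seed)
    classes <- vapply(specs, function(s)
      assign_class(s$frac_alpha, s$frac_beta), "")
    dup <- specs[[which(classes == "alpha_enriched")[1]]]$protein_id
    single <- specs[[which(classes == "beta_enriched")[1]]]$protein_id
    overrides <- stats::setNames(c(2L, 1L), c(dup, single))
    plan <- acquisition_plan(replicate_overrides = overrides)
  }
  library <- build_library(specs, plan, seed = seed)
  if (!is.null(dir)) write_library(library, dir)
  library
}
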