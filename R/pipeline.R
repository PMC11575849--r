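#' Pipeline configuration
#'
#' Single configuration object for the end-to-end pipeline
#' (simulate -> summarize -> stats -> psd -> cnn), mirroring the per-stage
#' configs with explicit seeds and stage toggles. Can also be read from a
#' YAML or JSON file with the same field names.
#'
#' @param cohort a [cohort_config()] or a list of overrides for it.
#' @param signal a [signal_config()] or a list of overrides for it.
#' @param folds_seed seed for the fold assignment.
#' @param train_seed seed for CNN training.
#' @param epochs CNN training epochs per fold.
#' @param cnn a [cnn_spec()] or list of overrides for it.
#' @param psd_window,psd_k Welch window (samples) and peaks per treatment.
#' @param glm_formula model formula for the morphometric GLM stage; the
#'   default is the study's full covariate set, which requires enough fish
#'   for a full-rank design (reduce it for very small cohorts).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "summarize", "stats", "psd", "cnn")`. Later stages
#'   require the earlier ones.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            signal = signal_config(),
                            folds_seed = 1L, train_seed = 1L,
                            epochs = 10L,
                            cnn = cnn_spec(),
                            psd_window = 256L, psd_k = 5L,
                            glm_formula = F3D_N ~ Sex + WW_g + TL_cm +
                              HW_cm + BD_cm + factor(FinSpreadClass) +
                              Arch_deg,
                            stages = c("simulate", "summarize", "stats",
                                       "psd", "cnn")) {
  if (is.list(cohort) && !inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, cohort)
  if (is.list(signal) && !inherits(signal, "signal_config"))
    signal <- do.call(signal_config, signal)
  if (is.list(cnn) && !inherits(cnn, "cnn_spec"))
    cnn <- do.call(cnn_spec, cnn)
  known <- c("simulate", "summarize", "stats", "psd", "cnn")
  if (!all(stages %in% known))
    stop_domain("unknown stages: ",
                paste(setdiff(stages, known), collapse = ", "))
  structure(list(cohort = cohort, signal = signal,
                 folds_seed = as.integer(folds_seed),
                 train_seed = as.integer(train_seed),
                 epochs = as.integer(epochs), cnn = cnn,
                 psd_window = as.integer(psd_window),
                 psd_k = as.integer(psd_k), glm_formula = glm_formula,
                 stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("cohort", "signal", "cnn"))
    if (!is.null(raw[[nm]])) args[[nm]] <- as.list(raw[[nm]])
  for (nm in c("folds_seed", "train_seed", "epochs", "psd_window", "psd_k",
               "stages"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$glm_formula))
    args$glm_formula <- stats::as.formula(raw$glm_formula)
  do.call(pipeline_config, args)
}

config_fingerprint <- function(config) {
  plain <- lapply(unclass(config), function(x) {
    if (inherits(x, "formula")) paste(deparse(x), collapse = " ")
    else unclass(x)
  })
  fnv1a32(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages selected in the config: synthetic experiment
#' generation, per-run force summaries, treatment statistics, per-treatment
#' PSD peak tables, and CNN cross-validation. Every artifact written is
#' stamped with the config fingerprint and seeds; progress is logged at
#' stage boundaries via `message()`. A stage failure halts the pipeline
#' with the failing stage named; artifacts from completed stages remain on
#' disk.
#'
#' @param config a [pipeline_config()], or a path to a YAML/JSON config.
#' @param out_dir output directory for artifacts.
#' @return Invisibly, a list with the in-memory results of each stage run.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = config_fingerprint(config),
                seeds = list(cohort = config$cohort$seed,
                             signal = config$signal$seed,
                             folds = config$folds_seed,
                             train = config$train_seed))
  res <- list(stamp = stamp)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    message(sprintf("[%s] stage started", name))
    out <- tryCatch(expr, error = function(e)
      stop_domain("stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("[%s] stage finished", name))
    out
  }

  res$bundle <- stage("simulate",
                      generate_experiment(config$cohort, config$signal))

  res$summaries <- stage("summarize", {
    s <- summarize_experiment(res$bundle, config$signal$lever_r)
    data.table::fwrite(s, file.path(out_dir, "run_summary.csv"))
    s
  })

  res$stats <- stage("stats", {
    joined <- merge(res$summaries[res$summaries$object_class == "preserved", ],
                    res$bundle$cohort, by.x = "fish_id", by.y = "ID")
    st <- treatment_stats(res$summaries)
    glm_fit <- fit_invgauss_glm(joined, config$glm_formula)
    out <- c(stamp, list(
      shapiro = st$shapiro,
      kruskal = st$kruskal,
      pairwise = st$pairwise,
      glm = list(coefficients = as.data.frame(glm_fit$coefficients),
                 null_deviance = glm_fit$null_deviance,
                 residual_deviance = glm_fit$residual_deviance,
                 n_obs = glm_fit$n_obs)))
    jsonlite::write_json(out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE, pretty = TRUE)
    list(stats = st, glm = glm_fit)
  })

  res$psd <- stage("psd", {
    ps <- psd_by_treatment(res$bundle, config$psd_window, k = config$psd_k,
                           r = config$signal$lever_r)
    curves <- do.call(rbind, lapply(names(ps$curves), function(tr)
      data.frame(treatment = tr, freq_Hz = ps$curves[[tr]]$freq,
                 power = ps$curves[[tr]]$power)))
    data.table::fwrite(curves, file.path(out_dir, "psd_curves.csv"))
    jsonlite::write_json(c(stamp, list(peaks = ps$peaks)),
                         file.path(out_dir, "psd_peaks.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    ps
  })

  res$cnn <- stage("cnn", {
    ds <- build_dataset(res$bundle, seed = config$folds_seed,
                        r = config$signal$lever_r)
    data.table::fwrite(ds$meta, file.path(out_dir, "dataset_manifest.csv"))
    cv <- cross_validate(ds, config$cnn, epochs = config$epochs,
                         seed = config$train_seed)
    out <- c(stamp, list(
      mean_F1 = as.list(stats::setNames(cv$mean_F1,
                                        names(sort(TREATMENT_LABELS)))),
      sd_F1 = as.list(stats::setNames(cv$sd_F1,
                                      names(sort(TREATMENT_LABELS)))),
      confusion = lapply(cv$metrics, function(mm)
        unclass(as.data.frame(mm$confusion))),
      Ac = lapply(cv$metrics, function(mm) as.list(mm$Ac))))
    jsonlite::write_json(out, file.path(out_dir, "cnn_metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    cv
  })

  summary_lines <- c(
    sprintf("benthoforce pipeline (config %s)", stamp$config_hash),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    if (!is.null(res$summaries))
      sprintf("runs summarised: %d", nrow(res$summaries)),
    if (!is.null(res$stats))
      sprintf("Kruskal-Wallis p = %.4g, effect size = %.3f",
              res$stats$stats$kruskal$p,
              res$stats$stats$kruskal$effect_size),
    if (!is.null(res$cnn))
      sprintf("CNN mean F1: %s",
              paste(sprintf("%s %.2f", names(sort(TREATMENT_LABELS)),
                            res$cnn$mean_F1), collapse = ", ")))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(res)
}
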