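#' Run configuration
#'
#' Gathers everything one end-to-end run needs: either an input CSV path or
#' a [generator_spec()] (exactly one), the predictor set, the model and CV
#' settings, the labelling criteria, the analysis grids and the output
#' directory. Can be loaded from a YAML file with [read_run_config()].
#'
#' @param input path to a cohort CSV, or NULL when simulating.
#' @param generator a [generator_spec()], or NULL when reading a file.
#' @param features predictor columns.
#' @param model a [model_spec()].
#' @param cv a [cv_config()].
#' @param criteria labelling criteria set.
#' @param cut_grid cut-point scan grid.
#' @param pt_grid decision-curve threshold grid.
#' @param power a [power_spec()] or NULL to derive the effect size from the
#'   generated cohort's fasting-glucose moments.
#' @param out_dir output directory.
#' @param seed global seed (overrides the seeds inside `generator` and `cv`).
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = generator_spec(),
                       features = c("a_fg", "a_hba1c"),
                       model = model_spec("sparse_logistic"),
                       cv = cv_config(), criteria = "NICE",
                       cut_grid = seq(0, 0.999, by = 0.001),
                       pt_grid = seq(0.01, 0.99, by = 0.01),
                       power = NULL, out_dir = "results", seed = 1L) {
  if (is.null(input) == is.null(generator)) {
    stop("exactly one of input path / generator spec must be given")
  }
  if (!is.null(generator)) generator$seed <- as.integer(seed)
  cv$seed <- as.integer(seed) + 1L
  structure(list(input = input, generator = generator, features = features,
                 model = model, cv = cv, criteria = criteria,
                 cut_grid = cut_grid, pt_grid = pt_grid, power = power,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised top-level keys: `input`, `generator` (n, prevalence,
#' outcome_model, b0, b, rho, missing_rate), `features`, `model` (family,
#' class_weighting), `cv` (outer, outer_k, inner_folds, inner_metric,
#' mice_iterations), `criteria`, `out_dir`, `seed`. Missing keys fall back
#' to the package defaults.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  # YAML 1.1 would read the bare generator key `n` (and `y`) as a boolean;
  # restrict boolean scalars to the spellings true/false
  keep_word <- function(x) {
    if (tolower(x) %in% c("true", "false")) tolower(x) == "true" else x
  }
  y <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_word,
                                             "bool#no" = keep_word))
  gen <- NULL
  if (is.null(y$input)) {
    ga <- y$generator
    gen <- generator_spec(
      n = ga$n %||% 394, prevalence = ga$prevalence %||% 0.2335,
      outcome_model = ga$outcome_model %||% "latent_logistic",
      b0 = ga$b0 %||% -8.36,
      b = if (!is.null(ga$b)) unlist(ga$b) else c(a_fg = 0.58, a_hba1c = 0.10),
      rho = ga$rho %||% 0.3, missing_rate = ga$missing_rate %||% 0)
  }
  mv <- y$model
  model <- model_spec(mv$family %||% "sparse_logistic",
                      class_weighting = mv$class_weighting %||% TRUE)
  cva <- y$cv
  cv <- cv_config(outer = cva$outer %||% "leave_one_out",
                  outer_k = cva$outer_k %||% 4L,
                  inner_folds = cva$inner_folds %||% 4L,
                  inner_metric = cva$inner_metric %||% "accuracy",
                  mice_iterations = cva$mice_iterations %||% 10L)
  run_config(input = y$input, generator = gen,
             features = unlist(y$features) %||% c("a_fg", "a_hba1c"),
             model = model, cv = cv, criteria = y$criteria %||% "NICE",
             out_dir = y$out_dir %||% "results", seed = y$seed %||% 1L)
}

#' Execute the full analysis pipeline
#'
#' simulate/ingest, label, nested-CV evaluation, final deployment model,
#' cut-point scan, decision curve analysis and power analysis — writing the
#' report bundle under `config$out_dir`: `cohort.csv`, `predictions.csv`,
#' `roc.csv`, `metrics.json`, `threshold_table.csv`, `cutpoints.json`,
#' `model.json`, `dca.csv`, `power.json`, and `run_log.json` with every seed
#' and per-fold chosen hyperparameter. Re-running with the same
#' configuration is bit-identical. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (cohort, preds, roc,
#'   scan, model, dca, power, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("ingest", {
    if (!is.null(config$generator)) {
      generate_cohort(config$generator)
    } else {
      read_cohort(config$input)
    }
  })
  cohort <- stage("label", {
    if (!all(c("p_fg", "p_pg", "p_hba1c") %in% names(cohort))) {
      stop("no postpartum columns (p_fg, p_pg, p_hba1c) to label the outcome from")
    }
    label_cohort(cohort, config$criteria)
  })
  write_cohort(cohort, p("cohort.csv"))

  preds <- stage("nested_cv", {
    nested_cv_evaluate(cohort, config$model, config$cv, config$features)
  })
  utils::write.csv(as.data.frame(preds), p("predictions.csv"), row.names = FALSE)

  roc <- stage("roc", roc_auc(preds))
  utils::write.csv(roc$points, p("roc.csv"), row.names = FALSE)
  stab <- feature_stability(preds)
  jsonlite::write_json(list(auc = roc$auc, brier = brier(preds),
                            n = nrow(preds),
                            prevalence = mean(preds$label),
                            feature_stability = stab),
                       p("metrics.json"), auto_unbox = TRUE, digits = NA)

  final <- stage("final_model", {
    fit_final_model(cohort, config$model, config$cv, config$features)
  })
  write_risk_model(final, p("model.json"))

  scan <- stage("cutpoints", scan_cutpoints(preds, config$cut_grid))
  utils::write.csv(scan$rows, p("threshold_table.csv"), row.names = FALSE)
  jsonlite::write_json(scan$selection, p("cutpoints.json"),
                       auto_unbox = TRUE, digits = NA)

  dca <- stage("dca", net_benefit(preds, config$pt_grid))
  utils::write.csv(dca, p("dca.csv"), row.names = FALSE)

  pw <- stage("power", {
    spec <- config$power
    if (is.null(spec)) {
      y <- outcome_binary(cohort)
      pos <- cohort$a_fg[y == 1 & !is.na(y)]
      neg <- cohort$a_fg[y == 0 & !is.na(y)]
      d <- abs(cohens_d(mean(pos, na.rm = TRUE), stats::sd(pos, na.rm = TRUE),
                        sum(!is.na(pos)),
                        mean(neg, na.rm = TRUE), stats::sd(neg, na.rm = TRUE),
                        sum(!is.na(neg))))
      spec <- power_spec(d = d, ratio = sum(y == 1, na.rm = TRUE) /
                           sum(y == 0, na.rm = TRUE))
    }
    c(solve_sample_size(spec), spec[c("d", "alpha", "power", "ratio")])
  })
  jsonlite::write_json(pw, p("power.json"), auto_unbox = TRUE, digits = NA)

  log <- list(seed = config$seed, criteria = config$criteria,
              features = config$features,
              model = list(family = config$model$family,
                           class_weighting = config$model$class_weighting),
              cv = unclass(config$cv),
              generator = if (!is.null(config$generator))
                unclass(config$generator)[c("n", "prevalence", "outcome_model",
                                            "b0", "b", "rho", "missing_rate",
                                            "seed")] else NULL,
              fold_hyper = lapply(attr(preds, "fold_hyper"), as.list))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, preds = preds, roc = roc, scan = scan,
                 model = final, dca = dca, power = pw,
                 paths = vapply(c("cohort.csv", "predictions.csv", "roc.csv",
                                  "metrics.json", "threshold_table.csv",
                                  "cutpoints.json", "model.json", "dca.csv",
                                  "power.json", "run_log.json"), p, "")))
}
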